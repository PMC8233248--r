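#' Population-proportion reweighting of group coefficients
#'
#' When under-represented groups (e.g. education bands or income halves)
#' show different relative valuations, group-specific coefficient vectors
#' are combined as a population-proportion-weighted average, entrywise.
#' The identification constraints (reference item at zero, joint pair
#' equal) are preserved by linearity and checked on the result.
#'
#' @param group_betas list of full beta vectors (one per group, identical
#'   constraint structure, length `n_items(instrument)`).
#' @param proportions numeric vector of population proportions, same length
#'   and order as `group_betas`; must sum to 1 (tolerance 1e-9).
#' @param instrument a `bws_instrument`.
#' @return combined beta vector.
#' @export
reweight_by_population <- function(group_betas, proportions,
                                   instrument = ascot_carer_instrument()) {
  if (length(group_betas) != length(proportions)) {
    stop("one proportion per group required")
  }
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("population proportions must sum to 1 (got ", sum(proportions), ")")
  }
  ni <- n_items(instrument)
  ref <- item_index(instrument, instrument$reference$domain,
                    instrument$reference$level)
  for (b in group_betas) {
    if (length(b) != ni) stop("every group must supply a full beta vector of length ", ni)
    if (abs(b[ref]) > 1e-9) stop("group beta violates the reference-item constraint")
    if (!is.null(instrument$joint)) {
      j <- item_index(instrument, instrument$joint$domain, instrument$joint$levels)
      if (abs(b[j[1]] - b[j[2]]) > 1e-9) {
        stop("group beta violates the joint-coefficient constraint")
      }
    }
  }
  out <- Reduce(`+`, Map(`*`, group_betas, proportions))
  lv <- enumerate_levels(instrument)
  names(out) <- paste(lv$domain, lv$level, sep = "_")
  out
}

#' Rescale utilities to 0-1 preference weights
#'
#' Maps fitted utilities to the deliverable preference-weight table: within
#' each domain the worst level is shifted to 0, and all domains share one
#' denominator (the sum of within-domain utility ranges) so that the total
#' score over all domains spans exactly 0 (all domains at their worst
#' level) to 1 (all at their best).
#'
#' w\[d\]\[l\] = (beta\[d\]\[l\] - min_l beta\[d\]\[l\]) / sum_d (max_l - min_l)
#'
#' @param beta full utility vector (length `n_items(instrument)`).
#' @param instrument a `bws_instrument`.
#' @param provenance optional list stored with the weights (source fit,
#'   reweighting applied, ...).
#' @return object of class `bws_weights`: data.frame with columns `domain`,
#'   `level`, `statement`, `weight`, plus attributes `denominator` and
#'   `provenance`.
#' @export
rescale_weights <- function(beta, instrument = ascot_carer_instrument(),
                            provenance = NULL) {
  ni <- n_items(instrument)
  if (length(beta) != ni) stop("beta must have length ", ni)
  lv <- enumerate_levels(instrument)
  dmin <- tapply(beta, lv$domain, min)[unique(lv$domain)]
  dmax <- tapply(beta, lv$domain, max)[unique(lv$domain)]
  C <- sum(dmax - dmin)
  if (C <= 0) stop("degenerate scale: all utilities are constant within every domain")
  w <- (beta - dmin[lv$domain]) / C
  out <- data.frame(domain = lv$domain, level = lv$level,
                    statement = lv$statement, weight = as.numeric(w),
                    stringsAsFactors = FALSE)
  structure(out, class = c("bws_weights", "data.frame"),
            denominator = C, provenance = provenance)
}

#' Score a carer quality-of-life state
#'
#' Total preference-weighted score of a complete response profile: the sum
#' over domains of the weight of the level reported in each domain. By the
#' rescaling construction the score lies in \[0, 1\], with 1 for the
#' all-best and 0 for the all-worst state.
#'
#' @param state named level vector (see [validate_state()]).
#' @param weights a `bws_weights` table.
#' @param instrument a `bws_instrument`; must match the weights.
#' @return scalar score in \[0, 1\].
#' @export
score_state <- function(state, weights, instrument = ascot_carer_instrument()) {
  stopifnot(inherits(weights, "bws_weights"))
  codes <- unique(weights$domain)
  if (!setequal(codes, names(instrument$domains))) {
    stop("weights and instrument disagree on the domain set")
  }
  st <- validate_state(state, instrument)
  key <- paste(weights$domain, weights$level, sep = "_")
  idx <- match(paste(names(st), st, sep = "_"), key)
  sum(weights$weight[idx])
}

#' Rank attribute-levels by valuation
#'
#' Orders all items of the instrument by descending weight (or utility).
#' Ties are broken by instrument order and flagged in the `tied` column.
#'
#' @param x a `bws_weights` table or a full beta vector.
#' @param instrument a `bws_instrument` (used when `x` is a beta vector).
#' @return data.frame sorted by descending value with columns `rank`,
#'   `domain`, `level`, `value`, `tied`.
#' @export
rank_items <- function(x, instrument = ascot_carer_instrument()) {
  if (inherits(x, "bws_weights")) {
    df <- data.frame(domain = x$domain, level = x$level, value = x$weight,
                     stringsAsFactors = FALSE)
  } else {
    lv <- enumerate_levels(instrument)
    if (length(x) != nrow(lv)) stop("beta must have length ", nrow(lv))
    df <- data.frame(domain = lv$domain, level = lv$level,
                     value = as.numeric(x), stringsAsFactors = FALSE)
  }
  ord <- order(-df$value, seq_len(nrow(df)))
  df <- df[ord, ]
  df$rank <- seq_len(nrow(df))
  df$tied <- duplicated(df$value) | duplicated(df$value, fromLast = TRUE)
  rownames(df) <- NULL
  df[, c("rank", "domain", "level", "value", "tied")]
}

#' Read / write a preference-weight table
#'
#' CSV with columns `domain`, `level`, `statement`, `weight` (weights
#' printed with 6 decimal places); an optional JSON sidecar stores
#' provenance and the rescaling denominator.
#'
#' @param weights a `bws_weights`.
#' @param path CSV path.
#' @param json_path optional provenance JSON path.
#' @return `read_weights()` returns a `bws_weights`; `write_weights()`
#'   returns `path` invisibly.
#' @export
write_weights <- function(weights, path, json_path = NULL) {
  stopifnot(inherits(weights, "bws_weights"))
  df <- as.data.frame(weights)
  df$weight <- sprintf("%.6f", df$weight)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(denominator = attr(weights, "denominator"),
           provenance = attr(weights, "provenance")),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("domain", "level", "statement", "weight")
  if (!all(need %in% names(df))) {
    stop("weights file must have columns ", paste(need, collapse = ", "))
  }
  structure(df[need], class = c("bws_weights", "data.frame"),
            denominator = NA_real_, provenance = NULL)
}
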