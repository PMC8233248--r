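#' S-MNL parameter vector
#'
#' Bundles the three parameter groups of the scale-adjusted multinomial logit
#' for a profile-case best-worst experiment:
#'
#' * `beta` — one utility coefficient per attribute-level (28 for the
#'   ASCOT-Carer), on a common latent scale with the reference item (`STS`
#'   level 4) pinned to 0 and the joint pair (`ENC` levels 1 and 2) sharing
#'   one coefficient;
#' * `delta` — positioning effects for best-type picks at display positions
#'   1-7, with position 1 (top of the list) as reference (`delta[1] = 0`);
#'   worst-type picks carry no positioning effect;
#' * `lambda` — multiplicative scale parameters for respondent groups
#'   (`not_understood`, `age35`, `slow`), inversely related to error
#'   variance, each relative to a reference group fixed at 1.
#'
#' The free parameterisation used by the optimiser has 26 beta + 6 delta +
#' 3 log-lambda = 35 entries.
#'
#' @param beta numeric vector of length `n_items(instrument)` in item order
#'   (see [enumerate_levels()]); must satisfy the reference and joint
#'   constraints.
#' @param delta numeric vector of length 7, `delta[1] == 0`.
#' @param lambda named numeric vector `c(not_understood=, age35=, slow=)`,
#'   all positive.
#' @param instrument a `bws_instrument`.
#' @return object of class `bws_parameters`.
#' @export
smnl_parameters <- function(beta, delta = rep(0, 7),
                            lambda = c(not_understood = 1, age35 = 1, slow = 1),
                            instrument = ascot_carer_instrument()) {
  ni <- n_items(instrument)
  if (length(beta) != ni) stop("beta must have length ", ni)
  if (length(delta) != 7L) stop("delta must have length 7")
  if (delta[1] != 0) stop("delta[1] is the reference position and must be 0")
  lambda <- lambda[c("not_understood", "age35", "slow")]
  if (anyNA(lambda)) stop("lambda must name not_understood, age35, slow")
  if (any(lambda <= 0)) stop("scale multipliers must be positive")
  ref <- item_index(instrument, instrument$reference$domain, instrument$reference$level)
  if (abs(beta[ref]) > 1e-12) {
    stop("reference item ", instrument$reference$domain, " level ",
         instrument$reference$level, " must have beta = 0")
  }
  if (!is.null(instrument$joint)) {
    j <- item_index(instrument, instrument$joint$domain, instrument$joint$levels)
    if (abs(beta[j[1]] - beta[j[2]]) > 1e-12) {
      stop("joint pair ", instrument$joint$domain, " levels ",
           paste(instrument$joint$levels, collapse = "/"),
           " must share one coefficient")
    }
  }
  lv <- enumerate_levels(instrument)
  names(beta) <- paste(lv$domain, lv$level, sep = "_")
  names(delta) <- paste0("pos", 1:7)
  structure(list(beta = beta, delta = delta, lambda = lambda,
                 instrument = instrument),
            class = "bws_parameters")
}

#' Published Austrian S-MNL estimates for the ASCOT-Carer
#'
#' The published Austrian valuation estimates: attribute-level utilities
#' relative to "Space and time to be yourself" at level 4, positioning
#' effects for best-type picks relative to the top list position, and scale
#' multipliers for the three respondent groups with elevated/reduced error
#' variance (reference groups at 1). These are the default generating values
#' for the synthetic-data module and the recovery benchmarks.
#'
#' @return a `bws_parameters` object.
#' @export
austria_parameters <- function() {
  beta <- c(
    3.53, 3.38, 1.34, 0.36,   # Occupation
    3.33, 3.08, 1.64, 0.37,   # Control over daily life
    2.82, 2.75, 0.99, 0.43,   # Looking after yourself
    2.56, 1.78, 1.10, 0.71,   # Personal safety
    2.94, 2.58, 1.34, 0.45,   # Social participation and involvement
    3.50, 3.39, 1.69, 0.00,   # Space and time to be yourself (L4 = reference)
    2.71, 2.71, 1.20, 0.41    # Feeling supported and encouraged (L1 = L2 joint)
  )
  delta <- c(0, -0.10, -0.18, -0.27, -0.32, -0.36, -0.40)
  smnl_parameters(beta, delta,
                  lambda = c(not_understood = 0.70, age35 = 0.80, slow = 1.66))
}

# ---- free-vector embedding -------------------------------------------------
# Free vector layout (length 35 for the default instrument):
#   [1..26]  beta free coefficients (items minus reference, minus aliased
#            second joint level which shares the first's slot)
#   [27..32] delta positions 2..7
#   [33..35] log lambda (not_understood, age35, slow)

free_map <- function(instrument) {
  ni <- n_items(instrument)
  ref <- item_index(instrument, instrument$reference$domain, instrument$reference$level)
  map <- integer(ni)
  lv <- enumerate_levels(instrument)
  nm <- character(0)
  k <- 0L
  alias_from <- alias_to <- NA_integer_
  if (!is.null(instrument$joint)) {
    j <- item_index(instrument, instrument$joint$domain, instrument$joint$levels)
    alias_from <- j[2]; alias_to <- j[1]
  }
  for (i in seq_len(ni)) {
    if (i == ref) { map[i] <- 0L; next }
    if (!is.na(alias_from) && i == alias_from) { map[i] <- map[alias_to]; next }
    k <- k + 1L
    map[i] <- k
    nm <- c(nm, paste0("beta_", lv$domain[i], "_", lv$level[i]))
  }
  list(beta_map = map, n_beta = k,
       names = c(nm, paste0("delta_pos", 2:7),
                 paste0("loglambda_", c("not_understood", "age35", "slow"))))
}

free_to_params <- function(free, instrument = ascot_carer_instrument()) {
  fm <- free_map(instrument)
  nf <- fm$n_beta + 6L + 3L
  if (length(free) != nf) stop("free vector must have length ", nf)
  if (any(!is.finite(free))) stop("non-finite entries in free parameter vector")
  beta <- c(0, free[seq_len(fm$n_beta)])[fm$beta_map + 1L]
  delta <- c(0, free[fm$n_beta + 1:6])
  lam <- exp(free[fm$n_beta + 6L + 1:3])
  names(lam) <- c("not_understood", "age35", "slow")
  smnl_parameters(beta, delta, lam, instrument)
}

params_to_free <- function(params) {
  instrument <- params$instrument
  fm <- free_map(instrument)
  free <- numeric(fm$n_beta + 9L)
  sel <- fm$beta_map > 0L
  free[fm$beta_map[sel]] <- params$beta[sel]
  free[fm$n_beta + 1:6] <- params$delta[2:7]
  free[fm$n_beta + 6L + 1:3] <- log(params$lambda)
  names(free) <- fm$names
  free
}

#' Read / write a parameter vector (JSON)
#'
#' @param params a `bws_parameters`.
#' @param path file path.
#' @return `read_params()` returns a `bws_parameters` (with the default
#'   ASCOT-Carer instrument unless one is embedded); `write_params()` returns
#'   `path` invisibly.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "bws_parameters"))
  obj <- list(beta = as.list(params$beta), delta = as.list(params$delta),
              lambda = as.list(params$lambda))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @param instrument instrument the parameters refer to.
#' @export
read_params <- function(path, instrument = ascot_carer_instrument()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  smnl_parameters(unlist(obj$beta), unlist(obj$delta), unlist(obj$lambda),
                  instrument)
}

#' @export
print.bws_parameters <- function(x, ...) {
  cat("S-MNL parameters:", length(x$beta), "item utilities,",
      "7 positioning effects, 3 scale multipliers\n")
  cat("lambda:", paste(sprintf("%s=%.3g", names(x$lambda), x$lambda),
                       collapse = ", "), "\n")
  invisible(x)
}
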