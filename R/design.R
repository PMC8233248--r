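#' Construct the 32-scenario orthogonal main-effects plan
#'
#' Builds an orthogonal array OA(32, 8, 4, 2): 32 runs, 8 four-level factors,
#' strength 2. Seven factors carry the instrument domains; the eighth is the
#' blocking factor that partitions the 32 scenarios into 4 blocks of 8 tasks.
#'
#' Construction: the 32 runs are the vectors of GF(2)^5; the 31 non-zero
#' linear forms over them are the columns of a Hadamard-derived two-level
#' array. A seeded randomised search selects 8 disjoint XOR-closed triples
#' \{a, b, a XOR b\} of forms (lines of the projective space PG(4,2)); each
#' triple's leading pair (a, b) is collapsed to one 4-level factor via
#' 2*<a,r> + <b,r>. Disjoint lines make the four defining bits of any two
#' factors linearly independent, which forces the strength-2 property; the
#' result is verified with [verify_design()] before it is returned. A vetted
#' copy of the array ships as a plain-text fixture and can be loaded with
#' [design_fixture()] so the pipeline never depends on the search.
#'
#' @param seed integer seed for the (deterministic) randomised search.
#' @param max_restarts number of greedy restarts before giving up.
#' @return A `bws_design`: 32 x 8 integer matrix with entries 0-3, columns
#'   named by the 7 domain codes plus `block`, with attributes `seed` and
#'   `method`.
#' @examples
#' plan <- build_design(seed = 1)
#' verify_design(plan)$pass
#' @export
build_design <- function(seed = 1L, max_restarts = 200L) {
  runs <- 0:31
  bit <- function(x, k) bitwAnd(bitwShiftR(x, k), 1L)
  # all 155 XOR-closed triples {a, b, a^b} of the 31 non-zero forms
  lines <- list()
  for (a in 1:30) for (b in (a + 1):31) {
    c3 <- bitwXor(a, b)
    if (c3 > b) lines[[length(lines) + 1L]] <- c(a, b, c3)
  }
  chosen <- with_seed(seed, {
    found <- NULL
    for (r in seq_len(max_restarts)) {
      ord <- sample.int(length(lines))
      used <- logical(31)
      sel <- list()
      for (li in ord) {
        tri <- lines[[li]]
        if (!any(used[tri])) {
          used[tri] <- TRUE
          sel[[length(sel) + 1L]] <- tri
          if (length(sel) == 8L) break
        }
      }
      if (length(sel) == 8L) { found <- sel; break }
    }
    found
  })
  if (is.null(chosen)) {
    stop("no disjoint-triple partition found after ", max_restarts,
         " restarts; load the shipped array with design_fixture()")
  }
  inner <- function(form, r) {
    v <- 0L
    for (k in 0:4) if (bit(form, k)) v <- bitwXor(v, bit(r, k))
    v
  }
  mat <- vapply(chosen, function(tri) {
    vapply(runs, function(r) 2L * inner(tri[1], r) + inner(tri[2], r), integer(1))
  }, integer(32))
  plan <- new_design(mat, seed = seed, method = "pg42-line-collapse")
  rep <- verify_design(plan)
  if (!rep$pass) stop("internal error: constructed array failed verification")
  plan
}

new_design <- function(mat, seed = NA_integer_, method = "unspecified",
                       domain_codes = c("OCC", "CTL", "SELF", "SAFE", "SOC", "STS", "ENC")) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "integer"
  if (ncol(mat) == length(domain_codes) + 1L) {
    colnames(mat) <- c(domain_codes, "block")
  }
  structure(mat, class = c("bws_design", "matrix", "array"),
            seed = seed, method = method)
}

#' Verify balance and strength-2 orthogonality of a design
#'
#' Checks, by exhaustive counting, that every column of the plan is balanced
#' (each symbol appears N/4 times) and that every pair of columns is
#' strength-2 orthogonal (each of the 16 ordered symbol pairs appears exactly
#' N/16 times). Nothing is sampled.
#'
#' @param plan integer matrix with entries in 0-3 (a `bws_design` or plain
#'   matrix).
#' @return list with `pass` (logical), `violations` (data.frame naming every
#'   offending column or column pair) and `pair_counts` (list of 4 x 4 count
#'   tables, one per column pair).
#' @export
verify_design <- function(plan) {
  mat <- unclass(plan)
  if (!is.matrix(mat)) stop("plan must be a matrix")
  if (!all(mat %in% 0:3)) stop("entries must be symbols 0-3")
  n <- nrow(mat); k <- ncol(mat)
  if (n %% 16L != 0L) stop("row count must be a multiple of 16 for strength 2 at 4 levels")
  cn <- colnames(mat) %||% paste0("C", seq_len(k))
  viol <- list()
  for (j in seq_len(k)) {
    cnt <- tabulate(mat[, j] + 1L, nbins = 4L)
    if (any(cnt != n / 4L)) {
      viol[[length(viol) + 1L]] <- data.frame(
        check = "balance", col_a = cn[j], col_b = NA_character_,
        detail = paste(cnt, collapse = "/"))
    }
  }
  pair_counts <- list()
  if (k >= 2L) {
    for (a in 1:(k - 1)) for (b in (a + 1):k) {
      tab <- table(factor(mat[, a], 0:3), factor(mat[, b], 0:3))
      pair_counts[[paste(cn[a], cn[b], sep = ":")]] <- tab
      if (any(tab != n / 16L)) {
        viol[[length(viol) + 1L]] <- data.frame(
          check = "strength2", col_a = cn[a], col_b = cn[b],
          detail = paste(range(tab), collapse = "-"))
      }
    }
  }
  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(check = character(), col_a = character(),
               col_b = character(), detail = character())
  list(pass = nrow(violations) == 0L, violations = violations,
       pair_counts = pair_counts)
}

#' Split the design into blocks of choice tasks
#'
#' Partitions the 32 scenarios by the blocking column's symbol into 4 blocks
#' of 8 choice tasks each. Each task shows one statement per domain; design
#' symbol s maps to outcome level s + 1. The blocking factor itself is not
#' rendered as an item.
#'
#' @param plan a `bws_design` passing [verify_design()].
#' @param instrument a `bws_instrument` (domain order must match the plan's
#'   domain columns).
#' @return data.frame of tasks with columns `scenario` (row of the plan),
#'   `block` (0-3), `task` (1-8 within block), and one column per domain code
#'   holding the level (1-4) shown.
#' @export
block_design <- function(plan, instrument = ascot_carer_instrument()) {
  mat <- unclass(plan)
  codes <- names(instrument$domains)
  if (!all(codes %in% colnames(mat))) {
    stop("plan lacks columns for domain(s): ",
         paste(setdiff(codes, colnames(mat)), collapse = ", "))
  }
  blk <- mat[, "block"]
  if (any(tabulate(blk + 1L, 4L) != nrow(mat) / 4L)) {
    stop("blocking column is not 4-way balanced")
  }
  ord <- order(blk, seq_len(nrow(mat)))
  levels <- mat[ord, codes, drop = FALSE] + 1L
  out <- data.frame(scenario = ord, block = blk[ord],
                    task = unlist(lapply(tabulate(blk + 1L, 4L), seq_len)))
  cbind(out, as.data.frame(levels))
}

#' Per-respondent display randomisation
#'
#' Draws one random permutation of the domains for a respondent; the same
#' permutation orders the statement list in all of that respondent's tasks,
#' so positioning effects can be separated from item utilities across
#' respondents. Deterministic for a fixed `respondent_seed`.
#'
#' @param respondent_seed integer seed identifying the respondent's draw.
#' @param n_domains number of domains (list length).
#' @return integer permutation `p` of `1:n_domains`; `p[pos]` is the domain
#'   shown at display position `pos` (1 = top of the list).
#' @export
randomize_display <- function(respondent_seed, n_domains = 7L) {
  with_seed(respondent_seed, sample.int(n_domains))
}

#' Read / write a design plan (CSV)
#'
#' One row per scenario; domain columns hold levels 1-4, the `block` column
#' 0-3. Header comment lines (prefixed `#`) record the seed and construction
#' method.
#'
#' @param plan a `bws_design`.
#' @param path file path.
#' @return `read_design()` returns a `bws_design`; `write_design()` returns
#'   `path` invisibly.
#' @export
write_design <- function(plan, path) {
  mat <- unclass(plan)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    paste0("# seed: ", attr(plan, "seed")),
    paste0("# method: ", attr(plan, "method")),
    "# symbol-to-level mapping: level = symbol + 1 (domain columns printed as levels 1-4)"
  ), con)
  df <- as.data.frame(mat)
  dom <- setdiff(colnames(mat), "block")
  df[dom] <- df[dom] + 1L
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  hdr <- readLines(path, n = 10L)
  seed <- NA_integer_
  m <- grep("^# seed:", hdr, value = TRUE)
  if (length(m)) seed <- suppressWarnings(as.integer(sub("^# seed: *", "", m[1])))
  df <- utils::read.csv(path, comment.char = "#")
  if (!"block" %in% names(df)) stop("design file lacks a 'block' column")
  dom <- setdiff(names(df), "block")
  mat <- as.matrix(df)
  mat[, dom] <- mat[, dom] - 1L
  new_design(mat, seed = seed, method = "file", domain_codes = dom)
}

#' Load the vetted OA(32, 8, 4, 2) shipped with the package
#'
#' @return a `bws_design` read from the packaged fixture.
#' @export
design_fixture <- function() {
  read_design(system.file("extdata", "oa_32_8_4_2.csv", package = "carerbws",
                          mustWork = TRUE))
}
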