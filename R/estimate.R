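#' @keywords internal
stage_names <- function() c("best", "worst", "second_best", "second_worst")

# best and second_best weight +utility and carry positioning effects;
# worst-type stages weight -utility and carry none
stage_sign <- function(stage) {
  s <- match(stage, stage_names())
  if (anyNA(s)) stop("unknown stage type: ", paste(unique(stage[is.na(s)]), collapse = ", "))
  ifelse(s %% 2L == 1L, 1, -1)
}

#' Stage-level choice probabilities
#'
#' The multinomial-logit probability of each available item being picked at
#' one stage of a profile-case best-worst task. Best-type stages (`best`,
#' `second_best`) use utility plus the positioning effect of the item's
#' display position; worst-type stages (`worst`, `second_worst`) use negated
#' utility and no positioning effect. Utilities are scaled by the
#' respondent's scale multiplier `lambda`. Computed with max-subtraction so
#' there is no overflow for |lambda * utility| up to about 700.
#'
#' @param utility numeric utilities of the available items.
#' @param stage one of `"best"`, `"worst"`, `"second_best"`, `"second_worst"`.
#' @param positions display positions of the available items (1 = top);
#'   positions keep their original values after items are removed.
#' @param delta positioning effects indexed by display position; `NULL`
#'   means none.
#' @param lambda positive scale multiplier.
#' @return numeric vector of probabilities summing to 1.
#' @examples
#' choice_probability(c(1, 0, -1), "best")           # softmax(1, 0, -1)
#' choice_probability(c(1, 0, -1), "worst")          # softmax(-1, 0, 1)
#' @export
choice_probability <- function(utility, stage, positions = seq_along(utility),
                               delta = NULL, lambda = 1) {
  if (length(utility) == 0L) stop("empty available set")
  if (length(stage) != 1L) stop("one stage at a time")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  s <- stage_sign(stage)
  u <- s * lambda * utility
  if (s > 0 && !is.null(delta)) u <- u + lambda * delta[positions]
  e <- exp(u - max(u))
  e / sum(e)
}

#' Log-likelihood of one task's four sequential picks
#'
#' The exploded sequential form: the task probability is the product of
#' stage probabilities over shrinking available sets in the order best,
#' worst, second best, second worst (available sizes 7, 6, 5, 4 for a
#' 7-domain instrument). This readable per-task version backs the fast
#' vectorised dataset likelihood and validates the data's sequential
#' structure as it goes.
#'
#' @param obs long-format rows of one task: columns `stage`, `domain`,
#'   `level`, `display_position`, `chosen_flag` (only available items are
#'   listed at each stage).
#' @param params a `bws_parameters`.
#' @param lambda the respondent's scale multiplier.
#' @return scalar log-likelihood.
#' @export
task_loglik <- function(obs, params, lambda = 1) {
  instrument <- params$instrument
  nd <- length(instrument$domains)
  ll <- 0
  prev_avail <- NULL
  prev_chosen <- NA_integer_
  for (k in seq_len(4L)) {
    st <- stage_names()[k]
    rows <- obs[obs$stage == st, , drop = FALSE]
    if (nrow(rows) != nd - k + 1L) {
      stop("stage '", st, "': expected ", nd - k + 1L, " available items, got ",
           nrow(rows))
    }
    items <- item_index(instrument, rows$domain, rows$level)
    if (!is.null(prev_avail) &&
        !setequal(items, setdiff(prev_avail, prev_chosen))) {
      stop("stage '", st, "': available set is not the previous set minus its pick")
    }
    ch <- which(rows$chosen_flag == 1L)
    if (length(ch) != 1L) stop("stage '", st, "': exactly one item must be chosen")
    p <- choice_probability(params$beta[items], st,
                            positions = rows$display_position,
                            delta = params$delta, lambda = lambda)
    ll <- ll + log(p[ch])
    prev_avail <- items
    prev_chosen <- items[ch]
  }
  as.numeric(ll)
}

# ---- model frame: long observations -> stage matrices ----------------------
# One entry per task: item/pos matrices and chosen column per stage, the
# respondent index, and the scale-group membership flags.
smnl_model_frame <- function(dataset, q1_threshold_minutes = 7) {
  stopifnot(inherits(dataset, "bws_dataset"))
  obs <- dataset$observations
  prof <- dataset$profiles
  instrument <- dataset$instrument
  nd <- length(instrument$domains)
  obs <- obs[obs$available_flag == 1L, , drop = FALSE]

  key <- paste(obs$respondent_id, obs$task_id, sep = "\r")
  tkeys <- unique(key)
  nt <- length(tkeys)
  tix <- match(key, tkeys)
  item <- item_index(instrument, obs$domain, obs$level)
  stg <- match(obs$stage, stage_names())
  if (anyNA(stg)) stop("unknown stage value in observations")

  sizes <- nd - 0:3
  items <- pos <- chosen <- vector("list", 4L)
  for (k in 1:4) {
    sel <- which(stg == k)
    o <- sel[order(tix[sel], obs$display_position[sel])]
    if (length(o) != nt * sizes[k]) {
      stop("stage '", stage_names()[k], "': expected ", sizes[k],
           " available items per task")
    }
    items[[k]] <- matrix(item[o], nt, sizes[k], byrow = TRUE)
    pos[[k]] <- matrix(obs$display_position[o], nt, sizes[k], byrow = TRUE)
    chm <- matrix(obs$chosen_flag[o], nt, sizes[k], byrow = TRUE)
    if (any(rowSums(chm) != 1L)) {
      stop("stage '", stage_names()[k], "': exactly one pick per task required")
    }
    chosen[[k]] <- max.col(chm, ties.method = "first")
  }
  # sequential-removal integrity
  for (k in 1:3) {
    kept <- drop_col(items[[k]], chosen[[k]])
    if (!all(apply(kept, 1, sort) == apply(items[[k + 1L]], 1, sort))) {
      stop("data integrity: stage ", k + 1L,
           " available sets are not stage ", k, " minus its pick")
    }
  }

  resp_key <- sub("\r.*$", "", tkeys)
  rids <- as.character(prof$respondent_id)
  resp <- match(resp_key, rids)
  if (anyNA(resp)) stop("observations reference respondents missing from profiles")
  G <- cbind(not_understood = as.numeric(!prof$understood),
             age35 = as.numeric(prof$age_35_plus),
             slow = as.numeric(prof$completion_minutes >= q1_threshold_minutes))

  # identification: every attribute-level must be on display at least once
  seen <- tabulate(items[[1L]], nbins = n_items(instrument))
  if (any(seen == 0L)) {
    lv <- enumerate_levels(instrument)
    miss <- paste(lv$domain[seen == 0L], lv$level[seen == 0L], sep = "_")
    stop("attribute-level(s) never shown, coefficients not identified: ",
         paste(miss, collapse = ", "))
  }

  list(nt = nt, n_resp = nrow(prof), resp = resp, G = G,
       items = items, pos = pos, chosen = chosen,
       sizes = sizes, instrument = instrument)
}

# ---- vectorised log-likelihood, gradient, per-respondent scores ------------
smnl_eval <- function(free, mf, want_grad = FALSE, want_scores = FALSE) {
  instrument <- mf$instrument
  fm <- free_map(instrument)
  if (any(!is.finite(free))) stop("non-finite entries in free parameter vector")
  # direct embedding (no user-facing validation): optimiser line searches may
  # probe extreme log-scales, which the clamp keeps finite
  beta <- c(0, free[seq_len(fm$n_beta)])[fm$beta_map + 1L]
  delta <- c(0, free[fm$n_beta + 1:6])
  loglam <- pmin(pmax(utils::tail(free, 3L), -300), 300)
  lam_task <- exp(as.vector(mf$G[mf$resp, , drop = FALSE] %*% loglam))

  nt <- mf$nt
  ni <- length(beta)
  ll <- 0
  gB <- numeric(ni); gD <- numeric(7L)
  tlam <- numeric(nt)   # per-task d loglik / d log lambda (common to all groups)
  trip_i <- trip_j <- trip_x <- list()

  for (k in 1:4) {
    s <- if (k %% 2L == 1L) 1 else -1
    it <- mf$items[[k]]; po <- mf$pos[[k]]; ch <- mf$chosen[[k]]
    U <- (s * lam_task) * matrix(beta[it], nt)
    if (s > 0) U <- U + lam_task * matrix(delta[po], nt)
    M <- U[cbind(seq_len(nt), max.col(U, ties.method = "first"))]
    E <- exp(U - M)
    S <- rowSums(E)
    uc <- U[cbind(seq_len(nt), ch)]
    ll <- ll + sum(uc - M - log(S))
    if (want_grad || want_scores) {
      P <- E / S
      W <- -P
      W[cbind(seq_len(nt), ch)] <- W[cbind(seq_len(nt), ch)] + 1
      wB <- (s * lam_task) * W
      idx <- as.vector(it)
      ag <- rowsum(as.vector(wB), idx)
      gB[as.integer(rownames(ag))] <- gB[as.integer(rownames(ag))] + ag
      if (s > 0) {
        wD <- lam_task * W
        ad <- rowsum(as.vector(wD), as.vector(po))
        gD[as.integer(rownames(ad))] <- gD[as.integer(rownames(ad))] + ad
      }
      tlam <- tlam + (uc - rowSums(P * U))
      if (want_scores) {
        pmap <- fm$beta_map[idx]
        keep <- pmap > 0L
        trip_i[[length(trip_i) + 1L]] <- rep(mf$resp, ncol(it))[keep]
        trip_j[[length(trip_j) + 1L]] <- pmap[keep]
        trip_x[[length(trip_x) + 1L]] <- as.vector(wB)[keep]
        if (s > 0) {
          pv <- as.vector(po)
          keep <- pv > 1L
          trip_i[[length(trip_i) + 1L]] <- rep(mf$resp, ncol(it))[keep]
          trip_j[[length(trip_j) + 1L]] <- fm$n_beta + pv[keep] - 1L
          trip_x[[length(trip_x) + 1L]] <- as.vector(wD)[keep]
        }
      }
    }
  }

  out <- list(loglik = ll)
  npar <- fm$n_beta + 9L
  if (want_grad || want_scores) {
    g <- numeric(npar)
    for (i in seq_len(ni)) {
      if (fm$beta_map[i] > 0L) g[fm$beta_map[i]] <- g[fm$beta_map[i]] + gB[i]
    }
    g[fm$n_beta + 1:6] <- gD[2:7]
    Gm <- mf$G[mf$resp, , drop = FALSE]
    g[fm$n_beta + 6L + 1:3] <- colSums(tlam * Gm)
    names(g) <- fm$names
    out$grad <- g
  }
  if (want_scores) {
    for (gcol in 1:3) {
      keep <- Gm[, gcol] > 0
      trip_i[[length(trip_i) + 1L]] <- mf$resp[keep]
      trip_j[[length(trip_j) + 1L]] <- rep(fm$n_beta + 6L + gcol, sum(keep))
      trip_x[[length(trip_x) + 1L]] <- tlam[keep]
    }
    Sc <- Matrix::sparseMatrix(i = unlist(trip_i), j = unlist(trip_j),
                               x = unlist(trip_x),
                               dims = c(mf$n_resp, npar))
    out$scores <- as.matrix(Sc)
    colnames(out$scores) <- fm$names
  }
  out
}

#' Dataset log-likelihood of the exploded S-MNL
#'
#' Sum of [task_loglik()] over all respondents and tasks, with each
#' respondent's scale multiplier derived from their covariates
#' ([scale_multiplier()]). Evaluated from the 35-entry free parameter vector
#' (26 utilities, 6 positioning effects, 3 log scale multipliers) through
#' the identification constraints.
#'
#' @param free free parameter vector (see [austria_parameters()] /
#'   `params_to_free`), or a `bws_parameters` object.
#' @param dataset a `bws_dataset` (cleaned; see [clean_dataset()]).
#' @param q1_threshold_minutes completion-time threshold for the "slower"
#'   scale group.
#' @return scalar log-likelihood.
#' @export
dataset_loglik <- function(free, dataset, q1_threshold_minutes = 7) {
  if (inherits(free, "bws_parameters")) free <- params_to_free(free)
  mf <- smnl_model_frame(dataset, q1_threshold_minutes)
  smnl_eval(free, mf)$loglik
}

#' Fit the scale-adjusted multinomial logit by maximum likelihood
#'
#' Maximises the exploded sequential best-worst likelihood over the free
#' parameters (utilities with the reference item at zero and the joint pair
#' aliased, positioning effects with position 1 at zero, scale multipliers
#' on the log scale for the three respondent groups with the reference
#' groups at 1). Optimisation is quasi-Newton (BFGS) with the analytic
#' gradient, followed by Newton polishing steps until the gradient max-norm
#' passes the convergence tolerance. The covariance is the cluster-robust
#' sandwich with respondents as clusters.
#'
#' @param dataset a `bws_dataset`; must have at least 2 respondents and show
#'   every attribute-level at least once.
#' @param start optional free-vector start (default: all zero).
#' @param q1_threshold_minutes completion-time threshold for the "slower"
#'   scale group (minutes).
#' @param control list: `maxit` (default 500), `gtol` (gradient max-norm
#'   tolerance, default 1e-5), `vcov` (compute robust covariance, default
#'   TRUE).
#' @return object of class `bws_fit`: `params` (embedded `bws_parameters`),
#'   `free` (estimates), `loglik`, `vcov` (robust, 35 x 35), `se`, `z`,
#'   `p_value` (two-sided, coefficient vs zero), `converged`, `grad_norm`,
#'   `iterations`, `n_respondents`, `n_tasks`.
#' @export
fit_smnl <- function(dataset, start = NULL, q1_threshold_minutes = 7,
                     control = list()) {
  ctl <- utils::modifyList(list(maxit = 500L, gtol = 1e-5, vcov = TRUE), control)
  if (nrow(dataset$profiles) < 2L) stop("need at least 2 respondents")
  mf <- smnl_model_frame(dataset, q1_threshold_minutes)
  fm <- free_map(mf$instrument)
  npar <- fm$n_beta + 9L
  if (is.null(start)) start <- numeric(npar)
  if (length(start) != npar) stop("start must have length ", npar)

  negll <- function(x) -smnl_eval(x, mf)$loglik
  neggr <- function(x) -smnl_eval(x, mf, want_grad = TRUE)$grad
  opt <- stats::optim(start, negll, neggr, method = "BFGS",
                      control = list(maxit = ctl$maxit, reltol = 1e-14))
  x <- opt$par
  ev <- smnl_eval(x, mf, want_grad = TRUE)
  iterations <- opt$counts[["function"]]

  # Newton polish to drive the gradient max-norm below tolerance
  H <- NULL
  for (it in 1:10) {
    if (max(abs(ev$grad)) < ctl$gtol) break
    H <- num_hessian(function(z) smnl_eval(z, mf, want_grad = TRUE)$grad, x)
    step <- tryCatch(solve(H, ev$grad), error = function(e) NULL)
    if (is.null(step)) break
    stepsize <- 1
    repeat {
      cand <- x - stepsize * step   # H is the hessian of loglik (negative definite)
      evc <- smnl_eval(cand, mf, want_grad = TRUE)
      if (evc$loglik >= ev$loglik || stepsize < 1e-4) break
      stepsize <- stepsize / 2
    }
    if (evc$loglik < ev$loglik) break
    x <- cand; ev <- evc
    iterations <- iterations + 1L
  }
  grad_norm <- max(abs(ev$grad))
  converged <- grad_norm < ctl$gtol
  if (!converged) {
    warning("fit_smnl did not reach gradient tolerance: max|grad| = ",
            format(grad_norm))
  }

  params <- free_to_params(x, mf$instrument)
  names(x) <- fm$names
  fit <- structure(list(params = params, free = x, loglik = ev$loglik,
                        vcov = NULL, se = NULL, z = NULL, p_value = NULL,
                        converged = converged, grad_norm = grad_norm,
                        iterations = iterations,
                        n_respondents = mf$n_resp, n_tasks = mf$nt,
                        q1_threshold_minutes = q1_threshold_minutes),
                   class = "bws_fit")
  if (ctl$vcov) {
    V <- robust_covariance(fit, dataset, hessian = H)
    fit$vcov <- V
    fit$se <- sqrt(diag(V))
    fit$z <- x / fit$se
    fit$p_value <- 2 * stats::pnorm(-abs(fit$z))
  }
  fit
}

# central-difference Jacobian of the analytic gradient, symmetrised
num_hessian <- function(gradfun, x, h = 1e-5) {
  n <- length(x)
  H <- matrix(0, n, n)
  for (j in seq_len(n)) {
    hj <- h * max(1, abs(x[j]))
    e <- numeric(n); e[j] <- hj
    H[, j] <- (gradfun(x + e) - gradfun(x - e)) / (2 * hj)
  }
  (H + t(H)) / 2
}

#' Cluster-robust sandwich covariance
#'
#' A^-1 B A^-1 with A the observed information (negative Hessian of the
#' log-likelihood at the optimum) and B the sum over respondents of the
#' outer products of their per-respondent score sums; respondents are the
#' clustering unit, accounting for the repeated tasks per person.
#'
#' @param fit a converged `bws_fit`.
#' @param dataset the dataset the fit was computed on.
#' @param hessian optional precomputed Hessian of the log-likelihood.
#' @return symmetric positive semi-definite matrix over the free parameters.
#' @export
robust_covariance <- function(fit, dataset, hessian = NULL) {
  stopifnot(inherits(fit, "bws_fit"))
  mf <- smnl_model_frame(dataset, fit$q1_threshold_minutes)
  x <- fit$free
  if (is.null(hessian)) {
    hessian <- num_hessian(function(z) smnl_eval(z, mf, want_grad = TRUE)$grad, x)
  }
  A <- -hessian
  ev <- smnl_eval(x, mf, want_scores = TRUE)
  B <- crossprod(ev$scores)
  Ainv <- tryCatch(solve(A), error = function(e) {
    ns <- eigen(A, symmetric = TRUE)
    stop("observed information is singular; null-space direction: ",
         paste(sprintf("%s=%.3f", names(x), ns$vectors[, length(x)]),
               collapse = " "))
  })
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  dimnames(V) <- list(names(x), names(x))
  V
}

#' Pairwise significance test between two attribute-levels
#'
#' Wald z ratio for the difference between two estimated item utilities,
#' using the robust covariance: z = (b_a - b_b) / sqrt(var_a + var_b -
#' 2 cov_ab), with a one-sided p-value 1 - Phi(|z|) (the convention used for
#' adjacent-level comparisons in published valuation tables; coefficient
#' vs zero tests in the fit use two-sided p-values).
#'
#' @param fit a `bws_fit` with covariance.
#' @param item_a,item_b items as `"DOMAIN_level"` strings (e.g. `"OCC_1"`).
#' @return list with `difference`, `z`, `p_value`; for the aliased joint
#'   pair the difference is exactly 0 and z/p are `NA` (no free difference
#'   exists).
#' @export
pairwise_level_test <- function(fit, item_a, item_b) {
  stopifnot(inherits(fit, "bws_fit"))
  if (is.null(fit$vcov)) stop("fit has no covariance; rerun with control$vcov = TRUE")
  if (identical(item_a, item_b)) stop("degenerate comparison: items are identical")
  instrument <- fit$params$instrument
  fm <- free_map(instrument)
  parse_item <- function(x) {
    parts <- strsplit(x, "_", fixed = TRUE)[[1]]
    lev <- as.integer(parts[length(parts)])
    dom <- paste(parts[-length(parts)], collapse = "_")
    item_index(instrument, dom, lev)
  }
  ia <- parse_item(item_a); ib <- parse_item(item_b)
  diffb <- fit$params$beta[ia] - fit$params$beta[ib]
  ka <- fm$beta_map[ia]; kb <- fm$beta_map[ib]
  if (ka == kb) {   # aliased joint pair: difference is structurally zero
    return(list(difference = 0, z = NA_real_, p_value = NA_real_,
                note = "aliased pair sharing one joint coefficient"))
  }
  va <- if (ka > 0L) fit$vcov[ka, ka] else 0
  vb <- if (kb > 0L) fit$vcov[kb, kb] else 0
  cab <- if (ka > 0L && kb > 0L) fit$vcov[ka, kb] else 0
  sed <- sqrt(va + vb - 2 * cab)
  z <- as.numeric(diffb / sed)
  list(difference = as.numeric(diffb), z = z,
       p_value = 1 - stats::pnorm(abs(z)))
}

#' Enumerate all ordered pick sequences of a task and their probabilities
#'
#' Exhaustively lists every ordered sequence of sequential picks (best,
#' worst, second best, second worst over shrinking available sets) and its
#' exploded-model probability. For a 7-item task with 4 picks there are
#' 7 * 6 * 5 * 4 = 840 sequences, whose probabilities sum to 1.
#'
#' @param utility item utilities.
#' @param positions display positions of the items.
#' @param delta positioning effects by display position.
#' @param lambda scale multiplier.
#' @param stages number of sequential picks.
#' @return data.frame with one row per sequence: pick columns `pick1`.. and
#'   `probability`.
#' @export
enumerate_sequences <- function(utility, positions = seq_along(utility),
                                delta = rep(0, max(positions)), lambda = 1,
                                stages = 4L) {
  stopifnot(length(utility) >= stages)
  recurse <- function(avail, k, prob, picks) {
    if (k > stages) {
      return(data.frame(matrix(picks, nrow = 1,
                               dimnames = list(NULL, paste0("pick", seq_len(stages)))),
                        probability = prob))
    }
    p <- choice_probability(utility[avail], stage_names()[k],
                            positions = positions[avail], delta = delta,
                            lambda = lambda)
    do.call(rbind, lapply(seq_along(avail), function(j) {
      recurse(avail[-j], k + 1L, prob * p[j], c(picks, avail[j]))
    }))
  }
  out <- recurse(seq_along(utility), 1L, 1, integer(0))
  rownames(out) <- NULL
  out
}

#' @export
print.bws_fit <- function(x, ...) {
  cat("Exploded S-MNL fit:", x$n_respondents, "respondents,", x$n_tasks,
      "tasks\n")
  cat(sprintf("log-likelihood %.3f | converged: %s (max|grad| %.2e, %d evals)\n",
              x$loglik, x$converged, x$grad_norm, x$iterations))
  if (!is.null(x$se)) {
    tab <- coef_table(x)
    print(utils::head(tab, 10))
    if (nrow(tab) > 10) cat("... (", nrow(tab) - 10, "more rows; see coef_table() )\n")
  }
  invisible(x)
}

#' Coefficient table of a fit
#'
#' One row per free parameter with robust standard error, z and two-sided
#' p-value, mirroring the layout of published valuation tables (scale
#' multipliers are reported on their natural scale).
#'
#' @param fit a `bws_fit`.
#' @return data.frame with columns `parameter`, `estimate`, `se_robust`,
#'   `z`, `p_value`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "bws_fit"))
  est <- fit$free
  se <- fit$se
  lam_idx <- grep("^loglambda_", names(est))
  out <- data.frame(parameter = names(est), estimate = est,
                    se_robust = se, z = fit$z, p_value = fit$p_value,
                    row.names = NULL)
  # delta-method transform of the log-scale entries to the natural scale
  out$estimate[lam_idx] <- exp(est[lam_idx])
  out$se_robust[lam_idx] <- exp(est[lam_idx]) * se[lam_idx]
  out$parameter[lam_idx] <- sub("^loglambda_", "lambda_", out$parameter[lam_idx])
  out
}
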