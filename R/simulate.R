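#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data generator:
#' a general-population online panel of 1001 respondents, each answering the
#' 8 tasks of one randomly assigned design block with 4 sequential picks per
#' task (32 choices), with scale heterogeneity across respondent groups and
#' a small planted fraction of "speeders" (completion under 4.5 minutes) to
#' exercise the cleaning filter.
#'
#' Covariate defaults mirror the published sample: 73.7% aged 35 and over;
#' task understanding ("not at all" or "only sometimes") is set at 15%, a
#' realistic share for an online panel since the published tables do not
#' report it. Completion times are log-normal with the first quartile at the
#' 7-minute threshold used to define the "slower" scale group; non-speeder
#' times are truncated above the 4.5-minute cleaning cut so the speeder
#' share is controlled exactly by `speeder_share`.
#'
#' @param n_respondents number of simulated respondents.
#' @param params generating `bws_parameters` (default: the published
#'   Austrian estimates, [austria_parameters()]).
#' @param share_age35 prevalence of age 35+.
#' @param share_not_understood prevalence of not/only-sometimes understanding
#'   the tasks.
#' @param speeder_share fraction with completion time below 4.5 minutes.
#' @param completion_meanlog,completion_sdlog log-normal completion-time
#'   parameters (minutes); defaults put the first quartile at 7 minutes.
#' @param q1_threshold_minutes completion-time threshold defining the
#'   "slower" scale group (first quartile, 7 minutes).
#' @param clean_threshold_minutes speeder exclusion threshold (4.5 minutes).
#' @param per_task_display if `TRUE`, a fresh display permutation is drawn
#'   for every task; default `FALSE` draws one permutation per respondent,
#'   constant across their 8 tasks.
#' @param seed master seed; every random draw in the simulator derives from it.
#' @return list of class `bws_sim_config`.
#' @export
sim_config <- function(n_respondents = 1001L,
                       params = austria_parameters(),
                       share_age35 = 0.737,
                       share_not_understood = 0.15,
                       speeder_share = 0.05,
                       completion_sdlog = 0.5,
                       completion_meanlog = log(7) + stats::qnorm(0.75) * completion_sdlog,
                       q1_threshold_minutes = 7,
                       clean_threshold_minutes = 4.5,
                       per_task_display = FALSE,
                       seed = 1L) {
  stopifnot(n_respondents >= 1L,
            share_age35 >= 0, share_age35 <= 1,
            share_not_understood >= 0, share_not_understood <= 1,
            speeder_share >= 0, speeder_share <= 1,
            q1_threshold_minutes > 0, clean_threshold_minutes > 0)
  structure(list(n_respondents = as.integer(n_respondents), params = params,
                 share_age35 = share_age35,
                 share_not_understood = share_not_understood,
                 speeder_share = speeder_share,
                 completion_meanlog = completion_meanlog,
                 completion_sdlog = completion_sdlog,
                 q1_threshold_minutes = q1_threshold_minutes,
                 clean_threshold_minutes = clean_threshold_minutes,
                 per_task_display = per_task_display,
                 seed = as.integer(seed)),
            class = "bws_sim_config")
}

#' Simulate respondent profiles
#'
#' Draws respondent covariates (age group, task understanding, completion
#' time), a uniformly random block assignment and a display permutation per
#' respondent, all deterministically from the configuration's master seed.
#' Completion times are reported in minutes, rounded to 0.01.
#'
#' @param config a `bws_sim_config`.
#' @return data.frame with columns `respondent_id`, `age_35_plus`,
#'   `understood`, `completion_minutes`, `block`, `display_order`
#'   (dash-separated domain indices, top position first; one permutation per
#'   respondent unless `per_task_display`).
#' @export
simulate_respondents <- function(config) {
  stopifnot(inherits(config, "bws_sim_config"))
  n <- config$n_respondents
  with_seed(config$seed, {
    age <- stats::runif(n) < config$share_age35
    not_und <- stats::runif(n) < config$share_not_understood
    speeder <- stats::runif(n) < config$speeder_share
    # non-speeders: log-normal truncated at the cleaning threshold
    lo <- stats::plnorm(config$clean_threshold_minutes,
                        config$completion_meanlog, config$completion_sdlog)
    u <- stats::runif(n, min = lo, max = 1)
    cm <- stats::qlnorm(u, config$completion_meanlog, config$completion_sdlog)
    cm[speeder] <- stats::runif(sum(speeder), 1.5,
                                config$clean_threshold_minutes - 0.02)
    cm <- round(cm, 2)
    blk <- sample(0:3, n, replace = TRUE)
    perms <- t(vapply(seq_len(n), function(i) sample.int(7L), integer(7)))
    data.frame(respondent_id = seq_len(n),
               age_35_plus = age,
               understood = !not_und,
               completion_minutes = cm,
               block = blk,
               display_order = apply(perms, 1, paste, collapse = "-"),
               stringsAsFactors = FALSE)
  })
}

#' Scale multiplier for a respondent
#'
#' The S-MNL scale is the product of the multipliers of every group the
#' respondent belongs to: `lambda_not_understood` if they did not (or only
#' sometimes) understand the tasks, `lambda_age35` if aged 35+, and
#' `lambda_slow` if their completion time is at or above the first-quartile
#' threshold. The reference respondent (understood, under 35, faster than
#' the threshold) has scale exactly 1.
#'
#' @param profile one-row data.frame (or list) with `age_35_plus`,
#'   `understood`, `completion_minutes`.
#' @param params a `bws_parameters`.
#' @param q1_threshold_minutes first-quartile completion threshold (minutes).
#' @return positive scalar (vectorised over rows of `profile`).
#' @export
scale_multiplier <- function(profile, params, q1_threshold_minutes = 7) {
  lam <- params$lambda
  if (any(lam <= 0)) stop("scale multipliers must be positive")
  ifelse(!profile$understood, lam[["not_understood"]], 1) *
    ifelse(profile$age_35_plus, lam[["age35"]], 1) *
    ifelse(profile$completion_minutes >= q1_threshold_minutes, lam[["slow"]], 1)
}

# parse "3-1-4-..." display_order strings to an n x 7 matrix: row r, col p =
# domain index shown at position p for respondent r
parse_display <- function(display_order, n_domains = 7L) {
  m <- t(vapply(strsplit(display_order, "-", fixed = TRUE),
                function(x) as.integer(x), integer(n_domains)))
  if (any(apply(m, 1, sort) != seq_len(n_domains))) {
    stop("display_order entries must be permutations of 1..", n_domains)
  }
  m
}

# remove per-row column `pick` from matrix, keeping column order
drop_col <- function(mat, pick) {
  n <- nrow(mat); m <- ncol(mat)
  ci <- matrix(rep(seq_len(m - 1L), each = n), n)
  ci <- ci + (ci >= pick)
  matrix(mat[cbind(rep(seq_len(n), m - 1L), as.vector(ci))], n)
}

# row-wise categorical draw: P n x m row-stochastic, u uniforms length n
draw_cat <- function(P, u) {
  m <- ncol(P)
  C <- P %*% upper.tri(diag(m), diag = TRUE)
  pmin(1L + rowSums(C < u), m)
}

#' Simulate the sequential picks of one choice task
#'
#' Samples the four picks (best, worst, second best, second worst) of a
#' profile-case task with removal, each stage distributed exactly as
#' [choice_probability()]: best-type stages weight item utility plus the
#' positioning effect of the item's display position, worst-type stages use
#' negated utilities and no positioning effect. Uses the current RNG stream;
#' seed beforehand for reproducibility.
#'
#' @param utility numeric utilities of the items on display (length >= 4).
#' @param positions display positions of those items (default: as listed).
#' @param delta positioning effects indexed by display position (default 0).
#' @param lambda scale multiplier.
#' @param stages how many sequential picks to make (default 4).
#' @return integer vector of picked item indices (into `utility`), named by
#'   stage.
#' @export
simulate_task_choices <- function(utility, positions = seq_along(utility),
                                  delta = rep(0, max(positions)),
                                  lambda = 1, stages = 4L) {
  stopifnot(length(utility) >= stages, length(positions) == length(utility))
  avail <- seq_along(utility)
  picks <- integer(stages)
  for (k in seq_len(stages)) {
    p <- choice_probability(utility[avail], stage_names()[k],
                            positions = positions[avail], delta = delta,
                            lambda = lambda)
    picks[k] <- avail[draw_cat(matrix(p, 1), stats::runif(1))]
    avail <- setdiff(avail, picks[k])
  }
  names(picks) <- stage_names()[seq_len(stages)]
  picks
}

#' Simulate a full best-worst choice dataset
#'
#' Generates respondent profiles, assigns each respondent the 8 tasks of
#' their block, and samples all four sequential picks per task under the
#' scale-adjusted multinomial logit data-generating process, giving 32
#' choice observations per respondent. Fully deterministic given the
#' configuration's master seed.
#'
#' @param config a `bws_sim_config`.
#' @param plan a `bws_design` passing [verify_design()].
#' @param instrument a `bws_instrument`.
#' @return A `bws_dataset`: list with `observations` (long data.frame, one
#'   row per available item per stage: `respondent_id`, `block`, `task_id`
#'   (scenario row), `stage`, `domain`, `level`, `display_position`,
#'   `available_flag`, `chosen_flag`), `profiles`, `plan`, `instrument`.
#' @export
simulate_dataset <- function(config, plan = design_fixture(),
                             instrument = ascot_carer_instrument()) {
  stopifnot(inherits(config, "bws_sim_config"))
  if (!verify_design(plan)$pass) stop("plan fails design verification")
  profiles <- simulate_respondents(config)
  params <- config$params
  n <- nrow(profiles)
  tasks <- block_design(plan, instrument)
  codes <- names(instrument$domains)
  nd <- length(codes)

  # expand respondent x task grid (8 tasks per respondent, from their block)
  tl <- split(seq_len(nrow(tasks)), tasks$block)
  task_rows <- unlist(tl[as.character(profiles$block)], use.names = FALSE)
  resp <- rep(seq_len(n), each = 8L)
  nt <- length(resp)

  # item ids shown in each task (columns = instrument domain order)
  lvl <- as.matrix(tasks[task_rows, codes])
  items <- sweep(lvl, 2, (seq_len(nd) - 1L) * 4L, `+`)

  # display position of each domain
  if (config$per_task_display) {
    pos_dom <- with_seed(config$seed + 1L,
                         t(vapply(seq_len(nt), function(i) {
                           p <- sample.int(nd)
                           match(seq_len(nd), p)
                         }, integer(nd))))
  } else {
    perms <- parse_display(profiles$display_order, nd)
    pos_dom <- t(apply(perms, 1, function(p) match(seq_len(nd), p)))[resp, , drop = FALSE]
  }

  lam <- scale_multiplier(profiles, params, config$q1_threshold_minutes)[resp]

  beta <- params$beta
  delta <- params$delta
  sizes <- nd - 0:3
  stage_items <- stage_pos <- stage_pick <- vector("list", 4L)
  cur_items <- items
  cur_pos <- pos_dom
  with_seed(config$seed + 2L, {
    for (k in 1:4) {
      s <- if (k %% 2L == 1L) 1 else -1            # best-type odd stages
      U <- (s * lam) * matrix(beta[cur_items], nt)
      if (s > 0) U <- U + lam * matrix(delta[cur_pos], nt)
      M <- U[cbind(seq_len(nt), max.col(U, ties.method = "first"))]
      E <- exp(U - M)
      P <- E / rowSums(E)
      pick <- draw_cat(P, stats::runif(nt))
      stage_items[[k]] <- cur_items
      stage_pos[[k]] <- cur_pos
      stage_pick[[k]] <- pick
      if (k < 4L) {
        cur_items <- drop_col(cur_items, pick)
        cur_pos <- drop_col(cur_pos, pick)
      }
    }
  })

  lv <- enumerate_levels(instrument)
  obs <- do.call(rbind, lapply(1:4, function(k) {
    m <- sizes[k]
    it <- as.vector(t(stage_items[[k]]))
    po <- as.vector(t(stage_pos[[k]]))
    ch <- as.vector(t(col(stage_items[[k]]) == stage_pick[[k]]))
    data.frame(respondent_id = rep(profiles$respondent_id[resp], each = m),
               block = rep(profiles$block[resp], each = m),
               task_id = rep(tasks$scenario[task_rows], each = m),
               stage = stage_names()[k],
               domain = lv$domain[it],
               level = lv$level[it],
               display_position = po,
               available_flag = 1L,
               chosen_flag = as.integer(ch),
               stringsAsFactors = FALSE)
  }))
  # canonical order: respondent, task, stage, display position
  obs <- obs[order(match(obs$respondent_id, profiles$respondent_id),
                   obs$task_id, match(obs$stage, stage_names()),
                   obs$display_position), ]
  rownames(obs) <- NULL
  new_dataset(obs, profiles, plan, instrument)
}

new_dataset <- function(observations, profiles, plan, instrument) {
  structure(list(observations = observations, profiles = profiles,
                 plan = plan, instrument = instrument),
            class = "bws_dataset")
}

#' @export
print.bws_dataset <- function(x, ...) {
  cat("Best-worst choice dataset:", nrow(x$profiles), "respondents,",
      length(unique(interaction(x$observations$respondent_id,
                                x$observations$task_id, drop = TRUE))),
      "tasks,", sum(x$observations$chosen_flag), "picks\n")
  invisible(x)
}
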