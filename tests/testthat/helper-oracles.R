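# Independent slow reference implementations used as oracles. These are
# deliberately written with plain loops and explicit formulas, sharing no
# code with the package's vectorised likelihood.

# softmax written out longhand
oracle_softmax <- function(u) {
  e <- exp(u)
  e / sum(e)
}

# probability of one stage pick, longhand
oracle_stage_prob <- function(beta_avail, stage, pos_avail, delta, lambda) {
  if (stage %in% c("best", "second_best")) {
    u <- lambda * (beta_avail + delta[pos_avail])
  } else {
    u <- -lambda * beta_avail
  }
  oracle_softmax(u)
}

# naive double-loop dataset log-likelihood
oracle_dataset_loglik <- function(dataset, params, q1 = 7) {
  lam_all <- scale_multiplier(dataset$profiles, params, q1)
  stages <- c("best", "worst", "second_best", "second_worst")
  ll <- 0
  instr <- dataset$instrument
  for (i in seq_len(nrow(dataset$profiles))) {
    rid <- dataset$profiles$respondent_id[i]
    robs <- dataset$observations[dataset$observations$respondent_id == rid, ]
    for (tid in unique(robs$task_id)) {
      tobs <- robs[robs$task_id == tid, ]
      for (st in stages) {
        sobs <- tobs[tobs$stage == st, ]
        b <- params$beta[item_index(instr, sobs$domain, sobs$level)]
        p <- oracle_stage_prob(b, st, sobs$display_position, params$delta,
                               lam_all[i])
        ll <- ll + log(p[sobs$chosen_flag == 1])
      }
    }
  }
  as.numeric(ll)
}

# long-format observation rows for one task, given the items on display
# (item order = display position) and the four picks (indices into items)
make_task_obs <- function(instr, levels_by_domain, picks,
                          display_perm = seq_along(levels_by_domain),
                          respondent_id = 1L, task_id = 1L) {
  nd <- length(levels_by_domain)
  codes <- names(instr$domains)
  stages <- c("best", "worst", "second_best", "second_worst")
  pos_of_domain <- match(seq_len(nd), display_perm)
  avail <- seq_len(nd)
  out <- list()
  for (k in seq_along(picks)) {
    out[[k]] <- data.frame(
      respondent_id = respondent_id, block = 0L, task_id = task_id,
      stage = stages[k], domain = codes[avail],
      level = levels_by_domain[avail],
      display_position = pos_of_domain[avail],
      available_flag = 1L,
      chosen_flag = as.integer(avail == picks[k]))
    avail <- setdiff(avail, picks[k])
  }
  do.call(rbind, out)
}

# small simulated dataset helper with fixed conditions
small_dataset <- function(n = 5, seed = 11, speeder_share = 0, ...) {
  cfg <- sim_config(n_respondents = n, seed = seed,
                    speeder_share = speeder_share, ...)
  simulate_dataset(cfg, design_fixture())
}

austria_free <- function() params_to_free(austria_parameters())
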