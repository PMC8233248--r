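test_that("stage probabilities are softmax in scaled utility with position offsets", {
  expect_equal(choice_probability(c(0, 0), "best"), c(0.5, 0.5))
  p_best <- choice_probability(c(1, 0, -1), "best")
  expect_equal(p_best, oracle_softmax(c(1, 0, -1)), tolerance = 1e-12)
  expect_equal(round(p_best, 5), c(0.66524, 0.24473, 0.09003))
  # worst-type: negated utilities, reversed ordering
  expect_equal(choice_probability(c(1, 0, -1), "worst"), rev(p_best),
               tolerance = 1e-12)
  # positioning effects enter best-type stages only
  d <- c(0, -0.5, -1)
  expect_equal(choice_probability(c(1, 0, -1), "second_best", positions = 1:3,
                                  delta = d),
               oracle_softmax(c(1, 0, -1) + d), tolerance = 1e-12)
  expect_equal(choice_probability(c(1, 0, -1), "second_worst", positions = 1:3,
                                  delta = d),
               oracle_softmax(-c(1, 0, -1)), tolerance = 1e-12)
  # scale enters multiplicatively; no overflow at extreme magnitudes
  expect_equal(choice_probability(c(1, 0, -1), "best", lambda = 2),
               oracle_softmax(2 * c(1, 0, -1)), tolerance = 1e-12)
  expect_equal(sum(choice_probability(c(350, 0, -350), "best")), 1)

  expect_error(choice_probability(numeric(0), "best"), "empty")
  expect_error(choice_probability(c(1, 0), "bestest"), "unknown stage")
})

test_that("task log-likelihood is the exploded product over shrinking sets", {
  instr <- ascot_carer_instrument()
  p0 <- smnl_parameters(rep(0, 28))
  obs <- make_task_obs(instr, levels_by_domain = rep(2L, 7), picks = c(1, 2, 3, 4))
  expect_equal(task_loglik(obs, p0), -log(840))
  expect_equal(task_loglik(obs, p0, lambda = 2), -log(840))  # lambda cancels

  # exhaustive enumeration: all 840 ordered sequences sum to one
  pa <- austria_parameters()
  seqs <- enumerate_sequences(pa$beta[seq(1, 28, by = 4)], positions = 1:7,
                              delta = pa$delta, lambda = 0.8)
  expect_equal(nrow(seqs), 840L)
  expect_equal(sum(seqs$probability), 1, tolerance = 1e-10)

  bad <- obs
  bad$chosen_flag[bad$stage == "best"] <- rev(bad$chosen_flag[bad$stage == "best"])
  expect_error(task_loglik(bad, p0), "minus its pick")
})

test_that("dataset log-likelihood matches the naive double-loop oracle", {
  ds <- small_dataset(n = 5, seed = 31)
  pa <- austria_parameters()
  expect_equal(dataset_loglik(params_to_free(pa), ds),
               oracle_dataset_loglik(ds, pa), tolerance = 1e-10)
  # uniform parameters: R x 8 x (-log 840)
  expect_equal(dataset_loglik(numeric(35), ds), 5 * 8 * (-log(840)))
  # invariant to relabelling respondent ids
  ds2 <- ds
  relab <- c(105, 104, 103, 102, 101)
  ds2$observations$respondent_id <- relab[ds2$observations$respondent_id]
  ds2$profiles$respondent_id <- relab[ds2$profiles$respondent_id]
  expect_equal(dataset_loglik(params_to_free(pa), ds2),
               dataset_loglik(params_to_free(pa), ds), tolerance = 1e-12)
  expect_error(dataset_loglik(c(NaN, numeric(34)), ds), "non-finite")
})

test_that("analytic gradient agrees with central finite differences", {
  ds <- small_dataset(n = 4, seed = 33)
  mf <- smnl_model_frame(ds, 7)
  set.seed(9)
  x <- rnorm(35, sd = 0.4)
  g <- smnl_eval(x, mf, want_grad = TRUE)$grad
  h <- 1e-6
  gnum <- vapply(1:35, function(j) {
    e <- numeric(35); e[j] <- h
    (smnl_eval(x + e, mf)$loglik - smnl_eval(x - e, mf)$loglik) / (2 * h)
  }, numeric(1))
  expect_equal(unname(g), gnum, tolerance = 1e-6)
})

test_that("maximum likelihood recovers generating parameters on a modest sample", {
  cfg <- sim_config(n_respondents = 150, seed = 51, speeder_share = 0)
  ds <- simulate_dataset(cfg)
  fit <- fit_smnl(ds)
  expect_true(fit$converged)
  expect_lt(fit$grad_norm, 1e-5)
  truth <- austria_free()
  expect_gt(cor(fit$free[1:26], truth[1:26]), 0.98)
  # determinism and start-invariance of the optimum
  fit_b <- fit_smnl(ds, start = truth + 0.2, control = list(vcov = FALSE))
  expect_lt(abs(fit_b$loglik - fit$loglik), 1e-5)
  expect_equal(fit_b$free, fit$free, tolerance = 1e-3)
})

test_that("estimates are jointly null when generated under equal utilities", {
  p0 <- smnl_parameters(rep(0, 28))
  cfg <- sim_config(n_respondents = 400, params = p0, seed = 52,
                    speeder_share = 0)
  fit <- fit_smnl(simulate_dataset(cfg))
  wald <- drop(t(fit$free[1:26]) %*%
                 solve(fit$vcov[1:26, 1:26], fit$free[1:26]))
  expect_lt(wald, qchisq(0.99, df = 26))
})

test_that("identification failures raise explicit errors", {
  ds <- small_dataset(n = 5, seed = 31)
  # make one attribute-level unobserved (shown tasks display level 2 instead)
  ds_cut <- ds
  occ1 <- ds_cut$observations$domain == "OCC" & ds_cut$observations$level == 1L
  ds_cut$observations$level[occ1] <- 2L
  expect_error(fit_smnl(ds_cut), "OCC_1")
  one <- ds
  one$profiles <- one$profiles[1, , drop = FALSE]
  one$observations <- one$observations[one$observations$respondent_id ==
                                         one$profiles$respondent_id, ]
  expect_error(fit_smnl(one), "at least 2 respondents")
})

test_that("robust sandwich covariance is symmetric PSD and scales under cluster duplication", {
  cfg <- sim_config(n_respondents = 60, seed = 53, speeder_share = 0)
  ds <- simulate_dataset(cfg)
  fit <- fit_smnl(ds)
  V <- fit$vcov
  expect_equal(V, t(V), tolerance = 1e-10)
  expect_true(all(eigen(V, symmetric = TRUE, only.values = TRUE)$values > -1e-10))
  expect_equal(fit$se, sqrt(diag(V)), tolerance = 1e-12)

  # duplicate every respondent as a new cluster: same optimum, half the sandwich
  prof2 <- ds$profiles
  prof2$respondent_id <- prof2$respondent_id + 1000L
  obs2 <- ds$observations
  obs2$respondent_id <- obs2$respondent_id + 1000L
  dup <- carerbws:::new_dataset(rbind(ds$observations, obs2),
                                rbind(ds$profiles, prof2),
                                ds$plan, ds$instrument)
  fit2 <- fit_smnl(dup, start = fit$free)
  expect_equal(fit2$free, fit$free, tolerance = 1e-5)
  expect_equal(fit2$vcov, V / 2, tolerance = 0.02)
})

test_that("pairwise level tests follow the published table conventions", {
  cfg <- sim_config(n_respondents = 200, seed = 54, speeder_share = 0)
  fit <- fit_smnl(simulate_dataset(cfg))
  # aliased joint pair: difference exactly zero by construction
  al <- pairwise_level_test(fit, "ENC_1", "ENC_2")
  expect_identical(al$difference, 0)
  expect_error(pairwise_level_test(fit, "OCC_1", "OCC_1"), "degenerate")
  # a generating gap of many standard errors is overwhelmingly significant
  big <- pairwise_level_test(fit, "OCC_1", "OCC_4")
  expect_gt(big$z, 5)
  expect_lt(big$p_value, 0.001)
  # equal estimates with diagonal covariance: z = 0, one-sided p = 0.5
  fake <- fit
  fake$params$beta[c("OCC_3", "SOC_3")] <- 1.34
  fm <- carerbws:::free_map(fit$params$instrument)
  fake$free[fm$beta_map[carerbws:::item_index(fit$params$instrument,
                                              c("OCC", "SOC"), c(3, 3))]] <- 1.34
  fake$vcov <- diag(0.1, 35)
  pt <- pairwise_level_test(fake, "OCC_3", "SOC_3")
  expect_equal(pt$z, 0)
  expect_equal(pt$p_value, 0.5)
})

test_that("scale-utility confounding cancels in the likelihood", {
  # multiplying beta and delta by c and dividing lambda by c leaves the
  # likelihood unchanged: the reference-group scale of 1 is what identifies it
  ds <- small_dataset(n = 5, seed = 35, share_not_understood = 1)
  pa <- austria_parameters()
  cc <- 1.7
  lam <- pa$lambda
  lam[["not_understood"]] <- lam[["not_understood"]] / cc  # in every product here
  scaled <- smnl_parameters(pa$beta * cc, pa$delta * cc, lam)
  expect_equal(oracle_dataset_loglik(ds, scaled), oracle_dataset_loglik(ds, pa),
               tolerance = 1e-8)
})
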