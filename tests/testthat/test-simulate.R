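test_that("respondent profiles match the configured prevalences and seed determinism", {
  cfg <- sim_config(n_respondents = 1001, seed = 5)
  prof <- simulate_respondents(cfg)
  expect_equal(nrow(prof), 1001L)
  expect_identical(prof, simulate_respondents(cfg))

  cfg0 <- sim_config(n_respondents = 500, speeder_share = 0, seed = 6)
  expect_true(all(simulate_respondents(cfg0)$completion_minutes >= 4.5))

  cfgN <- sim_config(n_respondents = 10000, share_age35 = 0.737, seed = 8)
  profN <- simulate_respondents(cfgN)
  expect_lt(abs(mean(profN$age_35_plus) - 0.737), 0.01)
  expect_true(all(profN$block %in% 0:3))
  expect_true(all(profN$completion_minutes > 0))
})

test_that("scale multipliers follow the product-of-groups rule with reference 1", {
  p <- austria_parameters()
  ref <- data.frame(age_35_plus = FALSE, understood = TRUE, completion_minutes = 5)
  expect_equal(scale_multiplier(ref, p), 1.0)
  slow <- data.frame(age_35_plus = FALSE, understood = TRUE, completion_minutes = 12)
  expect_equal(scale_multiplier(slow, p), 1.66)
  all3 <- data.frame(age_35_plus = TRUE, understood = FALSE, completion_minutes = 7)
  expect_equal(scale_multiplier(all3, p), 0.70 * 0.80 * 1.66)
  # threshold is inclusive: exactly at the first quartile counts as slower
  atq <- data.frame(age_35_plus = FALSE, understood = TRUE, completion_minutes = 7)
  expect_equal(scale_multiplier(atq, p), 1.66)

  bad <- p
  bad$lambda[["not_understood"]] <- -1
  expect_error(scale_multiplier(ref, bad), "positive")
})

test_that("task choice sampling matches the stage-level choice probabilities", {
  # symmetry: equal utilities, no positioning effect
  set.seed(21)
  best <- replicate(50000, simulate_task_choices(rep(0, 7), stages = 1L)[1])
  freq <- tabulate(best, 7) / 50000
  expect_true(all(abs(freq - 1 / 7) < 0.006))   # ~4 MC standard errors

  # softmax saturation: one dominant item
  set.seed(22)
  dom <- replicate(2000, simulate_task_choices(c(10, 0, 0, 0, 0, 0, 0),
                                               stages = 1L)[1])
  expect_gt(mean(dom == 1), 0.999)

  # closed-form softmax oracle on a 3-item toy
  set.seed(23)
  toy <- replicate(100000, simulate_task_choices(c(1, 0, -1), stages = 1L)[1])
  expect_true(all(abs(tabulate(toy, 3) / 100000 -
                        oracle_softmax(c(1, 0, -1))) < 0.005))
})

test_that("sequence frequencies follow the exploded model (chi-square, 24 sequences)", {
  u <- c(0.8, 0.2, -0.3, 0)
  delta <- c(0, -0.2, -0.3, -0.4)
  seqs <- enumerate_sequences(u, delta = delta, lambda = 1.3, stages = 4L)
  expect_equal(nrow(seqs), 24L)
  set.seed(31)
  n <- 50000
  draws <- replicate(n, paste(simulate_task_choices(u, delta = delta,
                                                    lambda = 1.3), collapse = "-"))
  keys <- apply(seqs[paste0("pick", 1:4)], 1, paste, collapse = "-")
  counts <- table(factor(draws, levels = keys))
  gof <- suppressWarnings(stats::chisq.test(counts, p = seqs$probability))
  expect_gt(gof$p.value, 0.01)
})

test_that("simulated datasets have the sequential structure and are reproducible", {
  cfg <- sim_config(n_respondents = 10, seed = 4)
  ds <- simulate_dataset(cfg)
  expect_equal(sum(ds$observations$chosen_flag), 10 * 8 * 4)  # 32 picks each
  counts <- table(ds$observations$stage) / (10 * 8)
  expect_equal(counts[c("best", "worst", "second_best", "second_worst")],
               c(best = 7, worst = 6, second_best = 5, second_worst = 4),
               ignore_attr = TRUE)
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$observations, ds2$observations)
  expect_identical(ds$profiles, ds2$profiles)
})

test_that("positioning effects make top-of-list items more often 'best'", {
  beta <- rep(0, 28)
  p <- smnl_parameters(beta, delta = austria_parameters()$delta,
                       lambda = c(not_understood = 1, age35 = 1, slow = 1))
  cfg <- sim_config(n_respondents = 600, params = p, seed = 17,
                    speeder_share = 0)
  ds <- simulate_dataset(cfg)
  best <- ds$observations[ds$observations$stage == "best" &
                            ds$observations$chosen_flag == 1L, ]
  n_best <- nrow(best)
  f1 <- mean(best$display_position == 1)
  f7 <- mean(best$display_position == 7)
  expect_gt(f1, f7)
  # monotone decline over the whole list
  freqs <- tabulate(best$display_position, 7) / n_best
  expect_lt(stats::cor(1:7, freqs), -0.9)
})
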