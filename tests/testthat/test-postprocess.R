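# two-domain toy instrument: utility ranges 1 and 3, shared denominator 4
toy_instr <- function() {
  new_instrument(
    list(list(code = "D1", label = "domain one", statements = paste("a", 1:4)),
         list(code = "D2", label = "domain two", statements = paste("b", 1:4))),
    reference = list(domain = "D2", level = 4L))
}
toy_beta <- c(1, 0.5, 0.2, 0, 3, 2, 1, 0)

test_that("population reweighting is the proportion-weighted entrywise average", {
  instr <- ascot_carer_instrument()
  pa <- austria_parameters()$beta
  expect_equal(reweight_by_population(list(pa), 1), pa, ignore_attr = TRUE)

  pb <- pa; pb[["OCC_3"]] <- pa[["OCC_3"]] + 2
  mid <- reweight_by_population(list(pa, pb), c(0.5, 0.5))
  expect_equal(mid[["OCC_3"]], pa[["OCC_3"]] + 1)
  expect_equal(mid[-3], pa[-3], ignore_attr = TRUE)

  # independent arithmetic oracle with three random groups
  set.seed(61)
  mk <- function() {
    b <- rnorm(28); b[24] <- 0; b[26] <- b[25]
    b
  }
  gs <- list(mk(), mk(), mk())
  pr <- c(0.2, 0.3, 0.5)
  manual <- 0.2 * gs[[1]] + 0.3 * gs[[2]] + 0.5 * gs[[3]]
  expect_equal(unname(reweight_by_population(gs, pr)), manual, tolerance = 1e-12)

  expect_equal(unname(reweight_by_population(gs, c(1, 1, 1) / 3)[24]), 0)
  expect_error(reweight_by_population(gs, c(0.2, 0.3, 0.4)), "sum to 1")
  bad <- gs; bad[[1]][24] <- 0.5
  expect_error(reweight_by_population(bad, pr), "reference")
})

test_that("rescaled weights put total scores exactly on [0, 1]", {
  instr <- toy_instr()
  w <- rescale_weights(toy_beta, instr)
  expect_equal(attr(w, "denominator"), 4)
  expect_equal(w$weight[w$domain == "D1" & w$level == 1], 0.25)
  expect_equal(w$weight[w$domain == "D2" & w$level == 1], 0.75)
  expect_equal(score_state(c(D1 = 1, D2 = 1), w, instr), 1.0)
  expect_equal(score_state(c(D1 = 4, D2 = 4), w, instr), 0.0)
  # mixed state, verified by hand: w(D1,2) + w(D2,3) = 0.5/4 + 1/4
  expect_equal(score_state(c(D1 = 2, D2 = 3), w, instr), 0.125 + 0.25)

  # published utilities: endpoints forced by the construction
  pa <- austria_parameters()$beta
  wa <- rescale_weights(pa)
  all_best <- setNames(rep(1L, 7), unique(wa$domain))
  all_worst <- setNames(rep(4L, 7), unique(wa$domain))
  expect_equal(score_state(all_best, wa), 1.0)
  expect_equal(score_state(all_worst, wa), 0.0)
  # rank preservation within domains
  for (d in unique(wa$domain)) {
    expect_equal(order(wa$weight[wa$domain == d], decreasing = TRUE),
                 order(pa[paste(d, 1:4, sep = "_")], decreasing = TRUE))
  }
  expect_error(rescale_weights(rep(2, 8), instr), "degenerate")
})

test_that("rescaling is invariant to per-domain shifts and positive scaling", {
  instr <- toy_instr()
  w0 <- rescale_weights(toy_beta, instr)
  shifted <- toy_beta + rep(c(5, -2), each = 4)   # constant within domain
  expect_equal(rescale_weights(shifted, instr)$weight, w0$weight,
               tolerance = 1e-12)
  expect_equal(rescale_weights(3.2 * toy_beta, instr)$weight, w0$weight,
               tolerance = 1e-12)
})

test_that("scores are monotone in single-domain improvements", {
  wa <- rescale_weights(austria_parameters()$beta)
  codes <- unique(wa$domain)
  base <- setNames(rep(3L, 7), codes)
  for (d in codes) for (l in 3:1) {
    better <- base; better[d] <- l
    worse <- base; worse[d] <- l + 1L
    expect_gte(score_state(better, wa), score_state(worse, wa))
  }
})

test_that("item ranking orders by value, flags ties, and is a permutation", {
  pa <- austria_parameters()$beta
  rk <- rank_items(pa)
  expect_equal(nrow(rk), 28L)
  expect_setequal(paste(rk$domain, rk$level), paste(rep(names(ascot_carer_instrument()$domains), each = 4), 1:4))
  expect_equal(rk$domain[1], "OCC"); expect_equal(rk$level[1], 1L)
  expect_equal(rk$domain[28], "STS"); expect_equal(rk$level[28], 4L)
  expect_true(all(diff(rk$value) <= 0))
  # the aliased joint pair ties and is flagged
  expect_true(all(rk$tied[rk$domain == "ENC" & rk$level %in% 1:2]))

  const <- rank_items(rep(1, 28))
  expect_true(all(const$tied))
})
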