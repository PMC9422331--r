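test_that("decision config validates sizes and scale factors", {
  expect_error(decision_config(n_bal = 0, n_imbal = 0), "at least one")
  expect_error(decision_config(alpha_bal = 1.2), "alpha")
  cfg <- decision_config()
  expect_equal(cfg$n_bal / cfg$n_imbal, 1.5)  # 3:2 as in the recorded ratio
})

test_that("silencing one group forces the decision", {
  # balanced silenced: imbalanced always wins strictly -> always integration
  cfg_b <- decision_config(alpha_bal = 0, n_rep = 500)
  cur <- decision_curve(cfg_b, deltas = c(0, 90, 180), seed = 1)
  expect_equal(cur$p_common, c(1, 1, 1))
  # both silenced: tie, and ties report separation
  cfg_t <- decision_config(alpha_bal = 0, alpha_imbal = 0, n_rep = 200)
  cur_t <- decision_curve(cfg_t, deltas = c(0, 90), seed = 1)
  expect_equal(cur_t$p_common, c(0, 0))
  expect_equal(single_decision(0, cfg_t, seed = 4), "separate")
})

test_that("a degenerate imbalanced preference at the cue yields integration", {
  dd <- make_disparity_distributions("degenerate", degenerate_at = 0)
  cfg <- decision_config(d_imbal = dd$balanced, n_rep = 2000,
                         f_bal = make_response_template("balanced", 40),
                         f_imbal = make_response_template("imbalanced", 40))
  cur <- decision_curve(cfg, deltas = 0, seed = 2)
  expect_gt(cur$p_common, 0.9)
})

test_that("decision probability falls with cue disparity for default configs", {
  cur <- decision_curve(decision_config(n_rep = 20000), seed = 11)
  expect_gt(cur$p_common[1], 0.5)
  expect_lt(cur$p_common[length(cur$p_common)], 0.1)
  expect_true(all(diff(cur$p_common) <= 0.02))
})

test_that("reliability scaling shifts the curve in the documented directions", {
  base <- decision_curve(decision_config(n_rep = 30000), seed = 7)
  up <- decision_curve(decision_config(alpha_bal = 0.8, n_rep = 30000),
                       seed = 7)
  down <- decision_curve(decision_config(alpha_imbal = 0.8, n_rep = 30000),
                         seed = 7)
  expect_true(all(up$p_common >= base$p_common - 1e-9))
  expect_true(all(down$p_common <= base$p_common + 1e-9))
  expect_gt(mean(up$p_common - base$p_common), 0.01)
  expect_gt(mean(base$p_common - down$p_common), 0.01)
})

test_that("swapping the groups' roles reflects the decision probability", {
  # tie-free asymmetric config: distinct templates and distributions
  dd <- make_disparity_distributions("paper_like")
  f1 <- make_response_template("balanced", width = 55, baseline = 1,
                               peak = 47)
  f2 <- make_response_template("imbalanced", width = 70, baseline = 2,
                               peak = 61)
  cfg <- decision_config(n_bal = 9, n_imbal = 6, d_bal = dd$balanced,
                         d_imbal = dd$imbalanced, f_bal = f1, f_imbal = f2,
                         n_rep = 40000)
  swapped <- decision_config(n_bal = 6, n_imbal = 9, d_bal = dd$imbalanced,
                             d_imbal = dd$balanced, f_bal = f2, f_imbal = f1,
                             n_rep = 40000)
  a <- decision_curve(cfg, deltas = c(0, 45, 90, 135), seed = 3)
  b <- decision_curve(swapped, deltas = c(0, 45, 90, 135), seed = 4)
  expect_equal(b$p_common, 1 - a$p_common, tolerance = 0.02)
})

test_that("identical seeds reproduce decision curves exactly", {
  cfg <- decision_config(n_rep = 5000)
  expect_identical(decision_curve(cfg, seed = 9)$p_common,
                   decision_curve(cfg, seed = 9)$p_common)
})

test_that("larger samples steepen the decision function", {
  ss <- sample_size_sweep(c(15, 150), decision_config(n_rep = 30000),
                          seed = 13)
  sl <- unique(ss[, c("total_size", "midpoint_slope")])
  expect_gt(sl$midpoint_slope[sl$total_size == 150],
            sl$midpoint_slope[sl$total_size == 15])
  # a very large symmetric sample approaches a step: near-binary plateaus
  big <- sample_size_sweep(1500, decision_config(n_rep = 4000), seed = 14)
  expect_gt(mean(big$p_common > 0.99 | big$p_common < 0.01), 0.6)
  expect_warning(sample_size_sweep(16, decision_config(n_rep = 100)),
                 "3:2")
})

test_that("Bayesian fits to sampling curves track reliability through the prior", {
  pri <- function(alpha_bal, alpha_imbal) {
    cur <- decision_curve(decision_config(alpha_bal = alpha_bal,
                                          alpha_imbal = alpha_imbal,
                                          n_rep = 30000), seed = 17)
    unname(fit_bci(cur[, c("dtheta_cue", "p_common")], sigma = 30,
                   fit = "prior")$estimate["prior"])
  }
  p_base <- pri(1, 1)
  expect_gt(pri(0.8, 1), p_base)   # weaker balanced -> larger prior
  expect_lt(pri(1, 0.8), p_base)   # weaker imbalanced -> smaller prior
})
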