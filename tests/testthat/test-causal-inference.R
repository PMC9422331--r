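test_that("fixed-criterion inference uses a strict boundary", {
  expect_equal(fc_infer(30, 30, kappa = 10), 1L)
  expect_equal(fc_infer(0, 90, kappa = 90), 2L)     # at the boundary: separate
  expect_equal(fc_infer(c(0, 0), c(10, 50), kappa = 30), c(1L, 2L))
})

test_that("Monte-Carlo FC curve agrees with the Gaussian closed form", {
  cur <- fc_integration_curve(90, 20, deltas = seq(0, 180, by = 15),
                              n = 40000, seed = 2)
  se <- sqrt(cur$p_int_exact * (1 - cur$p_int_exact) / 40000)
  expect_true(all(abs(cur$p_int - cur$p_int_exact) <= 3 * se + 1e-9))
  expect_equal(fc_closed_form(70, 90, 20), pnorm(1), tolerance = 1e-12)
  expect_equal(cur$p_int[cur$dtheta_uni == 90], 0.5, tolerance = 0.02)
  noiseless <- fc_integration_curve(90, 0, deltas = c(0, 89, 90, 180), n = 10)
  expect_equal(noiseless$p_int, c(1, 1, 0, 0))
})

test_that("fit_kappa recovers a planted criterion and handles edge targets", {
  target <- fc_integration_curve(120, 20, n = 50000, seed = 7)
  fit <- fit_kappa(target[, c("dtheta_uni", "p_int")], sigma_noise = 20)
  expect_equal(fit$kappa, 120, tolerance = 1)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "kappa"], fit$kappa)
  # a noise-free step-like target recovers the step location
  step_t <- tibble::tibble(dtheta_uni = seq(0, 180, by = 5),
                           p_int = as.numeric(seq(0, 180, by = 5) < 70))
  expect_equal(fit_kappa(step_t, sigma_noise = 3)$kappa, 70, tolerance = 3)
  ones <- tibble::tibble(dtheta_uni = seq(0, 180, by = 45), p_int = 1)
  expect_warning(f1 <- fit_kappa(ones, sigma_noise = 20), "degenerate")
  expect_equal(f1$kappa, 180, tolerance = 1)
})

test_that("the Bayesian posterior obeys its limits and a quadrature oracle", {
  expect_equal(bci_posterior(10, 60, prior = 1, sigma = 20), 1)
  expect_equal(bci_posterior(10, 60, prior = 0, sigma = 20), 0)
  p <- bci_posterior(45, 45, prior = 0.5, sigma = 20)
  expect_gt(p, 0.5)
  # brute-force quadrature over the common-source location
  quad_posterior <- function(xv, xe, prior, sigma, range = 360) {
    lik1 <- stats::integrate(function(s)
      dnorm(xv, s, sigma) * dnorm(xe, s, sigma) / range,
      -range / 2, range / 2)$value
    lik2 <- (stats::integrate(function(s) dnorm(xv, s, sigma) / range,
                              -range / 2, range / 2)$value) *
      (stats::integrate(function(s) dnorm(xe, s, sigma) / range,
                        -range / 2, range / 2)$value)
    prior * lik1 / (prior * lik1 + (1 - prior) * lik2)
  }
  for (case in list(c(0, 0), c(10, 40), c(-25, 35), c(0, 120))) {
    expect_equal(bci_posterior(case[1], case[2], 0.5, 20),
                 quad_posterior(case[1], case[2], 0.5, 20), tolerance = 1e-3)
  }
})

test_that("posterior is monotone in the prior and in the measured disparity", {
  priors <- seq(0.01, 0.99, length.out = 100)
  post_p <- bci_posterior(0, 30, priors, sigma = 25)
  expect_true(all(diff(post_p) > 0))
  disps <- seq(0, 180, length.out = 100)
  post_d <- bci_posterior(disps, 0, 0.5, sigma = 25)
  expect_true(all(diff(post_d) < 0))
})

test_that("the Bayesian report is strict at one half", {
  expect_equal(bci_report(0.51), 1L)
  expect_equal(bci_report(0.5), 2L)
  expect_equal(bci_report(0), 2L)
})

test_that("decision curves decrease with disparity and shift with the prior", {
  lo <- bci_decision_curve(0.4, 25, n = 20000, seed = 3)
  hi <- bci_decision_curve(0.7, 25, n = 20000, seed = 3)
  expect_true(all(diff(lo$p_common) <= 0.02))
  expect_true(all(hi$p_common >= lo$p_common - 1e-9))
  expect_gt(lo$p_common[1], 0.5)
  se <- sqrt(pmax(lo$p_common_exact * (1 - lo$p_common_exact), 1e-4) / 20000)
  expect_true(all(abs(lo$p_common - lo$p_common_exact) <= 4 * se))
})

test_that("fit_bci recovers a planted prior and fits sigma at fixed prior", {
  target <- bci_decision_curve(0.7, 30, n = 1e5, seed = 5)
  fit <- fit_bci(target[, c("dtheta_cue", "p_common")], sigma = 30,
                 fit = "prior")
  expect_equal(unname(fit$estimate["prior"]), 0.7, tolerance = 0.03)
  target_s <- bci_decision_curve(0.51, 20, n = 1e5, seed = 6)
  fit_s <- fit_bci(target_s[, c("dtheta_cue", "p_common")], prior = 0.51,
                   fit = "sigma")
  expect_equal(unname(fit_s$estimate["sigma"]), 20, tolerance = 1.5)
  ones <- tibble::tibble(dtheta_cue = seq(0, 180, by = 30), p_common = 1)
  expect_warning(f1 <- fit_bci(ones, sigma = 30), "flat")
  expect_gt(unname(f1$estimate["prior"]), 0.98)
  expect_equal(glance(fit)$term, "prior")
})
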