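#' Fixed-criterion causal inference of a single unit
#'
#' A unit with fixed boundary `kappa` infers a common cause (C = 1) when the
#' noisy measured disparity `|x_vis - x_ves| + xi` falls below `kappa`, and
#' separate causes (C = 2) otherwise; a measurement exactly at the boundary
#' reports separation. The boundary is explicit and independent of any
#' prior — a deterministic, non-Bayesian strategy.
#'
#' @param x_vis,x_ves Measured cue locations, degrees (vectorised).
#' @param kappa Criterion, degrees, in `[0, 180]`.
#' @param xi Measurement-noise draw(s) added to the disparity (default 0).
#' @return Integer vector of inferred causes (1 or 2).
#' @export
fc_infer <- function(x_vis, x_ves, kappa, xi = 0) {
  ifelse(abs(x_vis - x_ves) + xi < kappa, 1L, 2L)
}

#' Closed-form fixed-criterion integration probability
#'
#' With Gaussian disparity noise `xi ~ N(0, sigma_noise^2)` the probability
#' of inferring a common cause at true disparity `delta` is
#' `Phi((kappa - delta) / sigma_noise)`; with zero noise it is the step
#' function at `kappa`.
#'
#' @param delta True disparities, degrees.
#' @param kappa Criterion, degrees.
#' @param sigma_noise Noise SD, degrees (>= 0).
#' @return Integration probabilities.
#' @export
fc_closed_form <- function(delta, kappa, sigma_noise) {
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0", call. = FALSE)
  if (sigma_noise == 0) return(as.numeric(delta < kappa))
  stats::pnorm((kappa - delta) / sigma_noise)
}

#' Monte-Carlo fixed-criterion integration function
#'
#' Repeats the noisy fixed-criterion inference `n` times per disparity and
#' reports the integration fraction, alongside the closed-form probability.
#'
#' @param kappa Criterion, degrees.
#' @param sigma_noise Disparity-noise SD, degrees.
#' @param deltas Disparity grid, degrees.
#' @param n Repetitions per disparity (default 1e5).
#' @param seed Integer seed.
#' @return A tibble: `dtheta_uni`, `p_int`, `p_int_exact`.
#' @export
fc_integration_curve <- function(kappa, sigma_noise,
                                 deltas = seq(0, 180, by = 5), n = 1e5,
                                 seed = 0) {
  set.seed(seed)
  p <- vapply(deltas, function(d) {
    xi <- if (sigma_noise > 0) stats::rnorm(n, 0, sigma_noise) else 0
    mean(fc_infer(d, 0, kappa, xi) == 1L)
  }, numeric(1))
  tibble::tibble(dtheta_uni = deltas, p_int = p,
                 p_int_exact = fc_closed_form(deltas, kappa, sigma_noise))
}

#' Fit the fixed-criterion boundary to an integration function
#'
#' Least-squares fit of the closed-form fixed-criterion curve to a target
#' integration function, with the criterion `kappa` as the only free
#' parameter (bounded search on `[0, 180]`).
#'
#' @param target A tibble with columns `dtheta_uni` and `p_int` (values in
#'   `[0, 1]`; missing values dropped).
#' @param sigma_noise Fixed disparity-noise SD of the observer.
#' @return An object of class `"fc_fit"` with elements `kappa`,
#'   `sigma_noise`, `sse`, `fitted` and `target`.
#' @export
fit_kappa <- function(target, sigma_noise) {
  target <- target[stats::complete.cases(target[, c("dtheta_uni", "p_int")]), ]
  if (nrow(target) == 0) stop("empty target", call. = FALSE)
  if (max(target$p_int) - min(target$p_int) == 0)
    warning("constant target integration function; fit is degenerate")
  sse <- function(k)
    sum((fc_closed_form(target$dtheta_uni, k, sigma_noise) - target$p_int)^2)
  # coarse grid then golden-section refinement around the best cell
  grid <- seq(0, 180, by = 2)
  k0 <- grid[which.min(vapply(grid, sse, numeric(1)))]
  opt <- stats::optimize(sse, c(max(0, k0 - 2), min(180, k0 + 2)))
  fitted <- fc_closed_form(target$dtheta_uni, opt$minimum, sigma_noise)
  structure(list(kappa = opt$minimum, sigma_noise = sigma_noise,
                 sse = opt$objective, fitted = fitted, target = target),
            class = "fc_fit")
}

#' @export
print.fc_fit <- function(x, ...) {
  cat("<fc_fit> kappa =", round(x$kappa, 2), "deg (sigma_noise =",
      x$sigma_noise, "), sse =", signif(x$sse, 4), "\n")
  invisible(x)
}

#' Bayesian causal-inference posterior
#'
#' Posterior probability of a common cause given two measured cue locations,
#' under Gaussian measurement noise (`sigma_vis = sigma_ves = sigma`) and a
#' uniform common-source location prior of width `prior_range`. The
#' likelihood ratio then has the closed form
#' `P(x | C=1) / P(x | C=2) = prior_range * dnorm(x_vis - x_ves, 0,
#' sqrt(2) sigma)`, so the posterior depends on the measurements only through
#' their disparity.
#'
#' @param x_vis,x_ves Measured locations, degrees (vectorised).
#' @param prior Prior probability of a common cause, `P(C = 1)` in `[0, 1]`.
#' @param sigma Measurement SD, degrees (> 0).
#' @param prior_range Width of the uniform source prior, degrees.
#' @return Posterior probabilities `P(C = 1 | x_vis, x_ves)`.
#' @export
bci_posterior <- function(x_vis, x_ves, prior, sigma, prior_range = 360) {
  if (sigma <= 0) stop("`sigma` must be positive", call. = FALSE)
  if (any(prior < 0 | prior > 1)) stop("`prior` must lie in [0, 1]", call. = FALSE)
  lr <- prior_range * stats::dnorm(x_vis - x_ves, 0, sqrt(2) * sigma)
  num <- prior * lr
  num / (num + (1 - prior))
}

#' Binary report from the Bayesian posterior
#'
#' Reports integration when the posterior strictly exceeds 0.5; otherwise
#' separation (a posterior of exactly 0.5 reports separation).
#'
#' @param posterior Posterior probabilities in `[0, 1]`.
#' @return Integer vector of reported causes (1 or 2).
#' @export
bci_report <- function(posterior) ifelse(posterior > 0.5, 1L, 2L)

# closed-form decision curve: P(report C=1) as a function of cue disparity.
# The report criterion posterior > 0.5 is equivalent to |x_vis - x_ves| < c
# with c^2 = -4 sigma^2 log((1-p) sqrt(4 pi sigma^2) / (p prior_range)).
bci_closed_curve <- function(prior, sigma, deltas, prior_range = 360) {
  if (prior <= 0) return(rep(0, length(deltas)))
  if (prior >= 1) return(rep(1, length(deltas)))
  s2 <- sqrt(2) * sigma
  c2 <- -2 * s2^2 * log((1 - prior) * sqrt(2 * pi) * s2 /
                          (prior * prior_range))
  if (c2 <= 0) return(rep(0, length(deltas)))
  cc <- sqrt(c2)
  stats::pnorm((cc - deltas) / s2) - stats::pnorm((-cc - deltas) / s2)
}

#' Bayesian decision curve by Monte-Carlo sampling
#'
#' For each cue disparity, samples `x_vis ~ N(mu_vis, sigma)` and
#' `x_ves ~ N(mu_ves, sigma)` with `|mu_vis - mu_ves|` equal to the cue
#' disparity, reports via [bci_report()], and averages the reports.
#'
#' @param prior Prior probability of a common cause.
#' @param sigma Measurement SD, degrees.
#' @param deltas Cue-disparity grid, degrees.
#' @param n Repetitions per disparity (default 1e5).
#' @param seed Integer seed.
#' @param prior_range Width of the uniform source prior.
#' @return A tibble: `dtheta_cue`, `p_common`, `p_common_exact`.
#' @export
bci_decision_curve <- function(prior, sigma, deltas = seq(0, 180, by = 15),
                               n = 1e5, seed = 0, prior_range = 360) {
  set.seed(seed)
  p <- vapply(deltas, function(d) {
    xv <- stats::rnorm(n, d / 2, sigma)
    xe <- stats::rnorm(n, -d / 2, sigma)
    mean(bci_report(bci_posterior(xv, xe, prior, sigma, prior_range)) == 1L)
  }, numeric(1))
  tibble::tibble(dtheta_cue = deltas, p_common = p,
                 p_common_exact = bci_closed_curve(prior, sigma, deltas,
                                                   prior_range))
}

#' Fit the Bayesian observer to a decision curve
#'
#' Least-squares fit of the Bayesian decision curve to a target
#' `p_common(dtheta_cue)` curve. By default only the common-cause prior is
#' free (measurement SD fixed); with `fit = "sigma"` the measurement SD is
#' fitted instead at a fixed prior, the regime used to interpret sample-size
#' effects (larger populations behave like narrower measurement
#' distributions).
#'
#' @param target A tibble with columns `dtheta_cue` and `p_common`.
#' @param sigma Measurement SD (fixed when fitting the prior; initial
#'   bracket upper bound is 180 when fitting sigma).
#' @param prior Prior (fixed when fitting sigma; default 0.51).
#' @param fit `"prior"` or `"sigma"`.
#' @param prior_range Width of the uniform source prior.
#' @return An object of class `"bci_fit"` with the estimate, the fixed
#'   parameter, `sse`, `fitted` and `target`.
#' @export
fit_bci <- function(target, sigma = 30, prior = 0.51,
                    fit = c("prior", "sigma"), prior_range = 360) {
  fit <- match.arg(fit)
  target <- target[stats::complete.cases(
    target[, c("dtheta_cue", "p_common")]), ]
  if (nrow(target) == 0) stop("empty target", call. = FALSE)
  if (max(target$p_common) - min(target$p_common) == 0)
    warning("flat target decision curve; fit is degenerate")
  loss <- function(prior_, sigma_)
    sum((bci_closed_curve(prior_, sigma_, target$dtheta_cue, prior_range) -
           target$p_common)^2)
  if (fit == "prior") {
    opt <- stats::optimize(function(p) loss(p, sigma), c(0, 1))
    est <- c(prior = opt$minimum)
    fixed <- c(sigma = sigma)
    fitted <- bci_closed_curve(opt$minimum, sigma, target$dtheta_cue,
                               prior_range)
  } else {
    opt <- stats::optimize(function(s) loss(prior, s), c(0.5, 180))
    est <- c(sigma = opt$minimum)
    fixed <- c(prior = prior)
    fitted <- bci_closed_curve(prior, opt$minimum, target$dtheta_cue,
                               prior_range)
  }
  structure(list(estimate = est, fixed = fixed, sse = opt$objective,
                 prior_range = prior_range, fitted = fitted,
                 target = target, fit = fit),
            class = "bci_fit")
}

#' @export
print.bci_fit <- function(x, ...) {
  cat("<bci_fit>", names(x$estimate), "=", round(x$estimate, 4),
      "(fixed", names(x$fixed), "=", round(x$fixed, 4), "), sse =",
      signif(x$sse, 4), "\n")
  invisible(x)
}
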