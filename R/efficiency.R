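#' Inference efficiency of the balanced/imbalanced encoding bases
#'
#' Kullback-Leibler-style divergence between the integration functions of the
#' two encoders, `epsilon = sum(p_bal log2(p_imbal) - p_bal log2(p_bal))`
#' over the shared cue-disparity grid. The integration functions are not
#' probability distributions (they need not sum to one), so the terms are
#' evaluated point-wise on values clipped into `[delta, 1 - delta]`. For the
#' model's nested curves (the imbalanced function lies above the balanced
#' one) the statistic is zero for identical curves and grows as the curves
#' separate; the negated value (the formal KL divergence of `p_bal` from
#' `p_imbal`) is attached as attribute `"kl"`.
#'
#' @param p_bal,p_imbal Integration probabilities on a common disparity grid:
#'   numeric vectors, or tibbles with columns `dtheta_uni` and `p_int`.
#' @param delta Clipping bound (default `1e-6`).
#' @return Scalar efficiency with attribute `"kl"`.
#' @export
efficiency_bal_imbal <- function(p_bal, p_imbal, delta = 1e-6) {
  v <- align_curves(p_bal, p_imbal)
  p <- clip01(v$a, delta); q <- clip01(v$b, delta)
  eps <- sum(p * log2(q) - p * log2(p))
  structure(eps, kl = -eps)
}

#' Inference efficiency of the congruent/opposite encoding bases
#'
#' The congruent curve is the mean integration probability of neurons
#' preferring small disparities (0-90 degrees), pooled over the balanced and
#' imbalanced groups; the opposite curve is the pooled mean over 90-180
#' degrees. The two half-range curves are paired by offset within their
#' ranges and the divergence `epsilon' = sum(p_opp log2(p_cong) -
#' p_opp log2(p_opp))` is rescaled as `epsilon = 2 epsilon'` to align with
#' the balanced/imbalanced statistic computed over the full range.
#'
#' @param p_cong,p_opp Numeric vectors of equal length: the congruent curve
#'   on `[0, 90]` and the opposite curve on `[90, 180]`, paired by offset.
#' @param delta Clipping bound.
#' @return Scalar efficiency (`2 epsilon'`) with attribute `"kl"`.
#' @export
efficiency_cong_opp <- function(p_cong, p_opp, delta = 1e-6) {
  if (length(p_cong) != length(p_opp))
    stop("congruent and opposite curves must pair point-wise", call. = FALSE)
  if (length(p_cong) == 0) stop("empty half-range", call. = FALSE)
  pc <- clip01(p_cong, delta); po <- clip01(p_opp, delta)
  eps1 <- sum(po * log2(pc) - po * log2(po))
  structure(2 * eps1, kl = -2 * eps1)
}

clip01 <- function(p, delta) pmin(pmax(p, delta), 1 - delta)

# align two integration-function representations onto one grid
align_curves <- function(a, b) {
  get <- function(x) {
    if (is.data.frame(x)) {
      stopifnot(all(c("dtheta_uni", "p_int") %in% names(x)))
      x <- dplyr::arrange(x, .data$dtheta_uni)
      list(g = x$dtheta_uni, p = x$p_int)
    } else list(g = seq_along(x), p = as.numeric(x))
  }
  A <- get(a); B <- get(b)
  if (length(A$p) != length(B$p) || any(A$g != B$g))
    stop("integration functions must share one disparity grid", call. = FALSE)
  list(a = A$p, b = B$p)
}

#' Congruent and opposite pooled curves from an integration sweep
#'
#' Splits the disparity axis at 90 degrees, averages the integration
#' probability over the ratio conditions (both encoder groups), and pairs the
#' two half-range curves by offset for [efficiency_cong_opp()].
#'
#' @param sweep An [integration_sweep()] result at a single noise level with
#'   a disparity grid symmetric about 90 degrees.
#' @return A tibble with columns `offset`, `p_cong`, `p_opp`.
#' @export
cong_opp_curves <- function(sweep) {
  pooled <- dplyr::summarise(dplyr::group_by(sweep, .data$dtheta_uni),
                             p_int = mean(.data$p_int, na.rm = TRUE),
                             .groups = "drop")
  lo <- dplyr::filter(pooled, .data$dtheta_uni <= 90)
  hi <- dplyr::filter(pooled, .data$dtheta_uni >= 90)
  if (nrow(lo) != nrow(hi) || !90 %in% pooled$dtheta_uni)
    stop("disparity grid must be symmetric about 90 degrees", call. = FALSE)
  tibble::tibble(offset = lo$dtheta_uni, p_cong = lo$p_int, p_opp = hi$p_int)
}

#' Stochastic-resonance sweep of both encoding schemes
#'
#' For every noise level, simulates the integration functions of a typical
#' balanced (r = 1.28) and imbalanced (r = 2.35) neuron and computes the
#' inference efficiency of the balanced/imbalanced scheme and of the
#' congruent/opposite scheme. Moderate intrinsic noise maximises the
#' balanced/imbalanced efficiency (stochastic resonance), whereas the
#' congruent/opposite scheme peaks at low noise.
#'
#' @param noise_grid Noise SD grid (default covers `[0, 15]`).
#' @param ratios Typical group ratios (balanced first).
#' @param disparities Cue-disparity grid; must be symmetric about 90.
#' @param n_trials Trials per (noise, ratio, disparity) cell.
#' @param params A [cann_params()].
#' @param seed Integer seed.
#' @param delta Clipping bound for the efficiency statistics.
#' @param max_redraw Redraw rounds for excluded trials (high noise levels
#'   exclude many trials, so the cap bounds the sweep's cost).
#' @return A tibble of class `"sr_sweep"` with columns `sigma_noise`,
#'   `scheme` (`"balanced_imbalanced"` / `"congruent_opposite"`) and
#'   `epsilon`; the full per-cell sweep is attached as attribute `"sweep"`.
#' @export
sr_sweep <- function(noise_grid = c(0, 0.4, 0.8, 1.2, 2, 3, 4, 5, 6, 6.5, 7,
                                    8, 10, 12, 15),
                     ratios = c(1.28, 2.35),
                     disparities = seq(0, 180, by = 22.5),
                     n_trials = 60, params = cann_params(), seed = 0,
                     delta = 1e-6, max_redraw = 2) {
  seeds <- derive_seeds(seed, length(noise_grid))
  per_noise <- function(i) {
    sw <- integration_sweep(ratios, sigma_noise = noise_grid[i],
                            disparities = disparities, n_trials = n_trials,
                            params = params, seed = seeds[i],
                            max_redraw = max_redraw)
    bal <- dplyr::filter(sw, .data$ratio == ratios[1])
    imb <- dplyr::filter(sw, .data$ratio == ratios[2])
    co <- cong_opp_curves(sw)
    list(eff = tibble::tibble(
      sigma_noise = noise_grid[i],
      scheme = c("balanced_imbalanced", "congruent_opposite"),
      epsilon = c(as.numeric(efficiency_bal_imbal(bal, imb, delta)),
                  as.numeric(efficiency_cong_opp(co$p_cong, co$p_opp, delta)))),
      sweep = sw)
  }
  res <- lapply(seq_along(noise_grid), per_noise)
  out <- dplyr::bind_rows(lapply(res, `[[`, "eff"))
  attr(out, "sweep") <- dplyr::bind_rows(lapply(res, `[[`, "sweep"))
  class(out) <- c("sr_sweep", class(out))
  out
}

#' Optimal noise level of an efficiency curve
#'
#' @param eff An [sr_sweep()] result (or any tibble with `sigma_noise`,
#'   `scheme`, `epsilon`).
#' @param scheme Which encoding scheme to maximise over.
#' @return The noise level maximising the efficiency.
#' @export
sr_optimum <- function(eff, scheme = c("balanced_imbalanced",
                                       "congruent_opposite")) {
  scheme <- match.arg(scheme)
  e <- dplyr::filter(eff, .data$scheme == !!scheme)
  e$sigma_noise[which.max(e$epsilon)]
}
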