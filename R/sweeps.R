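#' Noise-free bifurcation boundary
#'
#' Smallest cue disparity at which a noise-free trial settles into two
#' independent response regions instead of one common bump, located by a
#' coarse sweep refined to 1-degree resolution. The boundary acts as the
#' fixed criterion of the modelled neuron and grows with the synaptic ratio.
#'
#' @param ratio Synaptic ratio >= 1.
#' @param params A [cann_params()].
#' @param coarse_step Step (degrees) of the initial sweep.
#' @param resolution Refinement step, degrees.
#' @return Boundary in degrees, or `NA` if no transition occurs in
#'   `[0, 180]`.
#' @export
noise_free_boundary <- function(ratio, params = cann_params(),
                                coarse_step = 10, resolution = 1) {
  two_at <- function(d) {
    tr <- run_trials(1L, d, ratio, params, sigma_noise = 0, seed = 1L)
    tr$outcome == "two_bumps"
  }
  coarse <- seq(0, 180, by = coarse_step)
  hit <- vapply(coarse, two_at, logical(1))
  i <- which(hit)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(0)
  for (d in seq(coarse[i - 1] + resolution, coarse[i], by = resolution))
    if (two_at(d)) return(d)
  coarse[i]
}

#' Integration functions across conditions
#'
#' For every combination of synaptic ratio, noise level, lateral scale and
#' cue disparity, runs `n_trials` classified trials and tabulates the
#' integration probability `p_int = n_int / (n_int + n_sep)`. Excluded trials
#' are re-drawn (with fresh noise) until the per-cell count is met or
#' `max_redraw` rounds are exhausted; remaining shortfalls are reported in
#' `n_excluded`.
#'
#' @param ratios,sigma_noise,beta_scales Condition grids (combined fully).
#' @param disparities Cue-disparity grid, degrees.
#' @param n_trials Classified trials per cell.
#' @param params A [cann_params()].
#' @param seed Integer seed.
#' @param max_redraw Redraw rounds for excluded trials.
#' @return A tibble with columns `ratio`, `sigma_noise`, `beta_scale`,
#'   `dtheta_uni`, `n_int`, `n_sep`, `n_excluded`, `p_int`.
#' @export
integration_sweep <- function(ratios, sigma_noise = 6, beta_scales = 1,
                              disparities = seq(0, 180, by = 45),
                              n_trials = 200, params = cann_params(),
                              seed = 0, max_redraw = 5) {
  grid <- tidyr::expand_grid(ratio = ratios, sigma_noise = sigma_noise,
                             beta_scale = beta_scales,
                             dtheta_uni = disparities)
  seeds <- derive_seeds(seed, nrow(grid) * (max_redraw + 1))
  dim(seeds) <- c(nrow(grid), max_redraw + 1)
  cell <- function(i) {
    g <- grid[i, ]
    n_int <- 0L; n_sep <- 0L; need <- n_trials
    for (round in seq_len(max_redraw + 1)) {
      tr <- run_trials(need, g$dtheta_uni, g$ratio, params,
                       sigma_noise = g$sigma_noise,
                       beta_scale = g$beta_scale,
                       seed = seeds[i, round])
      n_int <- n_int + sum(tr$outcome == "one_bump")
      n_sep <- n_sep + sum(tr$outcome == "two_bumps")
      need <- n_trials - n_int - n_sep
      if (need <= 0L) break
    }
    tibble::tibble(g, n_int = n_int, n_sep = n_sep,
                   n_excluded = max(need, 0L),
                   p_int = if (n_int + n_sep > 0)
                     n_int / (n_int + n_sep) else NA_real_)
  }
  dplyr::bind_rows(lapply(seq_len(nrow(grid)), cell))
}

#' Disparity-averaged integration probability per ratio
#'
#' Averages `p_int` over the cue-disparity grid for each condition, the
#' summary used to classify model neurons into integration and separation
#' encoders.
#'
#' @param sweep Output of [integration_sweep()].
#' @return A tibble with one row per (`ratio`, `sigma_noise`, `beta_scale`)
#'   and column `p_int_bar`.
#' @export
group_mean_pint <- function(sweep) {
  dplyr::summarise(
    dplyr::group_by(sweep, .data$ratio, .data$sigma_noise, .data$beta_scale),
    p_int_bar = mean(.data$p_int, na.rm = TRUE), .groups = "drop")
}

#' Ratio at which the disparity-averaged integration probability crosses 50%
#'
#' Locates the synaptic ratio where `p_int_bar` crosses `level` by linear
#' interpolation. Because each point carries Monte-Carlo error while the
#' underlying curve rises monotonically with the ratio, the sequence is
#' isotonically smoothed (non-decreasing least-squares fit) before the
#' crossing is interpolated.
#'
#' @param gm Output of [group_mean_pint()] (single noise/beta condition).
#' @param level Crossing level (default 0.5).
#' @param smooth Apply isotonic smoothing first (default `TRUE`).
#' @return The crossing ratio, or `NA` if the curve does not cross.
#' @export
pint_crossing <- function(gm, level = 0.5, smooth = TRUE) {
  gm <- dplyr::arrange(gm, .data$ratio)
  x <- gm$ratio; y <- gm$p_int_bar
  if (smooth && length(y) > 2) y <- stats::isoreg(x, y)$yf
  above <- y >= level
  if (all(above)) return(x[1])
  if (!any(above)) return(NA_real_)
  i <- which(above)[1]
  if (i == 1L) return(x[1])
  x[i - 1] + (level - y[i - 1]) / (y[i] - y[i - 1]) * (x[i] - x[i - 1])
}

#' Group experiment: population of trials with sampled ratios and disparities
#'
#' Emulates the 1000-trial group simulations: each trial draws its synaptic
#' ratio from the balanced or imbalanced ratio distribution and its cue
#' disparity from the 8 x 8 stimulus-pairing disparity mix
#' `{0: 1/8, 45: 1/4, 90: 1/4, 135: 1/4, 180: 1/8}`, then runs a full
#' three-layer trial at the default noise level. Excluded trials are re-drawn
#' up to `max_redraw` rounds so the classified count reaches `n_trials`.
#'
#' @param group `"balanced"` (ratios on `[1, 1.7]`, mean 1.28) or
#'   `"imbalanced"` (ratios on `[1.7, 4]`, mean 2.35).
#' @param n_trials Number of classified trials (default 1000).
#' @param params A [cann_params()].
#' @param seed Integer seed.
#' @param config A [generator_config()] supplying the ratio ranges and means.
#' @param max_redraw Redraw rounds for excluded trials.
#' @return A tibble of classified trials (as [run_trials()]), with the
#'   outcome fractions in `attr(, "fractions")`.
#' @export
group_outcome_experiment <- function(group = c("balanced", "imbalanced"),
                                     n_trials = 1000, params = cann_params(),
                                     seed = 0, config = generator_config(),
                                     max_redraw = 5) {
  group <- match.arg(group)
  rng <- if (group == "balanced") config$r_balanced_range else
    config$r_imbalanced_range
  mu <- if (group == "balanced") config$r_balanced_mean else
    config$r_imbalanced_mean
  mix_d <- c(0, 45, 90, 135, 180)
  mix_p <- c(1, 2, 2, 2, 1) / 8
  seeds <- derive_seeds(seed, 3 * (max_redraw + 1))
  out <- list(); got <- 0L
  for (round in seq_len(max_redraw + 1)) {
    need <- n_trials - got
    if (need <= 0L) break
    set.seed(seeds[3 * round - 2])
    ratios <- rtrunc_exp(need, rng, mu)
    set.seed(seeds[3 * round - 1])
    disps <- sample(mix_d, need, replace = TRUE, prob = mix_p)
    tr <- run_trials(need, disps, ratios, params, seed = seeds[3 * round])
    tr <- tr[tr$outcome != "excluded", ]
    out[[round]] <- tr
    got <- got + nrow(tr)
  }
  res <- dplyr::bind_rows(out)
  res$trial <- seq_len(nrow(res))
  attr(res, "group") <- group
  attr(res, "fractions") <- c(
    one_bump = mean(res$outcome == "one_bump"),
    two_bumps = mean(res$outcome == "two_bumps"))
  res
}
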