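#' Detect response bumps in a ring-layer state
#'
#' Thresholds a settled activity pattern and identifies contiguous
#' suprathreshold regions on the ring. One region is an integration
#' (common-bump) outcome; two regions are a separation outcome whose bump
#' disparity is the circular distance between the regions' activity-weighted
#' circular centres of mass. States with no suprathreshold neuron, with every
#' neuron suprathreshold (runaway response), or with more than two regions are
#' excluded.
#'
#' @param y Activity vector over the ring (length L).
#' @param threshold Effective-response threshold (default 0.15).
#' @param positions Ring positions in degrees (default `2 * (0:(L-1))`).
#' @return A list: `outcome` (`"one_bump"`, `"two_bumps"` or `"excluded"`),
#'   `n_regions`, `centers` (degrees) and `dtheta_mul` (0 for one bump, the
#'   centre disparity for two, `NA` when excluded).
#' @export
detect_bumps <- function(y, threshold = 0.15, positions = NULL) {
  L <- length(y)
  positions <- positions %||% ((seq_len(L) - 1) * 360 / L)
  m <- y > threshold
  if (!any(m) || all(m))
    return(list(outcome = "excluded", n_regions = if (all(m)) 1L else 0L,
                centers = numeric(0), dtheta_mul = NA_real_))
  # rotate so the run-length encoding never splits a wrapped region
  z <- which(!m)[1]
  rot <- c(z:L, seq_len(z - 1))
  mr <- m[rot]
  r <- rle(mr)
  n_regions <- sum(r$values)
  if (n_regions > 2L)
    return(list(outcome = "excluded", n_regions = as.integer(n_regions),
                centers = numeric(0), dtheta_mul = NA_real_))
  ends <- cumsum(r$lengths)
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  centers <- vapply(which(r$values), function(i) {
    seg <- rot[starts[i]:ends[i]]
    w <- y[seg]
    ang <- positions[seg] * pi / 180
    (atan2(sum(w * sin(ang)), sum(w * cos(ang))) * 180 / pi) %% 360
  }, numeric(1))
  if (n_regions == 1L)
    return(list(outcome = "one_bump", n_regions = 1L, centers = centers,
                dtheta_mul = 0))
  list(outcome = "two_bumps", n_regions = 2L, centers = centers,
       dtheta_mul = circular_disparity(centers[1], centers[2]))
}

# classify every column of a state matrix; returns a tibble
classify_states <- function(Y, threshold = 0.15) {
  out <- lapply(seq_len(ncol(Y)), function(i) detect_bumps(Y[, i], threshold))
  tibble::tibble(
    outcome = vapply(out, `[[`, "", "outcome"),
    n_regions = vapply(out, `[[`, 0L, "n_regions"),
    dtheta_mul = vapply(out, `[[`, 0, "dtheta_mul"))
}

# internal: run a batch through the compiled integrator.
# dtheta_uni, ratio, sigma_noise vectors are recycled to n trials; cues are
# placed symmetrically around ring position 90 (the ring is homogeneous).
cann_batch <- function(n, dtheta_uni, ratio, params, sigma_noise = NULL,
                       beta_scale = NULL, seed = 0, record_every = 0,
                       duration = NULL, dominant = NULL) {
  dtheta_uni <- rep_len(dtheta_uni, n)
  ratio <- rep_len(ratio, n)
  sigma_noise <- sigma_noise %||% params$sigma_noise
  beta_scale <- beta_scale %||% params$beta_scale
  duration <- duration %||% params$duration
  fw <- forward_weights(ratio, params)
  # random (or fixed) assignment of the dominant modality per trial
  dominant <- dominant %||% "random"
  if (identical(dominant, "random")) {
    set.seed(seed)
    vis_dom <- sample(c(TRUE, FALSE), n, replace = TRUE)
  } else vis_dom <- rep_len(identical(dominant, "visual"), n)
  w_mt <- ifelse(vis_dom, fw$w_dom, fw$w_sub)
  w_pivc <- ifelse(vis_dom, fw$w_sub, fw$w_dom)
  res <- cann_run_batch_cpp(
    theta_vis = 90 + dtheta_uni / 2, theta_ves = 90 - dtheta_uni / 2,
    w_mt = w_mt, w_pivc = w_pivc,
    amp_vis = rep(1, n), amp_ves = rep(1, n),
    par = params, sigma_noise = sigma_noise, beta_scale = beta_scale,
    duration = duration, seed = seed, record_every = record_every)
  res$w_mt <- w_mt; res$w_pivc <- w_pivc
  res$dtheta_uni <- dtheta_uni; res$ratio <- ratio
  res$sigma_noise <- sigma_noise; res$beta_scale <- beta_scale
  res
}

#' Run a batch of complete three-layer trials
#'
#' Applies the visual and vestibular inputs at t = 0, simulates the MT and
#' PIVC layers and the multisensory subnetwork for the full trial, and
#' classifies the final state of the subnetwork (mean over the terminal
#' `final_window`) into one-bump (integration), two-bump (separation) or
#' excluded outcomes.
#'
#' @param n Number of trials.
#' @param dtheta_uni Cue disparity (degrees), scalar or length-n vector.
#' @param ratio Synaptic ratio(s) >= 1, scalar or length-n.
#' @param params A [cann_params()].
#' @param sigma_noise,beta_scale Optional overrides of the parameter values.
#' @param seed Integer seed (noise-free runs are identical for any seed).
#' @param keep_states Attach the final-state matrices as attribute
#'   `"states"` (lists `mt`, `pivc`, `sub`).
#' @return A tibble with one row per trial: `trial`, `dtheta_uni`, `ratio`,
#'   `sigma_noise`, `beta_scale`, `outcome`, `n_regions`, `dtheta_mul`.
#' @export
run_trials <- function(n, dtheta_uni, ratio = 1, params = cann_params(),
                       sigma_noise = NULL, beta_scale = NULL, seed = 0,
                       keep_states = FALSE) {
  res <- cann_batch(n, dtheta_uni, ratio, params, sigma_noise, beta_scale,
                    seed = seed)
  cls <- classify_states(res$sub, params$bump_threshold)
  cls$outcome[!res$finite] <- "excluded"
  out <- tibble::tibble(
    trial = seq_len(n),
    dtheta_uni = res$dtheta_uni, ratio = res$ratio,
    sigma_noise = res$sigma_noise, beta_scale = res$beta_scale,
    outcome = cls$outcome, n_regions = cls$n_regions,
    dtheta_mul = cls$dtheta_mul)
  if (keep_states)
    attr(out, "states") <- list(mt = res$mt, pivc = res$pivc, sub = res$sub,
                                w_mt = res$w_mt, w_pivc = res$w_pivc)
  out
}

#' Run a single trial and track the bump disparity over time
#'
#' As [run_trials()] for one trial, but additionally records the subnetwork
#' state on a regular grid and derives the bump-disparity trajectory
#' `dtheta_mul(t)` plus its mean over the analysis window (`params$window`,
#' default 500-1500 ms). One-bump epochs contribute 0 degrees; excluded
#' epochs are dropped from the window mean.
#'
#' @inheritParams run_trials
#' @param record_every Recording interval, ms.
#' @return An object of class `"cann_trial"`: a list with the trial spec, the
#'   final `outcome`, bump `centers`, `dtheta_mul` (final), `window_mean`
#'   (window-averaged disparity, `NA` for excluded trials), the `trajectory`
#'   tibble (`time_ms`, `n_regions`, `dtheta_mul`) and the final-state
#'   activity vectors.
#' @export
run_trial <- function(dtheta_uni, ratio = 1, params = cann_params(),
                      sigma_noise = NULL, beta_scale = NULL, seed = 0,
                      record_every = 10) {
  res <- cann_batch(1L, dtheta_uni, ratio, params, sigma_noise, beta_scale,
                    seed = seed, record_every = record_every)
  thr <- params$bump_threshold
  final <- detect_bumps(res$sub[, 1], thr)
  if (!res$finite[1]) final$outcome <- "excluded"
  traj_states <- res$traj[, , 1]
  traj <- classify_states(traj_states, thr)
  traj <- tibble::tibble(time_ms = as.vector(res$times),
                         n_regions = traj$n_regions,
                         dtheta_mul = traj$dtheta_mul)
  in_win <- traj$time_ms >= params$window[1] & traj$time_ms <= params$window[2]
  window_mean <- if (final$outcome == "excluded") NA_real_ else
    mean(traj$dtheta_mul[in_win], na.rm = TRUE)
  structure(list(
    dtheta_uni = res$dtheta_uni[1], ratio = res$ratio[1],
    sigma_noise = res$sigma_noise, beta_scale = res$beta_scale,
    seed = seed, params = params,
    outcome = final$outcome, centers = final$centers,
    dtheta_mul = final$dtheta_mul, window_mean = window_mean,
    trajectory = traj,
    final_state = list(mt = res$mt[, 1], pivc = res$pivc[, 1],
                       sub = res$sub[, 1]),
    w_mt = res$w_mt[1], w_pivc = res$w_pivc[1]
  ), class = "cann_trial")
}

#' @export
print.cann_trial <- function(x, ...) {
  cat("<cann_trial> dtheta_uni =", x$dtheta_uni, "deg, ratio =",
      round(x$ratio, 3), ", sigma_noise =", x$sigma_noise, "\n")
  cat("  outcome:", x$outcome,
      if (x$outcome == "two_bumps")
        paste0("(dtheta_mul = ", round(x$dtheta_mul, 1), " deg)") else "",
      "\n")
  cat("  window-mean dtheta_mul:", round(x$window_mean, 1), "deg\n")
  invisible(x)
}

#' Lateral-to-forward input ratio in the settled subnetwork
#'
#' Ratio of the total recurrent (lateral) input to the total forward input
#' received by the bump-centre neuron (the activity maximum) of the settled
#' subnetwork, each input summed over its presynaptic sources. With the
#' published parameters and a one-bump trial the lateral drive is roughly a
#' fifth of the feedforward drive: subordinate in magnitude yet decisive for
#' the bifurcation.
#'
#' @param trial A `"cann_trial"` from [run_trial()].
#' @return The dimensionless input ratio.
#' @export
lateral_forward_ratio <- function(trial) {
  stopifnot(inherits(trial, "cann_trial"))
  p <- trial$params
  y <- trial$final_state$sub
  if (max(y) <= p$bump_threshold)
    stop("no suprathreshold response; run a one-bump trial", call. = FALSE)
  W <- lateral_kernel(p)
  I_r <- as.vector(W %*% y)
  I_f <- forward_input(trial$final_state$mt, trial$final_state$pivc,
                       trial$w_mt, trial$w_pivc, p)
  k <- which.max(y)
  if (I_f[k] == 0) stop("zero forward input at the bump centre", call. = FALSE)
  abs(I_r[k]) / I_f[k]
}
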