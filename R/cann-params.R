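#' Parameters of the three-layer ring-attractor model
#'
#' Bundles every parameter of the hierarchical continuous-attractor model:
#' two unisensory ring layers (MT, visual; PIVC, vestibular) drive a
#' multisensory subnetwork through topologically aligned Gaussian forward
#' projections. All three rings share the same Mexican-hat lateral kernel and
#' sigmoid rate dynamics, integrated with explicit Euler steps.
#'
#' The published kernel, input and noise parameters are the defaults
#' (`w_ex = 5`, `sigma_ex = 10`, `w_in = 3`, `sigma_in = 70`,
#' `w_external = 25`, `sigma_external = 160`, `sigma_forward = 5`,
#' `sigma_noise = 6`; all widths in degrees on the 360-degree ring of 180
#' units). The sigmoid gain and offset, the time constant and the overall
#' forward-weight scale are not published; the shipped defaults come from a
#' calibration that places the noise-free one-to-two-bump bifurcation boundary
#' near 70 degrees for equal forward weights, rising to about 150 degrees at
#' ratio 2.6 (see the methods vignette). The calibrated forward scale is a
#' ratio-dependent profile interpolated through `forward_profile`.
#'
#' @param gain,offset Sigmoid activation `S(I) = 1/(1 + exp(-gain (I - offset)))`.
#' @param tau Time constant, ms.
#' @param dt Euler step, ms (must be < `tau`).
#' @param w_ex,sigma_ex,w_in,sigma_in Mexican-hat excitatory/inhibitory
#'   weights and ranges (`w_ex > w_in`, `sigma_ex < sigma_in`).
#' @param w_external,sigma_external External-input peak and range for the
#'   unisensory layers.
#' @param sigma_forward Forward-projection range, degrees.
#' @param sigma_noise Intrinsic-noise SD (per neuron and Euler step, injected
#'   inside the activation together with the other inputs).
#' @param beta_scale Multiplier on both lateral kernel components.
#' @param L Neurons per ring (2 degrees of direction per neuron).
#' @param duration Trial length, ms (inputs applied from t = 0 throughout).
#' @param window Analysis window `[t1, t2]`, ms, for the window-averaged
#'   bump disparity.
#' @param final_window Length, ms, of the terminal interval whose mean state
#'   is classified (suppresses noise flicker).
#' @param bump_threshold Activity threshold separating an effective
#'   population response from background (and from a runaway whole-ring
#'   response; both extremes are excluded).
#' @param forward_profile List with numeric `ratio` and `scale`: the
#'   calibrated overall forward-weight scale per synaptic ratio, linearly
#'   interpolated and clamped outside the knot range.
#' @return A list of class `"cann_params"`.
#' @export
cann_params <- function(gain = 1.0, offset = 24, tau = 20, dt = 2,
                        w_ex = 5, sigma_ex = 10, w_in = 3, sigma_in = 70,
                        w_external = 25, sigma_external = 160,
                        sigma_forward = 5, sigma_noise = 6, beta_scale = 1,
                        L = 180L, duration = 3000, window = c(500, 1500),
                        final_window = 100, bump_threshold = 0.15,
                        forward_profile = list(
                          ratio = c(1, 1.28, 1.8, 2.2, 2.6),
                          scale = c(5.32, 6.28, 6.15, 4.70, 4.20))) {
  if (dt >= tau) stop("`dt` must be smaller than `tau`", call. = FALSE)
  if (gain <= 0) stop("sigmoid `gain` must be positive", call. = FALSE)
  if (w_ex <= w_in) stop("`w_ex` must exceed `w_in`", call. = FALSE)
  if (sigma_ex >= sigma_in) stop("`sigma_ex` must be below `sigma_in`", call. = FALSE)
  if (sigma_noise < 0) stop("`sigma_noise` must be >= 0", call. = FALSE)
  if (any(c(sigma_ex, sigma_in, sigma_external, sigma_forward) <= 0))
    stop("all ranges must be positive", call. = FALSE)
  structure(list(
    gain = gain, offset = offset, tau = tau, dt = dt,
    w_ex = w_ex, sigma_ex = sigma_ex, w_in = w_in, sigma_in = sigma_in,
    w_external = w_external, sigma_external = sigma_external,
    sigma_forward = sigma_forward, sigma_noise = sigma_noise,
    beta_scale = beta_scale, L = as.integer(L), duration = duration,
    window = window, final_window = final_window,
    bump_threshold = bump_threshold, forward_profile = forward_profile
  ), class = "cann_params")
}

# ring positions in degrees
ring_positions <- function(params) (seq_len(params$L) - 1) * 360 / params$L

# pairwise circular distance matrix in degrees
ring_distance_matrix <- function(params) {
  L <- params$L
  idx <- abs(outer(seq_len(L), seq_len(L), "-"))
  (360 / L) * pmin(idx, L - idx)
}

#' Mexican-hat lateral connection weight
#'
#' Difference-of-Gaussians lateral weight at circular distance `d` degrees,
#' scaled by `beta_scale`. Self-connections (d = 0 between a neuron and
#' itself) are zero in the kernel matrix; this function evaluates the profile
#' itself.
#'
#' @param d Circular distance(s), degrees, in `[0, 180]`.
#' @param params A [cann_params()].
#' @return Weight(s): `beta_scale (w_ex exp(-d^2/2 sigma_ex^2) -
#'   w_in exp(-d^2/2 sigma_in^2))`.
#' @export
mexican_hat_weight <- function(d, params = cann_params()) {
  stopifnot(all(d >= 0), all(d <= 180))
  params$beta_scale *
    (params$w_ex * exp(-d^2 / (2 * params$sigma_ex^2)) -
     params$w_in * exp(-d^2 / (2 * params$sigma_in^2)))
}

# full lateral kernel matrix (zero diagonal)
lateral_kernel <- function(params) {
  W <- mexican_hat_weight(ring_distance_matrix(params), params)
  diag(W) <- 0
  W
}

#' External input profile over a ring layer
#'
#' Gaussian input centred at `center` whose intensity decays with circular
#' distance from the centre.
#'
#' @param center Input centre, degrees.
#' @param params A [cann_params()].
#' @param amplitude Multiplier on the peak weight `w_external`.
#' @return Numeric vector of length `L`.
#' @export
external_input <- function(center, params = cann_params(), amplitude = 1) {
  d <- circular_disparity(ring_positions(params), center)
  amplitude * params$w_external * exp(-d^2 / (2 * params$sigma_external^2))
}

#' Forward input to the multisensory subnetwork
#'
#' Gaussian-weighted, topologically aligned projection of the two unisensory
#' layer states. Each subnetwork neuron receives maximally weighted input from
#' the upstream neurons at its own ring position; the ratio of `w_mt` to
#' `w_pivc` is the synaptic ratio of the modelled neuron.
#'
#' @param y_mt,y_pivc Upstream activity vectors (length `L`).
#' @param w_mt,w_pivc Forward weights from MT and PIVC.
#' @param params A [cann_params()].
#' @return Input vector of length `L`.
#' @export
forward_input <- function(y_mt, y_pivc, w_mt, w_pivc, params = cann_params()) {
  if (length(y_mt) != params$L || length(y_pivc) != params$L)
    stop("upstream state length must match `L`", call. = FALSE)
  K <- exp(-ring_distance_matrix(params)^2 / (2 * params$sigma_forward^2))
  as.vector(K %*% (w_mt * y_mt + w_pivc * y_pivc))
}

#' Sigmoid rate activation
#'
#' Increasing logistic activation `S(I) = 1/(1 + exp(-gain (I - offset)))`,
#' bounding activities to (0, 1).
#'
#' @param I Input current(s).
#' @param params A [cann_params()].
#' @export
sigmoid_activation <- function(I, params = cann_params()) {
  1 / (1 + exp(-params$gain * (I - params$offset)))
}

#' One Euler step of the rate dynamics
#'
#' Reference (pure R) implementation of the update
#' `y <- y + (dt/tau) (-y + S(I_total + noise))` used by the compiled batch
#' integrator; useful for unit-level reasoning about the dynamics.
#'
#' @param y Activity vector.
#' @param total_input Summed lateral, external/forward input per neuron.
#' @param params A [cann_params()].
#' @param noise Optional pre-drawn noise vector added inside the activation.
#' @return Updated activity vector.
#' @export
cann_step <- function(y, total_input, params = cann_params(), noise = 0) {
  if (any(!is.finite(y))) stop("non-finite activity; aborting trial", call. = FALSE)
  y + (params$dt / params$tau) *
    (-y + sigmoid_activation(total_input + noise, params))
}

#' Forward weights implementing a synaptic ratio
#'
#' Maps a synaptic ratio r >= 1 to the pair of forward weights
#' (dominant, subordinate) with `w_dom / w_sub = r`. The overall scale is the
#' calibrated profile `forward_profile` interpolated at r.
#'
#' @param ratio Synaptic ratio(s), >= 1.
#' @param params A [cann_params()].
#' @return A list with numeric vectors `w_dom` and `w_sub`.
#' @export
forward_weights <- function(ratio, params = cann_params()) {
  if (any(ratio < 1)) stop("synaptic `ratio` must be >= 1", call. = FALSE)
  fp <- params$forward_profile
  scale <- stats::approx(fp$ratio, fp$scale, xout = ratio, rule = 2)$y
  list(w_dom = scale * ratio, w_sub = scale)
}
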