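#' Parameters of the leaky integrate-and-fire read-out neuron
#'
#' A single model MST-d neuron reads out the ring-network computation: the
#' group output of an upstream layer is converted to an afferent current and
#' integrated by a leaky integrate-and-fire membrane. Membrane constants
#' follow common cortical values (`tau_m = C/g_l = 20` ms, threshold -50 mV,
#' reset at the resting potential -65 mV); the current rescaling `alpha` and
#' the signal-detection threshold `thr` are calibrated so the
#' preferred-direction rate sits well above baseline.
#'
#' @param C Membrane capacitance (nF).
#' @param g_l Leak conductance (uS).
#' @param v_rest Resting potential, mV (-65).
#' @param v_thresh Spike threshold, mV.
#' @param v_reset Post-spike reset, mV.
#' @param alpha Input rescaling (current per unit group output above `thr`).
#' @param thr Signal-detection threshold on the group output.
#' @param dt Integration step, ms.
#' @return A list of class `"lif_params"`.
#' @export
lif_params <- function(C = 1, g_l = 0.05, v_rest = -65, v_thresh = -50,
                       v_reset = -65, alpha = 0.3, thr = 5, dt = 0.1) {
  if (v_thresh <= v_rest) stop("`v_thresh` must exceed `v_rest`", call. = FALSE)
  if (C <= 0 || g_l <= 0) stop("`C` and `g_l` must be positive", call. = FALSE)
  structure(list(C = C, g_l = g_l, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, alpha = alpha, thr = thr, dt = dt),
            class = "lif_params")
}

#' Group output of a ring layer
#'
#' Sum of the neuronal activities of one layer — the population signal an
#' upstream area transmits to the read-out neuron.
#'
#' @param y Activity vector (or matrix with one column per time point).
#' @return Scalar sum, or per-column sums for a matrix.
#' @export
group_output <- function(y) {
  if (is.matrix(y)) colSums(y) else sum(y)
}

#' Afferent stimulus current from a group output
#'
#' `I_sti = alpha (Y - thr)`, floored at zero below the detection threshold
#' (sub-threshold group activity injects no current rather than a
#' hyperpolarising drive).
#'
#' @param Y Group output(s).
#' @param params A [lif_params()].
#' @return Current(s).
#' @export
stimulus_current <- function(Y, params = lif_params()) {
  pmax(params$alpha * (Y - params$thr), 0)
}

#' Integrate-and-fire spike count from a current trace
#'
#' Explicit-Euler integration of `C dV/dt = -g_l (V - v_rest) + I(t)` with
#' spike-and-reset. The current trace is given on a (possibly coarser) time
#' grid and held constant within its steps.
#'
#' @param I Current values, one per `i_dt` interval.
#' @param i_dt Time step of the current trace, ms.
#' @param params A [lif_params()].
#' @return Firing rate in spikes/s over the trace duration.
#' @export
lif_rate <- function(I, i_dt, params = lif_params()) {
  dt <- params$dt
  v <- params$v_rest
  n_spk <- 0L
  steps_per <- max(1L, round(i_dt / dt))
  for (k in seq_along(I)) {
    for (s in seq_len(steps_per)) {
      v <- v + dt / params$C * (-params$g_l * (v - params$v_rest) + I[k])
      if (!is.finite(v)) stop("non-finite membrane potential", call. = FALSE)
      if (v >= params$v_thresh) { n_spk <- n_spk + 1L; v <- params$v_reset }
    }
  }
  1000 * n_spk / (length(I) * i_dt)
}

#' Direction tuning curve of the read-out neuron
#'
#' Simulates, for each probe direction, the upstream ring layer(s) driven by
#' an external input whose amplitude decays as the probe direction deviates
#' from the layer's assigned preference, converts the group output(s) to
#' afferent current and counts read-out spikes. In the bimodal condition the
#' subnetwork preference update is emulated by switching the input centres
#' from the unisensory preferences to the multisensory pair after 30 ms, and
#' the MT- and PIVC-derived currents are summed.
#'
#' @param modality `"visual"`, `"vestibular"` or `"bimodal"`.
#' @param thetas Probe directions, degrees.
#' @param pref_vis,pref_ves Unisensory preferred directions, degrees.
#' @param pref_vis_mul,pref_ves_mul Multisensory preferred pair (bimodal
#'   condition; defaults to the unisensory preferences).
#' @param stim_width Width (degrees) of the amplitude decay of the external
#'   input with probe-preference mismatch.
#' @param lif A [lif_params()].
#' @param params A [cann_params()] for the ring layers (noise-free here).
#' @param duration Simulated time per probe, ms.
#' @param ratio Synaptic ratio used for the forward weights in the bimodal
#'   condition.
#' @param switch_ms Preference-update time, ms (bimodal).
#' @return A tibble: `theta`, `rate` (spikes/s).
#' @export
lif_tuning_curve <- function(modality = c("visual", "vestibular", "bimodal"),
                             thetas = seq(0, 359, by = 15),
                             pref_vis = 90, pref_ves = 90,
                             pref_vis_mul = NULL, pref_ves_mul = NULL,
                             stim_width = 60, lif = lif_params(),
                             params = cann_params(), duration = 1000,
                             ratio = 1, switch_ms = 30) {
  modality <- match.arg(modality)
  pref_vis_mul <- pref_vis_mul %||% pref_vis
  pref_ves_mul <- pref_ves_mul %||% pref_ves
  fw <- forward_weights(ratio, params)
  rec <- params$dt
  one <- function(theta) {
    amp_v <- circ_gauss(circular_disparity(theta, pref_vis), stim_width)
    amp_e <- circ_gauss(circular_disparity(theta, pref_ves), stim_width)
    if (modality == "bimodal") {
      ph1 <- cann_run_batch_cpp(pref_vis, pref_ves, fw$w_dom, fw$w_sub,
                                amp_v, amp_e, params, 0, params$beta_scale,
                                switch_ms, 1, rec)
      ph2 <- cann_run_batch_cpp(pref_vis_mul, pref_ves_mul, fw$w_dom,
                                fw$w_sub, amp_v, amp_e, params, 0,
                                params$beta_scale, duration - switch_ms, 1,
                                rec, y0_ = ph1$y_end)
      I <- stimulus_current(c(ph1$sum_mt, ph2$sum_mt), lif) +
        stimulus_current(c(ph1$sum_pivc, ph2$sum_pivc), lif)
    } else {
      amp <- if (modality == "visual") c(amp_v, 0) else c(0, amp_e)
      res <- cann_run_batch_cpp(pref_vis, pref_ves, 0, 0, amp[1], amp[2],
                                params, 0, params$beta_scale, duration, 1,
                                rec)
      Y <- if (modality == "visual") res$sum_mt else res$sum_pivc
      I <- stimulus_current(as.vector(Y), lif)
    }
    lif_rate(I, rec, lif)
  }
  tibble::tibble(theta = thetas,
                 rate = vapply(thetas, one, numeric(1)))
}
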