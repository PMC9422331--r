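#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a trial's bump-disparity trajectory
#'
#' @param object A `"cann_trial"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.cann_trial <- function(object, ...) {
  ggplot2::ggplot(object$trajectory,
                  ggplot2::aes(x = .data$time_ms, y = .data$dtheta_mul)) +
    ggplot2::geom_line(colour = "steelblue", na.rm = TRUE) +
    ggplot2::annotate("rect", xmin = object$params$window[1],
                      xmax = object$params$window[2], ymin = -Inf, ymax = Inf,
                      alpha = 0.08) +
    ggplot2::labs(x = "time (ms)", y = expression(Delta * theta["mul"] ~ (deg)),
                  title = sprintf(
                    "ratio %.2f, disparity %g deg, noise %g: %s",
                    object$ratio, object$dtheta_uni, object$sigma_noise,
                    object$outcome)) +
    ggplot2::theme_minimal()
}

#' Plot integration functions of a sweep
#'
#' @param sweep An [integration_sweep()] result.
#' @return A ggplot of `p_int` against cue disparity, coloured by ratio and
#'   faceted over noise levels when several are present.
#' @export
plot_integration_functions <- function(sweep) {
  p <- ggplot2::ggplot(sweep,
                       ggplot2::aes(x = .data$dtheta_uni, y = .data$p_int,
                                    colour = factor(.data$ratio),
                                    group = factor(.data$ratio))) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(Delta * theta["uni"] ~ (deg)),
                  y = expression(p["int"]), colour = "ratio") +
    ggplot2::ylim(0, 1) + ggplot2::theme_minimal()
  if (length(unique(sweep$sigma_noise)) > 1)
    p <- p + ggplot2::facet_wrap(~sigma_noise, labeller = ggplot2::label_both)
  p
}

#' Plot a stochastic-resonance efficiency sweep
#'
#' @param object An [sr_sweep()] result.
#' @param ... Unused.
#' @return A ggplot of efficiency against noise SD per encoding scheme.
#' @export
autoplot.sr_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma_noise,
                                       y = .data$epsilon,
                                       colour = .data$scheme)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = expression(sigma["noise"]),
                  y = expression(epsilon ~ "(a.u.)"), colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Plot a population decision curve
#'
#' @param object A `"decision_curve"`.
#' @param ... Unused.
#' @return A ggplot of `p_common` against cue disparity.
#' @export
autoplot.decision_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dtheta_cue,
                                       y = .data$p_common)) +
    ggplot2::geom_line(colour = "firebrick") + ggplot2::geom_point(size = 1) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = expression(Delta * theta["cue"] ~ (deg)),
                  y = expression(p["common"])) +
    ggplot2::theme_minimal()
}

#' Plot fitted observer curves over their targets
#'
#' @param object An `"fc_fit"` or `"bci_fit"`.
#' @param ... Unused.
#' @return A ggplot with the target points and the fitted curve.
#' @export
autoplot.fc_fit <- function(object, ...) {
  tg <- object$target
  fine <- tibble::tibble(dtheta_uni = seq(0, 180, by = 1))
  fine$p <- fc_closed_form(fine$dtheta_uni, object$kappa, object$sigma_noise)
  ggplot2::ggplot(tg, ggplot2::aes(x = .data$dtheta_uni, y = .data$p_int)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fine, ggplot2::aes(y = .data$p),
                       colour = "steelblue") +
    ggplot2::labs(x = expression(Delta * theta["uni"] ~ (deg)),
                  y = expression(p["int"]),
                  title = sprintf("fixed criterion fit: kappa = %.1f deg",
                                  object$kappa)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.fc_fit
#' @export
autoplot.bci_fit <- function(object, ...) {
  tg <- object$target
  pars <- c(object$estimate, object$fixed)
  fine <- tibble::tibble(dtheta_cue = seq(0, 180, by = 1))
  fine$p <- bci_closed_curve(pars[["prior"]], pars[["sigma"]],
                             fine$dtheta_cue, object$prior_range)
  ggplot2::ggplot(tg, ggplot2::aes(x = .data$dtheta_cue,
                                   y = .data$p_common)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fine, ggplot2::aes(y = .data$p),
                       colour = "steelblue") +
    ggplot2::labs(x = expression(Delta * theta["cue"] ~ (deg)),
                  y = expression(p["common"]),
                  title = sprintf("Bayesian fit: %s = %.3f",
                                  names(object$estimate), object$estimate)) +
    ggplot2::theme_minimal()
}
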