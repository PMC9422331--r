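#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fixed-criterion fit
#'
#' @param x An `"fc_fit"`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`, `fixed`).
#' @export
tidy.fc_fit <- function(x, ...) {
  tibble::tibble(term = c("kappa", "sigma_noise"),
                 estimate = c(x$kappa, x$sigma_noise),
                 fixed = c(FALSE, TRUE))
}

#' @rdname tidy.fc_fit
#' @export
glance.fc_fit <- function(x, ...) {
  tibble::tibble(kappa = x$kappa, sigma_noise = x$sigma_noise, sse = x$sse,
                 n = nrow(x$target))
}

#' Tidy a Bayesian-observer fit
#'
#' @param x A `"bci_fit"`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`, `fixed`).
#' @export
tidy.bci_fit <- function(x, ...) {
  tibble::tibble(term = c(names(x$estimate), names(x$fixed)),
                 estimate = c(unname(x$estimate), unname(x$fixed)),
                 fixed = c(FALSE, TRUE))
}

#' @rdname tidy.bci_fit
#' @export
glance.bci_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate),
                 sse = x$sse, n = nrow(x$target))
}

#' Tidy a simulated trial
#'
#' @param x A `"cann_trial"`.
#' @param ... Unused.
#' @return The bump-disparity trajectory (`time_ms`, `n_regions`,
#'   `dtheta_mul`).
#' @export
tidy.cann_trial <- function(x, ...) x$trajectory

#' @rdname tidy.cann_trial
#' @export
glance.cann_trial <- function(x, ...) {
  tibble::tibble(dtheta_uni = x$dtheta_uni, ratio = x$ratio,
                 sigma_noise = x$sigma_noise, beta_scale = x$beta_scale,
                 outcome = x$outcome, dtheta_mul = x$dtheta_mul,
                 window_mean = x$window_mean)
}
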