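#' Configuration of the population sampling decision
#'
#' A downstream decision neuron pools a small sample of MST-d neurons:
#' `n_bal` balanced and `n_imbal` imbalanced (3:2 by default, following the
#' recorded 70:45 proportion). On each trial every sampled neuron draws a
#' preferred disparity from its group's distribution and responds through its
#' group's response template at the mismatch between preference and the
#' applied cue disparity; responses are scaled by the group reliability
#' factors `alpha`. The decision neuron compares the summed group responses:
#' separation is reported when the balanced (separation-encoding) group
#' responds at least as strongly as the imbalanced (integration-encoding)
#' group, integration otherwise.
#'
#' @param n_bal,n_imbal Sampled neurons per group (defaults 9 and 6).
#' @param alpha_bal,alpha_imbal Response scale factors in `(0, 1]`
#'   (lowering one emulates reduced reliability of the cue that group
#'   tracks); `alpha_bal = 0` is allowed for silencing tests.
#' @param d_bal,d_imbal Preferred-disparity distributions (tibbles with
#'   `disparity`, `prob`; defaults from
#'   [make_disparity_distributions()]`("paper_like")`).
#' @param f_bal,f_imbal Response templates (defaults from
#'   [make_response_template()]).
#' @param n_rep Decision repetitions per cue disparity (default 1e5).
#' @param seed Integer seed.
#' @return A list of class `"decision_config"`.
#' @export
decision_config <- function(n_bal = 9, n_imbal = 6,
                            alpha_bal = 1, alpha_imbal = 1,
                            d_bal = NULL, d_imbal = NULL,
                            f_bal = NULL, f_imbal = NULL,
                            n_rep = 1e5, seed = 0) {
  if (n_bal < 0 || n_imbal < 0 || n_bal + n_imbal < 1)
    stop("sample sizes must be non-negative with at least one neuron",
         call. = FALSE)
  if (alpha_bal < 0 || alpha_bal > 1 || alpha_imbal < 0 || alpha_imbal > 1)
    stop("`alpha` factors must lie in [0, 1]", call. = FALSE)
  dd <- make_disparity_distributions("paper_like")
  structure(list(
    n_bal = as.integer(n_bal), n_imbal = as.integer(n_imbal),
    alpha_bal = alpha_bal, alpha_imbal = alpha_imbal,
    d_bal = d_bal %||% dd$balanced, d_imbal = d_imbal %||% dd$imbalanced,
    f_bal = f_bal %||% make_response_template("balanced"),
    f_imbal = f_imbal %||% make_response_template("imbalanced"),
    n_rep = as.integer(n_rep), seed = as.integer(seed)
  ), class = "decision_config")
}

# group response values at one cue disparity: template evaluated at the
# mismatch |preferred - cue| for each disparity bin
group_response_values <- function(dist, template, alpha, dtheta_cue) {
  alpha * template_response(template, abs(dist$disparity - dtheta_cue))
}

#' One population decision
#'
#' Draws the sampled preferences, sums the scaled group responses and
#' reports; ties (balanced sum equal to imbalanced sum) report separation.
#'
#' @param dtheta_cue Cue disparity, degrees.
#' @param config A [decision_config()].
#' @param seed Integer seed.
#' @return `"common"` or `"separate"`.
#' @export
single_decision <- function(dtheta_cue, config = decision_config(),
                            seed = config$seed) {
  set.seed(seed)
  rb <- group_response_values(config$d_bal, config$f_bal, config$alpha_bal,
                              dtheta_cue)
  ri <- group_response_values(config$d_imbal, config$f_imbal,
                              config$alpha_imbal, dtheta_cue)
  ib <- sample(seq_len(5), config$n_bal, replace = TRUE,
               prob = config$d_bal$prob)
  ii <- sample(seq_len(5), config$n_imbal, replace = TRUE,
               prob = config$d_imbal$prob)
  if (sum(rb[ib]) - sum(ri[ii]) >= 0) "separate" else "common"
}

#' Decision curve of the sampling population
#'
#' Repeats the population decision `n_rep` times per cue disparity and
#' reports the probability of a common-source report. Because each sampled
#' neuron contributes one of five template values, the group sums are
#' tabulated through multinomial draws over the disparity bins, which keeps
#' the 1e5-repetition default fast and exactly equivalent to per-neuron
#' sampling.
#'
#' @param config A [decision_config()].
#' @param deltas Cue-disparity grid, degrees.
#' @param seed Integer seed (defaults to the config seed).
#' @return A tibble of class `"decision_curve"`: `dtheta_cue`, `p_common`,
#'   with the config attached as attribute.
#' @export
decision_curve <- function(config = decision_config(),
                           deltas = seq(0, 180, by = 15),
                           seed = config$seed) {
  seeds <- derive_seeds(seed, length(deltas))
  p <- vapply(seq_along(deltas), function(i) {
    d <- deltas[i]
    rb <- group_response_values(config$d_bal, config$f_bal,
                                config$alpha_bal, d)
    ri <- group_response_values(config$d_imbal, config$f_imbal,
                                config$alpha_imbal, d)
    set.seed(seeds[i])
    cb <- if (config$n_bal > 0)
      stats::rmultinom(config$n_rep, config$n_bal, config$d_bal$prob)
      else matrix(0, 5, config$n_rep)
    ci <- if (config$n_imbal > 0)
      stats::rmultinom(config$n_rep, config$n_imbal, config$d_imbal$prob)
      else matrix(0, 5, config$n_rep)
    mean(colSums(cb * rb) - colSums(ci * ri) < 0)
  }, numeric(1))
  out <- tibble::tibble(dtheta_cue = deltas, p_common = p)
  attr(out, "config") <- config
  class(out) <- c("decision_curve", class(out))
  out
}

#' Decision curves across population sample sizes
#'
#' Repeats [decision_curve()] for a set of total sample sizes, keeping the
#' 3:2 balanced:imbalanced proportion (sizes that do not divide exactly are
#' rounded, with a warning). Larger samples average away sampling noise in
#' the group sums, steepening the decision function — the signature of
#' decisions made with more confidence.
#'
#' @param total_sizes Total numbers of sampled neurons (>= 5).
#' @param config Base [decision_config()].
#' @param deltas Cue-disparity grid.
#' @param seed Integer seed.
#' @return A tibble with columns `total_size`, `dtheta_cue`, `p_common` and
#'   `midpoint_slope` (per-degree decrease of `p_common` at the curve
#'   midpoint, repeated within size).
#' @export
sample_size_sweep <- function(total_sizes = c(15, 50, 150),
                              config = decision_config(),
                              deltas = seq(0, 180, by = 15), seed = 0) {
  if (any(total_sizes < 5)) stop("total sizes must be >= 5", call. = FALSE)
  seeds <- derive_seeds(seed, length(total_sizes))
  one <- function(i) {
    n <- total_sizes[i]
    nb <- round(n * 3 / 5); ni <- n - nb
    if (abs(nb / ni - 1.5) > 1e-8)
      warning("total size ", n, " rounded to ", nb, ":", ni,
              " to keep the 3:2 proportion", call. = FALSE)
    cfg <- config
    cfg$n_bal <- as.integer(nb); cfg$n_imbal <- as.integer(ni)
    cur <- decision_curve(cfg, deltas, seed = seeds[i])
    tibble::tibble(total_size = n, dtheta_cue = cur$dtheta_cue,
                   p_common = cur$p_common,
                   midpoint_slope = midpoint_slope(cur))
  }
  dplyr::bind_rows(lapply(seq_along(total_sizes), one))
}

#' Midpoint steepness of a decision curve
#'
#' Largest local decrease of `p_common` per degree around the point where
#' the curve crosses its own mid-level; a summary of decision confidence.
#'
#' @param curve A tibble with `dtheta_cue` and `p_common`.
#' @return Slope magnitude (probability per degree).
#' @export
midpoint_slope <- function(curve) {
  curve <- dplyr::arrange(curve, .data$dtheta_cue)
  dp <- -diff(curve$p_common) / diff(curve$dtheta_cue)
  mid <- (max(curve$p_common) + min(curve$p_common)) / 2
  below <- which(curve$p_common <= mid)[1]
  if (is.na(below) || below == 1) return(max(dp))
  max(dp[max(1, below - 2):min(length(dp), below + 1)])
}
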