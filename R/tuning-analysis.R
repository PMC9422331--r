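#' Repeat averaging with single-outlier removal
#'
#' Mean of the repeats after removing the single repeat deviating most (in
#' absolute value) from the median; ties remove the first such repeat. At
#' least three repeats are required — recordings with fewer repetitions are
#' excluded from analysis.
#'
#' @param x Numeric vector of per-repeat rates.
#' @return Mean of the remaining repeats.
#' @export
average_repeats <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 3)
    stop("fewer than three repetitions; condition excluded", call. = FALSE)
  drop <- which.max(abs(x - stats::median(x)))
  mean(x[-drop])
}

#' Window selection and trial averaging of binned responses
#'
#' Restricts 25-ms-binned trial responses to an analysis window, averages
#' bins within each trial, then averages repeats per stimulus condition with
#' single-outlier removal ([average_repeats()]).
#'
#' @param binned A data frame with columns `condition`, `theta_vis`,
#'   `theta_ves`, `rep`, `time_ms` (bin start) and `rate`.
#' @param window `[start, end)` in ms (default the validity window
#'   625-1250 ms).
#' @return A tibble with one row per stimulus condition and column
#'   `mean_rate`.
#' @export
select_window_and_average <- function(binned, window = c(625, 1250)) {
  stopifnot(all(c("condition", "theta_vis", "theta_ves", "rep", "time_ms",
                  "rate") %in% names(binned)))
  w <- dplyr::filter(binned, .data$time_ms >= window[1],
                     .data$time_ms < window[2])
  if (nrow(w) == 0) stop("no bins fall inside the window", call. = FALSE)
  per_trial <- dplyr::summarise(
    dplyr::group_by(w, .data$condition, .data$theta_vis, .data$theta_ves,
                    .data$rep),
    rate = mean(.data$rate), .groups = "drop")
  dplyr::summarise(
    dplyr::group_by(per_trial, .data$condition, .data$theta_vis,
                    .data$theta_ves),
    mean_rate = average_repeats(.data$rate), .groups = "drop")
}

#' Discriminative-tuning filter
#'
#' A neuron passes when, in both unisensory conditions, the maximum response
#' exceeds the minimum response of the same curve by at least
#' `threshold` spikes/s. Neurons failing either curve are treated as
#' unisensory-tuned or poorly tuned and removed from multisensory analysis.
#'
#' @param visual_curve,vestibular_curve Mean rates over the 8 directions.
#' @param threshold Span threshold, spikes/s (default 5).
#' @return Logical flag.
#' @export
discriminative_filter <- function(visual_curve, vestibular_curve,
                                  threshold = 5) {
  span <- function(x) max(x) - min(x)
  span(visual_curve) >= threshold && span(vestibular_curve) >= threshold
}

#' Response ratio between the two unisensory maxima
#'
#' `r = max(R_vis_max, R_ves_max) / min(R_vis_max, R_ves_max)`, with
#' `R_vis_max`/`R_ves_max` the maximal responses of the visual and vestibular
#' tuning curves. By definition r >= 1.
#'
#' @param visual_curve,vestibular_curve Mean rates over the 8 directions.
#' @return The response ratio.
#' @export
response_ratio <- function(visual_curve, vestibular_curve) {
  mv <- max(visual_curve); me <- max(vestibular_curve)
  if (min(mv, me) <= 0)
    stop("both curves need a positive maximal response", call. = FALSE)
  max(mv, me) / min(mv, me)
}

#' Balanced/imbalanced classification by response ratio
#'
#' Balanced neurons have `1 <= r <= threshold`; larger ratios are imbalanced.
#' A ratio exactly at the threshold is assigned to the balanced group.
#'
#' @param r Response ratio(s), >= 1.
#' @param threshold Classification threshold (default 1.7).
#' @return Character vector `"balanced"`/`"imbalanced"`.
#' @export
classify_neuron <- function(r, threshold = 1.7) {
  if (any(r < 1)) stop("response ratio must be >= 1", call. = FALSE)
  ifelse(r <= threshold, "balanced", "imbalanced")
}

#' Multisensory preference from the 8 x 8 response grid
#'
#' Locates the grid argmax — the preferred pair of visual and vestibular
#' directions under bimodal stimulation — and its circular disparity. Ties
#' are resolved toward the smallest disparity, then the smallest visual then
#' vestibular direction. A grid with all cells equal carries no preference
#' and is flagged degenerate.
#'
#' @param grid 8 x 8 matrix of mean rates; rows index the visual direction,
#'   columns the vestibular direction, both on `seq(0, 315, by = 45)`.
#' @return A list: `theta_vis_pref`, `theta_ves_pref`, `dtheta_mul`,
#'   `degenerate`.
#' @export
multisensory_preference <- function(grid) {
  stopifnot(is.matrix(grid), nrow(grid) == 8, ncol(grid) == 8)
  if (max(grid) - min(grid) == 0)
    return(list(theta_vis_pref = NA_real_, theta_ves_pref = NA_real_,
                dtheta_mul = NA_real_, degenerate = TRUE))
  hits <- which(grid == max(grid), arr.ind = TRUE)
  tv <- directions8[hits[, "row"]]
  te <- directions8[hits[, "col"]]
  dd <- circular_disparity(tv, te)
  o <- order(dd, tv, te)[1]
  list(theta_vis_pref = tv[o], theta_ves_pref = te[o], dtheta_mul = dd[o],
       degenerate = FALSE)
}

#' Rectify a preferred-disparity distribution
#'
#' Because directions are binned at 45-degree intervals, the 0- and
#' 180-degree disparity bins cover half the angular width of the interior
#' bins; doubling the end-bin masses aligns the bin widths. The result is
#' renormalised to sum to one so it can serve as a sampling distribution.
#'
#' @param counts Non-negative counts (or probabilities) over the bins
#'   `c(0, 45, 90, 135, 180)`.
#' @return A tibble with columns `disparity` and `prob`.
#' @export
rectify_distribution <- function(counts) {
  if (length(counts) != 5 || any(counts < 0))
    stop("`counts` must be 5 non-negative values over {0,45,...,180}",
         call. = FALSE)
  if (sum(counts) == 0) stop("all-zero counts cannot be rectified", call. = FALSE)
  w <- counts * c(2, 1, 1, 1, 2)
  tibble::tibble(disparity = disparity_bins, prob = w / sum(w))
}

#' Integration/separation encoding label
#'
#' Balanced neurons with multisensory preferred disparity in `{0, 45}` encode
#' integration and in `{90, 135, 180}` separation. Imbalanced neurons encode
#' integration in `{0, 45}` and separation in `{135, 180}`; imbalanced
#' neurons at 90 degrees are rare in both model and data and are omitted.
#'
#' @param group `"balanced"`/`"imbalanced"` (vectorised).
#' @param dtheta_mul Grid-valued disparity in `{0, 45, 90, 135, 180}`.
#' @return Character vector: `"integration"`, `"separation"` or `"omitted"`.
#' @export
encoding_label <- function(group, dtheta_mul) {
  stopifnot(all(group %in% c("balanced", "imbalanced")))
  out <- dplyr::case_when(
    dtheta_mul <= 45 ~ "integration",
    group == "balanced" & dtheta_mul >= 90 ~ "separation",
    group == "imbalanced" & dtheta_mul >= 135 ~ "separation",
    TRUE ~ "omitted")
  out
}

#' Per-neuron tuning analysis of a dataset
#'
#' Runs the full physiological analysis on a long-format tuning dataset:
#' repeat averaging with outlier removal, the discriminative-tuning filter,
#' the response ratio and balanced/imbalanced classification, unisensory and
#' multisensory preferred directions and disparities, and the encoding label.
#'
#' @param dataset A tuning dataset (from [generate_dataset()],
#'   [read_dataset()], or any tibble with the same long format).
#' @param ratio_threshold Balanced/imbalanced threshold (default 1.7).
#' @param filter_threshold Discriminative-filter span, spikes/s (default 5).
#' @return A tibble with one row per neuron: `neuron_id`, `r`, `group`,
#'   `passes_filter`, preferred directions, `dtheta_uni`, `dtheta_mul`,
#'   `degenerate` and `encoding`.
#' @export
analyze_neurons <- function(dataset, ratio_threshold = 1.7,
                            filter_threshold = 5) {
  means <- dplyr::summarise(
    dplyr::group_by(dataset, .data$neuron_id, .data$condition,
                    .data$theta_vis, .data$theta_ves),
    mean_rate = average_repeats(.data$rate), .groups = "drop")
  one <- function(d) {
    vis <- dplyr::arrange(dplyr::filter(d, .data$condition == "visual"),
                          .data$theta_vis)
    ves <- dplyr::arrange(dplyr::filter(d, .data$condition == "vestibular"),
                          .data$theta_ves)
    bi <- dplyr::filter(d, .data$condition == "bimodal")
    grid <- matrix(NA_real_, 8, 8)
    grid[cbind(match(bi$theta_vis, directions8),
               match(bi$theta_ves, directions8))] <- bi$mean_rate
    if (anyNA(grid)) stop("incomplete 8 x 8 multisensory grid", call. = FALSE)
    r <- response_ratio(vis$mean_rate, ves$mean_rate)
    group <- classify_neuron(r, ratio_threshold)
    pref <- multisensory_preference(grid)
    tv_uni <- vis$theta_vis[which.max(vis$mean_rate)]
    te_uni <- ves$theta_ves[which.max(ves$mean_rate)]
    tibble::tibble(
      r = r, group = group,
      passes_filter = discriminative_filter(vis$mean_rate, ves$mean_rate,
                                            filter_threshold),
      theta_vis_uni_pref = tv_uni, theta_ves_uni_pref = te_uni,
      dtheta_uni = circular_disparity(tv_uni, te_uni),
      theta_vis_mul_pref = pref$theta_vis_pref,
      theta_ves_mul_pref = pref$theta_ves_pref,
      dtheta_mul = pref$dtheta_mul, degenerate = pref$degenerate)
  }
  out <- dplyr::group_modify(dplyr::group_by(means, .data$neuron_id),
                             function(d, g) one(d))
  out <- dplyr::ungroup(out)
  out$encoding <- ifelse(out$degenerate, NA_character_,
                         encoding_label(out$group, out$dtheta_mul))
  out
}

#' Empirical integration function from classified neurons
#'
#' Fraction of integration-labelled neurons among the non-omitted neurons of
#' each group, per unisensory preferred-disparity bin. Bins containing no
#' labelled neuron are reported as missing rather than interpolated.
#'
#' @param summaries Output of [analyze_neurons()].
#' @return A tibble with columns `group`, `dtheta_uni`, `n_int`, `n_sep`,
#'   `p_int` (NA where undefined).
#' @export
empirical_integration_function <- function(summaries) {
  s <- dplyr::filter(summaries, .data$passes_filter, !.data$degenerate,
                     .data$encoding != "omitted")
  grid <- tidyr::expand_grid(group = c("balanced", "imbalanced"),
                             dtheta_uni = disparity_bins)
  tab <- dplyr::summarise(
    dplyr::group_by(s, .data$group, .data$dtheta_uni),
    n_int = sum(.data$encoding == "integration"),
    n_sep = sum(.data$encoding == "separation"), .groups = "drop")
  out <- dplyr::left_join(grid, tab, by = c("group", "dtheta_uni"))
  out$n_int[is.na(out$n_int)] <- 0L
  out$n_sep[is.na(out$n_sep)] <- 0L
  out$p_int <- ifelse(out$n_int + out$n_sep > 0,
                      out$n_int / (out$n_int + out$n_sep), NA_real_)
  out
}

#' Group response template from a dataset
#'
#' Averages the multisensory grid responses of one neuron group as a function
#' of the mismatch between the neuron's preferred disparity and the cue
#' disparity of each grid cell, `dtheta_prime = |dtheta_mul - dtheta_cue|`,
#' pooling over neurons and cells.
#'
#' @param dataset A tuning dataset.
#' @param group `"balanced"` or `"imbalanced"`.
#' @param summaries Optional precomputed [analyze_neurons()] output.
#' @return A `"response_template"` tibble (`dtheta_prime`, `response`).
#' @export
compute_response_template <- function(dataset,
                                      group = c("balanced", "imbalanced"),
                                      summaries = NULL) {
  group <- match.arg(group)
  summaries <- summaries %||% analyze_neurons(dataset)
  keep <- summaries$neuron_id[summaries$group == group &
                                summaries$passes_filter &
                                !summaries$degenerate]
  if (length(keep) == 0) stop("no usable neurons in group", call. = FALSE)
  bi <- dplyr::filter(dataset, .data$condition == "bimodal",
                      .data$neuron_id %in% keep)
  means <- dplyr::summarise(
    dplyr::group_by(bi, .data$neuron_id, .data$theta_vis, .data$theta_ves),
    mean_rate = average_repeats(.data$rate), .groups = "drop")
  means <- dplyr::left_join(
    means, summaries[, c("neuron_id", "dtheta_mul")], by = "neuron_id")
  means$dtheta_cue <- circular_disparity(means$theta_vis, means$theta_ves)
  means$dtheta_prime <- abs(means$dtheta_mul - means$dtheta_cue)
  out <- dplyr::summarise(dplyr::group_by(means, .data$dtheta_prime),
                          response = mean(.data$mean_rate), .groups = "drop")
  out <- dplyr::arrange(out, .data$dtheta_prime)
  names(out)[1] <- "dtheta_prime"
  attr(out, "tag") <- group
  class(out) <- c("response_template", class(out))
  out
}
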