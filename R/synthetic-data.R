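#' Configuration for the synthetic tuning-data generator
#'
#' Describes a population of model MST-d neurons whose tuning statistics mirror
#' the summaries reported for the recorded population: a balanced subgroup
#' (response ratio r between 1 and 1.7, group mean 1.28) and an imbalanced
#' subgroup (r between 1.7 and 4, group mean 2.35), with 70/115 of neurons
#' balanced by default.
#'
#' Ratios are drawn from a truncated-exponential density on the group range
#' whose rate is solved so the group mean matches `r_balanced_mean` /
#' `r_imbalanced_mean`; when a target mean equals the range midpoint the draw
#' reduces to uniform.
#'
#' @param n_neurons Number of neurons (default 115).
#' @param balanced_fraction Proportion of balanced neurons in `[0, 1]`
#'   (default 70/115).
#' @param r_balanced_range,r_imbalanced_range Ratio ranges for the two groups.
#' @param r_balanced_mean,r_imbalanced_mean Target group-mean ratios.
#' @param tuning_width Circular-Gaussian tuning width, degrees.
#' @param baseline_rate,peak_rate Baseline and preferred-direction firing
#'   rates, spikes/s.
#' @param trial_noise_sd Additive Gaussian per-trial rate noise SD, spikes/s
#'   (rates are clipped at zero after noise).
#' @param n_repeats Stimulus repetitions per condition; must be at least 3
#'   (recordings with fewer repetitions are excluded from analysis).
#' @param seed Integer seed; every stochastic draw in the generator is
#'   reproducible from it.
#' @return A list of class `"generator_config"`.
#' @export
generator_config <- function(n_neurons = 115,
                             balanced_fraction = 70 / 115,
                             r_balanced_range = c(1, 1.7),
                             r_imbalanced_range = c(1.7, 4),
                             r_balanced_mean = 1.28,
                             r_imbalanced_mean = 2.35,
                             tuning_width = 55,
                             baseline_rate = 5,
                             peak_rate = 60,
                             trial_noise_sd = 5,
                             n_repeats = 5,
                             seed = 0) {
  if (n_neurons < 1) stop("`n_neurons` must be at least 1", call. = FALSE)
  if (balanced_fraction < 0 || balanced_fraction > 1)
    stop("`balanced_fraction` must lie in [0, 1]", call. = FALSE)
  if (peak_rate <= 0) stop("`peak_rate` must be positive", call. = FALSE)
  if (baseline_rate < 0) stop("`baseline_rate` must be non-negative", call. = FALSE)
  if (baseline_rate >= peak_rate)
    stop("`baseline_rate` must be below `peak_rate`", call. = FALSE)
  if (n_repeats < 3)
    stop("`n_repeats` must be at least 3 (fewer repetitions are excluded)",
         call. = FALSE)
  if (diff(r_balanced_range) <= 0 || diff(r_imbalanced_range) <= 0 ||
      r_balanced_range[1] < 1)
    stop("ratio ranges must be ordered and start at or above 1", call. = FALSE)
  if (trial_noise_sd < 0) stop("`trial_noise_sd` must be >= 0", call. = FALSE)
  structure(list(
    n_neurons = as.integer(n_neurons),
    balanced_fraction = balanced_fraction,
    r_balanced_range = r_balanced_range,
    r_imbalanced_range = r_imbalanced_range,
    r_balanced_mean = r_balanced_mean,
    r_imbalanced_mean = r_imbalanced_mean,
    tuning_width = tuning_width,
    baseline_rate = baseline_rate,
    peak_rate = peak_rate,
    trial_noise_sd = trial_noise_sd,
    n_repeats = as.integer(n_repeats),
    seed = as.integer(seed)
  ), class = "generator_config")
}

# truncated-exponential sampler on [a, b] with prescribed mean
rtrunc_exp <- function(n, range, mean_target) {
  a <- range[1]; b <- range[2]; w <- b - a
  mid <- a + w / 2
  if (is.null(mean_target) || abs(mean_target - mid) < 1e-9)
    return(stats::runif(n, a, b))
  if (mean_target <= a || mean_target >= b)
    stop("target mean must lie strictly inside the ratio range", call. = FALSE)
  m <- function(lam) a + 1 / lam - w / (exp(lam * w) - 1)
  lam <- stats::uniroot(function(l) m(l) - mean_target,
                        interval = c(-200 / w, 200 / w), tol = 1e-10)$root
  u <- stats::runif(n)
  a - log(1 - u * (1 - exp(-lam * w))) / lam
}

#' Generate a synthetic per-neuron tuning dataset
#'
#' Produces, for each model neuron, two unisensory 8-direction tuning curves
#' and an 8 x 8 multisensory response grid with trial repeats, in spikes/s.
#' Each neuron has a planted response ratio (implemented as the ratio of the
#' two unisensory curve maxima), planted unisensory preferred directions with a
#' planted disparity, and a multisensory grid whose unique argmax implements a
#' planted multisensory preferred pair. The grid is a separable product of two
#' circular-Gaussian profiles re-centred on that pair. Per-trial Gaussian rate
#' noise is added and rates are clipped at zero.
#'
#' @param config A [generator_config()].
#' @return A tibble in long format with columns `neuron_id`, `condition`
#'   (`"visual"`, `"vestibular"` or `"bimodal"`), `theta_vis`, `theta_ves`
#'   (degrees; `NA` for the absent modality), `rep` and `rate` (spikes/s).
#'   The planted ground truth is attached as `attr(, "ground_truth")` (one row
#'   per neuron) and the generating config as `attr(, "config")`.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  n <- config$n_neurons
  n_bal <- round(n * config$balanced_fraction)
  group <- rep(c("balanced", "imbalanced"), c(n_bal, n - n_bal))

  r <- numeric(n)
  if (n_bal > 0)
    r[group == "balanced"] <- rtrunc_exp(n_bal, config$r_balanced_range,
                                         config$r_balanced_mean)
  if (n - n_bal > 0)
    r[group == "imbalanced"] <- rtrunc_exp(n - n_bal, config$r_imbalanced_range,
                                           config$r_imbalanced_mean)

  dominant <- sample(c("visual", "vestibular"), n, replace = TRUE)
  theta_vis_uni <- sample(directions8, n, replace = TRUE)
  dtheta_uni <- sample(disparity_bins, n, replace = TRUE)
  sign_uni <- sample(c(-1, 1), n, replace = TRUE)
  theta_ves_uni <- (theta_vis_uni + sign_uni * dtheta_uni) %% 360

  # multisensory preferred pair: disparity drawn from the group's distribution
  dd <- make_disparity_distributions("paper_like")
  draw_disp <- function(g) {
    d <- if (g == "balanced") dd$balanced else dd$imbalanced
    sample(d$disparity, 1, prob = d$prob)
  }
  dtheta_mul <- unname(vapply(group, draw_disp, numeric(1)))
  theta_vis_mul <- sample(directions8, n, replace = TRUE)
  sign_mul <- sample(c(-1, 1), n, replace = TRUE)
  theta_ves_mul <- (theta_vis_mul + sign_mul * dtheta_mul) %% 360

  base <- config$baseline_rate
  wdt <- config$tuning_width

  one_neuron <- function(i) {
    max_dom <- config$peak_rate
    max_sub <- config$peak_rate / r[i]
    vis_max <- if (dominant[i] == "visual") max_dom else max_sub
    ves_max <- if (dominant[i] == "visual") max_sub else max_dom
    vis_mean <- base + (vis_max - base) *
      circ_gauss(circular_disparity(directions8, theta_vis_uni[i]), wdt)
    ves_mean <- base + (ves_max - base) *
      circ_gauss(circular_disparity(directions8, theta_ves_uni[i]), wdt)
    gv <- circ_gauss(circular_disparity(directions8, theta_vis_mul[i]), wdt)
    ge <- circ_gauss(circular_disparity(directions8, theta_ves_mul[i]), wdt)
    grid_mean <- base + (config$peak_rate - base) * outer(gv, ge)

    cells <- dplyr::bind_rows(
      tibble::tibble(condition = "visual", theta_vis = directions8,
                     theta_ves = NA_real_, mean_rate = vis_mean),
      tibble::tibble(condition = "vestibular", theta_vis = NA_real_,
                     theta_ves = directions8, mean_rate = ves_mean),
      tibble::tibble(condition = "bimodal",
                     theta_vis = rep(directions8, times = 8),
                     theta_ves = rep(directions8, each = 8),
                     mean_rate = as.vector(grid_mean))
    )
    reps <- tidyr::expand_grid(cells, rep = seq_len(config$n_repeats))
    noise <- if (config$trial_noise_sd > 0)
      stats::rnorm(nrow(reps), 0, config$trial_noise_sd) else 0
    reps$rate <- pmax(reps$mean_rate + noise, 0)
    reps$neuron_id <- i
    reps[, c("neuron_id", "condition", "theta_vis", "theta_ves", "rep", "rate")]
  }

  out <- dplyr::bind_rows(lapply(seq_len(n), one_neuron))
  truth <- tibble::tibble(
    neuron_id = seq_len(n), group = group, r = r, dominant = dominant,
    theta_vis_uni = theta_vis_uni, theta_ves_uni = theta_ves_uni,
    dtheta_uni = dtheta_uni,
    theta_vis_mul = theta_vis_mul, theta_ves_mul = theta_ves_mul,
    dtheta_mul = dtheta_mul)
  attr(out, "ground_truth") <- truth
  attr(out, "config") <- config
  class(out) <- c("tuning_dataset", class(out))
  out
}

#' Planted per-neuron ground truth of a synthetic dataset
#'
#' @param dataset A dataset from [generate_dataset()] or [read_dataset()].
#' @return A tibble with one row per neuron (group, ratio, planted preferred
#'   directions and disparities).
#' @export
ground_truth <- function(dataset) {
  gt <- attr(dataset, "ground_truth")
  if (is.null(gt)) stop("dataset carries no ground-truth attribute", call. = FALSE)
  gt
}

#' Preferred-disparity distributions for the two neuron groups
#'
#' Distributions of the multisensory preferred disparity over the 45-degree
#' support `{0, 45, 90, 135, 180}`. The `"paper_like"` style mirrors the
#' reported population: balanced neurons spread nearly uniformly over all
#' disparities while imbalanced neurons prefer small disparities, with mass
#' decaying monotonically. `"uniform"` gives both groups equal mass per bin;
#' `"degenerate"` concentrates all mass in one bin (for boundary tests).
#'
#' @param style One of `"paper_like"`, `"uniform"`, `"degenerate"`.
#' @param degenerate_at Disparity bin receiving all mass when
#'   `style = "degenerate"`.
#' @return A list with elements `balanced` and `imbalanced`, each a tibble
#'   with columns `disparity` and `prob` (non-negative, summing to 1).
#' @export
make_disparity_distributions <- function(style = c("paper_like", "uniform",
                                                   "degenerate"),
                                         degenerate_at = 0) {
  style <- match.arg(style)
  bins <- disparity_bins
  dist_tbl <- function(p) tibble::tibble(disparity = bins, prob = p / sum(p))
  switch(style,
    uniform = list(balanced = dist_tbl(rep(1, 5)),
                   imbalanced = dist_tbl(rep(1, 5))),
    degenerate = {
      if (!degenerate_at %in% bins)
        stop("`degenerate_at` must be one of 0, 45, 90, 135, 180", call. = FALSE)
      p <- as.numeric(bins == degenerate_at)
      list(balanced = dist_tbl(p), imbalanced = dist_tbl(p))
    },
    paper_like = list(
      balanced = dist_tbl(rep(1, 5)),
      imbalanced = dist_tbl(0.5^(0:4))
    ))
}

#' Multisensory response template as a function of cue-preference mismatch
#'
#' Template describing the mean multisensory response of a neuron group as a
#' function of the mismatch between its preferred disparity and the applied
#' cue disparity. The response is maximal at zero mismatch and decays
#' monotonically toward 180 degrees.
#'
#' @param tag `"balanced"` or `"imbalanced"`.
#' @param width Decay width in degrees (> 0).
#' @param baseline Response floor, spikes/s (>= 0).
#' @param peak Peak response at zero mismatch, spikes/s.
#' @return A tibble of class `"response_template"` with columns
#'   `dtheta_prime` (0-180) and `response`, and a `tag` attribute.
#' @export
make_response_template <- function(tag = c("balanced", "imbalanced"),
                                   width = 60, baseline = 0, peak = 60) {
  tag <- match.arg(tag)
  if (width <= 0) stop("`width` must be positive", call. = FALSE)
  if (baseline < 0) stop("`baseline` must be non-negative", call. = FALSE)
  if (peak <= baseline) stop("`peak` must exceed `baseline`", call. = FALSE)
  d <- 0:180
  out <- tibble::tibble(dtheta_prime = d,
                        response = baseline + (peak - baseline) * circ_gauss(d, width))
  attr(out, "tag") <- tag
  class(out) <- c("response_template", class(out))
  out
}

#' Evaluate a response template at arbitrary mismatch values
#'
#' @param template A `"response_template"` (from [make_response_template()] or
#'   [compute_response_template()]).
#' @param dtheta_prime Mismatch values in degrees, clamped to `[0, 180]`.
#' @return Responses, linearly interpolated between template support points.
#' @export
template_response <- function(template, dtheta_prime) {
  stopifnot(inherits(template, "response_template"))
  d <- pmin(pmax(abs(dtheta_prime), 0), 180)
  stats::approx(template$dtheta_prime, template$response, xout = d,
                rule = 2)$y
}

#' Write / read a tuning dataset as CSV with a JSON ground-truth sidecar
#'
#' `write_dataset()` writes `<stem>.csv` (long trial table) and
#' `<stem>_truth.json` (planted ground truth plus generator config);
#' `read_dataset()` reads them back, restoring attributes.
#'
#' @param dataset A tuning dataset.
#' @param stem Path stem (without extension).
#' @return `write_dataset()` the stem, invisibly; `read_dataset()` the dataset.
#' @export
write_dataset <- function(dataset, stem) {
  readr::write_csv(as.data.frame(dataset), paste0(stem, ".csv"))
  side <- list(ground_truth = attr(dataset, "ground_truth"),
               config = unclass(attr(dataset, "config")))
  jsonlite::write_json(side, paste0(stem, "_truth.json"),
                       digits = NA, auto_unbox = TRUE, null = "null")
  invisible(stem)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(stem) {
  out <- readr::read_csv(paste0(stem, ".csv"), show_col_types = FALSE,
                         progress = FALSE)
  side_path <- paste0(stem, "_truth.json")
  if (file.exists(side_path)) {
    side <- jsonlite::read_json(side_path, simplifyVector = TRUE)
    attr(out, "ground_truth") <- tibble::as_tibble(side$ground_truth)
    cfg <- side$config
    if (!is.null(cfg)) {
      cfg_args <- cfg[intersect(names(cfg), names(formals(generator_config)))]
      attr(out, "config") <- do.call(generator_config, cfg_args)
    }
  }
  class(out) <- c("tuning_dataset", class(out))
  out
}
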