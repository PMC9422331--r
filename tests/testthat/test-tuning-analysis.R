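test_that("repeat averaging removes the most outlying repeat", {
  expect_equal(average_repeats(c(10, 10, 10, 10, 50)), 10)
  expect_equal(average_repeats(rep(7, 5)), 7)
  expect_error(average_repeats(c(3, 4)), "fewer than three")
})

test_that("window selection averages bins then repeats", {
  bins <- seq(0, 1975, by = 25)
  base <- tidyr::expand_grid(condition = "visual", theta_vis = 0,
                             theta_ves = NA_real_, rep = 1:5, time_ms = bins)
  # rate = 10 inside the window, 99 outside; one outlier repeat at 50
  base$rate <- ifelse(base$time_ms >= 625 & base$time_ms < 1250, 10, 99)
  base$rate[base$rep == 5 & base$time_ms >= 625 & base$time_ms < 1250] <- 50
  out <- select_window_and_average(base, window = c(625, 1250))
  expect_equal(nrow(out), 1)
  expect_equal(out$mean_rate, 10)
  expect_error(select_window_and_average(base, window = c(5000, 6000)),
               "window")
  two_reps <- dplyr::filter(base, rep <= 2)
  expect_error(select_window_and_average(two_reps), "fewer than three")
})

test_that("discriminative filter requires a 5 spikes/s span in both curves", {
  vis <- c(2, 3, 4, 6, 10, 8, 5, 3)   # span 8
  ves <- c(0, 1, 3, 5, 8, 6, 2, 1)    # span 8
  expect_true(discriminative_filter(vis, ves))
  ves_flat <- c(3, 4, 5, 6, 6, 5, 4, 3)  # span 3
  expect_false(discriminative_filter(vis, ves_flat))
  expect_false(discriminative_filter(rep(4, 8), rep(4, 8)))
})

test_that("response ratio is the ratio of curve maxima, bounded below by 1", {
  expect_equal(response_ratio(rep(24, 8), rep(12, 8)), 2)
  expect_equal(response_ratio(rep(10, 8), rep(10, 8)), 1)
  expect_equal(response_ratio(rep(10, 8), rep(17, 8)), 1.7)
  expect_error(response_ratio(rep(0, 8), rep(10, 8)), "positive")
})

test_that("ratio is invariant to common rescaling of both curves", {
  set.seed(1)
  vis <- runif(8, 1, 40); ves <- runif(8, 1, 40)
  for (c_ in c(0.1, 3, 100))
    expect_equal(response_ratio(c_ * vis, c_ * ves),
                 response_ratio(vis, ves))
})

test_that("classification assigns the threshold ratio to the balanced group", {
  expect_equal(classify_neuron(1.28), "balanced")
  expect_equal(classify_neuron(2.35), "imbalanced")
  expect_equal(classify_neuron(1.7), "balanced")
  expect_error(classify_neuron(0.9), ">= 1")
})

test_that("circular disparity wraps, is symmetric and obeys the triangle bound", {
  expect_equal(circular_disparity(10, 350), 20)
  expect_equal(circular_disparity(0, 180), 180)
  expect_equal(circular_disparity(123, 123), 0)
  set.seed(3)
  a <- runif(200, 0, 360); b <- runif(200, 0, 360); c_ <- runif(200, 0, 360)
  expect_equal(circular_disparity(a, b), circular_disparity(b, a))
  expect_true(all(circular_disparity(a, b) >= 0))
  expect_true(all(circular_disparity(a, b) <= 180))
  expect_true(all(circular_disparity(a, c_) <=
                    circular_disparity(a, b) + circular_disparity(b, c_) + 1e-9))
})

test_that("multisensory preference takes the grid argmax with stated tie-breaks", {
  dirs <- seq(0, 315, by = 45)
  g <- matrix(1, 8, 8)
  g[dirs == 90, dirs == 90] <- 5
  expect_equal(multisensory_preference(g)$dtheta_mul, 0)
  g2 <- matrix(1, 8, 8); g2[dirs == 0, dirs == 180] <- 5
  expect_equal(multisensory_preference(g2)$dtheta_mul, 180)
  # tie between a 90-degree and a 0-degree cell: smaller disparity wins
  g3 <- matrix(1, 8, 8)
  g3[dirs == 0, dirs == 90] <- 5
  g3[dirs == 45, dirs == 45] <- 5
  p3 <- multisensory_preference(g3)
  expect_equal(p3$dtheta_mul, 0)
  expect_equal(p3$theta_vis_pref, 45)
  # all-equal grid is degenerate
  expect_true(multisensory_preference(matrix(2, 8, 8))$degenerate)
})

test_that("rectification doubles the end bins and renormalises", {
  out <- rectify_distribution(c(0.1, 0.3, 0.2, 0.3, 0.1))
  expect_equal(out$prob, c(0.2, 0.3, 0.2, 0.3, 0.2) / 1.2)
  expect_equal(sum(out$prob), 1)
  expect_equal(rectify_distribution(c(1, 2, 2, 2, 1))$prob, rep(0.2, 5))
  expect_equal(rectify_distribution(c(0, 0, 1, 0, 0))$prob, c(0, 0, 1, 0, 0))
  expect_error(rectify_distribution(c(0, 0, 0, 0, 0)), "all-zero")
  expect_error(rectify_distribution(c(-1, 1, 1, 1, 1)), "non-negative")
})

test_that("encoding labels follow the group-specific disparity rules", {
  expect_equal(encoding_label("balanced", 90), "separation")
  expect_equal(encoding_label("imbalanced", 90), "omitted")
  expect_equal(encoding_label("imbalanced", 0), "integration")
  expect_equal(encoding_label(c("balanced", "balanced", "imbalanced"),
                              c(0, 180, 135)),
               c("integration", "separation", "separation"))
})

test_that("noise-free analysis recovers every planted quantity exactly", {
  ds <- generate_dataset(config_tiny(n = 30, seed = 9))
  sm <- analyze_neurons(ds)
  gt <- ground_truth(ds)
  expect_equal(sm$r, gt$r, tolerance = 1e-12)
  expect_equal(sm$group, gt$group)
  expect_equal(sm$dtheta_uni, gt$dtheta_uni)
  expect_equal(sm$dtheta_mul, gt$dtheta_mul)
  expect_equal(sm$theta_vis_uni_pref, gt$theta_vis_uni)
  expect_equal(sm$theta_ves_uni_pref, gt$theta_ves_uni)
  expect_equal(sm$theta_vis_mul_pref, gt$theta_vis_mul)
  expect_equal(sm$theta_ves_mul_pref, gt$theta_ves_mul)
  expect_true(all(sm$passes_filter))
})

test_that("empirical integration function reports fractions and flags empty bins", {
  sm <- tibble::tibble(
    neuron_id = 1:6,
    group = c(rep("balanced", 4), "imbalanced", "imbalanced"),
    dtheta_uni = c(45, 45, 45, 45, 90, 135),
    dtheta_mul = c(0, 45, 0, 90, 90, 0),
    passes_filter = TRUE, degenerate = FALSE)
  sm$encoding <- encoding_label(sm$group, sm$dtheta_mul)
  out <- empirical_integration_function(sm)
  bal45 <- out[out$group == "balanced" & out$dtheta_uni == 45, ]
  expect_equal(bal45$p_int, 0.75)  # 3 integration, 1 separation
  imb90 <- out[out$group == "imbalanced" & out$dtheta_uni == 90, ]
  expect_true(is.na(imb90$p_int))  # only an omitted neuron in the bin
  imb135 <- out[out$group == "imbalanced" & out$dtheta_uni == 135, ]
  expect_equal(imb135$p_int, 1)
})

test_that("response template from data peaks at zero mismatch", {
  ds <- generate_dataset(config_tiny(n = 24, seed = 13))
  sm <- analyze_neurons(ds)
  tpl <- compute_response_template(ds, "balanced", summaries = sm)
  expect_s3_class(tpl, "response_template")
  expect_equal(tpl$dtheta_prime[which.max(tpl$response)], 0)
  # pooling cells can only dilute the planted peak, never exceed it
  expect_lte(max(tpl$response), attr(ds, "config")$peak_rate)
  expect_gt(tpl$response[tpl$dtheta_prime == 0],
            tpl$response[tpl$dtheta_prime == 180])
  expect_error(compute_response_template(
    dplyr::filter(ds, neuron_id %in%
                    sm$neuron_id[sm$group == "balanced"]), "imbalanced"),
    "no usable neurons")
})
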