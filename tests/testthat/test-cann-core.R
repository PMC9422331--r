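test_that("Mexican-hat weights match direct arithmetic", {
  p <- cann_params()
  expect_equal(mexican_hat_weight(2, p),
               5 * exp(-4 / 200) - 3 * exp(-4 / 9800), tolerance = 1e-12)
  expect_equal(round(mexican_hat_weight(2, p), 3), 1.902)
  expect_equal(round(mexican_hat_weight(180, p), 3), -0.110)
  p0 <- cann_params(beta_scale = 0)
  expect_equal(mexican_hat_weight(c(0, 7, 180), p0), c(0, 0, 0))
  expect_error(mexican_hat_weight(200, p), "d <= 180")
})

test_that("lateral kernel is symmetric with equal row sums (ring homogeneity)", {
  W <- mstcann:::lateral_kernel(cann_params())
  expect_equal(W, t(W), tolerance = 1e-12)
  expect_equal(diag(W), rep(0, 180))
  rs <- rowSums(W)
  expect_lt(max(rs) - min(rs), 1e-9)
})

test_that("external input is a symmetric Gaussian with the stated values", {
  p <- cann_params()
  I <- external_input(90, p)
  pos <- mstcann:::ring_positions(p)
  expect_equal(I[pos == 90], 25)
  expect_equal(I[pos == 90 + 40], I[pos == 90 - 40], tolerance = 1e-12)
  expect_equal(I[pos == 90 + 160], 25 * exp(-0.5), tolerance = 1e-12)
})

test_that("forward input is aligned, linear and zero for silent layers", {
  p <- cann_params()
  z <- rep(0, 180)
  expect_equal(forward_input(z, z, 3, 3, p), z)
  one <- z; one[40] <- 1
  f <- forward_input(one, z, 2, 5, p)
  expect_equal(which.max(f), 40)
  f2 <- forward_input(one, z, 4, 5, p)
  expect_equal(f2, 2 * f, tolerance = 1e-12)
  f_mix <- forward_input(one, one, 2, 3, p)
  expect_equal(f_mix, forward_input(one, z, 2, 0, p) +
                 forward_input(z, one, 0, 3, p), tolerance = 1e-12)
  expect_error(forward_input(rep(0, 10), z, 1, 1, p), "length")
})

test_that("the Euler step has the sigmoid fixed point and leak decay", {
  p <- cann_params()
  I <- rep(30, 180)
  y_star <- sigmoid_activation(I, p)
  expect_equal(cann_step(y_star, I, p), y_star, tolerance = 1e-12)
  # with zero input the state decays toward S(0) ~ 0
  y <- rep(0.8, 180)
  for (i in 1:400) y <- cann_step(y, rep(0, 180), p)
  expect_lt(max(y), 0.01)
  expect_error(cann_step(c(NaN, rep(0, 179)), rep(0, 180), p), "non-finite")
})

test_that("halving dt halves the global Euler error (first-order scheme)", {
  p1 <- cann_params(dt = 2)
  p2 <- cann_params(dt = 1)
  pref <- cann_params(dt = 0.05)
  evolve <- function(p, t_end = 20) {
    y <- rep(0.2, 180)
    I <- external_input(90, p)
    for (i in seq_len(round(t_end / p$dt))) y <- cann_step(y, I, p)
    y
  }
  ref <- evolve(pref)
  e1 <- max(abs(evolve(p1) - ref))
  e2 <- max(abs(evolve(p2) - ref))
  expect_lt(e2, e1)
  expect_equal(e1 / e2, 2, tolerance = 0.35)  # first-order Euler halves with dt
})

test_that("simulated activities stay in [0, 1] and match the R reference step", {
  p <- params_fast()
  res <- mstcann:::cann_batch(1, 60, 1.3, p, sigma_noise = 0, seed = 4)
  for (layer in c("mt", "pivc", "sub")) {
    expect_true(all(res[[layer]] >= 0))
    expect_true(all(res[[layer]] <= 1))
  }
  # one noise-free step from rest equals the R reference update
  p1 <- params_fast(); p1$duration <- p1$dt; p1$final_window <- p1$dt
  res1 <- mstcann:::cann_batch(1, 0, 1, p1, sigma_noise = 0, seed = 1,
                               dominant = "visual")
  y_ref <- cann_step(rep(0, p1$L), external_input(90, p1), p1)
  expect_equal(as.vector(res1$mt), y_ref, tolerance = 1e-12)
})

test_that("noise-free dynamics are rotationally equivariant and mirror-symmetric", {
  p <- params_fast()
  delta <- 40  # 20 neurons
  # wide-disparity condition: both bumps survive, no symmetry breaking
  run_at <- function(tv, te) mstcann:::cann_run_batch_cpp(
    tv, te, 5.32, 5.32, 1, 1, p, 0, 1, p$duration, 1, 0)
  a <- run_at(150, 30)
  b <- run_at(150 + delta, 30 + delta)
  shift <- delta / 2
  rotate <- function(y, k) c(utils::tail(y, k), utils::head(y, -k))
  expect_equal(as.vector(b$sub[, 1]), rotate(as.vector(a$sub[, 1]), shift),
               tolerance = 1e-7)
  # equal forward weights: swapping the cues leaves the state unchanged, and
  # the two-bump state is itself mirror-symmetric about the cue midpoint
  m <- run_at(30, 150)
  expect_equal(as.vector(m$sub[, 1]), as.vector(a$sub[, 1]),
               tolerance = 1e-10)
  mirror <- function(y) {
    pos <- mstcann:::ring_positions(p)
    y[match((180 - pos) %% 360, pos)]  # reflection about the 90-deg midpoint
  }
  expect_equal(as.vector(a$sub[, 1]), mirror(as.vector(a$sub[, 1])),
               tolerance = 1e-6)
})

test_that("identical seeds reproduce noisy runs bit-for-bit", {
  p <- params_fast()
  a <- run_trials(3, 90, 1.2, p, sigma_noise = 6, seed = 99)
  b <- run_trials(3, 90, 1.2, p, sigma_noise = 6, seed = 99)
  expect_identical(a, b)
  c_ <- run_trials(3, 90, 1.2, p, sigma_noise = 6, seed = 100)
  expect_false(identical(a$dtheta_mul, c_$dtheta_mul))
})
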