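make_series <- function(values, n_pre = 20L, dt = 0.21) {
  structure(data.frame(frame = seq_along(values) - 1L,
                       time = (seq_along(values) - 1L - n_pre) * dt,
                       value = values),
            class = c("frap_series", "data.frame"),
            n_prebleach = n_pre, frame_interval = dt, source_id = "test")
}

test_that("extract_series reduces to the masked pixel means", {
  frames <- array(7, dim = c(5, 8, 8))
  movie <- frap_movie(frames, 0.21, 2L)
  mask <- matrix(FALSE, 8, 8)
  mask[3:5, 3:5] <- TRUE
  s <- extract_series(movie, mask)
  expect_equal(s$value, rep(7, 5))
  expect_equal(s$time, (0:4 - 2) * 0.21)

  # single-pixel mask returns that pixel's trace
  movie$frames[, 4, 6] <- 1:5
  m1 <- matrix(FALSE, 8, 8)
  m1[4, 6] <- TRUE
  expect_equal(extract_series(movie, m1)$value, 1:5)

  expect_error(extract_series(movie, matrix(FALSE, 8, 8)), "empty")
})

test_that("acquisition decay fit recovers exact and degenerate inputs", {
  t <- (0:499) * 0.21
  s <- make_series(c(rep(100, 20), 100 * exp(-0.01 * t)))
  fit <- fit_acquisition_decay(s)
  expect_equal(fit$A, 100, tolerance = 1e-6)
  expect_equal(fit$k, 0.01, tolerance = 1e-6)

  flat <- make_series(rep(42, 60))
  fit0 <- fit_acquisition_decay(flat)
  expect_equal(fit0$k, 0, tolerance = 1e-8)
  expect_equal(fit0$A, 42, tolerance = 1e-8)

  bad <- make_series(c(rep(1, 20), NaN, rep(1, 30)))
  expect_error(fit_acquisition_decay(bad), "non-finite")
  expect_error(fit_acquisition_decay(make_series(rep(1, 25))),
               "at least 10")
})

test_that("decay fit recovers the simulator rate within 5% under noise", {
  p <- small_params(acquisition_decay_rate = 0.002, noise_sd = 0.02,
                    n_postbleach = 200L, seed = 6L)
  sim <- simulate_frap_movie(p)
  nuc <- extract_series(sim$movie, sim$truth$nucleus_mask)
  fit <- fit_acquisition_decay(nuc)
  k_per_frame <- fit$k * p$frame_interval
  expect_equal(k_per_frame, 0.002, tolerance = 0.05)
})

test_that("correct_and_normalize pins the documented post-conditions", {
  p <- small_params(mobile_fraction = 0.3, tau = 3.75, bleach_depth = 0.9,
                    acquisition_decay_rate = 0.001, n_postbleach = 200L)
  sim <- simulate_frap_movie(p)
  roi <- extract_series(sim$movie, sim$truth$bleach_mask)
  nuc <- extract_series(sim$movie, sim$truth$nucleus_mask)
  decay <- fit_acquisition_decay(nuc)
  curve <- correct_and_normalize(roi, decay)

  expect_equal(mean(curve$normalized[curve$time < 0]), 1)
  expect_equal(curve$normalized[which(curve$time >= 0)[1]], 0)

  # noiseless curve matches m * (1 - exp(-t / tau)) within 1%
  post <- curve[curve$time >= 0, ]
  model <- 0.3 * (1 - exp(-post$time / 3.75))
  expect_lt(max(abs(post$normalized - model)), 0.01)
})

test_that("correction removes the decay and k = 0 is the identity", {
  # pure-decay movie: corrected pre-bleach values are flat
  p <- small_params(bleach_depth = 0, acquisition_decay_rate = 0.005,
                    n_postbleach = 100L)
  sim <- simulate_frap_movie(p)
  roi <- extract_series(sim$movie, sim$truth$bleach_mask)
  decay <- fit_acquisition_decay(extract_series(sim$movie,
                                                sim$truth$nucleus_mask))
  corrected <- roi$value / exp(-decay$k * roi$time)
  sl <- coef(lm(corrected ~ roi$time))[2]
  expect_lt(abs(sl) / mean(corrected), 1e-3)
  # and the flat corrected curve is rejected at normalization
  expect_error(correct_and_normalize(roi, decay), "no bleach detected")

  s <- make_series(c(rep(10, 20), 2, 3, 4, rep(5, 37)))
  curve <- correct_and_normalize(s, structure(list(A = 10, k = 0, rss = 0),
                                              class = "frap_decay"))
  expect_identical(curve$corrected, curve$raw)
})

test_that("normalization is scale-invariant and idempotent", {
  s <- make_series(c(rep(10, 20), 2, 3, 4, rep(5, 37)))
  decay <- structure(list(A = 10, k = 0.004, rss = 0),
                     class = "frap_decay")
  c1 <- correct_and_normalize(s, decay)
  s10 <- make_series(10 * s$value)
  c2 <- correct_and_normalize(s10, decay)
  expect_equal(c2$normalized, c1$normalized, tolerance = 1e-12)

  renorm <- make_series(c1$normalized)
  c3 <- correct_and_normalize(renorm,
                              structure(list(A = 1, k = 0, rss = 0),
                                        class = "frap_decay"))
  expect_equal(c3$normalized, c1$normalized, tolerance = 1e-12)
})
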