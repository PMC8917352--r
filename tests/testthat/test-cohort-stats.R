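sim_curve <- function(values, dt = 0.21, n_pre = 3L) {
  n <- length(values)
  structure(data.frame(frame = seq_len(n) - 1L,
                       time = (seq_len(n) - 1L - n_pre) * dt,
                       raw = values, corrected = values,
                       normalized = values),
            class = c("frap_curve", "data.frame"),
            n_prebleach = n_pre, frame_interval = dt, source_id = "c")
}

test_that("mean_sem_curves averages, propagates s.e.m. and truncates", {
  a <- sim_curve(c(1, 1, 1, 0, 0.2, 0.4))
  b <- sim_curve(c(1, 1, 1, 0, 0.2, 0.4))
  cc <- mean_sem_curves(list(a, b))
  expect_equal(cc$mean, a$normalized)
  expect_equal(cc$sem, rep(0, 6))

  b2 <- sim_curve(c(1, 1, 1, 0, 0.4, 0.4))
  cc2 <- mean_sem_curves(list(a, b2))
  i <- which(cc2$time == a$time[5])
  expect_equal(cc2$mean[i], 0.3)
  expect_equal(cc2$sem[i], sd(c(0.2, 0.4)) / sqrt(2))
  expect_equal(cc2$sem[i], 0.1, tolerance = 1e-12)

  long <- sim_curve(c(1, 1, 1, 0, 0.2, 0.4, 0.5, 0.6))
  cc3 <- mean_sem_curves(list(a, long))
  expect_identical(nrow(cc3), 6L)

  bad <- sim_curve(c(1, 1, 1, 0, 0.2, 0.4), dt = 0.5)
  expect_error(mean_sem_curves(list(a, bad)), "frame interval")
  expect_error(mean_sem_curves(list(a)), "length")
})

test_that("summarize_group reports median, IQR and 5/95 whiskers", {
  s <- summarize_group(c(0.1, 0.2, 0.3))
  expect_equal(s$median, 0.2)
  expect_equal(s$n, 3L)

  one <- summarize_group(0.42)
  expect_true(all(unlist(one[c("median", "q1", "q3", "p5", "p95")]) == 0.42))

  set.seed(2)
  v <- rnorm(1000)
  s2 <- summarize_group(v)
  expect_equal(s2$q1, unname(quantile(v, 0.25)))
  expect_equal(s2$p95, unname(quantile(v, 0.95)))
  expect_true(s2$p5 <= s2$q1 && s2$q1 <= s2$median &&
                s2$median <= s2$q3 && s2$q3 <= s2$p95)
})

test_that("pooled t-test matches the closed form and stats::t.test", {
  a <- c(1.1, 2.3, 3.1, 4.8)
  b <- c(2.0, 2.2, 5.1)
  res <- compare_groups(a, b)
  oracle <- t.test(a, b, var.equal = TRUE)
  expect_equal(res$t, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(oracle$parameter))

  resw <- compare_groups(a, b, welch = TRUE)
  oraclew <- t.test(a, b)
  expect_equal(resw$t, unname(oraclew$statistic), tolerance = 1e-12)
  expect_equal(resw$p, oraclew$p.value, tolerance = 1e-12)

  # hand-computable input
  hand <- compare_groups(c(1, 2, 3), c(11, 12, 13))
  sp2 <- 1  # both variances 1
  expect_equal(hand$t, -10 / sqrt(sp2 * (2 / 3)), tolerance = 1e-12)
  expect_equal(hand$p, 2 * pt(-10 / sqrt(2 / 3), 4), tolerance = 1e-12)
  expect_lt(hand$p, 1e-3)

  # identical groups and degenerate cases
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$t, 0)
  expect_equal(compare_groups(c(1, 2, 3), c(1, 2, 3))$p, 1)
  deg <- compare_groups(c(2, 2), c(5, 5))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 0)
  deg2 <- compare_groups(c(2, 2), c(2, 2))
  expect_true(deg2$degenerate)
  expect_equal(deg2$p, 1)
})

test_that("intensity_density bins by 20 and conserves mass", {
  d <- intensity_density(list(c(5, 25)))
  expect_equal(d$density[1:2], c(1, 1))
  expect_equal(d$lower[1:2], c(0, 20))

  # two identical images: density equals the single-image histogram
  img <- c(1, 15, 30, 200, 205)
  d1 <- intensity_density(list(img))
  d2 <- intensity_density(list(img, img))
  expect_equal(d1$density, d2$density)

  # conservation: sum(density) * n_images = total pixel count
  set.seed(3)
  imgs <- lapply(1:4, function(i) runif(sample(50:200, 1), 0, 500))
  dd <- intensity_density(imgs)
  expect_equal(sum(dd$density) * length(imgs),
               sum(lengths(imgs)))

  expect_error(intensity_density(list(numeric(0))), "empty")
})

test_that("Mann-Whitney U equals brute-force pair counting", {
  brute_u <- function(a, b) {
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  u_eq <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_equal(u_eq$U, 9 / 2)
  expect_gt(u_eq$p, 0.9)

  set.seed(19)
  for (i in 1:50) {
    a <- sample(0:10, sample(2:12, 1), replace = TRUE)
    b <- sample(0:10, sample(2:12, 1), replace = TRUE)
    res <- mann_whitney(a, b)
    expect_equal(res$U, brute_u(a, b))
    # U + U' = n_a * n_b
    expect_equal(res$U + mann_whitney(b, a)$U, length(a) * length(b))
  }
})

test_that("Mann-Whitney p matches the tie-corrected normal approximation", {
  set.seed(23)
  a <- rnorm(200)
  b <- rnorm(250, 0.3)
  res <- mann_whitney(a, b)
  oracle <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(res$p, oracle$p.value, tolerance = 1e-10)
})
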