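toy_track <- function(seed = 1L, bin_size = 1e4) {
  set.seed(seed)
  binned_track(list(chrI = rnorm(60, 3, 1), chrII = rnorm(80, 3, 1),
                    chrX = rnorm(50, 5, 1)), bin_size)
}

test_that("z-score standardization centres the background", {
  tr <- zscore_standardize(toy_track(), c("chrI", "chrII"))
  bg <- c(tr$values$chrI, tr$values$chrII)
  expect_equal(mean(bg), 0, tolerance = 1e-12)
  expect_equal(sd(bg), 1, tolerance = 1e-12)

  # idempotent on the background
  tr2 <- zscore_standardize(tr, c("chrI", "chrII"))
  expect_equal(tr2$values, tr$values, tolerance = 1e-12)

  # a bin at mu + 2 sigma maps to exactly 2
  raw <- toy_track()
  bg0 <- c(raw$values$chrI, raw$values$chrII)
  raw$values$chrX[1] <- mean(bg0) + 2 * sd(bg0)
  expect_equal(zscore_standardize(raw, c("chrI", "chrII"))$values$chrX[1], 2)

  const <- binned_track(list(chrI = rep(1, 10), chrX = rnorm(10)), 1e4)
  expect_error(zscore_standardize(const, "chrI"), "constant")
  expect_error(zscore_standardize(raw, "chrVII"), "absent")
})

test_that("equalize_total fixes the target sum to one", {
  tr <- toy_track()
  eq <- equalize_total(tr, "chrX")
  expect_equal(sum(eq$values$chrX), 1, tolerance = 1e-12)
  # all chromosomes share the one scaling constant
  expect_equal(eq$values$chrI, tr$values$chrI / sum(tr$values$chrX))
  # idempotent once the target total is 1
  expect_equal(equalize_total(eq, "chrX")$values, eq$values,
               tolerance = 1e-12)
  # replicate tracks end up with identical target totals
  eq2 <- equalize_total(toy_track(seed = 2L), "chrX")
  expect_equal(sum(eq2$values$chrX), sum(eq$values$chrX),
               tolerance = 1e-12)

  zero <- binned_track(list(chrI = rep(0, 10)), 1e4)
  expect_error(equalize_total(zero, "chrI"), "zero")
})

test_that("sliding_mean equals the brute-force window average", {
  tr <- toy_track(seed = 7L, bin_size = 1e4)
  win <- 1e5
  stp <- 2e4
  sm <- sliding_mean(tr, window = win, step = stp)
  # brute force on a 1 Mb-scale toy chromosome
  for (ch in names(tr$values)) {
    v <- tr$values[[ch]]
    wb <- win / 1e4
    sb <- stp / 1e4
    starts <- seq(1, length(v) - wb + 1, by = sb)
    expected <- sapply(starts, function(s) mean(v[s:(s + wb - 1)]))
    got <- sm$value[sm$chrom == ch]
    expect_equal(got, expected, tolerance = 1e-12)
  }

  # constant track: every window mean is the constant
  const <- binned_track(list(chrI = rep(3.5, 100)), 1e4)
  expect_true(all(sliding_mean(const, 1e5, 5e4)$value == 3.5))

  # step = window: non-overlapping block means
  blocks <- sliding_mean(const, 1e5, 1e5)
  expect_equal(nrow(blocks), 10L)

  # window longer than the chromosome: no rows
  short <- binned_track(list(chrI = rep(1, 5)), 1e4)
  expect_identical(nrow(sliding_mean(short, 1e5, 5e4)), 0L)

  expect_error(sliding_mean(tr, window = 1.5e4), "multiples")
})

test_that("contact_decay averages the off-diagonals", {
  # only the main diagonal populated: P(s) = 0 for s > 0
  m <- diag(5)
  dc <- contact_decay(m, bin_size = 5000)
  expect_true(all(dc$p == 0))
  expect_equal(dc$s, (1:4) * 5000)

  # first off-diagonal = 2
  m2 <- matrix(0, 5, 5)
  m2[cbind(1:4, 2:5)] <- 2
  m2 <- m2 + t(m2)
  expect_equal(contact_decay(m2, bin_size = 5000)$p[1], 2)

  # max_depth truncates the separation grid
  expect_identical(nrow(contact_decay(m, 5000, max_depth = 10000)), 2L)
})

test_that("noiseless generator round-trips the power law exactly", {
  sim <- simulate_contact_matrix(n_bins = 100L, x_factor = 1,
                                 depth = 1000, seed = 2L)
  dec <- contact_decay(sim$matrices)
  d <- dec$chrI$s / 5000
  expect_equal(dec$chrI$p, 1000 * d^(-1.5), tolerance = 1e-12)
  # log-log slope of the recovered curve
  sl <- coef(lm(log(dec$chrI$p) ~ log(dec$chrI$s)))[2]
  expect_equal(unname(sl), -1.5, tolerance = 1e-9)
  # without enrichment, X equals the autosomes
  expect_equal(dec$chrX$p, dec$chrI$p)
  # determinism under Poisson noise
  a <- simulate_contact_matrix(n_bins = 50L, noise = "poisson", seed = 5L)
  b <- simulate_contact_matrix(n_bins = 50L, noise = "poisson", seed = 5L)
  expect_identical(a$matrices$matrices$chrX, b$matrices$matrices$chrX)
  expect_equal(a$matrices$matrices$chrX, t(a$matrices$matrices$chrX))
})

test_that("unity normalization and the X/A ratio behave as documented", {
  sim <- simulate_contact_matrix(n_bins = 300L, x_factor = 1.5, seed = 3L)
  decs <- lapply(contact_decay(sim$matrices), unity_normalize_decay)
  for (dc in decs) {
    sel <- dc$s >= 5e3 & dc$s <= 4e6
    expect_equal(sum(dc$p[sel]), 1, tolerance = 1e-9)
  }
  # scale invariance
  dc0 <- contact_decay(sim$matrices$matrices$chrI, bin_size = 5000)
  dc10 <- dc0
  dc10$p <- dc10$p * 10
  expect_equal(unity_normalize_decay(dc10)$p, unity_normalize_decay(dc0)$p)

  ratio <- xa_ratio(decs, x_chrom = "chrX",
                    autosomes = c("chrI", "chrII", "chrIII", "chrIV"))
  inside <- ratio$s >= 5e4 & ratio$s <= 1e6
  expect_true(all(ratio$ratio[inside] > 1.2))
  outside <- ratio$s > 1.1e6
  expect_true(all(ratio$ratio[outside] < 1.1))

  # X identical to autosomes: ratio of exactly 1
  sim1 <- simulate_contact_matrix(n_bins = 100L, x_factor = 1, seed = 4L)
  decs1 <- lapply(contact_decay(sim1$matrices), unity_normalize_decay)
  r1 <- xa_ratio(decs1, x_chrom = "chrX",
                 autosomes = c("chrI", "chrII", "chrIII", "chrIV"))
  expect_equal(r1$ratio, rep(1, nrow(r1)), tolerance = 1e-12)

  # pre-normalization rescaling of the autosomes leaves the ratio unchanged
  mats <- sim1$matrices$matrices
  mats$chrI <- mats$chrI * 2
  decs2 <- lapply(contact_decay(contact_matrix_set(mats, 5000)),
                  unity_normalize_decay)
  r2 <- xa_ratio(decs2, x_chrom = "chrX",
                 autosomes = c("chrI", "chrII", "chrIII", "chrIV"))
  expect_equal(r2$ratio, r1$ratio, tolerance = 1e-12)

  expect_error(unity_normalize_decay(data.frame(s = 1e7, p = 1)),
               "no support")
})

test_that("contact matrices round-trip through bins + triplets text", {
  sim <- simulate_contact_matrix(n_bins = 20L, noise = "poisson",
                                 seed = 9L)
  bins <- withr::local_tempfile(fileext = ".tsv")
  trips <- withr::local_tempfile(fileext = ".tsv")
  write_contact_matrix(sim$matrices, bins, trips)
  back <- read_contact_matrix(bins, trips)
  expect_equal(back$bin_size, 5000)
  for (ch in names(sim$matrices$matrices)) {
    expect_equal(back$matrices[[ch]], sim$matrices$matrices[[ch]])
  }
})

test_that("dense TSV matrices load as a one-chromosome set", {
  m <- matrix(c(4, 2, 1, 2, 4, 2, 1, 2, 4), 3, 3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write.table(m, f, sep = "\t", row.names = FALSE, col.names = FALSE)
  cms <- read_dense_matrix(f, bin_size = 5000, chrom = "chrX")
  expect_equal(cms$matrices$chrX, m)
})

test_that("spreading-track generator shows decay across the boundary", {
  sim <- simulate_spreading_track(n_bins_bg = 200L, n_bins_fusion = 400L,
                                  noise_sd = 0.05, seed = 11L)
  tr <- sim$track
  b <- sim$truth$boundary_bin
  v <- tr$values$chrXV
  # X-derived side sits at the enrichment plateau, far autosomal side at 1
  expect_equal(mean(v[1:b]), sim$truth$enrichment, tolerance = 0.05)
  expect_equal(mean(tail(v, 50)), 1, tolerance = 0.05)
  # windowed profile decreases across the boundary
  sm <- sliding_mean(tr, window = 5e5, step = 5e4)
  smx <- sm[sm$chrom == "chrXV", ]
  expect_gt(smx$value[1], tail(smx$value, 1) + 0.5)
})

test_that("bedGraph round-trip preserves the track", {
  tr <- toy_track(seed = 13L)
  f <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(tr, f)
  back <- read_bedgraph(f)
  expect_equal(back$bin_size, tr$bin_size)
  for (ch in names(tr$values)) {
    expect_equal(back$values[[ch]], tr$values[[ch]], tolerance = 1e-6)
  }
})
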