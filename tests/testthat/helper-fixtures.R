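# Small-geometry simulation parameters for fast unit tests; acceptance
# tests use the full default geometry instead.
small_params <- function(...) {
  defaults <- list(image_size = c(64L, 64L), nucleus_radius = 20,
                   bleach_radius = 4, n_postbleach = 80L)
  do.call(frap_sim_params, utils::modifyList(defaults, list(...)))
}

# Band-limited random test image: white noise low-passed in Fourier space
# so that sub-pixel Fourier translation is exact.
band_limited_image <- function(h = 64L, w = 64L, cutoff = 0.25, seed = 1L) {
  set.seed(seed)
  img <- matrix(rnorm(h * w), h, w)
  ky <- frapkit:::fft_freq(h) / h
  kx <- frapkit:::fft_freq(w) / w
  keep <- outer(abs(ky) <= cutoff / 2, abs(kx) <= cutoff / 2, "&")
  ft <- stats::fft(img)
  ft[!keep] <- 0
  Re(stats::fft(ft, inverse = TRUE)) / (h * w)
}

# Brute-force integer-shift correlation: slides `moving` over all integer
# circular shifts and returns the alignment shift maximizing the dot
# product with `reference`.  O(n^4); tiny images only.
brute_force_integer_shift <- function(reference, moving) {
  h <- nrow(reference)
  w <- ncol(reference)
  best <- c(0L, 0L)
  best_val <- -Inf
  roll <- function(m, dy, dx) {
    m[((seq_len(h) - 1 - dy) %% h) + 1, ((seq_len(w) - 1 - dx) %% w) + 1]
  }
  for (dy in 0:(h - 1)) {
    for (dx in 0:(w - 1)) {
      val <- sum(reference * roll(moving, dy, dx))
      if (val > best_val) {
        best_val <- val
        best <- c(dy, dx)
      }
    }
  }
  if (best[1] > h / 2) best[1] <- best[1] - h
  if (best[2] > w / 2) best[2] <- best[2] - w
  best
}

# Exhaustive Otsu oracle on the same histogram construction as
# otsu_threshold: evaluates the between-class variance at every cut point
# directly from class sums and returns the winning bin edge.
brute_force_otsu <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  n <- sum(counts)
  best <- NA_integer_
  best_val <- -Inf
  for (cut in seq_len(n_bins - 1L)) {
    c0 <- sum(counts[1:cut])
    c1 <- n - c0
    if (c0 == 0 || c1 == 0) next
    mu0 <- sum(counts[1:cut] * mids[1:cut]) / c0
    mu1 <- sum(counts[(cut + 1):n_bins] * mids[(cut + 1):n_bins]) / c1
    val <- (c0 / n) * (c1 / n) * (mu0 - mu1)^2
    if (val > best_val) {   # strict: ties keep the lower cut
      best_val <- val
      best <- cut
    }
  }
  edges[best + 1L]
}

jaccard <- function(a, b) sum(a & b) / sum(a | b)
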