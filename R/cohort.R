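## Cohort-level summaries: mean +/- s.e.m. recovery curves, boxplot-style
## group summaries (median, IQR, 5th/95th percentiles), a pooled-variance
## two-sample t-test, pixel-intensity density histograms and the
## Mann-Whitney U rank test.

#' Mean and s.e.m. recovery curve across repeats
#'
#' Curves are aligned at `t = 0` and truncated to the shortest
#' post-bleach length (and shortest pre-bleach length), then averaged per
#' time point; the s.e.m. is `sd / sqrt(n)`.
#'
#' @param curves List of at least two `frap_curve` objects sharing the
#'   same frame interval.
#' @return A `frap_cohort_curve` data.frame: `time`, `mean`, `sem`, `n`.
#' @export
mean_sem_curves <- function(curves) {
  stopifnot(length(curves) >= 2L)
  dts <- vapply(curves, function(cv) attr(cv, "frame_interval"), numeric(1))
  if (max(dts) - min(dts) > 1e-9 * max(dts)) {
    stop("curves have mixed frame intervals")
  }
  n_pre <- min(vapply(curves, function(cv) sum(cv$time < 0), integer(1)))
  n_post <- min(vapply(curves, function(cv) sum(cv$time >= 0), integer(1)))
  mat <- vapply(curves, function(cv) {
    pre <- utils::tail(cv$normalized[cv$time < 0], n_pre)
    post <- utils::head(cv$normalized[cv$time >= 0], n_post)
    c(pre, post)
  }, numeric(n_pre + n_post))
  cv1 <- curves[[1]]
  time <- c(utils::tail(cv1$time[cv1$time < 0], n_pre),
            utils::head(cv1$time[cv1$time >= 0], n_post))
  n <- length(curves)
  structure(data.frame(time = time,
                       mean = rowMeans(mat),
                       sem = apply(mat, 1L, stats::sd) / sqrt(n),
                       n = n),
            class = c("frap_cohort_curve", "data.frame"))
}

#' Boxplot-style summary of a group of values
#'
#' Median, quartiles (linear interpolation) and 5th/95th percentiles, the
#' whisker convention used for mobile-fraction and half-time boxplots.
#'
#' @param values Numeric vector, `n >= 1`.
#' @return Named list: `median`, `q1`, `q3`, `p5`, `p95`, `n`.
#' @export
summarize_group <- function(values) {
  stopifnot(length(values) >= 1L)
  q <- stats::quantile(values, c(0.05, 0.25, 0.5, 0.75, 0.95),
                       names = FALSE, type = 7)
  list(median = q[3], q1 = q[2], q3 = q[4], p5 = q[1], p95 = q[5],
       n = length(values))
}

#' Two-sample t-test between groups
#'
#' Student's independent two-sample t-test with pooled variance (the
#' unqualified default; set `welch = TRUE` for unequal variances) and a
#' two-tailed p-value. Degenerate zero-variance input yields `p = 1` for
#' equal means and `p = 0` (flagged) for unequal means.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @param welch Use the Welch unequal-variance statistic instead.
#' @return List: `t`, `df`, `p`, `mean_a`, `mean_b`, `degenerate`.
#' @export
compare_groups <- function(a, b, welch = FALSE) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 2L, nb >= 2L)
  ma <- mean(a); mb <- mean(b)
  va <- stats::var(a); vb <- stats::var(b)
  if (welch) {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  } else {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- na + nb - 2
  }
  if (se2 <= 0) {
    if (ma == mb) {
      return(list(t = 0, df = df, p = 1, mean_a = ma, mean_b = mb,
                  degenerate = TRUE))
    }
    return(list(t = sign(ma - mb) * Inf, df = df, p = 0, mean_a = ma,
                mean_b = mb, degenerate = TRUE))
  }
  tval <- (ma - mb) / sqrt(se2)
  list(t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
       mean_a = ma, mean_b = mb, degenerate = FALSE)
}

#' Per-condition pixel-intensity density
#'
#' Pixel intensities are binned to fixed-width ranges (`[0, bw)`,
#' `[bw, 2 bw)`, ...), counts are summed over all images of the condition
#' and divided by the number of images.
#'
#' @param pixel_samples List of numeric vectors, one per image.
#' @param bin_width Intensity bin width (default 20).
#' @return data.frame: `lower`, `upper`, `density` (mean count per image).
#' @export
intensity_density <- function(pixel_samples, bin_width = 20) {
  stopifnot(length(pixel_samples) >= 1L)
  all_vals <- unlist(pixel_samples)
  if (!length(all_vals)) stop("empty pixel samples")
  if (min(all_vals) < 0) stop("negative intensities not supported")
  n_bins <- max(1L, ceiling((max(all_vals) + .Machine$double.eps) /
                              bin_width))
  counts <- numeric(n_bins)
  for (img in pixel_samples) {
    bin <- pmin(floor(img / bin_width) + 1L, n_bins)
    counts <- counts + tabulate(bin, nbins = n_bins)
  }
  data.frame(lower = (seq_len(n_bins) - 1L) * bin_width,
             upper = seq_len(n_bins) * bin_width,
             density = counts / length(pixel_samples))
}

#' Mann-Whitney U rank test
#'
#' `U = #\{a_i > b_j\} + ties / 2`, computed from midranks; the two-tailed
#' p-value uses the normal approximation with tie correction and a 0.5
#' continuity correction (appropriate for the large pixel samples this
#' test is applied to).
#'
#' @param a,b Numeric vectors, `n >= 1` each.
#' @return List: `U`, `p`, `n_a`, `n_b`.
#' @export
mann_whitney <- function(a, b) {
  na <- length(a); nb <- length(b)
  stopifnot(na >= 1L, nb >= 1L)
  r <- rank(c(a, b))                     # midranks for ties
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  nn <- na + nb
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  sigma2 <- na * nb / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  mu <- na * nb / 2
  p <- if (sigma2 <= 0) 1 else {
    z <- (abs(u - mu) - 0.5) / sqrt(sigma2)
    z <- max(z, 0)
    2 * stats::pnorm(-z)
  }
  list(U = u, p = min(p, 1), n_a = na, n_b = nb)
}
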