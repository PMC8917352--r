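## Bleach-spot detection: Otsu thresholding of the difference between the
## mean pre-bleach image and the mean of the first few post-bleach images,
## restricted to the nucleus, followed by selection of the 8-connected
## supra-threshold component containing the difference maximum (the bleach
## point), which makes the rule robust to bright-speckle artifacts.

#' Otsu threshold of an intensity sample
#'
#' Builds an equal-width histogram over the observed range and returns the
#' bin edge maximizing the between-class variance
#' `w0 * w1 * (mu0 - mu1)^2` over all cut points; ties are broken toward
#' the lower threshold.
#'
#' @param values Numeric sample with at least two distinct values.
#' @param n_bins Number of histogram bins (default 256).
#' @return Threshold intensity: values `> threshold` form the upper class.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  rng <- range(values)
  if (length(values) < 2L || rng[1] == rng[2]) {
    stop("Otsu threshold undefined for a constant sample")
  }
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  ## findInterval puts the maximum in its own right-closed top bin
  bin <- findInterval(values, edges, rightmost.closed = TRUE,
                      all.inside = TRUE)
  counts <- tabulate(bin, nbins = n_bins)
  mids <- (edges[-1] + edges[-(n_bins + 1L)]) / 2
  p <- counts / sum(counts)
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[n_bins]
  cut <- seq_len(n_bins - 1L)
  w1 <- 1 - w0[cut]
  valid <- w0[cut] > 0 & w1 > 0
  sigma_b <- rep(-Inf, n_bins - 1L)
  mu0 <- mu_cum[cut][valid] / w0[cut][valid]
  mu1 <- (mu_tot - mu_cum[cut][valid]) / w1[valid]
  sigma_b[valid] <- w0[cut][valid] * w1[valid] * (mu0 - mu1)^2
  best <- which.max(sigma_b)          # first maximum = lower threshold
  edges[best + 1L]
}

#' Label the 8-connected component containing a seed pixel
#' @noRd
connected_component <- function(mask, seed) {
  h <- nrow(mask)
  w <- ncol(mask)
  comp <- matrix(FALSE, h, w)
  if (!mask[seed[1], seed[2]]) return(comp)
  queue <- matrix(seed, ncol = 2L)
  comp[seed[1], seed[2]] <- TRUE
  offs <- cbind(rep(-1:1, 3), rep(-1:1, each = 3))
  offs <- offs[rowSums(offs == 0) < 2, ]
  while (nrow(queue)) {
    cur <- queue[nrow(queue), ]
    queue <- queue[-nrow(queue), , drop = FALSE]
    nb <- cbind(cur[1] + offs[, 1], cur[2] + offs[, 2])
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= h & nb[, 2] >= 1 & nb[, 2] <= w, ,
             drop = FALSE]
    keep <- mask[nb] & !comp[nb]
    if (any(keep)) {
      nb <- nb[keep, , drop = FALSE]
      comp[nb] <- TRUE
      queue <- rbind(queue, nb)
    }
  }
  comp
}

#' Dilate a binary mask by square structuring elements
#' @noRd
dilate_mask <- function(mask, iterations = 1L) {
  for (i in seq_len(iterations)) {
    h <- nrow(mask); w <- ncol(mask)
    out <- mask
    out[-1, ] <- out[-1, ] | mask[-h, ]
    out[-h, ] <- out[-h, ] | mask[-1, ]
    out[, -1] <- out[, -1] | mask[, -w]
    out[, -w] <- out[, -w] | mask[, -1]
    mask <- out
  }
  mask
}

#' Detect the bleached region from a registered movie
#'
#' Computes `diff = mean(pre-bleach frames) - mean(first n_post_for_diff
#' post-bleach frames)`, thresholds `diff` inside the nucleus with
#' [otsu_threshold()], and returns the 8-connected supra-threshold
#' component containing the maximum of `diff`, intersected with the
#' nucleus. Pixels outside the nucleus never vote.
#'
#' @param movie A registered [frap_movie()].
#' @param nucleus Logical nucleus mask (same spatial shape as the frames,
#'   at least 50 pixels).
#' @param n_post_for_diff Number of initial post-bleach frames averaged
#'   for the difference image (default 5).
#' @param n_bins Histogram bins for the Otsu threshold.
#' @param roi_dilate Optional dilation of the detected ROI, pixels.
#' @return A `frap_roi` list: `mask` (logical), `area` (pixels),
#'   `centroid` `(y, x)`, `mean_diff_value`, `threshold`.
#' @export
detect_bleach_roi <- function(movie, nucleus, n_post_for_diff = 5L,
                              n_bins = 256L, roi_dilate = 0L) {
  d <- dim(movie$frames)
  stopifnot(identical(dim(nucleus), d[2:3]))
  if (sum(nucleus) < 50L) stop("nucleus mask must contain >= 50 pixels")
  n_pre <- movie$n_prebleach
  if (d[1] < n_pre + n_post_for_diff) {
    stop("movie too short for the requested difference window")
  }
  pre <- colMeans(movie$frames[seq_len(n_pre), , , drop = FALSE], dims = 1L)
  post <- colMeans(movie$frames[n_pre + seq_len(n_post_for_diff), , ,
                                drop = FALSE], dims = 1L)
  diff <- pre - post

  vals <- diff[nucleus]
  th <- tryCatch(otsu_threshold(vals, n_bins = n_bins),
                 error = function(e) NULL)
  if (is.null(th)) stop("bleach not detected (difference image is flat)")
  supra <- nucleus & diff > th
  if (!any(supra)) stop("bleach not detected (no supra-threshold pixels)")

  ## seed at the in-nucleus difference maximum (the bleach point)
  dmasked <- diff
  dmasked[!nucleus] <- -Inf
  seed <- arrayInd(which.max(dmasked), d[2:3])[1, ]
  roi <- connected_component(supra, seed)
  if (roi_dilate > 0) roi <- dilate_mask(roi, roi_dilate) & nucleus
  area <- sum(roi)
  if (area < 4L) stop("bleach not detected (ROI smaller than 4 pixels)")
  idx <- which(roi, arr.ind = TRUE)
  structure(list(mask = roi,
                 area = area,
                 centroid = c(y = mean(idx[, 1]), x = mean(idx[, 2])),
                 mean_diff_value = mean(diff[roi]),
                 threshold = th),
            class = "frap_roi")
}

#' @export
print.frap_roi <- function(x, ...) {
  cat(sprintf(
    "bleach ROI: %d px, centroid (%.1f, %.1f), mean diff %.3f (thr %.3f)\n",
    x$area, x$centroid[1], x$centroid[2], x$mean_diff_value, x$threshold))
  invisible(x)
}
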