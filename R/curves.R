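## Recovery-curve processing: ROI/nucleus intensity extraction, removal of
## acquisition photobleaching by a fitted monoexponential decay, and double
## normalization (pre-bleach mean = 1, immediate post-bleach = 0).

#' Mean-intensity time series of a masked region
#'
#' @param movie A [frap_movie()] (usually registered).
#' @param mask Logical matrix, same spatial shape as the frames, nonempty.
#' @return A `frap_series` data.frame with columns `frame` (0-based),
#'   `time` (seconds, `t = 0` at the first post-bleach frame) and `value`
#'   (arithmetic mean of the masked pixels); attributes `n_prebleach`,
#'   `frame_interval`, `source_id`.
#' @export
extract_series <- function(movie, mask) {
  d <- dim(movie$frames)
  stopifnot(identical(dim(mask), d[2:3]))
  idx <- which(mask)
  if (!length(idx)) stop("mask is empty")
  flat <- matrix(movie$frames, nrow = d[1])       # frames x (h*w)
  value <- rowMeans(flat[, idx, drop = FALSE])
  out <- data.frame(frame = seq_len(d[1]) - 1L,
                    time = frame_times(movie),
                    value = value)
  structure(out, class = c("frap_series", "data.frame"),
            n_prebleach = movie$n_prebleach,
            frame_interval = movie$frame_interval,
            source_id = movie$source_id)
}

#' Fit the acquisition-photobleaching decay
#'
#' Least-squares fit of `A * exp(-k * t)` to the post-bleach portion of a
#' whole-nucleus intensity series (`t` in seconds from the first
#' post-bleach frame). Initialized at `A0 =` first post-bleach value and
#' `k0` from a log-linear regression of the positive values; `k` is
#' bounded below by 0.
#'
#' @param series A `frap_series` from [extract_series()] (whole nucleus).
#' @return A `frap_decay` list: `A`, `k` (per second), `rss`.
#' @export
fit_acquisition_decay <- function(series) {
  post <- series[series$time >= 0, ]
  if (nrow(post) < 10L) stop("need at least 10 post-bleach points")
  y <- post$value
  t <- post$time
  if (!all(is.finite(y))) stop("non-finite intensities in decay fit")

  a0 <- y[1]
  pos <- y > 0
  k0 <- 0
  if (sum(pos) >= 2L) {
    sl <- stats::coef(stats::lm(log(y[pos]) ~ t[pos]))[2]
    k0 <- max(-sl, 0)
  }
  rss_fun <- function(par) sum((y - par[1] * exp(-par[2] * t))^2)
  fit <- stats::optim(c(A = max(a0, .Machine$double.eps), k = k0), rss_fun,
                      method = "L-BFGS-B",
                      lower = c(1e-12, 0),
                      control = list(factr = 1e2, maxit = 500L))
  structure(list(A = unname(fit$par[1]), k = unname(fit$par[2]),
                 rss = fit$value),
            class = "frap_decay")
}

#' Correct acquisition bleaching and double-normalize a recovery curve
#'
#' The ROI series is divided by `exp(-k * t)` on the shared experiment
#' clock (pre-bleach frames carry negative `t` and are corrected on the
#' same clock), then rescaled to `(corrected - C0) / (C_pre - C0)` where
#' `C_pre` is the mean corrected pre-bleach value and `C0` the corrected
#' value at the first post-bleach frame. By construction the normalized
#' pre-bleach mean is exactly 1 and the first post-bleach value exactly 0.
#'
#' @param roi_series A `frap_series` of the bleach-ROI mean intensity.
#' @param decay A `frap_decay` from [fit_acquisition_decay()].
#' @return A `frap_curve` data.frame: columns `frame`, `time`, `raw`,
#'   `corrected`, `normalized`; attributes as in [extract_series()].
#' @export
correct_and_normalize <- function(roi_series, decay) {
  if (!is_number(decay$k)) stop("decay rate k must be finite")
  n_pre <- attr(roi_series, "n_prebleach")
  t <- roi_series$time
  raw <- roi_series$value
  corrected <- raw / exp(-decay$k * t)
  pre <- t < 0
  c_pre <- mean(corrected[pre])
  c0 <- corrected[which(t >= 0)[1]]
  denom <- c_pre - c0
  if (!is.finite(denom) ||
      abs(denom) <= 1e-12 * max(abs(c_pre), abs(c0), 1)) {
    stop("no bleach detected in curve (pre-bleach and post-bleach levels ",
         "coincide)")
  }
  normalized <- (corrected - c0) / denom
  out <- data.frame(frame = roi_series$frame, time = t, raw = raw,
                    corrected = corrected, normalized = normalized)
  structure(out, class = c("frap_curve", "data.frame"),
            n_prebleach = n_pre,
            frame_interval = attr(roi_series, "frame_interval"),
            source_id = attr(roi_series, "source_id"))
}

#' Write a recovery curve as CSV
#' @param curve A `frap_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  utils::write.csv(as.data.frame(curve)[, c("frame", "time", "raw",
                                            "corrected", "normalized")],
                   path, row.names = FALSE)
  invisible(path)
}
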