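## Monoexponential recovery fitting.  The normalized post-bleach curve is
## fitted with F(t) = M * (1 - exp(-t / tau)); no offset term is needed
## because normalization pins F(0) = 0.  The mobile fraction is the fitted
## model evaluated at the last recorded time point, and the half-time is
## read directly from the data (first crossing of half the tail-mean
## "maximum", linearly interpolated).

#' Fit the monoexponential recovery model
#'
#' Nonlinear least squares of `F(t) = M * (1 - exp(-t / tau))` to the
#' normalized post-bleach points. `tau` is profiled out by a bounded 1-D
#' golden-section search on `log(tau)` with the amplitude solved in closed
#' form at each step (clamped to `[0, 1.5]`), which is robust for
#' zero-residual and degenerate inputs. Initialization: `M0` from the mean
#' of the final 5% of points, `tau0` from the first crossing of
#' `(1 - 1/e) * M0` (fallback `T_last / 3`). The mobile fraction is the
#' fitted model value at `T_last`; out-of-`[0, 1]` values are flagged in
#' `qc_flags`, never clamped.
#'
#' @param curve A `frap_curve` from [correct_and_normalize()] with at
#'   least 20 post-bleach points.
#' @param tail_fraction Fraction of final points defining the plateau
#'   initialization (default 0.05).
#' @return A `frap_fit` list: `plateau` (M), `tau` (s), `mobile_fraction`,
#'   `t_half` (filled by [estimate_t_half()] in the pipeline, else `NA`),
#'   `rss`, `converged`, `qc_flags`, `n_pre`, `n_post`, `source_id`.
#' @export
fit_recovery <- function(curve, tail_fraction = 0.05) {
  post <- curve[curve$time >= 0, ]
  if (nrow(post) < 20L) stop("need at least 20 post-bleach points")
  y <- post$normalized
  t <- post$time
  if (!all(is.finite(y))) stop("non-finite values in normalized curve")
  t_last <- t[length(t)]
  qc <- character(0)

  n_tail <- max(1L, ceiling(tail_fraction * length(y)))
  m0 <- mean(utils::tail(y, n_tail))
  cross <- which(y >= (1 - exp(-1)) * m0 & t > 0)
  tau0 <- if (length(cross) && m0 > 0) t[cross[1]] else t_last / 3
  if (tau0 <= 0) tau0 <- t_last / 3

  ## profile amplitude: for fixed tau the LS-optimal M is
  ## sum(y * g) / sum(g^2), g = 1 - exp(-t / tau), clamped to the bounds
  prof_m <- function(tau) {
    g <- 1 - exp(-t / tau)
    s2 <- sum(g^2)
    if (s2 == 0) return(0)
    min(max(sum(y * g) / s2, 0), 1.5)
  }
  prof_rss <- function(ltau) {
    tau <- exp(ltau)
    g <- 1 - exp(-t / tau)
    sum((y - prof_m(tau) * g)^2)
  }
  lower <- log(min(t[t > 0]) / 100)
  upper <- log(100 * t_last)
  opt <- tryCatch(
    stats::optimize(prof_rss, interval = c(lower, upper), tol = 1e-12),
    error = function(e) NULL)
  converged <- !is.null(opt)
  if (converged) {
    ## a profile minimum this close to the search bounds means tau is not
    ## identified by the data (e.g. flat curves)
    at_bound <- opt$minimum < lower + 1e-6 || opt$minimum > upper - 1e-6
    tau_hat <- exp(opt$minimum)
    m_hat <- prof_m(tau_hat)
    rss <- opt$objective
    ## seed comparison: keep the initialization if it is already better
    rss0 <- sum((y - prof_m(tau0) * (1 - exp(-t / tau0)))^2)
    if (rss0 < rss) {
      tau_hat <- tau0
      m_hat <- prof_m(tau0)
      rss <- rss0
    }
    if (m_hat < 1e-8) {
      qc <- c(qc, "no_recovery")
    } else if (at_bound) {
      qc <- c(qc, "tau_at_bound")
    }
  } else {
    tau_hat <- tau0
    m_hat <- prof_m(tau0)
    rss <- sum((y - m_hat * (1 - exp(-t / tau_hat)))^2)
    qc <- c(qc, "fit_failed")
  }
  mobile <- m_hat * (1 - exp(-t_last / tau_hat))
  if (mobile < 0 || mobile > 1) qc <- c(qc, "mobile_out_of_range")

  structure(list(plateau = m_hat,
                 tau = tau_hat,
                 mobile_fraction = mobile,
                 t_half = NA_real_,
                 rss = rss,
                 converged = converged,
                 qc_flags = qc,
                 n_pre = attr(curve, "n_prebleach"),
                 n_post = nrow(post),
                 source_id = attr(curve, "source_id")),
            class = "frap_fit")
}

#' @export
print.frap_fit <- function(x, ...) {
  cat(sprintf(
    "recovery fit '%s': mobile fraction %.3f, tau %.3f s, t_half %.3f s\n",
    x$source_id %||% "?", x$mobile_fraction, x$tau, x$t_half))
  if (length(x$qc_flags)) cat("  qc:", paste(x$qc_flags, collapse = ", "),
                              "\n")
  invisible(x)
}

#' Half-time of recovery, read directly from the data
#'
#' The fluorescence "maximum" is the mean of the normalized values over
#' the final `tail_fraction` of post-bleach points; `t_half` is the first
#' time the normalized data crosses half that maximum, with linear
#' interpolation between the bracketing frames. Returns `NA` (and records
#' a QC flag on `fit` if supplied) when the curve never crosses.
#'
#' @param curve A `frap_curve`.
#' @param fit Optional `frap_fit` to annotate; its `t_half` field is
#'   filled in.
#' @param tail_fraction Tail window defining the maximum (default 0.05).
#' @return If `fit` is supplied, the annotated `frap_fit`; otherwise the
#'   half-time in seconds (`NA` if undefined).
#' @export
estimate_t_half <- function(curve, fit = NULL, tail_fraction = 0.05) {
  post <- curve[curve$time >= 0, ]
  y <- post$normalized
  t <- post$time
  n_tail <- max(1L, ceiling(tail_fraction * length(y)))
  ref <- mean(utils::tail(y, n_tail))
  half <- ref / 2
  th <- NA_real_
  if (ref > 0) {
    hit <- which(y >= half)
    hit <- hit[hit > 1L]                  # y[1] = 0 by construction
    if (length(hit)) {
      i <- hit[1]
      y0 <- y[i - 1L]; y1 <- y[i]
      th <- if (y1 > y0) {
        t[i - 1L] + (half - y0) / (y1 - y0) * (t[i] - t[i - 1L])
      } else {
        t[i]
      }
    }
  }
  if (is.null(fit)) return(th)
  fit$t_half <- th
  if (is.na(th)) fit$qc_flags <- union(fit$qc_flags, "t_half_undefined")
  fit
}

#' Run the full per-movie FRAP pipeline
#'
#' Composes, in order: drift correction ([register_stack()]), bleach-ROI
#' detection ([detect_bleach_roi()]), ROI and whole-nucleus series
#' extraction ([extract_series()]), acquisition-bleaching fit
#' ([fit_acquisition_decay()]), double normalization
#' ([correct_and_normalize()]), recovery fit ([fit_recovery()]) and
#' half-time estimation ([estimate_t_half()]). Any stage error is
#' re-thrown tagged with the stage name and the movie's `source_id`.
#'
#' @param movie A [frap_movie()].
#' @param nucleus Logical nucleus mask.
#' @param config Configuration list, see [default_config()].
#' @return List with `fit` (`frap_fit`), `curve` (`frap_curve`), `roi`
#'   (`frap_roi`), `drift` (registration trajectory data.frame), `decay`
#'   (`frap_decay`).
#' @export
analyze_movie <- function(movie, nucleus, config = default_config()) {
  sid <- movie$source_id
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stage_stop(stage, sid, conditionMessage(e))
    })
  }
  reg <- run("registration",
             register_stack(movie, upsample = config$upsample))
  roi <- run("bleach_detection",
             detect_bleach_roi(reg$movie, nucleus,
                               n_post_for_diff = config$n_post_for_diff,
                               n_bins = config$otsu_bins,
                               roi_dilate = config$roi_dilate))
  roi_series <- run("extraction", extract_series(reg$movie, roi$mask))
  nuc_mask <- nucleus
  if (isTRUE(config$decay_exclude_roi)) nuc_mask <- nucleus & !roi$mask
  nuc_series <- run("extraction", extract_series(reg$movie, nuc_mask))
  decay <- run("decay_fit", fit_acquisition_decay(nuc_series))
  curve <- run("normalization", correct_and_normalize(roi_series, decay))
  fit <- run("recovery_fit",
             fit_recovery(curve, tail_fraction = config$tail_fraction))
  fit <- run("t_half",
             estimate_t_half(curve, fit,
                             tail_fraction = config$tail_fraction))
  list(fit = fit, curve = curve, roi = roi, drift = reg$drift,
       decay = decay)
}

#' QC plot of a fitted recovery curve
#'
#' Normalized data with the fitted monoexponential overlay and the
#' half-time marker.
#'
#' @param x A `frap_curve`.
#' @param fit Optional `frap_fit` overlay.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.frap_curve <- function(x, fit = NULL, ...) {
  graphics::plot(x$time, x$normalized, pch = 16, cex = 0.4,
                 col = "grey40", xlab = "time (s)",
                 ylab = "normalized intensity", ...)
  graphics::abline(h = c(0, 1), lty = 3, col = "grey70")
  if (!is.null(fit)) {
    tt <- seq(0, max(x$time), length.out = 200)
    graphics::lines(tt, fit$plateau * (1 - exp(-tt / fit$tau)),
                    col = "firebrick", lwd = 2)
    if (is.finite(fit$t_half %||% NA)) {
      graphics::abline(v = fit$t_half, lty = 2, col = "steelblue")
    }
  }
  invisible(x)
}
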