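## Internal helpers shared across modules.

#' Signed DFT frequency indices for a length-n axis
#'
#' Returns integer frequencies `0, 1, ..., floor(n/2), -(n - floor(n/2) - 1),
#' ..., -1` in FFT storage order (Nyquist kept positive for even n).
#' @noRd
fft_freq <- function(n) {
  k <- 0L:(n - 1L)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

#' Disk mask on a pixel grid
#'
#' Pixel (y, x) is inside when the distance of its centre from `center`
#' is <= `radius`. 1-based pixel coordinates.
#' @noRd
disk_mask <- function(h, w, center, radius) {
  dy <- (1:h) - center[1]
  dx <- (1:w) - center[2]
  outer(dy^2, dx^2, "+") <= radius^2
}

#' Translate an image by (dy, dx) pixels via Fourier phase shift
#'
#' Positive dy moves content toward larger row indices; periodic boundary.
#' The DC term is untouched, so the total intensity is preserved.
#' @noRd
fourier_translate <- function(image, dy, dx) {
  if (dy == 0 && dx == 0) return(image)
  h <- nrow(image)
  w <- ncol(image)
  ky <- fft_freq(h)
  kx <- fft_freq(w)
  phase <- exp(-2i * pi * (outer(ky, rep(1, w)) * dy / h +
                           outer(rep(1, h), kx) * dx / w))
  Re(stats::fft(stats::fft(image) * phase, inverse = TRUE)) / (h * w)
}

#' Stop with a stage-tagged error message
#' @noRd
stage_stop <- function(stage, source_id, message) {
  stop(sprintf("[stage %s] [%s] %s", stage, source_id %||% "unknown", message),
       call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Check a scalar is a finite number
#' @noRd
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
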