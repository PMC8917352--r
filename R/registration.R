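## Sub-pixel translational registration by upsampled cross-correlation:
## the integer-pixel estimate comes from the inverse-FFT cross-correlation
## peak and is refined by a matrix-multiply DFT evaluated only in a
## 1.5 x 1.5-pixel neighborhood of the peak at a resolution of 1/upsample
## pixel.  This avoids ever forming the fully upsampled correlation plane.

#' Estimate the translation aligning one image onto another
#'
#' Returns the shift that [apply_shift()] must receive to align `moving`
#' onto `reference`: if `moving` equals `reference` translated by
#' `(sy, sx)`, the estimate is `(-sy, -sx)`.
#'
#' @param reference,moving Numeric matrices of identical dimensions.
#' @param upsample Integer refinement factor (>= 1); final resolution is
#'   `1/upsample` pixel.
#' @return A `frap_shift` list with elements `dy`, `dx` (signed sub-pixel
#'   shifts) and `peak_error` (normalized inverse correlation-peak height;
#'   0 for a perfect match).
#' @references Guizar-Sicairos, Thurman & Fienup (2008) Efficient subpixel
#'   image registration algorithms. Optics Letters 33, 156-158.
#' @export
estimate_shift <- function(reference, moving, upsample = 100L) {
  stopifnot(identical(dim(reference), dim(moving)), upsample >= 1)
  if (stats::sd(reference) == 0 || stats::sd(moving) == 0) {
    stop("cannot register an all-constant image (no correlation peak)")
  }
  h <- nrow(reference)
  w <- ncol(reference)
  f1 <- stats::fft(reference)
  f2 <- stats::fft(moving)
  cp <- f1 * Conj(f2)
  cc <- stats::fft(cp, inverse = TRUE) / (h * w)
  pk <- which.max(Mod(cc))
  py <- (pk - 1L) %% h
  px <- (pk - 1L) %/% h
  dy <- as.numeric(if (py > h / 2) py - h else py)
  dx <- as.numeric(if (px > w / 2) px - w else px)
  peak <- cc[pk] * (h * w)

  if (upsample > 1) {
    us <- as.integer(upsample)
    npts <- ceiling(1.5 * us) + 1L
    off <- ((0:(npts - 1L)) - floor(npts / 2)) / us
    ugrid <- dy + off
    vgrid <- dx + off
    ky <- fft_freq(h)
    kx <- fft_freq(w)
    kernr <- exp(2i * pi * outer(ugrid, ky) / h)   # npts x h
    kernc <- exp(2i * pi * outer(kx, vgrid) / w)   # w x npts
    ccu <- kernr %*% cp %*% kernc
    pk2 <- arrayInd(which.max(Mod(ccu)), dim(ccu))
    dy <- ugrid[pk2[1]]
    dx <- vgrid[pk2[2]]
    peak <- ccu[pk2[1], pk2[2]]
  }
  denom <- sqrt(sum(Mod(f1)^2) * sum(Mod(f2)^2))
  err <- sqrt(max(0, 1 - Mod(peak)^2 / denom^2))
  structure(list(dy = dy, dx = dx, peak_error = err), class = "frap_shift")
}

#' @export
print.frap_shift <- function(x, ...) {
  cat(sprintf("shift (dy, dx) = (%.4f, %.4f), peak_error = %.4g\n",
              x$dy, x$dx, x$peak_error))
  invisible(x)
}

#' Translate an image by a sub-pixel shift
#'
#' Fourier phase shift with periodic boundary conditions; the DC term is
#' unchanged, so total intensity is preserved to floating-point precision.
#'
#' @param image Numeric matrix.
#' @param shift A `frap_shift`, or a length-2 numeric `(dy, dx)`.
#' @return Translated image (real matrix).
#' @export
apply_shift <- function(image, shift) {
  if (inherits(shift, "frap_shift")) shift <- c(shift$dy, shift$dx)
  stopifnot(length(shift) == 2L, all(is.finite(shift)))
  fourier_translate(image, shift[1], shift[2])
}

#' Register every frame of a movie to the pre-bleach mean
#'
#' The reference is the mean of the pre-bleach frames (highest SNR and
#' unaffected by the bleach pulse). Each frame's shift is estimated
#' independently against this fixed reference and applied by Fourier phase
#' shift.
#'
#' @param movie A [frap_movie()].
#' @param upsample Registration refinement factor, see [estimate_shift()].
#' @return List with `movie` (registered [frap_movie()]) and `drift`
#'   (data.frame `frame` (0-based), `dy`, `dx`: the alignment shift applied
#'   to each frame; the negated estimated drift).
#' @export
register_stack <- function(movie, upsample = 100L) {
  n <- dim(movie$frames)[1]
  stopifnot(n >= 2L)
  reference <- colMeans(movie$frames[seq_len(movie$n_prebleach), , ,
                                     drop = FALSE], dims = 1L)
  registered <- movie$frames
  dy <- numeric(n)
  dx <- numeric(n)
  for (f in seq_len(n)) {
    sh <- tryCatch(
      estimate_shift(reference, movie$frames[f, , ], upsample = upsample),
      error = function(e) {
        stop(sprintf("registration failed at frame %d: %s", f - 1L,
                     conditionMessage(e)), call. = FALSE)
      })
    dy[f] <- sh$dy
    dx[f] <- sh$dx
    if (sh$dy != 0 || sh$dx != 0) {
      registered[f, , ] <- apply_shift(movie$frames[f, , ], sh)
    }
  }
  out <- movie
  out$frames <- registered
  list(movie = out,
       drift = data.frame(frame = seq_len(n) - 1L, dy = dy, dx = dx))
}
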