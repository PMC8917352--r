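## Fixed-bin genomic signal tracks and the ChIP spreading statistics:
## z-score standardization to an autosomal background, equalization of
## total signal over a target chromosome set, and moving-window averaging.
## Coordinates are zero-based half-open bins of constant size.

#' Fixed-bin genomic signal track
#'
#' @param values Named list of numeric vectors, one per chromosome, in
#'   bin order (bin `i` covers `[(i-1) * bin_size, i * bin_size)`).
#' @param bin_size Bin size in bp.
#' @return A `binned_track` object.
#' @export
binned_track <- function(values, bin_size) {
  stopifnot(is.list(values), length(values) >= 1L,
            !is.null(names(values)), all(nzchar(names(values))))
  if (!is_number(bin_size) || bin_size <= 0) {
    stop("bin_size must be a positive number")
  }
  structure(list(values = lapply(values, as.numeric),
                 bin_size = as.numeric(bin_size)),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("binned_track: %d chromosome(s), %g bp bins\n",
              length(x$values), x$bin_size))
  for (ch in names(x$values)) {
    cat(sprintf("  %s: %d bins\n", ch, length(x$values[[ch]])))
  }
  invisible(x)
}

#' @export
as.data.frame.binned_track <- function(x, ...) {
  do.call(rbind, lapply(names(x$values), function(ch) {
    v <- x$values[[ch]]
    data.frame(chrom = ch,
               start = (seq_along(v) - 1L) * x$bin_size,
               end = seq_along(v) * x$bin_size,
               value = v, stringsAsFactors = FALSE)
  }))
}

check_chroms <- function(track, chroms) {
  missing <- setdiff(chroms, names(track$values))
  if (length(missing)) {
    stop("chromosomes absent from track: ", paste(missing, collapse = ", "))
  }
}

#' Z-score standardization against a background chromosome set
#'
#' Every bin genome-wide is transformed to
#' `z = (value - mu_bg) / sigma_bg`, where the mean and s.d. are computed
#' from the bins of the background chromosomes only (typically the
#' autosomes not involved in the enrichment, e.g. chromosomes I-IV). The
#' background set is an explicit required argument and is never inferred.
#'
#' @param track A [binned_track()].
#' @param background_chroms Character vector of background chromosomes.
#' @return Standardized [binned_track()].
#' @export
zscore_standardize <- function(track, background_chroms) {
  check_chroms(track, background_chroms)
  bg <- unlist(track$values[background_chroms], use.names = FALSE)
  if (length(bg) < 2L) stop("background must contain at least 2 bins")
  mu <- mean(bg)
  sigma <- stats::sd(bg)
  if (sigma == 0) stop("background signal is constant; z-score undefined")
  track$values <- lapply(track$values, function(v) (v - mu) / sigma)
  track
}

#' Equalize the total signal over a target chromosome set to 1
#'
#' All bins genome-wide are scaled by the single constant that makes the
#' sum of the signal over `target_chroms` equal to 1, so replicate tracks
#' become directly comparable.
#'
#' @param track A [binned_track()].
#' @param target_chroms Character vector of chromosomes whose summed
#'   signal is fixed to 1 (e.g. a fusion chromosome).
#' @return Rescaled [binned_track()].
#' @export
equalize_total <- function(track, target_chroms) {
  check_chroms(track, target_chroms)
  total <- sum(unlist(track$values[target_chroms], use.names = FALSE))
  if (total == 0) stop("total signal on target chromosomes is zero")
  track$values <- lapply(track$values, function(v) v / total)
  track
}

#' Moving-window average of a track
#'
#' For every window start on the step grid, the mean of the covered bins.
#' Windows never span chromosomes; trailing partial windows are dropped.
#'
#' @param track A [binned_track()].
#' @param window Window size in bp (default 500 kb); must be a multiple
#'   of the bin size and at least one bin.
#' @param step Step size in bp (default 50 kb); must be a multiple of the
#'   bin size.
#' @return data.frame: `chrom`, `start`, `end`, `value` (window mean).
#'   Chromosomes shorter than one window contribute no rows.
#' @export
sliding_mean <- function(track, window = 5e5, step = 5e4) {
  bs <- track$bin_size
  if (window < bs) stop("window must be at least one bin")
  if (window %% bs != 0 || step %% bs != 0) {
    stop("window and step must be multiples of the bin size")
  }
  wb <- as.integer(window / bs)
  sb <- as.integer(step / bs)
  out <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    n <- length(v)
    if (n < wb) return(NULL)
    starts <- seq.int(1L, n - wb + 1L, by = sb)
    cs <- c(0, cumsum(v))
    means <- (cs[starts + wb] - cs[starts]) / wb
    data.frame(chrom = ch,
               start = (starts - 1L) * bs,
               end = (starts - 1L) * bs + window,
               value = means, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), value = numeric(0))
  }
  rownames(out) <- NULL
  out
}

#' Read a bedGraph file into a binned track
#'
#' Uses \pkg{rtracklayer} for parsing. Intervals must tile each
#' chromosome with a single constant width (fixed-bin track).
#'
#' @param path bedGraph path.
#' @return A [binned_track()].
#' @export
read_bedgraph <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE)) {
    stop("read_bedgraph requires the rtracklayer package")
  }
  gr <- rtracklayer::import(path, format = "bedGraph")
  df <- as.data.frame(gr)
  widths <- unique(df$width)
  if (length(widths) != 1L) {
    stop("bedGraph is not a fixed-bin track (mixed interval widths)")
  }
  bs <- widths
  values <- lapply(split(df, as.character(df$seqnames)), function(d) {
    d <- d[order(d$start), ]
    if (any((d$start - 1) %% bs != 0)) {
      stop("bedGraph intervals are not aligned to the bin grid")
    }
    n <- max(d$end) / bs
    v <- numeric(n)
    v[(d$start - 1) / bs + 1] <- d$score
    v
  })
  binned_track(values, bs)
}

#' Write a binned track as bedGraph
#'
#' @param track A [binned_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  df <- as.data.frame(track)
  df$start <- as.integer(df$start)     # avoid scientific notation
  df$end <- as.integer(df$end)
  dt <- data.table::as.data.table(df[, c("chrom", "start", "end", "value")])
  data.table::fwrite(dt, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
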