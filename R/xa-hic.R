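## Hi-C contact-decay statistics on balanced, binned contact matrices:
## per-chromosome average contact probability P(s) by off-diagonal
## distance, unity normalization over a stated separation range, and the
## X-to-autosome ratio curve.  Matrix balancing itself is out of scope;
## inputs are taken as already-normalized counts.

#' Contact matrix set
#'
#' @param matrices Named list of symmetric, non-negative, per-chromosome
#'   square matrices of binned contact counts.
#' @param bin_size Bin size in bp (default 5000).
#' @return A `contact_matrix_set` object.
#' @export
contact_matrix_set <- function(matrices, bin_size = 5000) {
  stopifnot(is.list(matrices), length(matrices) >= 1L,
            !is.null(names(matrices)))
  for (ch in names(matrices)) {
    m <- matrices[[ch]]
    if (!is.matrix(m) || nrow(m) != ncol(m)) {
      stop("contact matrix for ", ch, " must be square")
    }
    if (!all(is.finite(m))) stop("non-finite entries in matrix for ", ch)
    if (max(abs(m - t(m))) > 1e-8 * max(abs(m), 1)) {
      stop("contact matrix for ", ch, " is not symmetric")
    }
  }
  structure(list(matrices = matrices, bin_size = as.numeric(bin_size)),
            class = "contact_matrix_set")
}

#' Average contact probability by genomic separation
#'
#' For each off-diagonal distance `d = s / bin_size` up to `max_depth`,
#' the mean of the matrix entries at that distance: `P(s)` for
#' `s = bin_size, 2 * bin_size, ...`.
#'
#' @param matrix Symmetric square matrix of contact counts, or a
#'   [contact_matrix_set()] (then a named list of curves is returned).
#' @param bin_size Bin size in bp (ignored for a set).
#' @param max_depth Largest separation considered, bp (default 20 Mb).
#' @return data.frame `s`, `p` (or a named list of such data.frames).
#' @export
contact_decay <- function(matrix, bin_size = 5000, max_depth = 2e7) {
  if (inherits(matrix, "contact_matrix_set")) {
    return(lapply(matrix$matrices, contact_decay,
                  bin_size = matrix$bin_size, max_depth = max_depth))
  }
  n <- nrow(matrix)
  dmax <- min(n - 1L, floor(max_depth / bin_size))
  if (dmax < 1L) {
    return(structure(data.frame(s = numeric(0), p = numeric(0)),
                     class = c("decay_curve", "data.frame")))
  }
  p <- vapply(seq_len(dmax), function(d) {
    i <- seq_len(n - d)
    mean(matrix[cbind(i, i + d)])
  }, numeric(1))
  structure(data.frame(s = seq_len(dmax) * bin_size, p = p),
            class = c("decay_curve", "data.frame"))
}

#' Normalize a contact-decay curve to unity over a separation range
#'
#' Divides the curve by the sum of `P(s)` over `range[1] <= s <=
#' range[2]` (default 5 kb to 4 Mb) so that sum becomes exactly 1,
#' making curves from differently sequenced samples comparable.
#'
#' @param curve A `decay_curve` data.frame (`s`, `p`).
#' @param range Length-2 numeric separation range in bp.
#' @return Normalized `decay_curve`.
#' @export
unity_normalize_decay <- function(curve, range = c(5e3, 4e6)) {
  sel <- curve$s >= range[1] & curve$s <= range[2]
  if (!any(sel)) stop("decay curve has no support in the given range")
  total <- sum(curve$p[sel])
  if (total == 0) stop("zero total contact probability in the given range")
  curve$p <- curve$p / total
  curve
}

#' X-to-autosome contact-decay ratio curve
#'
#' `ratio(s) = P(s, chrX) / mean_A P(s, chrA)`, the unweighted mean over
#' autosomes, computed on the shared separation grid of unity-normalized
#' per-chromosome curves. Undefined (NA) where the autosomal mean is 0.
#'
#' @param decays Named list of unity-normalized `decay_curve` objects.
#' @param x_chrom Name of the X chromosome entry.
#' @param autosomes Character vector of autosome entries.
#' @return data.frame `s`, `ratio`.
#' @export
xa_ratio <- function(decays, x_chrom = "chrX",
                     autosomes = setdiff(names(decays), x_chrom)) {
  stopifnot(x_chrom %in% names(decays), length(autosomes) >= 1L,
            all(autosomes %in% names(decays)))
  s <- decays[[x_chrom]]$s
  for (ch in autosomes) s <- intersect(s, decays[[ch]]$s)
  if (!length(s)) stop("no overlapping separation support across curves")
  s <- sort(s)
  px <- decays[[x_chrom]]$p[match(s, decays[[x_chrom]]$s)]
  pa <- rowMeans(vapply(autosomes, function(ch) {
    decays[[ch]]$p[match(s, decays[[ch]]$s)]
  }, numeric(length(s))))
  ratio <- ifelse(pa > 0, px / pa, NA_real_)
  data.frame(s = s, ratio = ratio)
}

#' Simulate power-law contact matrices with an X-specific enrichment band
#'
#' Autosome matrices have expected entries proportional to
#' `(d * bin_size)^-alpha` at off-diagonal distance `d`; the X-chromosome
#' matrix is additionally multiplied by `x_factor` for separations inside
#' `x_band`. Matrices are symmetric by construction; optional Poisson
#' counting noise is applied to the upper triangle and mirrored.
#'
#' @param n_bins Bins per chromosome (default 400).
#' @param bin_size Bin size in bp (default 5000).
#' @param alpha Power-law decay exponent (> 0, default 1.5).
#' @param n_autosomes Number of autosome matrices (default 4, named
#'   chrI..chrIV).
#' @param x_band Length-2 separation range (bp) of the X enrichment
#'   (default 50 kb to 1 Mb).
#' @param x_factor Multiplicative X enrichment inside the band
#'   (default 1.5; 1 = no enrichment).
#' @param depth Expected count at one-bin separation, sets the Poisson
#'   signal-to-noise (default 20000, a deeply sequenced, replicate-merged
#'   map; entries are normalized counts, not raw reads).
#' @param noise `"none"` (expected values) or `"poisson"`.
#' @param seed Integer seed.
#' @return List: `matrices` (a [contact_matrix_set()]), `truth` (list
#'   `alpha`, `x_factor`, `x_band`).
#' @export
simulate_contact_matrix <- function(n_bins = 400L, bin_size = 5000,
                                    alpha = 1.5, n_autosomes = 4L,
                                    x_band = c(5e4, 1e6), x_factor = 1.5,
                                    depth = 20000,
                                    noise = c("none", "poisson"),
                                    seed = 1L) {
  noise <- match.arg(noise)
  stopifnot(alpha > 0, x_band[1] < x_band[2], n_bins >= 2L)
  set.seed(seed)
  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  s <- d * bin_size
  expected <- matrix(0, n_bins, n_bins)
  expected[d > 0] <- depth * (d[d > 0])^(-alpha)
  diag(expected) <- depth                        # self-contact plateau
  band <- s >= x_band[1] & s <= x_band[2]

  realize <- function(mu) {
    if (noise == "none") return(mu)
    m <- matrix(0, n_bins, n_bins)
    up <- upper.tri(m, diag = TRUE)
    m[up] <- stats::rpois(sum(up), lambda = mu[up])
    m + t(m) - diag(diag(m))
  }
  chroms <- paste0("chr", c("I", "II", "III", "IV", "V")[seq_len(n_autosomes)])
  mats <- setNames(lapply(chroms, function(ch) realize(expected)), chroms)
  mu_x <- expected
  mu_x[band] <- mu_x[band] * x_factor
  mats$chrX <- realize(mu_x)
  list(matrices = contact_matrix_set(mats, bin_size = bin_size),
       truth = list(alpha = alpha, x_factor = x_factor, x_band = x_band))
}
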