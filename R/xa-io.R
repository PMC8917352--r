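## Text interchange for contact matrices (bin-table + triplet TSV, dense
## per-chromosome TSV) and the synthetic ChIP spreading-track generator.

#' Write a contact matrix set as bin-table plus triplet TSV
#'
#' The bin table has columns `chrom, start, end, bin_id` (zero-based
#' half-open bins, `bin_id` global and zero-based); the triplet file has
#' `bin1, bin2, count` for the upper triangle of nonzero entries.
#'
#' @param cms A [contact_matrix_set()].
#' @param bins_path,triplets_path Output TSV paths.
#' @return Invisibly, a list of the two paths.
#' @export
write_contact_matrix <- function(cms, bins_path, triplets_path) {
  offset <- 0L
  bins <- list()
  trips <- list()
  for (ch in names(cms$matrices)) {
    m <- cms$matrices[[ch]]
    n <- nrow(m)
    bins[[ch]] <- data.frame(chrom = ch,
                             start = (seq_len(n) - 1L) * cms$bin_size,
                             end = seq_len(n) * cms$bin_size,
                             bin_id = offset + seq_len(n) - 1L)
    idx <- which(upper.tri(m, diag = TRUE) & m != 0, arr.ind = TRUE)
    trips[[ch]] <- data.frame(bin1 = offset + idx[, 1] - 1L,
                              bin2 = offset + idx[, 2] - 1L,
                              count = m[idx])
    offset <- offset + n
  }
  data.table::fwrite(data.table::as.data.table(do.call(rbind, bins)),
                     bins_path, sep = "\t")
  data.table::fwrite(data.table::as.data.table(do.call(rbind, trips)),
                     triplets_path, sep = "\t")
  invisible(list(bins = bins_path, triplets = triplets_path))
}

#' Read a contact matrix set from bin-table plus triplet TSV
#'
#' Inverse of [write_contact_matrix()]. Triplets may address either
#' triangle; the result is symmetrized.
#'
#' @param bins_path,triplets_path Input TSV paths.
#' @return A [contact_matrix_set()].
#' @export
read_contact_matrix <- function(bins_path, triplets_path) {
  bins <- data.table::fread(bins_path, sep = "\t")
  trips <- data.table::fread(triplets_path, sep = "\t")
  stopifnot(all(c("chrom", "start", "end", "bin_id") %in% names(bins)),
            all(c("bin1", "bin2", "count") %in% names(trips)))
  bs <- unique(bins$end - bins$start)
  if (length(bs) != 1L) stop("bin table has mixed bin sizes")
  chrom_of <- bins$chrom[match(trips$bin1, bins$bin_id)]
  chrom_of2 <- bins$chrom[match(trips$bin2, bins$bin_id)]
  if (any(chrom_of != chrom_of2)) {
    stop("inter-chromosomal triplets are not supported")
  }
  mats <- lapply(split(seq_len(nrow(bins)), bins$chrom), function(rows) {
    ids <- bins$bin_id[rows]
    n <- length(ids)
    m <- matrix(0, n, n)
    sel <- trips$bin1 %in% ids
    i <- match(trips$bin1[sel], ids)
    j <- match(trips$bin2[sel], ids)
    m[cbind(i, j)] <- trips$count[sel]
    m[cbind(j, i)] <- trips$count[sel]
    m
  })
  contact_matrix_set(mats, bin_size = bs)
}

#' Read a dense per-chromosome contact matrix from TSV
#'
#' @param path Dense whitespace-separated numeric matrix, no header.
#' @param bin_size Bin size in bp.
#' @param chrom Chromosome name for the single matrix.
#' @return A [contact_matrix_set()] with one chromosome.
#' @export
read_dense_matrix <- function(path, bin_size = 5000, chrom = "chr") {
  m <- as.matrix(data.table::fread(path, sep = "\t", header = FALSE))
  dimnames(m) <- NULL
  contact_matrix_set(setNames(list(m), chrom), bin_size = bin_size)
}

#' Simulate a ChIP enrichment track with a spreading domain
#'
#' Emulates the spreading of an X-specific complex into the autosomal arm
#' of a fusion chromosome: background chromosomes fluctuate around a
#' baseline ratio of 1, while the fusion chromosome carries an enrichment
#' plateau on its X-derived part that decays exponentially across the
#' fusion boundary into the autosomal part.
#'
#' @param n_bins_bg Bins per background chromosome (default 1000).
#' @param n_bins_fusion Bins on the fusion chromosome (default 2000).
#' @param boundary_bin Bin index of the fusion boundary; X-derived bins
#'   lie before it (default halfway).
#' @param bin_size Bin size in bp (default 10 kb).
#' @param enrichment Plateau enrichment over background (default 2).
#' @param decay_length Spreading decay length across the boundary, bp
#'   (default 500 kb).
#' @param noise_sd Gaussian noise s.d. (default 0.3).
#' @param n_background Number of background chromosomes (default 4,
#'   chrI..chrIV).
#' @param fusion_name Name of the fusion chromosome (default "chrXV").
#' @param seed Integer seed.
#' @return List: `track` (a [binned_track()]), `truth` (list `enrichment`,
#'   `decay_length`, `boundary_bin`).
#' @export
simulate_spreading_track <- function(n_bins_bg = 1000L,
                                     n_bins_fusion = 2000L,
                                     boundary_bin = n_bins_fusion %/% 2L,
                                     bin_size = 1e4,
                                     enrichment = 2,
                                     decay_length = 5e5,
                                     noise_sd = 0.3,
                                     n_background = 4L,
                                     fusion_name = "chrXV",
                                     seed = 1L) {
  set.seed(seed)
  chroms <- paste0("chr",
                   c("I", "II", "III", "IV", "V")[seq_len(n_background)])
  values <- setNames(lapply(chroms, function(ch) {
    1 + stats::rnorm(n_bins_bg, sd = noise_sd)
  }), chroms)
  i <- seq_len(n_bins_fusion)
  dist_bp <- pmax(i - boundary_bin, 0) * bin_size
  profile <- 1 + (enrichment - 1) * exp(-dist_bp / decay_length)
  values[[fusion_name]] <- profile + stats::rnorm(n_bins_fusion,
                                                  sd = noise_sd)
  list(track = binned_track(values, bin_size),
       truth = list(enrichment = enrichment, decay_length = decay_length,
                    boundary_bin = boundary_bin))
}
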