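## Movie container and file I/O: TIFF stacks with a JSON metadata sidecar,
## mask images, per-nucleus result tables and experiment configuration.
## Intensities are carried as doubles throughout and never rescaled on
## load; timing metadata lives in the sidecar, not in TIFF tags.

#' FRAP movie container
#'
#' @param frames 3D non-negative numeric array indexed `[frame, y, x]`.
#' @param frame_interval Seconds per frame (> 0).
#' @param n_prebleach Number of pre-bleach frames (< total frames).
#' @param source_id Free-text identifier carried into results.
#' @return A `frap_movie` object.
#' @export
frap_movie <- function(frames, frame_interval, n_prebleach,
                       source_id = "movie") {
  stopifnot(length(dim(frames)) == 3L)
  if (!is_number(frame_interval) || frame_interval <= 0) {
    stop("frame_interval must be a positive number")
  }
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach >= dim(frames)[1]) {
    stop("n_prebleach must be smaller than the total frame count")
  }
  structure(list(frames = frames, frame_interval = frame_interval,
                 n_prebleach = n_prebleach, source_id = source_id),
            class = "frap_movie")
}

#' @export
print.frap_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "frap_movie '%s': %d frames (%d pre-bleach) of %dx%d px, dt = %g s\n",
    x$source_id, d[1], x$n_prebleach, d[2], d[3], x$frame_interval))
  invisible(x)
}

#' Frame times of a movie
#'
#' Times in seconds on the experiment clock: `t = 0` at the first
#' post-bleach frame, pre-bleach frames at negative times.
#' @param movie A [frap_movie()].
#' @return Numeric vector, one time per frame.
#' @export
frame_times <- function(movie) {
  n <- dim(movie$frames)[1]
  (seq_len(n) - 1L - movie$n_prebleach) * movie$frame_interval
}

#' Read a FRAP stack and its metadata sidecar
#'
#' @param path Multi-page grayscale TIFF.
#' @param metadata_path JSON sidecar; must contain `frame_interval_s` and
#'   `n_prebleach`.
#' @return A [frap_movie()]; pixel values are cast to double unchanged.
#' @export
read_stack <- function(path, metadata_path) {
  meta <- jsonlite::read_json(metadata_path, simplifyVector = TRUE)
  for (key in c("frame_interval_s", "n_prebleach")) {
    if (is.null(meta[[key]])) {
      stop("metadata is missing required key '", key, "': ", metadata_path)
    }
  }
  frames <- read_tiff_stack(path)
  if (dim(frames)[1] <= meta$n_prebleach) {
    stop(sprintf("stack has %d frames but n_prebleach = %d",
                 dim(frames)[1], meta$n_prebleach))
  }
  frap_movie(frames,
             frame_interval = meta$frame_interval_s,
             n_prebleach = meta$n_prebleach,
             source_id = meta$source_id %||%
               tools::file_path_sans_ext(basename(path)))
}

#' Write a FRAP movie as TIFF plus JSON sidecar
#'
#' @param movie A [frap_movie()].
#' @param path Output TIFF path; the sidecar is written next to it
#'   (same name, `.json`) unless `metadata_path` is given.
#' @param metadata_path Optional sidecar path.
#' @param truth Optional `frap_ground_truth`; its scalar fields are stored
#'   under `ground_truth` in the sidecar.
#' @param dtype On-disk sample format, see [write_tiff_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(movie, path, metadata_path = NULL, truth = NULL,
                        dtype = "float32") {
  if (is.null(metadata_path)) {
    metadata_path <- paste0(tools::file_path_sans_ext(path), ".json")
  }
  write_tiff_stack(movie$frames, path, dtype = dtype)
  meta <- list(frame_interval_s = movie$frame_interval,
               n_prebleach = movie$n_prebleach,
               source_id = movie$source_id)
  if (!is.null(truth)) {
    meta$ground_truth <- list(m = truth$m, tau = truth$tau, k = truth$k,
                              beta = truth$beta, s_pre = truth$s_pre,
                              expected_t_half = truth$expected_t_half)
    meta$seed <- truth$params$seed
  }
  jsonlite::write_json(meta, metadata_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a binary mask image
#'
#' Any nonzero pixel is TRUE. Grayscale TIFF only.
#'
#' @param path Mask image path.
#' @return Logical matrix.
#' @export
read_mask <- function(path) {
  arr <- read_tiff_stack(path)
  if (dim(arr)[1] != 1L) stop("mask file must contain a single image")
  arr[1, , ] != 0
}

#' Write a binary mask image
#' @param mask Logical matrix.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  write_tiff_stack(matrix(as.numeric(mask) * 255, nrow(mask), ncol(mask)),
                   path, dtype = "uint8")
}

RESULT_COLUMNS <- c("source_id", "mobile_fraction", "tau_s", "t_half_s",
                    "plateau_M", "fit_rss", "n_pre", "n_post", "converged",
                    "qc_flags")

#' Write per-nucleus fit results as CSV
#'
#' One row per nucleus with columns `source_id, mobile_fraction, tau_s,
#' t_half_s, plateau_M, fit_rss, n_pre, n_post, converged, qc_flags`
#' (flags joined by `;`). An empty result list yields a header-only file.
#'
#' @param results List of `frap_fit` objects (see [fit_recovery()]).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  rows <- lapply(results, function(r) {
    data.frame(source_id = r$source_id %||% NA_character_,
               mobile_fraction = r$mobile_fraction,
               tau_s = r$tau,
               t_half_s = r$t_half %||% NA_real_,
               plateau_M = r$plateau,
               fit_rss = r$rss,
               n_pre = r$n_pre %||% NA_integer_,
               n_post = r$n_post %||% NA_integer_,
               converged = r$converged,
               qc_flags = paste(r$qc_flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(setNames(rep(list(character(0)), length(RESULT_COLUMNS)),
                           RESULT_COLUMNS))
  df <- df[, RESULT_COLUMNS]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a results CSV written by [write_results()]
#' @param path CSV path.
#' @return data.frame with the documented columns.
#' @export
read_results <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Default experiment configuration
#'
#' @return Named list of pipeline settings: `frame_interval` (0.21 s),
#'   `n_prebleach` (20), `n_post_for_diff` (5, frames averaged for the
#'   bleach-detection difference image), `upsample` (100, registration
#'   refinement factor), `otsu_bins` (256), `roi_dilate` (0 px),
#'   `tail_fraction` (0.05, tail window defining the recovery "maximum"),
#'   `decay_exclude_roi` (FALSE: the whole-nucleus trace used for the
#'   photobleaching fit includes the bleached spot).
#' @export
default_config <- function() {
  list(frame_interval = 0.21,
       n_prebleach = 20L,
       n_post_for_diff = 5L,
       upsample = 100L,
       otsu_bins = 256L,
       roi_dilate = 0L,
       tail_fraction = 0.05,
       decay_exclude_roi = FALSE)
}

#' Load an experiment configuration file
#'
#' Accepts JSON or flat `key: value` YAML (scalars only; comments with
#' `#`). Absent keys take the defaults of [default_config()]; unknown keys
#' warn and are ignored.
#'
#' @param path Config file; `NULL` returns the defaults.
#' @return Fully resolved configuration list.
#' @export
load_experiment_config <- function(path = NULL) {
  cfg <- default_config()
  user <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    user <- if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      read_flat_yaml(path)
    }
  }
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown)) {
    warning("ignoring unknown config keys: ", paste(unknown, collapse = ", "))
  }
  for (key in intersect(names(user), names(cfg))) cfg[[key]] <- user[[key]]
  for (key in c("n_prebleach", "n_post_for_diff", "upsample", "otsu_bins")) {
    cfg[[key]] <- as.integer(cfg[[key]])
    if (cfg[[key]] <= 0) stop(key, " must be a positive integer")
  }
  if (cfg$frame_interval <= 0) stop("frame_interval must be > 0")
  if (cfg$tail_fraction <= 0 || cfg$tail_fraction > 1) {
    stop("tail_fraction must lie in (0, 1]")
  }
  cfg
}

## Flat YAML subset: "key: value" lines, '#' comments, blank lines.
## Sufficient for pipeline configs; full YAML is out of scope.
read_flat_yaml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([A-Za-z0-9_.-]+)\\s*:\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) stop("cannot parse config line: ", ln)
    val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[m[2]]] <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "yes")) TRUE
      else if (tolower(val) %in% c("false", "no")) FALSE
      else gsub("^['\"]|['\"]$", "", val)
  }
  out
}
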