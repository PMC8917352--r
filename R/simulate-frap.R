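## Synthetic FRAP movie generator.  The stated world: a disk-shaped
## intestine nucleus, a point-bleached spot whose mean intensity recovers by
## single-exponential exchange of a mobile pool, multiplicative per-frame
## acquisition bleaching, optional lateral drift and additive Gaussian
## noise.  Every movie is returned together with its ground truth so the
## downstream pipeline can be benchmarked at known (m, tau, k, beta).

#' Simulation parameters for a synthetic FRAP movie
#'
#' Defaults mirror a typical confocal FRAP acquisition of a large polyploid
#' intestine nucleus: 20 pre-bleach frames followed by 500 recovery frames
#' at 0.21 s per frame, a small bleach spot well inside the nucleus, and a
#' recovery regime (mobile fraction 0.3, tau 3.75 s, so a half-time of
#' about 2.6 s) matching chromatin-bound SMC-complex subunits.
#'
#' @param image_size Integer `(H, W)` in pixels.
#' @param nucleus_center `(y, x)` pixel coordinates; default image centre.
#' @param nucleus_radius Nucleus disk radius, pixels.
#' @param baseline_intensity Mean fluorescence inside the nucleus,
#'   arbitrary units.
#' @param background_intensity Fluorescence outside the nucleus, same units.
#' @param n_prebleach Number of pre-bleach frames (>= 1).
#' @param n_postbleach Number of post-bleach frames (>= 10).
#' @param frame_interval Seconds per frame.
#' @param bleach_center `(y, x)` centre of the bleach spot; default the
#'   nucleus centre.
#' @param bleach_radius Bleach disk radius, pixels.
#' @param bleach_depth Fraction of signal removed by the bleach pulse,
#'   `beta` in (0, 1].
#' @param mobile_fraction Fraction of molecules exchanged during recovery,
#'   `m` in \[0, 1\].
#' @param tau Recovery time constant, seconds (> 0).
#' @param acquisition_decay_rate Per-frame fractional intensity loss rate
#'   `k` (>= 0); frame `f` is scaled by `exp(-k * f)` counting from frame 0.
#' @param drift_per_frame Either a length-2 `(dy, dx)` per-frame step or an
#'   `n_frames x 2` matrix of per-frame steps; applied cumulatively, so
#'   frame `f` is translated by the sum of the first `f` steps.
#' @param noise_sd Additive Gaussian noise s.d. as a fraction of
#'   `baseline_intensity` (>= 0).
#' @param noise_model `"gaussian"` (default) or `"poisson"` (shot noise;
#'   pixel values drawn as Poisson counts).
#' @param bleach_edge_sigma Gaussian softening of the bleach-disk edge in
#'   pixels; 0 (default) renders a hard disk.
#' @param seed Integer seed controlling noise realizations.
#' @return A `frap_sim_params` list, validated.
#' @export
frap_sim_params <- function(image_size = c(128L, 128L),
                            nucleus_center = NULL,
                            nucleus_radius = 40,
                            baseline_intensity = 1000,
                            background_intensity = 100,
                            n_prebleach = 20L,
                            n_postbleach = 500L,
                            frame_interval = 0.21,
                            bleach_center = NULL,
                            bleach_radius = 6,
                            bleach_depth = 0.9,
                            mobile_fraction = 0.3,
                            tau = 3.75,
                            acquisition_decay_rate = 0,
                            drift_per_frame = c(0, 0),
                            noise_sd = 0,
                            noise_model = c("gaussian", "poisson"),
                            bleach_edge_sigma = 0,
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (is.null(nucleus_center)) nucleus_center <- (image_size + 1) / 2
  if (is.null(bleach_center)) bleach_center <- nucleus_center
  p <- list(image_size = as.integer(image_size),
            nucleus_center = nucleus_center,
            nucleus_radius = nucleus_radius,
            baseline_intensity = baseline_intensity,
            background_intensity = background_intensity,
            n_prebleach = as.integer(n_prebleach),
            n_postbleach = as.integer(n_postbleach),
            frame_interval = frame_interval,
            bleach_center = bleach_center,
            bleach_radius = bleach_radius,
            bleach_depth = bleach_depth,
            mobile_fraction = mobile_fraction,
            tau = tau,
            acquisition_decay_rate = acquisition_decay_rate,
            drift_per_frame = drift_per_frame,
            noise_sd = noise_sd,
            noise_model = noise_model,
            bleach_edge_sigma = bleach_edge_sigma,
            seed = as.integer(seed))
  class(p) <- "frap_sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(length(p$image_size) == 2L, all(p$image_size >= 8L))
  if (p$n_prebleach < 1L) stop("n_prebleach must be >= 1")
  if (p$n_postbleach < 10L) stop("n_postbleach must be >= 10")
  if (p$frame_interval <= 0) stop("frame_interval must be > 0")
  if (p$tau <= 0) stop("tau must be > 0")
  if (p$bleach_depth <= 0 && p$bleach_depth != 0 ||
      p$bleach_depth > 1 || p$bleach_depth < 0) {
    stop("bleach_depth must lie in [0, 1]")
  }
  if (p$mobile_fraction < 0 || p$mobile_fraction > 1) {
    stop("mobile_fraction must lie in [0, 1]")
  }
  if (p$acquisition_decay_rate < 0) {
    stop("acquisition_decay_rate must be >= 0")
  }
  if (p$noise_sd < 0) stop("noise_sd must be >= 0")
  if (p$nucleus_radius <= 0 || p$bleach_radius <= 0) {
    stop("radii must be positive")
  }
  ## bleach disk fully inside the nucleus disk
  sep <- sqrt(sum((p$bleach_center - p$nucleus_center)^2))
  if (sep + p$bleach_radius > p$nucleus_radius) {
    stop("bleach disk must lie fully inside the nucleus disk")
  }
  invisible(p)
}

#' Cumulative drift trajectory implied by the parameters
#'
#' @param params A [frap_sim_params()] object.
#' @return An `n_frames x 2` matrix of cumulative `(dy, dx)` displacements;
#'   frame 0 has zero drift.
#' @export
drift_trajectory <- function(params) {
  n <- params$n_prebleach + params$n_postbleach
  d <- params$drift_per_frame
  if (is.function(d)) {
    ## per-realization drift model, e.g. function(n, seed)
    ## drift_random_walk(n, 0.1, seed); keyed to the movie seed so cohort
    ## members drift independently
    d <- d(n, params$seed)
  }
  if (is.null(dim(d))) {
    steps <- matrix(rep(as.numeric(d), each = n), ncol = 2L)
  } else {
    if (nrow(d) != n || ncol(d) != 2L) {
      stop("drift_per_frame matrix must be n_frames x 2")
    }
    steps <- d
  }
  traj <- apply(steps, 2L, cumsum)
  traj <- rbind(c(0, 0), traj[-n, , drop = FALSE])  # frame 0 undrifted
  colnames(traj) <- c("dy", "dx")
  traj
}

#' Random-walk drift path
#'
#' A realistic bounded stage-drift model: each frame moves by a fixed step
#' length in a uniformly random direction, so the cumulative excursion
#' grows like `step * sqrt(n)` and a nucleus placed away from the image
#' border stays in frame.
#'
#' @param n_frames Number of frames.
#' @param step Per-frame step length in pixels.
#' @param seed Integer seed.
#' @return `n_frames x 2` matrix of per-frame `(dy, dx)` steps, suitable
#'   for `drift_per_frame`.
#' @export
drift_random_walk <- function(n_frames, step, seed = 1L) {
  set.seed(seed)
  theta <- stats::runif(n_frames, 0, 2 * pi)
  cbind(dy = step * sin(theta), dx = step * cos(theta))
}

#' Closed-form mean intensity of the bleached region
#'
#' Analytic oracle for the simulator: the expected mean intensity inside
#' the true bleach mask at post-bleach time `t` (seconds, `t = 0` at the
#' first post-bleach frame) is
#' `S_pre * [(1 - beta) + beta * m * (1 - exp(-t / tau))] * exp(-k * f(t))`
#' where `f(t) = n_prebleach + t / frame_interval` is the global frame
#' index and `S_pre` the baseline intensity.
#'
#' @param params A [frap_sim_params()] object.
#' @param t Post-bleach time(s) in seconds, `>= 0`.
#' @return Expected ROI mean intensity (vectorized over `t`).
#' @export
roi_mean_closed_form <- function(params, t) {
  stopifnot(all(t >= 0))
  f <- params$n_prebleach + t / params$frame_interval
  recov <- (1 - params$bleach_depth) +
    params$bleach_depth * params$mobile_fraction * (1 - exp(-t / params$tau))
  params$baseline_intensity * recov * exp(-params$acquisition_decay_rate * f)
}

#' Simulate a FRAP movie with known ground truth
#'
#' Renders `n_prebleach + n_postbleach` frames of a disk-shaped nucleus.
#' Pre-bleach frames show the nucleus at baseline; from the first
#' post-bleach frame the bleach disk follows the single-exponential
#' exchange model `S(t) = S_pre * [(1 - beta) + beta * m *
#' (1 - exp(-t / tau))]`. Every frame `f` is additionally scaled by
#' `exp(-k * f)` (acquisition bleaching), translated by the cumulative
#' drift (Fourier phase shift, periodic boundary) and corrupted by noise;
#' pixel values are clipped at zero.
#'
#' @param params A [frap_sim_params()] object.
#' @return A list with elements `movie` (a [frap_movie()]) and `truth`
#'   (a `frap_ground_truth` list with fields `m`, `tau`, `k`, `beta`,
#'   `drift`, `bleach_mask`, `nucleus_mask`, `s_pre`, `expected_t_half`).
#' @examples
#' sim <- simulate_frap_movie(frap_sim_params(
#'   image_size = c(64, 64), nucleus_radius = 20, bleach_radius = 4,
#'   n_postbleach = 50))
#' dim(sim$movie$frames)
#' @export
simulate_frap_movie <- function(params) {
  validate_sim_params(params)
  h <- params$image_size[1]
  w <- params$image_size[2]
  n_pre <- params$n_prebleach
  n_post <- params$n_postbleach
  n <- n_pre + n_post
  dt <- params$frame_interval

  nucleus <- disk_mask(h, w, params$nucleus_center, params$nucleus_radius)
  bleach <- disk_mask(h, w, params$bleach_center, params$bleach_radius)

  ## bleach weight field: 1 inside the spot, 0 outside; optional soft edge
  if (params$bleach_edge_sigma > 0) {
    dy <- (1:h) - params$bleach_center[1]
    dx <- (1:w) - params$bleach_center[2]
    r <- sqrt(outer(dy^2, dx^2, "+"))
    wgt <- 1 / (1 + exp((r - params$bleach_radius) /
                          params$bleach_edge_sigma))
  } else {
    wgt <- bleach * 1
  }

  base <- matrix(params$background_intensity, h, w)
  base[nucleus] <- params$baseline_intensity

  traj <- drift_trajectory(params)
  set.seed(params$seed)
  frames <- array(0, dim = c(n, h, w))
  for (f in seq_len(n) - 1L) {
    if (f < n_pre) {
      img <- base
    } else {
      t_post <- (f - n_pre) * dt
      s_fac <- (1 - params$bleach_depth) +
        params$bleach_depth * params$mobile_fraction *
          (1 - exp(-t_post / params$tau))
      img <- base * (1 - wgt * (1 - s_fac))
    }
    img <- img * exp(-params$acquisition_decay_rate * f)
    if (any(traj[f + 1L, ] != 0)) {
      img <- fourier_translate(img, traj[f + 1L, 1], traj[f + 1L, 2])
    }
    if (params$noise_sd > 0) {
      if (params$noise_model == "poisson") {
        img <- matrix(stats::rpois(h * w, lambda = pmax(img, 0)), h, w)
      } else {
        img <- img + matrix(
          stats::rnorm(h * w, sd = params$noise_sd *
                         params$baseline_intensity), h, w)
      }
    }
    frames[f + 1L, , ] <- pmax(img, 0)
  }

  movie <- frap_movie(frames, frame_interval = dt, n_prebleach = n_pre,
                      source_id = sprintf("sim-seed%d", params$seed))
  truth <- structure(
    list(m = params$mobile_fraction,
         tau = params$tau,
         k = params$acquisition_decay_rate,
         beta = params$bleach_depth,
         drift = traj,
         bleach_mask = bleach,
         nucleus_mask = nucleus,
         s_pre = params$baseline_intensity,
         expected_t_half = params$tau * log(2),
         params = params),
    class = "frap_ground_truth")
  list(movie = movie, truth = truth)
}

#' Simulate a cohort of independent FRAP movies
#'
#' Generates `n` movies sharing the same parameters but with independent
#' noise (and, for random drift paths, independent drift) realizations.
#' Movie `i` uses sub-seed `seed + i`, so the cohort is deterministic given
#' `seed` and `simulate_cohort(1, params, seed)` reproduces
#' `simulate_frap_movie` at seed `seed + 1`.
#'
#' @param n Number of movies (>= 1).
#' @param params A [frap_sim_params()] object (its `seed` is ignored).
#' @param seed Cohort master seed.
#' @return List of `n` elements, each as returned by
#'   [simulate_frap_movie()].
#' @export
simulate_cohort <- function(n, params, seed = 1L) {
  stopifnot(n >= 1)
  lapply(seq_len(n), function(i) {
    p <- params
    p$seed <- as.integer(seed + i)
    simulate_frap_movie(p)
  })
}
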