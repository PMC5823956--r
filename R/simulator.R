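#' Calcium indicator parameters
#'
#' Double-exponential kinetics (rise `tau_r`, decay `tau_d`) plus a
#' saturating cubic nonlinearity with polynomial coefficients `p2`, `p3`.
#' The saturation level `c_max` is the positive root of the derivative of
#' the cubic,
#' `c_max = (-2 p2 - sqrt(4 p2^2 + 12 p3 (p2 + p3 - 1))) / (6 p3)`,
#' beyond which the cubic would start decreasing. Presets follow published
#' average GCaMP6 kinetics.
#'
#' @param preset `"gcamp6f"` (p2 = 0.85, p3 = -0.006, tau_r = 0.0156 s,
#'   tau_d = 0.76 s) or `"gcamp6s"` (p2 = 0.81, p3 = -0.056,
#'   tau_r = 0.0702 s, tau_d = 1.87 s); ignored when the coefficients are
#'   given explicitly.
#' @param amplitude Fluorescence change per spike, `A` (default 0.3, in the
#'   same arbitrary units as the simulated background).
#' @param p2,p3,tau_r,tau_d Explicit model coefficients (override the
#'   preset).
#' @return Object of class `indicator_params` with the derived `c_max`.
#' @export
indicator_params <- function(preset = c("gcamp6f", "gcamp6s"),
                             amplitude = 0.3, p2 = NULL, p3 = NULL,
                             tau_r = NULL, tau_d = NULL) {
  preset <- match.arg(preset)
  def <- switch(preset,
    gcamp6f = list(p2 = 0.85, p3 = -0.006, tau_r = 0.0156, tau_d = 0.76),
    gcamp6s = list(p2 = 0.81, p3 = -0.056, tau_r = 0.0702, tau_d = 1.87))
  p2 <- if (is.null(p2)) def$p2 else p2
  p3 <- if (is.null(p3)) def$p3 else p3
  tau_r <- if (is.null(tau_r)) def$tau_r else tau_r
  tau_d <- if (is.null(tau_d)) def$tau_d else tau_d
  if (p3 == 0) stop("p3 = 0: saturation level undefined")
  stopifnot(tau_d > tau_r, tau_r > 0, amplitude >= 0)
  c_max <- (-2 * p2 - sqrt(4 * p2^2 + 12 * p3 * (p2 + p3 - 1))) / (6 * p3)
  if (!is.finite(c_max) || c_max <= 0)
    stop("derived saturation level c_max is not positive for these ",
         "coefficients")
  structure(list(p2 = p2, p3 = p3, tau_r = tau_r, tau_d = tau_d,
                 amplitude = amplitude, c_max = c_max),
            class = "indicator_params")
}

#' Simulated cell specification
#'
#' One doughnut-shaped cell: an annular spatial kernel (difference of two
#' 2-D Gaussians, plus a soma step where the annulus is bright) carrying a
#' Poisson spike train passed through the indicator dynamics.
#'
#' @param centre `(x, y)` offset of the cell centre from the field centre,
#'   in pixels (`c(0, 0)` is the middle of the field of view).
#' @param sigma2 Spatial spread (variance, pixels^2) of the kernel.
#' @param rho Off-diagonal covariance term (kernel skew); `abs(rho)` must be
#'   below `sigma2`.
#' @param soma_offset Step height `c` added where the normalised annulus
#'   exceeds `soma_threshold` (default 0.2).
#' @param soma_threshold Threshold `T` defining the soma extent
#'   (default 0.5).
#' @param firing_rate Baseline Poisson rate in Hz.
#' @param indicator An [indicator_params()] object (its `amplitude` is this
#'   cell's transient magnitude).
#' @return Object of class `cell_spec`.
#' @export
cell_spec <- function(centre = c(0, 0), sigma2 = 50, rho = 0,
                      soma_offset = 0.2, soma_threshold = 0.5,
                      firing_rate = 0.5, indicator = indicator_params()) {
  stopifnot(sigma2 > 0, firing_rate >= 0, length(centre) == 2)
  if (abs(rho) >= sigma2)
    stop("abs(rho) must be below sigma2 for a positive-definite spread")
  structure(list(centre = centre, sigma2 = sigma2, rho = rho,
                 soma_offset = soma_offset, soma_threshold = soma_threshold,
                 firing_rate = firing_rate, indicator = indicator),
            class = "cell_spec")
}

#' Background (neuropil) specification
#'
#' A spatially smooth background: a Wiener-process time course (scale `eta`)
#' plus a square-wave stimulus component, spread over the field by a random
#' sum-of-Gaussians kernel.
#'
#' @param eta Wiener increment scale (default 0.05; increment sd per step is
#'   `eta * sqrt(dt)`).
#' @param square_amplitude Unipolar square-wave magnitude added during
#'   stimulus-on epochs (default 0.1).
#' @param n_gaussians Number of Gaussians in the spatial kernel
#'   (default 10).
#' @param sigma2_range Range the Gaussian variances are drawn from
#'   (default `c(100, 200)`).
#' @param initial_level Background level at time 0 (default 1, so Poisson
#'   rates start positive).
#' @return Object of class `background_spec`.
#' @export
background_spec <- function(eta = 0.05, square_amplitude = 0.1,
                            n_gaussians = 10, sigma2_range = c(100, 200),
                            initial_level = 1) {
  stopifnot(eta >= 0, n_gaussians >= 1, length(sigma2_range) == 2)
  structure(list(eta = eta, square_amplitude = square_amplitude,
                 n_gaussians = as.integer(n_gaussians),
                 sigma2_range = sigma2_range,
                 initial_level = initial_level),
            class = "background_spec")
}

#' Simulation configuration
#'
#' @param cells List of [cell_spec()].
#' @param field_size `c(height, width)` in pixels (default 80 x 80).
#' @param duration Seconds (default 120).
#' @param frame_rate Hz (default 100).
#' @param background A [background_spec()].
#' @param stimulus_period Epoch length in seconds (default 15): stimulus-off
#'   and stimulus-on epochs alternate (off first), doubling all firing rates
#'   and raising the background square wave while on.
#' @param mask_threshold Kernel threshold defining each cell's ground-truth
#'   mask (default 0.5).
#' @param photon_scale Photon-count calibration: the Poisson rate at a pixel
#'   is `photon_scale` times the noise-free fluorescence. The default was
#'   calibrated once so that the measured-trace fidelity in the single-cell
#'   benchmark scene matches the reference level (see the package vignette).
#' @param seed Optional integer seed; sub-streams for spikes, background
#'   time course, background kernel and photon noise are drawn in that fixed
#'   order, so each component is reproducible.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(cells, field_size = c(80, 80), duration = 120,
                       frame_rate = 100, background = background_spec(),
                       stimulus_period = 15, mask_threshold = 0.5,
                       photon_scale = 3, seed = NULL) {
  if (inherits(cells, "cell_spec")) cells <- list(cells)
  n_frames <- duration * frame_rate
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("duration x frame_rate must be an integer number of frames")
  if (photon_scale <= 0) stop("photon_scale must be positive")
  structure(list(cells = cells, field_size = as.integer(field_size),
                 duration = duration, frame_rate = frame_rate,
                 background = background, stimulus_period = stimulus_period,
                 mask_threshold = mask_threshold,
                 photon_scale = photon_scale, seed = seed),
            class = "sim_config")
}

## stimulus schedule: alternating epochs (off first); TRUE while the
## stimulus is on (firing rates doubled, square wave high)
stimulus_on <- function(times, period) {
  (floor(times / period) %% 2) == 1
}

#' Poisson spike counts per frame
#'
#' Independent Poisson counts per time bin with mean `rate(t) * dt`, where
#' the rate is doubled during stimulus-on epochs.
#'
#' @param rate Baseline rate in Hz.
#' @param duration Seconds.
#' @param dt Bin width in seconds.
#' @param modulation Apply the epoch rate-doubling (default TRUE).
#' @param period Epoch length in seconds (default 15).
#' @return Integer vector of counts, one per bin.
#' @export
poisson_spikes <- function(rate, duration, dt, modulation = TRUE,
                           period = 15) {
  stopifnot(rate >= 0, dt > 0, duration > 0)
  n <- round(duration / dt)
  times <- (seq_len(n) - 1) * dt
  r <- rep(rate, n)
  if (modulation) r <- r * (1 + stimulus_on(times, period))
  stats::rpois(n, r * dt)
}

#' Indicator calcium dynamics
#'
#' Integrates the two linear decay ODEs driven by the spike train with
#' exact per-bin exponential updates (the recursions
#' `c[t] = exp(-dt/tau) * c[t-1] + s[t]` for decay and rise), and returns
#' their difference, the overall calcium level.
#'
#' @param spikes Spike counts per bin.
#' @param indicator An [indicator_params()].
#' @param dt Bin width in seconds; must be well below `tau_r`.
#' @return Non-negative numeric series `c(t)`, same length as `spikes`.
#' @export
calcium_dynamics <- function(spikes, indicator, dt) {
  stopifnot(inherits(indicator, "indicator_params"))
  if (dt >= indicator$tau_r)
    stop("dt = ", dt, " s does not resolve the rise time tau_r = ",
         indicator$tau_r, " s")
  cd <- as.numeric(stats::filter(spikes, exp(-dt / indicator$tau_d),
                                 method = "recursive"))
  cr <- as.numeric(stats::filter(spikes, exp(-dt / indicator$tau_r),
                                 method = "recursive"))
  pmax(cd - cr, 0)
}

#' Indicator fluorescence response
#'
#' Saturating cubic nonlinearity applied to the calcium level:
#' `d = min(c, c_max)`;
#' `f = A * (d + p2 * (d^2 - d) + p3 * (d^3 - d))`.
#'
#' @param c_level Non-negative calcium series (see [calcium_dynamics()]).
#' @param indicator An [indicator_params()].
#' @return Fluorescence series `f(t)`.
#' @export
indicator_response <- function(c_level, indicator) {
  stopifnot(inherits(indicator, "indicator_params"))
  d <- pmin(c_level, indicator$c_max)
  indicator$amplitude *
    (d + indicator$p2 * (d^2 - d) + indicator$p3 * (d^3 - d))
}

## pixel-centre coordinate grids as offsets from the field centre
field_coords <- function(field_size) {
  h <- field_size[1]; w <- field_size[2]
  list(x = matrix(seq_len(w) - 1 - (w - 1) / 2, h, w, byrow = TRUE),
       y = matrix(seq_len(h) - 1 - (h - 1) / 2, h, w))
}

#' Doughnut-shaped cell kernel
#'
#' The annulus is the difference of two Gaussians sharing the centre, with
#' covariances `Sigma` and `Sigma/2`; since its raw maximum is exactly 1/4
#' for any isotropic spread, the annulus is normalised to peak 1 before the
#' soma step `soma_offset` is added where it exceeds `soma_threshold`, and
#' the result is normalised again so the returned kernel has maximum
#' exactly 1. A consequence is that mask thresholds above 1 select no
#' pixels (see [ground_truth_mask()]).
#'
#' @param spec A [cell_spec()].
#' @param field_size `c(height, width)` in pixels.
#' @return Numeric `height x width` kernel grid.
#' @export
cell_kernel <- function(spec, field_size) {
  stopifnot(inherits(spec, "cell_spec"))
  co <- field_coords(field_size)
  dx <- co$x - spec$centre[1]
  dy <- co$y - spec$centre[2]
  det <- spec$sigma2^2 - spec$rho^2
  # quadratic form (d' Sigma^-1 d) for Sigma = [[s2, rho], [rho, s2]]
  q <- (spec$sigma2 * dx^2 - 2 * spec$rho * dx * dy + spec$sigma2 * dy^2) /
    det
  doughnut <- exp(-q / 2) - exp(-q)
  doughnut <- doughnut / max(doughnut)
  k <- doughnut + spec$soma_offset * (doughnut > spec$soma_threshold)
  k / max(k)
}

#' Ground-truth mask of a simulated cell
#'
#' The superlevel set of the cell kernel at `threshold`.
#'
#' @param spec A [cell_spec()].
#' @param field_size `c(height, width)`.
#' @param threshold Mask threshold (default 0.5).
#' @param label Mask label.
#' @return A `roi_mask`.
#' @export
ground_truth_mask <- function(spec, field_size, threshold = 0.5,
                              label = "cell") {
  k <- cell_kernel(spec, field_size)
  if (!any(k > threshold))
    stop("mask threshold ", threshold, " exceeds the kernel maximum ",
         signif(max(k), 4))
  roi_mask(k > threshold, label)
}

#' Background time course
#'
#' Discretised Wiener process (increments of sd `eta * sqrt(dt)`) cumulated
#' from the initial level, plus the unipolar square wave raised during
#' stimulus-on epochs.
#'
#' @param spec A [background_spec()].
#' @param duration Seconds.
#' @param dt Step in seconds.
#' @param period Stimulus epoch length in seconds (default 15).
#' @return Numeric series `B(t)`.
#' @export
background_trace <- function(spec, duration, dt, period = 15) {
  stopifnot(inherits(spec, "background_spec"), dt > 0)
  n <- round(duration / dt)
  times <- (seq_len(n) - 1) * dt
  b <- spec$initial_level +
    cumsum(c(0, stats::rnorm(n - 1, 0, spec$eta * sqrt(dt))))
  b + spec$square_amplitude * stimulus_on(times, period)
}

#' Background spatial kernel
#'
#' Sum of `n_gaussians` isotropic Gaussians with variances drawn uniformly
#' from `sigma2_range` and centres drawn uniformly within the field.
#' Strictly positive everywhere.
#'
#' @param spec A [background_spec()].
#' @param field_size `c(height, width)`.
#' @return Numeric `height x width` grid.
#' @export
background_kernel <- function(spec, field_size) {
  stopifnot(inherits(spec, "background_spec"))
  co <- field_coords(field_size)
  h <- field_size[1]; w <- field_size[2]
  mux <- stats::runif(spec$n_gaussians, -(w - 1) / 2, (w - 1) / 2)
  muy <- stats::runif(spec$n_gaussians, -(h - 1) / 2, (h - 1) / 2)
  s2 <- stats::runif(spec$n_gaussians, spec$sigma2_range[1],
                     spec$sigma2_range[2])
  k <- matrix(0, h, w)
  for (i in seq_len(spec$n_gaussians))
    k <- k + exp(-((co$x - mux[i])^2 + (co$y - muy[i])^2) / (2 * s2[i]))
  k
}

#' Render a synthetic calcium imaging movie
#'
#' Draws the spike trains, integrates the indicator dynamics, forms the
#' noise-free fluorescence field
#' `F(x, y, t) = sum_i K_i(x, y) f_i(t) + K_bg(x, y) B(t)`
#' (negative values, possible through the Wiener background, are clipped to
#' zero and counted), and draws the movie as per-pixel Poisson counts with
#' rate `photon_scale * F`.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_output`: `movie` (a `movie` of integer
#'   counts), `spike_trains`, `source_traces` (noise-free `f_i(t)` per
#'   cell), `background` (`B(t)`), `kernels` (per cell and `$bg`),
#'   `masks` (ground-truth `roi_mask` per cell), `clipped` (number of
#'   negative rate values clipped), `config`.
#' @export
render <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  h <- config$field_size[1]; w <- config$field_size[2]
  dt <- 1 / config$frame_rate
  n <- round(config$duration * config$frame_rate)
  ncell <- length(config$cells)
  seeds <- derive_seeds(config$seed, 4)
  # 1) spikes (one sub-stream shared across cells, drawn in cell order)
  if (!is.null(seeds)) set.seed(seeds[1])
  spikes <- lapply(config$cells, function(cl)
    poisson_spikes(cl$firing_rate, config$duration, dt,
                   period = config$stimulus_period))
  sources <- lapply(seq_len(ncell), function(i) {
    cl <- config$cells[[i]]
    indicator_response(calcium_dynamics(spikes[[i]], cl$indicator, dt),
                       cl$indicator)
  })
  # 2) background time course
  if (!is.null(seeds)) set.seed(seeds[2])
  bg <- background_trace(config$background, config$duration, dt,
                         config$stimulus_period)
  # 3) background kernel
  if (!is.null(seeds)) set.seed(seeds[3])
  kbg <- background_kernel(config$background, config$field_size)
  kernels <- lapply(config$cells, cell_kernel, field_size = config$field_size)
  masks <- lapply(seq_len(ncell), function(i)
    ground_truth_mask(config$cells[[i]], config$field_size,
                      config$mask_threshold, sprintf("cell%02d", i)))
  # 4) photon noise
  if (!is.null(seeds)) set.seed(seeds[4])
  if (ncell > 0) {
    kmat <- cbind(matrix(unlist(kernels), h * w, ncell), as.numeric(kbg),
                  deparse.level = 0)
    smat <- rbind(matrix(unlist(sources), ncell, n, byrow = TRUE),
                  bg, deparse.level = 0)
  } else {
    kmat <- matrix(as.numeric(kbg), ncol = 1)
    smat <- matrix(bg, nrow = 1)
  }
  rate <- config$photon_scale * (kmat %*% smat)
  clipped <- 0L
  if (min(rate) < 0) {
    neg <- rate < 0
    clipped <- sum(neg)
    rate[neg] <- 0
  }
  frames <- stats::rpois(length(rate), rate)
  rm(rate)
  # store counts as doubles: extraction multiplies against the pixel matrix
  # with BLAS, which would otherwise re-convert the whole stack each call
  frames <- as.double(frames)
  dim(frames) <- c(h, w, n)
  if (clipped > 0)
    message(clipped, " negative rate values clipped to 0 before the ",
            "Poisson draw")
  # construct the movie directly: rpois output is finite and non-negative
  # by construction, so load_movie's full-stack validation scan is redundant
  structure(list(movie = new_movie(frames, c(h, w, n), config$frame_rate,
                                   "simulated"),
                 spike_trains = spikes, source_traces = sources,
                 background = bg,
                 kernels = c(kernels, list(bg = kbg)),
                 masks = masks, clipped = clipped, config = config),
            class = "sim_output")
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("<sim_output: %d cell(s), %d x %d px, %d frames @ %g Hz>\n",
              length(x$masks), x$config$field_size[1],
              x$config$field_size[2], x$movie$dim[3],
              x$config$frame_rate))
  invisible(x)
}

## reproducible sub-stream seeds below 2^31
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(NULL)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

#' Benchmark simulation scenes
#'
#' The three standard test scenes with increasing contamination:
#' \describe{
#'   \item{A}{one central doughnut cell (spread 50, centre of field,
#'     0.5 Hz, amplitude 0.3) over the fluctuating background;}
#'   \item{B}{as A plus a partially overlapping cell (spread 50, centre
#'     offset (13, 13), 0.3 Hz, amplitude 2);}
#'   \item{C}{as B plus a small bright source (spread 10, offset
#'     (-15, -15), 0.3 Hz, amplitude 4).}
#' }
#'
#' @param case `"A"`, `"B"` or `"C"`.
#' @param seed Optional seed passed to [sim_config()].
#' @param ... Overrides passed on to [sim_config()] (e.g. `duration`,
#'   `photon_scale`).
#' @return A [sim_config()] for the scene; the central cell is always
#'   `cells[[1]]`.
#' @export
benchmark_scene <- function(case = c("A", "B", "C"), seed = NULL, ...) {
  case <- match.arg(case)
  cells <- list(cell_spec(centre = c(0, 0), sigma2 = 50, firing_rate = 0.5,
                          indicator = indicator_params(amplitude = 0.3)))
  if (case %in% c("B", "C"))
    cells <- c(cells, list(
      cell_spec(centre = c(13, 13), sigma2 = 50, firing_rate = 0.3,
                indicator = indicator_params(amplitude = 2))))
  if (case == "C")
    cells <- c(cells, list(
      cell_spec(centre = c(-15, -15), sigma2 = 10, firing_rate = 0.3,
                indicator = indicator_params(amplitude = 4))))
  sim_config(cells = cells, seed = seed, ...)
}
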