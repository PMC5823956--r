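#' Zero-phase low-pass filter
#'
#' 2nd-order Butterworth low-pass applied forward and backward
#' (`signal::filtfilt`), so the output has no phase distortion — important
#' when filtered traces are compared by correlation.
#'
#' @param x Numeric series.
#' @param cutoff Cutoff frequency in Hz; must be below the Nyquist frequency.
#' @param frame_rate Sampling rate in Hz.
#' @return Filtered series, same length as `x`.
#' @export
lowpass <- function(x, cutoff, frame_rate) {
  stopifnot(is.numeric(x), length(x) >= 1, frame_rate > 0)
  if (cutoff <= 0 || cutoff >= frame_rate / 2)
    stop("cutoff must lie in (0, frame_rate/2) = (0, ", frame_rate / 2,
         ") Hz; got ", cutoff)
  flt <- signal::butter(2, cutoff / (frame_rate / 2), type = "low")
  filtfilt_stable(flt$b, flt$a, x)
}

## single-pass IIR filter, direct form II transposed, with initial state
lfilter_df2t <- function(b, a, x, zi) {
  n <- length(x)
  y <- numeric(n)
  z1 <- zi[1]; z2 <- zi[2]
  for (i in seq_len(n)) {
    xi <- x[i]
    yi <- b[1] * xi + z1
    z1 <- b[2] * xi - a[2] * yi + z2
    z2 <- b[3] * xi - a[3] * yi
    y[i] <- yi
  }
  y
}

## steady-state filter state for a unit step (so constants filter exactly)
lfilter_zi <- function(b, a) {
  im_a <- diag(2) - rbind(c(-a[2], 1), c(-a[3], 0))
  solve(im_a, c(b[2] - b[1] * a[2], b[3] - b[1] * a[3]))
}

## forward-backward filtering with odd-reflection padding and steady-state
## initial conditions, so constant signals pass through exactly and there is
## no start-up transient inside the data
filtfilt_stable <- function(b, a, x) {
  n <- length(x)
  pad <- min(n - 1, 9L)
  ext <- if (pad > 0)
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  else x
  zi <- lfilter_zi(b, a)
  y <- lfilter_df2t(b, a, ext, zi * ext[1])
  y <- rev(lfilter_df2t(b, a, rev(y), zi * y[length(y)]))
  if (pad > 0) y[(pad + 1):(pad + n)] else y
}

#' Baseline fluorescence f0
#'
#' The baseline is the 5th percentile (linear interpolation) of the trace
#' after 1 Hz zero-phase low-pass filtering, a robust floor estimate that
#' ignores transients.
#'
#' @param x Numeric trace.
#' @param frame_rate Sampling rate in Hz.
#' @param percentile Percentile used (default 0.05).
#' @param cutoff Low-pass cutoff in Hz (default 1).
#' @return Scalar baseline estimate.
#' @export
estimate_f0 <- function(x, frame_rate, percentile = 0.05, cutoff = 1) {
  minlen <- ceiling(3 * frame_rate / cutoff)
  if (length(x) < minlen)
    stop("trace too short for a ", cutoff, " Hz baseline filter: need >= ",
         minlen, " samples (", signif(minlen / frame_rate, 3), " s), got ",
         length(x))
  unname(stats::quantile(lowpass(x, cutoff, frame_rate), percentile,
                         type = 7))
}

#' Relative fluorescence change delta-f/f0
#'
#' `(x - f0) / f0`. For decontaminated traces the convention is to use the
#' `f0` of the *uncorrected* ROI trace, so that the scaling is not biased by
#' the decontamination itself.
#'
#' @param x Numeric trace.
#' @param f0 Positive baseline (see [estimate_f0()]).
#' @return Numeric trace of relative changes.
#' @export
delta_f <- function(x, f0) {
  if (!is.numeric(f0) || length(f0) != 1 || f0 <= 0)
    stop("`f0` must be a positive scalar")
  (x - f0) / f0
}

#' Classical neuropil subtraction
#'
#' `f_roi - k * f_npil`, the standard comparison method. The output can go
#' negative when the neuropil signal exceeds the somatic one — the known
#' failure mode this package's separation approach avoids.
#'
#' @param f_roi ROI-mean trace.
#' @param f_npil Neuropil-mean trace (mean over the whole surrounding
#'   region, i.e. the union of all subregions).
#' @param k Subtraction weight; 1 for the simulated benchmark, 0.7 is the
#'   published choice for in vivo data.
#' @return Corrected trace.
#' @export
subtract_neuropil <- function(f_roi, f_npil, k = 1) {
  if (length(f_roi) != length(f_npil))
    stop("trace length mismatch: ", length(f_roi), " vs ", length(f_npil))
  f_roi - k * f_npil
}

#' Pearson correlation between two traces
#'
#' @param a,b Equal-length numeric series, both non-constant.
#' @return Correlation coefficient in `[-1, 1]`.
#' @export
pearson <- function(a, b) {
  if (length(a) != length(b))
    stop("trace length mismatch: ", length(a), " vs ", length(b))
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("correlation undefined for a zero-variance trace")
  stats::cor(a, b)
}

#' Locomotion modulation index
#'
#' Normalized difference between the mean delta-f/f during locomotion
#' (`r_locomotion`) and stationary (`r_stationary`) periods:
#' `(R_L - R_s) / (R_L + R_s)`. Lies in `[-1, 1]` when both inputs are
#' non-negative.
#'
#' @param r_locomotion,r_stationary Mean delta-f/f in each behavioural state.
#' @return The index.
#' @export
lmi <- function(r_locomotion, r_stationary) {
  s <- r_locomotion + r_stationary
  if (s == 0) stop("LMI undefined: R_L + R_s = 0")
  (r_locomotion - r_stationary) / s
}
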