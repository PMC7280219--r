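#' Spatially bin a decay cube with a moving square window
#'
#' Sums each pixel's decay over the (2n+1) x (2n+1) window centred on it,
#' the standard SPCImage-style binning used to raise the signal-to-noise
#' ratio of per-pixel TCSPC traces before lifetime fitting. The window is
#' clipped at the frame edges (edge pixels sum over the available part of
#' the window); \code{n = 0} is the identity.
#'
#' @param cube a \linkS4class{DecayCube}
#' @param n binning factor (non-negative integer); the default \code{n = 4}
#'   gives a 9 x 9 window
#' @return a \linkS4class{DecayCube} of the same shape with window-summed
#'   counts
#' @export
spatialBin <- function(cube, n = 4L) {
  stopifnot(is(cube, "DecayCube"))
  if (length(n) != 1L || is.na(n) || n < 0 || n != round(n))
    flim_error("flim_invalid_config",
               "binning factor n must be a single non-negative integer")
  if (n == 0L) return(cube)
  d <- dim(cube@counts)
  out <- cpp_bin_cube(as.numeric(cube@counts), d[1], d[2], d[3], as.integer(n))
  DecayCube(array(out, d), cube@time_bin_ns, cube@depth_um)
}

#' Fit a bi-exponential decay model to a single trace
#'
#' Least-squares fit of f(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) to a photon
#' histogram under Poisson weighting (weight 1/max(count, 1)), by variable
#' projection: amplitudes are solved linearly for every candidate lifetime
#' pair and a deterministic Nelder-Mead search runs over the two lifetimes
#' only. The initializer is a log-linear fit to the decay tail (tau2 start)
#' with tau1 starting at tau2/5; there is no randomness. Lifetimes are
#' bounded to [0.01, 10] ns and components are reported in ascending
#' lifetime order. Near-equal lifetime pairs (ratio < 1.1) and negligible
#' second components collapse to a single-component report with a2 = 0.
#'
#' @param trace numeric vector of photon counts per time bin (length >= 8)
#' @param time_bin_ns time-bin width in ns
#' @param min_photons minimum total counts required to attempt the fit;
#'   below it the trace is considered unfittable background
#' @param max_iter Nelder-Mead iteration cap
#' @param ftol relative objective tolerance for convergence
#' @return a \linkS4class{BiexpFit}
#' @examples
#' t <- (0:255) * 12.5 / 256
#' fit <- fitBiexponential(1000 * exp(-t / 0.3) + 500 * exp(-t / 2.5),
#'                         12.5 / 256)
#' @export
fitBiexponential <- function(trace, time_bin_ns, min_photons = 100,
                             max_iter = 400L, ftol = 1e-12) {
  if (!is.numeric(trace) || length(trace) < 8L)
    flim_error("flim_invalid_config", "trace must have at least 8 time bins")
  if (time_bin_ns <= 0)
    flim_error("flim_invalid_config", "time_bin_ns must be positive")
  n_photons <- sum(trace)
  if (n_photons < min_photons)
    flim_error("flim_below_threshold",
               "trace has %.0f photons, below the threshold of %.0f",
               n_photons, min_photons)
  r <- cpp_fit_biexp(as.numeric(trace), time_bin_ns, as.integer(max_iter),
                     ftol)
  new("BiexpFit", a1 = r$a1, a2 = r$a2, tau1_ns = r$tau1_ns,
      tau2_ns = r$tau2_ns,
      chi2_reduced = if (r$converged) r$chi2_reduced else NA_real_,
      n_photons = n_photons, converged = r$converged)
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' @param fit a \linkS4class{BiexpFit}
#' @return (a1 tau1 + a2 tau2) / (a1 + a2) in ns
#' @export
meanLifetime <- function(fit) {
  stopifnot(is(fit, "BiexpFit"))
  s <- fit@a1 + fit@a2
  if (s <= 0)
    flim_error("flim_undefined_value",
               "mean lifetime undefined when a1 + a2 = 0")
  (fit@a1 * fit@tau1_ns + fit@a2 * fit@tau2_ns) / s
}

#' Percentage of fluorescence per decay component
#'
#' Amplitude percentages p_i = 100 a_i / (a1 + a2), the SPCImage default
#' reading of "percentage of fluorescence originating from a component".
#' Set \code{intensity_weighted = TRUE} for the alternative
#' 100 a_i tau_i / (a1 tau1 + a2 tau2), which weights by emitted photons
#' rather than excited-state population.
#'
#' @param fit a \linkS4class{BiexpFit}
#' @param intensity_weighted use the intensity-weighted definition
#' @return named numeric c(p1_percent, p2_percent); sums to 100
#' @export
componentPercentages <- function(fit, intensity_weighted = FALSE) {
  stopifnot(is(fit, "BiexpFit"))
  w <- if (intensity_weighted)
    c(fit@a1 * fit@tau1_ns, fit@a2 * fit@tau2_ns) else c(fit@a1, fit@a2)
  s <- sum(w)
  if (s <= 0)
    flim_error("flim_undefined_value",
               "component percentages undefined when a1 + a2 = 0")
  c(p1_percent = 100 * w[1] / s, p2_percent = 100 * w[2] / s)
}

#' Fit a bi-exponential model to every pixel of a decay cube
#'
#' Applies \code{\link{spatialBin}} then per-pixel
#' \code{\link{fitBiexponential}} and assembles a \linkS4class{LifetimeMap}.
#' Pixels whose binned trace falls below \code{min_photons}, or whose fit
#' does not converge, are masked. A \code{stride} larger than 1 fits every
#' stride-th pixel in both directions (the remaining pixels stay masked) --
#' a regular subsample that leaves frame-level lifetime statistics unbiased
#' while cutting fitting cost by stride^2.
#'
#' @param cube a \linkS4class{DecayCube}
#' @param n binning factor (default 4, i.e. a 9 x 9 window)
#' @param min_photons photon threshold per binned trace (default 100)
#' @param stride pixel stride for fitting (default 1 = every pixel)
#' @param max_iter,ftol fit controls, see \code{\link{fitBiexponential}}
#' @return a \linkS4class{LifetimeMap}
#' @export
fitFrame <- function(cube, n = 4L, min_photons = 100, stride = 1L,
                     max_iter = 150L, ftol = 1e-10) {
  stopifnot(is(cube, "DecayCube"))
  if (stride < 1 || stride != round(stride))
    flim_error("flim_invalid_config", "stride must be a positive integer")
  if (n < 0 || n != round(n))
    flim_error("flim_invalid_config",
               "binning factor n must be a non-negative integer")
  d <- dim(cube@counts)
  r <- cpp_fit_frame(as.numeric(cube@counts), d[1], d[2], d[3],
                     cube@time_bin_ns, as.integer(n), min_photons,
                     as.integer(stride), as.integer(max_iter), ftol)
  mask <- !is.na(r$tau1)
  if (!any(mask))
    flim_error("flim_empty_map",
               "no pixel produced a valid fit (all below threshold or non-converged)")
  s <- r$a1 + r$a2
  s[!mask | s <= 0] <- NA_real_
  mean_lt <- (r$a1 * r$tau1 + r$a2 * r$tau2) / s
  p1 <- 100 * r$a1 / s
  p2 <- 100 * r$a2 / s
  # a pixel with zero total amplitude has no defined percentages: mask it
  bad <- mask & is.na(s)
  mask[bad] <- FALSE
  for (nm in c("tau1", "tau2", "a1", "a2", "chi2")) r[[nm]][bad] <- NA_real_
  if (!any(mask))
    flim_error("flim_empty_map", "no pixel produced a valid fit")
  new("LifetimeMap", tau1 = r$tau1, tau2 = r$tau2, a1 = r$a1, a2 = r$a2,
      mean_lifetime = mean_lt, p1 = p1, p2 = p2, chi2 = r$chi2,
      n_photons = r$n_photons, mask = mask, depth_um = cube@depth_um,
      stride = as.integer(stride))
}

#' Frame-level lifetime statistics
#'
#' Mean and population (divisor N) standard deviation of tau1 and tau2 over
#' the valid pixels of a lifetime map, plus mean amplitude percentages --
#' the per-frame numbers that feed the subject feature vectors.
#'
#' @param map a \linkS4class{LifetimeMap}
#' @return named numeric: tau1_mean, tau1_sd, tau2_mean, tau2_sd, p1_mean,
#'   p2_mean, mean_lifetime_mean, n_valid
#' @export
frameLifetimeStats <- function(map) {
  stopifnot(is(map, "LifetimeMap"))
  m <- map@mask
  if (sum(m) < 2L)
    flim_error("flim_insufficient_data",
               "need at least 2 valid pixels, got %d", sum(m))
  c(tau1_mean = mean(map@tau1[m]), tau1_sd = pop_sd(map@tau1[m]),
    tau2_mean = mean(map@tau2[m]), tau2_sd = pop_sd(map@tau2[m]),
    p1_mean = mean(map@p1[m]), p2_mean = mean(map@p2[m]),
    mean_lifetime_mean = mean(map@mean_lifetime[m]),
    n_valid = sum(m))
}
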