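#' DecayCube: per-pixel photon-decay histograms for one optical section
#'
#' The raw unit of an optical biopsy: a (y, x, time-bin) array of photon
#' counts recorded by time-correlated single-photon counting, together with
#' the time-bin width and the axial depth of the section below the skin
#' surface.
#'
#' @slot counts three-dimensional non-negative numeric array (y, x, time bin)
#' @slot time_bin_ns width of one time bin in nanoseconds
#' @slot depth_um axial position of the section in micrometres
#' @export
setClass("DecayCube",
  representation(counts = "array", time_bin_ns = "numeric",
                 depth_um = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@counts)) != 3L)
      msg <- c(msg, "counts must be a 3-D (y, x, time-bin) array")
    if (any(object@counts < 0, na.rm = TRUE))
      msg <- c(msg, "counts must be non-negative")
    if (length(object@time_bin_ns) != 1L || object@time_bin_ns <= 0)
      msg <- c(msg, "time_bin_ns must be a single positive number")
    if (length(msg)) msg else TRUE
  })

#' Construct a DecayCube
#'
#' @param counts 3-D non-negative array (y, x, time bin)
#' @param time_bin_ns time-bin width in ns
#' @param depth_um axial depth of the section in micrometres
#' @return a \linkS4class{DecayCube}
#' @export
DecayCube <- function(counts, time_bin_ns, depth_um = NA_real_) {
  new("DecayCube", counts = counts, time_bin_ns = as.numeric(time_bin_ns),
      depth_um = as.numeric(depth_um))
}

#' BiexpFit: one bi-exponential decay fit
#'
#' Result of fitting f(t) = a1 exp(-t/tau1) + a2 exp(-t/tau2) to a single
#' decay trace. Components are always reported in ascending lifetime order
#' (tau1 is the short component); a collapsed single-component fit is
#' reported with a2 = 0 and tau2 = tau1.
#'
#' @slot a1,a2 component amplitudes (counts at t = 0, non-negative)
#' @slot tau1_ns,tau2_ns component lifetimes in ns, tau1_ns <= tau2_ns
#' @slot chi2_reduced weighted residual sum of squares per degree of freedom
#' @slot n_photons total counts in the fitted trace
#' @slot converged logical fit-convergence flag
#' @export
setClass("BiexpFit",
  representation(a1 = "numeric", a2 = "numeric", tau1_ns = "numeric",
                 tau2_ns = "numeric", chi2_reduced = "numeric",
                 n_photons = "numeric", converged = "logical"),
  validity = function(object) {
    msg <- character()
    if (object@a1 < 0 || object@a2 < 0)
      msg <- c(msg, "amplitudes must be non-negative")
    if (object@tau1_ns > object@tau2_ns)
      msg <- c(msg, "components must be ordered with tau1_ns <= tau2_ns")
    if (length(msg)) msg else TRUE
  })

#' LifetimeMap: per-pixel fitted lifetime parameters for one frame
#'
#' Per-pixel bi-exponential fit parameters, derived mean lifetime and
#' amplitude percentages, and a validity mask. Pixels are masked where the
#' (binned) trace fell below the photon threshold, where the fit failed to
#' converge, or where the pixel was skipped by the fitting stride.
#'
#' @slot tau1,tau2,a1,a2,mean_lifetime,p1,p2,chi2,n_photons numeric matrices
#'   (NA on masked pixels); p1/p2 are amplitude percentages summing to 100
#' @slot mask logical matrix, TRUE on valid (fitted) pixels
#' @slot depth_um axial depth of the source frame
#' @slot stride pixel stride used during fitting (1 = every pixel)
#' @export
setClass("LifetimeMap",
  representation(tau1 = "matrix", tau2 = "matrix", a1 = "matrix",
                 a2 = "matrix", mean_lifetime = "matrix", p1 = "matrix",
                 p2 = "matrix", chi2 = "matrix", n_photons = "matrix",
                 mask = "matrix", depth_um = "numeric", stride = "integer"),
  validity = function(object) {
    m <- object@mask
    if (!is.logical(m)) return("mask must be a logical matrix")
    if (any(m & (is.na(object@tau1) | is.na(object@tau2))))
      return("mask must be FALSE wherever lifetimes are undefined")
    ps <- object@p1[m] + object@p2[m]
    if (length(ps) && any(abs(ps - 100) > 1e-6, na.rm = TRUE))
      return("p1 + p2 must equal 100 on valid pixels")
    TRUE
  })

#' SeverityModel: standardization + PCA severity scorer
#'
#' Fitted per-feature standardization parameters, an orthonormal PCA
#' rotation, per-component explained-variance ratios and a sign that orients
#' the first principal component so that larger scores indicate more severe
#' skin condition.
#'
#' @slot center,scale per-feature mean and population standard deviation
#' @slot rotation orthonormal loadings matrix (features x components)
#' @slot explained_variance_ratio non-increasing, sums to 1 over all
#'   principal axes of the table
#' @slot pc1_sign +1 or -1 orientation of the severity axis
#' @slot features feature schema (column names, fixed order)
#' @export
setClass("SeverityModel",
  representation(center = "numeric", scale = "numeric", rotation = "matrix",
                 explained_variance_ratio = "numeric", pc1_sign = "numeric",
                 features = "character"),
  validity = function(object) {
    msg <- character()
    g <- crossprod(object@rotation)
    if (max(abs(g - diag(ncol(object@rotation)))) > 1e-8)
      msg <- c(msg, "rotation columns must be orthonormal")
    evr <- object@explained_variance_ratio
    if (abs(sum(evr) - 1) > 1e-8)
      msg <- c(msg, "explained_variance_ratio must sum to 1")
    if (is.unsorted(rev(evr), strictly = FALSE))
      msg <- c(msg, "explained_variance_ratio must be non-increasing")
    if (!object@pc1_sign %in% c(-1, 1))
      msg <- c(msg, "pc1_sign must be +1 or -1")
    if (length(object@center) != length(object@features) ||
        length(object@scale) != length(object@features))
      msg <- c(msg, "center/scale must match the feature schema")
    if (length(msg)) msg else TRUE
  })

setMethod("show", "DecayCube", function(object) {
  d <- dim(object@counts)
  cat(sprintf("DecayCube: %d x %d px, %d time bins (%.4g ns/bin), depth %.4g um, %d photons\n",
              d[1], d[2], d[3], object@time_bin_ns, object@depth_um,
              sum(object@counts)))
})

setMethod("show", "BiexpFit", function(object) {
  cat(sprintf("BiexpFit: tau1 = %.4g ns (a1 = %.4g), tau2 = %.4g ns (a2 = %.4g), chi2_red = %.4g%s\n",
              object@tau1_ns, object@a1, object@tau2_ns, object@a2,
              object@chi2_reduced,
              if (object@converged) "" else " [not converged]"))
})

setMethod("show", "LifetimeMap", function(object) {
  cat(sprintf("LifetimeMap: %d x %d px at depth %.4g um; %d/%d valid pixels (stride %d)\n",
              nrow(object@mask), ncol(object@mask), object@depth_um,
              sum(object@mask), length(object@mask), object@stride))
})

setMethod("show", "SeverityModel", function(object) {
  cat(sprintf("SeverityModel: %d features, %d components; PC1 explains %.1f%% (sign %+d)\n",
              length(object@features), ncol(object@rotation),
              100 * object@explained_variance_ratio[1], object@pc1_sign))
  cat("features:", paste(object@features, collapse = ", "), "\n")
})
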