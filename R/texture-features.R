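#' Mean spectral magnitude inside a Fourier annulus
#'
#' Computes the 2-D discrete Fourier transform of an intensity frame,
#' centres the zero frequency, and averages the absolute spectral magnitude
#' over pixels whose distance d from the centre satisfies
#' r_inner <= d < r_outer (inner-inclusive, outer-exclusive, so adjacent
#' annuli partition the spectrum without double counting).
#'
#' @param frame 2-D numeric matrix of non-negative intensities
#' @param r_inner,r_outer annulus radii in FFT pixels, 0 < r_inner < r_outer
#'   <= min(dim(frame)) / 2
#' @return mean |F| over the annulus
#' @export
radialAnnulusAverage <- function(frame, r_inner, r_outer) {
  check_intensity_frame(frame)
  if (r_inner <= 0 || r_outer <= r_inner)
    flim_error("flim_invalid_config",
               "annulus radii must satisfy 0 < r_inner < r_outer")
  if (r_outer > min(dim(frame)) / 2)
    flim_error("flim_invalid_config",
               "outer radius %.1f px exceeds the Nyquist box of a %d x %d frame",
               r_outer, nrow(frame), ncol(frame))
  fmag <- fftshift_mod(frame)
  d <- centre_distance(dim(frame))
  sel <- d >= r_inner & d < r_outer
  mean(fmag[sel])
}

#' Fourier parameter: high-to-medium spatial-frequency ratio
#'
#' Ratio of the mean spectral magnitude in a high-frequency annulus to that
#' in a medium-frequency annulus. Sharp sub-cellular structures (e.g.
#' perinuclear mitochondrial clusters in inflamed keratinocytes) raise the
#' high-frequency content of a two-photon image, so the ratio acts as a
#' texture biomarker. Low frequencies are excluded as bulk structure, very
#' high frequencies as noise-dominated. The default radii (14, 24) and
#' (24, 36) px refer to a \code{reference_size} x \code{reference_size}
#' frame; for other frame sizes the radii are scaled proportionally so the
#' annuli select the same physical spatial frequencies. The ratio is
#' invariant to adding a constant to the frame (the DC bin lies outside
#' every annulus).
#'
#' @param frame 2-D numeric intensity matrix
#' @param medium,high annulus radii c(r_inner, r_outer) in FFT pixels of the
#'   reference frame size
#' @param invert return medium/high instead of high/medium
#' @param reference_size frame size the radii are quoted for (default 512)
#' @return unitless spectral ratio
#' @export
fourierParameter <- function(frame, medium = c(14, 24), high = c(24, 36),
                             invert = FALSE, reference_size = 512) {
  check_intensity_frame(frame)
  sc <- min(dim(frame)) / reference_size
  m <- radialAnnulusAverage(frame, medium[1] * sc, medium[2] * sc)
  h <- radialAnnulusAverage(frame, high[1] * sc, high[2] * sc)
  if (invert) {
    if (h == 0)
      flim_error("flim_degenerate_spectrum",
                 "high-frequency annulus average is zero")
    return(m / h)
  }
  if (m == 0)
    flim_error("flim_degenerate_spectrum",
               "medium-frequency annulus average is zero (degenerate spectrum)")
  h / m
}

#' Per-pixel local Shannon entropy under a disk structuring element
#'
#' The frame is quantized to \code{levels} grey levels over its min-max
#' range; each pixel's entropy (base 2) is that of the grey-level histogram
#' inside the disk of the given radius centred on it (distance <= radius; a
#' radius of 2 px gives the 13-pixel disk). Neighbourhoods are clipped at
#' the frame border. Because quantization is min-max based, the result is
#' invariant to affine rescaling of the intensities; a constant frame has
#' entropy 0 everywhere.
#'
#' @param frame 2-D numeric intensity matrix
#' @param radius disk radius in px (>= 1)
#' @param levels number of grey levels (>= 2)
#' @return matrix of per-pixel entropies in bits
#' @export
localEntropyMap <- function(frame, radius = 2L, levels = 256L) {
  check_intensity_frame(frame)
  if (radius < 1) flim_error("flim_invalid_config", "radius must be >= 1")
  if (levels < 2) flim_error("flim_invalid_config", "levels must be >= 2")
  q <- quantize_frame(frame, levels)
  ny <- nrow(q); nx <- ncol(q)
  off <- disk_offsets(radius)
  noff <- nrow(off)
  # shifted copies of the quantized frame, NA outside the border
  shifted <- vector("list", noff)
  for (i in seq_len(noff)) {
    dy <- off[i, 1]; dx <- off[i, 2]
    s <- matrix(NA_real_, ny, nx)
    ys <- max(1, 1 - dy):min(ny, ny - dy)
    xs <- max(1, 1 - dx):min(nx, nx - dx)
    s[ys, xs] <- q[ys + dy, xs + dx]
    shifted[[i]] <- s
  }
  # per-pixel neighbourhood size m and, for each member i, the count c_i of
  # neighbours sharing its grey level; then
  # H = -(1/m) * sum_i log2(c_i / m), which equals the histogram entropy
  # because each level l is visited n_l times with c_i = n_l
  m <- Reduce(`+`, lapply(shifted, function(s) !is.na(s)))
  acc <- matrix(0, ny, nx)
  for (i in seq_len(noff)) {
    ci <- matrix(0, ny, nx)
    for (j in seq_len(noff)) {
      eq <- shifted[[i]] == shifted[[j]]
      eq[is.na(eq)] <- 0
      ci <- ci + eq
    }
    term <- log2(ci / m)
    term[is.na(shifted[[i]])] <- 0
    acc <- acc + term
  }
  -acc / m
}

#' Mean local entropy of a frame
#'
#' Average of \code{\link{localEntropyMap}} over all pixels; the per-frame
#' structural-uniformity feature.
#'
#' @inheritParams localEntropyMap
#' @return mean entropy in bits
#' @export
localEntropyMean <- function(frame, radius = 2L, levels = 256L) {
  mean(localEntropyMap(frame, radius, levels))
}

#' Total-photon intensity image of a decay cube
#'
#' Sums the photon histogram over time, giving the two-photon intensity
#' frame used as input to the texture features.
#'
#' @param cube a \linkS4class{DecayCube}
#' @return 2-D numeric matrix
#' @export
intensityImage <- function(cube) {
  stopifnot(is(cube, "DecayCube"))
  d <- dim(cube@counts)
  matrix(rowSums(matrix(cube@counts, d[1] * d[2], d[3])), d[1], d[2])
}

# --- internal helpers -------------------------------------------------------

check_intensity_frame <- function(frame) {
  if (!is.matrix(frame) || !is.numeric(frame) || length(frame) == 0L)
    flim_error("flim_invalid_config",
               "frame must be a non-empty numeric matrix")
  if (any(!is.finite(frame)))
    flim_error("flim_invalid_config", "frame values must be finite")
  invisible(TRUE)
}

# |FFT| with the zero frequency moved to (floor(n/2) + 1, floor(m/2) + 1)
fftshift_mod <- function(frame) {
  f <- Mod(stats::fft(frame))
  ny <- nrow(f); nx <- ncol(f)
  iy <- c((floor(ny / 2) + 1):ny, seq_len(floor(ny / 2)))
  ix <- c((floor(nx / 2) + 1):nx, seq_len(floor(nx / 2)))
  f[iy, ix]
}

centre_distance <- function(d) {
  cy <- floor(d[1] / 2) + 1
  cx <- floor(d[2] / 2) + 1
  sqrt(outer((seq_len(d[1]) - cy)^2, (seq_len(d[2]) - cx)^2, `+`))
}

quantize_frame <- function(frame, levels) {
  rng <- range(frame)
  if (rng[1] == rng[2]) return(matrix(0, nrow(frame), ncol(frame)))
  pmin(floor((frame - rng[1]) / (rng[2] - rng[1]) * levels), levels - 1)
}

disk_offsets <- function(radius) {
  r <- floor(radius)
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= radius^2, , drop = FALSE]
  as.matrix(g)
}
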