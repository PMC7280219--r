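# Independent oracles used across test files. Each is deliberately naive
# (brute force / direct definition) and shares no code with the package
# implementation paths it checks.

# dense grid search over (tau1, tau2) with amplitudes solved by weighted
# linear least squares; oracle for the bi-exponential fitter
grid_biexp_oracle <- function(trace, dt, tau1_grid, tau2_grid) {
  t <- (seq_along(trace) - 1) * dt
  w <- 1 / pmax(trace, 1)
  best <- list(sse = Inf)
  for (t1 in tau1_grid) for (t2 in tau2_grid) {
    if (t2 <= t1) next
    B <- cbind(exp(-t / t1), exp(-t / t2))
    fit <- stats::lm.wfit(B, trace, w)
    a <- fit$coefficients
    if (any(a < 0)) next
    sse <- sum(w * fit$residuals^2)
    if (sse < best$sse)
      best <- list(sse = sse, tau1 = t1, tau2 = t2, a1 = a[1], a2 = a[2])
  }
  best
}

# brute-force moving-window decay sum (clipped at edges)
window_sum_oracle <- function(cube, n) {
  d <- dim(cube)
  out <- array(0, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    ys <- max(1, i - n):min(d[1], i + n)
    xs <- max(1, j - n):min(d[2], j + n)
    out[i, j, ] <- apply(cube[ys, xs, , drop = FALSE], 3, sum)
  }
  out
}

# brute-force per-pixel local entropy: explicit histogram in the clipped
# disk neighbourhood of every pixel
entropy_oracle <- function(frame, radius = 2, levels = 256) {
  rng <- range(frame)
  q <- if (rng[1] == rng[2]) matrix(0, nrow(frame), ncol(frame))
       else pmin(floor((frame - rng[1]) / (rng[2] - rng[1]) * levels),
                 levels - 1)
  ny <- nrow(q); nx <- ncol(q)
  out <- matrix(0, ny, nx)
  r <- floor(radius)
  for (i in seq_len(ny)) for (j in seq_len(nx)) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r) {
      if (dy^2 + dx^2 > radius^2) next
      ii <- i + dy; jj <- j + dx
      if (ii >= 1 && ii <= ny && jj >= 1 && jj <= nx)
        vals <- c(vals, q[ii, jj])
    }
    p <- table(vals) / length(vals)
    out[i, j] <- -sum(p * log2(p))
  }
  out
}

# flat, noise-dominated generator parameters for Poisson-statistics checks
flat_params <- function(photons = 200, a2 = 0.3) {
  groupParams("control", tau1_ns = 0.3, tau2_ns = 2.0, a2_fraction = a2,
              sg_depth_um = 25, sb_depth_um = 55, puncta_density = 0,
              photons_per_pixel = photons, texture_contrast = 0,
              a2_sd = 0, lifetime_sd_ns = 0)
}

# small, fast simulation/analysis configuration for unit tests; caller
# overrides win over the tiny defaults
tiny_config <- function(...) {
  args <- list(frame_size = 96L, n_time_bins = 64L, render = "layers",
               fit = list(stride = 3L))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(cohortConfig, args)
}
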