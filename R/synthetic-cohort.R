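#' Generative parameters for one study group
#'
#' Bundles the physical and clinical parameters the synthetic-cohort
#' generator uses for a study group: decay-model parameters (the short and
#' long NAD(P)H lifetime components and the amplitude fraction of the long
#' component), epidermal layer geometry (stratum granulosum and stratum
#' basale depths), texture parameters (bright sub-cellular puncta modelling
#' perinuclear mitochondrial clustering, cell contrast, smooth spatial
#' lifetime heterogeneity), the photon budget, and the clinical-score
#' generator moments.
#'
#' @param group_label one of "control", "pseudo_control", "psoriasis",
#'   "eczema"
#' @param tau1_ns,tau2_ns mean short / long lifetime components (ns),
#'   0 < tau1_ns < tau2_ns
#' @param a2_fraction mean amplitude fraction of the long component in
#'   [0, 1]
#' @param sg_depth_um,sb_depth_um SG and SB layer depths (um), SG < SB
#' @param puncta_density expected per-frame count of bright 1-2 px puncta
#' @param photons_per_pixel mean total photon count per pixel
#' @param texture_contrast amplitude of the cellular texture (0 = flat)
#' @param a2_sd spatial SD of the amplitude-fraction field
#' @param lifetime_sd_ns spatial SD of the long-lifetime field (ns)
#' @param fov_um lateral field of view (um)
#' @param pasi_mean,pasi_sd,lis_mean,lis_sd clinical-score generator moments
#'   (NA for groups without clinical scores)
#' @return a validated list of class "GroupParams"
#' @export
groupParams <- function(group_label, tau1_ns, tau2_ns, a2_fraction,
                        sg_depth_um, sb_depth_um, puncta_density,
                        photons_per_pixel, texture_contrast = 0.5,
                        a2_sd = 0.03, lifetime_sd_ns = 0.05, fov_um = 200,
                        pasi_mean = NA_real_, pasi_sd = NA_real_,
                        lis_mean = NA_real_, lis_sd = NA_real_) {
  group_label <- match.arg(group_label,
    c("control", "pseudo_control", "psoriasis", "eczema"))
  p <- list(group_label = group_label, tau1_ns = tau1_ns, tau2_ns = tau2_ns,
            a2_fraction = a2_fraction, sg_depth_um = sg_depth_um,
            sb_depth_um = sb_depth_um, puncta_density = puncta_density,
            photons_per_pixel = photons_per_pixel,
            texture_contrast = texture_contrast, a2_sd = a2_sd,
            lifetime_sd_ns = lifetime_sd_ns, fov_um = fov_um,
            pasi_mean = pasi_mean, pasi_sd = pasi_sd, lis_mean = lis_mean,
            lis_sd = lis_sd)
  validate_group_params(p)
  class(p) <- "GroupParams"
  p
}

validate_group_params <- function(p) {
  if (!(p$tau1_ns > 0 && p$tau1_ns < p$tau2_ns))
    flim_error("flim_invalid_config",
               "lifetimes must satisfy 0 < tau1_ns < tau2_ns")
  if (p$a2_fraction < 0 || p$a2_fraction > 1)
    flim_error("flim_invalid_config", "a2_fraction must lie in [0, 1]")
  if (p$sg_depth_um >= p$sb_depth_um)
    flim_error("flim_invalid_config", "sg_depth_um must be < sb_depth_um")
  if (p$puncta_density < 0)
    flim_error("flim_invalid_config", "puncta_density must be >= 0")
  if (p$photons_per_pixel <= 0)
    flim_error("flim_invalid_config", "photons_per_pixel must be positive")
  invisible(TRUE)
}

#' Default generative parameters per study group
#'
#' Simulation defaults, not measurements: effect directions follow the
#' qualitative picture of psoriatic skin -- longer mean lifetime, epidermal
#' thickening, perinuclear mitochondrial clustering (more bright puncta,
#' raising the Fourier parameter), higher metabolic heterogeneity (larger
#' lifetime spread) in lesional skin -- with the pseudo-control group
#' (visually uninvolved skin of psoriasis patients) placed between control
#' and psoriasis on the metabolic parameters while keeping control-like
#' epidermal geometry (thickening is a lesion-local change), and eczema
#' between pseudo-control and psoriasis. Cellular texture contrast is held
#' equal across groups so the Fourier parameter responds to puncta density,
#' not to bulk cell contrast. All magnitudes are free parameters; override
#' any of them via \code{\link{cohortConfig}}.
#'
#' @param group_label study group name
#' @return a "GroupParams" list
#' @export
defaultGroupParams <- function(group_label = c("control", "pseudo_control",
                                               "eczema", "psoriasis")) {
  group_label <- match.arg(group_label)
  switch(group_label,
    control = groupParams("control", tau1_ns = 0.30, tau2_ns = 2.0,
      a2_fraction = 0.25, sg_depth_um = 25, sb_depth_um = 55,
      puncta_density = 30, photons_per_pixel = 500,
      lifetime_sd_ns = 0.05),
    pseudo_control = groupParams("pseudo_control", tau1_ns = 0.32,
      tau2_ns = 2.2, a2_fraction = 0.28, sg_depth_um = 26, sb_depth_um = 56,
      puncta_density = 45, photons_per_pixel = 500,
      lifetime_sd_ns = 0.08),
    eczema = groupParams("eczema", tau1_ns = 0.33, tau2_ns = 2.3,
      a2_fraction = 0.30, sg_depth_um = 28, sb_depth_um = 78,
      puncta_density = 60, photons_per_pixel = 500,
      lifetime_sd_ns = 0.10),
    psoriasis = groupParams("psoriasis", tau1_ns = 0.35, tau2_ns = 2.4,
      a2_fraction = 0.33, sg_depth_um = 30, sb_depth_um = 90,
      puncta_density = 60, photons_per_pixel = 500,
      lifetime_sd_ns = 0.12,
      pasi_mean = 10, pasi_sd = 6, lis_mean = 5, lis_sd = 2))
}

#' Cohort-level simulation and analysis configuration
#'
#' One object carrying every tunable of the pipeline: acquisition geometry
#' (frame size, time axis, 40 optical sections in 5 um steps to 200 um),
#' group generative parameters, between-subject variability, clinical-score
#' coupling, and the analysis defaults (binning factor 4, photon threshold,
#' Fourier annuli (14, 24) and (24, 36) px, entropy disk radius 2 px,
#' 256 grey levels).
#'
#' @param ... named overrides of any top-level entry
#' @return configuration list
#' @export
cohortConfig <- function(...) {
  cfg <- list(
    frame_size = 512L,
    n_time_bins = 256L,
    time_range_ns = 12.5,
    n_sections = 40L,
    depth_step_um = 5,
    render = "full",              # "full" or "layers" (SG/SB sections only)
    groups = list(
      control = defaultGroupParams("control"),
      pseudo_control = defaultGroupParams("pseudo_control"),
      eczema = defaultGroupParams("eczema"),
      psoriasis = defaultGroupParams("psoriasis")),
    group_order = c("control", "pseudo_control", "eczema", "psoriasis"),
    # between-subject SDs of the generative parameters (one latent severity
    # draw per subject scales all of them coherently)
    subject_sd = c(tau1_ns = 0.010, tau2_ns = 0.08, a2_fraction = 0.020,
                   sg_depth_um = 1.5, sb_depth_um = 4.0,
                   puncta_density = 8),
    pseudo_site_coupling = 0.5,   # systemic effect strength at the pseudo site
    pasi_coupling_r = 0.5,        # target corr(latent severity, PASI)
    lis_coupling_r = 0.5,
    fit = list(n_bin = 4L, min_photons = 100, stride = 1L,
               max_iter = 150L, ftol = 1e-10),
    fourier = list(medium = c(14, 24), high = c(24, 36),
                   reference_size = 512),
    entropy = list(radius = 2L, levels = 256L))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cfg))
      flim_error("flim_invalid_config", "unknown configuration entry '%s'", nm)
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(dots[[nm]]) &&
                     !is(dots[[nm]], "GroupParams"))
      utils::modifyList(cfg[[nm]], dots[[nm]]) else dots[[nm]]
  }
  cfg
}

#' Simulate one optical section as a decay cube
#'
#' Builds a per-pixel expected decay
#' A(x, y) [(1 - q) exp(-t/tau1) + q exp(-t/tau2)] and draws photon counts
#' per time bin from a Poisson law. A (the amplitude scale) is modulated by
#' a cellular texture -- cell-sized blobs with bright ring-like cytoplasm,
#' darker nuclei, and \code{puncta_density} bright 1-2 px puncta -- and
#' normalized so the mean per-pixel total count equals
#' \code{photons_per_pixel}. q (the long-component amplitude fraction) and
#' the lifetimes themselves are modulated by smooth spatial fields whose
#' SDs come from the group parameters, emulating metabolic heterogeneity
#' across the frame. Identical (params, seed) gives bit-identical output;
#' the instrument response is treated as an ideal delta (no IRF
#' convolution).
#'
#' @param params a "GroupParams" list
#' @param depth_um axial depth recorded in the cube metadata
#' @param frame_size frame side in pixels (>= 64)
#' @param n_time_bins number of TCSPC bins (>= 32)
#' @param time_range_ns length of the time axis in ns (12.5 ns matches an
#'   80 MHz excitation repetition rate)
#' @param seed RNG seed; the generator is a pure function of (params, seed)
#' @return a \linkS4class{DecayCube}
#' @export
generateDecayFrame <- function(params, depth_um, frame_size = 512L,
                               n_time_bins = 256L, time_range_ns = 12.5,
                               seed = 1L) {
  validate_group_params(params)
  if (frame_size < 64)
    flim_error("flim_invalid_config", "frame_size must be >= 64")
  if (n_time_bins < 32)
    flim_error("flim_invalid_config", "n_time_bins must be >= 32")
  if (time_range_ns <= 0)
    flim_error("flim_invalid_config", "time_range_ns must be positive")
  n <- as.integer(frame_size)
  K <- as.integer(n_time_bins)
  dt <- time_range_ns / K
  with_seed(seed, {
    ppu <- n / params$fov_um     # pixels per micrometre
    I <- render_texture(n, params, ppu)
    # amplitude fraction of the long component
    if (params$a2_fraction %in% c(0, 1) || params$a2_sd == 0) {
      q <- rep(params$a2_fraction, n * n)
    } else {
      q <- clamp(params$a2_fraction +
                   params$a2_sd * gaussian_field(n, 2 * ppu), 0, 0.98)
    }
    # smooth spatial lifetime heterogeneity
    if (params$lifetime_sd_ns > 0) {
      tau2f <- params$tau2_ns +
        params$lifetime_sd_ns * gaussian_field(n, 4 * ppu)
      tau1f <- params$tau1_ns +
        (params$lifetime_sd_ns / 8) * gaussian_field(n, 4 * ppu)
    } else {
      tau2f <- rep(params$tau2_ns, n * n)
      tau1f <- rep(params$tau1_ns, n * n)
    }
    tau1f <- pmax(tau1f, 0.05)
    tau2f <- pmax(tau2f, tau1f * 1.5)
    # quantize the smooth lifetime fields so the per-level exponential
    # bases can be shared across pixels
    lv1 <- quantize_levels(tau1f, 24L)
    lv2 <- quantize_levels(tau2f, 24L)
    tk <- (0:(K - 1)) * dt
    U1 <- exp(-outer(1 / lv1$values, tk))   # levels x K
    U2 <- exp(-outer(1 / lv2$values, tk))
    S <- (1 - q) * rowSums(U1)[lv1$index] + q * rowSums(U2)[lv2$index]
    A <- params$photons_per_pixel * (as.numeric(I) / mean(I)) / S
    lam <- (A * (1 - q)) * U1[lv1$index, , drop = FALSE] +
           (A * q) * U2[lv2$index, , drop = FALSE]
    counts <- array(rpois(n * n * K, as.numeric(lam)), c(n, n, K))
    DecayCube(counts, dt, depth_um)
  })
}

# cellular texture: base intensity 1, cells as bright cytoplasm rings with
# darker nuclei, plus bright sub-cellular puncta; values clamped >= 0.05
render_texture <- function(n, params, ppu) {
  I <- matrix(1, n, n)
  ctr <- params$texture_contrast
  if (ctr > 0) {
    n_cells <- rpois(1, 180 * (params$fov_um / 200)^2)
    for (i in seq_len(n_cells)) {
      cy <- runif(1, 1, n); cx <- runif(1, 1, n)
      rc <- runif(1, 5, 8) * ppu
      rn <- 0.45 * rc
      ys <- max(1, floor(cy - rc)):min(n, ceiling(cy + rc))
      xs <- max(1, floor(cx - rc)):min(n, ceiling(cx + rc))
      d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
      patch <- I[ys, xs]
      patch[d <= rc & d > rn] <- patch[d <= rc & d > rn] + ctr
      patch[d <= rn] <- patch[d <= rn] - 0.8 * ctr
      I[ys, xs] <- patch
    }
  }
  if (params$puncta_density > 0) {
    n_p <- rpois(1, params$puncta_density)
    for (i in seq_len(n_p)) {
      py <- runif(1, 1, n); px <- runif(1, 1, n)
      pr <- runif(1, 1, 2)
      ys <- max(1, floor(py - pr)):min(n, ceiling(py + pr))
      xs <- max(1, floor(px - pr)):min(n, ceiling(px + pr))
      d <- sqrt(outer((ys - py)^2, (xs - px)^2, `+`))
      I[ys, xs][d <= pr] <- I[ys, xs][d <= pr] + 1.0
    }
  }
  pmax(I, 0.05)
}

# unit-variance smooth Gaussian random field via FFT filtering
gaussian_field <- function(n, sigma_px) {
  z <- matrix(rnorm(n * n), n, n)
  if (sigma_px <= 0) return(as.numeric(z))
  fx <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  h <- exp(-2 * pi^2 * sigma_px^2 * outer(fx^2, fx^2, `+`))
  g <- Re(stats::fft(stats::fft(z) * h, inverse = TRUE)) / (n * n)
  g <- g - mean(g)
  as.numeric(g / pop_sd(g))
}

quantize_levels <- function(x, n_levels) {
  rng <- range(x)
  if (rng[1] == rng[2])
    return(list(values = rng[1], index = rep(1L, length(x))))
  br <- seq(rng[1], rng[2], length.out = n_levels + 1L)
  idx <- pmin(findInterval(x, br, rightmost.closed = TRUE), n_levels)
  list(values = (br[-1] + br[-length(br)]) / 2, index = idx)
}

#' Simulate one subject (all imaging sites and clinical scores)
#'
#' Draws one latent severity deviate per subject that coherently shifts all
#' generative parameters, builds the imaging site(s) -- psoriasis subjects
#' get an inflamed site plus a non-lesional contralateral "pseudo-control"
#' site whose shift is attenuated by \code{pseudo_site_coupling}; every
#' other group gets one site -- and samples PASI and LIS for psoriasis
#' subjects with the configured coupling to the latent severity. Sections
#' are placed at \code{depth_step_um} steps; with \code{render = "layers"}
#' only the SG and SB sections carry photon data (the rest keep depth
#' metadata only), which is sufficient for the downstream analysis.
#'
#' @param group study group label
#' @param config a \code{\link{cohortConfig}} list
#' @param seed RNG seed
#' @param subject_id identifier string
#' @return a list of class "SyntheticSubject" with elements subject_id,
#'   group_label, sites, pasi, lis and truth (the latent severity and the
#'   per-site parameters actually used)
#' @export
generateSubject <- function(group, config = cohortConfig(), seed = 1L,
                            subject_id = paste0(group, "_1")) {
  if (!group %in% names(config$groups))
    flim_error("flim_invalid_config", "unknown group label '%s'", group)
  with_seed(seed, {
    s <- rnorm(1)
    z_pasi <- rnorm(1); z_lis <- rnorm(1)
    site_specs <- if (group == "psoriasis") {
      list(list(label = "psoriasis", site = "inflamed",
                params = perturb_params(config$groups$psoriasis,
                                        s, config$subject_sd)),
           list(label = "pseudo_control", site = "pseudo_control",
                params = perturb_params(config$groups$pseudo_control,
                                        config$pseudo_site_coupling * s,
                                        config$subject_sd)))
    } else {
      list(list(label = group,
                site = if (group == "eczema") "inflamed" else group,
                params = perturb_params(config$groups[[group]], s,
                                        config$subject_sd)))
    }
    depths <- seq(config$depth_step_um, by = config$depth_step_um,
                  length.out = config$n_sections)
    sites <- lapply(site_specs, function(sp) {
      fseeds <- sample.int(.Machine$integer.max - 1L, config$n_sections)
      rendered <- if (identical(config$render, "layers")) {
        unique(c(which.min(abs(depths - sp$params$sg_depth_um)),
                 which.min(abs(depths - sp$params$sb_depth_um))))
      } else seq_along(depths)
      frames <- vector("list", length(depths))
      for (i in rendered) {
        frames[[i]] <- generateDecayFrame(sp$params, depths[i],
                                          config$frame_size,
                                          config$n_time_bins,
                                          config$time_range_ns,
                                          seed = fseeds[i])
      }
      list(subject_id = subject_id, group_label = sp$label, site = sp$site,
           frames = frames, depth_um = depths,
           sg_depth_um = sp$params$sg_depth_um,
           sb_depth_um = sp$params$sb_depth_um, params = sp$params)
    })
    pasi <- lis <- NA_integer_
    if (group == "psoriasis") {
      gp <- config$groups$psoriasis
      r_p <- config$pasi_coupling_r
      pasi <- as.integer(clamp(round(gp$pasi_mean + gp$pasi_sd *
               (r_p * s + sqrt(1 - r_p^2) * z_pasi)), 1, 29))
      r_l <- config$lis_coupling_r
      lis <- as.integer(clamp(round(gp$lis_mean + gp$lis_sd *
               (r_l * s + sqrt(1 - r_l^2) * z_lis)), 1, 10))
    }
    structure(list(subject_id = subject_id, group_label = group,
                   sites = sites, pasi = pasi, lis = lis,
                   truth = list(severity = s,
                                params = lapply(sites, `[[`, "params"))),
              class = "SyntheticSubject")
  })
}

perturb_params <- function(gp, s, subject_sd) {
  for (nm in names(subject_sd)) gp[[nm]] <- gp[[nm]] + s * subject_sd[[nm]]
  gp$tau1_ns <- max(gp$tau1_ns, 0.05)
  gp$tau2_ns <- max(gp$tau2_ns, gp$tau1_ns * 2)
  gp$a2_fraction <- clamp(gp$a2_fraction, 0.02, 0.95)
  gp$sg_depth_um <- max(gp$sg_depth_um, 5)
  gp$sb_depth_um <- max(gp$sb_depth_um, gp$sg_depth_um + 5)
  gp$puncta_density <- max(gp$puncta_density, 0)
  gp
}

#' Simulate a full study cohort
#'
#' Deterministically (for a fixed seed) generates subjects for each
#' requested group and assembles a truth table with the generative
#' parameters and clinical scores of every subject, for recovery tests.
#'
#' @param n_per_group named integer vector, e.g.
#'   \code{c(control = 18, psoriasis = 33, eczema = 7)} (the enrolled group
#'   sizes of a typical single-centre study); groups given 0 are omitted
#' @param config a \code{\link{cohortConfig}} list
#' @param seed RNG seed
#' @return list of class "SyntheticCohort" with elements subjects, truth
#'   (data.frame) and config
#' @export
generateCohort <- function(n_per_group = c(control = 18, psoriasis = 33,
                                           eczema = 7),
                           config = cohortConfig(), seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    flim_error("flim_invalid_config", "n_per_group must be a named vector")
  bad <- setdiff(names(n_per_group), names(config$groups))
  if (length(bad))
    flim_error("flim_invalid_config", "unknown group label '%s'", bad[1])
  n_per_group <- n_per_group[n_per_group > 0]
  with_seed(seed, {
    total <- sum(n_per_group)
    seeds <- sample.int(.Machine$integer.max - 1L, total)
    subjects <- vector("list", total)
    rows <- vector("list", total)
    k <- 0L
    for (g in names(n_per_group)) {
      for (i in seq_len(n_per_group[[g]])) {
        k <- k + 1L
        id <- sprintf("%s_%02d", g, i)
        subj <- generateSubject(g, config, seed = seeds[k], subject_id = id)
        subjects[[k]] <- subj
        pp <- subj$sites[[1]]$params
        rows[[k]] <- data.frame(subject_id = id, group = g,
          severity = subj$truth$severity, tau1_ns = pp$tau1_ns,
          tau2_ns = pp$tau2_ns, a2_fraction = pp$a2_fraction,
          sg_depth_um = pp$sg_depth_um, sb_depth_um = pp$sb_depth_um,
          dist_sg_sb_um = pp$sb_depth_um - pp$sg_depth_um,
          puncta_density = pp$puncta_density, pasi = subj$pasi,
          lis = subj$lis, stringsAsFactors = FALSE)
      }
    }
    structure(list(subjects = subjects, truth = do.call(rbind, rows),
                   config = config), class = "SyntheticCohort")
  })
}

#' @export
print.SyntheticCohort <- function(x, ...) {
  tab <- table(x$truth$group)
  cat("SyntheticCohort:", nrow(x$truth), "subjects (",
      paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), ")\n")
  invisible(x)
}

#' @export
print.SyntheticSubject <- function(x, ...) {
  cat(sprintf("SyntheticSubject %s (%s), %d site(s)%s\n", x$subject_id,
              x$group_label, length(x$sites),
              if (!is.na(x$pasi)) sprintf(", PASI %d, LIS %d", x$pasi, x$lis)
              else ""))
  invisible(x)
}
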