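#' Condition feature schema (8 features)
#'
#' Fixed, documented column order of the skin-condition feature vector:
#' the Fourier parameter at the SB, mean and SD of the fitted lifetime
#' components at the named layers, SG imaging depth, SG-to-SB optical
#' distance, and mean local entropy at the SG.
#' @export
CONDITION_FEATURES <- c("fourier_SB", "tau1_mean_SB", "tau2_mean_SB",
                        "tau1_std_SB", "tau2_std_SG", "depth_SG_um",
                        "dist_SG_SB_um", "entropy_SG")

#' PASI feature schema (5 features)
#'
#' Fixed column order of the PASI-analysis feature vector; all ratios are
#' inflamed site over pseudo-control site of the same subject.
#' @export
PASI_FEATURES <- c("dist_SG_SB_inflamed_um", "dist_ratio_inflamed_over_pseudo",
                   "p2_SG_ratio_inflamed_over_pseudo",
                   "fourier_SB_ratio_inflamed_over_pseudo",
                   "p1_SB_inflamed_percent")

#' Select the SG and SB frames of an image stack
#'
#' Picks the stratum granulosum and stratum basale sections of a site by
#' axial depth metadata: either explicit frame indices or target depths
#' (defaulting to the SG/SB depths stored in the site metadata, which for
#' synthetic data are the generative truth). Only sections that carry
#' photon data are eligible.
#'
#' @param site one imaging site (as produced by
#'   \code{\link{generateSubject}})
#' @param targets optional numeric c(sg, sb) target depths in um
#' @param indices optional integer c(sg, sb) explicit frame indices
#' @return list of class "LayerSelection": sg_index, sb_index, sg_depth_um,
#'   sb_depth_um
#' @export
selectLayers <- function(site, targets = NULL, indices = NULL) {
  depths <- site$depth_um
  rendered <- which(!vapply(site$frames, is.null, logical(1)))
  if (length(rendered) == 0L)
    flim_error("flim_invalid_config", "site has no rendered frames")
  if (!is.null(indices)) {
    if (length(indices) != 2L || any(!indices %in% rendered))
      flim_error("flim_invalid_config",
                 "indices must name two rendered frames")
    sg_i <- indices[1]; sb_i <- indices[2]
  } else {
    if (is.null(targets)) targets <- c(site$sg_depth_um, site$sb_depth_um)
    sg_i <- rendered[which.min(abs(depths[rendered] - targets[1]))]
    sb_i <- rendered[which.min(abs(depths[rendered] - targets[2]))]
  }
  if (depths[sg_i] >= depths[sb_i])
    flim_error("flim_inconsistent_layers",
               "selected SG depth (%.1f um) is not above SB depth (%.1f um)",
               depths[sg_i], depths[sb_i])
  structure(list(sg_index = sg_i, sb_index = sb_i,
                 sg_depth_um = depths[sg_i], sb_depth_um = depths[sb_i]),
            class = "LayerSelection")
}

#' Depth features of a layer selection
#'
#' SG imaging depth and SG-to-SB optical distance. "Optical distance" is
#' the raw stage-depth difference read from metadata, with no
#' refractive-index correction.
#'
#' @param sel a "LayerSelection"
#' @return named numeric c(depth_SG_um, dist_SG_SB_um)
#' @export
depthFeatures <- function(sel) {
  stopifnot(inherits(sel, "LayerSelection"))
  c(depth_SG_um = sel$sg_depth_um,
    dist_SG_SB_um = sel$sb_depth_um - sel$sg_depth_um)
}

#' Per-site analysis summary
#'
#' Runs the whole per-site measurement chain once: layer selection,
#' lifetime fitting of the SG and SB frames, frame lifetime statistics,
#' Fourier parameter at the SB and mean local entropy at the SG (both from
#' the time-summed intensity image). Every subject feature is assembled
#' from these scalars.
#'
#' @param site one imaging site
#' @param config a \code{\link{cohortConfig}} list
#' @return named list of per-site scalars
#' @export
siteSummary <- function(site, config = cohortConfig()) {
  sel <- selectLayers(site)
  fit <- config$fit
  map_sg <- fitFrame(site$frames[[sel$sg_index]], n = fit$n_bin,
                     min_photons = fit$min_photons, stride = fit$stride,
                     max_iter = fit$max_iter, ftol = fit$ftol)
  map_sb <- fitFrame(site$frames[[sel$sb_index]], n = fit$n_bin,
                     min_photons = fit$min_photons, stride = fit$stride,
                     max_iter = fit$max_iter, ftol = fit$ftol)
  st_sg <- frameLifetimeStats(map_sg)
  st_sb <- frameLifetimeStats(map_sb)
  int_sg <- intensityImage(site$frames[[sel$sg_index]])
  int_sb <- intensityImage(site$frames[[sel$sb_index]])
  dep <- depthFeatures(sel)
  list(subject_id = site$subject_id, group_label = site$group_label,
       site = site$site,
       fourier_SB = fourierParameter(int_sb, config$fourier$medium,
                                     config$fourier$high,
                                     reference_size = config$fourier$reference_size),
       entropy_SG = localEntropyMean(int_sg, config$entropy$radius,
                                     config$entropy$levels),
       tau1_mean_SG = st_sg[["tau1_mean"]], tau2_mean_SG = st_sg[["tau2_mean"]],
       tau1_std_SG = st_sg[["tau1_sd"]], tau2_std_SG = st_sg[["tau2_sd"]],
       tau1_mean_SB = st_sb[["tau1_mean"]], tau2_mean_SB = st_sb[["tau2_mean"]],
       tau1_std_SB = st_sb[["tau1_sd"]], tau2_std_SB = st_sb[["tau2_sd"]],
       p1_SB_percent = st_sb[["p1_mean"]], p2_SB_percent = st_sb[["p2_mean"]],
       p1_SG_percent = st_sg[["p1_mean"]], p2_SG_percent = st_sg[["p2_mean"]],
       depth_SG_um = dep[["depth_SG_um"]],
       dist_SG_SB_um = dep[["dist_SG_SB_um"]])
}

#' Assemble the 8-feature skin-condition vector for one site
#'
#' @param summary a \code{\link{siteSummary}} result
#' @return named numeric vector in \code{\link{CONDITION_FEATURES}} order
#' @export
conditionFeatures <- function(summary) {
  v <- c(fourier_SB = summary$fourier_SB,
         tau1_mean_SB = summary$tau1_mean_SB,
         tau2_mean_SB = summary$tau2_mean_SB,
         tau1_std_SB = summary$tau1_std_SB,
         tau2_std_SG = summary$tau2_std_SG,
         depth_SG_um = summary$depth_SG_um,
         dist_SG_SB_um = summary$dist_SG_SB_um,
         entropy_SG = summary$entropy_SG)
  if (any(is.na(v) | !is.finite(v)))
    flim_error("flim_incomplete_subject",
               "missing feature(s) %s for %s/%s",
               paste(names(v)[!is.finite(v)], collapse = ", "),
               summary$subject_id, summary$site)
  v[CONDITION_FEATURES]
}

#' Assemble the 5-feature PASI vector for one psoriasis subject
#'
#' All ratios are inflamed over pseudo-control site of the same subject.
#'
#' @param inflamed,pseudo \code{\link{siteSummary}} results for the two
#'   sites of a psoriasis subject
#' @return named numeric vector in \code{\link{PASI_FEATURES}} order
#' @export
pasiFeatures <- function(inflamed, pseudo) {
  if (is.null(inflamed) || is.null(pseudo))
    flim_error("flim_incomplete_subject",
               "PASI features require both an inflamed and a pseudo-control site")
  den <- c(dist = pseudo$dist_SG_SB_um, p2 = pseudo$p2_SG_percent,
           fourier = pseudo$fourier_SB)
  if (any(den == 0))
    flim_error("flim_degenerate_ratio",
               "zero pseudo-control denominator: %s",
               paste(names(den)[den == 0], collapse = ", "))
  v <- c(dist_SG_SB_inflamed_um = inflamed$dist_SG_SB_um,
         dist_ratio_inflamed_over_pseudo =
           inflamed$dist_SG_SB_um / pseudo$dist_SG_SB_um,
         p2_SG_ratio_inflamed_over_pseudo =
           inflamed$p2_SG_percent / pseudo$p2_SG_percent,
         fourier_SB_ratio_inflamed_over_pseudo =
           inflamed$fourier_SB / pseudo$fourier_SB,
         p1_SB_inflamed_percent = inflamed$p1_SB_percent)
  if (any(is.na(v) | !is.finite(v)))
    flim_error("flim_incomplete_subject", "missing PASI feature(s) for %s",
               inflamed$subject_id)
  v[PASI_FEATURES]
}

#' Compute per-site summaries for a whole cohort
#'
#' Sites whose processing fails (all pixels masked, inconsistent layers,
#' ...) are excluded and listed with their reason, mirroring the
#' usable-data accounting of a clinical imaging study.
#'
#' @param cohort a "SyntheticCohort"
#' @param config analysis configuration; defaults to the cohort's own
#' @return list with elements summaries (per subject: list of per-site
#'   summaries) and excluded (data.frame subject_id, site, reason)
#' @export
cohortSiteSummaries <- function(cohort, config = cohort$config) {
  excluded <- list()
  summaries <- list()
  for (subj in cohort$subjects) {
    per_site <- list()
    for (site in subj$sites) {
      res <- tryCatch(siteSummary(site, config), flim_error = function(e) e)
      if (inherits(res, "error")) {
        excluded[[length(excluded) + 1L]] <-
          data.frame(subject_id = subj$subject_id, site = site$site,
                     reason = conditionMessage(res),
                     stringsAsFactors = FALSE)
      } else {
        per_site[[site$site]] <- res
      }
    }
    summaries[[subj$subject_id]] <- per_site
  }
  list(summaries = summaries,
       excluded = if (length(excluded)) do.call(rbind, excluded)
                  else data.frame(subject_id = character(),
                                  site = character(), reason = character()))
}

#' Build a cohort feature table
#'
#' In "condition" mode, one row per subject-site with the 8-feature
#' skin-condition vector and the site's group label (a psoriasis subject
#' contributes a "psoriasis" row from its inflamed site and a
#' "pseudo_control" row from its non-lesional site). In "pasi" mode, one
#' row per psoriasis subject with the 5-feature vector and the clinical
#' PASI/LIS scores. Subjects with any unusable constituent are excluded
#' (never imputed) and recorded in the "excluded" attribute.
#'
#' @param cohort a "SyntheticCohort"
#' @param mode "condition" or "pasi"
#' @param config analysis configuration
#' @param site_summaries optional precomputed
#'   \code{\link{cohortSiteSummaries}} result (avoids refitting when both
#'   modes are needed)
#' @return data.frame with attribute "excluded"
#' @export
cohortFeatureTable <- function(cohort, mode = c("condition", "pasi"),
                               config = cohort$config,
                               site_summaries = NULL) {
  mode <- match.arg(mode)
  if (is.null(site_summaries))
    site_summaries <- cohortSiteSummaries(cohort, config)
  excluded <- site_summaries$excluded
  rows <- list()
  for (subj in cohort$subjects) {
    per_site <- site_summaries$summaries[[subj$subject_id]]
    if (mode == "condition") {
      for (sm in per_site) {
        feat <- tryCatch(conditionFeatures(sm), flim_error = function(e) e)
        if (inherits(feat, "error")) {
          excluded <- rbind(excluded,
            data.frame(subject_id = subj$subject_id, site = sm$site,
                       reason = conditionMessage(feat),
                       stringsAsFactors = FALSE))
          next
        }
        rows[[length(rows) + 1L]] <- data.frame(
          subject_id = subj$subject_id, site = sm$site,
          group = sm$group_label, pasi = subj$pasi, lis = subj$lis,
          as.list(feat), stringsAsFactors = FALSE)
      }
    } else {
      if (subj$group_label != "psoriasis") next
      feat <- tryCatch(
        pasiFeatures(per_site[["inflamed"]], per_site[["pseudo_control"]]),
        flim_error = function(e) e)
      if (inherits(feat, "error") || is.null(per_site[["inflamed"]])) {
        excluded <- rbind(excluded,
          data.frame(subject_id = subj$subject_id, site = "subject",
                     reason = if (inherits(feat, "error"))
                       conditionMessage(feat) else "missing inflamed site",
                     stringsAsFactors = FALSE))
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = subj$subject_id, pasi = subj$pasi, lis = subj$lis,
        as.list(feat), stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    flim_error("flim_incomplete_subject", "no usable subject in cohort")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
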