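#' Simulate a cohort and summarize it site by site
#'
#' Streaming equivalent of \code{\link{generateCohort}} followed by
#' \code{\link{cohortSiteSummaries}}: each subject's decay cubes are
#' generated, summarized (layer selection, lifetime fitting, texture and
#' depth features) and released before the next subject is drawn, so peak
#' memory stays at one subject's frames rather than a whole cohort's. The
#' RNG stream matches \code{generateCohort} exactly, so for a given
#' (n_per_group, config, seed) the summaries are identical to the
#' materialized route.
#'
#' @inheritParams generateCohort
#' @return list with elements cohort (a frame-less "SyntheticCohort":
#'   subjects keep metadata, clinical scores and truth, but no pixel
#'   data) and site_summaries (as \code{\link{cohortSiteSummaries}}:
#'   summaries + excluded)
#' @export
simulateCohortSummaries <- function(n_per_group, config = cohortConfig(),
                                    seed = 1L) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == ""))
    flim_error("flim_invalid_config", "n_per_group must be a named vector")
  bad <- setdiff(names(n_per_group), names(config$groups))
  if (length(bad))
    flim_error("flim_invalid_config", "unknown group label '%s'", bad[1])
  n_per_group <- n_per_group[n_per_group > 0]
  total <- sum(n_per_group)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, total))
  subjects <- vector("list", total)
  rows <- vector("list", total)
  summaries <- list()
  excluded <- list()
  k <- 0L
  for (g in names(n_per_group)) {
    for (i in seq_len(n_per_group[[g]])) {
      k <- k + 1L
      id <- sprintf("%s_%02d", g, i)
      subj <- generateSubject(g, config, seed = seeds[k], subject_id = id)
      per_site <- list()
      for (site in subj$sites) {
        res <- tryCatch(siteSummary(site, config),
                        flim_error = function(e) e)
        if (inherits(res, "error")) {
          excluded[[length(excluded) + 1L]] <-
            data.frame(subject_id = id, site = site$site,
                       reason = conditionMessage(res),
                       stringsAsFactors = FALSE)
        } else {
          per_site[[site$site]] <- res
        }
      }
      summaries[[id]] <- per_site
      pp <- subj$sites[[1]]$params
      rows[[k]] <- data.frame(subject_id = id, group = g,
        severity = subj$truth$severity, tau1_ns = pp$tau1_ns,
        tau2_ns = pp$tau2_ns, a2_fraction = pp$a2_fraction,
        sg_depth_um = pp$sg_depth_um, sb_depth_um = pp$sb_depth_um,
        dist_sg_sb_um = pp$sb_depth_um - pp$sg_depth_um,
        puncta_density = pp$puncta_density, pasi = subj$pasi,
        lis = subj$lis, stringsAsFactors = FALSE)
      # keep metadata, drop pixel data
      subj$sites <- lapply(subj$sites, function(s) {
        s$frames <- NULL
        s
      })
      subjects[[k]] <- subj
    }
  }
  cohort <- structure(list(subjects = subjects,
                           truth = do.call(rbind, rows), config = config),
                      class = "SyntheticCohort")
  list(cohort = cohort,
       site_summaries = list(
         summaries = summaries,
         excluded = if (length(excluded)) do.call(rbind, excluded)
                    else data.frame(subject_id = character(),
                                    site = character(),
                                    reason = character())))
}
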