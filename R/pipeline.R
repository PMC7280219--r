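#' Run the full severity-scoring pipeline on a cohort
#'
#' Ties the stages together: per-site measurement (lifetime fitting +
#' texture + depth features), feature-table assembly, standardization, PCA,
#' PC1 orientation and scoring, and the clinical correlations. Two
#' analyses are produced: a "condition" analysis with one row per
#' subject-site and the 8-feature vector (group clustering along PC1), and
#' -- when the cohort contains psoriasis subjects -- a "pasi" analysis with
#' one row per psoriasis subject and the 5-feature vector, correlated with
#' the PASI score. The whole run is a pure function of (cohort, config).
#'
#' @param cohort a "SyntheticCohort" (from \code{\link{generateCohort}} or
#'   \code{\link{readCohort}})
#' @param config analysis configuration; defaults to the cohort's own
#' @param modes which analyses to run
#' @param site_summaries optional precomputed per-site summaries (from
#'   \code{\link{cohortSiteSummaries}} or
#'   \code{\link{simulateCohortSummaries}}); when given, no pixel data is
#'   touched
#' @return list with elements condition (table, model, scores, separation,
#'   excluded) and pasi (table, model, scores, pearson_r_pasi,
#'   pearson_r_pasi_lis)
#' @export
runSeverityPipeline <- function(cohort, config = cohort$config,
                                modes = c("condition", "pasi"),
                                site_summaries = NULL) {
  ss <- if (is.null(site_summaries)) cohortSiteSummaries(cohort, config)
        else site_summaries
  out <- list()
  if ("condition" %in% modes) {
    tab <- cohortFeatureTable(cohort, "condition", config,
                              site_summaries = ss)
    model <- fitSeverityModel(tab, CONDITION_FEATURES)
    model <- orientPC1(model, tab, tab$group)
    scores <- projectScores(model, tab)
    # separation needs at least two groups with two members each
    sep <- if (sum(table(tab$group) >= 2) >= 2)
      groupSeparation(scores, tab$group) else NULL
    out$condition <- list(table = tab, model = model, scores = scores,
                          separation = sep,
                          excluded = attr(tab, "excluded"))
  }
  n_pso <- sum(vapply(cohort$subjects, `[[`, character(1), "group_label") ==
               "psoriasis")
  if ("pasi" %in% modes && n_pso >= 3L) {
    tab <- cohortFeatureTable(cohort, "pasi", config, site_summaries = ss)
    model <- fitSeverityModel(tab, PASI_FEATURES)
    model <- orientPC1ByFeature(model)
    scores <- projectScores(model, tab)
    r_pasi <- if (all(is.finite(tab$pasi)) && nrow(tab) >= 3L)
      pearsonR(scores[, 1], tab$pasi) else NA_real_
    r_pl <- if (all(is.finite(tab$pasi)) && all(is.finite(tab$lis)) &&
                nrow(tab) >= 3L)
      pearsonR(scores[, 1], tab$pasi + tab$lis) else NA_real_
    out$pasi <- list(table = tab, model = model, scores = scores,
                     pearson_r_pasi = r_pasi, pearson_r_pasi_lis = r_pl,
                     excluded = attr(tab, "excluded"))
  }
  out
}
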