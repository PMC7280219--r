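#' Region severity score
#'
#' Sum of the erythema (redness), induration (thickness) and scaling
#' grades of one body region, each graded 0-4, so the region severity runs
#' 0-12.
#'
#' @param redness,thickness,scaling integer grades in 0-4
#' @return integer severity in 0-12
#' @export
regionSeverity <- function(redness, thickness, scaling) {
  for (g in list(redness = redness, thickness = thickness,
                 scaling = scaling)) check_grade(g, 0L, 4L)
  as.integer(redness + thickness + scaling)
}

#' Region area-times-severity score
#'
#' Product of the area-of-involvement grade (0-6) and the region severity
#' (0-12), so the region score runs 0-72.
#'
#' @param area_grade integer area grade in 0-6
#' @param severity integer region severity in 0-12
#' @return integer in 0-72
#' @export
regionScore <- function(area_grade, severity) {
  check_grade(area_grade, 0L, 6L)
  check_grade(severity, 0L, 12L)
  as.integer(area_grade * severity)
}

#' Assessment of one body region
#'
#' @param region one of "head", "upper_limbs", "trunk", "lower_limbs"
#' @param redness,thickness,scaling integer grades 0-4
#' @param area_grade integer area grade 0-6
#' @return validated list of class "RegionAssessment"
#' @export
regionAssessment <- function(region, redness, thickness, scaling,
                             area_grade) {
  region <- match.arg(region, c("head", "upper_limbs", "trunk",
                                "lower_limbs"))
  sev <- regionSeverity(redness, thickness, scaling)
  structure(list(region = region, redness = as.integer(redness),
                 thickness = as.integer(thickness),
                 scaling = as.integer(scaling),
                 area_grade = as.integer(area_grade),
                 severity = sev, score = regionScore(area_grade, sev)),
            class = "RegionAssessment")
}

#' Total PASI score
#'
#' Weighted sum of the four region area-times-severity scores with
#' body-surface weights (the standard convention: head 0.1, upper limbs
#' 0.2, trunk 0.3, lower limbs 0.4; weights must sum to 1), giving a total
#' in 0-72.
#'
#' @param regions list of four \code{\link{regionAssessment}} objects, one
#'   per body region
#' @param weights named per-region weights summing to 1
#' @return numeric PASI total in [0, 72]
#' @export
pasiTotal <- function(regions,
                      weights = c(head = 0.1, upper_limbs = 0.2,
                                  trunk = 0.3, lower_limbs = 0.4)) {
  if (abs(sum(weights) - 1) > 1e-9)
    flim_error("flim_invalid_config", "region weights must sum to 1")
  got <- vapply(regions, function(r) {
    if (!inherits(r, "RegionAssessment"))
      flim_error("flim_invalid_config",
                 "regions must be RegionAssessment objects")
    r$region
  }, character(1))
  need <- c("head", "upper_limbs", "trunk", "lower_limbs")
  if (!setequal(got, need) || length(got) != 4L)
    flim_error("flim_invalid_config",
               "need exactly one assessment per region (%s)",
               paste(setdiff(need, got), collapse = ", "))
  sum(vapply(regions, function(r) weights[[r$region]] * r$score, numeric(1)))
}

#' PASI severity band
#'
#' Splits PASI totals at the conventional threshold of 10: totals of 9 or
#' less are "low" (mild psoriasis), 10 or more are "high" (moderate to
#' severe). The banding was defined on a cohort spanning totals 1-29;
#' values outside that range raise an out-of-cohort-range warning but are
#' still banded by the same threshold.
#'
#' @param pasi_total numeric PASI total
#' @return "low" or "high"
#' @export
pasiBand <- function(pasi_total) {
  if (length(pasi_total) != 1L || !is.finite(pasi_total) ||
      pasi_total < 0 || pasi_total > 72)
    flim_error("flim_invalid_config", "pasi_total must lie in [0, 72]")
  if (pasi_total < 1 || pasi_total > 29)
    flim_warning("flim_out_of_cohort_range",
                 "PASI %.1f is outside the banded cohort range [1, 29]",
                 pasi_total)
  if (pasi_total <= 9) "low" else "high"
}

#' Validate a Local Inflammation Severity grade
#'
#' LIS is clinician-assigned input data (1 = least, 10 = most severe); it
#' is validated, never computed.
#'
#' @param lis integer grade
#' @return the validated integer
#' @export
validateLis <- function(lis) {
  check_grade(lis, 1L, 10L)
  as.integer(lis)
}

#' Combined PASI + LIS severity predicate
#'
#' A configurable two-band grouping that folds the local inflammation
#' severity into the PASI banding; the default calls a subject "high" if
#' PASI >= 10 or LIS >= 7. This combined grouping has no canonical
#' clinical definition -- it is an analysis convenience, exposed so the
#' thresholds can be changed.
#'
#' @param pasi_total numeric PASI total
#' @param lis integer LIS grade
#' @param pasi_threshold,lis_threshold band thresholds
#' @return "low" or "high"
#' @export
pasiLisBand <- function(pasi_total, lis, pasi_threshold = 10,
                        lis_threshold = 7) {
  validateLis(lis)
  if (pasi_total >= pasi_threshold || lis >= lis_threshold) "high" else "low"
}

check_grade <- function(x, lo, hi) {
  if (length(x) != 1L || !is.finite(x) || x != round(x) || x < lo || x > hi)
    flim_error("flim_validation",
               "grade must be a single integer in [%d, %d], got %s", lo, hi,
               paste(format(x), collapse = ","))
  invisible(TRUE)
}
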