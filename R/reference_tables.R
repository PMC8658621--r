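#' Published cohort-average six-component volumes
#'
#' The average volumetric distribution of the six tissue components reported
#' for a 239-breast multicenter diagnostic UST cohort (mean total breast
#' volume 737 cc), entered from the published summary table. Bundled so that
#' the table's internal arithmetic (component percentages, tissue subtotals,
#' fibroglandular softness fractions) can be recomputed and used as a target
#' composition for synthetic cohorts.
#'
#' @return a \code{\link{component_volume_table}} with fat components
#'   (soft, intermediate, hard) = (347, 160, 16) cc and fibroglandular
#'   components = (61, 87, 66) cc.
#' @export
reference_cohort_volumes <- function() {
  component_volume_table(fat = c(347, 160, 16),
                         fibroglandular = c(61, 87, 66))
}

#' Published small-cancer stiffness-class pixel averages
#'
#' Mean within-ROI stiffness-class percentages for cancers <= 1.5 cm, as
#' published for the unfiltered and the high-pass-filtered stiffness maps.
#' The filtering step moved pixels from the intermediate into the hard class
#' (hard: 61.5% to 84.6%); the reported hard-component increase is the
#' difference of these pixel averages.
#'
#' @return list with numeric vectors \code{unfiltered} and \code{filtered}
#'   (named elements \code{hard} and \code{intermediate}, in percent).
#' @export
reference_small_cancer_filtering <- function() {
  list(unfiltered = c(hard = 61.5, intermediate = 30.8),
       filtered = c(hard = 84.6, intermediate = 11.5))
}

#' Published cohort mass counts
#'
#' Mass histology and size-class counts for the published diagnostic cohort:
#' 298 masses in 239 breasts from 206 women, split at 1.5 cm diameter.
#' Bundled for cohort count arithmetic (masses per woman / per breast,
#' fibrotic share of small solid masses).
#'
#' @return list with \code{counts} (data frame: histology, small, large),
#'   \code{n_women}, \code{n_breasts}, and \code{n_small_fibrosis} (small
#'   other-benign masses with underlying fibrosis).
#' @export
reference_mass_counts <- function() {
  counts <- data.frame(
    histology = c("cancer", "fibroadenoma", "cyst", "other_benign"),
    small = c(52L, 88L, 80L, 21L),
    large = c(26L, 17L, 11L, 3L),
    stringsAsFactors = FALSE
  )
  list(counts = counts, n_women = 206L, n_breasts = 239L,
       n_small_fibrosis = 21L)
}
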