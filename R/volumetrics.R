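#' Six-component volume table
#'
#' Builds the per-breast volumetric summary from a six-component label map:
#' volume of each component by voxel counting (count x voxel volume), percent
#' of total breast volume, and fat / fibroglandular subtotals. The six
#' component volumes sum to the breast-mask volume by construction.
#'
#' @param labels six-component label \code{\link{image_stack}} (codes 0..6)
#'   from \code{\link{intersect_six}}.
#' @param spacing voxel spacing in mm; defaults to the label stack's.
#' @return a \code{component_volume_table}: data frame with one row per
#'   component (columns \code{component}, \code{tissue}, \code{stiffness},
#'   \code{voxels}, \code{volume_cc}, \code{pct_total}) and attributes
#'   \code{total_cc}, \code{fg_cc}, \code{fat_cc}.
#' @export
component_volumes <- function(labels, spacing = NULL) {
  stopifnot(is_image_stack(labels))
  if (is.null(spacing)) spacing <- labels$spacing
  codes <- labels$data
  if (any(!(codes %in% 0:6)))
    stop("label stack contains codes outside 0..6")
  counts <- vapply(1:6, function(k) sum(codes == k), numeric(1))
  vv <- voxel_volume_cc(spacing)
  vols <- counts * vv
  make_volume_table(vols, voxels = counts)
}

# Assemble a component_volume_table from six component volumes (cc), in the
# order of six_component_names().
make_volume_table <- function(volumes_cc, voxels = NA_real_) {
  stopifnot(length(volumes_cc) == 6L, all(volumes_cc >= 0))
  comp <- six_component_names()
  total <- sum(volumes_cc)
  tbl <- data.frame(
    component = comp,
    tissue = rep(c("fat", "fibroglandular"), each = 3L),
    stiffness = rep(c("soft", "intermediate", "hard"), 2L),
    voxels = voxels,
    volume_cc = as.numeric(volumes_cc),
    pct_total = if (total > 0) 100 * volumes_cc / total else rep(0, 6L),
    stringsAsFactors = FALSE
  )
  structure(tbl,
            total_cc = total,
            fat_cc = sum(volumes_cc[1:3]),
            fg_cc = sum(volumes_cc[4:6]),
            class = c("component_volume_table", "data.frame"))
}

#' Construct a component volume table from known volumes
#'
#' Useful for entering published cohort-average volumes directly (e.g. to
#' recompute a report table's internal percentages).
#'
#' @param fat,fibroglandular length-3 numeric vectors of volumes in cc, in
#'   the order soft, intermediate, hard.
#' @return a \code{component_volume_table}.
#' @export
component_volume_table <- function(fat, fibroglandular) {
  stopifnot(length(fat) == 3L, length(fibroglandular) == 3L)
  make_volume_table(c(as.numeric(fat), as.numeric(fibroglandular)))
}

#' @export
print.component_volume_table <- function(x, digits = 1, ...) {
  cat("Six-component breast volumes\n")
  df <- as.data.frame(x)
  df$volume_cc <- round(df$volume_cc, digits)
  df$pct_total <- round(df$pct_total, digits)
  print(df, row.names = FALSE)
  cat(sprintf("Totals: fibroglandular %.*f cc (%.*f%%), fat %.*f cc (%.*f%%), breast %.*f cc\n",
              digits, attr(x, "fg_cc"),
              digits, 100 * attr(x, "fg_cc") / max(attr(x, "total_cc"), 1e-12),
              digits, attr(x, "fat_cc"),
              digits, 100 * attr(x, "fat_cc") / max(attr(x, "total_cc"), 1e-12),
              digits, attr(x, "total_cc")))
  invisible(x)
}

#' Report-shaped layout of a volume table
#'
#' Re-arranges a \code{component_volume_table} into the conventional
#' stiffness-by-tissue layout: rows hard / intermediate / soft / total,
#' columns fibroglandular, fat and total, each with cc and percent of total
#' breast volume.
#'
#' @param tbl a \code{component_volume_table}.
#' @param digits rounding for display columns (default 1, the usual report
#'   precision); percentages are computed before rounding.
#' @return data frame with columns \code{stiffness}, \code{fg_cc},
#'   \code{fg_pct}, \code{fat_cc}, \code{fat_pct}, \code{total_cc},
#'   \code{total_pct}.
#' @export
volume_report <- function(tbl, digits = 1) {
  stopifnot(inherits(tbl, "component_volume_table"))
  total <- attr(tbl, "total_cc")
  get <- function(tissue, stiff) tbl$volume_cc[tbl$tissue == tissue & tbl$stiffness == stiff]
  rows <- c("hard", "intermediate", "soft")
  fg <- vapply(rows, function(s) get("fibroglandular", s), numeric(1))
  fat <- vapply(rows, function(s) get("fat", s), numeric(1))
  df <- data.frame(
    stiffness = c(rows, "total"),
    fg_cc = c(fg, sum(fg)),
    fat_cc = c(fat, sum(fat)),
    stringsAsFactors = FALSE
  )
  df$total_cc <- df$fg_cc + df$fat_cc
  pct <- function(v) if (total > 0) 100 * v / total else 0 * v
  df$fg_pct <- pct(df$fg_cc)
  df$fat_pct <- pct(df$fat_cc)
  df$total_pct <- pct(df$total_cc)
  num <- c("fg_cc", "fg_pct", "fat_cc", "fat_pct", "total_cc", "total_pct")
  df[num] <- lapply(df[num], round, digits = digits)
  df[, c("stiffness", "fg_cc", "fg_pct", "fat_cc", "fat_pct", "total_cc", "total_pct")]
}

#' Cohort average of per-breast volume tables
#'
#' Averages component volumes across breasts; percentages are recomputed from
#' the mean volumes (not averaged), which keeps the table's internal
#' arithmetic exact (percent = mean cc / mean total cc).
#'
#' @param tables nonempty list of \code{component_volume_table}s.
#' @return a \code{component_volume_table} of mean volumes.
#' @export
cohort_average <- function(tables) {
  if (!length(tables)) stop("need at least one volume table")
  stopifnot(all(vapply(tables, inherits, TRUE, "component_volume_table")))
  vols <- rowMeans(vapply(tables, function(t) t$volume_cc, numeric(6)))
  make_volume_table(vols)
}

#' Correlation between sound speed and stiffness
#'
#' Pearson correlation of within-mask voxel values, used to check that the
#' stiffness map carries information beyond its sound-speed component.
#'
#' @param ss sound-speed \code{image_stack}.
#' @param S stiffness \code{image_stack} on the same grid.
#' @param mask breast mask, nonempty.
#' @return Pearson r; \code{NA} with a warning if either input has zero
#'   variance within the mask.
#' @export
ss_stiffness_correlation <- function(ss, S, mask) {
  stopifnot(is_image_stack(ss), is_image_stack(S))
  stop_if_geometry_mismatch(ss, S)
  m <- as_mask_array(mask, ss)
  if (!any(m)) stop("mask is empty")
  x <- ss$data[m]; y <- S$data[m]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance within mask: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}
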