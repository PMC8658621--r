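#' Single-slice mass region of interest
#'
#' A hand-traced (or synthetic) mass contour on one coronal slice: a simple
#' polygon in mm coordinates plus the slice index and histology. Metrics are
#' computed strictly inside the contour (the peritumoral region is excluded).
#'
#' @param polygon n x 2 matrix of (x, y) vertices in mm, n >= 3, describing a
#'   simple (non-self-intersecting) polygon.
#' @param slice_index 1-based coronal slice index.
#' @param histology one of \code{"cancer"}, \code{"fibroadenoma"},
#'   \code{"cyst"}, \code{"other_benign"}.
#' @param breast_id identifier of the breast the ROI belongs to.
#' @return a \code{mass_roi} object.
#' @export
mass_roi <- function(polygon, slice_index,
                     histology = c("cancer", "fibroadenoma", "cyst", "other_benign"),
                     breast_id = "breast_1") {
  histology <- match.arg(histology)
  polygon <- as.matrix(polygon)
  if (ncol(polygon) != 2L || nrow(polygon) < 3L)
    stop("`polygon` must be an n x 2 matrix with n >= 3 vertices")
  if (!all(is.finite(polygon))) stop("polygon vertices must be finite")
  if (polygon_self_intersects(polygon))
    stop("polygon is self-intersecting; ROI must be a simple polygon")
  structure(list(polygon = polygon, slice_index = as.integer(slice_index),
                 histology = histology, breast_id = breast_id),
            class = "mass_roi")
}

# Segment-intersection test over non-adjacent edge pairs (proper crossings).
polygon_self_intersects <- function(p) {
  n <- nrow(p)
  seg <- cbind(p, p[c(2:n, 1), ])
  cross <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2L)) {
    for (j in (i + 2L):n) {
      if (i == 1L && j == n) next  # adjacent around the wrap
      d1 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 1], seg[j, 2])
      d2 <- cross(seg[i, 1], seg[i, 2], seg[i, 3], seg[i, 4], seg[j, 3], seg[j, 4])
      d3 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 1], seg[i, 2])
      d4 <- cross(seg[j, 1], seg[j, 2], seg[j, 3], seg[j, 4], seg[i, 3], seg[i, 4])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Rasterize an ROI polygon onto the pixel grid
#'
#' A pixel belongs to the ROI iff its centre lies inside the polygon by the
#' even-odd (ray-casting) rule, so the rasterized area is the pixel count
#' times the pixel area.
#'
#' @param roi a \code{\link{mass_roi}} (or bare n x 2 vertex matrix).
#' @param geometry in-plane grid geometry from \code{\link{grid_geometry}}:
#'   list with \code{shape}, \code{spacing}, \code{origin} (mm).
#' @return logical matrix of shape \code{geometry$shape}.
#' @export
rasterize_roi <- function(roi, geometry) {
  poly <- if (inherits(roi, "mass_roi")) roi$polygon else as.matrix(roi)
  if (nrow(poly) < 3L) stop("degenerate polygon: fewer than 3 vertices")
  nx <- geometry$shape[1]; ny <- geometry$shape[2]
  cx <- geometry$origin[1] + (seq_len(nx) - 0.5) * geometry$spacing[1]
  cy <- geometry$origin[2] + (seq_len(ny) - 0.5) * geometry$spacing[2]
  px <- rep(cx, times = ny)
  py <- rep(cy, each = nx)
  inside <- rep(FALSE, nx * ny)
  n <- nrow(poly)
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  matrix(inside, nx, ny)
}

#' Mean stiffness index of a mass ROI
#'
#' The per-mass stiffness index on the 0-1 scale: the arithmetic mean of the
#' stiffness pixel values inside the rasterized contour.
#'
#' @param S_slice numeric matrix, the stiffness slice the ROI was traced on.
#' @param roi_mask logical matrix from \code{\link{rasterize_roi}}.
#' @return scalar in [0, 1].
#' @export
stiffness_index <- function(S_slice, roi_mask) {
  if (!any(roi_mask)) stop("ROI mask is empty")
  mean(S_slice[roi_mask])
}

#' Stiffness-class and six-component percentages inside an ROI
#'
#' Intersects the whole-breast component label slice with the ROI and
#' returns the percentage of ROI pixels in each stiffness class (soft,
#' intermediate, hard; summing to 100) and in each of the six components.
#' ROI pixels falling outside the breast mask (label 0) are excluded with a
#' warning.
#'
#' @param label_slice integer matrix of six-component codes (0..6) for the
#'   ROI's slice.
#' @param roi_mask logical matrix from \code{\link{rasterize_roi}}.
#' @return list with \code{stiffness_pct} (named length-3) and
#'   \code{component_pct} (named length-6).
#' @export
roi_component_percentages <- function(label_slice, roi_mask) {
  if (!any(roi_mask)) stop("ROI mask is empty")
  codes <- label_slice[roi_mask]
  if (any(codes == 0)) {
    warning("ROI extends outside the breast mask; outside pixels excluded")
    codes <- codes[codes != 0]
    if (!length(codes)) stop("ROI lies entirely outside the breast mask")
  }
  comp <- vapply(1:6, function(k) sum(codes == k), numeric(1))
  names(comp) <- six_component_names()
  stiff <- c(soft = comp[[1]] + comp[[4]],
             intermediate = comp[[2]] + comp[[5]],
             hard = comp[[3]] + comp[[6]])
  list(stiffness_pct = 100 * stiff / sum(stiff),
       component_pct = 100 * comp / sum(comp))
}

#' GLCM homogeneity of a mass ROI
#'
#' Texture homogeneity from symmetric, normalised gray-level co-occurrence
#' matrices: stiffness values in [0, 1] are uniformly quantised into
#' \code{levels} bins, co-occurrences are counted over pixel pairs that are
#' both inside the ROI for each offset, and homogeneity is
#' \code{sum(P / (1 + |i - j|))}, averaged over the offsets that contribute
#' at least one pair. A constant region scores exactly 1.
#'
#' @param S_slice numeric matrix of stiffness values in [0, 1].
#' @param roi_mask logical matrix from \code{\link{rasterize_roi}}.
#' @param levels number of gray levels (default 8).
#' @param offsets list of (row, col) displacement pairs; default the four
#'   standard directions (0,1), (1,0), (1,1), (1,-1).
#' @return homogeneity in (0, 1], or \code{NA} with a warning if no offset
#'   yields a valid pixel pair.
#' @export
glcm_homogeneity <- function(S_slice, roi_mask, levels = 8L,
                             offsets = list(c(0L, 1L), c(1L, 0L),
                                            c(1L, 1L), c(1L, -1L))) {
  if (sum(roi_mask) < 2L) stop("ROI must contain at least 2 pixels")
  q <- pmin(pmax(floor(pmin(pmax(S_slice, 0), 1) * levels), 0), levels - 1L)
  d <- dim(S_slice)
  vals <- numeric(0)
  for (off in offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr):min(d[1], d[1] - dr)
    c1 <- max(1L, 1L - dc):min(d[2], d[2] - dc)
    if (!length(r1) || !length(c1)) next
    a_ok <- roi_mask[r1, c1, drop = FALSE] &
      roi_mask[r1 + dr, c1 + dc, drop = FALSE]
    if (!any(a_ok)) next
    gi <- q[r1, c1, drop = FALSE][a_ok]
    gj <- q[r1 + dr, c1 + dc, drop = FALSE][a_ok]
    # symmetric accumulation: count (i,j) and (j,i)
    diffs <- abs(gi - gj)
    vals <- c(vals, sum(1 / (1 + diffs)) / length(diffs))
  }
  if (!length(vals)) {
    warning("no valid pixel pairs in ROI for any offset: homogeneity undefined")
    return(NA_real_)
  }
  mean(vals)
}

#' Size class of a mass ROI
#'
#' Equivalent circular diameter from the rasterized area,
#' \code{d = 2 sqrt(area / pi)}; masses with d <= 1.5 cm are "small", larger
#' ones "large" (a tie at exactly 1.5 cm is small).
#'
#' @param roi a \code{\link{mass_roi}}.
#' @param geometry in-plane grid geometry (see \code{\link{rasterize_roi}}).
#' @return list with \code{area_mm2}, \code{equivalent_diameter_cm} and
#'   \code{size_class} ("small" or "large").
#' @export
classify_size <- function(roi, geometry) {
  m <- rasterize_roi(roi, geometry)
  area <- sum(m) * prod(geometry$spacing)
  d_mm <- 2 * sqrt(area / pi)
  list(area_mm2 = area,
       equivalent_diameter_cm = d_mm / 10,
       size_class = if (d_mm <= 15) "small" else "large")
}

#' Per-mass metric record
#'
#' Computes the full set of single-slice mass metrics for one ROI against a
#' stiffness stack and its six-component label map: 0-1 stiffness index,
#' stiffness-class and six-component percentages, GLCM homogeneity,
#' equivalent diameter and size class.
#'
#' @param roi a \code{\link{mass_roi}}.
#' @param S stiffness \code{\link{image_stack}} in [0, 1].
#' @param labels six-component label \code{image_stack} derived from \code{S}.
#' @param filtered logical flag recorded in the output (whether \code{S} is
#'   the high-pass-filtered map).
#' @param glcm_levels gray levels for the homogeneity feature.
#' @return one-row data frame (a \code{mass_record}).
#' @export
measure_mass <- function(roi, S, labels, filtered = FALSE, glcm_levels = 8L) {
  stopifnot(inherits(roi, "mass_roi"), is_image_stack(S), is_image_stack(labels))
  stop_if_geometry_mismatch(S, labels)
  k <- roi$slice_index
  if (k < 1L || k > dim(S$data)[3]) stop("slice index outside the stack")
  geom <- grid_geometry(S)
  rm_ <- rasterize_roi(roi, geom)
  if (!any(rm_)) stop("rasterized ROI is empty on this grid")
  S_slice <- S$data[, , k]
  lab_slice <- labels$data[, , k]
  pct <- roi_component_percentages(lab_slice, rm_)
  sz <- classify_size(roi, geom)
  rec <- data.frame(
    breast_id = roi$breast_id,
    histology = roi$histology,
    slice_index = k,
    filtered = filtered,
    stiffness_index = stiffness_index(S_slice, rm_),
    pct_soft = pct$stiffness_pct[["soft"]],
    pct_intermediate = pct$stiffness_pct[["intermediate"]],
    pct_hard = pct$stiffness_pct[["hard"]],
    homogeneity = glcm_homogeneity(S_slice, rm_, levels = glcm_levels),
    area_mm2 = sz$area_mm2,
    equivalent_diameter_cm = sz$equivalent_diameter_cm,
    size_class = sz$size_class,
    stringsAsFactors = FALSE
  )
  for (i in 1:6) rec[[paste0("pct_", six_component_names()[i])]] <-
    pct$component_pct[[i]]
  rec
}

#' Circular ROI polygon
#'
#' Convenience constructor for a regular-polygon approximation of a circle,
#' mainly for synthetic masses whose true outline is known.
#'
#' @param center (x, y) mm.
#' @param radius mm.
#' @param n_vertices number of polygon vertices.
#' @return n x 2 vertex matrix.
#' @export
circle_polygon <- function(center, radius, n_vertices = 32L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}
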