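#' Fusion parameters
#'
#' Controls the per-breast normalisation and the rule combining normalised
#' sound speed and attenuation into the relative stiffness (bulk-modulus
#' surrogate) map.
#'
#' @param lo_percentile,hi_percentile percentiles (0-100) mapped to 0 and 1
#'   in the robust per-breast rescaling; defaults 1 and 99.
#' @param combine_rule \code{"geometric_mean"} (default): the voxelwise
#'   stiffness is \code{sqrt(ss_norm * att_norm)}, so zero attenuation forces
#'   zero stiffness (cysts stay soft however fast they are) and maximal
#'   stiffness requires tissue that is both dense and attenuating.
#'   \code{"weighted_mean"}: \code{w1*ss_norm + w2*att_norm}.
#' @param weights nonnegative pair summing to 1 (weighted_mean only).
#' @param percentile_erosion in-plane voxels to erode off the mask before
#'   estimating percentiles, so a high-attenuation skin rim cannot dominate
#'   the per-breast scale; the rescaling itself is applied to the full mask.
#' @return A \code{fusion_params} list.
#' @export
fusion_params <- function(lo_percentile = 1, hi_percentile = 99,
                          combine_rule = c("geometric_mean", "weighted_mean"),
                          weights = c(0.5, 0.5),
                          percentile_erosion = 2L) {
  combine_rule <- match.arg(combine_rule)
  if (!(lo_percentile >= 0 && lo_percentile < hi_percentile && hi_percentile <= 100))
    stop("need 0 <= lo_percentile < hi_percentile <= 100")
  if (combine_rule == "weighted_mean") {
    if (length(weights) != 2L || any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
      stop("`weights` must be two nonnegative values summing to 1")
  }
  structure(list(lo_percentile = lo_percentile, hi_percentile = hi_percentile,
                 combine_rule = combine_rule, weights = weights,
                 percentile_erosion = as.integer(percentile_erosion)),
            class = "fusion_params")
}

#' Robust per-breast normalisation to [0, 1]
#'
#' Linearly rescales within-mask voxel values so the \code{lo}-th percentile
#' maps to 0 and the \code{hi}-th to 1, then clips to [0, 1]. The scale is
#' fitted per breast (not per cohort): the map is optimised for relative
#' contrast within that breast. Outside-mask voxels are set to 0.
#'
#' @param stack an \code{\link{image_stack}}.
#' @param mask breast mask (stack or logical array), nonempty.
#' @param lo,hi percentiles in [0, 100], \code{lo < hi}.
#' @param percentile_erosion in-plane erosion (voxels) of the mask used only
#'   for percentile estimation (skin-rim exclusion); 0 disables it.
#' @return a unitless \code{image_stack} in [0, 1].
#' @export
robust_normalize <- function(stack, mask, lo = 1, hi = 99,
                             percentile_erosion = 2L) {
  stopifnot(is_image_stack(stack))
  m <- as_mask_array(mask, stack)
  if (!any(m)) stop("mask is empty")
  if (!(lo >= 0 && lo < hi && hi <= 100)) stop("need 0 <= lo < hi <= 100")
  mfit <- if (percentile_erosion > 0L) {
    e <- erode_mask_inplane(m, percentile_erosion)
    if (any(e)) e else m
  } else m
  q <- stats::quantile(stack$data[mfit], c(lo, hi) / 100, type = 7, names = FALSE)
  out <- array(0, dim(stack$data))
  if (q[2] - q[1] <= 0) {
    warning("constant stack within mask: normalised map set to all zeros")
  } else {
    out[m] <- pmin(pmax((stack$data[m] - q[1]) / (q[2] - q[1]), 0), 1)
  }
  image_stack(out, stack$spacing, "stiffness", "unitless",
              origin = stack$origin)
}

#' Fuse normalised sound speed and attenuation into a stiffness map
#'
#' Voxelwise combination of the two normalised transmission maps into the
#' relative bulk-modulus surrogate on a 0-1 scale. Under the default
#' geometric-mean rule, stiffness is zero wherever attenuation is zero
#' (non-solid lesions such as cysts stay soft regardless of their sound
#' speed) and reaches 1 only where both inputs are 1.
#'
#' @param ss_norm,att_norm \code{image_stack}s in [0, 1] on the same grid
#'   (from \code{\link{robust_normalize}}).
#' @param params a \code{\link{fusion_params}}.
#' @return stiffness \code{image_stack} in [0, 1].
#' @export
fuse_stiffness <- function(ss_norm, att_norm, params = fusion_params()) {
  stopifnot(is_image_stack(ss_norm), is_image_stack(att_norm))
  stop_if_geometry_mismatch(ss_norm, att_norm)
  rng <- range(ss_norm$data, att_norm$data)
  if (rng[1] < -1e-9 || rng[2] > 1 + 1e-9)
    stop("inputs must be normalised to [0, 1]")
  s <- switch(params$combine_rule,
    geometric_mean = sqrt(pmax(ss_norm$data, 0) * pmax(att_norm$data, 0)),
    weighted_mean = params$weights[1] * ss_norm$data +
                    params$weights[2] * att_norm$data)
  image_stack(s, ss_norm$spacing, "stiffness", "unitless",
              origin = ss_norm$origin)
}

#' Stiffness colour rendering
#'
#' Maps 0-1 stiffness values onto the display convention soft = blue-black,
#' intermediate = green-yellow, hard = orange-red, along a monotone hue path
#' (blue through green and yellow to red).
#'
#' @param S numeric vector/matrix/array of stiffness values in [0, 1], or a
#'   stiffness \code{image_stack}.
#' @return character array of hex colours with the shape of the input.
#' @export
stiffness_colormap <- function(S) {
  x <- if (is_image_stack(S)) S$data else S
  if (any(x < -1e-9 | x > 1 + 1e-9, na.rm = TRUE))
    stop("stiffness values must lie in [0, 1]")
  ramp <- grDevices::colorRamp(c("#000018", "#1030B0", "#108030", "#B0B010",
                                 "#E08010", "#FF0000"), space = "rgb")
  v <- pmin(pmax(as.numeric(x), 0), 1)
  rgbm <- ramp(v)
  out <- grDevices::rgb(rgbm[, 1], rgbm[, 2], rgbm[, 3], maxColorValue = 255)
  if (!is.null(dim(x))) dim(out) <- dim(x)
  out
}
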