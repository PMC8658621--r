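#' Whole-breast stiffness analysis
#'
#' The end-to-end analysis for one breast: robust per-breast normalisation of
#' the co-registered sound-speed and attenuation stacks, fusion into the 0-1
#' relative stiffness map, 2-class sound-speed and 3-class stiffness K-means
#' segmentation intersected into the six tissue components, voxel-count
#' volumetrics, stiffness vs sound-speed correlation, the >1.5 cm high-pass
#' filtered stiffness map with its own 3-class segmentation, and per-mass
#' metrics for any supplied ROIs on both the unfiltered and filtered maps.
#'
#' Whole-breast volumetrics are always computed from the unfiltered map; the
#' filtered map is used for mass characterisation only.
#'
#' @param ss sound-speed \code{\link{image_stack}} (m/s).
#' @param att attenuation \code{image_stack} (relative units), co-registered.
#' @param breast_mask breast mask stack or logical array.
#' @param rois list of \code{\link{mass_roi}} objects (may be empty).
#' @param fusion a \code{\link{fusion_params}}.
#' @param filter a \code{\link{filter_params}}; \code{NULL} skips the
#'   filtered branch.
#' @param seed RNG seed for the K-means restarts.
#' @return object of class \code{breast_stiffness} with elements
#'   \code{stiffness}, \code{stiffness_filtered}, \code{labels},
#'   \code{labels_filtered}, \code{volumes}, \code{correlation},
#'   \code{masses} (per-mass records, unfiltered and filtered),
#'   \code{centroids}, plus the parameter objects.
#' @export
breast_stiffness <- function(ss, att, breast_mask, rois = list(),
                             fusion = fusion_params(),
                             filter = filter_params(),
                             seed = 1L) {
  stopifnot(is_image_stack(ss), is_image_stack(att))
  stop_if_geometry_mismatch(ss, att)
  m <- as_mask_array(breast_mask, ss)
  if (!any(m)) stop("breast mask is empty")

  ss_n <- robust_normalize(ss, m, fusion$lo_percentile, fusion$hi_percentile,
                           fusion$percentile_erosion)
  att_n <- robust_normalize(att, m, fusion$lo_percentile, fusion$hi_percentile,
                            fusion$percentile_erosion)
  S <- fuse_stiffness(ss_n, att_n, fusion)

  ssm <- segment_sound_speed(ss, m, seed = seed)
  stm <- segment_stiffness(S, m, seed = seed)
  mask_stack <- image_stack(m + 0, ss$spacing, "mask", "binary",
                            origin = ss$origin)
  labels <- intersect_six(ssm, stm, mask_stack)
  volumes <- component_volumes(labels)
  r <- ss_stiffness_correlation(ss, S, m)

  S_f <- NULL; labels_f <- NULL; stm_f <- NULL
  if (!is.null(filter)) {
    S_f <- apply_highpass_stack(S, m, filter)
    stm_f <- segment_stiffness(S_f, m, seed = seed)
    labels_f <- intersect_six(ssm, stm_f, mask_stack)
  }

  masses <- NULL
  if (length(rois)) {
    recs <- lapply(rois, function(roi) {
      un <- measure_mass(roi, S, labels, filtered = FALSE)
      if (!is.null(S_f)) rbind(un, measure_mass(roi, S_f, labels_f, filtered = TRUE))
      else un
    })
    masses <- do.call(rbind, recs)
    rownames(masses) <- NULL
  }

  structure(list(
    stiffness = S, stiffness_filtered = S_f,
    labels = labels, labels_filtered = labels_f,
    volumes = volumes, correlation = r, masses = masses,
    centroids = list(sound_speed = ssm$centroids,
                     stiffness = stm$centroids,
                     stiffness_filtered = if (!is.null(stm_f)) stm_f$centroids),
    breast_mask = mask_stack,
    fusion = fusion, filter = filter, seed = as.integer(seed)
  ), class = "breast_stiffness")
}

#' @export
print.breast_stiffness <- function(x, ...) {
  cat("Whole-breast stiffness analysis\n")
  tot <- attr(x$volumes, "total_cc")
  fg <- attr(x$volumes, "fg_cc")
  cat(sprintf("  breast volume: %.1f cc; fibroglandular: %.1f cc (%.1f%%)\n",
              tot, fg, 100 * fg / tot))
  hard <- sum(x$volumes$volume_cc[x$volumes$stiffness == "hard"])
  cat(sprintf("  hard component: %.1f cc (%.1f%% of breast)\n",
              hard, 100 * hard / tot))
  cat(sprintf("  stiffness vs sound-speed correlation: r = %.4f\n",
              x$correlation))
  if (!is.null(x$masses))
    cat(sprintf("  masses measured: %d ROI(s) x %s map(s)\n",
                length(unique(paste(x$masses$breast_id, x$masses$slice_index,
                                    x$masses$histology))),
                if (any(x$masses$filtered)) "2" else "1"))
  invisible(x)
}

#' @export
summary.breast_stiffness <- function(object, ...) {
  out <- list(volumes = volume_report(object$volumes),
              correlation = object$correlation,
              centroids = object$centroids,
              masses = object$masses)
  class(out) <- "summary.breast_stiffness"
  out
}

#' @export
print.summary.breast_stiffness <- function(x, ...) {
  cat("Six-component volume report (cc, % of breast):\n")
  print(x$volumes, row.names = FALSE)
  cat(sprintf("\nStiffness vs sound-speed correlation: r = %.4f\n",
              x$correlation))
  cat(sprintf("Sound-speed centroids (m/s): %s\n",
              paste(round(x$centroids$sound_speed, 1), collapse = ", ")))
  cat(sprintf("Stiffness centroids: %s\n",
              paste(round(x$centroids$stiffness, 3), collapse = ", ")))
  if (!is.null(x$masses)) {
    cat("\nPer-mass records:\n")
    cols <- c("histology", "size_class", "filtered", "stiffness_index",
              "pct_hard", "homogeneity")
    df <- x$masses[, cols]
    df$stiffness_index <- round(df$stiffness_index, 3)
    df$pct_hard <- round(df$pct_hard, 1)
    df$homogeneity <- round(df$homogeneity, 3)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Plot a stiffness slice
#'
#' Renders one coronal slice of the (filtered or unfiltered) stiffness map
#' with the soft = blue-black, intermediate = green-yellow, hard = orange-red
#' colour convention.
#'
#' @param x a \code{breast_stiffness} object.
#' @param slice coronal slice index (default: middle slice).
#' @param filtered plot the filtered map instead of the unfiltered one.
#' @param ... passed to \code{graphics::rasterImage} (unused).
#' @export
plot.breast_stiffness <- function(x, slice = NULL,
                                  filtered = FALSE, ...) {
  S <- if (filtered) x$stiffness_filtered else x$stiffness
  if (is.null(S)) stop("no filtered map in this object")
  d <- dim(S$data)
  if (is.null(slice)) slice <- max(1L, d[3] %/% 2L)
  cols <- stiffness_colormap(S$data[, , slice])
  img <- grDevices::as.raster(t(cols)[d[2]:1, , drop = FALSE])
  graphics::plot(c(0, d[1] * S$spacing[1]), c(0, d[2] * S$spacing[2]),
                 type = "n", asp = 1, xlab = "x (mm)", ylab = "y (mm)",
                 main = sprintf("%s stiffness, slice %d",
                                if (filtered) "Filtered" else "Unfiltered", slice))
  graphics::rasterImage(img, 0, 0, d[1] * S$spacing[1], d[2] * S$spacing[2])
  invisible(x)
}

# Non-overlapping mass slots for the synthetic cohorts: positions on a ring
# of radius 15 mm at depth 25 mm, inside a 30 mm-radius breast.
cohort_mass_slots <- function(n_slots = 5L, ring_radius = 15, depth_mm = 25) {
  th <- 2 * pi * (seq_len(n_slots) - 1L) / n_slots
  lapply(th, function(a) c(ring_radius * cos(a), ring_radius * sin(a), depth_mm))
}

#' Simulate a cohort of masses and measure them
#'
#' Generates phantoms carrying synthetic masses of the requested histologies
#' (assigned round-robin), runs the full analysis on each phantom, and
#' measures every mass through a circular ROI traced just inside its known
#' outline on its central slice. This is the workhorse for validating the
#' mass-level metrics: the acoustic profiles encode the qualitative
#' signatures (cysts non-attenuating and soft, fibroadenomas homogeneous and
#' intermediate, cancers fast, attenuating and internally heterogeneous).
#'
#' @param n_per_class masses per histology class.
#' @param classes histology classes to simulate (cancer / fibroadenoma /
#'   cyst / fibrosis).
#' @param diameter_mm mass diameter.
#' @param grid_shape,breast_radius,fg_fraction phantom geometry and
#'   composition (see \code{\link{phantom_spec}}).
#' @param masses_per_phantom masses placed per phantom (max 5 slots).
#' @param seed cohort seed; phantom p uses \code{seed * 1000 + p}.
#' @param filter a \code{\link{filter_params}} (or \code{NULL} to skip the
#'   filtered branch).
#' @return data frame of per-mass records (one row per mass per map).
#' @export
simulate_mass_cohort <- function(n_per_class = 20L,
                                 classes = c("cancer", "fibroadenoma", "cyst"),
                                 diameter_mm = 10,
                                 grid_shape = c(96, 96, 16),
                                 breast_radius = 30,
                                 fg_fraction = 0.25,
                                 masses_per_phantom = 5L,
                                 seed = 1L,
                                 filter = filter_params()) {
  masses_per_phantom <- min(masses_per_phantom, 5L)
  histologies <- rep(classes, length.out = n_per_class * length(classes))
  n_total <- length(histologies)
  n_phantoms <- ceiling(n_total / masses_per_phantom)
  slots <- cohort_mass_slots(masses_per_phantom)
  records <- vector("list", n_phantoms)
  idx <- 1L
  for (p in seq_len(n_phantoms)) {
    k <- min(masses_per_phantom, n_total - idx + 1L)
    hist_p <- histologies[idx:(idx + k - 1L)]
    idx <- idx + k
    specs <- mapply(function(h, s) mass_spec(h, center = s, diameter = diameter_mm),
                    hist_p, slots[seq_len(k)], SIMPLIFY = FALSE)
    spec <- phantom_spec(grid_shape = grid_shape, breast_radius = breast_radius,
                         fibroglandular_fraction = fg_fraction,
                         seed = seed * 1000L + p, masses = specs)
    ph <- generate_phantom(spec)
    zc <- phantom_coords(spec)$z
    rois <- lapply(seq_len(k), function(i) {
      ctr <- slots[[i]]
      histo <- if (hist_p[i] == "fibrosis") "other_benign" else hist_p[i]
      mass_roi(circle_polygon(ctr[1:2], 0.45 * diameter_mm),
               slice_index = which.min(abs(zc - ctr[3])),
               histology = histo,
               breast_id = sprintf("phantom_%03d", p))
    })
    fit <- breast_stiffness(ph$ss, ph$att, ph$breast_mask, rois = rois,
                            filter = filter, seed = spec$seed)
    records[[p]] <- fit$masses
  }
  out <- do.call(rbind, records)
  rownames(out) <- NULL
  out
}

#' Small stiff mass obscured by a hard parenchymal grouping
#'
#' Builds the configuration the high-pass filter is designed for: a stiff
#' mass of sub-cutoff size lying at the edge of a hard fibroglandular
#' grouping much larger than the cutoff scale (a smooth attenuation mound).
#' On the unfiltered map the grouping sets the top of the per-breast
#' stiffness scale, so the hard cluster is anchored above much of the mass
#' and the mass's hard-component percentage is diluted. Filtering suppresses
#' the large-scale grouping while the mass keeps its local contrast, which
#' should raise the mass's hard percentage -- the mass-emphasis effect the
#' filter exists for. The grouping's own hard share drops at the same time.
#'
#' @param seed phantom seed.
#' @param mass_diameter_mm mass size (default 10 mm, below the 15 mm cutoff).
#' @param parenchyma_sigma_mm Gaussian scale of the hard grouping (default
#'   14 mm: full width at half maximum about 33 mm, above the cutoff).
#' @param parenchyma_amplitude peak attenuation elevation of the grouping
#'   (relative units); the default 0.9 makes its core stiffer than the mass,
#'   which is what obscures the mass on the unfiltered map.
#' @param separation_mm distance between mass and grouping centres.
#' @param filter a \code{\link{filter_params}}.
#' @return data frame: the mass record (histology \code{"cancer"}) and a
#'   probe record over the grouping core (histology \code{"other_benign"}),
#'   each on the unfiltered and the filtered map.
#' @export
simulate_embedded_mass <- function(seed = 1L, mass_diameter_mm = 10,
                                   parenchyma_sigma_mm = 14,
                                   parenchyma_amplitude = 0.9,
                                   separation_mm = 26,
                                   filter = filter_params()) {
  mass_ctr <- c(-separation_mm / 2, 0, 25)
  blob_ctr <- c(separation_mm / 2, 0, 25)
  spec <- phantom_spec(
    grid_shape = c(96, 96, 16), breast_radius = 30,
    fibroglandular_fraction = 0.2, seed = seed,
    masses = list(mass_spec("cancer", center = mass_ctr,
                            diameter = mass_diameter_mm)),
    att_mounds = list(list(center = blob_ctr, sigma = parenchyma_sigma_mm,
                           amplitude = parenchyma_amplitude)))
  ph <- generate_phantom(spec)
  zc <- phantom_coords(spec)$z
  k <- which.min(abs(zc - 25))
  rois <- list(
    mass_roi(circle_polygon(mass_ctr[1:2], 0.45 * mass_diameter_mm),
             slice_index = k, histology = "cancer", breast_id = "obscured"),
    mass_roi(circle_polygon(blob_ctr[1:2], 0.45 * mass_diameter_mm),
             slice_index = k, histology = "other_benign",
             breast_id = "parenchyma_probe"))
  fit <- breast_stiffness(ph$ss, ph$att, ph$breast_mask, rois = rois,
                          filter = filter, seed = seed)
  fit$masses
}
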