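#' Tissue labels used in phantom ground truth
#'
#' @return Named integer vector mapping tissue names to the codes stored in
#'   the ground-truth label stack (0 = outside the breast).
#' @export
phantom_labels <- function() {
  c(outside = 0L, fat = 1L, fibroglandular = 2L, cyst = 3L,
    fibroadenoma = 4L, cancer = 5L, fibrosis = 6L, skin = 7L)
}

# Default acoustic profiles. Values are deliberately on a relative scale:
# the downstream analysis normalises per breast, so only the ordering of the
# contrasts matters (fat slow/low-attenuating, fibroglandular fast/mid,
# cysts fast but nearly transparent, cancers fast and strongly attenuating).
mass_profiles <- function() {
  list(
    cyst         = list(ss = 1520, att = 0.02, heterogeneity = 0.05),
    fibroadenoma = list(ss = 1510, att = 0.45, heterogeneity = 0.10),
    cancer       = list(ss = 1570, att = 0.85, heterogeneity = 0.50),
    fibrosis     = list(ss = 1555, att = 0.80, heterogeneity = 0.40)
  )
}

#' Describe a synthetic mass
#'
#' @param mass_type one of \code{"cyst"}, \code{"fibroadenoma"},
#'   \code{"cancer"}, \code{"fibrosis"}. Determines the default acoustic
#'   profile (sound speed, attenuation, internal speckle).
#' @param center length-3 mm coordinates (x, y in-plane relative to the
#'   breast axis; z from the nipple-most slice).
#' @param diameter sphere diameter in mm (> 0).
#' @param ss_value,att_value optional overrides of the profile values.
#' @param heterogeneity internal speckle amplitude in [0, 1]; 0 gives a
#'   perfectly homogeneous interior before acquisition noise.
#' @return A \code{mass_spec} list.
#' @export
mass_spec <- function(mass_type = c("cyst", "fibroadenoma", "cancer", "fibrosis"),
                      center, diameter,
                      ss_value = NULL, att_value = NULL,
                      heterogeneity = NULL) {
  mass_type <- match.arg(mass_type)
  if (!is.numeric(center) || length(center) != 3L)
    stop("`center` must be three mm coordinates")
  if (!is.numeric(diameter) || length(diameter) != 1L || diameter <= 0)
    stop("`diameter` must be a single positive mm value")
  prof <- mass_profiles()[[mass_type]]
  if (is.null(ss_value)) ss_value <- prof$ss
  if (is.null(att_value)) att_value <- prof$att
  if (is.null(heterogeneity)) heterogeneity <- prof$heterogeneity
  if (heterogeneity < 0 || heterogeneity > 1)
    stop("`heterogeneity` must lie in [0, 1]")
  structure(list(mass_type = mass_type, center = as.numeric(center),
                 diameter = diameter, ss_value = ss_value,
                 att_value = att_value, heterogeneity = heterogeneity),
            class = "mass_spec")
}

#' Describe a synthetic breast phantom
#'
#' Defines a pendant-breast coronal stack: slice 1 is the nipple, slices
#' increase toward the chest wall, and the in-plane breast outline follows a
#' hemispherical profile reaching \code{breast_radius} at the chest wall.
#' Fat/fibroglandular structure comes from a Gaussian-smoothed random field
#' thresholded inside the mask at the quantile that realises the requested
#' fibroglandular fraction.
#'
#' @param grid_shape voxels (nx, ny, nslices).
#' @param spacing mm voxel size; default the clinical 0.75 x 0.75 x 2.5 mm.
#' @param breast_radius mm radius of the breast at the chest wall.
#' @param fibroglandular_fraction target fraction of in-mask voxels that are
#'   fibroglandular, in [0, 1].
#' @param fg_texture_scale mm correlation length of the fibroglandular blob
#'   field (Gaussian smoothing sigma).
#' @param noise_sd_ss acquisition noise SD on sound speed, m/s.
#' @param noise_sd_att acquisition noise SD on attenuation (relative units).
#' @param att_fg_texture amplitude of the smoothed within-fibroglandular
#'   attenuation variation that produces a soft/intermediate/hard spread
#'   inside dense tissue (relative units).
#' @param skin_rim if \code{TRUE}, a 2-voxel in-plane high-attenuation rim is
#'   added inside the mask edge (emulating the skin stiffness artifact).
#' @param seed integer RNG seed; the phantom is deterministic given the seed.
#' @param masses list of \code{\link{mass_spec}} objects.
#' @param fg_discs optional list of \code{list(center=, diameter=)} spheres
#'   forced to fibroglandular tissue (deterministic parenchymal regions, e.g.
#'   to embed a mass in dense tissue); an optional \code{att} element sets the
#'   region's attenuation baseline (a hard parenchymal grouping).
#' @param att_mounds optional list of \code{list(center=, sigma=, amplitude=)}
#'   smooth Gaussian attenuation mounds (relative units) added inside the
#'   mask: large-scale hard parenchymal groupings with no sharp boundary.
#'   Voxels within the mound's half-maximum radius are labelled
#'   fibroglandular.
#' @return A \code{phantom_spec} list.
#' @export
phantom_spec <- function(grid_shape = c(128, 128, 24),
                         spacing = c(0.75, 0.75, 2.5),
                         breast_radius = 40,
                         fibroglandular_fraction = 0.291,
                         fg_texture_scale = 8,
                         noise_sd_ss = 5,
                         noise_sd_att = 0.03,
                         att_fg_texture = 0.18,
                         skin_rim = FALSE,
                         seed = 1L,
                         masses = list(),
                         fg_discs = list(),
                         att_mounds = list()) {
  if (fibroglandular_fraction < 0 || fibroglandular_fraction > 1)
    stop("`fibroglandular_fraction` must lie in [0, 1]")
  if (any(spacing <= 0)) stop("`spacing` must be strictly positive")
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 1L))
    stop("`grid_shape` must be three positive voxel counts")
  if (2 * breast_radius > grid_shape[1] * spacing[1] ||
      2 * breast_radius > grid_shape[2] * spacing[2])
    stop("grid too small to contain `breast_radius`")
  if (length(masses) && !all(vapply(masses, inherits, TRUE, "mass_spec")))
    stop("`masses` must be a list of mass_spec objects")
  structure(list(grid_shape = grid_shape, spacing = as.numeric(spacing),
                 breast_radius = breast_radius,
                 fibroglandular_fraction = fibroglandular_fraction,
                 fg_texture_scale = fg_texture_scale,
                 noise_sd_ss = noise_sd_ss, noise_sd_att = noise_sd_att,
                 att_fg_texture = att_fg_texture, skin_rim = skin_rim,
                 seed = as.integer(seed), masses = masses,
                 fg_discs = fg_discs, att_mounds = att_mounds),
            class = "phantom_spec")
}

# Background tissue acoustic baselines (m/s; relative attenuation units).
tissue_baselines <- function() {
  list(water = list(ss = 1500, att = 0),
       fat   = list(ss = 1425, att = 0.20),
       fg    = list(ss = 1530, att = 0.40),
       skin  = list(ss = 1480, att = 0.90))
}

# Voxel-centre coordinate vectors (mm) for a phantom grid.
phantom_coords <- function(spec) {
  d <- spec$grid_shape; sp <- spec$spacing
  list(x = (seq_len(d[1]) - 0.5) * sp[1] - d[1] * sp[1] / 2,
       y = (seq_len(d[2]) - 0.5) * sp[2] - d[2] * sp[2] / 2,
       z = (seq_len(d[3]) - 0.5) * sp[3])
}

# Pendant-breast mask: hemispherical radial profile, pole at the nipple
# (slice 1), full radius at the chest wall (last slice).
breast_mask_array <- function(spec) {
  d <- spec$grid_shape
  co <- phantom_coords(spec)
  R2 <- outer(co$x^2, co$y^2, "+")
  depth <- d[3] * spec$spacing[3]
  m <- array(FALSE, d)
  for (k in seq_len(d[3])) {
    u <- min(co$z[k] / depth, 1)
    rk <- spec$breast_radius * sqrt(max(u * (2 - u), 0))
    m[, , k] <- R2 <= rk^2
  }
  m
}

# Logical sphere by the centre-of-voxel test.
sphere_mask <- function(spec, center, diameter) {
  co <- phantom_coords(spec)
  d2 <- outer(outer((co$x - center[1])^2, (co$y - center[2])^2, "+"),
              (co$z - center[3])^2, "+")
  d2 <= (diameter / 2)^2
}

#' Insert a mass into phantom stacks
#'
#' Overwrites a spherical (ellipsoidal in voxel space, given the anisotropic
#' spacing) region with the mass acoustic profile and updates the ground
#' truth. The region is selected by the centre-of-voxel test. Internal
#' speckle of amplitude \code{heterogeneity} multiplies both sound speed and
#' attenuation contrasts.
#'
#' @param ss,att,truth \code{image_stack}s from \code{\link{generate_phantom}}
#'   (or being assembled by it).
#' @param breast_mask breast mask stack or logical array.
#' @param m a \code{\link{mass_spec}}.
#' @param rng_seed seed for the speckle field (deterministic insertion).
#' @return list with updated \code{ss}, \code{att}, \code{truth}.
#' @export
insert_mass <- function(ss, att, truth, breast_mask, m, rng_seed = 1L) {
  stopifnot(inherits(m, "mass_spec"))
  stop_if_geometry_mismatch(ss, att)
  stop_if_geometry_mismatch(ss, truth)
  spec_geom <- list(grid_shape = dim(ss$data), spacing = ss$spacing)
  co <- list(x = ss$origin[1] + (seq_len(dim(ss$data)[1]) - 0.5) * ss$spacing[1],
             y = ss$origin[2] + (seq_len(dim(ss$data)[2]) - 0.5) * ss$spacing[2],
             z = ss$origin[3] + (seq_len(dim(ss$data)[3]) - 0.5) * ss$spacing[3])
  d2 <- outer(outer((co$x - m$center[1])^2, (co$y - m$center[2])^2, "+"),
              (co$z - m$center[3])^2, "+")
  reg <- d2 <= (m$diameter / 2)^2
  if (!any(reg)) stop("mass region contains no voxels at this grid resolution")
  bm <- as_mask_array(breast_mask, ss)
  if (any(reg & !bm)) stop("mass extends outside the breast mask")
  lab <- phantom_labels()
  if (any(truth$data[reg] >= lab[["cyst"]]))
    stop("mass overlaps an existing mass; ground truth would be ambiguous")
  # internal speckle: a smoothed random field (1.5 mm correlation length,
  # the finest structure the imaging resolution can carry) with RMS
  # amplitude equal to `heterogeneity`, multiplying both acoustic contrasts
  sp <- array(0, dim(ss$data))
  if (m$heterogeneity > 0) {
    sp <- with_seed(rng_seed, {
      f <- smooth_field3(array(stats::rnorm(length(sp)), dim(sp)),
                         1.5 / ss$spacing)
      f / max(stats::sd(f[reg]), 1e-12) * m$heterogeneity
    })
    sp <- pmin(pmax(sp, -1), 1)
  }
  ss$data[reg] <- m$ss_value * (1 + 0.02 * sp[reg])
  att$data[reg] <- pmax(m$att_value * (1 + sp[reg]), 0)
  truth$data[reg] <- lab[[m$mass_type]]
  list(ss = ss, att = att, truth = truth)
}

#' Generate a synthetic breast phantom
#'
#' Produces co-registered sound-speed and attenuation stacks with a
#' ground-truth label stack and a breast mask. The breast interior is filled
#' with fat (1425 m/s) and fibroglandular blobs (1530 m/s) obtained by
#' thresholding a Gaussian-smoothed random field at the in-mask quantile
#' matching the requested fibroglandular fraction, so the realised fraction
#' matches the request to within a voxel-quantisation error. Attenuation
#' follows tissue class (fat low, fibroglandular mid, plus a smoothed
#' within-class variation) with independent acquisition noise; voxels outside
#' the mask are water (1500 m/s, zero attenuation). Deterministic given
#' \code{spec$seed}.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list of class \code{ust_phantom} with elements \code{ss},
#'   \code{att}, \code{truth}, \code{breast_mask} (all \code{image_stack})
#'   and the originating \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_shape
  bl <- tissue_baselines()
  lab <- phantom_labels()
  mask <- breast_mask_array(spec)
  n_mask <- sum(mask)
  if (n_mask == 0L) stop("breast mask is empty on this grid")
  f <- spec$fibroglandular_fraction
  if (n_mask < 50L && f > 0 && f < 1)
    stop("grid too small to realise the requested fibroglandular fraction")

  out <- with_seed(spec$seed, {
    # fibroglandular blob field
    fg <- array(FALSE, d)
    if (f >= 1) {
      fg <- mask
    } else if (f > 0) {
      field <- smooth_field3(array(stats::rnorm(prod(d)), d),
                             spec$fg_texture_scale / spec$spacing)
      thr <- stats::quantile(field[mask], 1 - f, type = 7, names = FALSE)
      fg <- field > thr & mask
    }
    for (disc in spec$fg_discs) {
      reg <- sphere_mask(spec, disc$center, disc$diameter)
      fg <- fg | (reg & mask)
    }

    truth <- array(lab[["outside"]], d)
    truth[mask] <- lab[["fat"]]
    truth[fg] <- lab[["fibroglandular"]]

    ssd <- array(bl$water$ss, d)
    ssd[mask] <- bl$fat$ss
    ssd[fg] <- bl$fg$ss
    attd <- array(bl$water$att, d)
    attd[mask] <- bl$fat$att
    attd[fg] <- bl$fg$att

    # smoothed within-fibroglandular stiffness texture: dense tissue is not
    # uniformly hard, which is what gives the soft/intermediate/hard spread
    tex <- NULL
    if (spec$att_fg_texture > 0 && any(fg)) {
      tex <- smooth_field3(array(stats::rnorm(prod(d)), d),
                           spec$fg_texture_scale / spec$spacing)
      tex <- tex / max(stats::sd(tex[fg]), 1e-12)
      attd[fg] <- attd[fg] + spec$att_fg_texture * tex[fg]
    }

    # forced parenchymal regions may carry their own attenuation baseline
    # (e.g. a hard fibroglandular grouping that can obscure an embedded mass)
    for (disc in spec$fg_discs) {
      if (!is.null(disc$att)) {
        reg <- sphere_mask(spec, disc$center, disc$diameter) & mask
        attd[reg] <- disc$att +
          if (!is.null(tex)) spec$att_fg_texture * tex[reg] else 0
      }
    }

    # smooth large-scale hard parenchymal groupings: additive Gaussian
    # attenuation mounds with no boundary step (real dense groupings blend
    # into their surroundings); the half-maximum core is labelled
    # fibroglandular and given fibroglandular sound speed
    for (mound in spec$att_mounds) {
      co <- phantom_coords(spec)
      r2 <- outer(outer((co$x - mound$center[1])^2,
                        (co$y - mound$center[2])^2, "+"),
                  (co$z - mound$center[3])^2, "+")
      attd[mask] <- attd[mask] +
        mound$amplitude * exp(-r2[mask] / (2 * mound$sigma^2))
      core <- r2 <= (1.1774 * mound$sigma)^2 & mask
      truth[core] <- lab[["fibroglandular"]]
      ssd[core] <- bl$fg$ss
    }

    if (spec$skin_rim) {
      rim <- mask & !erode_mask_inplane(mask, 2L)
      truth[rim] <- lab[["skin"]]
      ssd[rim] <- bl$skin$ss
      attd[rim] <- bl$skin$att
    }

    ss <- image_stack(ssd, spec$spacing, "sound_speed", "m/s")
    att <- image_stack(attd, spec$spacing, "attenuation", "relative")
    tr <- image_stack(truth + 0, spec$spacing, "label", "tissue code")

    bm <- image_stack(mask + 0, spec$spacing, "mask", "binary")
    for (i in seq_along(spec$masses)) {
      upd <- insert_mass(ss, att, tr, bm, spec$masses[[i]],
                         rng_seed = spec$seed + i)
      ss <- upd$ss; att <- upd$att; tr <- upd$truth
    }

    # acquisition noise, independent between modalities, inside the mask only
    ss$data[mask] <- ss$data[mask] + stats::rnorm(n_mask, sd = spec$noise_sd_ss)
    att$data[mask] <- pmax(att$data[mask] +
                             stats::rnorm(n_mask, sd = spec$noise_sd_att), 0)
    list(ss = ss, att = att, truth = tr, breast_mask = bm)
  })

  realised <- mean(out$truth$data[mask] == lab[["fibroglandular"]])
  structure(c(out, list(spec = spec, realised_fg_fraction = realised)),
            class = "ust_phantom")
}

#' @export
print.ust_phantom <- function(x, ...) {
  d <- x$spec$grid_shape
  cat(sprintf("<ust_phantom> %d x %d x %d voxels, breast radius %.0f mm\n",
              d[1], d[2], d[3], x$spec$breast_radius))
  cat(sprintf("  fibroglandular fraction: requested %.3f, realised %.3f\n",
              x$spec$fibroglandular_fraction, x$realised_fg_fraction))
  cat(sprintf("  masses: %d; seed %d\n", length(x$spec$masses), x$spec$seed))
  invisible(x)
}
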