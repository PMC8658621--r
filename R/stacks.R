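#' Image stack container
#'
#' A minimal container for a co-registered 3-D voxel grid: a numeric array
#' plus the physical voxel spacing in mm, an in-plane origin, and a modality
#' tag. All stacks derived from one breast (sound speed, attenuation,
#' stiffness, labels, mask) share shape, spacing and origin, which is what
#' every downstream operation assumes.
#'
#' Coordinate convention: voxel centre \code{i} along an axis sits at
#' \code{origin + (i - 0.5) * spacing}. The in-plane origin defaults to
#' \code{-extent/2} so that (0, 0) is the centre of the coronal plane (the
#' breast axis); the through-plane origin is 0 at the nipple-most slice.
#'
#' @param data numeric 3-D array of voxel values (must be finite).
#' @param spacing numeric length-3, voxel size in mm (default the clinical
#'   0.75 x 0.75 x 2.5 mm coronal grid).
#' @param modality one of \code{"sound_speed"}, \code{"attenuation"},
#'   \code{"stiffness"}, \code{"reflection"}, \code{"label"}, \code{"mask"}.
#' @param units free-text unit string (e.g. \code{"m/s"}).
#' @param origin numeric length-3 origin in mm; \code{NULL} gives the
#'   centred default described above.
#' @return An object of class \code{image_stack}.
#' @export
image_stack <- function(data,
                        spacing = c(0.75, 0.75, 2.5),
                        modality = c("sound_speed", "attenuation", "stiffness",
                                     "reflection", "label", "mask"),
                        units = "",
                        origin = NULL) {
  modality <- match.arg(modality)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a 3-D array")
  if (!all(is.finite(data)))
    stop("`data` contains non-finite values")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be three strictly positive mm values")
  d <- dim(data)
  if (is.null(origin))
    origin <- c(-d[1] * spacing[1] / 2, -d[2] * spacing[2] / 2, 0)
  structure(
    list(data = data, spacing = spacing, modality = modality,
         units = units, origin = as.numeric(origin)),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_stack> %s [%s]\n", x$modality,
              if (nzchar(x$units)) x$units else "unitless"))
  cat(sprintf("  %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  range [%.4g, %.4g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' @export
dim.image_stack <- function(x) dim(x$data)

is_image_stack <- function(x) inherits(x, "image_stack")

#' Check that two stacks share geometry
#'
#' @param a,b \code{image_stack} objects.
#' @param tol spacing/origin tolerance in mm.
#' @return \code{TRUE} or \code{FALSE}.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  identical(dim(a$data), dim(b$data)) &&
    all(abs(a$spacing - b$spacing) < tol) &&
    all(abs(a$origin - b$origin) < tol)
}

stop_if_geometry_mismatch <- function(a, b) {
  if (!same_geometry(a, b))
    stop("input stacks do not share shape/spacing/origin")
  invisible(TRUE)
}

#' Voxel volume in cc
#'
#' @param spacing length-3 voxel spacing in mm.
#' @return Volume of one voxel in cubic centimetres. At the default
#'   0.75 x 0.75 x 2.5 mm grid this is 1.40625 mm^3 = 0.00140625 cc.
#' @export
voxel_volume_cc <- function(spacing) prod(spacing) / 1000

#' In-plane grid geometry of a stack
#'
#' Extracts the 2-D (coronal-plane) geometry used by the polygon
#' rasterizer: pixel grid shape, spacing and origin in mm.
#'
#' @param stack an \code{image_stack}.
#' @return list with \code{shape}, \code{spacing}, \code{origin}.
#' @export
grid_geometry <- function(stack) {
  d <- dim(stack$data)
  list(shape = d[1:2], spacing = stack$spacing[1:2], origin = stack$origin[1:2])
}

# Coerce a mask argument (image_stack or logical/numeric array) to a logical
# array matching `ref`.
as_mask_array <- function(mask, ref = NULL) {
  m <- if (is_image_stack(mask)) mask$data else mask
  if (!is.array(m) || length(dim(m)) != 3L)
    stop("mask must be a 3-D array or image_stack")
  if (!is.null(ref) && !identical(dim(m), dim(if (is_image_stack(ref)) ref$data else ref)))
    stop("mask shape does not match stack shape")
  m != 0
}

# Binary erosion of each coronal slice by a 3x3 square structuring element,
# repeated `iter` times. Used to peel the (potentially artifact-bearing)
# skin rim off the breast mask before percentile estimation.
erode_mask_inplane <- function(mask, iter = 2L) {
  m <- mask != 0
  if (iter < 1L) return(m)
  d <- dim(m)
  for (it in seq_len(iter)) {
    out <- m
    for (k in seq_len(d[3])) {
      sl <- m[, , k]
      e <- sl
      # shift in the 8 directions; erosion = AND of all shifts
      pad <- function(s, dr, dc) {
        r <- matrix(FALSE, d[1], d[2])
        rs <- max(1, 1 + dr):min(d[1], d[1] + dr)
        cs <- max(1, 1 + dc):min(d[2], d[2] + dc)
        r[rs, cs] <- s[rs - dr, cs - dc]
        r
      }
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        e <- e & pad(sl, dr, dc)
      }
      out[, , k] <- e
    }
    m <- out
  }
  m
}

# Evaluate code with a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
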