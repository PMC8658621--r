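#' High-pass spatial filter parameters
#'
#' The filter suppresses structures larger than \code{cutoff_scale} (default
#' 15 mm) to emphasise mass-scale stiffness against larger parenchymal
#' groupings. The default kernel subtracts a Gaussian blur whose FWHM equals
#' the cutoff scale; a Fourier Butterworth high-pass is available as an
#' alternative for sensitivity analysis (sharper cutoff, some ringing).
#'
#' @param cutoff_scale mm spatial scale above which structures are
#'   suppressed (> 0; default 15 mm = 1.5 cm).
#' @param kernel \code{"gaussian_subtraction"} (default) or
#'   \code{"fourier_butterworth"}.
#' @param renormalize if \code{TRUE} (default) the filtered stack is
#'   re-stretched per breast to [0, 1] with \code{\link{robust_normalize}},
#'   so downstream 3-class clustering and stiffness indices stay on the 0-1
#'   scale.
#' @param butterworth_order filter order for the Butterworth kernel.
#' @return a \code{filter_params} list.
#' @export
filter_params <- function(cutoff_scale = 15,
                          kernel = c("gaussian_subtraction", "fourier_butterworth"),
                          renormalize = TRUE,
                          butterworth_order = 2L) {
  kernel <- match.arg(kernel)
  if (cutoff_scale <= 0) stop("`cutoff_scale` must be positive")
  structure(list(cutoff_scale = cutoff_scale, kernel = kernel,
                 renormalize = renormalize,
                 butterworth_order = as.integer(butterworth_order)),
            class = "filter_params")
}

# FWHM -> sigma for a Gaussian.
fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))

#' High-pass filter one coronal slice
#'
#' Default rule: \code{F = S - G_sigma(S)} where the Gaussian blur has
#' FWHM = \code{cutoff_scale} (sigma = cutoff/2.3548 mm, converted to pixels
#' via the in-plane spacing) with edge-renormalised truncated kernels, so a
#' constant slice filters to exactly zero. The operation is linear in the
#' input.
#'
#' @param slice2d numeric matrix (one coronal slice).
#' @param spacing_xy in-plane pixel spacing in mm (length 2).
#' @param params a \code{\link{filter_params}}.
#' @param mask optional logical matrix; when given (Gaussian kernel only),
#'   the blur is a mask-normalised convolution, so tissue near the breast
#'   outline is compared against tissue only, not against the water
#'   background -- otherwise the boundary itself would dominate the filtered
#'   scale as a bright rim.
#' @return filtered matrix of the same shape (zero-mean at large scales;
#'   values may be negative).
#' @export
highpass_slice <- function(slice2d, spacing_xy, params = filter_params(),
                           mask = NULL) {
  if (!is.matrix(slice2d)) stop("`slice2d` must be a matrix")
  spacing_xy <- as.numeric(spacing_xy)
  if (length(spacing_xy) != 2L || any(spacing_xy <= 0))
    stop("`spacing_xy` must be two positive mm values")
  if (params$cutoff_scale < 2 * max(spacing_xy))
    stop("cutoff scale below 2 pixels: nothing would be preserved")
  if (params$kernel == "gaussian_subtraction") {
    sigma_px <- fwhm_to_sigma(params$cutoff_scale) / spacing_xy
    if (is.null(mask)) return(slice2d - smooth_slice(slice2d, sigma_px))
    m <- mask != 0
    if (!any(m)) return(slice2d * 0)
    w <- smooth_slice(m + 0, sigma_px)
    sm <- smooth_slice(slice2d * m, sigma_px)
    out <- slice2d * 0
    out[m] <- slice2d[m] - sm[m] / w[m]
    out
  } else {
    butterworth_highpass(slice2d, spacing_xy, params$cutoff_scale,
                         params$butterworth_order)
  }
}

# Fourier-domain Butterworth high-pass; cutoff frequency = 1/cutoff_mm.
butterworth_highpass <- function(x, spacing_xy, cutoff_mm, order) {
  d <- dim(x)
  fx <- stats::fft(x)
  f1 <- c(0:(d[1] %/% 2), -((d[1] - d[1] %/% 2 - 1):1)) / (d[1] * spacing_xy[1])
  f2 <- c(0:(d[2] %/% 2), -((d[2] - d[2] %/% 2 - 1):1)) / (d[2] * spacing_xy[2])
  fr2 <- outer(f1^2, f2^2, "+")
  fc <- 1 / cutoff_mm
  H <- 1 / (1 + (fc^2 / pmax(fr2, 1e-300))^order)
  H[1, 1] <- 0
  Re(stats::fft(fx * H, inverse = TRUE)) / prod(d)
}

#' High-pass filter a stiffness stack
#'
#' Applies \code{\link{highpass_slice}} to every coronal slice (2-D, per
#' slice: the through-plane spacing is coarse relative to the cutoff), zeroes
#' the result outside the breast mask, and, if \code{params$renormalize},
#' re-stretches the within-mask values to [0, 1] per breast so that the
#' filtered map feeds the same 3-class clustering and 0-1 stiffness indices
#' as the unfiltered one.
#'
#' @param S stiffness \code{\link{image_stack}}.
#' @param breast_mask mask stack or logical array, nonempty.
#' @param params a \code{\link{filter_params}}.
#' @return filtered stiffness \code{image_stack} (in [0, 1] when
#'   renormalised).
#' @export
apply_highpass_stack <- function(S, breast_mask, params = filter_params()) {
  stopifnot(is_image_stack(S))
  m <- as_mask_array(breast_mask, S)
  if (!any(m)) stop("breast mask is empty")
  d <- dim(S$data)
  out <- S$data
  for (k in seq_len(d[3]))
    out[, , k] <- highpass_slice(S$data[, , k], S$spacing[1:2], params,
                                 mask = if (params$kernel == "gaussian_subtraction")
                                   m[, , k])
  out[!m] <- 0
  fs <- image_stack(out, S$spacing, "stiffness", "unitless", origin = S$origin)
  if (params$renormalize) fs <- robust_normalize(fs, m) else fs
}
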