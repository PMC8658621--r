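#' Write an image stack to NIfTI with a JSON sidecar
#'
#' The voxel data and spacing go into a NIfTI-1 volume (float64, so the
#' round-trip is bitwise); modality, units and origin go into a JSON sidecar
#' next to the volume (same path with extension \code{.json}).
#'
#' @param stack an \code{\link{image_stack}}.
#' @param path output path ending in \code{.nii} or \code{.nii.gz}.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(is_image_stack(stack))
  img <- RNifti::asNifti(stack$data)
  RNifti::pixdim(img) <- stack$spacing
  RNifti::writeNifti(img, path, datatype = "double")
  side <- list(modality = stack$modality, units = stack$units,
               origin = stack$origin, spacing = stack$spacing)
  jsonlite::write_json(side, sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}

#' Read an image stack written by \code{\link{write_stack}}
#'
#' @param path path to the NIfTI volume; the JSON sidecar must sit next to it.
#' @return an \code{\link{image_stack}}.
#' @export
read_stack <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing JSON sidecar (modality/units metadata): ", sc)
  side <- jsonlite::read_json(sc, simplifyVector = TRUE)
  for (fld in c("modality", "units", "spacing", "origin"))
    if (is.null(side[[fld]]))
      stop("sidecar is missing required metadata field: ", fld)
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("NIfTI header carries no valid voxel spacing")
  if (any(abs(spacing - side$spacing) > 1e-4))
    stop("sidecar spacing disagrees with NIfTI header spacing")
  image_stack(array(as.numeric(img), dim(img)), spacing = spacing,
              modality = side$modality, units = side$units,
              origin = side$origin)
}
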