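#' Read and write volumes as NIfTI-1
#'
#' Volumes are stored with voxel spacing in the header and the world origin
#' in the sform/qform translation; values are written as float32. Reading
#' reconstructs the [grid_spec()] from the header and refuses oblique
#' (rotated) orientations, which the package's axis-aligned grids cannot
#' represent.
#'
#' @param vol a [voxel_volume()].
#' @param path file path, conventionally `.nii.gz`.
#' @param type volume type assigned on read (see [voxel_volume()]).
#' @return `write_volume()` returns `path` invisibly; `read_volume()` returns
#'   a [voxel_volume()].
#' @export
write_volume <- function(vol, path) {
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$grid$spacing_mm
  aff <- diag(c(vol$grid$spacing_mm, 1))
  aff[1:3, 4] <- vol$grid$origin_mm
  RNifti::qform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' @rdname write_volume
#' @export
read_volume <- function(path, type = "generic") {
  if (!file.exists(path))
    stop(sprintf("volume file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("malformed NIfTI file %s: %s", path,
                                 conditionMessage(e))))
  if (length(dim(img)) != 3L)
    stop(sprintf("malformed NIfTI file %s: expected 3-D image, got %d-D",
                 path, length(dim(img))))
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (max(abs(rot - diag(diag(rot)))) > 1e-4)
    stop(sprintf("malformed NIfTI file %s: oblique orientation unsupported",
                 path))
  grid <- grid_spec(dim(img), abs(diag(rot)), aff[1:3, 4])
  voxel_volume(array(as.numeric(img), dim(img)), grid, type)
}
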