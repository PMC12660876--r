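#' Read a 4-D NIfTI volume into a scans x voxels matrix
#'
#' Optional volumetric entry point (requires the `RNifti` package). Voxels
#' are selected by a logical/0-1 mask volume; columns follow the mask's
#' array order.
#'
#' @param path Path to a 4-D NIfTI-1 file.
#' @param mask 3-D array (or path to a mask volume) of the voxels to keep.
#' @return List with `Y` (scans x voxels matrix) and `mask_idx` (linear
#'   voxel indices).
#' @export
read_nifti_timeseries <- function(path, mask) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("read_nifti_timeseries: the 'RNifti' package is required",
         call. = FALSE)
  }
  img <- RNifti::readNifti(path)
  if (is.character(mask)) mask <- RNifti::readNifti(mask)
  mask_idx <- which(as.array(mask) != 0)
  d <- dim(img)
  mat <- matrix(as.numeric(img), prod(d[1:3]), d[4])
  list(Y = t(mat[mask_idx, , drop = FALSE]), mask_idx = mask_idx)
}

#' Write per-voxel scores back into a NIfTI volume
#'
#' @param values Numeric per-voxel scores.
#' @param mask_idx Linear voxel indices the scores belong to.
#' @param dim 3-D volume dimensions.
#' @param path Output path.
#' @param reference Optional NIfTI image supplying header geometry.
#' @return The path, invisibly.
#' @export
write_scores_nifti <- function(values, mask_idx, dim, path,
                               reference = NULL) {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    stop("write_scores_nifti: the 'RNifti' package is required",
         call. = FALSE)
  }
  vol <- array(0, dim)
  vol[mask_idx] <- values
  img <- if (is.null(reference)) RNifti::asNifti(vol) else
    RNifti::asNifti(vol, reference = reference)
  RNifti::writeNifti(img, path)
  invisible(path)
}
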