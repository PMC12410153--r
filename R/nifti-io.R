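#' NIfTI import/export for BOLD data and statistic maps
#'
#' Thin wrappers around RNifti for moving between the package's flat
#' voxel x time matrices and 4-D NIfTI-1 files. The voxel axis is the
#' flattening of a 3-D grid in standard (fastest-first) order; spatial
#' geometry is respected for I/O only, no analysis depends on it.
#'
#' @param bold Voxel x time matrix.
#' @param path Output `.nii` / `.nii.gz` path.
#' @param dim3d Integer 3-vector; `prod(dim3d)` must equal the voxel count.
#' @param tr Repetition time stored in the header (seconds).
#' @return `path`, invisibly.
#' @export
write_bold_nifti <- function(bold, path, dim3d, tr = 2.6) {
  .need_rnifti()
  bold <- as.matrix(bold)
  if (prod(dim3d) != nrow(bold)) {
    abort("prod(dim3d) must equal the number of voxels.",
          class = "sc_parameter_error")
  }
  arr <- array(bold, dim = c(dim3d, ncol(bold)))
  img <- RNifti::asNifti(arr, pixdim = c(1, 1, 1, tr))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @return For `read_bold_nifti()`: a voxel x time matrix with a `dim3d`
#'   attribute.
#' @export
read_bold_nifti <- function(path) {
  .need_rnifti()
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) != 4L) {
    abort("Expected a 4-D NIfTI volume.", class = "sc_schema_error")
  }
  d <- dim(arr)
  out <- matrix(arr, nrow = prod(d[1:3]), ncol = d[4])
  attr(out, "dim3d") <- d[1:3]
  out
}

#' @rdname write_bold_nifti
#' @param map Numeric or logical voxel map to write as a 3-D volume.
#' @export
write_map_nifti <- function(map, path, dim3d) {
  .need_rnifti()
  if (prod(dim3d) != length(map)) {
    abort("prod(dim3d) must equal the map length.",
          class = "sc_parameter_error")
  }
  arr <- array(as.numeric(map), dim = dim3d)
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

.need_rnifti <- function() {
  if (!requireNamespace("RNifti", quietly = TRUE)) {
    abort("NIfTI I/O requires the RNifti package.", class = "sc_dependency_error")
  }
}
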