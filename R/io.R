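#' Read a 3D volume from NIfTI
#'
#' @param path a readable `.nii` or `.nii.gz` file containing a 3D
#'   volume; 4D (or higher) inputs are rejected.
#' @return list with `image` (3D array), `spacing` (3 positive reals) and
#'   `reference` (the RNifti image carrying orientation metadata for
#'   write-back).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("malformed NIfTI file: ", path,
                                           " (", conditionMessage(e), ")"))
  d <- dim(img)
  if (length(d) != 3) {
    stop("expected a 3D volume, got ", length(d), "D: ", path)
  }
  list(image = array(as.numeric(img), dim = d),
       spacing = as.numeric(RNifti::pixdim(img)),
       reference = img)
}

#' Write an integer label volume to NIfTI
#'
#' The output is integer-typed and aligned with the reference image's
#' grid (spacing and orientation are copied from the reference).
#'
#' @param labels 3D integer label array.
#' @param reference the `reference` element from [read_volume()], or a
#'   spacing vector for phantoms without a source file.
#' @param path output path (`.nii` or `.nii.gz`).
#' @return the path, invisibly.
#' @export
write_labels <- function(labels, reference, path) {
  stopifnot(length(dim(labels)) == 3)
  storage.mode(labels) <- "integer"
  if (inherits(reference, "niftiImage")) {
    if (!all(dim(labels) == dim(reference))) {
      stop("label geometry does not match the reference image")
    }
    out <- RNifti::asNifti(labels, reference = reference, datatype = "int16")
  } else {
    stopifnot(length(reference) == 3, all(reference > 0))
    out <- RNifti::asNifti(labels,
                           reference = list(pixdim = c(-1, reference, 0, 0,
                                                       0, 0)),
                           datatype = "int16")
  }
  RNifti::writeNifti(out, path)
  invisible(path)
}

#' Write an image volume to NIfTI
#'
#' @param image 3D real array (e.g. pseudo-HU phantom image).
#' @param spacing voxel spacing (3 positive reals).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_image <- function(image, spacing, path) {
  stopifnot(length(dim(image)) == 3, all(spacing > 0))
  out <- RNifti::asNifti(image)
  RNifti::pixdim(out) <- as.numeric(spacing)
  RNifti::writeNifti(out, path)
  invisible(path)
}
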