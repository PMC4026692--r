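#' Binary segmentation mask
#'
#' Constructs the package's voxel-domain container: a 3D array of 0/1
#' foreground indicators plus the physical voxel spacing in mm. The mask is
#' the bounded domain on which volumes and Dirichlet Laplacian spectra are
#' computed.
#'
#' @param voxels 3D array; any nonzero value is treated as foreground
#'   (segmentations are often label maps, e.g. a FreeSurfer label value).
#' @param spacing numeric length-3, voxel edge lengths (dx, dy, dz) in mm,
#'   all strictly positive.
#' @param origin numeric length-3, world-space offset in mm of voxel (1,1,1).
#' @return An object of class \code{binary_mask} with elements
#'   \code{voxels} (integer 0/1 array), \code{spacing}, \code{origin}.
#' @examples
#' m <- binary_mask(array(1, dim = c(4, 4, 4)), spacing = c(1, 1, 1.4))
#' mask_volume(m)
#' @export
binary_mask <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("'voxels' must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be three strictly positive values (mm)")
  vox <- array(as.integer(voxels != 0), dim = dim(voxels))
  if (sum(vox) == 0L) stop("empty segmentation: no foreground voxels")
  structure(list(voxels = vox, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "binary_mask")
}

#' @method print binary_mask
#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("binary_mask: %s grid, %d foreground voxels, spacing %s mm\n",
              paste(dim(x$voxels), collapse = "x"), sum(x$voxels),
              paste(format(x$spacing), collapse = " x ")))
  invisible(x)
}

#' Read a binary mask from a NIfTI-1 file
#'
#' Reads a 3D NIfTI image and binarises it: every nonzero voxel becomes
#' foreground. Voxel spacing is taken from the header pixdim.
#'
#' @param path path to a .nii or .nii.gz file containing a 3D image.
#' @return A \code{\link{binary_mask}}.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("mask file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- img[, , , 1]
    d <- dim(img)
  }
  if (length(d) != 3L)
    stop("expected a 3D image, got ", length(d), "D: ", path)
  sp <- RNifti::pixdim(img)[1:3]
  binary_mask(array(as.integer(img != 0), dim = d), spacing = sp)
}

#' Write a binary mask to NIfTI-1
#'
#' @param mask a \code{\link{binary_mask}}.
#' @param path output path (.nii or .nii.gz).
#' @return \code{path}, invisibly.
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "binary_mask"))
  img <- RNifti::asNifti(array(as.integer(mask$voxels),
                               dim = dim(mask$voxels)))
  RNifti::pixdim(img) <- mask$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' World-space coordinates of foreground voxel centres
#'
#' @param mask a \code{\link{binary_mask}}.
#' @return n x 3 matrix of mm coordinates (index * spacing + origin).
#' @keywords internal
mask_coordinates <- function(mask) {
  w <- which(mask$voxels != 0L, arr.ind = TRUE)
  sweep(sweep(w, 2L, mask$spacing, "*"), 2L, mask$origin, "+")
}
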