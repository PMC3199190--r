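#' fMRI dataset container
#'
#' Bundles a 4-D BOLD array stored as `(x, y, z, t)` (x fastest) with a 3-D
#' brain mask, the repetition time and the voxel size. This is the object
#' every stage of the pipeline transforms.
#'
#' @param data 4-D numeric array indexed `(x, y, z, t)`.
#' @param mask 3-D logical array with the same spatial shape as `data`, or
#'   `NULL` for an all-true mask.
#' @param tr Repetition time in seconds (> 0).
#' @param voxel_size Numeric length-3 vector `(dx, dy, dz)` in mm.
#' @param affine Optional 4x4 NIfTI affine, preserved on write but never
#'   interpreted (no resampling).
#'
#' @return An object of class `fmri_dataset` with fields `data`, `mask`,
#'   `tr`, `voxel_size` and `affine`.
#' @export
fmri_dataset <- function(data, mask = NULL, tr = 2, voxel_size = c(3.75, 3.75, 3.75),
                         affine = NULL) {
  if (length(dim(data)) != 4L) {
    stopf("`data` must be a 4-D (x,y,z,t) array, got %d dimension(s)",
          length(dim(data)))
  }
  sdim <- dim(data)[1:3]
  if (is.null(mask)) {
    mask <- array(TRUE, dim = sdim)
  }
  if (!identical(as.integer(dim(mask)), as.integer(sdim))) {
    stopf("mask shape (%s) does not match volume shape (%s)",
          paste(dim(mask), collapse = "x"), paste(sdim, collapse = "x"))
  }
  mask <- array(as.logical(mask), dim = sdim)
  if (!any(mask)) stopf("mask contains no voxels")
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stopf("`tr` must be a positive scalar (seconds)")
  }
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stopf("`voxel_size` must be three positive numbers (mm)")
  }
  vm <- as_voxel_matrix(data)[as.vector(mask), , drop = FALSE]
  if (any(!is.finite(vm))) stopf("non-finite values inside the mask")
  structure(
    list(data = data, mask = mask, tr = tr, voxel_size = voxel_size,
         affine = affine),
    class = "fmri_dataset"
  )
}

#' @export
print.fmri_dataset <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<fmri_dataset> %dx%dx%d voxels, %d volumes, TR %.3g s\n",
              d[1], d[2], d[3], d[4], x$tr))
  cat(sprintf("  voxel size %.3g x %.3g x %.3g mm; %d of %d voxels in mask\n",
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              sum(x$mask), prod(d[1:3])))
  invisible(x)
}

#' @export
dim.fmri_dataset <- function(x) dim(x$data)

#' Read a 4-D NIfTI volume (and optional mask) into an [fmri_dataset()]
#'
#' @param path_volume Path to a 4-D NIfTI-1 file (`.nii` / `.nii.gz`).
#' @param path_mask Optional path to a 3-D mask volume with the same spatial
#'   shape; nonzero voxels are taken as in-brain. `NULL` gives an all-true
#'   mask.
#' @return An [fmri_dataset()]. TR and voxel sizes are taken from the NIfTI
#'   header (`pixdim`); the affine is preserved but not interpreted.
#' @export
read_fmri <- function(path_volume, path_mask = NULL) {
  img <- RNifti::readNifti(path_volume)
  if (length(dim(img)) != 4L) {
    stopf("'%s' is %d-D; a 4-D volume is required", path_volume, length(dim(img)))
  }
  pd <- attr(RNifti::niftiHeader(img), "pixdim") %||% RNifti::pixdim(img)
  vox <- RNifti::pixdim(img)[1:3]
  tr <- RNifti::pixdim(img)[4]
  if (!is.finite(tr) || tr <= 0) tr <- 1
  mask <- NULL
  if (!is.null(path_mask)) {
    m <- RNifti::readNifti(path_mask)
    if (length(dim(m)) != 3L) stopf("mask '%s' must be 3-D", path_mask)
    if (!identical(as.integer(dim(m)), as.integer(dim(img)[1:3]))) {
      stopf("mask shape (%s) does not match volume shape (%s)",
            paste(dim(m), collapse = "x"), paste(dim(img)[1:3], collapse = "x"))
    }
    mask <- array(as.array(m) != 0, dim = dim(m))
  }
  fmri_dataset(as.array(img), mask = mask, tr = tr, voxel_size = vox,
               affine = RNifti::xform(img))
}

#' Write an [fmri_dataset()] (or a plain array) as NIfTI-1
#'
#' @param x An `fmri_dataset`, or a 3-D/4-D numeric array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param tr,voxel_size Header geometry used when `x` is a plain array.
#' @return `path`, invisibly.
#' @export
write_fmri <- function(x, path, tr = 2, voxel_size = c(3.75, 3.75, 3.75)) {
  if (inherits(x, "fmri_dataset")) {
    arr <- x$data
    tr <- x$tr
    voxel_size <- x$voxel_size
  } else {
    arr <- x
  }
  nd <- length(dim(arr))
  pixdim <- c(voxel_size, if (nd == 4L) tr)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- pixdim
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Brain segmentation by intensity thresholding
#'
#' A voxel is inside the brain iff its mean intensity is at least
#' `threshold_fraction` times the maximum mean intensity, the simple
#' thresholding segmentation the permutation pipeline restricts its analysis
#' to.
#'
#' @param mean_volume 3-D array of temporal-mean intensities (or a 4-D array,
#'   which is averaged over time first).
#' @param threshold_fraction Fraction of the maximum intensity in (0, 1);
#'   default 0.2.
#' @return 3-D logical array.
#' @export
make_mask <- function(mean_volume, threshold_fraction = 0.2) {
  if (length(dim(mean_volume)) == 4L) {
    mean_volume <- apply_time_mean(mean_volume)
  }
  if (length(dim(mean_volume)) != 3L) stopf("`mean_volume` must be 3-D")
  if (any(!is.finite(mean_volume))) stopf("`mean_volume` has non-finite values")
  if (!(threshold_fraction > 0 && threshold_fraction < 1)) {
    stopf("`threshold_fraction` must lie strictly between 0 and 1")
  }
  mx <- max(mean_volume)
  if (mx <= 0) stopf("volume is non-positive everywhere; mask would be empty")
  mask <- array(mean_volume >= threshold_fraction * mx, dim = dim(mean_volume))
  if (!any(mask)) stopf("thresholding produced an empty mask")
  mask
}

# Mean over the 4th dimension without apply() overhead.
apply_time_mean <- function(data4d) {
  d <- dim(data4d)
  array(rowMeans(as_voxel_matrix(data4d)), dim = d[1:3])
}
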