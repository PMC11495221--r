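#' Grey-matter volume container
#'
#' A `gm_volume` holds a 3D array of grey-matter probabilities in `[0, 1]`
#' plus the voxel spacing in millimetres per axis. It is the input to both
#' network extraction and total grey-matter volume computation.
#'
#' @param values 3D numeric array of grey-matter probabilities.
#' @param spacing Numeric length-3 vector, mm per axis (default 2 mm
#'   isotropic, the reslicing used for network extraction).
#' @return An object of class `gm_volume`.
#' @export
gm_volume <- function(values, spacing = c(2, 2, 2)) {
  values <- drop(values)
  if (length(dim(values)) != 3) stop("volume must be 3D")
  values <- array(as.numeric(values), dim(values))  # strip foreign attributes
  if (!all(is.finite(values))) stop("volume values must all be finite")
  if (!all(spacing > 0) || length(spacing) != 3) stop("spacing must be 3 positive values")
  if (any(values < 0) || any(values > 1)) {
    warning("grey-matter probabilities outside [0, 1]; clipping")
    values <- pmin(pmax(values, 0), 1)
  }
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "gm_volume")
}

#' @export
print.gm_volume <- function(x, ...) {
  cat("gm_volume:", paste(dim(x$values), collapse = " x "), "voxels,",
      paste(x$spacing, collapse = " x "), "mm\n")
  invisible(x)
}

#' Read a grey-matter segmentation volume from NIfTI
#'
#' Reads a scalar NIfTI volume, squeezes singleton trailing dimensions, takes
#' the voxel spacing from the header, and clips values to `[0, 1]` (with a
#' warning) since the pipeline expects tissue probabilities.
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [gm_volume].
#' @export
read_gm_volume <- function(path) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  arr <- drop(as.array(img))
  if (length(dim(arr)) != 3) stop("volume must be 3D (got ",
                                  length(dim(arr)), " non-singleton dimensions)")
  sp <- RNifti::pixdim(img)[seq_len(3)]
  if (any(!is.finite(sp)) || any(sp <= 0)) stop("volume header has no valid voxel spacing")
  gm_volume(arr, spacing = sp)
}

#' Write a grey-matter volume to NIfTI
#'
#' @param vol A [gm_volume].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_gm_volume <- function(vol, path) {
  stopifnot(inherits(vol, "gm_volume"))
  img <- RNifti::asNifti(vol$values)
  RNifti::pixdim(img) <- vol$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Total grey-matter volume in millilitres
#'
#' Sum of grey-matter probabilities times the voxel volume. Serves as the
#' global atrophy covariate in the small-world trajectory model.
#'
#' @param vol A [gm_volume].
#' @return Total grey-matter volume in ml.
#' @export
total_gm_volume <- function(vol) {
  stopifnot(inherits(vol, "gm_volume"))
  voxel_mm3 <- prod(vol$spacing)
  sum(vol$values) * voxel_mm3 / 1000
}
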