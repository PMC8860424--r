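#' CT volume container
#'
#' A 3D grid of CT intensities in Hounsfield units (HU) with physical
#' voxel spacing.  Arrays are stored in R's column-major layout with
#' axis order (column, row, slice): the first array dimension is the
#' in-plane left-right ("horizontal") axis used for GLCM adjacency.
#'
#' @param voxels 3D numeric array of HU values.
#' @param spacing numeric length-3, per-axis voxel size in mm (all > 0).
#' @param origin numeric length-3, physical coordinates of voxel (1,1,1).
#' @return object of class `ct_volume`.
#' @export
ct_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  voxels <- as.array(voxels)
  if (length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array")
  if (any(dim(voxels) < 1L))
    stop("voxel grid needs at least 1 voxel per axis")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive finite numbers")
  structure(list(voxels = voxels, spacing = spacing,
                 origin = as.numeric(origin)),
            class = "ct_volume")
}

#' Lesion mask container
#'
#' A binary 3D grid congruent with its reference [ct_volume()],
#' demarcating one segmented lesion.  Must contain at least one true
#' voxel.
#'
#' @param flags 3D logical (or 0/1 numeric) array.
#' @param lesion_id label string.
#' @return object of class `lesion_mask`.
#' @export
lesion_mask <- function(flags, lesion_id = "lesion") {
  flags <- as.array(flags)
  if (length(dim(flags)) != 3L)
    stop("mask must be a 3D array")
  flags <- array(flags != 0, dim = dim(flags))
  if (!any(flags))
    stop("empty mask: a lesion must contain at least one voxel")
  structure(list(flags = flags, lesion_id = lesion_id),
            class = "lesion_mask")
}

#' @export
print.ct_volume <- function(x, ...) {
  cat("CT volume:", paste(dim(x$voxels), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "),
      "mm\n  HU range:", paste(signif(range(x$voxels), 5), collapse = " .. "),
      "\n")
  invisible(x)
}

#' @export
print.lesion_mask <- function(x, ...) {
  cat("Lesion mask '", x$lesion_id, "': ",
      paste(dim(x$flags), collapse = " x "), " grid, ",
      sum(x$flags), " lesion voxels\n", sep = "")
  invisible(x)
}

#' Read a CT volume from NIfTI or a DICOM series directory
#'
#' NIfTI files (`.nii`, `.nii.gz`) are read through RNifti.  A directory
#' is interpreted as one DICOM series: slices are sorted by the
#' projection of ImagePositionPatient on the slice normal, the rescale
#' slope/intercept is applied to recover HU, and mixed series or
#' non-uniform slice spacing (beyond `spacing_tol`, a fraction of the
#' median inter-slice gap) are rejected.
#'
#' @param path NIfTI file or DICOM series directory.
#' @param spacing_tol allowed relative deviation of any inter-slice gap
#'   from the median gap (default 0.1).
#' @return a [ct_volume()].
#' @export
read_volume <- function(path, spacing_tol = 0.1) {
  if (!file.exists(path))
    stop("path does not exist: ", path)
  if (dir.exists(path))
    return(read_dicom_series(path, spacing_tol = spacing_tol))
  img <- RNifti::readNifti(path)
  vox <- array(as.numeric(img), dim = dim(img))
  sp <- abs(RNifti::pixdim(img))[seq_len(3)]
  org <- tryCatch(as.numeric(RNifti::voxelToWorld(c(1, 1, 1), img)),
                  error = function(e) c(0, 0, 0))
  ct_volume(vox, spacing = sp, origin = org)
}

#' Read a lesion mask aligned to a reference volume
#'
#' @param path NIfTI mask file; nonzero voxels are lesion.
#' @param reference the paired [ct_volume()]; grid shapes must match.
#' @param lesion_id label for the mask.
#' @return a [lesion_mask()].
#' @export
read_mask <- function(path, reference, lesion_id = basename(path)) {
  if (!file.exists(path))
    stop("path does not exist: ", path)
  img <- RNifti::readNifti(path)
  flags <- array(as.numeric(img) != 0, dim = dim(img))
  if (!identical(dim(flags), dim(reference$voxels)))
    stop("mask shape (", paste(dim(flags), collapse = "x"),
         ") does not match reference volume shape (",
         paste(dim(reference$voxels), collapse = "x"), ")")
  lesion_mask(flags, lesion_id = lesion_id)
}

#' Write a volume or mask as NIfTI (fixture writer)
#'
#' @param x a [ct_volume()] or [lesion_mask()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_nifti_volume <- function(x, path) {
  arr <- if (inherits(x, "ct_volume")) x$voxels else x$flags * 1
  img <- RNifti::asNifti(arr)
  sp <- if (inherits(x, "ct_volume")) x$spacing else c(1, 1, 1)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Crop the volume of interest around a lesion
#'
#' Returns the tight bounding box of lesion voxels dilated by `margin`
#' voxels per axis (clipped at grid boundaries).  Voxel values and mask
#' flags inside the box are unchanged; GLCM/histogram features only use
#' in-mask voxels, so the margin does not affect feature values.
#'
#' @param volume a [ct_volume()].
#' @param mask the aligned [lesion_mask()].
#' @param margin non-negative integer dilation in voxels (default 2).
#' @return list with cropped `volume` and `mask`.
#' @export
extract_voi <- function(volume, mask, margin = 2) {
  if (!identical(dim(volume$voxels), dim(mask$flags)))
    stop("volume and mask shapes differ")
  if (margin < 0) stop("margin must be >= 0")
  dm <- dim(mask$flags)
  idx <- which(mask$flags, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2, min) - margin, 1L)
  hi <- pmin(apply(idx, 2, max) + margin, dm)
  vox <- volume$voxels[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  flg <- mask$flags[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  list(volume = ct_volume(vox, spacing = volume$spacing,
                          origin = volume$origin + (lo - 1) * volume$spacing),
       mask = lesion_mask(flg, lesion_id = mask$lesion_id))
}
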