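#' Construct a CT volume
#'
#' A `ct_volume` holds a 3-D grid of attenuation values in Hounsfield units
#' (HU) together with its physical voxel spacing. The axis convention is fixed
#' throughout the package: the array is indexed `[x, y, z]` and z is
#' cranio-caudal, ascending toward the head. The T5-T11 slab logic depends on
#' this convention, so readers reorient into it rather than carrying
#' orientation metadata downstream.
#'
#' @param data 3-D numeric array of HU values; all values must be finite.
#' @param spacing Numeric length-3, voxel edge lengths `(dx, dy, dz)` in mm;
#'   all strictly positive.
#' @param origin Numeric length-3 physical offset in mm (carried through I/O,
#'   not used by the pipeline).
#'
#' @return An object of class `ct_volume`: a list with elements `data`,
#'   `spacing`, `origin`.
#' @export
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 4)), spacing = c(1, 1, 3))
#' voxel_volume_mm3(vol)
ct_volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    abort("`data` must be a 3-D array of HU values.")
  }
  if (length(data) == 0L) abort("`data` must be non-empty.")
  if (!all(is.finite(data))) abort("All voxel values must be finite HU.")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || !all(is.finite(spacing)) || any(spacing <= 0)) {
    abort("`spacing` must be three strictly positive lengths in mm.")
  }
  structure(
    list(data = data, spacing = spacing, origin = as.numeric(origin)),
    class = "ct_volume"
  )
}

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<ct_volume> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm, HU range [%.0f, %.0f]\n",
    d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3],
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' Physical volume of one voxel in mm^3
#' @param volume A `ct_volume`, `compartment_map`, or `tissue_label_map`.
#' @return Scalar voxel volume in mm^3.
#' @export
voxel_volume_mm3 <- function(volume) prod(volume$spacing)

#' Read a CT volume from a NIfTI file
#'
#' Reads a single-channel 3-D NIfTI-1 image and returns it as a [ct_volume()]
#' with spacing taken from the header `pixdim`. Values are returned as stored
#' (assumed HU).
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @return A [ct_volume()].
#' @export
read_ct_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("File does not exist: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img <- array(as.array(img), d[1:3])
    d <- d[1:3]
  }
  if (length(d) != 3L) {
    abort(sprintf(
      "Expected a 3-D scalar image, got %d dimensions in %s", length(d), path
    ))
  }
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0)) {
    abort(sprintf("Non-positive voxel spacing in NIfTI header of %s", path))
  }
  xf <- try(RNifti::xform(img), silent = TRUE)
  origin <- if (inherits(xf, "try-error")) c(0, 0, 0) else as.numeric(xf[1:3, 4])
  vals <- as.array(img)
  attributes(vals) <- list(dim = d)
  ct_volume(vals, spacing = sp, origin = origin)
}

#' Write a CT volume or labelmap to NIfTI
#'
#' @param volume A [ct_volume()] or a bare 3-D array (in which case `spacing`
#'   must be given).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm, only for bare arrays.
#' @param datatype NIfTI on-disk datatype; `"uint8"` for masks/labelmaps,
#'   `"float"` or `"double"` for HU volumes.
#' @return `path`, invisibly.
#' @export
write_ct_volume <- function(volume, path, spacing = NULL, datatype = "double") {
  if (inherits(volume, "ct_volume")) {
    arr <- volume$data
    spacing <- volume$spacing
  } else {
    arr <- volume
    if (is.null(spacing)) abort("`spacing` required when writing a bare array.")
  }
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

mask_slot_names <- function() {
  c("lungs", "heart", paste0("vertebra_T", 1:12), "eat", "body")
}

#' Construct an organ mask set
#'
#' Named binary masks aligned to one CT grid. Recognized names are `lungs`,
#' `heart`, `vertebra_T1` ... `vertebra_T12`, `eat` (epicardial adipose
#' tissue), and `body`; additional mediastinal masks are carried through and
#' may be included in the hull union. Masks are binarized (any nonzero value
#' becomes `TRUE`) and vertebra masks must be pairwise disjoint.
#'
#' @param masks Named list of 3-D arrays (logical or numeric) on a common grid.
#' @param spacing Voxel spacing in mm.
#' @return An object of class `organ_mask_set`.
#' @export
organ_mask_set <- function(masks, spacing = c(1, 1, 1)) {
  if (length(masks) == 0L || is.null(names(masks)) || any(names(masks) == "")) {
    abort("`masks` must be a non-empty named list.")
  }
  ref_dim <- dim(masks[[1]])
  out <- lapply(names(masks), function(nm) {
    m <- masks[[nm]]
    if (!is.array(m) || length(dim(m)) != 3L) {
      abort(sprintf("Mask '%s' is not a 3-D array.", nm))
    }
    if (!identical(dim(m), ref_dim)) {
      abort(sprintf("Mask '%s' has shape %s, expected %s.", nm,
                    paste(dim(m), collapse = "x"),
                    paste(ref_dim, collapse = "x")))
    }
    b <- m != 0
    attributes(b) <- list(dim = dim(m))
    b
  })
  names(out) <- names(masks)
  vert <- grep("^vertebra_T", names(out), value = TRUE)
  if (length(vert) > 1L) {
    tot <- Reduce(`+`, lapply(out[vert], function(m) as.integer(m)))
    if (any(tot > 1L)) abort("Vertebra masks overlap; they must be pairwise disjoint.")
  }
  structure(list(masks = out, spacing = as.numeric(spacing)), class = "organ_mask_set")
}

#' @export
print.organ_mask_set <- function(x, ...) {
  cat("<organ_mask_set>", length(x$masks), "masks:",
      paste(names(x$masks), collapse = ", "), "\n")
  invisible(x)
}

#' Read a set of organ masks from NIfTI files
#'
#' Each file must hold an integer or binary image on the same grid as
#' `reference`; values are binarized (nonzero -> 1). A shape mismatch fails
#' with the name of the offending mask.
#'
#' @param paths Named character vector or list mapping mask name to file path.
#' @param reference A [ct_volume()] defining the expected grid.
#' @return An [organ_mask_set()].
#' @export
read_mask_set <- function(paths, reference) {
  stopifnot(inherits(reference, "ct_volume"))
  paths <- unlist(paths)
  if (is.null(names(paths)) || any(names(paths) == "")) {
    abort("`paths` must be named by mask.")
  }
  ref_dim <- dim(reference$data)
  masks <- lapply(names(paths), function(nm) {
    p <- paths[[nm]]
    if (!file.exists(p)) abort(sprintf("Mask file for '%s' does not exist: %s", nm, p))
    img <- RNifti::readNifti(p)
    d <- dim(img)
    if (length(d) == 4L && d[4] == 1L) d <- d[1:3]
    if (!identical(as.integer(d), as.integer(ref_dim))) {
      abort(sprintf(
        "Mask '%s' has shape %s but the reference volume is %s.",
        nm, paste(d, collapse = "x"), paste(ref_dim, collapse = "x")
      ))
    }
    arr <- as.array(img)
    attributes(arr) <- list(dim = as.integer(ref_dim))
    arr
  })
  names(masks) <- names(paths)
  organ_mask_set(masks, spacing = reference$spacing)
}

#' Write an organ mask set to NIfTI files
#'
#' @param masks An [organ_mask_set()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_mask_set <- function(masks, dir) {
  stopifnot(inherits(masks, "organ_mask_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(masks$masks), function(nm) {
    p <- file.path(dir, paste0(nm, ".nii.gz"))
    write_ct_volume(array(as.integer(masks$masks[[nm]]), dim(masks$masks[[nm]])),
                    p, spacing = masks$spacing, datatype = "uint8")
    p
  }, character(1))
  invisible(paths)
}
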