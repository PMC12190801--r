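#' Extract the body mask from a CT volume
#'
#' Thresholds the volume at `threshold` HU, keeps the largest 3-D connected
#' component (26-connectivity), and fills internal holes (lungs, bowel gas)
#' slice by slice, so the returned mask is the solid body outline.
#'
#' The default threshold of -500 HU sits midway between lung parenchyma and
#' soft tissue, separating the body from surrounding air.
#'
#' @param volume A [ct_volume()].
#' @param threshold Air/body HU threshold (default -500).
#' @return A logical 3-D array.
#' @export
extract_body_mask <- function(volume, threshold = -500) {
  stopifnot(inherits(volume, "ct_volume"))
  fg <- volume$data >= threshold
  if (!any(fg)) abort("Empty field of view: no voxel above the body threshold.")
  dims <- dim(volume$data)
  labels <- .cc_label_3d(fg, dims, 26L)
  tab <- tabulate(labels[labels > 0L])
  keep <- which.max(tab)
  body <- labels == keep
  body <- .fill_holes_slicewise(body, dims)
  body
}

# rasterize the filled convex hull of the TRUE voxels of a 2-D slice;
# voxel centres exactly on the hull boundary are included (integer-exact
# cross products, so no tolerance is needed)
hull_fill_slice <- function(slice) {
  out <- matrix(FALSE, nrow(slice), ncol(slice))
  if (!any(slice)) return(out)
  pts <- which(slice, arr.ind = TRUE)
  n <- nrow(pts)
  if (n == 1L) { out[pts] <- TRUE; return(out) }
  xs <- pts[, 1]; ys <- pts[, 2]
  bb_x <- min(xs):max(xs); bb_y <- min(ys):max(ys)
  cand <- as.matrix(expand.grid(x = bb_x, y = bb_y))
  h <- chull(xs, ys)                       # vertices, clockwise
  v <- pts[h, , drop = FALSE]
  nv <- nrow(v)
  if (nv <= 2L) {
    # degenerate: all points collinear; keep integer points on the segment
    a <- v[1, ]; b <- v[nv, ]
    d <- b - a
    cr <- (cand[, 1] - a[1]) * d[2] - (cand[, 2] - a[2]) * d[1]
    dt <- (cand[, 1] - a[1]) * d[1] + (cand[, 2] - a[2]) * d[2]
    keep <- cr == 0 & dt >= 0 & dt <= sum(d^2)
    out[cand[keep, , drop = FALSE]] <- TRUE
    return(out)
  }
  nxt <- c(seq_len(nv)[-1], 1L)
  area2 <- sum(v[, 1] * v[nxt, 2] - v[nxt, 1] * v[, 2])  # sign gives orientation
  inside <- rep(TRUE, nrow(cand))
  for (i in seq_len(nv)) {
    a <- v[i, ]; b <- v[nxt[i], ]
    cr <- (b[1] - a[1]) * (cand[, 2] - a[2]) - (b[2] - a[2]) * (cand[, 1] - a[1])
    inside <- inside & (if (area2 > 0) cr >= 0 else cr <= 0)
  }
  out[cand[inside, , drop = FALSE]] <- TRUE
  out
}

#' Slice-wise convex hull over the intrathoracic organs
#'
#' For every axial slice, computes the filled 2-D convex hull of the union of
#' the intrathoracic organ masks. The hull encloses every organ voxel and is
#' convex per slice; slices with no organ voxels get an empty hull. The hull
#' is computed in 2-D (per slice) rather than 3-D for robustness to
#' cranio-caudal truncation.
#'
#' @param masks An [organ_mask_set()].
#' @param organs Mask names forming the hull union; of the defaults, any that
#'   are present are used (lungs and heart are required).
#' @return A logical 3-D array.
#' @export
intrathoracic_hull <- function(masks, organs = c("lungs", "heart", "eat")) {
  stopifnot(inherits(masks, "organ_mask_set"))
  required <- c("lungs", "heart")
  missing <- setdiff(required, names(masks$masks))
  if (length(missing)) {
    abort(sprintf("Required organ mask(s) missing: %s", paste(missing, collapse = ", ")))
  }
  use <- intersect(organs, names(masks$masks))
  union <- Reduce(`|`, masks$masks[use])
  if (!any(union)) abort("The intrathoracic organ union is empty on every slice.")
  dims <- dim(union)
  hull <- array(FALSE, dims)
  nz_slices <- which(apply(union, 3, any))
  for (z in nz_slices) hull[, , z] <- hull_fill_slice(union[, , z])
  hull
}

#' T5-T11 vertebral slab
#'
#' Returns the inclusive z-index range spanned by the T5 through T11 vertebra
#' masks: the full cranio-caudal extent from the most caudal T11 voxel to the
#' most cranial T5 voxel (head toward high z). Scans whose masks do not cover
#' the entire T5-T11 range are rejected, mirroring the study exclusion rule.
#'
#' @param masks An [organ_mask_set()] with non-empty `vertebra_T5` ...
#'   `vertebra_T11`.
#' @return Integer length-2 vector `c(zmin, zmax)`.
#' @export
vertebral_slab <- function(masks) {
  stopifnot(inherits(masks, "organ_mask_set"))
  levels <- paste0("vertebra_T", 5:11)
  zr <- integer(0)
  for (lv in levels) {
    m <- masks$masks[[lv]]
    if (is.null(m) || !any(m)) {
      abort(sprintf(
        "Scan does not capture the entire range between T5 and T11 vertebrae: '%s' is missing or empty.",
        lv
      ))
    }
    zs <- which(apply(m, 3, any))
    zr <- range(c(zr, zs))
  }
  as.integer(zr)
}

#' Build the compartment map
#'
#' Within the T5-T11 slab, splits the body into an intrathoracic compartment
#' (body voxels inside the organ hull, excluding bone-density voxels) and an
#' extrathoracic compartment (all remaining body voxels, bone always
#' extrathoracic). Outside the slab everything is labelled outside-body.
#'
#' @param body Logical body mask (see [extract_body_mask()]).
#' @param hull Logical hull mask (see [intrathoracic_hull()]).
#' @param bone_mask Logical mask of bone-density voxels (HU in the bone
#'   interval), see [classify_hu()].
#' @param slab Integer `c(zmin, zmax)` from [vertebral_slab()].
#' @param spacing Voxel spacing in mm, carried through.
#' @return A `compartment_map`: list with integer array `labels`
#'   (0 outside, 1 intrathoracic, 2 extrathoracic), `slab`, `spacing`.
#' @export
build_compartments <- function(body, hull, bone_mask, slab, spacing = c(1, 1, 1)) {
  dims <- dim(body)
  if (!identical(dims, dim(hull)) || !identical(dims, dim(bone_mask))) {
    abort("body, hull and bone_mask must share one grid.")
  }
  slab <- as.integer(slab)
  if (slab[1] < 1L || slab[2] > dims[3] || slab[1] > slab[2]) {
    abort("Slab z-range lies outside the grid.")
  }
  labels <- array(0L, dims)
  zs <- slab[1]:slab[2]
  intra <- body & hull & !bone_mask
  extra <- body & !intra
  lab_slab <- array(0L, c(dims[1], dims[2], length(zs)))
  lab_slab[intra[, , zs]] <- 1L
  lab_slab[extra[, , zs]] <- 2L
  labels[, , zs] <- lab_slab
  structure(list(labels = labels, slab = slab, spacing = as.numeric(spacing)),
            class = "compartment_map")
}

#' @export
print.compartment_map <- function(x, ...) {
  cat(sprintf(
    "<compartment_map> slab z [%d, %d]; intrathoracic %d, extrathoracic %d voxels\n",
    x$slab[1], x$slab[2], sum(x$labels == 1L), sum(x$labels == 2L)
  ))
  invisible(x)
}
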