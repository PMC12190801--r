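#' Hounsfield-unit classification intervals
#'
#' Closed intervals assigning a density class to each voxel: adipose tissue
#' -190 to -30 HU, muscle -29 to +150 HU, bone +151 to +1200 HU. The
#' intervals are pairwise disjoint and contiguous on the integer HU scale;
#' values outside all three (air, lung parenchyma, contrast) stay unassigned.
#'
#' @param adipose,muscle,bone Length-2 numeric `c(min, max)` closed intervals.
#' @return An object of class `hu_ranges`.
#' @export
#' @examples
#' classify_hu(c(-100, -30, -29, 150, 151, -1000), hu_ranges())
hu_ranges <- function(adipose = c(-190, -30), muscle = c(-29, 150),
                      bone = c(151, 1200)) {
  for (iv in list(adipose, muscle, bone)) {
    if (length(iv) != 2L || iv[1] > iv[2]) abort("Each interval must be c(min, max).")
  }
  if (adipose[2] >= muscle[1] || muscle[2] >= bone[1]) {
    abort("Intervals must be disjoint and ordered adipose < muscle < bone.")
  }
  structure(list(adipose = adipose, muscle = muscle, bone = bone),
            class = "hu_ranges")
}

#' Classify HU values into density classes
#'
#' Vectorized closed-interval membership: returns `"adipose"`, `"muscle"`,
#' `"bone"`, or `"unassigned"` for each finite HU value.
#'
#' @param values Numeric HU values.
#' @param ranges A [hu_ranges()].
#' @return Character vector of density classes.
#' @export
classify_hu <- function(values, ranges = hu_ranges()) {
  stopifnot(inherits(ranges, "hu_ranges"))
  out <- rep("unassigned", length(values))
  out[values >= ranges$adipose[1] & values <= ranges$adipose[2]] <- "adipose"
  out[values >= ranges$muscle[1] & values <= ranges$muscle[2]] <- "muscle"
  out[values >= ranges$bone[1] & values <= ranges$bone[2]] <- "bone"
  out
}

# 2-D (slice-wise) surface shell: body voxels with a 4-neighbour outside the
# body in-plane, i.e. the outermost one-voxel skin layer
body_surface_shell <- function(body) {
  dims <- dim(body)
  pad <- function(arr, dx, dy) {
    out <- array(FALSE, dims)
    xs <- seq_len(dims[1]); ys <- seq_len(dims[2])
    sx <- xs + dx; sy <- ys + dy
    okx <- sx >= 1 & sx <= dims[1]; oky <- sy >= 1 & sy <= dims[2]
    out[xs[okx], ys[oky], ] <- arr[sx[okx], sy[oky], ]
    out
  }
  interior <- body & pad(body, 1, 0) & pad(body, -1, 0) &
    pad(body, 0, 1) & pad(body, 0, -1)
  body & !interior
}

#' Split extrathoracic adipose tissue into SAT and IMAT
#'
#' Connected components (26-connectivity, 3-D) of the extrathoracic
#' adipose-density mask that touch the body-surface shell (the outermost
#' one-voxel layer of the body mask, taken slice-wise) are subcutaneous
#' adipose tissue; all other components are intermuscular adipose tissue.
#' The two outputs partition the input.
#'
#' @param adipose_mask Logical mask of extrathoracic adipose-density voxels.
#' @param body_mask Logical body mask on the same grid.
#' @return List with logical masks `sat` and `imat`.
#' @export
split_sat_imat <- function(adipose_mask, body_mask) {
  if (!identical(dim(adipose_mask), dim(body_mask))) {
    abort("adipose_mask and body_mask must share one grid.")
  }
  sat <- array(FALSE, dim(adipose_mask))
  imat <- sat
  if (!any(adipose_mask)) return(list(sat = sat, imat = imat))
  labels <- .cc_label_3d(adipose_mask, dim(adipose_mask), 26L)
  shell <- body_surface_shell(body_mask)
  touching <- unique(labels[shell & labels > 0L])
  is_sat <- labels > 0L & array(labels %in% touching, dim(labels))
  sat[is_sat] <- TRUE
  imat[labels > 0L & !is_sat] <- TRUE
  list(sat = sat, imat = imat)
}

#' Assign tissue labels from HU values and compartments
#'
#' Applies the attribution rules within the T5-T11 slab: intrathoracic
#' adipose-density voxels are epicardial adipose tissue (EAT) if covered by
#' the EAT mask and visceral adipose tissue (VAT) otherwise; bone-density
#' voxels are bone in any compartment; extrathoracic muscle-density voxels
#' are skeletal muscle (SM); extrathoracic adipose-density voxels are split
#' into subcutaneous (SAT, skin contact) and intermuscular (IMAT) depots;
#' everything else (including intrathoracic muscle density, e.g. the
#' myocardium) stays unassigned.
#'
#' @param volume A [ct_volume()].
#' @param compartments A `compartment_map` from [build_compartments()].
#' @param eat_mask Logical EAT mask (may be all-`FALSE`).
#' @param ranges A [hu_ranges()].
#' @param eat_density_gated If `TRUE` (default) the EAT label is restricted to
#'   adipose-density voxels of the EAT mask, so EAT mean density is computed
#'   over fat-density voxels like the other adipose depots; if `FALSE` every
#'   intrathoracic EAT-mask voxel is labelled EAT regardless of density.
#' @return A `tissue_label_map`: list with integer array `labels` (codes per
#'   [tissue_codes()]), `slab`, `spacing`.
#' @export
assign_tissues <- function(volume, compartments, eat_mask = NULL,
                           ranges = hu_ranges(), eat_density_gated = TRUE) {
  stopifnot(inherits(volume, "ct_volume"), inherits(compartments, "compartment_map"))
  dims <- dim(volume$data)
  if (!identical(dims, dim(compartments$labels))) {
    abort("Volume and compartment map are misaligned.")
  }
  if (is.null(eat_mask)) eat_mask <- array(FALSE, dims)
  if (!identical(dims, dim(eat_mask))) abort("EAT mask is misaligned with the volume.")

  codes <- tissue_codes()
  hu <- volume$data
  comp <- compartments$labels
  adipose <- hu >= ranges$adipose[1] & hu <= ranges$adipose[2]
  muscle <- hu >= ranges$muscle[1] & hu <= ranges$muscle[2]
  bone <- hu >= ranges$bone[1] & hu <= ranges$bone[2]
  intra <- comp == 1L
  extra <- comp == 2L
  body <- intra | extra

  labels <- array(codes[["unassigned"]], dims)
  labels[body & bone] <- codes[["bone"]]
  labels[extra & muscle] <- codes[["SM"]]
  if (eat_density_gated) {
    labels[intra & adipose & eat_mask] <- codes[["EAT"]]
    labels[intra & adipose & !eat_mask] <- codes[["VAT"]]
  } else {
    labels[intra & adipose & !eat_mask] <- codes[["VAT"]]
    labels[intra & (eat_mask & body)] <- codes[["EAT"]]
  }
  ext_fat <- extra & adipose
  if (any(ext_fat)) {
    split <- split_sat_imat(ext_fat, body)
    labels[split$sat] <- codes[["SAT"]]
    labels[split$imat] <- codes[["IMAT"]]
  }
  structure(list(labels = labels, slab = compartments$slab,
                 spacing = compartments$spacing),
            class = "tissue_label_map")
}

#' @export
print.tissue_label_map <- function(x, ...) {
  codes <- tissue_codes()
  counts <- vapply(codes, function(cd) sum(x$labels == cd), numeric(1))
  cat("<tissue_label_map> voxel counts:\n")
  print(counts)
  invisible(x)
}

#' Run the full segmentation stage on one volume
#'
#' Convenience wrapper chaining [extract_body_mask()], [intrathoracic_hull()],
#' [vertebral_slab()], [build_compartments()], and [assign_tissues()].
#'
#' @param volume A [ct_volume()].
#' @param masks An [organ_mask_set()] with lungs, heart, T5-T11 vertebrae, and
#'   optionally `eat`.
#' @param ranges A [hu_ranges()].
#' @param body_threshold Air/body HU threshold.
#' @param hull_organs Mask names forming the hull union.
#' @param eat_density_gated See [assign_tissues()].
#' @return List with `labels` (`tissue_label_map`), `compartments`, `body`,
#'   `hull`, `slab`.
#' @export
segment_volume <- function(volume, masks, ranges = hu_ranges(),
                           body_threshold = -500,
                           hull_organs = c("lungs", "heart", "eat"),
                           eat_density_gated = TRUE) {
  body <- extract_body_mask(volume, threshold = body_threshold)
  hull <- intrathoracic_hull(masks, organs = hull_organs)
  slab <- vertebral_slab(masks)
  bone_mask <- volume$data >= ranges$bone[1] & volume$data <= ranges$bone[2]
  comp <- build_compartments(body, hull, bone_mask, slab, spacing = volume$spacing)
  eat <- masks$masks[["eat"]]
  labels <- assign_tissues(volume, comp, eat_mask = eat, ranges = ranges,
                           eat_density_gated = eat_density_gated)
  list(labels = labels, compartments = comp, body = body, hull = hull, slab = slab)
}
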