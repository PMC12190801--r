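#' Tissue label codes used in labelmaps
#'
#' Fixed integer code table for [tissue_label_map] arrays and phantom ground
#' truth: 0 unassigned, 1 SM, 2 bone, 3 SAT, 4 IMAT, 5 VAT, 6 EAT.
#' @return Named integer vector.
#' @export
tissue_codes <- function() {
  c(unassigned = 0L, SM = 1L, bone = 2L, SAT = 3L, IMAT = 4L, VAT = 5L, EAT = 6L)
}

# internal extra codes used only during phantom construction
.PH_LUNG <- 8L
.PH_HEART <- 9L
.PH_CAVITY <- 10L

ellipse2d <- function(nx, ny, cx, cy, rx, ry) {
  dx2 <- ((seq_len(nx) - cx) / rx)^2
  dy2 <- ((seq_len(ny) - cy) / ry)^2
  outer(dx2, dy2, `+`) <= 1
}

ellipsoid3 <- function(dims, centre, radii) {
  dx2 <- ((seq_len(dims[1]) - centre[1]) / radii[1])^2
  dy2 <- ((seq_len(dims[2]) - centre[2]) / radii[2])^2
  dz2 <- ((seq_len(dims[3]) - centre[3]) / radii[3])^2
  arr <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
  arr
}

rep_slices <- function(mask2d, dims, zmin = 1L, zmax = dims[3]) {
  arr <- array(FALSE, dims)
  arr[, , zmin:zmax] <- mask2d
  arr
}

box_mask <- function(dims, xr, yr, zr) {
  arr <- array(FALSE, dims)
  arr[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- TRUE
  arr
}

#' Specification of a thoracic CT phantom
#'
#' Defines a slice-wise elliptical body with a subcutaneous fat rim and a
#' muscle wall enclosing a convex thoracic cavity; inside the cavity sit two
#' lung ellipsoids, a heart ellipsoid with an epicardial fat shell, visceral
#' fat pockets placed between the lungs, and a 12-level vertebral column;
#' intermuscular fat pockets and rib blocks sit in the muscle wall. Every
#' tissue voxel is known exactly by construction, so the phantom serves as the
#' ground-truth oracle for the segmentation and quantification stages.
#'
#' The default tissue means (fat -100, muscle +40, bone +400, lung -800,
#' mediastinal filler -250, heart +35, air -1000 HU) are each safely interior
#' to (or deliberately outside) the classification intervals; the filler value
#' falls in the unclassified gap between air and adipose so cavity voxels
#' outside any organ stay unassigned. Means are validated against `hu_ranges`.
#'
#' @param dims Grid shape, default `c(160, 160, 120)`.
#' @param spacing Voxel spacing in mm, default `c(1.5, 1.5, 2.5)`.
#' @param body_radii Body ellipse semi-axes (voxels) in x and y.
#' @param sat_thickness,muscle_thickness Shell thicknesses (voxels) of the
#'   subcutaneous fat rim and muscle wall.
#' @param lung_offset_x Lateral offset of each lung centre from the midline.
#' @param lung_radii,heart_radii,eat_outer_radii Ellipsoid semi-axes (voxels).
#' @param lung_centre_z,heart_centre,vat_pockets,imat_pockets,rib_boxes
#'   Placement of structures; pockets/boxes are lists of
#'   `list(x = c(lo, hi), y = ..., z = ...)` index ranges.
#' @param vertebra_x,vertebra_y Index ranges of the vertebral column.
#' @param vertebra_top_z,vertebra_height,vertebra_gap Cranio-caudal layout of
#'   the 12 vertebral blocks (T1 most cranial, head toward high z).
#' @param hu_means Named list of per-tissue mean HU.
#' @param noise_sd Gaussian HU noise SD applied after construction (>= 0).
#' @param seed Default random seed used by [generate_phantom()].
#' @param ranges Classification intervals ([hu_ranges()]) used to validate `hu_means`.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(dims = c(160L, 160L, 120L),
                         spacing = c(1.5, 1.5, 2.5),
                         body_radii = c(72, 52),
                         sat_thickness = 6,
                         muscle_thickness = 8,
                         lung_offset_x = 32.5,
                         lung_radii = c(16, 26, 40),
                         lung_centre_z = 65,
                         heart_centre = c(0, -10.5, 55),
                         heart_radii = c(12, 13, 16),
                         eat_outer_radii = c(15, 16, 19),
                         vat_pockets = list(
                           list(x = c(74, 87), y = c(88, 98), z = c(45, 60)),
                           list(x = c(74, 87), y = c(70, 86), z = c(78, 88))
                         ),
                         imat_pockets = list(
                           list(x = c(70, 90), y = c(37, 40), z = c(30, 50)),
                           list(x = c(70, 90), y = c(121, 124), z = c(60, 80))
                         ),
                         rib_boxes = list(
                           list(x = c(16, 21), y = c(77, 84), z = c(30, 34)),
                           list(x = c(16, 21), y = c(77, 84), z = c(60, 64)),
                           list(x = c(140, 145), y = c(77, 84), z = c(30, 34)),
                           list(x = c(140, 145), y = c(77, 84), z = c(60, 64))
                         ),
                         vertebra_x = c(74, 87),
                         vertebra_y = c(104, 116),
                         vertebra_top_z = 119,
                         vertebra_height = 7,
                         vertebra_gap = 2,
                         hu_means = list(fat = -100, muscle = 40, bone = 400,
                                         lung = -800, cavity = -250,
                                         heart = 35, air = -1000),
                         noise_sd = 0,
                         seed = 20260101L,
                         ranges = hu_ranges()) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 8L)) abort("`dims` must be three sizes >= 8.")
  if (noise_sd < 0) abort("`noise_sd` must be >= 0.")
  inner <- body_radii - sat_thickness - muscle_thickness
  if (sat_thickness <= 0 || muscle_thickness <= 0 || any(inner <= 4)) {
    abort("Impossible anatomy: fat rim plus muscle wall leaves no thoracic cavity.")
  }
  rng <- ranges
  chk <- function(value, lo, hi, what) {
    if (value < lo || value > hi) {
      abort(sprintf("hu_means$%s = %g lies outside its intended interval [%g, %g].",
                    what, value, lo, hi))
    }
  }
  chk(hu_means$fat, rng$adipose[1], rng$adipose[2], "fat")
  chk(hu_means$muscle, rng$muscle[1], rng$muscle[2], "muscle")
  chk(hu_means$bone, rng$bone[1], rng$bone[2], "bone")
  chk(hu_means$heart, rng$muscle[1], rng$muscle[2], "heart")
  # lung / cavity / air must fall in no interval at all (stay unassigned)
  for (w in c("lung", "cavity", "air")) {
    v <- hu_means[[w]]
    if (classify_hu(v, rng) != "unassigned") {
      abort(sprintf("hu_means$%s = %g must lie outside every classification interval.", w, v))
    }
  }
  n_lev <- 12L
  z_hi <- vertebra_top_z - (seq_len(n_lev) - 1L) * (vertebra_height + vertebra_gap)
  z_lo <- z_hi - vertebra_height + 1L
  if (any(z_lo < 1L) || any(z_hi > dims[3])) {
    abort("Vertebral column does not fit the grid cranio-caudally.")
  }
  structure(
    list(dims = dims, spacing = as.numeric(spacing), body_radii = body_radii,
         sat_thickness = sat_thickness, muscle_thickness = muscle_thickness,
         lung_offset_x = lung_offset_x, lung_radii = lung_radii,
         lung_centre_z = lung_centre_z, heart_centre = heart_centre,
         heart_radii = heart_radii, eat_outer_radii = eat_outer_radii,
         vat_pockets = vat_pockets, imat_pockets = imat_pockets,
         rib_boxes = rib_boxes, vertebra_x = vertebra_x,
         vertebra_y = vertebra_y, vertebra_z = cbind(lo = z_lo, hi = z_hi),
         hu_means = hu_means, noise_sd = noise_sd, seed = seed,
         hu_ranges = rng),
    class = "phantom_spec"
  )
}

#' Boundary-stress phantom specifications
#'
#' Variants of the default phantom with tissue means placed exactly at the
#' closed-interval boundaries of the HU classification ranges, to pin
#' interval-edge behaviour: `"fat_muscle"` sets fat to -30 and muscle (and
#' heart) to -29 HU; `"muscle_bone"` sets muscle to +150 and bone to +151 HU.
#' Noise is zero so classification must be exact.
#'
#' @param case Which boundary to stress.
#' @param ... Passed on to [phantom_spec()].
#' @return A `phantom_spec`.
#' @export
boundary_phantom_spec <- function(case = c("fat_muscle", "muscle_bone"), ...) {
  case <- match.arg(case)
  hu <- list(fat = -100, muscle = 40, bone = 400, lung = -800,
             cavity = -250, heart = 35, air = -1000)
  if (case == "fat_muscle") {
    hu$fat <- -30; hu$muscle <- -29; hu$heart <- -29
  } else {
    hu$muscle <- 150; hu$heart <- 150; hu$bone <- 151
  }
  phantom_spec(hu_means = hu, noise_sd = 0, ...)
}

# Jarvis-march (gift-wrapping) convex hull of integer points, plus half-plane
# fill. Independent of the chull()-based path used by the segmentation stage;
# serves as the generator's own oracle for the thoracic-cavity ground truth.
gift_wrap_fill <- function(pts, nx, ny) {
  out <- matrix(FALSE, nx, ny)
  n <- nrow(pts)
  if (n == 0L) return(out)
  if (n == 1L) { out[pts[1, 1], pts[1, 2]] <- TRUE; return(out) }
  cross <- function(o, a, b) (a[1] - o[1]) * (b[2] - o[2]) - (a[2] - o[2]) * (b[1] - o[1])
  # collinearity check
  base <- pts[1, ]
  rel <- sweep(pts, 2, base)
  collin <- all(rel[, 1] * rel[2, 2] - rel[, 2] * rel[2, 1] == 0) && n >= 2
  xs <- pts[, 1]; ys <- pts[, 2]
  bb_x <- min(xs):max(xs); bb_y <- min(ys):max(ys)
  cand <- as.matrix(expand.grid(x = bb_x, y = bb_y))
  if (collin) {
    d <- rel[which.max(rowSums(rel^2)), ]
    if (all(d == 0)) { out[base[1], base[2]] <- TRUE; return(out) }
    cr <- (cand[, 1] - base[1]) * d[2] - (cand[, 2] - base[2]) * d[1]
    dt <- (cand[, 1] - base[1]) * d[1] + (cand[, 2] - base[2]) * d[2]
    keep <- cr == 0 & dt >= 0 & dt <= sum(d^2)
    out[cand[keep, , drop = FALSE]] <- TRUE
    return(out)
  }
  # gift wrap counterclockwise from the lowest point
  start <- which(ys == min(ys))
  start <- start[which.min(xs[start])]
  hull <- integer(0)
  p <- start
  repeat {
    hull <- c(hull, p)
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p || r == q) next
      cr <- cross(pts[p, ], pts[q, ], pts[r, ])
      if (cr < 0) q <- r
      else if (cr == 0) {
        # collinear: take the farther point
        if (sum((pts[r, ] - pts[p, ])^2) > sum((pts[q, ] - pts[p, ])^2)) q <- r
      }
    }
    p <- q
    if (p == start) break
    if (length(hull) > n) abort("gift wrapping failed to terminate")
  }
  v <- pts[hull, , drop = FALSE]
  nv <- nrow(v)
  inside <- rep(TRUE, nrow(cand))
  for (i in seq_len(nv)) {
    a <- v[i, ]; b <- v[if (i == nv) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (cand[, 2] - a[2]) - (b[2] - a[2]) * (cand[, 1] - a[1])
    inside <- inside & cr <= 0  # clockwise orientation from min-y start
  }
  # orientation may be CCW depending on traversal; accept either by testing both
  if (!any(inside)) {
    inside <- rep(TRUE, nrow(cand))
    for (i in seq_len(nv)) {
      a <- v[i, ]; b <- v[if (i == nv) 1L else i + 1L, ]
      cr <- (b[1] - a[1]) * (cand[, 2] - a[2]) - (b[2] - a[2]) * (cand[, 1] - a[1])
      inside <- inside & cr >= 0
    }
  }
  out[cand[inside, , drop = FALSE]] <- TRUE
  out
}

#' Generate a thoracic CT phantom with exact ground truth
#'
#' Builds the HU volume, the organ mask set (lungs, heart, EAT, vertebrae
#' T1-T12, body), and a ground-truth composition table with per-tissue voxel
#' counts, volumes and mean HU within the T5-T11 slab. With `noise_sd = 0`
#' every voxel of a tissue equals its mean HU, so the full pipeline must
#' recover the ground truth exactly. The same seed yields bit-identical
#' output.
#'
#' @param spec A [phantom_spec()].
#' @param seed Random seed (only used when `spec$noise_sd > 0`).
#' @return A list with elements `volume` ([ct_volume()]), `masks`
#'   ([organ_mask_set()]), and `truth` (a tibble, one row per tissue, with
#'   attributes `body_voxels`, `cavity_voxels`, `lung_voxels`, `slab`,
#'   `voxel_volume_mm3`).
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$dims
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  rx <- spec$body_radii[1]; ry <- spec$body_radii[2]
  mid_r <- c(rx, ry) - spec$sat_thickness
  inner_r <- mid_r - spec$muscle_thickness

  body2 <- ellipse2d(nx, ny, cx, cy, rx, ry)
  mid2 <- ellipse2d(nx, ny, cx, cy, mid_r[1], mid_r[2])
  inner2 <- ellipse2d(nx, ny, cx, cy, inner_r[1], inner_r[2])

  codes <- tissue_codes()
  lab <- array(0L, dims)
  lab[rep_slices(body2 & !mid2, dims)] <- codes[["SAT"]]
  lab[rep_slices(mid2 & !inner2, dims)] <- codes[["SM"]]
  lab[rep_slices(inner2, dims)] <- .PH_CAVITY

  for (p in spec$imat_pockets) {
    bx <- box_mask(dims, p$x, p$y, p$z)
    if (!all(lab[bx] == codes[["SM"]])) {
      abort("Impossible anatomy: an IMAT pocket is not fully inside the muscle wall.")
    }
    lab[bx] <- codes[["IMAT"]]
  }
  for (p in spec$rib_boxes) lab[box_mask(dims, p$x, p$y, p$z)] <- codes[["bone"]]

  vert_masks <- vector("list", 12L)
  names(vert_masks) <- paste0("vertebra_T", 1:12)
  for (i in 1:12) {
    bx <- box_mask(dims, spec$vertebra_x, spec$vertebra_y,
                   c(spec$vertebra_z[i, "lo"], spec$vertebra_z[i, "hi"]))
    vert_masks[[i]] <- bx
    lab[bx] <- codes[["bone"]]
  }

  lung1 <- ellipsoid3(dims, c(cx - spec$lung_offset_x, cy, spec$lung_centre_z), spec$lung_radii)
  lung2 <- ellipsoid3(dims, c(cx + spec$lung_offset_x, cy, spec$lung_centre_z), spec$lung_radii)
  lungs <- lung1 | lung2
  if (!all(lab[lungs] == .PH_CAVITY)) {
    abort("Impossible anatomy: lungs are not fully inside the thoracic cavity.")
  }
  lab[lungs] <- .PH_LUNG

  hc <- c(cx + spec$heart_centre[1], cy + spec$heart_centre[2], spec$heart_centre[3])
  heart <- ellipsoid3(dims, hc, spec$heart_radii)
  if (!all(lab[heart] == .PH_CAVITY)) {
    abort("Impossible anatomy: the heart is not fully inside the thoracic cavity.")
  }
  lab[heart] <- .PH_HEART
  eat_shell <- ellipsoid3(dims, hc, spec$eat_outer_radii) & !heart & lab == .PH_CAVITY
  lab[eat_shell] <- codes[["EAT"]]

  for (p in spec$vat_pockets) {
    bx <- box_mask(dims, p$x, p$y, p$z) & lab == .PH_CAVITY
    lab[bx] <- codes[["VAT"]]
  }

  hu_of_code <- numeric(11)
  hu_of_code[1 + codes[["SM"]]] <- spec$hu_means$muscle
  hu_of_code[1 + codes[["bone"]]] <- spec$hu_means$bone
  hu_of_code[1 + c(codes[["SAT"]], codes[["IMAT"]], codes[["VAT"]], codes[["EAT"]])] <- spec$hu_means$fat
  hu_of_code[1 + .PH_LUNG] <- spec$hu_means$lung
  hu_of_code[1 + .PH_HEART] <- spec$hu_means$heart
  hu_of_code[1 + .PH_CAVITY] <- spec$hu_means$cavity
  hu_of_code[1] <- spec$hu_means$air
  hu <- array(hu_of_code[lab + 1L], dims)

  volume <- ct_volume(hu, spacing = spec$spacing)
  if (spec$noise_sd > 0) volume <- degrade_phantom(volume, spec$noise_sd, seed = seed)

  masks <- organ_mask_set(
    c(list(lungs = lungs, heart = heart, eat = eat_shell,
           body = rep_slices(body2, dims)), vert_masks),
    spacing = spec$spacing
  )

  # ground truth within the T5-T11 slab (full z-extent of those levels)
  slab <- c(spec$vertebra_z[11, "lo"], spec$vertebra_z[5, "hi"])
  slab_idx <- slab[1]:slab[2]
  lab_slab <- lab[, , slab_idx]
  vv <- prod(spec$spacing)
  tissue_names <- c("SM", "bone", "SAT", "IMAT", "VAT", "EAT")
  mean_of <- c(SM = spec$hu_means$muscle, bone = spec$hu_means$bone,
               SAT = spec$hu_means$fat, IMAT = spec$hu_means$fat,
               VAT = spec$hu_means$fat, EAT = spec$hu_means$fat)
  counts <- vapply(tissue_names, function(tn) sum(lab_slab == codes[[tn]]), integer(1))
  truth <- tibble(
    tissue = tissue_names,
    voxels = unname(as.integer(counts)),
    volume_cm3 = unname(counts * vv / 1000),
    mean_hu = unname(ifelse(counts > 0, mean_of[tissue_names], NA_real_))
  )

  # thoracic-cavity ground truth: body & gift-wrapped hull of lungs+heart+EAT,
  # minus bone voxels, slice by slice within the slab
  organ <- lungs | heart | eat_shell
  cavity_count <- 0L
  for (z in slab_idx) {
    sl <- organ[, , z]
    if (!any(sl)) next
    pts <- which(sl, arr.ind = TRUE)
    fill <- gift_wrap_fill(pts, nx, ny)
    cavity_count <- cavity_count +
      sum(fill & body2 & lab[, , z] != codes[["bone"]])
  }

  attr(truth, "body_voxels") <- sum(rep_slices(body2, dims)[, , slab_idx])
  attr(truth, "cavity_voxels") <- as.integer(cavity_count)
  attr(truth, "lung_voxels") <- sum(lab_slab == .PH_LUNG)
  attr(truth, "slab") <- as.integer(slab)
  attr(truth, "voxel_volume_mm3") <- vv
  attr(truth, "hu_means") <- spec$hu_means

  list(volume = volume, masks = masks, truth = truth)
}

#' Add Gaussian HU noise to a volume
#'
#' Additive zero-mean Gaussian noise, voxelwise. `noise_sd = 0` returns the
#' input unchanged; a fixed seed reproduces the same degraded volume.
#'
#' @param volume A [ct_volume()].
#' @param noise_sd Noise standard deviation in HU (>= 0).
#' @param seed Optional integer seed.
#' @return A [ct_volume()].
#' @export
degrade_phantom <- function(volume, noise_sd, seed = NULL) {
  stopifnot(inherits(volume, "ct_volume"))
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    abort("`noise_sd` must be a single non-negative number.")
  }
  if (noise_sd == 0) return(volume)
  if (!is.null(seed)) set.seed(seed)
  noisy <- volume$data + array(rnorm(length(volume$data), 0, noise_sd), dim(volume$data))
  ct_volume(noisy, spacing = volume$spacing, origin = volume$origin)
}
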