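test_that("body extraction recovers the phantom body mask exactly", {
  ph <- small_phantom()
  body <- extract_body_mask(ph$volume)
  expect_identical(body, ph$masks$masks$body)
})

test_that("body extraction fails on an all-air volume and fills lung holes", {
  air <- ct_volume(array(-1000, c(8, 8, 8)))
  expect_error(extract_body_mask(air), "Empty field of view")
  # lungs (-800) are interior holes and get filled
  ph <- small_phantom()
  body <- extract_body_mask(ph$volume)
  expect_true(all(body[ph$masks$masks$lungs]))
})

test_that("slice hulls are convex, minimal, and match simple shapes", {
  dims <- c(20L, 20L, 3L)
  rect <- array(FALSE, dims)
  rect[5:12, 6:15, 2] <- TRUE
  ms <- organ_mask_set(list(lungs = rect, heart = array(FALSE, dims)))
  hull <- intrathoracic_hull(ms)
  # a convex input is its own hull; other slices stay empty
  expect_identical(hull[, , 2], rect[, , 2])
  expect_false(any(hull[, , c(1, 3)]))

  # two disjoint squares: the hull bridges them, matching the angular oracle
  two <- array(FALSE, dims)
  two[2:5, 3:6, 1] <- TRUE
  two[12:15, 10:13, 1] <- TRUE
  ms2 <- organ_mask_set(list(lungs = two, heart = array(FALSE, dims)))
  hull2 <- intrathoracic_hull(ms2)
  expect_identical(hull2[, , 1], hull_fill_oracle(two[, , 1]))
  expect_gt(sum(hull2[, , 1]), sum(two[, , 1]))
})

test_that("hull equals the brute-force membership oracle on random slices", {
  set.seed(401)
  for (rep in 1:25) {
    dims <- c(24L, 24L, 1L)
    sl <- array(FALSE, dims)
    n_pts <- sample(1:30, 1)
    idx <- cbind(sample(dims[1], n_pts, TRUE), sample(dims[2], n_pts, TRUE), 1L)
    sl[idx] <- TRUE
    ms <- organ_mask_set(list(lungs = sl, heart = array(FALSE, dims)))
    hull <- intrathoracic_hull(ms)
    expect_identical(hull[, , 1], hull_fill_oracle(sl[, , 1]),
                     info = paste("random slice", rep))
  }
})

test_that("hull is idempotent and monotone in its organ masks", {
  ph <- small_phantom()
  hull <- intrathoracic_hull(ph$masks)
  ms_hull <- organ_mask_set(list(lungs = hull, heart = array(FALSE, dim(hull))))
  expect_identical(intrathoracic_hull(ms_hull), hull)

  # enlarging an organ mask never shrinks the hull
  grown <- ph$masks$masks
  g <- grown$heart
  g[30:50, 30:50, 25:29] <- TRUE
  grown$heart <- g
  hull2 <- intrathoracic_hull(organ_mask_set(grown))
  expect_true(all(hull2[hull]))
})

test_that("vertebral slab spans the full T5-T11 extent and enforces coverage", {
  ph <- small_phantom()
  sp <- small_phantom_spec()
  slab <- vertebral_slab(ph$masks)
  expect_equal(slab, c(sp$vertebra_z[11, "lo"], sp$vertebra_z[5, "hi"]),
               ignore_attr = TRUE)
  expect_identical(slab, attr(ph$truth, "slab"))
  # slab length equals the per-vertebra extents plus inter-vertebral gaps
  expect_identical(diff(slab) + 1L, 7L * 3L + 6L * 2L)

  # an emptied T8 mirrors the study exclusion
  broken <- ph$masks$masks
  broken$vertebra_T8[] <- FALSE
  expect_error(vertebral_slab(organ_mask_set(broken)),
               "entire range between T5 and T11")

  # direct construction: T5 at z 60-69, T11 at z 10-19 (head at high z)
  dims <- c(8L, 8L, 80L)
  zr <- list(60:69, 53:55, 48:50, 41:43, 35:37, 28:30, 10:19)
  masks <- lapply(zr, function(zz) {
    m <- array(FALSE, dims)
    m[3:6, 3:6, zz] <- TRUE
    m
  })
  names(masks) <- paste0("vertebra_T", 5:11)
  expect_equal(vertebral_slab(organ_mask_set(masks)), c(10L, 69L))
})

test_that("compartments partition the body and keep bone extrathoracic", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  comp <- seg$compartments
  zs <- comp$slab[1]:comp$slab[2]

  # compartment counts match the generator's independent hull oracle
  expect_identical(sum(comp$labels == 1L), as.integer(attr(ph$truth, "cavity_voxels")))
  expect_identical(
    sum(comp$labels == 1L) + sum(comp$labels == 2L),
    as.integer(attr(ph$truth, "body_voxels"))
  )

  # within the slab every body voxel has exactly one compartment label
  body_slab <- ph$masks$masks$body[, , zs]
  lab_slab <- comp$labels[, , zs]
  expect_true(all(lab_slab[body_slab] %in% c(1L, 2L)))
  expect_true(all(lab_slab[!body_slab] == 0L))
  # nothing labelled outside the slab
  expect_true(all(comp$labels[, , -zs] == 0L))

  # bone-density voxels inside the hull are extrathoracic
  bone_vox <- ph$volume$data >= 151 & seg$hull
  expect_true(any(bone_vox[, , zs]))  # the vertebral column pierces the hull
  expect_true(all(comp$labels[bone_vox & comp$labels > 0L] == 2L))
})

test_that("a hull covering the whole body leaves only bone extrathoracic", {
  ph <- small_phantom()
  body <- extract_body_mask(ph$volume)
  hull_all <- array(TRUE, dim(body))
  bone <- ph$volume$data >= 151 & ph$volume$data <= 1200
  slab <- vertebral_slab(ph$masks)
  comp <- build_compartments(body, hull_all, bone, slab, ph$volume$spacing)
  zs <- slab[1]:slab[2]
  extra <- comp$labels == 2L
  expect_true(all(bone[, , zs][extra[, , zs]]))
  expect_error(build_compartments(body, hull_all, bone, c(1, 1000)), "outside the grid")
})
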