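test_that("HU density classes follow the printed closed intervals", {
  r <- hu_ranges()
  expect_equal(classify_hu(-100, r), "adipose")
  expect_equal(classify_hu(c(-190, -30), r), c("adipose", "adipose"))
  expect_equal(classify_hu(c(-29, 150), r), c("muscle", "muscle"))
  expect_equal(classify_hu(c(151, 1200), r), c("bone", "bone"))
  expect_equal(classify_hu(c(-1000, -191, 1201, 0.5), r),
               c("unassigned", "unassigned", "unassigned", "muscle"))
  expect_error(hu_ranges(adipose = c(-190, 0)), "disjoint")
})

test_that("intrathoracic fat is EAT inside the EAT mask and VAT otherwise", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  codes <- tissue_codes()
  eat_mask <- ph$masks$masks$eat
  expect_true(all(seg$labels$labels[eat_mask] == codes[["EAT"]]))

  # with the EAT mask withheld, those voxels become VAT
  no_eat <- ph$masks$masks
  no_eat$eat[] <- FALSE
  seg2 <- segment_volume(ph$volume, organ_mask_set(no_eat, ph$masks$spacing))
  expect_true(all(seg2$labels$labels[eat_mask] == codes[["VAT"]]))
})

test_that("muscle-density voxels inside the hull stay unassigned", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  heart <- ph$masks$masks$heart
  zs <- seg$slab[1]:seg$slab[2]
  in_slab <- array(FALSE, dim(heart)); in_slab[, , zs] <- TRUE
  expect_true(all(seg$labels$labels[heart & in_slab] == 0L))
})

test_that("SAT/IMAT split follows skin contact at component level", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  comp <- seg$compartments
  ext_fat <- comp$labels == 2L & seg$labels$labels %in%
    tissue_codes()[c("SAT", "IMAT")]
  body <- comp$labels > 0L

  split <- split_sat_imat(ext_fat, body)
  expect_true(all(xor(split$sat[ext_fat], split$imat[ext_fat])))
  expect_identical(split$sat | split$imat, ext_fat, ignore_attr = TRUE)

  # phantom truth: the rim is SAT, the pockets are IMAT
  expect_identical(sum(seg$labels$labels == tissue_codes()[["SAT"]]),
                   as.integer(ph$truth$voxels[ph$truth$tissue == "SAT"]))
  expect_identical(sum(seg$labels$labels == tissue_codes()[["IMAT"]]),
                   as.integer(ph$truth$voxels[ph$truth$tissue == "IMAT"]))

  # empty input -> both outputs empty
  empty <- array(FALSE, dim(body))
  s0 <- split_sat_imat(empty, body)
  expect_false(any(s0$sat) || any(s0$imat))

  # one component spanning from the surface deep inward is entirely SAT
  dims <- c(12L, 12L, 4L)
  bodyc <- array(TRUE, dims)
  fat <- array(FALSE, dims)
  fat[1:9, 6, 2] <- TRUE   # touches the x = 1 surface
  s1 <- split_sat_imat(fat, bodyc)
  expect_identical(s1$sat, fat, ignore_attr = TRUE)
  expect_false(any(s1$imat))
})

test_that("every slab body voxel gets exactly one label and counts conserve", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  zs <- seg$slab[1]:seg$slab[2]
  body_slab <- ph$masks$masks$body[, , zs]
  lab_slab <- seg$labels$labels[, , zs]
  # labels only inside the body
  expect_true(all(lab_slab[!body_slab] == 0L))
  counts <- table(factor(lab_slab[body_slab], levels = 0:6))
  expect_identical(sum(counts), sum(body_slab))
  # no labels outside the slab
  expect_true(all(seg$labels$labels[, , -zs] == 0L))
})

test_that("zero-noise phantom recovery is exact for all six tissues", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  m <- summarize_composition(seg$labels, ph$volume, seg$compartments,
                             lungs = ph$masks$masks$lungs)
  expect_identical(m$voxels, ph$truth$voxels)
  expect_equal(m$volume_cm3, ph$truth$volume_cm3)
  expect_equal(m$mean_density_hu, ph$truth$mean_hu)
})

test_that("volumes stay within 3% under 15 HU Gaussian noise", {
  ph <- small_phantom()
  noisy <- degrade_phantom(ph$volume, 15, seed = 99)
  seg <- segment_volume(noisy, ph$masks)
  m <- summarize_composition(seg$labels, noisy, seg$compartments,
                             lungs = ph$masks$masks$lungs)
  rel_err <- abs(m$volume_cm3 - ph$truth$volume_cm3) / ph$truth$volume_cm3
  expect_true(all(rel_err <= 0.03), info = paste(round(rel_err, 4), collapse = " "))
})

test_that("misaligned grids are rejected", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  small <- ct_volume(array(0, c(4, 4, 4)))
  expect_error(assign_tissues(small, seg$compartments), "misaligned")
})
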