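test_that("DuBois BSA matches direct evaluation and its limit behaviour", {
  expect_equal(compute_bsa(180, 80), 0.007184 * 80^0.425 * 180^0.725)
  expect_equal(compute_bsa(180, 80), 1.996, tolerance = 1e-3)
  expect_equal(compute_bsa(160, 60), 1.622, tolerance = 1e-3)
  expect_lt(compute_bsa(180, 1e-6), 1e-2)
  expect_error(compute_bsa(-170, 70), "positive")
})

test_that("indexed volumes and fractions follow the defining arithmetic", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  subj <- subject("s", "male", bsa = 2.0)
  m <- summarize_composition(seg$labels, ph$volume, seg$compartments,
                             subj = subj, lungs = ph$masks$masks$lungs)
  expect_equal(m$volume_index_cm3_m2, m$volume_cm3 / 2.0)
  # indexed volume times BSA recovers the volume
  expect_equal(m$volume_index_cm3_m2 * 2.0, m$volume_cm3)
  tt <- attr(m, "total_thoracic_volume_cm3")
  expect_equal(m$thoracic_fraction_pct, 100 * m$volume_cm3 / tt)
  expect_true(all(m$thoracic_fraction_pct >= 0))

  # missing BSA flags indexed values as undefined, not zero
  m2 <- summarize_composition(seg$labels, ph$volume, seg$compartments,
                              lungs = ph$masks$masks$lungs)
  expect_true(all(is.na(m2$volume_index_cm3_m2)))
  expect_true(is.na(attr(m2, "bsa_m2")))
})

test_that("doubling dz doubles volumes and leaves densities unchanged", {
  sp1 <- small_phantom_spec()
  sp2 <- small_phantom_spec(spacing = c(1, 1, 2))
  ph1 <- generate_phantom(sp1)
  ph2 <- generate_phantom(sp2)
  s1 <- segment_volume(ph1$volume, ph1$masks)
  s2 <- segment_volume(ph2$volume, ph2$masks)
  m1 <- summarize_composition(s1$labels, ph1$volume, s1$compartments)
  m2 <- summarize_composition(s2$labels, ph2$volume, s2$compartments)
  expect_equal(m2$volume_cm3, 2 * m1$volume_cm3)
  expect_equal(m2$mean_density_hu, m1$mean_density_hu)
})

test_that("volume conservation holds over the labelled slab", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  m <- summarize_composition(seg$labels, ph$volume, seg$compartments)
  zs <- seg$slab[1]:seg$slab[2]
  body_vol <- sum(ph$masks$masks$body[, , zs]) * voxel_volume_mm3(ph$volume) / 1000
  unassigned <- sum(seg$labels$labels[, , zs] == 0L &
                      ph$masks$masks$body[, , zs]) *
    voxel_volume_mm3(ph$volume) / 1000
  expect_equal(sum(m$volume_cm3) + unassigned, body_vol)
})

test_that("metrics are invariant to a 90-degree in-plane rotation", {
  ph <- small_phantom()
  rot2 <- function(a) {
    # rotate each axial slice 90 degrees (x, y) -> (y, nx - x + 1)
    aperm(a, c(2, 1, 3))[, dim(a)[1]:1, , drop = FALSE]
  }
  vol_r <- ct_volume(rot2(ph$volume$data), spacing = ph$volume$spacing)
  masks_r <- organ_mask_set(lapply(ph$masks$masks, rot2), ph$masks$spacing)
  seg <- segment_volume(ph$volume, ph$masks)
  seg_r <- segment_volume(vol_r, masks_r)
  m <- summarize_composition(seg$labels, ph$volume, seg$compartments)
  m_r <- summarize_composition(seg_r$labels, vol_r, seg_r$compartments)
  expect_equal(m_r$volume_cm3, m$volume_cm3)
  expect_equal(m_r$mean_density_hu, m$mean_density_hu)
})

test_that("empty tissues report zero volume and undefined density", {
  sp <- small_phantom_spec(vat_pockets = list())
  ph <- generate_phantom(sp)
  seg <- segment_volume(ph$volume, ph$masks)
  m <- summarize_composition(seg$labels, ph$volume, seg$compartments)
  vat <- m[m$tissue == "VAT", ]
  expect_identical(vat$voxels, 0L)
  expect_equal(vat$volume_cm3, 0)
  expect_true(is.na(vat$mean_density_hu))
})

test_that("composition_row flattens to stable wide column names", {
  ph <- small_phantom()
  seg <- segment_volume(ph$volume, ph$masks)
  m <- summarize_composition(seg$labels, ph$volume, seg$compartments,
                             subj = subject("s", "female", 165, 70),
                             lungs = ph$masks$masks$lungs)
  row <- composition_row(m, id = "s")
  expect_true(all(c("sm_vol_idx", "vat_density_hu", "sat_vol_cm3",
                    "total_thoracic_vol_cm3", "lung_vol_cm3") %in% names(row)))
  expect_equal(row$vat_density_hu, m$mean_density_hu[m$tissue == "VAT"])
})
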