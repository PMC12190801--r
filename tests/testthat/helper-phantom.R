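# Small phantom used throughout the unit tests: same anatomy as the default,
# half the grid, 1 mm isotropic spacing so voxel counts equal volumes in mm^3.
small_phantom_spec <- function(...) {
  args <- small_phantom_args()
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(phantom_spec, args)
}

small_phantom_args <- function() {
  list(
    dims = c(80L, 80L, 60L), spacing = c(1, 1, 1),
    body_radii = c(36, 26), sat_thickness = 3, muscle_thickness = 4,
    lung_offset_x = 16, lung_radii = c(8, 13, 20), lung_centre_z = 32,
    heart_centre = c(0, -5, 27), heart_radii = c(6, 6, 8),
    eat_outer_radii = c(7.5, 7.5, 9.5),
    vat_pockets = list(list(x = c(37, 44), y = c(44, 49), z = c(22, 30)),
                       list(x = c(37, 44), y = c(35, 43), z = c(39, 44))),
    imat_pockets = list(list(x = c(35, 45), y = c(19, 20), z = c(15, 25)),
                        list(x = c(35, 45), y = c(60, 61), z = c(30, 40))),
    rib_boxes = list(list(x = c(6, 9), y = c(38, 42), z = c(15, 17)),
                     list(x = c(6, 9), y = c(38, 42), z = c(30, 32)),
                     list(x = c(72, 75), y = c(38, 42), z = c(15, 17)),
                     list(x = c(72, 75), y = c(38, 42), z = c(30, 32))),
    vertebra_x = c(37, 44), vertebra_y = c(52, 58),
    vertebra_top_z = 59, vertebra_height = 3, vertebra_gap = 2
  )
}

small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(small_phantom_spec())
    cache
  }
})
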