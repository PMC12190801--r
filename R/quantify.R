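#' Body surface area by the DuBois formula
#'
#' BSA = 0.007184 * weight^0.425 * height^0.725, with height in cm and weight
#' in kg, returning m^2. Vectorized.
#'
#' @param height_cm Height in cm (> 0).
#' @param weight_kg Weight in kg (> 0).
#' @return BSA in m^2.
#' @export
#' @examples
#' compute_bsa(180, 80) # ~1.996
compute_bsa <- function(height_cm, weight_kg) {
  if (any(height_cm <= 0, na.rm = TRUE) || any(weight_kg <= 0, na.rm = TRUE)) {
    abort("Height and weight must be strictly positive.")
  }
  0.007184 * weight_kg^0.425 * height_cm^0.725
}

#' Subject descriptor
#'
#' @param id Subject identifier.
#' @param sex `"female"` or `"male"` (required for sex-specific thresholds).
#' @param height_cm,weight_kg Height and weight; used to derive BSA when
#'   `bsa` is not given.
#' @param bsa Body surface area in m^2; computed by [compute_bsa()] if `NULL`
#'   and height/weight are available.
#' @return A `subject` list.
#' @export
subject <- function(id = "subject", sex = c("female", "male"),
                    height_cm = NULL, weight_kg = NULL, bsa = NULL) {
  sex <- match.arg(sex)
  if (is.null(bsa) && !is.null(height_cm) && !is.null(weight_kg)) {
    bsa <- compute_bsa(height_cm, weight_kg)
  }
  structure(list(id = id, sex = sex, height_cm = height_cm,
                 weight_kg = weight_kg, bsa = bsa), class = "subject")
}

#' Summarize body composition from a tissue labelmap
#'
#' Computes, for each of the six tissues (SM, bone, SAT, IMAT, VAT, EAT)
#' within the T5-T11 slab: volume in cm^3 (voxel count x voxel volume), mean
#' density in HU over all voxels carrying the label, volume indexed to body
#' surface area (cm^3/m^2), and volume as a percentage of the total thoracic
#' volume. Total thoracic volume is the volume of the union of the
#' intrathoracic compartment and the lungs within the slab.
#'
#' Empty tissues get volume 0 and an undefined (`NA`) mean density; when no
#' BSA is available the indexed volumes are `NA`, never silently zero.
#'
#' @param labels A `tissue_label_map` from [assign_tissues()].
#' @param volume The [ct_volume()] the labels were derived from.
#' @param compartments The `compartment_map`.
#' @param subj A [subject()] or `NULL`.
#' @param lungs Optional logical lung mask; needed for lung volume and for the
#'   thoracic-volume denominator.
#' @return A tibble with one row per tissue and columns `tissue`, `voxels`,
#'   `volume_cm3`, `volume_index_cm3_m2`, `thoracic_fraction_pct`,
#'   `mean_density_hu`; attributes `total_thoracic_volume_cm3`,
#'   `lung_volume_cm3`, `bsa_m2`.
#' @export
summarize_composition <- function(labels, volume, compartments, subj = NULL,
                                  lungs = NULL) {
  stopifnot(inherits(labels, "tissue_label_map"), inherits(volume, "ct_volume"))
  dims <- dim(volume$data)
  if (!identical(dims, dim(labels$labels))) abort("Labels misaligned with volume.")
  vv <- voxel_volume_mm3(volume)
  codes <- tissue_codes()
  tissue_names <- c("SM", "bone", "SAT", "IMAT", "VAT", "EAT")

  zs <- labels$slab[1]:labels$slab[2]
  lab <- labels$labels
  hu <- volume$data
  counts <- vapply(tissue_names, function(tn) sum(lab == codes[[tn]]), numeric(1))
  mean_hu <- vapply(tissue_names, function(tn) {
    sel <- lab == codes[[tn]]
    if (!any(sel)) NA_real_ else mean(hu[sel])
  }, numeric(1))

  intra <- compartments$labels == 1L
  lung_vol <- NA_real_
  thorax_mask <- intra
  if (!is.null(lungs)) {
    lung_slab <- array(FALSE, dims)
    lung_slab[, , zs] <- lungs[, , zs]
    lung_vol <- sum(lung_slab) * vv / 1000
    thorax_mask <- intra | lung_slab
  }
  total_thoracic <- sum(thorax_mask) * vv / 1000

  bsa <- if (!is.null(subj)) subj$bsa else NULL
  counts <- unname(counts)
  mean_hu <- unname(mean_hu)
  vols <- counts * vv / 1000
  out <- tibble(
    tissue = tissue_names,
    voxels = as.integer(counts),
    volume_cm3 = vols,
    volume_index_cm3_m2 = if (is.null(bsa)) NA_real_ else vols / bsa,
    thoracic_fraction_pct = if (total_thoracic > 0) 100 * vols / total_thoracic else NA_real_,
    mean_density_hu = mean_hu
  )
  attr(out, "total_thoracic_volume_cm3") <- total_thoracic
  attr(out, "lung_volume_cm3") <- lung_vol
  attr(out, "bsa_m2") <- if (is.null(bsa)) NA_real_ else bsa
  out
}

#' Flatten a composition table to one wide row
#'
#' Produces the per-subject row consumed by the risk models, with stable
#' column names such as `sm_vol_idx`, `vat_density_hu`, `sat_vol_cm3`, plus
#' `total_thoracic_vol_cm3` and `lung_vol_cm3`. Undefined metrics stay `NA`.
#'
#' @param metrics Output of [summarize_composition()].
#' @param id Optional subject id column value.
#' @return A one-row tibble.
#' @export
composition_row <- function(metrics, id = NULL) {
  key <- tolower(metrics$tissue)
  row <- list()
  if (!is.null(id)) row$id <- id
  for (i in seq_len(nrow(metrics))) {
    row[[paste0(key[i], "_vol_cm3")]] <- metrics$volume_cm3[i]
    row[[paste0(key[i], "_vol_idx")]] <- metrics$volume_index_cm3_m2[i]
    row[[paste0(key[i], "_thoracic_pct")]] <- metrics$thoracic_fraction_pct[i]
    row[[paste0(key[i], "_density_hu")]] <- metrics$mean_density_hu[i]
  }
  row$total_thoracic_vol_cm3 <- attr(metrics, "total_thoracic_volume_cm3")
  row$lung_vol_cm3 <- attr(metrics, "lung_volume_cm3")
  row$bsa_m2 <- attr(metrics, "bsa_m2")
  as_tibble(row)
}

#' Bar chart of tissue volumes and mean densities
#'
#' @param metrics Output of [summarize_composition()].
#' @return A ggplot object (two panels: indexed volume, mean density).
#' @export
plot_composition <- function(metrics) {
  long <- tidyr::pivot_longer(
    dplyr::select(metrics, "tissue", "volume_cm3", "mean_density_hu"),
    cols = c("volume_cm3", "mean_density_hu"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$tissue, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Thoracic body composition (T5-T11)") +
    ggplot2::theme_minimal()
}
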