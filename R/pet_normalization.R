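#' Tumor-to-background normalization of FET-PET uptake
#'
#' Divides raw amino-acid PET uptake by the mean uptake over a white-matter
#' background region, yielding the unitless tumor-to-background ratio (TBR)
#' conventional in FET quantification. The background region is the WM
#' tissue map minus all lesion compartments (CET, necrosis, edema), so that
#' tumor spill-in cannot bias the reference.
#'
#' @param pet_raw 3D volume of raw uptake (any positive scale).
#' @param wm_mask logical white-matter tissue map.
#' @param exclusion_masks list of logical volumes removed from the
#'   reference region (typically `cet`, `necrosis`, `edema`).
#' @param min_reference_voxels floor on the reference region size; guards
#'   against degenerate tissue maps (default 100).
#' @return An object of class `tbr_map` with fields `tbr` (volume),
#'   `background_value` and `reference_voxel_count`.
#' @export
#' @examples
#' g <- vox_geometry(c(16, 16, 16))
#' pet <- as_volume(array(5, c(16, 16, 16)), g)
#' wm <- as_volume(array(TRUE, c(16, 16, 16)), g)
#' res <- tbr_normalize(pet, wm, exclusion_masks = list())
#' res$background_value  # 5; tbr is identically 1
tbr_normalize <- function(pet_raw, wm_mask, exclusion_masks = list(),
                          min_reference_voxels = 100L) {
  do.call(assert_same_grid, c(list(pet_raw, wm_mask), exclusion_masks))
  ref <- wm_mask
  for (m in exclusion_masks) ref <- ref & !m
  n_ref <- sum(ref)
  if (n_ref < min_reference_voxels)
    stop(sprintf("reference region has %d voxels (< %d required)",
                 n_ref, min_reference_voxels), call. = FALSE)
  bg <- mean(pet_raw[ref])
  if (!is.finite(bg) || bg <= 0)
    stop("non-positive background mean uptake", call. = FALSE)
  tbr <- as_volume(array(pet_raw / bg, dim = dim(pet_raw)),
                   geometry_of(pet_raw))
  structure(list(tbr = tbr, background_value = bg,
                 reference_voxel_count = n_ref,
                 reference_mask = ref),
            class = "tbr_map")
}

#' @export
print.tbr_map <- function(x, ...) {
  cat(sprintf("<tbr_map> background %.4g over %d reference voxels; max TBR %.3g\n",
              x$background_value, x$reference_voxel_count, max(x$tbr)))
  invisible(x)
}
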