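#' Configure a synthetic multimodal phantom cohort
#'
#' Defines the study-like conditions emulated by the phantom generator: a
#' roughly spherical enhancing tumor rim inside a brain sphere, with
#' spatially contiguous true-progression (TP) and pseudoprogression (PsP)
#' sub-regions planted inside the contrast-enhancing tumor (CET). Channel
#' statistics differ between the two classes in the directions observed
#' clinically: TP tissue shows higher tumor-to-background FET uptake (TBR)
#' and higher cerebral blood volume (CBV) than PsP tissue, and grows /
#' brightens at follow-up while PsP fades.
#'
#' @param n_patients number of distinct patients.
#' @param cases_per_patient cases generated per patient (default 1).
#' @param n_repeat_patients number of patients additionally included a
#'   second time (two cases sharing one `patient_id`), exercising
#'   patient-grouped cross-validation. Default 0; the study-analogue cohort
#'   of [default_cohort_config()] turns this on.
#' @param geometry common voxel grid, a [vox_geometry()].
#' @param tumor_radius_mm outer radius of the enhancing lesion.
#' @param rim_thickness_mm thickness of the enhancing rim (CET); the core
#'   inside the rim is necrosis.
#' @param edema_margin_mm thickness of the edema shell outside the rim.
#' @param tp_fraction target fraction of CET voxels planted as TP.
#' @param blob_scale_mm correlation length of the random field whose
#'   threshold defines the TP/PsP geography (larger = fewer, larger blobs).
#' @param class_means,class_sds named lists with entries `TBR`, `CBV`,
#'   `T1c`, each a numeric `c(TP=, PsP=)` pair: per-class voxel means / SDs
#'   on the TBR scale (unitless ratio), relative CBV scale (white matter
#'   about 1), and z-scored T1c scale respectively.
#' @param noise_sd per-channel independent Gaussian noise SD, named as above.
#' @param spatial_correlation_mm smoothing scale of the within-class
#'   heterogeneity field.
#' @param followup_growth_mm outward dilation of TP regions at follow-up
#'   (new enhancement beyond the baseline CET).
#' @param followup_boost relative intensity increase of TP enhancement at
#'   follow-up; `psp_fade` is the relative decrease over PsP regions.
#' @param psp_fade see above.
#' @param rician if `TRUE` noise is Rician (magnitude of complex Gaussian)
#'   instead of additive Gaussian.
#' @param with_dsc if `TRUE` each bundle also carries a synthetic 4D DSC
#'   series consistent with its CBV map (memory-heavy; off by default).
#' @param seed integer seed; the whole cohort is deterministic given it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 10,
                          cases_per_patient = 1,
                          n_repeat_patients = 0,
                          geometry = vox_geometry(c(64, 64, 64), c(2, 2, 2)),
                          tumor_radius_mm = 20,
                          rim_thickness_mm = 8,
                          edema_margin_mm = 6,
                          tp_fraction = 0.5,
                          blob_scale_mm = 8,
                          class_means = list(TBR = c(TP = 2.6, PsP = 1.9),
                                             CBV = c(TP = 2.1, PsP = 1.3),
                                             T1c = c(TP = 3.4, PsP = 3.0)),
                          class_sds = list(TBR = c(TP = 0.35, PsP = 0.35),
                                           CBV = c(TP = 0.45, PsP = 0.45),
                                           T1c = c(TP = 0.7, PsP = 0.7)),
                          noise_sd = c(TBR = 0.15, CBV = 0.2, T1c = 0.2),
                          spatial_correlation_mm = 3,
                          followup_growth_mm = 2,
                          followup_boost = 0.3,
                          psp_fade = 0.2,
                          rician = FALSE,
                          with_dsc = FALSE,
                          seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients),
              cases_per_patient = as.integer(cases_per_patient),
              n_repeat_patients = as.integer(n_repeat_patients),
              geometry = geometry,
              tumor_radius_mm = tumor_radius_mm,
              rim_thickness_mm = rim_thickness_mm,
              edema_margin_mm = edema_margin_mm,
              tp_fraction = tp_fraction,
              blob_scale_mm = blob_scale_mm,
              class_means = class_means,
              class_sds = class_sds,
              noise_sd = noise_sd,
              spatial_correlation_mm = spatial_correlation_mm,
              followup_growth_mm = followup_growth_mm,
              followup_boost = followup_boost,
              psp_fade = psp_fade,
              rician = isTRUE(rician),
              with_dsc = isTRUE(with_dsc),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  if (cfg$n_patients < 1L) stop("n_patients must be >= 1", call. = FALSE)
  if (any(cfg$geometry$shape < 8L))
    stop("cohort grids need >= 8 voxels per axis", call. = FALSE)
  if (cfg$n_repeat_patients > cfg$n_patients)
    stop("n_repeat_patients cannot exceed n_patients", call. = FALSE)
  if (cfg$tp_fraction < 0 || cfg$tp_fraction > 1)
    stop("tp_fraction must lie in [0, 1]", call. = FALSE)
  for (ch in c("TBR", "CBV", "T1c")) {
    if (any(cfg$class_sds[[ch]] < 0))
      stop("class SDs must be >= 0", call. = FALSE)
  }
  if (cfg$rim_thickness_mm >= cfg$tumor_radius_mm)
    stop("rim_thickness_mm must be smaller than tumor_radius_mm", call. = FALSE)
  if (!(cfg$class_means$TBR["TP"] > cfg$class_means$TBR["PsP"]))
    warning("TP mean TBR does not exceed PsP mean TBR; ",
            "the planted contrast is reversed relative to the default direction")
  invisible(cfg)
}

#' Study-analogue cohort conditions
#'
#' The default synthetic cohort used throughout validation: 30 patients of
#' which 3 are included twice (mirroring repeat inclusion in real cohorts),
#' one case per inclusion, on a 64^3 grid at 2 mm isotropic spacing.
#'
#' @param seed integer seed.
#' @param n_patients,n_repeat_patients study-analogue defaults, overridable.
#' @param ... further overrides passed on to [cohort_config()].
#' @return A `cohort_config`.
#' @export
default_cohort_config <- function(seed = 1L, n_patients = 30,
                                  n_repeat_patients = 3, ...) {
  cohort_config(n_patients = n_patients,
                n_repeat_patients = min(n_repeat_patients, n_patients),
                seed = seed, ...)
}

#' Plant contiguous TP/PsP response regions inside the enhancing rim
#'
#' Thresholds a spatially smoothed Gaussian random field inside the CET mask
#' at the quantile matching `tp_fraction`, producing contiguous mixed-response
#' geography (coherent TP blobs embedded in PsP tissue) rather than
#' salt-and-pepper labels.
#'
#' @param cet_mask logical 3D volume of the contrast-enhancing tumor.
#' @param tp_fraction fraction of CET voxels to label TP, in \[0, 1\].
#' @param blob_scale_mm smoothing scale of the label field.
#' @param seed optional integer seed; `NULL` draws from the ambient RNG.
#' @param geometry grid geometry (taken from `cet_mask` when attached).
#' @return A `response_labels` object (see [response_labels()]) with
#'   provenance `"synthetic-truth"`.
#' @export
plant_response_regions <- function(cet_mask, tp_fraction, blob_scale_mm = 8,
                                   seed = NULL,
                                   geometry = geometry_of(cet_mask)) {
  if (tp_fraction < 0 || tp_fraction > 1)
    stop("tp_fraction must lie in [0, 1]", call. = FALSE)
  idx <- which(cet_mask)
  if (length(idx) == 0L) stop("cet_mask is empty", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lab <- array(0L, dim = geometry$shape)
  if (tp_fraction == 0) {
    lab[idx] <- 2L
  } else if (tp_fraction == 1) {
    lab[idx] <- 1L
  } else {
    f <- smoothed_unit_field(geometry, blob_scale_mm)
    thr <- stats::quantile(f[idx], probs = 1 - tp_fraction, type = 7)
    lab[idx] <- ifelse(f[idx] >= thr, 1L, 2L)
  }
  response_labels(as_volume(lab, geometry), cet_mask,
                  provenance = "synthetic-truth")
}

# Geometric masks for one phantom case. The lesion centre is jittered per
# case; errors out when the lesion (incl. edema) would not fit in the brain.
build_phantom_masks <- function(cfg, centre_jitter_mm) {
  g <- cfg$geometry
  extent <- g$shape * g$spacing
  brain_radius <- min(extent) / 2 - 2 * max(g$spacing)
  brain_centre <- extent / 2
  lesion_extent <- cfg$tumor_radius_mm + cfg$edema_margin_mm
  if (lesion_extent + sqrt(sum(centre_jitter_mm^2)) >= brain_radius)
    stop(sprintf(
      "tumor (radius %.1f mm + %.1f mm edema) does not fit inside the brain (radius %.1f mm)",
      cfg$tumor_radius_mm, cfg$edema_margin_mm, brain_radius), call. = FALSE)
  tumor_centre <- brain_centre + centre_jitter_mm
  d2_brain <- dist2_to_point(g, brain_centre)
  d2_tumor <- dist2_to_point(g, tumor_centre)
  brain <- d2_brain <= brain_radius^2
  r_inner <- cfg$tumor_radius_mm - cfg$rim_thickness_mm
  necrosis <- d2_tumor < r_inner^2
  cet <- d2_tumor >= r_inner^2 & d2_tumor < cfg$tumor_radius_mm^2
  edema <- d2_tumor >= cfg$tumor_radius_mm^2 &
    d2_tumor < (cfg$tumor_radius_mm + cfg$edema_margin_mm)^2 & brain
  lesion <- necrosis | cet | edema
  gm <- brain & d2_brain > (brain_radius - 2 * max(g$spacing))^2 & !lesion
  # small central CSF pocket placed opposite the lesion jitter
  csf_centre <- brain_centre - centre_jitter_mm
  csf <- dist2_to_point(g, csf_centre) <= 6^2 & brain & !lesion & !gm
  wm <- brain & !lesion & !gm & !csf
  lapply(list(brain = brain, cet = cet, necrosis = necrosis, edema = edema,
              wm = wm, gm = gm, csf = csf),
         function(m) as_volume(m, g))
}

# One multimodal channel: crisp per-tissue mean map + within-class
# correlated heterogeneity (scaled by a per-tissue SD map) + voxel noise.
# Returns the noisy volume plus the noise-free anatomy, so a follow-up
# acquisition can be emulated as clean anatomy x response + fresh noise of
# the same magnitude (re-scan noise is independent, not cumulative).
synth_channel <- function(cfg, masks, truth, channel, background) {
  g <- cfg$geometry
  mu <- array(0, dim = g$shape)
  sdmap <- array(0, dim = g$shape)
  mu[masks$brain] <- background["brain"]
  mu[masks$gm] <- background["gm"]
  mu[masks$csf] <- background["csf"]
  mu[masks$edema] <- background["edema"]
  mu[masks$necrosis] <- background["necrosis"]
  sdmap[masks$brain] <- background["sd"]
  tp <- truth$labels == 1L
  psp <- truth$labels == 2L
  mu[tp] <- cfg$class_means[[channel]]["TP"]
  mu[psp] <- cfg$class_means[[channel]]["PsP"]
  sdmap[tp] <- cfg$class_sds[[channel]]["TP"]
  sdmap[psp] <- cfg$class_sds[[channel]]["PsP"]
  het <- smoothed_unit_field(g, cfg$spatial_correlation_mm)
  clean <- mu + sdmap * het
  noisy <- add_scan_noise(clean, cfg$noise_sd[[channel]], cfg$rician)
  clean[!masks$brain] <- 0
  noisy[!masks$brain] <- 0
  list(noisy = as_volume(array(noisy, dim = g$shape), g),
       clean = as_volume(array(clean, dim = g$shape), g))
}

add_scan_noise <- function(clean, ns, rician) {
  if (rician) {
    sqrt((clean + stats::rnorm(length(clean), sd = ns))^2 +
           stats::rnorm(length(clean), sd = ns)^2)
  } else {
    clean + stats::rnorm(length(clean), sd = ns)
  }
}

#' Generate a synthetic multimodal cohort
#'
#' Produces one [case_bundle()] per case: baseline T1c, raw FET-PET and CBV
#' channels, tissue and tumor sub-region masks, a registered follow-up T1c
#' in which planted TP regions grow (`followup_growth_mm`) and brighten
#' (`followup_boost`) while PsP regions fade (`psp_fade`), and the ground
#' truth response label map covering the CET exactly.
#'
#' @param config a [cohort_config()].
#' @return A list of `case_bundle` objects.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_config(n_patients = 2, seed = 7))
#' names(cohort[[1]]$channels)
generate_cohort <- function(config) {
  validate_cohort_config(config)
  set.seed(config$seed)
  g <- config$geometry
  patient_ids <- sprintf("P%03d", seq_len(config$n_patients))
  schedule <- data.frame(
    patient_id = rep(patient_ids, each = config$cases_per_patient),
    stringsAsFactors = FALSE)
  if (config$n_repeat_patients > 0L) {
    repeats <- sample(patient_ids, config$n_repeat_patients)
    schedule <- rbind(schedule, data.frame(patient_id = repeats))
  }
  schedule$case_id <- sprintf("%s_C%d", schedule$patient_id,
                              stats::ave(seq_len(nrow(schedule)),
                                         schedule$patient_id, FUN = seq_along))
  lapply(seq_len(nrow(schedule)), function(i) {
    jitter_dir <- stats::rnorm(3)
    jitter_dir <- jitter_dir / sqrt(sum(jitter_dir^2))
    extent <- g$shape * g$spacing
    brain_radius <- min(extent) / 2 - 2 * max(g$spacing)
    max_jit <- max(0, brain_radius - config$tumor_radius_mm -
                     config$edema_margin_mm - max(g$spacing))
    jitter <- jitter_dir * stats::runif(1, 0, min(0.25 * brain_radius, max_jit))
    masks <- build_phantom_masks(config, jitter)
    truth <- plant_response_regions(masks$cet, config$tp_fraction,
                                    config$blob_scale_mm, seed = NULL,
                                    geometry = g)
    tbr_true <- synth_channel(config, masks, truth, "TBR",
                              c(brain = 1, gm = 1.1, csf = 0.3,
                                edema = 1.1, necrosis = 0.5, sd = 0.08))
    cbv <- synth_channel(config, masks, truth, "CBV",
                         c(brain = 1, gm = 1.6, csf = 0.2,
                           edema = 0.8, necrosis = 0.3, sd = 0.1))
    t1c <- synth_channel(config, masks, truth, "T1c",
                         c(brain = 0, gm = 0.2, csf = -0.5,
                           edema = 0.5, necrosis = -0.5, sd = 0.3))
    # raw PET = true TBR field times an arbitrary per-case scanner scale;
    # tbr_normalize() recovers the ratio from the WM reference
    pet_scale <- stats::runif(1, 0.8, 1.2)
    pet_raw <- as_volume(array(tbr_true$noisy * pet_scale, dim = g$shape), g)
    # follow-up acquisition: multiplicative response factor on the clean
    # baseline anatomy, plus fresh scan noise of the baseline magnitude
    factor <- array(1, dim = g$shape)
    tp_mask <- truth$labels == 1L
    grown <- dilate_mm(as_volume(tp_mask, g), config$followup_growth_mm)
    growth_ring <- grown & !masks$cet & masks$brain
    factor[tp_mask | growth_ring] <- 1 + config$followup_boost
    factor[truth$labels == 2L] <- 1 - config$psp_fade
    fu <- add_scan_noise(t1c$clean * factor, config$noise_sd[["T1c"]],
                         config$rician)
    fu[!masks$brain] <- 0
    channels <- list(T1c_baseline = t1c$noisy, PET_raw = pet_raw,
                     CBV = cbv$noisy)
    dsc <- NULL
    if (config$with_dsc)
      dsc <- simulate_dsc_from_cbv(cbv$noisy, masks$brain)
    case_bundle(case_id = schedule$case_id[i],
                patient_id = schedule$patient_id[i],
                channels = channels,
                masks = masks,
                followup_T1c = as_volume(array(fu, dim = g$shape), g),
                truth_labels = truth,
                dsc = dsc)
  })
}

#' A single imaging case
#'
#' Container for the co-registered multimodal stack of one case: baseline
#' channels, tumor sub-region and tissue masks, the registered follow-up
#' T1c, and (synthetic cases only) the ground-truth response label map.
#'
#' @param case_id,patient_id identifiers; several cases may share a
#'   `patient_id` (repeat inclusion).
#' @param channels named list of 3D volumes; must include `T1c_baseline`
#'   and `PET_raw`, plus `CBV` (precomputed) unless a DSC series is given.
#' @param masks named list of logical volumes: `cet`, `necrosis`, `edema`,
#'   `wm`, `gm`, `csf`, `brain`.
#' @param followup_T1c registered follow-up contrast-enhanced T1w volume.
#' @param truth_labels optional `response_labels` ground truth.
#' @param dsc optional [dsc_series()] (alternative to a `CBV` channel).
#' @return An object of class `case_bundle`.
#' @export
case_bundle <- function(case_id, patient_id, channels, masks, followup_T1c,
                        truth_labels = NULL, dsc = NULL) {
  b <- structure(list(case_id = case_id, patient_id = patient_id,
                      channels = channels, masks = masks,
                      followup_T1c = followup_T1c,
                      truth_labels = truth_labels, dsc = dsc),
                 class = "case_bundle")
  validate_case_bundle(b)
  b
}

validate_case_bundle <- function(b) {
  stopifnot(inherits(b, "case_bundle"))
  need <- c("cet", "necrosis", "edema", "wm", "brain")
  missing <- setdiff(need, names(b$masks))
  if (length(missing))
    stop("case ", b$case_id, ": missing mask(s) ",
         paste(missing, collapse = ", "), call. = FALSE)
  for (ch in c("T1c_baseline", "PET_raw"))
    if (is.null(b$channels[[ch]]))
      stop("case ", b$case_id, ": missing channel ", ch, call. = FALSE)
  if (is.null(b$channels$CBV) && is.null(b$dsc))
    stop("case ", b$case_id,
         ": needs either a CBV channel or a DSC series", call. = FALSE)
  vols <- c(b$channels, b$masks, list(b$followup_T1c))
  do.call(assert_same_grid, vols)
  if (!any(b$masks$cet)) stop("case ", b$case_id, ": CET mask is empty",
                              call. = FALSE)
  if (!any(b$masks$wm)) stop("case ", b$case_id, ": WM mask is empty",
                             call. = FALSE)
  overlap <- sum(b$masks$cet & b$masks$necrosis) +
    sum(b$masks$cet & b$masks$edema) + sum(b$masks$necrosis & b$masks$edema)
  if (overlap > 0)
    stop("case ", b$case_id, ": CET/necrosis/edema masks overlap",
         call. = FALSE)
  invisible(b)
}

#' @export
print.case_bundle <- function(x, ...) {
  g <- geometry_of(x$masks$cet)
  cat(sprintf("<case_bundle> %s (patient %s): %d CET voxels on %dx%dx%d grid\n",
              x$case_id, x$patient_id, sum(x$masks$cet),
              g$shape[1], g$shape[2], g$shape[3]))
  invisible(x)
}
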