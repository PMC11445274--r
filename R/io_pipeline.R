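#' Read / write volumes in NIfTI-1 format
#'
#' Scalar volumes are stored as 32-bit float, label/mask volumes as 32-bit
#' integer; voxel spacing travels in the NIfTI pixdim and is restored into
#' the volume's geometry attribute on read. Integer volumes round-trip
#' bit-exactly; scalars to 32-bit float precision.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @param volume 3D array (with geometry attribute) to write.
#' @return `read_volume`: the array with its `vox_geometry` attached.
#'   `write_volume`: `path`, invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("no such volume: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  a <- as.array(img)
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) a <- a[, , , 1]
  sp <- RNifti::pixdim(img)[1:3]
  g <- vox_geometry(dim(a)[1:3], sp)
  if (length(dim(a)) == 3L) as_volume(a, g) else structure(a, geometry = g)
}

#' @rdname read_volume
#' @export
write_volume <- function(volume, path) {
  g <- geometry_of(volume)
  a <- as.array(volume)
  attributes(a) <- list(dim = dim(volume))
  datatype <- if (is.logical(a) || is.integer(a)) {
    storage.mode(a) <- "integer"
    "int32"
  } else "float"
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- g$spacing
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Pipeline configuration
#'
#' Bundles every stage's configuration for a reproducible end-to-end run.
#' In synthetic mode the cohort is generated; in manifest mode a delimited
#' table names each case's channel/mask files on disk.
#'
#' @param out_dir output directory (created if absent).
#' @param seed master seed; propagated to every stochastic stage.
#' @param mode `"synthetic"` or `"manifest"`.
#' @param cohort a [cohort_config()] (synthetic mode).
#' @param manifest path to a case manifest CSV (manifest mode) with columns
#'   `case_id`, `patient_id` and per-volume path columns.
#' @param slic a [slic_config()].
#' @param rf an [rf_config()].
#' @param disc a [discretization_spec()].
#' @param progression_threshold relative-change threshold for voxel
#'   labeling (default 0.10).
#' @param n_folds cross-validation folds (default 10).
#' @param use_truth_labels use the phantom's ground-truth labels instead of
#'   the automatic labeler (synthetic mode only; default `FALSE`).
#' @param force recompute stages whose outputs already exist.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            mode = c("synthetic", "manifest"),
                            cohort = default_cohort_config(seed = seed),
                            manifest = NULL,
                            slic = slic_config(seed = seed),
                            rf = rf_config(seed = seed),
                            disc = discretization_spec(),
                            progression_threshold = 0.10,
                            n_folds = 10L,
                            use_truth_labels = FALSE,
                            force = FALSE) {
  mode <- match.arg(mode)
  if (mode == "manifest") {
    if (is.null(manifest) || !file.exists(manifest))
      stop("manifest mode needs an existing manifest file", call. = FALSE)
  }
  structure(list(out_dir = out_dir, seed = as.integer(seed), mode = mode,
                 cohort = cohort, manifest = manifest, slic = slic, rf = rf,
                 disc = disc,
                 progression_threshold = progression_threshold,
                 n_folds = as.integer(n_folds),
                 use_truth_labels = isTRUE(use_truth_labels),
                 force = isTRUE(force)),
            class = "pipeline_config")
}

#' Load case bundles from a manifest table
#'
#' The manifest CSV must carry `case_id`, `patient_id` and path columns
#' `t1c_baseline`, `pet_raw`, `followup_t1c`, `cet`, `necrosis`, `edema`,
#' `wm`, `brain` (plus optional `gm`, `csf`, `cbv`, `truth_labels`). All
#' volumes of a case must share one grid; a missing file errors naming the
#' case and channel.
#'
#' @param path manifest CSV path.
#' @return List of [case_bundle()]s.
#' @export
read_case_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "patient_id", "t1c_baseline", "pet_raw",
            "followup_t1c", "cet", "necrosis", "edema", "wm", "brain")
  missing <- setdiff(need, names(man))
  if (length(missing))
    stop("manifest lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(man)), function(i) {
    row <- man[i, ]
    rd <- function(col, logical = FALSE) {
      p <- row[[col]]
      if (is.null(p) || is.na(p) || !nzchar(p)) return(NULL)
      if (!file.exists(p))
        stop("case ", row$case_id, ": missing ", col, " volume: ", p,
             call. = FALSE)
      v <- read_volume(p)
      if (logical) {
        g <- geometry_of(v)
        v <- as_volume(array(v != 0, dim = dim(v)), g)
      }
      v
    }
    masks <- list(cet = rd("cet", TRUE), necrosis = rd("necrosis", TRUE),
                  edema = rd("edema", TRUE), wm = rd("wm", TRUE),
                  brain = rd("brain", TRUE))
    for (opt in c("gm", "csf"))
      if (!is.null(row[[opt]])) masks[[opt]] <- rd(opt, TRUE)
    truth <- NULL
    if (!is.null(row$truth_labels) && !is.na(row$truth_labels) &&
        nzchar(row$truth_labels)) {
      lv <- rd("truth_labels")
      g <- geometry_of(lv)
      truth <- response_labels(as_volume(array(as.integer(round(lv)),
                                               dim = dim(lv)), g),
                               masks$cet, provenance = "manual")
    }
    channels <- list(T1c_baseline = rd("t1c_baseline"),
                     PET_raw = rd("pet_raw"))
    if (!is.null(row$cbv)) channels$CBV <- rd("cbv")
    case_bundle(case_id = row$case_id, patient_id = row$patient_id,
                channels = channels, masks = masks,
                followup_T1c = rd("followup_t1c"), truth_labels = truth)
  })
}

# per-case processing: TBR, CBV passthrough/fit, z-scored T1c, labels, SLIC
process_case <- function(b, cfg) {
  masks <- b$masks
  excl <- list(masks$cet, masks$necrosis, masks$edema)
  tbr <- tbr_normalize(b$channels$PET_raw, masks$wm, excl)
  cbv <- b$channels$CBV
  if (is.null(cbv)) {
    dr2 <- signal_to_delta_r2(b$dsc, masks$brain)
    ref_mask <- masks$brain & !masks$cet & !masks$necrosis & !masks$edema
    res <- leakage_corrected_cbv(dr2, ref_mask)
    g <- geometry_of(masks$brain)
    cbv <- res$cbv
    cbv[!is.finite(cbv)] <- 0
    cbv <- as_volume(cbv, g)
  }
  nonenh <- masks$brain & !masks$cet
  t1c_z <- znorm_to_region(b$channels$T1c_baseline, nonenh)
  if (cfg$use_truth_labels && !is.null(b$truth_labels)) {
    labels <- b$truth_labels
  } else {
    labels <- label_voxels(b$channels$T1c_baseline, b$followup_T1c,
                           masks$cet, cfg$progression_threshold,
                           brain_mask = masks$brain)
  }
  svx <- slic_supervoxels(list(CBV = cbv, PET = tbr$tbr, T1c = t1c_z),
                          masks$cet, cfg$slic)
  list(channels = list(CBV = cbv, PET = tbr$tbr, T1c = t1c_z),
       labels = labels, svx = svx, majority = majority_label(svx, labels))
}

#' Run the full pipeline
#'
#' Executes simulate (or manifest ingest) -> CBV -> TBR -> label ->
#' cluster -> featurize -> train -> report in order, persisting each
#' stage's artifacts under `out_dir` and recording an md5 hash for every
#' written file. Identical config and seed give identical artifact hashes.
#' When outputs already exist and `force` is `FALSE`, completed stages are
#' reused from disk.
#'
#' @param cfg a [pipeline_config()].
#' @return A `run_manifest` object: artifact registry with hashes, the
#'   feature table, the [cross_validate()] result and the percentile
#'   contrasts.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  feat_path <- file.path(cfg$out_dir, "features.csv")
  if (file.exists(feat_path) && !cfg$force) {
    table <- read_feature_table(feat_path)
    class(table) <- c("feature_table", "data.frame")
  } else {
    cases <- if (cfg$mode == "synthetic") generate_cohort(cfg$cohort)
    else read_case_manifest(cfg$manifest)
    channel_sets <- list(); svx_maps <- list(); svx_labels <- list()
    case_dir <- file.path(cfg$out_dir, "cases")
    dir.create(case_dir, showWarnings = FALSE)
    for (b in cases) {
      pr <- process_case(b, cfg)
      cid <- b$case_id
      channel_sets[[cid]] <- pr$channels
      svx_maps[[cid]] <- pr$svx
      svx_labels[[cid]] <- pr$majority
      cdir <- file.path(case_dir, cid)
      dir.create(cdir, showWarnings = FALSE)
      write_volume(pr$channels$CBV, file.path(cdir, "cbv.nii.gz"))
      write_volume(pr$channels$PET, file.path(cdir, "tbr.nii.gz"))
      write_volume(pr$channels$T1c, file.path(cdir, "t1c_z.nii.gz"))
      write_volume(pr$labels$labels, file.path(cdir, "labels.nii.gz"))
      write_volume(pr$svx$ids, file.path(cdir, "supervoxels.nii.gz"))
    }
    table <- extract_feature_table(cases, channel_sets, svx_maps,
                                   svx_labels, cfg$disc)
    write_feature_table(table, feat_path)
    # downstream stages consume the persisted table, so a resumed run sees
    # bit-identical inputs to a fresh one
    table <- read_feature_table(feat_path)
  }
  folds <- grouped_folds(table, cfg$n_folds, seed = cfg$seed)
  cv <- cross_validate(table, folds, cfg$rf)
  assert_no_leakage(cv)
  contrasts <- compare_percentile_features(table)
  utils::write.csv(cv$predictions,
                   file.path(cfg$out_dir, "predictions.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(feature = names(cv$importances),
                              importance = unname(cv$importances)),
                   file.path(cfg$out_dir, "importances.csv"),
                   row.names = FALSE)
  utils::write.csv(cv$per_fold, file.path(cfg$out_dir, "fold_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(contrasts, file.path(cfg$out_dir, "contrasts.csv"),
                   row.names = FALSE)
  metrics <- data.frame(
    metric = c("macro_auc", "accuracy", "balanced_accuracy", "sensitivity",
               "specificity", "tp_precision", "tp_recall", "tp_f1",
               "psp_precision", "psp_recall", "psp_f1"),
    value = c(cv$macro_auc, cv$pooled$accuracy, cv$pooled$balanced_accuracy,
              cv$pooled$sensitivity, cv$pooled$specificity,
              cv$pooled$per_class["TP", ], cv$pooled$per_class["PsP", ]))
  utils::write.csv(metrics, file.path(cfg$out_dir, "metrics.csv"),
                   row.names = FALSE)
  files <- list.files(cfg$out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("run_manifest", files)]
  registry <- data.frame(path = sub(paste0("^", cfg$out_dir, "/?"), "",
                                    files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.csv(registry, file.path(cfg$out_dir, "run_manifest.csv"),
                   row.names = FALSE)
  structure(list(registry = registry, table = table, cv = cv,
                 contrasts = contrasts, metrics = metrics, config = cfg),
            class = "run_manifest")
}

#' @export
print.run_manifest <- function(x, ...) {
  cat(sprintf("<run_manifest> %d artifacts in %s\n", nrow(x$registry),
              x$config$out_dir))
  print(x$cv)
  invisible(x)
}
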