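#' Canonical 126-feature schema
#'
#' Column names follow `<channel>__<family>__<feature>` with channels
#' `CBV`, `PET`, `T1c` and families `firstorder` (18 features) and `glcm`
#' (24 features): 42 per channel, 126 in total.
#'
#' @return Character vector of 126 stable column names.
#' @export
feature_schema <- function() {
  unlist(lapply(c("CBV", "PET", "T1c"), function(ch)
    c(paste(ch, "firstorder", first_order_names, sep = "__"),
      paste(ch, "glcm", glcm_names, sep = "__"))))
}

# 42 features for one supervoxel on one channel
channel_features <- function(volume, voxel_idx, disc, gspec,
                             voxel_volume_mm3) {
  vals <- as.numeric(volume[voxel_idx])
  fo <- first_order_features(vals, disc, voxel_volume_mm3)
  gl <- glcm_features(volume, voxel_idx, disc, gspec)
  list(features = c(fo, gl),
       degenerate = isTRUE(attr(gl, "degenerate")) ||
         length(unique(discretize_values(vals, disc))) < 2L)
}

#' Extract the supervoxel feature table for a cohort
#'
#' One record per supervoxel: patient/case metadata, majority response
#' label, voxel count, and the 126 radiomics features (42 per channel from
#' CBV, TBR-normalized PET and T1c). Supervoxels that are degenerate on any
#' channel (a single gray level after discretization, so texture is
#' undefined) are excluded from the table rather than imputed; exclusions
#' are logged in the `excluded` attribute with a reason.
#'
#' @param cases list of [case_bundle()]s.
#' @param channel_sets named list (by `case_id`) of 3-channel lists
#'   `list(CBV=, PET=, T1c=)` as clustered (i.e. TBR-normalized PET,
#'   leakage-corrected CBV, z-scored T1c).
#' @param svx_maps named list (by `case_id`) of [slic_supervoxels()] maps.
#' @param svx_labels named list (by `case_id`) of [majority_label()] frames.
#' @param disc a [discretization_spec()].
#' @param gspec a [glcm_spec()].
#' @return A `data.frame` of class `feature_table`; attribute `excluded`
#'   records dropped supervoxels.
#' @export
extract_feature_table <- function(cases, channel_sets, svx_maps, svx_labels,
                                  disc = discretization_spec(),
                                  gspec = glcm_spec()) {
  schema <- feature_schema()
  rows <- list()
  excluded <- list()
  for (b in cases) {
    cid <- b$case_id
    chans <- channel_sets[[cid]]
    for (ch in c("CBV", "PET", "T1c"))
      if (is.null(chans[[ch]]))
        stop("case ", cid, ": missing channel ", ch, call. = FALSE)
    svx <- svx_maps[[cid]]
    labs <- svx_labels[[cid]]
    if (is.null(svx) || is.null(labs))
      stop("case ", cid, ": missing supervoxel map or labels", call. = FALSE)
    g <- geometry_of(svx$ids)
    voxvol <- prod(g$spacing)
    for (sid in seq_len(svx$n_supervoxels)) {
      vidx <- which(svx$ids == sid)
      feats <- numeric(0)
      degen <- FALSE
      for (ch in c("CBV", "PET", "T1c")) {
        cf <- channel_features(chans[[ch]], vidx, disc, gspec, voxvol)
        feats <- c(feats, cf$features)
        degen <- degen || cf$degenerate
      }
      if (degen) {
        excluded[[length(excluded) + 1L]] <- data.frame(
          case_id = cid, svx_id = sid, n_voxels = length(vidx),
          reason = "degenerate gray levels", stringsAsFactors = FALSE)
        next
      }
      names(feats) <- schema
      row <- data.frame(patient_id = b$patient_id, case_id = cid,
                        svx_id = sid,
                        n_voxels = labs$n_voxels[labs$svx_id == sid],
                        label = labs$label[labs$svx_id == sid],
                        majority_fraction =
                          labs$majority_fraction[labs$svx_id == sid],
                        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(row, as.data.frame(as.list(feats)))
    }
  }
  if (!length(rows)) stop("no valid supervoxels in cohort", call. = FALSE)
  out <- do.call(rbind, rows)
  names(out)[-(1:6)] <- schema
  rownames(out) <- NULL
  class(out) <- c("feature_table", "data.frame")
  attr(out, "excluded") <- if (length(excluded)) do.call(rbind, excluded)
  else data.frame(case_id = character(0), svx_id = integer(0),
                  n_voxels = integer(0), reason = character(0))
  out
}

#' Columns of a feature table that hold features
#'
#' @param table a `feature_table` (or compatible data frame).
#' @return Character vector of the 126 feature column names present.
#' @export
feature_columns <- function(table) intersect(feature_schema(), names(table))

#' Write / read a feature table with its sidecar schema
#'
#' The table is persisted as CSV; the 126 feature names are written next to
#' it as a JSON schema file (`<path>.schema.json`).
#'
#' @param table a `feature_table`.
#' @param path CSV output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  jsonlite::write_json(list(features = feature_schema(),
                            metadata = setdiff(names(table),
                                               feature_schema())),
                       paste0(path, ".schema.json"), auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  class(out) <- c("feature_table", "data.frame")
  out
}
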