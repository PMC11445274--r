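#' Voxel-level response label map
#'
#' Label codes: 0 = background, 1 = true progression (TP), 2 =
#' pseudoprogression (PsP). Nonzero labels live only on the baseline CET
#' mask and every CET voxel carries a label.
#'
#' @param labels integer 3D volume with codes in \{0, 1, 2\}.
#' @param cet_mask logical volume the labels must cover.
#' @param provenance one of `"manual"`, `"automatic"`, `"synthetic-truth"`.
#' @return An object of class `response_labels`.
#' @export
response_labels <- function(labels, cet_mask,
                            provenance = c("automatic", "manual",
                                           "synthetic-truth")) {
  provenance <- match.arg(provenance)
  assert_same_grid(labels, cet_mask)
  if (!all(labels %in% c(0L, 1L, 2L)))
    stop("label codes must be 0 (background), 1 (TP) or 2 (PsP)",
         call. = FALSE)
  outside <- sum(labels != 0L & !cet_mask)
  if (outside > 0)
    stop(outside, " labeled voxel(s) lie outside the CET mask", call. = FALSE)
  unlabeled <- sum(cet_mask & labels == 0L)
  if (unlabeled > 0)
    warning(unlabeled, " CET voxel(s) are unlabeled")
  structure(list(labels = labels, provenance = provenance,
                 n_tp = sum(labels == 1L), n_psp = sum(labels == 2L)),
            class = "response_labels")
}

#' @export
print.response_labels <- function(x, ...) {
  n <- x$n_tp + x$n_psp
  cat(sprintf("<response_labels> (%s) %d voxels: %d TP (%.1f%%), %d PsP (%.1f%%)\n",
              x$provenance, n, x$n_tp, 100 * x$n_tp / max(n, 1),
              x$n_psp, 100 * x$n_psp / max(n, 1)))
  invisible(x)
}

# z-normalize a volume to the mean/SD of a reference region
znorm_to_region <- function(vol, region_mask) {
  mu <- mean(vol[region_mask])
  s <- stats::sd(vol[region_mask])
  if (!is.finite(s) || s <= 0)
    stop("degenerate normalization region (zero variance)", call. = FALSE)
  as_volume(array((vol - mu) / s, dim = dim(vol)), geometry_of(vol))
}

#' Label baseline CET voxels as TP or PsP from the registered follow-up scan
#'
#' Automatic surrogate for expert voxel labeling: after z-normalizing both
#' contrast-enhanced T1w volumes to the mean/SD of the nonenhancing brain
#' (brain minus CET, or an explicit `normalization_mask`), a CET voxel is
#' labeled TP when its relative enhancement change
#' \eqn{(FU - BL) / BL} exceeds `progression_threshold`, else PsP.
#' Voxels with non-positive baseline intensity (where the ratio is
#' undefined) are filled in by the majority label of their 26-neighbourhood.
#' New enhancement outside the baseline CET is deliberately ignored: labels
#' live on the baseline CET only.
#'
#' @param t1c_baseline,t1c_followup co-registered contrast-enhanced T1w
#'   volumes on one grid (registration is a precondition, not performed here).
#' @param cet_mask baseline contrast-enhancing tumor mask.
#' @param progression_threshold relative-change fraction above which a voxel
#'   counts as progressing (default 0.10).
#' @param brain_mask brain mask used to build the default normalization
#'   region; required unless `normalization_mask` is given.
#' @param normalization_mask optional explicit nonenhancing reference region.
#' @return A `response_labels` object with provenance `"automatic"` and an
#'   attribute `flagged` holding linear indices of neighbourhood-filled
#'   voxels.
#' @export
label_voxels <- function(t1c_baseline, t1c_followup, cet_mask,
                         progression_threshold = 0.10,
                         brain_mask = NULL, normalization_mask = NULL) {
  assert_same_grid(t1c_baseline, t1c_followup, cet_mask)
  g <- geometry_of(cet_mask)
  if (is.null(normalization_mask)) {
    if (is.null(brain_mask))
      stop("either brain_mask or normalization_mask is required", call. = FALSE)
    normalization_mask <- brain_mask & !cet_mask
  }
  bl <- znorm_to_region(t1c_baseline, normalization_mask)
  fu <- znorm_to_region(t1c_followup, normalization_mask)
  idx <- which(cet_mask)
  if (length(idx) == 0L) stop("cet_mask is empty", call. = FALSE)
  lab <- array(0L, dim = g$shape)
  blv <- bl[idx]
  rel <- (fu[idx] - blv) / blv
  ok <- blv > 0
  lab[idx[ok]] <- ifelse(rel[ok] > progression_threshold, 1L, 2L)
  flagged <- idx[!ok]
  if (length(flagged)) {
    # fill by 26-neighbourhood majority over already-labeled CET voxels;
    # repeat until stable in case flagged voxels cluster
    sh <- g$shape
    repeat {
      todo <- flagged[lab[flagged] == 0L]
      if (!length(todo)) break
      changed <- FALSE
      for (v in todo) {
        nb <- neighbour_indices_26(v, sh)
        votes <- lab[nb]
        votes <- votes[votes > 0L]
        if (length(votes)) {
          n_tp <- sum(votes == 1L)
          lab[v] <- if (n_tp >= length(votes) - n_tp) 1L else 2L
          changed <- TRUE
        }
      }
      if (!changed) { lab[todo] <- 2L; break }  # isolated: default PsP
    }
  }
  out <- response_labels(as_volume(lab, g), cet_mask,
                         provenance = "automatic")
  attr(out, "flagged") <- flagged
  out
}

neighbour_indices_26 <- function(v, sh) {
  v0 <- v - 1L
  i <- v0 %% sh[1]; j <- (v0 %/% sh[1]) %% sh[2]; k <- v0 %/% (sh[1] * sh[2])
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ni <- i + offs$dx; nj <- j + offs$dy; nk <- k + offs$dz
  ok <- ni >= 0 & ni < sh[1] & nj >= 0 & nj < sh[2] & nk >= 0 & nk < sh[3]
  ni[ok] + sh[1] * (nj[ok] + sh[2] * nk[ok]) + 1L
}

#' Validate an externally supplied (e.g. manually drawn) label volume
#'
#' @param label_volume integer volume with codes in \{0, 1, 2\}.
#' @param cet_mask baseline CET mask the labels must respect.
#' @return A `response_labels` with provenance `"manual"`; warns with the
#'   count of unlabeled CET voxels, errors on labels outside the CET.
#' @export
accept_external_labels <- function(label_volume, cet_mask) {
  if (!all(label_volume %in% c(0L, 1L, 2L)))
    stop("label codes must be a subset of {0, 1, 2}", call. = FALSE)
  if (is.null(attr(label_volume, "geometry")) &&
      all(dim(label_volume) == dim(cet_mask)))
    label_volume <- as_volume(label_volume, geometry_of(cet_mask))
  response_labels(label_volume, cet_mask, provenance = "manual")
}
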