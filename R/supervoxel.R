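#' SLIC clustering configuration
#'
#' @param target_size intended voxels per supervoxel (default 200,
#'   balancing region size against assessment granularity).
#' @param compactness spatial-vs-intensity weight `m` of the SLIC distance;
#'   applied after per-case channel standardization, so small values favour
#'   intensity homogeneity (default 0.1).
#' @param max_iterations local k-means sweeps (default 10).
#' @param seed integer seed (used only for degenerate tie-breaking; the
#'   algorithm itself is deterministic).
#' @param standardize_channels z-score each channel over the CET voxels
#'   before clustering (default `TRUE`; CBV, TBR and T1c live on
#'   incommensurate scales).
#' @return An object of class `slic_config`.
#' @export
slic_config <- function(target_size = 200L, compactness = 0.1,
                        max_iterations = 10L, seed = 1L,
                        standardize_channels = TRUE) {
  if (target_size < 8L) stop("target_size must be >= 8 voxels", call. = FALSE)
  if (compactness <= 0) stop("compactness must be positive", call. = FALSE)
  structure(list(target_size = as.integer(target_size),
                 compactness = compactness,
                 max_iterations = as.integer(max_iterations),
                 seed = as.integer(seed),
                 standardize_channels = isTRUE(standardize_channels)),
            class = "slic_config")
}

#' Partition the CET mask into multi-channel-homogeneous supervoxels
#'
#' Masked 3D SLIC: local k-means over the CET voxels only, with the
#' combined distance
#' \deqn{D = \sqrt{d_{int}^2 + (d_{spatial}/S)^2\, m^2},}
#' where \eqn{d_{int}} is the Euclidean distance over the (standardized)
#' channels, \eqn{d_{spatial}} the physical distance in mm (voxel spacing
#' honoured), \eqn{S} the seed grid interval and \eqn{m} the compactness.
#' Seeds start on a regular physical grid inside the mask; after
#' convergence, connectivity is enforced by merging orphan 26-connected
#' fragments into the adjacent supervoxel with the nearest centroid. Ids
#' are canonicalized by ascending centroid order, so identical inputs give
#' an identical id volume.
#'
#' @param channels list of 3 aligned volumes, conventionally
#'   `list(CBV = , PET = , T1c = )`.
#' @param cet_mask logical contrast-enhancing tumor mask.
#' @param config a [slic_config()].
#' @return An object of class `supervoxel_map`: integer `ids` volume
#'   (positive inside CET, 0 outside), `n_supervoxels`, per-id `voxel_counts`
#'   and centroid table.
#' @export
slic_supervoxels <- function(channels, cet_mask, config = slic_config()) {
  stopifnot(inherits(config, "slic_config"))
  do.call(assert_same_grid, c(unname(channels), list(cet_mask)))
  g <- geometry_of(cet_mask)
  idx <- which(cet_mask)
  n <- length(idx)
  if (n == 0L) stop("cet_mask is empty", call. = FALSE)
  feats <- vapply(channels, function(v) as.numeric(v[idx]), numeric(n))
  if (is.null(dim(feats))) feats <- matrix(feats, nrow = n)
  if (config$standardize_channels) {
    feats <- apply(feats, 2L, function(col) {
      s <- stats::sd(col)
      if (!is.finite(s) || s == 0) s <- 1
      (col - mean(col)) / s
    })
    if (is.null(dim(feats))) feats <- matrix(feats, nrow = n)
  }
  coords <- voxel_coords_mm(idx, g)
  if (n < config$target_size) {
    warning("CET mask smaller than target_size; emitting a single supervoxel")
    ids <- array(0L, dim = g$shape)
    ids[idx] <- 1L
    return(new_supervoxel_map(as_volume(ids, g), idx, rep(1L, n), coords))
  }
  k <- max(1L, as.integer(round(n / config$target_size)))
  voxvol <- prod(g$spacing)
  S <- (n * voxvol / k)^(1 / 3)          # seed grid interval, mm
  seeds <- slic_initial_seeds(coords, S, k)
  k <- nrow(seeds$centres)
  cent_sp <- seeds$centres               # k x 3 mm
  cent_ft <- feats[seeds$vox, , drop = FALSE]
  m2_over_S2 <- (config$compactness / S)^2
  assign <- integer(n)
  for (it in seq_len(config$max_iterations)) {
    best_d <- rep(Inf, n)
    assign_new <- integer(n)
    for (c in seq_len(k)) {
      win <- abs(coords[, 1] - cent_sp[c, 1]) <= 2 * S &
        abs(coords[, 2] - cent_sp[c, 2]) <= 2 * S &
        abs(coords[, 3] - cent_sp[c, 3]) <= 2 * S
      w <- which(win)
      if (!length(w)) next
      d_sp2 <- (coords[w, 1] - cent_sp[c, 1])^2 +
        (coords[w, 2] - cent_sp[c, 2])^2 +
        (coords[w, 3] - cent_sp[c, 3])^2
      d_int2 <- rowSums((feats[w, , drop = FALSE] -
                           matrix(cent_ft[c, ], length(w), ncol(feats),
                                  byrow = TRUE))^2)
      D2 <- d_int2 + d_sp2 * m2_over_S2
      upd <- D2 < best_d[w]
      best_d[w[upd]] <- D2[upd]
      assign_new[w[upd]] <- c
    }
    # voxels outside every window: nearest centroid spatially
    orphan <- which(assign_new == 0L)
    if (length(orphan)) {
      for (v in orphan) {
        d2 <- rowSums((cent_sp - matrix(coords[v, ], k, 3, byrow = TRUE))^2)
        assign_new[v] <- which.min(d2)
      }
    }
    if (it > 1L && all(assign_new == assign)) { assign <- assign_new; break }
    assign <- assign_new
    empty <- integer(0)
    for (c in seq_len(k)) {
      mem <- assign == c
      if (any(mem)) {
        cent_sp[c, ] <- colMeans(coords[mem, , drop = FALSE])
        cent_ft[c, ] <- colMeans(feats[mem, , drop = FALSE])
      } else {
        empty <- c(empty, c)
      }
    }
    # empty-cluster repair: reseed at the voxel farthest from the occupied
    # centroids, keeping the supervoxel count near |CET| / target_size
    for (c in empty) {
      occ <- setdiff(seq_len(k), empty)
      if (!length(occ)) break
      dmin <- rep(Inf, n)
      for (oc in occ) {
        d2 <- (coords[, 1] - cent_sp[oc, 1])^2 +
          (coords[, 2] - cent_sp[oc, 2])^2 +
          (coords[, 3] - cent_sp[oc, 3])^2
        dmin <- pmin(dmin, d2)
      }
      v <- which.max(dmin)
      cent_sp[c, ] <- coords[v, ]
      cent_ft[c, ] <- feats[v, ]
      empty <- setdiff(empty, c)
    }
  }
  # drop emptied clusters
  keep <- sort(unique(assign))
  assign <- match(assign, keep)
  cent_sp <- cent_sp[keep, , drop = FALSE]
  assign <- enforce_connectivity(assign, idx, coords, cent_sp, g)
  ids <- array(0L, dim = g$shape)
  ids[idx] <- assign
  new_supervoxel_map(as_volume(ids, g), idx, assign, coords)
}

# seeds on a regular physical grid snapped to the nearest in-mask voxel,
# thinned deterministically to the target count k (hollow or irregular
# masks otherwise overseed relative to their volume)
slic_initial_seeds <- function(coords, S, k) {
  lo <- apply(coords, 2L, min)
  hi <- apply(coords, 2L, max)
  grid_ax <- lapply(1:3, function(a) {
    p <- seq(lo[a] + S / 2, hi[a], by = S)
    if (!length(p)) p <- (lo[a] + hi[a]) / 2
    p
  })
  pts <- as.matrix(expand.grid(grid_ax[[1]], grid_ax[[2]], grid_ax[[3]]))
  vox <- integer(0)
  for (r in seq_len(nrow(pts))) {
    d2 <- (coords[, 1] - pts[r, 1])^2 + (coords[, 2] - pts[r, 2])^2 +
      (coords[, 3] - pts[r, 3])^2
    j <- which.min(d2)
    if (d2[j] <= 3 * (S / 2)^2 && !(j %in% vox)) vox <- c(vox, j)
  }
  if (!length(vox)) {                      # fallback: mask medoid
    mid <- colMeans(coords)
    d2 <- rowSums((coords - matrix(mid, nrow(coords), 3, byrow = TRUE))^2)
    vox <- which.min(d2)
  }
  if (length(vox) > k) {
    # evenly spaced thinning over the raster-ordered candidate list
    vox <- sort(vox)
    vox <- vox[unique(round(seq(1, length(vox), length.out = k)))]
  } else if (length(vox) < k) {
    # hollow or thin masks under-fill the volume-derived grid; top up by
    # deterministic farthest-point sampling so the count still tracks k
    dmin <- rep(Inf, nrow(coords))
    for (v in vox)
      dmin <- pmin(dmin, (coords[, 1] - coords[v, 1])^2 +
                     (coords[, 2] - coords[v, 2])^2 +
                     (coords[, 3] - coords[v, 3])^2)
    while (length(vox) < k) {
      v <- which.max(dmin)
      vox <- c(vox, v)
      dmin <- pmin(dmin, (coords[, 1] - coords[v, 1])^2 +
                     (coords[, 2] - coords[v, 2])^2 +
                     (coords[, 3] - coords[v, 3])^2)
    }
  }
  list(centres = coords[vox, , drop = FALSE], vox = vox)
}

# merge orphan fragments: every 26-connected fragment of a label that is not
# that label's largest fragment is reassigned to the adjacent supervoxel
# with the nearest (spatial) centroid; repeats until the partition is clean
enforce_connectivity <- function(assign, idx, coords, cent_sp, g) {
  sh <- g$shape
  repeat {
    changed <- FALSE
    for (lab in sort(unique(assign))) {
      sel <- which(assign == lab)
      if (length(sel) <= 1L) next
      sub_idx <- idx[sel]
      sub_mask <- array(FALSE, dim = sh)
      sub_mask[sub_idx] <- TRUE
      comp <- connected_components_26(sub_mask, sub_idx)
      if (max(comp) == 1L) next
      # component 1 is the largest (components are labelled largest-first)
      for (fc in 2:max(comp)) {
        frag <- sel[comp == fc]
        nb_labels <- fragment_neighbour_labels(idx[frag], assign, idx, sh)
        nb_labels <- setdiff(nb_labels, lab)
        if (!length(nb_labels)) next      # isolated island: keep as its label
        fcent <- colMeans(coords[frag, , drop = FALSE])
        d2 <- rowSums((cent_sp[nb_labels, , drop = FALSE] -
                         matrix(fcent, length(nb_labels), 3, byrow = TRUE))^2)
        assign[frag] <- nb_labels[which.min(d2)]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  # isolated islands that kept a label also used elsewhere must become their
  # own supervoxel (each id must be connected)
  repeat {
    split_done <- FALSE
    for (lab in sort(unique(assign))) {
      sel <- which(assign == lab)
      sub_idx <- idx[sel]
      sub_mask <- array(FALSE, dim = sh)
      sub_mask[sub_idx] <- TRUE
      comp <- connected_components_26(sub_mask, sub_idx)
      if (max(comp) > 1L) {
        for (fc in 2:max(comp)) {
          newlab <- max(assign) + 1L
          assign[sel[comp == fc]] <- newlab
          cent_sp <- rbind(cent_sp,
                           colMeans(coords[sel[comp == fc], , drop = FALSE]))
        }
        split_done <- TRUE
      }
    }
    if (!split_done) break
  }
  # canonical ids: ascending centroid order (x, then y, then z)
  labs <- sort(unique(assign))
  cents <- t(vapply(labs, function(l)
    colMeans(coords[assign == l, , drop = FALSE]), numeric(3)))
  ord <- order(cents[, 1], cents[, 2], cents[, 3])
  remap <- integer(max(labs))
  remap[labs[ord]] <- seq_along(labs)
  remap[assign]
}

fragment_neighbour_labels <- function(frag_idx, assign, idx, sh) {
  pos <- integer(prod(sh))
  pos[idx] <- seq_along(idx)
  nb <- unlist(lapply(frag_idx, neighbour_indices_26, sh = sh))
  nb_pos <- pos[nb]
  unique(assign[nb_pos[nb_pos > 0L]])
}

new_supervoxel_map <- function(ids, idx, assign, coords) {
  counts <- tabulate(assign)
  cents <- t(vapply(seq_along(counts), function(l) {
    m <- assign == l
    colMeans(coords[m, , drop = FALSE])
  }, numeric(3)))
  structure(list(ids = ids, n_supervoxels = length(counts),
                 voxel_counts = counts,
                 centroids_mm = cents),
            class = "supervoxel_map")
}

#' @export
print.supervoxel_map <- function(x, ...) {
  cat(sprintf("<supervoxel_map> %d supervoxels over %d voxels (mean size %.1f)\n",
              x$n_supervoxels, sum(x$voxel_counts),
              mean(x$voxel_counts)))
  invisible(x)
}

#' Majority response label per supervoxel
#'
#' Each supervoxel is assigned the follow-up label (TP or PsP) held by the
#' majority of its voxels; exact ties go to TP (conservative toward not
#' missing progression; documented and deliberate).
#'
#' @param svx a [slic_supervoxels()] map.
#' @param labels a `response_labels` map covering the same CET.
#' @return A data frame with one row per supervoxel id: `svx_id`,
#'   `n_voxels`, `n_tp`, `n_psp`, `label` (`"TP"`/`"PsP"`) and
#'   `majority_fraction`.
#' @export
majority_label <- function(svx, labels) {
  stopifnot(inherits(svx, "supervoxel_map"),
            inherits(labels, "response_labels"))
  assert_same_grid(svx$ids, labels$labels)
  idx <- which(svx$ids > 0L)
  ids <- svx$ids[idx]
  lab <- labels$labels[idx]
  if (any(lab == 0L))
    stop("response labels do not cover every supervoxel voxel", call. = FALSE)
  n_tp <- tapply(lab == 1L, ids, sum)
  n_psp <- tapply(lab == 2L, ids, sum)
  ord <- order(as.integer(names(n_tp)))
  n_tp <- as.integer(n_tp[ord]); n_psp <- as.integer(n_psp[ord])
  total <- n_tp + n_psp
  stopifnot(all(total > 0L))
  is_tp <- n_tp >= n_psp                  # tie -> TP
  data.frame(svx_id = seq_along(total),
             n_voxels = total,
             n_tp = n_tp, n_psp = n_psp,
             label = ifelse(is_tp, "TP", "PsP"),
             majority_fraction = pmax(n_tp, n_psp) / total,
             stringsAsFactors = FALSE)
}
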