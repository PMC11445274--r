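#' Voxel-grid geometry
#'
#' All volumes handled by this package live on a common rectilinear voxel
#' grid described by a shape (voxels per axis) and a physical spacing in mm
#' per axis. After co-registration every channel and mask of a case shares
#' one geometry; functions validate this before combining volumes.
#'
#' @param shape integer vector of length 3, voxels per axis. Cohort grids
#'   require at least 8 voxels per axis (enforced by [cohort_config()]);
#'   small scratch grids are allowed here.
#' @param spacing numeric vector of length 3, voxel edge length in mm
#'   (each > 0). Anisotropic grids (e.g. 1.75 x 1.75 x 4 mm DSC) are
#'   supported; all physical distances in the package honour the spacing.
#' @return An object of class `vox_geometry`.
#' @export
#' @examples
#' vox_geometry(c(64, 64, 64), c(2, 2, 2))
vox_geometry <- function(shape, spacing = c(1, 1, 1)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  if (length(shape) != 3L || length(spacing) != 3L)
    stop("shape and spacing must each have length 3", call. = FALSE)
  if (any(shape < 1L))
    stop("all shape entries must be positive", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("all spacings must be positive", call. = FALSE)
  structure(list(shape = shape, spacing = spacing), class = "vox_geometry")
}

#' @export
print.vox_geometry <- function(x, ...) {
  cat(sprintf("<vox_geometry> %d x %d x %d voxels @ %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Attach a geometry to a 3D array
#'
#' @param x numeric or integer 3D array.
#' @param geometry a [vox_geometry()].
#' @return `x` with the geometry stored in its attributes.
#' @export
as_volume <- function(x, geometry) {
  stopifnot(inherits(geometry, "vox_geometry"))
  if (length(dim(x)) != 3L || !all(dim(x) == geometry$shape))
    stop("array dimensions do not match geometry shape", call. = FALSE)
  attr(x, "geometry") <- geometry
  x
}

#' Recover the geometry of a volume
#'
#' @param x a volume created by [as_volume()] or read by [read_volume()].
#' @param default geometry to assume when `x` carries none (unit spacing).
#' @return A `vox_geometry`.
#' @export
geometry_of <- function(x, default = NULL) {
  g <- attr(x, "geometry")
  if (!is.null(g)) return(g)
  if (!is.null(default)) return(default)
  if (length(dim(x)) != 3L) stop("not a 3D volume", call. = FALSE)
  vox_geometry(dim(x), c(1, 1, 1))
}

#' @rdname geometry_of
#' @export
spacing_of <- function(x) geometry_of(x)$spacing

#' Check that volumes share one grid
#'
#' @param ... volumes (3D arrays, optionally with geometry attributes).
#' @return `TRUE` invisibly; errors listing shapes/spacings on mismatch.
#' @export
assert_same_grid <- function(...) {
  vols <- list(...)
  if (length(vols) < 2L) return(invisible(TRUE))
  g1 <- geometry_of(vols[[1]])
  for (i in seq_along(vols)[-1]) {
    gi <- geometry_of(vols[[i]])
    if (!all(gi$shape == g1$shape) || !isTRUE(all.equal(gi$spacing, g1$spacing)))
      stop(sprintf(
        "geometry mismatch: volume 1 is %s @ %s mm but volume %d is %s @ %s mm",
        paste(g1$shape, collapse = "x"), paste(signif(g1$spacing, 4), collapse = "x"),
        i, paste(gi$shape, collapse = "x"), paste(signif(gi$spacing, 4), collapse = "x")),
        call. = FALSE)
  }
  invisible(TRUE)
}

# mm coordinates of voxel centres, one row per voxel of `idx` (linear indices)
voxel_coords_mm <- function(idx, geometry) {
  sh <- geometry$shape
  sp <- geometry$spacing
  idx0 <- idx - 1L
  i <- idx0 %% sh[1]
  j <- (idx0 %/% sh[1]) %% sh[2]
  k <- idx0 %/% (sh[1] * sh[2])
  cbind((i + 0.5) * sp[1], (j + 0.5) * sp[2], (k + 0.5) * sp[3])
}

# 3D array of squared mm distance to a centre point (mm)
dist2_to_point <- function(geometry, centre_mm) {
  sh <- geometry$shape
  sp <- geometry$spacing
  dx <- ((seq_len(sh[1]) - 0.5) * sp[1] - centre_mm[1])^2
  dy <- ((seq_len(sh[2]) - 0.5) * sp[2] - centre_mm[2])^2
  dz <- ((seq_len(sh[3]) - 0.5) * sp[3] - centre_mm[3])^2
  outer(outer(dx, dy, `+`), dz, `+`)
}

# Separable Gaussian smoothing with physical sigma (mm); kernel truncated at
# 3 sigma per axis and renormalised so a constant volume is preserved.
gaussian_smooth <- function(vol, sigma_mm, geometry = geometry_of(vol)) {
  if (sigma_mm <= 0) return(vol)
  sh <- geometry$shape
  sp <- geometry$spacing
  a <- as.array(vol)
  attributes(a) <- list(dim = sh)
  smooth_axis <- function(arr, ax) {
    n <- sh[ax]
    off <- (seq_len(n) - 1) * sp[ax]
    K <- stats::dnorm(outer(off, off, `-`), sd = sigma_mm)
    K[abs(outer(off, off, `-`)) > 3 * sigma_mm] <- 0
    K <- K / rowSums(K)
    if (ax == 1L) {
      array(K %*% matrix(arr, nrow = n), dim = sh)
    } else {
      perm <- seq_len(3L)
      perm[c(1L, ax)] <- perm[c(ax, 1L)]
      m <- aperm(arr, perm)
      dm <- dim(m)
      m <- array(K %*% matrix(m, nrow = n), dim = dm)
      aperm(m, perm)
    }
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  as_volume(a, geometry)
}

# Zero-mean, unit-variance spatially correlated Gaussian field (draws from
# the ambient RNG stream; callers manage seeding).
smoothed_unit_field <- function(geometry, scale_mm) {
  f <- array(stats::rnorm(prod(geometry$shape)), dim = geometry$shape)
  f <- gaussian_smooth(as_volume(f, geometry), scale_mm)
  s <- stats::sd(f)
  if (s < .Machine$double.eps) s <- 1
  as_volume((f - mean(f)) / s, geometry)
}

# Binary dilation of a mask by a physical radius (mm), via distance to the
# mask surface evaluated on a local neighbourhood stencil.
dilate_mm <- function(mask, radius_mm, geometry = geometry_of(mask)) {
  if (radius_mm <= 0) return(mask)
  sp <- geometry$spacing
  sh <- geometry$shape
  r_vox <- ceiling(radius_mm / sp)
  out <- array(FALSE, dim = sh)
  offs <- expand.grid(dx = -r_vox[1]:r_vox[1], dy = -r_vox[2]:r_vox[2],
                      dz = -r_vox[3]:r_vox[3])
  d2 <- (offs$dx * sp[1])^2 + (offs$dy * sp[2])^2 + (offs$dz * sp[3])^2
  offs <- offs[d2 <= radius_mm^2, , drop = FALSE]
  m <- as.array(mask); attributes(m) <- list(dim = sh)
  for (r in seq_len(nrow(offs))) {
    dx <- offs$dx[r]; dy <- offs$dy[r]; dz <- offs$dz[r]
    xs <- max(1, 1 - dx):min(sh[1], sh[1] - dx)
    ys <- max(1, 1 - dy):min(sh[2], sh[2] - dy)
    zs <- max(1, 1 - dz):min(sh[3], sh[3] - dz)
    out[xs + dx, ys + dy, zs + dz] <- out[xs + dx, ys + dy, zs + dz] |
      m[xs, ys, zs]
  }
  as_volume(out, geometry)
}

# 26-connected components over the TRUE voxels of a mask (or over a subset
# of linear indices). Returns an integer vector of component ids parallel to
# `idx`, labelled 1..n_components in decreasing size order.
connected_components_26 <- function(mask, idx = which(mask)) {
  if (length(idx) == 0L) return(integer(0))
  sh <- dim(mask)
  pos <- integer(prod(sh))
  pos[idx] <- seq_along(idx)
  idx0 <- idx - 1L
  ci <- idx0 %% sh[1]
  cj <- (idx0 %/% sh[1]) %% sh[2]
  ck <- idx0 %/% (sh[1] * sh[2])
  edges_from <- integer(0)
  edges_to <- integer(0)
  for (dx in -1:1) for (dy in -1:1) for (dz in 0:1) {
    if (dz == 0 && (dx < 0 || (dx == 0 && dy <= 0))) next  # half stencil
    ni <- ci + dx; nj <- cj + dy; nk <- ck + dz
    ok <- ni >= 0 & ni < sh[1] & nj >= 0 & nj < sh[2] & nk >= 0 & nk < sh[3]
    nidx <- ni[ok] + sh[1] * (nj[ok] + sh[2] * nk[ok]) + 1L
    tgt <- pos[nidx]
    keep <- tgt > 0L
    edges_from <- c(edges_from, pos[idx][ok][keep])
    edges_to <- c(edges_to, tgt[keep])
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (length(edges_from))
    g <- igraph::add_edges(g, rbind(edges_from, edges_to))
  comp <- igraph::components(g)$membership
  # relabel components largest-first for stable downstream behaviour
  sizes <- tabulate(comp)
  rank <- integer(length(sizes))
  rank[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  rank[comp]
}
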