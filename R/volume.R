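# Volume data model and geometry.
#
# Convention (documented once, asserted in the I/O tests):
#   * arrays are indexed [z, y, x] where z is the stack page, y the image row,
#     x the image column;
#   * physical coordinates are in micrometres, given in the same (z, y, x)
#     order, with the centre of voxel (0,0,0) at `origin` (0-based voxel
#     indices, voxel-centred coordinates);
#   * grey values are kept as doubles during analysis and only rounded/clamped
#     to the 16-bit range when written to TIFF.

#' Construct a grey-level volume
#'
#' @param values 3D numeric array indexed `[z, y, x]` (z = stack page, y = row,
#'   x = column); grey levels are an uncalibrated mineral-density proxy.
#' @param voxel_size voxel edge in micrometres; a single number (isotropic,
#'   default 7) or a length-3 vector in (z, y, x) order.
#' @param origin physical coordinate (um, (z, y, x)) of the centre of voxel
#'   (0, 0, 0); default `c(0, 0, 0)`.
#' @return object of class `grey_volume`.
#' @export
grey_volume <- function(values, voxel_size = 7, origin = c(0, 0, 0)) {
  if (!is.array(values) || length(dim(values)) != 3L) {
    stop("`values` must be a 3D array indexed [z, y, x]", call. = FALSE)
  }
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("`voxel_size` must be positive (um per axis)", call. = FALSE)
  }
  if (length(origin) != 3L || any(!is.finite(origin))) {
    stop("`origin` must be a finite physical point (z, y, x) in um", call. = FALSE)
  }
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "grey_volume"
  )
}

#' @export
print.grey_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("grey_volume: %d x %d x %d voxels [z,y,x], voxel %s um, origin (%s) um\n",
              d[1], d[2], d[3],
              paste(format(x$voxel_size), collapse = " x "),
              paste(format(x$origin), collapse = ", ")))
  invisible(x)
}

#' @export
dim.grey_volume <- function(x) dim(x$values)

# physical extent [lo, hi] per axis (voxel-centre bounds)
vol_bounds <- function(vol) {
  d <- dim(vol$values)
  lo <- vol$origin
  hi <- vol$origin + (d - 1) * vol$voxel_size
  rbind(lo = lo, hi = hi)
}

point_inside <- function(vol, pt, tol = 1e-9) {
  b <- vol_bounds(vol)
  all(pt >= b["lo", ] - tol) && all(pt <= b["hi", ] + tol)
}

# Trilinear interpolation of `vol` at physical points `pts` (n x 3, um,
# (z,y,x)). Points outside the voxel-centre hull get `fill` (or error when
# fill = NA and error_outside = TRUE).
vol_interp <- function(vol, pts, fill = 0, error_outside = FALSE) {
  d <- dim(vol$values)
  g <- sweep(sweep(pts, 2L, vol$origin, "-"), 2L, vol$voxel_size, "/")
  eps <- 1e-9
  inside <- g[, 1] >= -eps & g[, 1] <= d[1] - 1 + eps &
    g[, 2] >= -eps & g[, 2] <= d[2] - 1 + eps &
    g[, 3] >= -eps & g[, 3] <= d[3] - 1 + eps
  if (error_outside && !all(inside)) {
    bad <- pts[which(!inside)[1L], ]
    stopf("point (%g, %g, %g) um lies outside the volume", bad[1], bad[2], bad[3])
  }
  out <- rep(fill, nrow(pts))
  if (!any(inside)) return(out)
  g <- g[inside, , drop = FALSE]
  g <- pmin(pmax(g, 0), matrix(d - 1, nrow(g), 3L, byrow = TRUE))
  i0 <- pmin(floor(g), matrix(d - 2L, nrow(g), 3L, byrow = TRUE))
  i0 <- pmax(i0, 0)
  f <- g - i0
  v <- vol$values
  acc <- numeric(nrow(g))
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    w <- (if (dz) f[, 1] else 1 - f[, 1]) *
      (if (dy) f[, 2] else 1 - f[, 2]) *
      (if (dx) f[, 3] else 1 - f[, 3])
    idx <- cbind(i0[, 1] + dz, i0[, 2] + dy, i0[, 3] + dx) + 1L
    acc <- acc + w * v[idx]
  }
  out[inside] <- acc
  out
}

#' Extract a grey-level transect between two landmarks
#'
#' Samples the volume by trilinear interpolation along the straight line from
#' `surface_pt` to `dej_pt`, at every voxel-size step; both endpoints are
#' always sampled (a final sample is appended when the length is not an exact
#' multiple of the step). With `width_um > edge`, a bundle of parallel lines is
#' averaged (emulating a wide-line plot profile): lines are offset at
#' voxel-size spacing along `width_axis`, the volume axis most orthogonal to
#' the transect direction by default.
#'
#' @param vol a [grey_volume()].
#' @param surface_pt,dej_pt physical points (um, (z, y, x)); the transect runs
#'   surface -> DEJ.
#' @param width_um full width of the averaged line bundle in um; default 0
#'   (single line).
#' @param width_axis axis index (1 = z, 2 = y, 3 = x) for the lateral offsets,
#'   or `NULL` to pick the axis with the smallest direction component.
#' @return object of class `transect`: list with `start` (surface), `end`
#'   (DEJ), `samples`, `step` (um), `length_um`, `start_label`, `end_label`,
#'   `width_um`.
#' @export
extract_transect <- function(vol, surface_pt, dej_pt, width_um = 0,
                             width_axis = NULL) {
  stopifnot(inherits(vol, "grey_volume"))
  surface_pt <- as.numeric(surface_pt); dej_pt <- as.numeric(dej_pt)
  if (length(surface_pt) != 3L || length(dej_pt) != 3L) {
    stop("landmark points must be physical (z, y, x) coordinates in um", call. = FALSE)
  }
  for (pt in list(surface_pt, dej_pt)) {
    if (!point_inside(vol, pt)) {
      stopf("point (%g, %g, %g) um lies outside the volume", pt[1], pt[2], pt[3])
    }
  }
  L <- sqrt(sum((dej_pt - surface_pt)^2))
  if (L == 0) stop("coincident landmark points: transect undefined", call. = FALSE)
  step <- vol$voxel_size[[1L]]
  if (length(unique(vol$voxel_size)) != 1L) {
    stop("transect sampling assumes isotropic voxels", call. = FALSE)
  }
  t_pos <- seq(0, L, by = step)
  if (max(t_pos) < L - 1e-9) t_pos <- c(t_pos, L)  # endpoint always sampled
  dir <- (dej_pt - surface_pt) / L

  offsets <- 0
  ax <- NULL
  if (width_um > step) {
    ax <- if (is.null(width_axis)) which.min(abs(dir)) else as.integer(width_axis)
    half <- (width_um - step) / 2
    offsets <- seq(-step * floor(half / step), step * floor(half / step), by = step)
  }
  samples <- numeric(length(t_pos))
  for (off in offsets) {
    o <- c(0, 0, 0); if (!is.null(ax)) o[ax] <- off
    pts <- cbind(surface_pt[1] + t_pos * dir[1] + o[1],
                 surface_pt[2] + t_pos * dir[2] + o[2],
                 surface_pt[3] + t_pos * dir[3] + o[3])
    samples <- samples + vol_interp(vol, pts, error_outside = TRUE)
  }
  samples <- samples / length(offsets)

  structure(
    list(start = surface_pt, end = dej_pt, samples = samples, step = step,
         length_um = L, start_label = "surface", end_label = "dej",
         width_um = width_um),
    class = "transect"
  )
}

#' @export
print.transect <- function(x, ...) {
  cat(sprintf("transect %s -> %s: %.1f um, %d samples at %g um step\n",
              x$start_label, x$end_label, x$length_um, length(x$samples), x$step))
  invisible(x)
}

#' Reslice a volume to the cervical plane of section
#'
#' Resamples the volume so its first axis is normal to the plane through three
#' landmark points (two on the buccal cervical surface, one on the lingual
#' cervical surface), emulating reconstruction of slices parallel to the
#' cervical plane. Grey values are obtained by trilinear interpolation; voxel
#' size and array shape are preserved; the output grid is centred on the input
#' volume's physical centre. Voxels falling outside the input are filled with
#' `fill`.
#'
#' The orthonormal frame is deterministic: axis 1 is the plane normal (sign
#' fixed so its largest-magnitude component is positive), axis 2 the direction
#' `p_buccal2 - p_buccal1`, axis 3 their cross product.
#'
#' @param vol a [grey_volume()].
#' @param p_buccal1,p_buccal2,p_lingual physical points (um, (z, y, x)) inside
#'   the volume, non-collinear.
#' @param fill value for output voxels outside the input volume; default 0.
#' @return a [grey_volume()] with the same shape and voxel size, origin 0.
#' @export
reslice_to_plane <- function(vol, p_buccal1, p_buccal2, p_lingual, fill = 0) {
  stopifnot(inherits(vol, "grey_volume"))
  p1 <- as.numeric(p_buccal1); p2 <- as.numeric(p_buccal2); p3 <- as.numeric(p_lingual)
  for (pt in list(p1, p2, p3)) {
    if (length(pt) != 3L || !point_inside(vol, pt)) {
      stop("plane landmarks must be physical points inside the volume", call. = FALSE)
    }
  }
  v1 <- p2 - p1
  v2 <- p3 - p1
  n <- cross3(v1, v2)
  scale <- sqrt(sum(v1^2)) * sqrt(sum(v2^2))
  if (scale == 0 || sqrt(sum(n^2)) < 1e-9 * scale) {
    stop("degenerate plane: landmarks are collinear or coincident", call. = FALSE)
  }
  n <- n / sqrt(sum(n^2))
  k <- which.max(abs(n))
  if (n[k] < 0) n <- -n
  e1 <- v1 / sqrt(sum(v1^2))
  e2 <- cross3(n, e1)

  d <- dim(vol$values)
  vs <- vol$voxel_size[[1L]]
  centre <- vol$origin + (d - 1) / 2 * vol$voxel_size
  ci <- (seq_len(d[1]) - 1) - (d[1] - 1) / 2
  cj <- (seq_len(d[2]) - 1) - (d[2] - 1) / 2
  ck <- (seq_len(d[3]) - 1) - (d[3] - 1) / 2
  # full grid of output voxel coordinates in the input frame
  I <- rep(ci, times = d[2] * d[3])
  J <- rep(rep(cj, each = d[1]), times = d[3])
  K <- rep(ck, each = d[1] * d[2])
  pts <- cbind(
    centre[1] + vs * (I * n[1] + J * e1[1] + K * e2[1]),
    centre[2] + vs * (I * n[2] + J * e1[2] + K * e2[2]),
    centre[3] + vs * (I * n[3] + J * e1[3] + K * e2[3])
  )
  vals <- vol_interp(vol, pts, fill = fill)
  out <- array(vals, dim = d)
  grey_volume(out, voxel_size = vol$voxel_size, origin = c(0, 0, 0))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
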