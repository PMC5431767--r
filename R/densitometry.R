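# 3D densitometry: five analysis cubes per transect, paired normal/discoloured
# mean grey levels over two measurement rounds, the mineral-density-difference
# (mdd) table, and the per-tooth paired Wilcoxon test.

#' Place five analysis cubes along a transect
#'
#' Cube 1 sits at the enamel surface, cube 5 at the DEJ, cube 3 midway between
#' them, cube 2 midway between 1 and 3 and cube 4 midway between 3 and 5 —
#' i.e. unclamped centres at fractions 0, 1/4, 1/2, 3/4, 1 of the
#' surface-to-DEJ transect. Each centre is then clamped so that every voxel
#' centre covered by its cube lies within the transect span (the end cubes
#' must sit fully inside enamel to be measurable).
#'
#' @param transect a [extract_transect()] result (surface -> DEJ).
#' @param edge cube edge in um; default 49 (7 voxels at 7 um).
#' @return object of class `cube_set`: data.frame with `cube` (1 = surface
#'   ... 5 = DEJ), `t_um` (position along the transect), `z/y/x` centre
#'   coordinates (um); attribute `edge`.
#' @export
place_cubes <- function(transect, edge = 49) {
  stopifnot(inherits(transect, "transect"))
  L <- transect$length_um
  if (L < edge) {
    stopf("transect (%g um) is shorter than one cube edge (%g um)", L, edge)
  }
  half <- (edge - transect$step) / 2  # covered voxel centres must stay in span
  t_pos <- pmin(pmax(c(0, 0.25, 0.5, 0.75, 1) * L, half), L - half)
  dir <- (transect$end - transect$start) / L
  centers <- cbind(
    transect$start[1] + t_pos * dir[1],
    transect$start[2] + t_pos * dir[2],
    transect$start[3] + t_pos * dir[3]
  )
  out <- data.frame(cube = 1:5, t_um = t_pos,
                    z = centers[, 1], y = centers[, 2], x = centers[, 3])
  attr(out, "edge") <- edge
  class(out) <- c("cube_set", "data.frame")
  out
}

#' Mean grey level inside an axis-aligned cube
#'
#' Arithmetic mean of all voxels whose centres fall inside the closed
#' axis-aligned cube of side `edge` centred at `center`.
#'
#' @param vol a [grey_volume()].
#' @param center physical cube centre (um, (z, y, x)).
#' @param edge cube edge, um.
#' @return mean grey level (double).
#' @export
cube_mean <- function(vol, center, edge = 49) {
  stopifnot(inherits(vol, "grey_volume"))
  center <- as.numeric(center)
  d <- dim(vol$values)
  tol <- 1e-9 * edge
  lo <- ceiling((center - edge / 2 - vol$origin) / vol$voxel_size - tol)
  hi <- floor((center + edge / 2 - vol$origin) / vol$voxel_size + tol)
  if (any(lo < 0) || any(hi > d - 1)) {
    stopf("cube at (%g, %g, %g) um with edge %g um extends outside the volume",
          center[1], center[2], center[3], edge)
  }
  mean(vol$values[(lo[1] + 1):(hi[1] + 1),
                  (lo[2] + 1):(hi[2] + 1),
                  (lo[3] + 1):(hi[3] + 1)])
}

#' Paired five-cube densitometry over two measurement rounds
#'
#' For each of two analysis rounds, places five cubes on a normal-area and a
#' discoloured-area transect (taken at the same coronal height), measures mean
#' grey levels, forms the ten mineral density differences
#' `mdd = normal - discoloured`, and tests them against zero with a two-sided
#' Wilcoxon signed-rank test. The ten values from both rounds are pooled into
#' a single per-tooth test. A result is flagged significant when p < 0.05.
#'
#' @param vol a [grey_volume()].
#' @param normal_transects,discoloured_transects lists of exactly two
#'   [extract_transect()] results (rounds 1 and 2).
#' @param edge cube edge, um; default 49.
#' @param method Wilcoxon method, `"normal_approx"` (default) or `"exact"`.
#' @param tooth_id optional label.
#' @return object of class `mdd_table`: list with `tooth_id`, `table`
#'   (data.frame `round`, `cube`, `normal_GL`, `discoloured_GL`, `mdd`),
#'   `mdd`, `p_value`, `significant`, `test` (a `wilcoxon_result`, or `NULL`
#'   with `label = "no difference"` when every mdd is zero), `heights`
#'   (recorded transect start points).
#' @export
paired_cube_analysis <- function(vol, normal_transects, discoloured_transects,
                                 edge = 49, method = "normal_approx",
                                 tooth_id = NULL) {
  if (length(normal_transects) != 2L || length(discoloured_transects) != 2L) {
    stop("exactly 2 analysis rounds are required for each area", call. = FALSE)
  }
  rows <- list()
  for (r in 1:2) {
    cn <- place_cubes(normal_transects[[r]], edge)
    cd <- place_cubes(discoloured_transects[[r]], edge)
    for (k in 1:5) {
      n_gl <- cube_mean(vol, unlist(cn[k, c("z", "y", "x")]), edge)
      d_gl <- cube_mean(vol, unlist(cd[k, c("z", "y", "x")]), edge)
      rows[[length(rows) + 1L]] <- data.frame(
        round = r, cube = k, normal_GL = n_gl, discoloured_GL = d_gl,
        mdd = n_gl - d_gl
      )
    }
  }
  tab <- do.call(rbind, rows)
  mdd <- tab$mdd

  if (all(mdd == 0)) {
    res <- list(tooth_id = tooth_id, table = tab, mdd = mdd,
                p_value = NA_real_, significant = FALSE, test = NULL,
                label = "no difference",
                heights = lapply(c(normal_transects, discoloured_transects),
                                 `[[`, "start"))
  } else {
    test <- wilcoxon_signed_rank(mdd, method = method)
    res <- list(tooth_id = tooth_id, table = tab, mdd = mdd,
                p_value = test$p_two_sided,
                significant = test$p_two_sided < 0.05, test = test,
                label = NULL,
                heights = lapply(c(normal_transects, discoloured_transects),
                                 `[[`, "start"))
  }
  class(res) <- "mdd_table"
  res
}

#' @export
print.mdd_table <- function(x, ...) {
  cat("Paired cube densitometry",
      if (!is.null(x$tooth_id)) sprintf("(%s)", x$tooth_id) else "", "\n")
  m <- matrix(x$mdd, nrow = 2, byrow = TRUE,
              dimnames = list(c("round 1", "round 2"), paste0("mdd", 1:5)))
  print(round(m, 1))
  if (!is.null(x$label)) {
    cat("  ", x$label, "\n")
  } else {
    cat(sprintf("  two-sided p = %.3f%s\n", x$p_value,
                if (x$significant) " *" else ""))
  }
  invisible(x)
}

#' @export
as.data.frame.mdd_table <- function(x, ...) x$table
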