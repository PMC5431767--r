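# 2D analysis: DEJ-to-surface density line profiles resampled to 99
# equidistant points, lesion/normal deficit curves, and gradient-direction
# classification (normal enamel density rises DEJ -> surface; hypomineralised
# enamel shows the reverse gradient).

#' Resample a transect to a 99-point DEJ-to-surface density profile
#'
#' Linearly interpolates the raw grey-level samples at 99 equidistant
#' positions; endpoints are preserved exactly. The output is always ordered
#' DEJ (point 1, u = 0) to surface (point 99, u = 1), reversing the raw
#' samples when the transect was recorded surface-first.
#'
#' @param raw a [extract_transect()] result (>= 2 samples).
#' @param n number of equidistant points; default 99.
#' @return object of class `density_profile`: list with `values` (length
#'   `n`), `positions` (normalised u, 0 = DEJ, 1 = surface), `source`
#'   metadata.
#' @export
resample_profile <- function(raw, n = 99) {
  stopifnot(inherits(raw, "transect"))
  s <- raw$samples
  if (length(s) < 2L) stop("need at least 2 raw samples to resample", call. = FALSE)
  t_pos <- seq(0, raw$length_um, by = raw$step)
  if (max(t_pos) < raw$length_um - 1e-9) t_pos <- c(t_pos, raw$length_um)
  if (length(t_pos) != length(s)) {
    stop("transect samples do not match the native sampling grid", call. = FALSE)
  }
  # orient DEJ -> surface; sample positions are re-derived, not just reversed,
  # because the appended endpoint makes the reversed grid non-uniform
  pos_dej <- if (identical(raw$start_label, "surface")) raw$length_um - t_pos else t_pos
  o <- order(pos_dej)
  x_rel <- pos_dej[o] / raw$length_um
  y <- s[o]
  u <- seq(0, 1, length.out = n)
  values <- stats::approx(x_rel, y, xout = u, rule = 2)$y
  values[1L] <- y[1L]; values[n] <- y[length(y)]  # endpoints exact
  structure(
    list(values = values, positions = u,
         source = list(length_um = raw$length_um, step = raw$step,
                       width_um = raw$width_um)),
    class = "density_profile"
  )
}

#' @export
print.density_profile <- function(x, ...) {
  cat(sprintf("density profile: %d points DEJ -> surface, GL %.0f .. %.0f\n",
              length(x$values), x$values[1], x$values[length(x$values)]))
  invisible(x)
}

#' Least-squares gradient direction of a density profile
#'
#' Fits grey level against normalised position u by least squares and computes
#' the Spearman rank correlation. Labels: `reversed` when slope < 0 and rank
#' correlation <= -`rank_threshold`; `increasing` when slope > 0 and rank
#' correlation >= `rank_threshold`; otherwise `flat`. The rank-correlation
#' guard keeps weak/noisy trends out of the two directional classes.
#'
#' @param profile a [resample_profile()] result.
#' @param rank_threshold absolute Spearman correlation needed for a
#'   directional label; default 0.3.
#' @return object of class `gradient_result`: list with `slope` (grey level
#'   per unit u), `rank_corr`, `label`.
#' @export
gradient_direction <- function(profile, rank_threshold = 0.3) {
  stopifnot(inherits(profile, "density_profile"))
  u <- profile$positions
  v <- profile$values
  slope <- if (stats::var(u) == 0) 0 else stats::cov(u, v) / stats::var(u)
  rank_corr <- if (stats::var(v) == 0) 0 else
    suppressWarnings(stats::cor(v, u, method = "spearman"))
  if (is.na(rank_corr)) rank_corr <- 0
  label <- if (slope < 0 && rank_corr <= -rank_threshold) "reversed"
  else if (slope > 0 && rank_corr >= rank_threshold) "increasing"
  else "flat"
  structure(list(slope = slope, rank_corr = rank_corr, label = label),
            class = "gradient_result")
}

#' @export
print.gradient_result <- function(x, ...) {
  cat(sprintf("gradient: %s (slope %.1f GL/u, rank corr %.2f)\n",
              x$label, x$slope, x$rank_corr))
  invisible(x)
}

#' Compare a lesion density profile against its normal reference
#'
#' Computes the pointwise fractional deficit `(normal - lesion) / normal`, its
#' maximum, its mean over the mid-enamel window, and the gradient direction of
#' both profiles. Both profiles must be sampled at the same positions.
#'
#' @param normal,lesion [resample_profile()] results (normal values must be
#'   strictly positive).
#' @param mid_window integer indices of the mid-enamel window; default
#'   `45:55` (u in roughly 0.45-0.55, symmetric about the DEJ-surface
#'   midpoint).
#' @return object of class `profile_comparison`: list with `deficit_curve`,
#'   `positions`, `max_deficit`, `mid_deficit`, `gradient_normal`,
#'   `gradient_lesion`, `mid_window`.
#' @export
compare_profiles <- function(normal, lesion, mid_window = 45:55) {
  stopifnot(inherits(normal, "density_profile"), inherits(lesion, "density_profile"))
  if (length(normal$values) != length(lesion$values)) {
    stop("profiles must have the same number of points", call. = FALSE)
  }
  if (any(normal$values <= 0)) {
    stop("normal profile has non-positive values: deficit undefined", call. = FALSE)
  }
  if (any(mid_window < 1) || any(mid_window > length(normal$values))) {
    stop("`mid_window` indices out of range", call. = FALSE)
  }
  deficit <- (normal$values - lesion$values) / normal$values
  structure(
    list(deficit_curve = deficit, positions = normal$positions,
         max_deficit = max(deficit), mid_deficit = mean(deficit[mid_window]),
         gradient_normal = gradient_direction(normal),
         gradient_lesion = gradient_direction(lesion),
         mid_window = mid_window),
    class = "profile_comparison"
  )
}

#' @export
print.profile_comparison <- function(x, ...) {
  cat(sprintf("profile comparison: mid-enamel deficit %.1f%%, max %.1f%%\n",
              100 * x$mid_deficit, 100 * x$max_deficit))
  cat("  normal:", x$gradient_normal$label,
      " lesion:", x$gradient_lesion$label, "\n")
  invisible(x)
}

#' @export
as.data.frame.profile_comparison <- function(x, ...) {
  data.frame(point = seq_along(x$deficit_curve), u = x$positions,
             deficit = x$deficit_curve)
}

#' Plot normal and lesion profiles (DEJ left, surface right)
#'
#' @param normal,lesion [resample_profile()] results.
#' @param main plot title.
#' @return invisibly `NULL`; draws on the current device.
#' @export
plot_profiles <- function(normal, lesion, main = "Mineral density profiles") {
  ylim <- range(normal$values, lesion$values)
  graphics::plot(normal$positions, normal$values, type = "l", col = "blue",
                 lwd = 2, ylim = ylim, xlab = "normalised position (DEJ -> surface)",
                 ylab = "grey level", main = main)
  graphics::lines(lesion$positions, lesion$values, col = "red", lwd = 2)
  graphics::legend("bottomright", legend = c("normal", "discoloured"),
                   col = c("blue", "red"), lwd = 2, bty = "n")
  invisible(NULL)
}
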