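# Synthetic enamel phantoms with known ground truth.
#
# Geometry: a flat enamel slab. The x axis runs from the dento-enamel junction
# (DEJ, x = 0) to the outer surface (x = enamel_thickness); the normalised
# depth coordinate is u = x / enamel_thickness, u = 0 at the DEJ and u = 1 at
# the surface. Two parallel bands along y act as the "discoloured" (lesion)
# area and its mirrored "normal" reference area at the same coronal height.
#
# Density model (grey level is an uncalibrated mineral-density proxy):
#   normal enamel   N(u) = dej_grey + (surface_grey - dej_grey) * u   (rising)
#   hypomineralised L(u) = (1 - deficit_mid) * N(1 - u)               (falling)
# L is linear, strictly decreasing (the "reverse gradient"), carries exactly
# deficit_mid fractional deficit at u = 0.5, and stays below N everywhere
# provided (1 - deficit_mid) * surface_grey < dej_grey. Taphonomic staining
# leaves grey levels untouched; acid dissolution removes density only in the
# outer shell u > 1 - dissolution_depth_fraction.

PHANTOM_CLASSES <- c("sound", "hypomineralised", "taphonomic_stain",
                     "hypomineralised_with_uptake", "acid_dissolution")
XRF_ELEMENTS <- c("Mn", "Fe", "Cu", "Pb")

#' Specification of a synthetic enamel phantom
#'
#' @param lesion_class one of `sound`, `hypomineralised`, `taphonomic_stain`,
#'   `hypomineralised_with_uptake`, `acid_dissolution`.
#' @param deficit_mid fractional mineral-density deficit at mid-enamel
#'   (u = 0.5), in `[0, 0.5)`; default 0.07 (the mid-enamel deficit reported
#'   for archaeological hypomineralised lesions; contemporary lesions span
#'   roughly 0.05-0.28).
#' @param voxel_size isotropic voxel edge, um; default 7.
#' @param enamel_thickness DEJ-to-surface thickness, um; default 686
#'   (98 voxel steps, so a transect carries 99 native samples). Must be at
#'   least five cube edges (5 x 7 voxels).
#' @param shape optional `c(nz, ny)` lateral extent in voxels; default
#'   `c(20, 60)`. The x extent is `enamel_thickness / voxel_size + 1`.
#' @param dej_grey,surface_grey noiseless normal-enamel grey level at the DEJ
#'   and surface. Defaults 25000 and 26000: the scale is arbitrary (16-bit
#'   reconstruction), chosen so mid-enamel density differences land in the
#'   10^3-10^4 range of real measurements, and the DEJ->surface rise (4%) is
#'   small enough that a decreasing lesion profile with >= 5% mid deficit
#'   stays below normal enamel over the whole depth.
#' @param dissolution_depth_fraction outer fraction of the depth affected by
#'   acid dissolution, in (0, 1); default 0.25.
#' @param noise_sd additive Gaussian grey-level noise; default 510 (2% of the
#'   mid-enamel grey level).
#' @param lesion_footprint lateral (y) extent of the discoloured band, um;
#'   default 147 (21 voxels, comfortably wider than one analysis cube).
#' @param element_multipliers named per-element (Mn, Fe, Cu, Pb) contamination
#'   factors for the discoloured area, or `NULL` for class defaults: all 1 for
#'   `sound`, `hypomineralised` and `acid_dissolution`; Mn = 10, Fe = 10 for
#'   `taphonomic_stain` and `hypomineralised_with_uptake` (soil staining by Fe
#'   and/or Mn at roughly tenfold enrichment).
#' @param seed integer RNG seed; default 1.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(lesion_class = "hypomineralised",
                         deficit_mid = 0.07,
                         voxel_size = 7,
                         enamel_thickness = 686,
                         shape = c(20, 60),
                         dej_grey = 25000,
                         surface_grey = 26000,
                         dissolution_depth_fraction = 0.25,
                         noise_sd = 510,
                         lesion_footprint = 147,
                         element_multipliers = NULL,
                         seed = 1) {
  lesion_class <- match.arg(lesion_class, PHANTOM_CLASSES)
  if (!is_scalar_num(deficit_mid) || deficit_mid < 0 || deficit_mid >= 0.5) {
    stop("`deficit_mid` must lie in [0, 0.5)", call. = FALSE)
  }
  if (!is_scalar_num(voxel_size) || voxel_size <= 0) {
    stop("`voxel_size` must be a positive length in um", call. = FALSE)
  }
  if (surface_grey <= dej_grey) {
    stop("`surface_grey` must exceed `dej_grey`: normal enamel density rises from DEJ to surface",
         call. = FALSE)
  }
  if (!is_scalar_num(dissolution_depth_fraction) ||
      dissolution_depth_fraction <= 0 || dissolution_depth_fraction >= 1) {
    stop("`dissolution_depth_fraction` must lie in (0, 1)", call. = FALSE)
  }
  min_thickness <- 5 * 7 * voxel_size  # five cube edges of 7 voxels each
  if (enamel_thickness < min_thickness) {
    stopf("degenerate geometry: enamel_thickness = %g um is below the minimum %g um (five %g um cube edges)",
          enamel_thickness, min_thickness, 7 * voxel_size)
  }
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (length(shape) != 2L || any(shape < 4)) {
    stop("`shape` must give c(nz, ny) lateral voxel counts >= 4", call. = FALSE)
  }
  mult <- c(Mn = 1, Fe = 1, Cu = 1, Pb = 1)
  if (is.null(element_multipliers)) {
    if (lesion_class %in% c("taphonomic_stain", "hypomineralised_with_uptake")) {
      mult[c("Mn", "Fe")] <- 10
    }
  } else {
    bad <- setdiff(names(element_multipliers), XRF_ELEMENTS)
    if (length(bad) || is.null(names(element_multipliers))) {
      stopf("unknown element(s) %s; supported elements: %s",
            paste(bad, collapse = ", "), paste(XRF_ELEMENTS, collapse = ", "))
    }
    mult[names(element_multipliers)] <- element_multipliers
  }
  if (lesion_class %in% c("sound", "hypomineralised") && any(mult != 1)) {
    # invariant: no elemental uptake without a post-mortem process
    stop("element_multipliers must all be 1 for class sound and pure hypomineralised",
         call. = FALSE)
  }

  nx <- as.integer(round(enamel_thickness / voxel_size)) + 1L
  ny <- as.integer(shape[2L])
  footprint_vox <- max(3L, as.integer(round(lesion_footprint / voxel_size)))
  if (footprint_vox >= ny / 2) {
    stop("`lesion_footprint` too wide: the lesion and mirrored normal bands must not touch",
         call. = FALSE)
  }
  structure(
    list(lesion_class = lesion_class, deficit_mid = deficit_mid,
         voxel_size = voxel_size, enamel_thickness = enamel_thickness,
         shape = c(as.integer(shape[1L]), ny, nx),
         dej_grey = dej_grey, surface_grey = surface_grey,
         dissolution_depth_fraction = dissolution_depth_fraction,
         noise_sd = noise_sd, lesion_footprint = lesion_footprint,
         element_multipliers = mult, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

# noiseless depth profiles, u in [0, 1]
phantom_normal_profile <- function(spec, u) {
  spec$dej_grey + (spec$surface_grey - spec$dej_grey) * u
}

phantom_lesion_profile <- function(spec, u) {
  N <- phantom_normal_profile
  switch(spec$lesion_class,
    sound = ,
    taphonomic_stain = N(spec, u),
    hypomineralised = ,
    hypomineralised_with_uptake = (1 - spec$deficit_mid) * N(spec, 1 - u),
    acid_dissolution = N(spec, u) *
      (1 - spec$deficit_mid * (u > 1 - spec$dissolution_depth_fraction + 1e-12))
  )
}

# y-index ranges (1-based) of the lesion band and its mirrored normal band
phantom_bands <- function(spec) {
  ny <- spec$shape[2L]
  half <- floor(max(3L, round(spec$lesion_footprint / spec$voxel_size)) / 2)
  c_lesion <- floor(ny / 4) + 1L
  c_normal <- ny - floor(ny / 4)
  list(
    lesion = (c_lesion - half):(c_lesion + half),
    normal = (c_normal - half):(c_normal + half),
    centers = c(lesion = c_lesion, normal = c_normal)
  )
}

#' Generate a synthetic enamel phantom volume with ground truth
#'
#' @param spec a [phantom_spec()].
#' @return a list of class `phantom` with elements
#' \describe{
#'   \item{volume}{[grey_volume()], grey levels as doubles (clamped only on
#'     TIFF export).}
#'   \item{truth}{list: `lesion_mask` (logical array, the discoloured band),
#'     `deficit_field` (per-voxel fractional deficit, 0 outside the mask),
#'     `class_label`, `element_multipliers`, `spec`.}
#' }
#' @examples
#' ph <- generate_phantom(phantom_spec(lesion_class = "hypomineralised",
#'                                     deficit_mid = 0.07, noise_sd = 0))
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$shape
  nz <- d[1L]; ny <- d[2L]; nx <- d[3L]
  u <- (seq_len(nx) - 1) / (nx - 1)
  bands <- phantom_bands(spec)

  n_prof <- phantom_normal_profile(spec, u)
  l_prof <- phantom_lesion_profile(spec, u)

  base_yx <- matrix(rep(n_prof, each = ny), nrow = ny, ncol = nx)
  base_yx[bands$lesion, ] <- matrix(rep(l_prof, each = length(bands$lesion)),
                                    nrow = length(bands$lesion))
  vol <- array(rep(as.vector(base_yx), each = nz), dim = c(nz, ny, nx))
  if (spec$noise_sd > 0) {
    vol <- vol + with_seed(spec$seed, stats::rnorm(length(vol), sd = spec$noise_sd))
  }

  mask <- array(FALSE, dim = d)
  mask[, bands$lesion, ] <- TRUE
  deficit_yx <- matrix(0, nrow = ny, ncol = nx)
  deficit_yx[bands$lesion, ] <- matrix(rep(1 - l_prof / n_prof,
                                           each = length(bands$lesion)),
                                       nrow = length(bands$lesion))
  deficit <- array(rep(as.vector(deficit_yx), each = nz), dim = d)

  structure(
    list(
      volume = grey_volume(vol, voxel_size = spec$voxel_size),
      truth = list(lesion_mask = mask, deficit_field = deficit,
                   class_label = spec$lesion_class,
                   element_multipliers = spec$element_multipliers,
                   spec = spec)
    ),
    class = "phantom"
  )
}

#' Measurement landmarks for a phantom
#'
#' Returns surface and DEJ landmark points for two analysis rounds in the
#' discoloured band and two in the mirrored normal band, at the same coronal
#' height. Rounds are laterally offset by +-3.5 voxels so that their analysis
#' cubes do not overlap (independent measurements, as when the operator picks
#' "another selected tooth area").
#'
#' @param spec a [phantom_spec()] (or a `phantom`).
#' @return data.frame with columns `area` (`normal`/`lesion`), `round`,
#'   `surface_z/y/x`, `dej_z/y/x` (um).
#' @export
phantom_landmarks <- function(spec) {
  if (inherits(spec, "phantom")) spec <- spec$truth$spec
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- spec$voxel_size
  d <- spec$shape
  bands <- phantom_bands(spec)
  z_um <- floor(d[1L] / 2) * vs
  x_surface <- (d[3L] - 1) * vs
  offs <- c(`1` = -3.5 * vs, `2` = 3.5 * vs)
  rows <- list()
  for (area in c("normal", "lesion")) {
    y_c <- (bands$centers[[area]] - 1) * vs
    for (r in c(1L, 2L)) {
      y_um <- y_c + offs[[r]]
      rows[[length(rows) + 1L]] <- data.frame(
        area = area, round = r,
        surface_z = z_um, surface_y = y_um, surface_x = x_surface,
        dej_z = z_um, dej_y = y_um, dej_x = 0
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate paired X-ray-fluorescence spot measurements
#'
#' Generates per-spot relative concentrations for the four enamel-staining
#' elements (Mn, Fe, Cu, Pb) in the discoloured (`DC`) and normal (`NO`)
#' condition. Spot values are lognormal with the requested coefficient of
#' variation; the stained-spot mean is `baseline * element_multiplier`, the
#' normal-spot mean is `baseline`. With `cv = 0` values equal their means
#' exactly.
#'
#' @param truth a `phantom` truth record (or any list with
#'   `element_multipliers`), or a named multiplier vector.
#' @param baseline named per-element mean relative concentration in normal
#'   enamel; defaults are typical normal-enamel values on the relative scale
#'   of portable-XRF screening tables.
#' @param cv per-spot coefficient of variation; default 0.5.
#' @param n_repeats paired spots per condition (>= 2); default 2 (two measures
#'   per area in two distinct zones).
#' @param seed integer seed.
#' @param tooth_id label for the output table.
#' @return data.frame of class `xrf_table` with columns
#'   `tooth`, `element`, `condition` (`DC`/`NO`), `repeat`, `value`.
#' @export
simulate_xrf <- function(truth,
                         baseline = c(Mn = 0.05, Fe = 0.04, Cu = 0.01, Pb = 0.03),
                         cv = 0.5, n_repeats = 2, seed = 1,
                         tooth_id = "synthetic") {
  mult <- if (is.list(truth)) truth$element_multipliers else truth
  if (is.null(names(mult)) || !all(names(mult) %in% XRF_ELEMENTS)) {
    stopf("unknown element key(s) in multipliers; supported elements: %s",
          paste(XRF_ELEMENTS, collapse = ", "))
  }
  bad <- setdiff(names(baseline), XRF_ELEMENTS)
  if (length(bad) || !all(XRF_ELEMENTS %in% names(baseline))) {
    stopf("`baseline` must name exactly the supported elements %s%s",
          paste(XRF_ELEMENTS, collapse = ", "),
          if (length(bad)) sprintf(" (unknown: %s)", paste(bad, collapse = ", ")) else "")
  }
  if (any(baseline <= 0)) stop("`baseline` must be positive for all elements", call. = FALSE)
  if (!is_scalar_num(n_repeats) || n_repeats < 2) {
    stop("`n_repeats` must be at least 2", call. = FALSE)
  }
  if (cv < 0) stop("`cv` must be non-negative", call. = FALSE)
  full_mult <- c(Mn = 1, Fe = 1, Cu = 1, Pb = 1)
  full_mult[names(mult)] <- mult

  grid <- expand.grid(element = XRF_ELEMENTS, condition = c("DC", "NO"),
                      rep = seq_len(n_repeats),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  means <- ifelse(grid$condition == "DC",
                  baseline[grid$element] * full_mult[grid$element],
                  baseline[grid$element])
  values <- if (cv == 0) {
    as.numeric(means)
  } else {
    sdlog <- sqrt(log(1 + cv^2))
    with_seed(seed, stats::rlnorm(nrow(grid),
                                  meanlog = log(means) - sdlog^2 / 2,
                                  sdlog = sdlog))
  }
  out <- data.frame(tooth = tooth_id, element = grid$element,
                    condition = grid$condition, `repeat` = grid$rep,
                    value = values, check.names = FALSE)
  class(out) <- c("xrf_table", "data.frame")
  out
}

#' Rater panel model for diagnosis questionnaires
#'
#' @param n_raters number of raters per item; default 19 (the size of the
#'   specialist panel this model emulates).
#' @param categories response categories; default `yes`, `no`, `unsure`.
#' @param confusion matrix of per-true-class probability vectors over the
#'   categories (rows = true classes, named; each row sums to 1).
#' @param seed integer seed.
#' @return object of class `rater_model`.
#' @export
rater_model <- function(n_raters = 19,
                        categories = c("yes", "no", "unsure"),
                        confusion, seed = 1) {
  confusion <- as.matrix(confusion)
  if (ncol(confusion) != length(categories)) {
    stop("`confusion` must have one column per category", call. = FALSE)
  }
  if (is.null(rownames(confusion))) {
    stop("`confusion` rows must be named by true class", call. = FALSE)
  }
  if (any(confusion < 0) || any(abs(rowSums(confusion) - 1) > 1e-8)) {
    stop("each `confusion` row must be a probability vector summing to 1", call. = FALSE)
  }
  colnames(confusion) <- categories
  structure(list(n_raters = as.integer(n_raters), categories = categories,
                 confusion = confusion, seed = as.integer(seed)),
            class = "rater_model")
}

#' Simulate a panel of categorical ratings
#'
#' Each item receives `n_raters` independent categorical responses drawn from
#' the confusion row of its true class.
#'
#' @param true_classes character vector (>= 2 items) of true class labels,
#'   matching the rows of the model's confusion matrix.
#' @param model a [rater_model()].
#' @return items-by-categories count matrix of class `rating_table` (rows sum
#'   to `n_raters`), suitable for [fleiss_kappa()].
#' @export
simulate_ratings <- function(true_classes, model) {
  stopifnot(inherits(model, "rater_model"))
  if (length(true_classes) < 2L) {
    stop("need at least 2 items to rate", call. = FALSE)
  }
  missing_cls <- setdiff(unique(true_classes), rownames(model$confusion))
  if (length(missing_cls)) {
    stopf("true class(es) %s missing from the confusion matrix",
          paste(missing_cls, collapse = ", "))
  }
  counts <- with_seed(model$seed, {
    t(vapply(true_classes, function(cls) {
      as.integer(stats::rmultinom(1L, model$n_raters, model$confusion[cls, ]))
    }, integer(length(model$categories))))
  })
  dimnames(counts) <- list(item = seq_along(true_classes),
                           category = model$categories)
  structure(counts, class = c("rating_table", "matrix"))
}
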