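# End-to-end pipeline: phantom (or real volume + landmarks + XRF files) ->
# densitometry -> profiles -> XRF screen -> differential diagnosis, with
# CSV/JSON/plot outputs.

#' Run the full analysis chain on one phantom
#'
#' Convenience wrapper used by [run_pipeline()] and the validation suite:
#' extracts the two-round normal/discoloured transects from the phantom's own
#' landmarks, runs paired cube densitometry, builds the 99-point profile
#' comparison from the round-1 transects, simulates the paired XRF screen from
#' the phantom truth, and classifies the tooth.
#'
#' @param phantom a [generate_phantom()] result.
#' @param edge cube edge, um.
#' @param profile_width_um width of the averaged profile line bundle, um
#'   (wide-line plot profile); default 49.
#' @param thresholds a [diagnosis_thresholds()] list.
#' @param xrf_seed seed for the simulated XRF screen; default phantom seed + 1.
#' @param xrf_cv per-spot coefficient of variation for the XRF screen.
#' @param with_xrf include XRF evidence? Default `TRUE`.
#' @param method Wilcoxon method for the density test.
#' @return list with `evidence` (bundle for [classify_tooth()]), `diagnosis`,
#'   `profiles` (normal/lesion `density_profile`s), `xrf_table`.
#' @export
analyse_phantom <- function(phantom, edge = 49, profile_width_um = 49,
                            thresholds = diagnosis_thresholds(),
                            xrf_seed = NULL, xrf_cv = 0.5, with_xrf = TRUE,
                            method = "normal_approx") {
  stopifnot(inherits(phantom, "phantom"))
  spec <- phantom$truth$spec
  vol <- phantom$volume
  lm <- phantom_landmarks(spec)
  tr <- function(area, round) {
    row <- lm[lm$area == area & lm$round == round, ]
    extract_transect(vol,
                     surface_pt = c(row$surface_z, row$surface_y, row$surface_x),
                     dej_pt = c(row$dej_z, row$dej_y, row$dej_x),
                     width_um = profile_width_um)
  }
  normal_tr <- list(tr("normal", 1), tr("normal", 2))
  lesion_tr <- list(tr("lesion", 1), tr("lesion", 2))

  density_test <- paired_cube_analysis(vol, normal_tr, lesion_tr, edge = edge,
                                       method = method,
                                       tooth_id = spec$lesion_class)
  prof_normal <- resample_profile(normal_tr[[1L]])
  prof_lesion <- resample_profile(lesion_tr[[1L]])
  profile_cmp <- compare_profiles(prof_normal, prof_lesion)

  xrf_table <- NULL
  xrf_flags <- NULL
  if (with_xrf) {
    if (is.null(xrf_seed)) xrf_seed <- spec$seed + 1L
    xrf_table <- simulate_xrf(phantom$truth, cv = xrf_cv, seed = xrf_seed,
                              tooth_id = spec$lesion_class)
    xrf_flags <- element_enrichment(xrf_table, spec$lesion_class)
  }
  evidence <- list(density_test = density_test, profile_cmp = profile_cmp,
                   xrf_flags = xrf_flags, tooth_id = spec$lesion_class)
  list(evidence = evidence,
       diagnosis = classify_tooth(evidence, thresholds),
       profiles = list(normal = prof_normal, lesion = prof_lesion),
       xrf_table = xrf_table)
}

#' Read landmark points from CSV
#'
#' Expected columns: `label`, `x_um`, `y_um`, `z_um`. Labels follow
#' `<area>_<end>_<round>` with area `normal`/`discoloured`, end
#' `surface`/`dej`, round 1/2 (e.g. `normal_surface_1`).
#'
#' @param path CSV file path.
#' @return data.frame with `label` and physical point columns `z`, `y`, `x`
#'   (um, internal axis order).
#' @export
read_landmarks_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "x_um", "y_um", "z_um")
  if (!all(need %in% names(tab))) {
    stopf("landmark CSV must have columns %s", paste(need, collapse = ", "))
  }
  data.frame(label = tab$label, z = tab$z_um, y = tab$y_um, x = tab$x_um)
}

landmark_point <- function(lm, label) {
  row <- lm[lm$label == label, ]
  if (nrow(row) != 1L) stopf("missing landmark '%s'", label)
  c(row$z, row$y, row$x)
}

#' Run the full pipeline from a configuration
#'
#' The configuration (a list or a YAML file path) names either a synthetic
#' phantom (`phantom:` section with [phantom_spec()] arguments) or real data
#' (`volume:` TIFF path, `landmarks:` CSV path, optional `xrf:` CSV path).
#' Optional sections: `thresholds` ([diagnosis_thresholds()] arguments),
#' `edge`, `profile_width_um`, `method`, `xrf_cv`, `tooth_id`.
#'
#' When `out_dir` is given, writes: `mdd.csv` (round, cube, normal_GL,
#' discoloured_GL, mdd), `profiles.csv` (point, u, normal_GL, lesion_GL,
#' deficit), `xrf.csv` and `xrf_summary.csv`, `profiles.pdf` (normal and
#' discoloured profile lines, DEJ left), and `report.json` (versioned
#' diagnostic report, logging every threshold used). The report is a pure
#' function of config + seed, so identical runs produce byte-identical JSON.
#'
#' @param config list or YAML file path.
#' @param seed optional integer overriding the phantom seed.
#' @param out_dir optional output directory (created if needed).
#' @return the report, invisibly (list).
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML file path", call. = FALSE)
  if (is.null(config$phantom) && is.null(config$volume)) {
    stop("config must name inputs: either a `phantom` section (synthetic mode) or `volume` + `landmarks` files (data mode)",
         call. = FALSE)
  }
  thresholds <- do.call(diagnosis_thresholds,
                        if (is.null(config$thresholds)) list() else config$thresholds)
  edge <- if (is.null(config$edge)) 49 else config$edge
  width <- if (is.null(config$profile_width_um)) 49 else config$profile_width_um
  method <- if (is.null(config$method)) "normal_approx" else config$method
  xrf_cv <- if (is.null(config$xrf_cv)) 0.5 else config$xrf_cv

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if (!is.null(config$phantom)) {
    args <- config$phantom
    if (!is.null(seed)) args$seed <- seed
    spec <- stage("phantom", do.call(phantom_spec, args))
    phantom <- stage("phantom", generate_phantom(spec))
    ana <- stage("analysis",
                 analyse_phantom(phantom, edge = edge, profile_width_um = width,
                                 thresholds = thresholds, xrf_cv = xrf_cv,
                                 method = method))
    truth_label <- spec$lesion_class
    tooth_id <- if (is.null(config$tooth_id)) spec$lesion_class else config$tooth_id
  } else {
    if (is.null(config$landmarks)) {
      stop("data mode requires a `landmarks` CSV alongside `volume`", call. = FALSE)
    }
    vol <- stage("volume", read_volume(config$volume))
    lm <- stage("landmarks", read_landmarks_csv(config$landmarks))
    tooth_id <- if (is.null(config$tooth_id)) "tooth" else config$tooth_id
    tr <- function(area, round) {
      extract_transect(vol,
                       landmark_point(lm, sprintf("%s_surface_%d", area, round)),
                       landmark_point(lm, sprintf("%s_dej_%d", area, round)),
                       width_um = width)
    }
    normal_tr <- stage("transects", list(tr("normal", 1), tr("normal", 2)))
    lesion_tr <- stage("transects", list(tr("discoloured", 1), tr("discoloured", 2)))
    density_test <- stage("densitometry",
                          paired_cube_analysis(vol, normal_tr, lesion_tr,
                                               edge = edge, method = method,
                                               tooth_id = tooth_id))
    prof_normal <- stage("profiles", resample_profile(normal_tr[[1L]]))
    prof_lesion <- stage("profiles", resample_profile(lesion_tr[[1L]]))
    profile_cmp <- stage("profiles", compare_profiles(prof_normal, prof_lesion))
    xrf_table <- NULL; xrf_flags <- NULL
    if (!is.null(config$xrf)) {
      xrf_table <- stage("xrf", read_xrf_csv(config$xrf))
      xrf_flags <- stage("xrf", element_enrichment(xrf_table, tooth_id))
    }
    evidence <- list(density_test = density_test, profile_cmp = profile_cmp,
                     xrf_flags = xrf_flags, tooth_id = tooth_id)
    ana <- list(evidence = evidence,
                diagnosis = stage("diagnosis", classify_tooth(evidence, thresholds)),
                profiles = list(normal = prof_normal, lesion = prof_lesion),
                xrf_table = xrf_table)
    truth_label <- NULL
  }

  report <- list(
    schema = "paleoenamel-report/1",
    tooth_id = tooth_id,
    mode = if (!is.null(config$phantom)) "synthetic" else "data",
    truth_label = truth_label,
    parameters = list(edge_um = edge, profile_width_um = width,
                      method = method, xrf_cv = xrf_cv,
                      thresholds = thresholds, seed = seed),
    densitometry = list(
      mdd = ana$evidence$density_test$mdd,
      p_value = ana$evidence$density_test$p_value,
      significant = ana$evidence$density_test$significant
    ),
    profile = list(
      mid_deficit = ana$evidence$profile_cmp$mid_deficit,
      max_deficit = ana$evidence$profile_cmp$max_deficit,
      gradient_normal = ana$evidence$profile_cmp$gradient_normal$label,
      gradient_lesion = ana$evidence$profile_cmp$gradient_lesion$label
    ),
    xrf = if (is.null(ana$evidence$xrf_flags)) NULL else list(
      flagged = as.character(
        ana$evidence$xrf_flags$element[ana$evidence$xrf_flags$flagged]),
      fold = stats::setNames(ana$evidence$xrf_flags$fold,
                             ana$evidence$xrf_flags$element)
    ),
    diagnosis = list(label = ana$diagnosis$label,
                     rule_trace = ana$diagnosis$rule_trace)
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    dt <- ana$evidence$density_test
    mdd_tab <- cbind(tooth = tooth_id, dt$table)
    utils::write.csv(mdd_tab, file.path(out_dir, "mdd.csv"), row.names = FALSE)
    pn <- ana$profiles$normal; pl <- ana$profiles$lesion
    utils::write.csv(
      data.frame(point = seq_along(pn$values), u = pn$positions,
                 normal_GL = pn$values, lesion_GL = pl$values,
                 deficit = ana$evidence$profile_cmp$deficit_curve),
      file.path(out_dir, "profiles.csv"), row.names = FALSE)
    if (!is.null(ana$xrf_table)) {
      write_xrf_csv(ana$xrf_table, file.path(out_dir, "xrf.csv"))
      s <- xrf_summary(ana$xrf_table)
      utils::write.csv(s$stats, file.path(out_dir, "xrf_summary.csv"),
                       row.names = FALSE)
    }
    grDevices::pdf(file.path(out_dir, "profiles.pdf"), width = 7, height = 5)
    plot_profiles(pn, pl, main = sprintf("Density profiles (%s)", tooth_id))
    grDevices::dev.off()
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         null = "null")
  }
  invisible(report)
}
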