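# Differential diagnosis: combine densitometry, profile and XRF evidence into
# an ante-mortem (hypomineralisation) vs post-mortem (taphonomic) call.
#
# Evidence predicates:
#   D  significant density deficit: paired-test p < alpha AND median mdd > 0
#      (the median guard rejects significance driven by the discoloured area
#      being *denser* than normal, a case never labelled here)
#   R  gradient reversal: lesion profile reversed AND normal profile rising
#   C  elemental contamination: any staining element flagged by XRF
#   S  surface-shell deficit: the deficit curve is ~0 below the dissolution
#      boundary and substantial above it (acid dissolution demineralises from
#      the surface inward, unlike hypomineralisation which spans the depth)
#
# Rules, in order:
#   D & R & C   -> hypomineralised_with_postmortem_uptake
#   D & R & !C  -> hypomineralised
#   !D & C      -> taphonomic_stain
#   D & !R & S  -> acid_dissolution_suspect
#   !D & !C     -> sound
#   otherwise   -> indeterminate

#' Thresholds for the diagnostic decision table
#'
#' @param alpha significance level for the density test; default 0.05.
#' @param shell_boundary normalised depth u separating "inner" from "outer
#'   shell" for the acid-dissolution predicate; default 0.70 (slightly inside
#'   the default dissolution front at u = 0.75, leaving margin for
#'   interpolation smear at the step edge).
#' @param inner_tol maximum absolute deficit tolerated in the inner region for
#'   the shell predicate ("approximately zero"); default 0.02.
#' @param shell_min minimum mean deficit in the outer shell for the shell
#'   predicate; default 0.05.
#' @return named list of thresholds.
#' @export
diagnosis_thresholds <- function(alpha = 0.05, shell_boundary = 0.70,
                                 inner_tol = 0.02, shell_min = 0.05) {
  list(alpha = alpha, shell_boundary = shell_boundary,
       inner_tol = inner_tol, shell_min = shell_min)
}

#' Classify a tooth from its evidence bundle
#'
#' @param evidence list with components `density_test` (an `mdd_table` from
#'   [paired_cube_analysis()]), `profile_cmp` (a `profile_comparison` from
#'   [compare_profiles()]), optional `xrf_flags` (from
#'   [element_enrichment()]), optional `tooth_id`. Density and profile
#'   evidence are mandatory.
#' @param thresholds a [diagnosis_thresholds()] list.
#' @return object of class `diagnostic_result`: list with `label` (one of
#'   `sound`, `hypomineralised`, `hypomineralised_with_postmortem_uptake`,
#'   `taphonomic_stain`, `acid_dissolution_suspect`, `indeterminate`),
#'   `rule_trace` (ordered evaluated predicates and the fired rule),
#'   `evidence` summary.
#' @export
classify_tooth <- function(evidence, thresholds = diagnosis_thresholds()) {
  if (is.null(evidence$density_test) || is.null(evidence$profile_cmp)) {
    stop("evidence bundle must contain `density_test` and `profile_cmp`", call. = FALSE)
  }
  dt <- evidence$density_test
  pc <- evidence$profile_cmp
  stopifnot(inherits(dt, "mdd_table"), inherits(pc, "profile_comparison"))

  D <- !is.na(dt$p_value) && dt$p_value < thresholds$alpha &&
    stats::median(dt$mdd) > 0
  R <- pc$gradient_lesion$label == "reversed" &&
    pc$gradient_normal$label == "increasing"
  C <- !is.null(evidence$xrf_flags) && any(evidence$xrf_flags$flagged)
  inner <- pc$positions < thresholds$shell_boundary
  S <- any(!inner) &&
    max(abs(pc$deficit_curve[inner])) <= thresholds$inner_tol &&
    mean(pc$deficit_curve[!inner]) >= thresholds$shell_min

  trace <- c(
    sprintf("D (density deficit: p %s %s and median mdd %.1f > 0) = %s",
            if (is.na(dt$p_value)) "NA" else sprintf("%.4g", dt$p_value),
            sprintf("< %g", thresholds$alpha), stats::median(dt$mdd), D),
    sprintf("R (gradient reversal: lesion %s, normal %s) = %s",
            pc$gradient_lesion$label, pc$gradient_normal$label, R),
    sprintf("C (elemental contamination: %s) = %s",
            if (is.null(evidence$xrf_flags)) "no XRF evidence"
            else paste0(evidence$xrf_flags$element[evidence$xrf_flags$flagged],
                        collapse = ",") , C),
    sprintf("S (surface-shell deficit, boundary u = %g) = %s",
            thresholds$shell_boundary, S)
  )

  label <- if (D && R && C) "hypomineralised_with_postmortem_uptake"
  else if (D && R && !C) "hypomineralised"
  else if (!D && C) "taphonomic_stain"
  else if (D && !R && S) "acid_dissolution_suspect"
  else if (!D && !C) "sound"
  else "indeterminate"
  trace <- c(trace, sprintf("fired: %s", label))

  structure(
    list(label = label, rule_trace = trace,
         evidence = list(
           tooth_id = evidence$tooth_id,
           p_value = dt$p_value, median_mdd = stats::median(dt$mdd),
           mid_deficit = pc$mid_deficit, max_deficit = pc$max_deficit,
           gradient_normal = pc$gradient_normal$label,
           gradient_lesion = pc$gradient_lesion$label,
           flagged_elements = if (is.null(evidence$xrf_flags)) character(0)
           else as.character(evidence$xrf_flags$element[evidence$xrf_flags$flagged]),
           thresholds = thresholds)),
    class = "diagnostic_result"
  )
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat("Diagnosis:", x$label, "\n")
  for (line in x$rule_trace) cat(" ", line, "\n")
  invisible(x)
}
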