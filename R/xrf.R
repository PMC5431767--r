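# Paired X-ray-fluorescence elemental screening: discoloured (DC) vs normal
# (NO) relative concentrations of the four enamel-staining elements
# (Mn, Fe, Cu, Pb), per-tooth paired Wilcoxon test and per-element enrichment
# flags that feed the diagnosis module's contamination evidence.

XRF_REQUIRED_COLS <- c("tooth", "element", "condition", "repeat", "value")

validate_xrf_table <- function(table) {
  if (!is.data.frame(table) || !all(XRF_REQUIRED_COLS %in% names(table))) {
    stopf("XRF table must have columns %s", paste(XRF_REQUIRED_COLS, collapse = ", "))
  }
  if (!all(table$condition %in% c("DC", "NO"))) {
    stop("XRF condition must be 'DC' (discoloured) or 'NO' (normal)", call. = FALSE)
  }
  if (any(table$value < 0)) stop("relative concentrations must be non-negative", call. = FALSE)
  invisible(table)
}

# DC and NO sub-tables for one tooth, screened to the four staining elements;
# other recorded elements (e.g. Sn, Zn, Sr, P, Ca) are retained in the table
# but excluded from the screen
xrf_pairs <- function(table, tooth_id, elements = XRF_ELEMENTS) {
  validate_xrf_table(table)
  tab <- table[table$tooth == tooth_id & table$element %in% elements, ]
  if (nrow(tab) == 0L) stopf("no XRF rows for tooth '%s'", tooth_id)
  out <- list()
  for (el in elements) {
    for (r in sort(unique(tab$`repeat`[tab$element == el]))) {
      dc <- tab$value[tab$element == el & tab$condition == "DC" & tab$`repeat` == r]
      no <- tab$value[tab$element == el & tab$condition == "NO" & tab$`repeat` == r]
      if (length(dc) != 1L || length(no) != 1L) {
        stopf("incomplete paired data for tooth '%s': element %s, repeat %d needs one DC and one NO value",
              tooth_id, el, r)
      }
      out[[length(out) + 1L]] <- data.frame(element = el, rep = r, DC = dc, NO = no)
    }
  }
  do.call(rbind, out)
}

#' Per-tooth paired Wilcoxon test on XRF concentrations
#'
#' Forms the differences `DC - NO` for every (element, repeat) pair of the
#' four staining elements (8 pairs at the default two repeats) and applies the
#' two-sided Wilcoxon signed-rank test. Repeat index i in DC pairs with repeat
#' index i in NO (homologous spots at the same coronal height).
#'
#' @param table an XRF table (columns `tooth`, `element`, `condition`,
#'   `repeat`, `value`), e.g. from [simulate_xrf()] or [read_xrf_csv()].
#' @param tooth_id tooth to test.
#' @param method `"normal_approx"` (default) or `"exact"`.
#' @return a `wilcoxon_result` (see [wilcoxon_signed_rank()]) with an extra
#'   `n_pairs` field.
#' @export
xrf_paired_test <- function(table, tooth_id, method = "normal_approx") {
  pairs <- xrf_pairs(table, tooth_id)
  res <- wilcoxon_signed_rank(pairs$DC - pairs$NO, method = method)
  res$n_pairs <- nrow(pairs)
  res
}

#' Per-element enrichment flags for taphonomic contamination
#'
#' An element is flagged as taphonomically enriched in the discoloured area
#' when its fold change `mean(DC) / mean(NO)` reaches `fold_threshold` AND
#' every DC repeat exceeds every NO repeat (non-overlapping repeats). When
#' `mean(NO) == 0` the fold change is infinite and the element is flagged iff
#' all DC repeats are positive.
#'
#' @param table an XRF table.
#' @param tooth_id tooth to screen.
#' @param fold_threshold minimum fold change; default 3.
#' @return data.frame of class `xrf_flags` with columns `element`, `mean_DC`,
#'   `mean_NO`, `fold`, `flagged`.
#' @export
element_enrichment <- function(table, tooth_id, fold_threshold = 3) {
  pairs <- xrf_pairs(table, tooth_id)
  rows <- lapply(XRF_ELEMENTS, function(el) {
    p <- pairs[pairs$element == el, ]
    m_dc <- mean(p$DC); m_no <- mean(p$NO)
    fold <- if (m_no > 0) m_dc / m_no else Inf
    flagged <- if (m_no > 0) {
      fold >= fold_threshold && min(p$DC) > max(p$NO)
    } else {
      all(p$DC > 0)
    }
    data.frame(element = el, mean_DC = m_dc, mean_NO = m_no,
               fold = fold, flagged = flagged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("xrf_flags", "data.frame")
  out
}

#' Summarise an XRF table (means, SDs, per-tooth test, enrichment)
#'
#' @param table an XRF table.
#' @param fold_threshold passed to [element_enrichment()].
#' @param method passed to [xrf_paired_test()].
#' @return list of class `xrf_summary` with `stats` (per tooth/element/
#'   condition mean and n-1 SD), `tests` (per-tooth p-values), `flags`
#'   (per-tooth enrichment flags).
#' @export
xrf_summary <- function(table, fold_threshold = 3, method = "normal_approx") {
  validate_xrf_table(table)
  teeth <- unique(table$tooth)
  scr <- table[table$element %in% XRF_ELEMENTS, ]
  stats_df <- do.call(rbind, lapply(split(
    scr, list(scr$tooth, scr$element, scr$condition), drop = TRUE
  ), function(g) {
    data.frame(tooth = g$tooth[1], element = g$element[1],
               condition = g$condition[1], mean = mean(g$value),
               sd = stats::sd(g$value))
  }))
  rownames(stats_df) <- NULL
  tests <- do.call(rbind, lapply(teeth, function(tt) {
    p <- tryCatch(xrf_paired_test(table, tt, method = method)$p_two_sided,
                  error = function(e) NA_real_)
    data.frame(tooth = tt, p_value = p,
               significant = !is.na(p) && p < 0.05)
  }))
  flags <- lapply(stats::setNames(teeth, teeth), function(tt) {
    element_enrichment(table, tt, fold_threshold)
  })
  structure(list(stats = stats_df, tests = tests, flags = flags),
            class = "xrf_summary")
}

#' Read / write XRF tables as CSV
#'
#' The CSV layout is `tooth, element, condition, repeat, value` with
#' condition `DC` (discoloured) or `NO` (normal).
#'
#' @param path CSV file path.
#' @return for `read_xrf_csv`, a validated XRF table.
#' @export
read_xrf_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_xrf_table(tab)
  class(tab) <- c("xrf_table", "data.frame")
  tab
}

#' @rdname read_xrf_csv
#' @param table an XRF table to write.
#' @export
write_xrf_csv <- function(table, path) {
  validate_xrf_table(table)
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}
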