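# Paired XRF screen: per-tooth test, enrichment flags, invariances.

make_xrf <- function(dc, no, tooth = "T1") {
  # dc/no: named list element -> length-2 repeat values
  rows <- list()
  for (el in names(dc)) {
    for (r in 1:2) {
      rows[[length(rows) + 1L]] <- data.frame(
        tooth = tooth, element = el,
        condition = c("DC", "NO"), `repeat` = r,
        value = c(dc[[el]][r], no[[el]][r]), check.names = FALSE)
    }
  }
  do.call(rbind, rows)
}

base_dc <- list(Mn = c(0.5, 0.6), Fe = c(0.2, 0.18), Cu = c(0.02, 0.021), Pb = c(0.1, 0.11))
base_no <- list(Mn = c(0.04, 0.05), Fe = c(0.03, 0.025), Cu = c(0.01, 0.012), Pb = c(0.03, 0.04))

test_that("all-DC-above-NO gives the closed-form n = 8 p-value", {
  tab <- make_xrf(base_dc, base_no)
  res <- xrf_paired_test(tab, "T1")
  expect_equal(res$n_pairs, 8)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 2 * pnorm(-18 / sqrt(51)))
  expect_equal(round(res$p_two_sided, 3), 0.012)
})

test_that("identical conditions raise the no-nonzero-pairs error", {
  tab <- make_xrf(base_no, base_no)
  expect_error(xrf_paired_test(tab, "T1"), "no nonzero pairs")
})

test_that("exact method matches the 256-pattern enumeration oracle", {
  d <- c(5, -1, 4, 3, 2, 6, 7, 8)
  no <- list(Mn = c(1, 1), Fe = c(1, 1), Cu = c(1, 1), Pb = c(1, 1))
  dc <- list(Mn = 1 + d[1:2], Fe = 1 + d[3:4], Cu = 1 + d[5:6], Pb = 1 + d[7:8])
  tab <- make_xrf(dc, no)
  expect_equal(xrf_paired_test(tab, "T1", method = "exact")$p_two_sided,
               oracle_exact_p(d))
})

test_that("enrichment flags follow the fold + non-overlap rule", {
  # Mn fold ~ 12 with non-overlapping repeats -> flagged; others not
  dc <- list(Mn = c(0.55, 0.58), Fe = c(0.05, 0.04), Cu = c(0.01, 0.01), Pb = c(0.05, 0.05))
  no <- list(Mn = c(0.045, 0.049), Fe = c(0.03, 0.026), Cu = c(0.01, 0.01), Pb = c(0.04, 0.048))
  flags <- element_enrichment(make_xrf(dc, no), "T1")
  expect_equal(as.character(flags$element[flags$flagged]), "Mn")
  expect_gt(flags$fold[flags$element == "Mn"], 10)
  # equal conditions -> nothing flagged
  flags0 <- element_enrichment(make_xrf(base_no, base_no), "T1")
  expect_false(any(flags0$flagged))
  # overlap vetoes a large fold: one DC repeat below one NO repeat
  dc_ov <- list(Mn = c(0.55, 0.02), Fe = c(0.03, 0.026), Cu = c(0.01, 0.01), Pb = c(0.04, 0.05))
  fo <- element_enrichment(make_xrf(dc_ov, no), "T1")
  expect_false(fo$flagged[fo$element == "Mn"])
})

test_that("zero normal mean: infinite fold, flagged iff DC positive", {
  dc <- list(Mn = c(0.1, 0.2), Fe = c(0, 0), Cu = c(0.01, 0.01), Pb = c(0.04, 0.05))
  no <- list(Mn = c(0, 0), Fe = c(0, 0), Cu = c(0.01, 0.01), Pb = c(0.04, 0.05))
  flags <- element_enrichment(make_xrf(dc, no), "T1")
  expect_equal(flags$fold[flags$element == "Mn"], Inf)
  expect_true(flags$flagged[flags$element == "Mn"])
  expect_false(flags$flagged[flags$element == "Fe"])  # DC repeats are zero
})

test_that("DC/NO swap inverts folds and keeps the two-sided p; rescaling is neutral", {
  tab <- make_xrf(base_dc, base_no)
  swapped <- tab
  swapped$condition <- ifelse(tab$condition == "DC", "NO", "DC")
  f1 <- element_enrichment(tab, "T1")
  f2 <- element_enrichment(swapped, "T1")
  expect_equal(f2$fold, 1 / f1$fold)
  expect_equal(xrf_paired_test(swapped, "T1")$p_two_sided,
               xrf_paired_test(tab, "T1")$p_two_sided)
  scaled <- tab; scaled$value <- tab$value * 37.3
  expect_equal(element_enrichment(scaled, "T1")$fold, f1$fold)
})

test_that("missing condition is reported with the gap named", {
  tab <- make_xrf(base_dc, base_no)
  tab <- tab[!(tab$element == "Fe" & tab$condition == "NO" & tab$`repeat` == 2), ]
  expect_error(xrf_paired_test(tab, "T1"), "Fe, repeat 2")
})

test_that("summary reports n-1 SDs and significance stars", {
  tab <- make_xrf(base_dc, base_no)
  s <- xrf_summary(tab)
  mn_dc <- s$stats[s$stats$element == "Mn" & s$stats$condition == "DC", ]
  expect_equal(mn_dc$mean, mean(base_dc$Mn))
  expect_equal(mn_dc$sd, sd(base_dc$Mn))
  expect_true(s$tests$significant[s$tests$tooth == "T1"])
})

test_that("false-flag rate on uncontaminated simulations stays low", {
  truth <- list(element_multipliers = c(Mn = 1, Fe = 1, Cu = 1, Pb = 1))
  flagged <- vapply(1:200, function(s) {
    any(element_enrichment(simulate_xrf(truth, seed = s), "synthetic")$flagged)
  }, logical(1))
  expect_lte(mean(flagged), 0.05)
})

test_that("CSV round trip preserves the table", {
  tab <- make_xrf(base_dc, base_no)
  path <- file.path(withr::local_tempdir(), "xrf.csv")
  write_xrf_csv(tab, path)
  back <- read_xrf_csv(path)
  expect_equal(back$value, tab$value)
  expect_equal(back$condition, tab$condition)
})
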