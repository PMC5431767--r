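# Self-contained nonparametric statistics: Wilcoxon signed-rank matched-pairs
# test (exact enumeration and normal approximation) and Fleiss' kappa.
#
# These are implemented from first principles rather than wrapping
# stats::wilcox.test because the pipeline needs (a) the exact two-sided p by
# full enumeration over sign assignments of midranks (ties included) and
# (b) a normal approximation *without* continuity correction, the variant
# whose two-sided p for ten same-sign pairs is 0.005 to three decimals.

#' Wilcoxon signed-rank test for paired differences
#'
#' Tests whether paired differences are symmetrically distributed around zero.
#' Zero differences are dropped (Wilcoxon's original convention); tied absolute
#' values receive midranks.
#'
#' Two methods are available:
#' \describe{
#'   \item{`normal_approx`}{`z = (W - n(n+1)/4) / sqrt(n(n+1)(2n+1)/24)` with
#'     `W = min(W+, W-)`, two-sided, no continuity correction. With
#'     `tie_correction = TRUE` the variance is reduced by
#'     `sum(t^3 - t)/48` over tie groups.}
#'   \item{`exact`}{full enumeration over all `2^n` equally likely sign
#'     assignments of the observed absolute midranks; the two-sided p-value is
#'     `P(|W+ - E[W+]| >= |w+ - E[W+]|)` under that distribution. Valid with
#'     ties because the enumeration uses the observed midranks.}
#' }
#'
#' @param differences numeric vector of paired differences.
#' @param method `"normal_approx"` (default) or `"exact"`.
#' @param tie_correction logical; apply the tie variance correction in the
#'   normal approximation. Default `FALSE`.
#' @return an object of class `wilcoxon_result`: a list with `n_used`,
#'   `w_plus`, `w_minus`, `statistic` (`min(w_plus, w_minus)`), `method`,
#'   `p_two_sided`.
#' @examples
#' wilcoxon_signed_rank(c(3, 5, 1, 8, 2, 9, 4, 7, 6, 10))          # p = 0.005
#' wilcoxon_signed_rank(c(1, -2, 3, -4), method = "exact")         # p = 0.875
#' @export
wilcoxon_signed_rank <- function(differences,
                                 method = c("normal_approx", "exact"),
                                 tie_correction = FALSE) {
  method <- match.arg(method)
  if (!is.numeric(differences) || length(differences) == 0L) {
    stop("`differences` must be a non-empty numeric vector", call. = FALSE)
  }
  if (anyNA(differences)) stop("`differences` must not contain NA", call. = FALSE)
  d <- differences[differences != 0]
  if (length(d) == 0L) stop("no nonzero pairs", call. = FALSE)

  n <- length(d)
  r <- rank(abs(d))                       # midranks for ties
  w_plus <- sum(r[d > 0])
  w_minus <- sum(r[d < 0])
  statistic <- min(w_plus, w_minus)

  if (method == "normal_approx") {
    mu <- n * (n + 1) / 4
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24
    if (tie_correction) {
      t_tab <- table(r)
      t_sizes <- as.numeric(t_tab[t_tab > 1])
      if (length(t_sizes)) sigma2 <- sigma2 - sum(t_sizes^3 - t_sizes) / 48
    }
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (statistic - mu) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(z))
    }
  } else {
    p <- exact_signed_rank_p(r, w_plus)
  }

  structure(
    list(n_used = n, w_plus = w_plus, w_minus = w_minus,
         statistic = statistic, method = method, p_two_sided = p),
    class = "wilcoxon_result"
  )
}

# Exact two-sided p by dynamic programming over the distribution of W+ across
# all 2^n sign assignments of the observed midranks. Midranks are multiples of
# 1/2, so doubling makes every rank integral and the distribution a vector of
# counts over 0..2*T.
exact_signed_rank_p <- function(ranks, w_plus) {
  r2 <- as.integer(round(2 * ranks))
  total2 <- sum(r2)
  counts <- numeric(total2 + 1L)  # counts[v + 1] = #assignments with 2*W+ == v
  counts[1L] <- 1
  for (ri in r2) {
    shifted <- c(numeric(ri), counts[seq_len(length(counts) - ri)])
    counts <- counts + shifted
  }
  dev_obs <- abs(2 * w_plus - total2 / 2)  # deviation of 2*W+ from its mean
  v <- 0:total2
  sum(counts[abs(v - total2 / 2) >= dev_obs - 1e-9]) / 2^length(ranks)
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat("Wilcoxon signed-rank test (", x$method, ")\n", sep = "")
  cat(sprintf("  n = %d, W+ = %g, W- = %g, statistic = %g\n",
              x$n_used, x$w_plus, x$w_minus, x$statistic))
  cat(sprintf("  two-sided p = %.4g\n", x$p_two_sided))
  invisible(x)
}

#' Fleiss' kappa for inter-rater agreement
#'
#' Chance-corrected agreement among a fixed number of raters assigning each of
#' several items to one of several categories. Standard Fleiss formulation:
#' per-item agreement `P_i = (sum_j n_ij^2 - n) / (n (n - 1))`, mean observed
#' agreement `p_bar = mean(P_i)`, expected agreement `p_e = sum_j p_j^2` with
#' `p_j` the overall category proportions, and
#' `kappa = (p_bar - p_e) / (1 - p_e)`.
#'
#' @param table an items-by-categories matrix of counts (or a `rating_table`
#'   from [simulate_ratings()]); every row must sum to the same number of
#'   raters.
#' @return an object of class `kappa_result`: list with `kappa`, `p_bar`,
#'   `p_e`, `P_i` (per-item agreement), `n_raters`. If every rating falls in
#'   one category (`p_e == 1`) `kappa` is `NA` with an explanatory note.
#' @examples
#' fleiss_kappa(rbind(c(2, 1), c(1, 2)))  # kappa = -1/3
#' @export
fleiss_kappa <- function(table) {
  m <- unclass(as.matrix(table))
  if (!is.numeric(m) || anyNA(m) || any(m < 0)) {
    stop("`table` must be a non-negative numeric count matrix", call. = FALSE)
  }
  if (nrow(m) < 2L) stop("Fleiss' kappa needs at least 2 items", call. = FALSE)
  if (ncol(m) < 2L) stop("Fleiss' kappa needs at least 2 categories", call. = FALSE)
  n_raters <- rowSums(m)
  if (length(unique(n_raters)) != 1L) {
    stop("unequal raters per item: every row must sum to the same count",
         call. = FALSE)
  }
  n <- n_raters[[1L]]
  if (n < 2L) stop("Fleiss' kappa needs at least 2 raters per item", call. = FALSE)

  P_i <- (rowSums(m^2) - n) / (n * (n - 1))
  p_bar <- mean(P_i)
  p_j <- colSums(m) / (nrow(m) * n)
  p_e <- sum(p_j^2)
  kappa <- if (abs(1 - p_e) < .Machine$double.eps^0.5) NA_real_ else (p_bar - p_e) / (1 - p_e)

  structure(
    list(kappa = kappa, p_bar = p_bar, p_e = p_e, P_i = unname(P_i),
         n_raters = unname(n),
         note = if (is.na(kappa)) "all ratings in one category; kappa undefined (p_e = 1)" else NULL),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("Fleiss' kappa\n")
  if (is.na(x$kappa)) {
    cat("  kappa undefined:", x$note, "\n")
  } else {
    cat(sprintf("  kappa = %.4f (p_bar = %.4f, p_e = %.4f, %d raters, %d items)\n",
                x$kappa, x$p_bar, x$p_e, x$n_raters, length(x$P_i)))
  }
  invisible(x)
}
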