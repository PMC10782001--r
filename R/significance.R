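# Resampling-based comparison of predictors: random protein subsets, an
# Anderson-Darling normality gate, paired t / Wilcoxon signed-rank tests and
# the +/-/= verdict notation used in the report tables.

#' Build random protein subsets for significance testing
#'
#' Two schemes: `disjoint_5pct` shuffles the ids once and slices them into 20
#' pairwise disjoint subsets of near-equal size (floor or ceiling of n/20),
#' used for residue-level and content comparisons; `sampled_20pct` draws 20
#' subsets of ceiling(0.2 n) ids independently without replacement within
#' each subset, used on the small fully-disordered-protein sets where 5%
#' slices would be too sparse. Deterministic under a fixed seed.
#'
#' @param ids Character vector of protein identifiers.
#' @param mode `"disjoint_5pct"` or `"sampled_20pct"`.
#' @param seed Integer seed.
#' @param n_subsets Number of subsets, default 20.
#' @return Object of class `subset_plan`.
#' @export
make_subsets <- function(ids, mode = c("disjoint_5pct", "sampled_20pct"),
                         seed, n_subsets = 20L) {
  mode <- match.arg(mode)
  n <- length(ids)
  subsets <- local({
    set.seed(as.integer(seed))
    if (mode == "disjoint_5pct") {
      if (n < n_subsets)
        stop(sprintf("disjoint mode needs at least %d proteins, got %d",
                     n_subsets, n), call. = FALSE)
      shuffled <- sample(ids)
      grp <- sort(rep_len(seq_len(n_subsets), n))
      unname(split(shuffled, grp))
    } else {
      k <- ceiling(0.2 * n)
      lapply(seq_len(n_subsets), function(i) sample(ids, k))
    }
  })
  structure(list(mode = mode, subsets = subsets, seed = as.integer(seed)),
            class = "subset_plan")
}

#' Evaluate a metric on every subset of a plan
#'
#' Calls `evaluator(ids)` for each subset; the evaluator returns one value
#' per method (a named numeric vector). Subsets where the evaluator fails
#' (for instance AUC on a subset with no ordered residues) are recorded as
#' `NA` and flagged; if every subset is degenerate this is an error.
#'
#' @param plan A `subset_plan` from [make_subsets()].
#' @param evaluator Function taking a character vector of ids and returning a
#'   named numeric vector (one value per method).
#' @return Matrix of size n_subsets x n_methods with attribute
#'   `"degenerate"` marking skipped subsets.
#' @export
subset_metric_series <- function(plan, evaluator) {
  vals <- lapply(plan$subsets, function(ids) {
    tryCatch(evaluator(ids), error = function(e) NULL)
  })
  ok <- !vapply(vals, is.null, TRUE)
  if (!any(ok)) stop("metric undefined on every subset", call. = FALSE)
  template <- vals[[which(ok)[1]]]
  m <- matrix(NA_real_, nrow = length(vals), ncol = length(template),
              dimnames = list(NULL, names(template)))
  for (i in which(ok)) m[i, ] <- vals[[i]][colnames(m)]
  attr(m, "degenerate") <- which(!ok)
  m
}

#' Paired significance verdict between two metric series
#'
#' The paired differences are first screened with the Anderson-Darling
#' normality test at p = 0.05; when normality is not rejected a two-sided
#' paired t-test is used, otherwise the two-sided Wilcoxon signed-rank test.
#' The verdict symbol is `+` when A is significantly better than B, `-` when
#' significantly worse, `=` otherwise; for error-type metrics set
#' `higher_better = FALSE` to invert the orientation. All-zero differences
#' yield `=` with p = 1 by convention.
#'
#' @param seriesA,seriesB Paired numeric series (one value per subset).
#' @param alpha Significance level, default 0.05.
#' @param higher_better Metric orientation, default `TRUE`.
#' @return Object of class `verdict` with `symbol`, `p_value`, `test_used`.
#' @export
paired_verdict <- function(seriesA, seriesB, alpha = 0.05, higher_better = TRUE) {
  if (length(seriesA) != length(seriesB))
    stop("paired series differ in length", call. = FALSE)
  keep <- is.finite(seriesA) & is.finite(seriesB)
  a <- seriesA[keep]; b <- seriesB[keep]
  if (length(a) < 5L)
    stop("need at least 5 paired observations", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(structure(list(symbol = "=", p_value = 1, test_used = "none",
                          mean_diff = 0), class = "verdict"))
  if (stats::sd(d) == 0 || length(d) < 8L) {
    # constant non-zero differences are as non-normal as it gets; the
    # Anderson-Darling statistic also needs 8 observations
    normal <- FALSE
  } else {
    normal <- nortest::ad.test(d)$p.value >= 0.05
  }
  if (normal) {
    p <- stats::t.test(a, b, paired = TRUE)$p.value
    test <- "paired_t"
  } else {
    p <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE)$p.value)
    test <- "wilcoxon"
  }
  better <- if (higher_better) mean(d) > 0 else mean(d) < 0
  symbol <- if (p >= alpha) "=" else if (better) "+" else "-"
  structure(list(symbol = symbol, p_value = p, test_used = test,
                 mean_diff = mean(d)), class = "verdict")
}

#' @export
print.verdict <- function(x, ...) {
  cat(sprintf("<verdict> %s  p=%.3g  test=%s\n", x$symbol, x$p_value, x$test_used))
  invisible(x)
}
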