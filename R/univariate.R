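#' Benjamini-Hochberg step-up FDR control
#'
#' Computes BH-adjusted q-values and the reject set at level \code{delta}.
#' The q-value of the i-th smallest p is \code{min_{j >= i} m p_(j) / j},
#' capped at 1; a feature is rejected when its q-value is at most
#' \code{delta}.
#'
#' @param pvalues numeric vector of p-values in [0, 1] (names preserved).
#' @param delta FDR level (default 0.10).
#' @return list with \code{q} (adjusted q-values) and \code{reject}
#'   (logical vector).
#' @export
bh_fdr <- function(pvalues, delta = 0.10) {
  assert_fraction(delta, "delta")
  if (length(pvalues) == 0) {
    return(list(q = numeric(0), reject = logical(0), delta = delta))
  }
  if (any(is.na(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, reject = q <= delta, delta = delta)
}

# Shared scaffolding for the per-feature screens.
screen_result <- function(feature_id, statistic, p, delta, test) {
  fdr <- bh_fdr(p, delta)
  res <- data.frame(
    feature_id = feature_id,
    statistic = as.numeric(statistic),
    p = as.numeric(p),
    q = as.numeric(fdr$q),
    significant = fdr$reject,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(result = res, test = test, delta = delta),
            class = "univariate_screen")
}

#' @export
print.univariate_screen <- function(x, ...) {
  cat(sprintf("Univariate screen (%s), %d features, delta = %.2f: %d significant\n",
              x$test, nrow(x$result), x$delta, sum(x$result$significant)))
  invisible(x)
}

#' Per-feature Mann-Whitney screen with FDR control
#'
#' Applies a two-sided Mann-Whitney (Wilcoxon rank-sum) test to every
#' feature of a two-group table and controls the false discovery rate by
#' the Benjamini-Hochberg procedure. The exact null distribution is used
#' when the combined sample size is at most \code{exact_max} and the
#' feature has no ties; otherwise the normal approximation with tie
#' correction is used, the variant appropriate at typical study sizes.
#'
#' @param table feature table (no QC rows).
#' @param groups two-level factor/character vector aligned with the rows of
#'   \code{table}.
#' @param delta FDR level (default 0.10).
#' @param exact_max largest combined n for which the exact distribution is
#'   used (default 20); set to 0 to force the asymptotic form.
#' @return \code{univariate_screen} object; \code{$result} has columns
#'   feature_id, statistic (U for the first group level), p, q,
#'   significant.
#' @export
mann_whitney_screen <- function(table, groups, delta = 0.10, exact_max = 20) {
  assert_feature_table(table)
  groups <- as.character(groups)
  if (length(groups) != nrow(table)) {
    stop("`groups` must have one label per sample", call. = FALSE)
  }
  lev <- unique(groups)
  if (length(lev) != 2) {
    stop("exactly two groups are required, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  if (any(table(groups) < 2)) {
    stop("both groups need at least 2 samples", call. = FALSE)
  }
  g1 <- groups == lev[1]
  n <- nrow(table)
  res <- vapply(seq_len(ncol(table)), function(j) {
    x <- table[g1, j]
    y <- table[!g1, j]
    exact <- n <= exact_max && !anyDuplicated(c(x, y))
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, exact = exact, correct = FALSE)
    )
    c(wt$statistic, wt$p.value)
  }, numeric(2))
  screen_result(colnames(table), res[1, ], res[2, ], delta, "mann-whitney")
}

#' Per-feature paired Wilcoxon screen with FDR control
#'
#' Two-sided Wilcoxon signed-rank test on the within-subject T1 - T0
#' differences of every feature, with Benjamini-Hochberg FDR control.
#' Zero differences are dropped (the classical signed-rank convention);
#' a feature whose differences are all zero gets p = 1.
#'
#' @param table feature table containing the paired samples.
#' @param meta data.frame with sample_id, subject_id, timepoint ("T0"/"T1")
#'   covering the rows of \code{table}; every subject must appear exactly
#'   once per timepoint.
#' @param delta FDR level (default 0.10).
#' @param exact_max largest number of pairs for which the exact
#'   distribution is used (default 20).
#' @return \code{univariate_screen} object (statistic = V, the positive-rank
#'   sum).
#' @export
wilcoxon_paired_screen <- function(table, meta, delta = 0.10, exact_max = 20) {
  assert_feature_table(table)
  pairs <- match_pairs(meta, rownames(table))
  if (nrow(pairs) < 5) {
    warning("fewer than 5 pairs: the exact signed-rank test cannot reach ",
            "typical significance levels", call. = FALSE)
  }
  d <- table[pairs$t1, , drop = FALSE] - table[pairs$t0, , drop = FALSE]
  res <- vapply(seq_len(ncol(d)), function(j) {
    dj <- d[, j]
    dj <- dj[dj != 0]
    if (length(dj) == 0) {
      return(c(0, 1))
    }
    exact <- length(dj) <= exact_max && !anyDuplicated(abs(dj))
    wt <- suppressWarnings(
      stats::wilcox.test(dj, exact = exact, correct = FALSE)
    )
    c(wt$statistic, wt$p.value)
  }, numeric(2))
  screen_result(colnames(table), res[1, ], res[2, ], delta, "wilcoxon-paired")
}

# Resolve the T0/T1 sample ids per subject; errors name unmatched subjects.
match_pairs <- function(meta, sample_ids) {
  m <- meta[meta$sample_id %in% sample_ids & !is.na(meta$subject_id) &
              meta$timepoint %in% c("T0", "T1"), , drop = FALSE]
  split_tp <- split(m, m$subject_id)
  bad <- names(split_tp)[vapply(split_tp, function(s) {
    !setequal(s$timepoint, c("T0", "T1")) || nrow(s) != 2
  }, logical(1))]
  if (length(bad)) {
    stop("subject(s) without exactly one T0 and one T1 sample: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (length(split_tp) == 0) stop("no paired samples found", call. = FALSE)
  data.frame(
    subject_id = names(split_tp),
    t0 = vapply(split_tp, function(s) s$sample_id[s$timepoint == "T0"], ""),
    t1 = vapply(split_tp, function(s) s$sample_id[s$timepoint == "T1"], ""),
    row.names = NULL, stringsAsFactors = FALSE
  )
}
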