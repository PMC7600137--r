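#' Filter features by QC coefficient of variation
#'
#' Removes every feature whose coefficient of variation (sample standard
#' deviation over mean, computed on the observed intensities of the pooled
#' QC replicate injections) exceeds \code{threshold}. This is the standard
#' untargeted-LC-MS technical-reproducibility filter: a feature that cannot
#' be measured reproducibly on identical pooled material carries no usable
#' biological signal.
#'
#' @param table feature table (samples x features) including the QC rows.
#' @param qc_sample_ids sample ids of the QC replicate rows (>= 2).
#' @param threshold CV threshold; features with CV > threshold are excluded
#'   (default 0.25).
#' @param drop_qc drop the QC rows from the returned table (default TRUE;
#'   QC injections have served their purpose once the filter is applied).
#' @return list with \code{table} (filtered) and \code{report}, a data.frame
#'   of removed features with their CV and the reason
#'   (\code{"cv_above_threshold"}, \code{"zero_mean"}, \code{"no_qc_signal"}).
#' @export
qc_cv_filter <- function(table, qc_sample_ids, threshold = 0.25,
                         drop_qc = TRUE) {
  assert_feature_table(table)
  assert_fraction(threshold, "threshold", hi = Inf)
  qc_sample_ids <- as.character(qc_sample_ids)
  if (!all(qc_sample_ids %in% rownames(table))) {
    stop("unknown QC sample id(s): ",
         paste(setdiff(qc_sample_ids, rownames(table)), collapse = ", "),
         call. = FALSE)
  }
  if (length(qc_sample_ids) < 2) {
    stop("at least 2 QC samples are required to estimate a CV", call. = FALSE)
  }
  qc <- table[qc_sample_ids, , drop = FALSE]
  n_obs <- colSums(!is.na(qc))
  m <- colMeans(qc, na.rm = TRUE)
  s <- apply(qc, 2, stats::sd, na.rm = TRUE)  # n-1 denominator
  cv <- s / m

  reason <- rep(NA_character_, ncol(table))
  reason[n_obs == 0] <- "no_qc_signal"
  reason[n_obs > 0 & m == 0] <- "zero_mean"
  reason[is.na(reason) & n_obs < 2] <- "no_qc_signal"
  reason[is.na(reason) & cv > threshold] <- "cv_above_threshold"
  drop <- !is.na(reason)

  report <- data.frame(
    feature_id = colnames(table)[drop],
    qc_cv = cv[drop],
    reason = reason[drop],
    row.names = NULL, stringsAsFactors = FALSE
  )
  out <- table[, !drop, drop = FALSE]
  if (drop_qc) {
    out <- out[!(rownames(out) %in% qc_sample_ids), , drop = FALSE]
  }
  list(table = out, report = report, threshold = threshold)
}

#' Impute missing values from below the observed feature minimum
#'
#' Each missing cell of a feature is replaced by an independent uniform draw
#' strictly between zero and the minimum observed intensity of that feature,
#' the usual treatment for values missing because they fell below the
#' effective detection level. Observed values are untouched, so the rank
#' order of observed intensities within a feature is preserved.
#'
#' @param table feature table with NA for missing cells.
#' @param seed RNG seed for reproducible draws.
#' @return complete feature table, with attribute \code{"n_imputed"}.
#' @export
impute_missing <- function(table, seed = NULL) {
  assert_feature_table(table)
  miss <- is.na(table)
  if (!any(miss)) {
    attr(table, "n_imputed") <- 0L
    return(table)
  }
  all_missing <- colSums(!miss) == 0
  if (any(all_missing)) {
    stop("feature(s) entirely missing, cannot impute: ",
         paste(colnames(table)[all_missing], collapse = ", "), call. = FALSE)
  }
  with_seed(seed, {
    for (j in which(colSums(miss) > 0)) {
      lo <- min(table[, j], na.rm = TRUE)
      idx <- which(miss[, j])
      table[idx, j] <- runif(length(idx), min = 0, max = lo)
    }
    attr(table, "n_imputed") <- sum(miss)
    table
  })
}

#' Probabilistic quotient normalization
#'
#' Corrects sample-to-sample dilution: for each sample the quotients of its
#' intensities to a reference spectrum are formed and the sample is divided
#' by the median quotient, the most probable single dilution factor.
#'
#' @param table complete, strictly positive feature table (impute first).
#' @param reference \code{"median"} (default: per-feature median spectrum of
#'   \code{table}) or a numeric vector of length \code{ncol(table)}.
#' @return list with \code{table} (normalized) and \code{quotients}, the
#'   per-sample median quotient applied.
#' @export
pqn_normalize <- function(table, reference = "median") {
  assert_feature_table(table)
  if (anyNA(table)) {
    stop("table contains missing values; run impute_missing() before PQN",
         call. = FALSE)
  }
  if (any(table <= 0)) {
    stop("table contains nonpositive entries; PQN requires strictly ",
         "positive intensities (impute first)", call. = FALSE)
  }
  if (identical(reference, "median")) {
    ref <- apply(table, 2, stats::median)
  } else {
    ref <- as.numeric(reference)
    if (length(ref) != ncol(table)) {
      stop("`reference` must have one value per feature", call. = FALSE)
    }
  }
  use <- ref > 0
  if (!any(use)) stop("reference spectrum has no positive entries", call. = FALSE)
  q <- apply(table[, use, drop = FALSE], 1,
             function(x) stats::median(x / ref[use]))
  out <- table / q
  list(table = out, quotients = stats::setNames(q, rownames(table)),
       reference = ref)
}

#' Log-transform and mean-center a feature table
#'
#' Natural log applied elementwise, then each feature's mean is subtracted.
#' The log base only rescales columns and is immaterial to centered
#' projection models; it is exposed for completeness.
#'
#' @param table strictly positive feature table.
#' @param base logarithm base (default \code{exp(1)}).
#' @return feature table of centered log intensities (column means 0).
#' @export
log_center <- function(table, base = exp(1)) {
  assert_feature_table(table)
  bad <- which(is.na(table) | table <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "nonpositive or missing entry at sample '%s', feature '%s'; %s",
      rownames(table)[bad[1, 1]], colnames(table)[bad[1, 2]],
      "log_center() requires strictly positive complete data"
    ), call. = FALSE)
  }
  lx <- log(table, base = base)
  scale(lx, center = TRUE, scale = FALSE)[, , drop = FALSE]
}

#' Autoscale a feature table
#'
#' Centers each feature to mean zero and scales to unit sample standard
#' deviation (n-1 denominator), the conventional pretreatment for targeted
#' panels where analytes live on incomparable concentration scales.
#' Constant features cannot be scaled and are dropped with a warning.
#'
#' @param table complete feature table.
#' @return autoscaled feature table.
#' @export
autoscale <- function(table) {
  assert_feature_table(table)
  if (anyNA(table)) {
    stop("table contains missing values; impute before autoscaling",
         call. = FALSE)
  }
  s <- apply(table, 2, stats::sd)
  if (any(s == 0)) {
    warning("dropping constant feature(s): ",
            paste(colnames(table)[s == 0], collapse = ", "), call. = FALSE)
    table <- table[, s > 0, drop = FALSE]
    s <- s[s > 0]
  }
  scale(table, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Impute targeted measurements below the limit of quantification
#'
#' Censored entries (NA, or values at or below the analyte's LOQ when
#' \code{censor_at_loq = TRUE}) are replaced by uniform draws in
#' (0, LOQ); quantified entries are untouched.
#'
#' @param values analyte measurement matrix (samples x analytes); NA marks
#'   a below-LOQ determination.
#' @param loq named per-analyte limit of quantification (> 0), or a single
#'   value recycled.
#' @param seed RNG seed.
#' @param censor_at_loq also treat observed values <= LOQ as censored
#'   (default FALSE: only NA cells are censored).
#' @return completed matrix with attribute \code{"n_imputed"}.
#' @export
impute_below_loq <- function(values, loq, seed = NULL, censor_at_loq = FALSE) {
  assert_feature_table(values, arg = "values")
  p <- ncol(values)
  if (length(loq) == 1 && is.null(names(loq))) {
    loq <- stats::setNames(rep(as.numeric(loq), p), colnames(values))
  }
  loq <- loq[colnames(values)]
  cens <- is.na(values)
  if (censor_at_loq) {
    cens <- cens | sweep(values, 2, as.numeric(loq), `<=`)
    cens[is.na(cens)] <- TRUE
  }
  has_cens <- colSums(cens) > 0
  bad <- has_cens & (is.na(loq) | loq <= 0)
  if (any(bad)) {
    stop("missing or nonpositive LOQ for censored analyte(s): ",
         paste(colnames(values)[bad], collapse = ", "), call. = FALSE)
  }
  if (!any(cens)) {
    attr(values, "n_imputed") <- 0L
    return(values)
  }
  with_seed(seed, {
    for (j in which(has_cens)) {
      idx <- which(cens[, j])
      values[idx, j] <- runif(length(idx), min = 0, max = loq[j])
    }
    attr(values, "n_imputed") <- sum(cens)
    values
  })
}

#' Full untargeted preprocessing chain
#'
#' Applies, in order: QC-CV feature filter, below-minimum stochastic
#' imputation, probabilistic quotient normalization, log transform and
#' mean centering. The order is fixed: normalization and the log transform
#' require complete positive data, which imputation guarantees.
#'
#' @param table raw feature table including QC rows.
#' @param qc_sample_ids ids of the QC replicate rows.
#' @param cv_threshold QC CV filter threshold (default 0.25).
#' @param seed RNG seed for the imputation draws.
#' @return list with \code{table} (analysis-ready matrix, QC rows removed)
#'   and \code{report} (filter report, imputation count, PQN quotients).
#' @export
preprocess_untargeted <- function(table, qc_sample_ids, cv_threshold = 0.25,
                                  seed = NULL) {
  filt <- qc_cv_filter(table, qc_sample_ids, threshold = cv_threshold)
  imp <- impute_missing(filt$table, seed = seed)
  pqn <- pqn_normalize(imp)
  out <- log_center(pqn$table)
  list(
    table = out,
    report = list(
      removed_features = filt$report,
      n_imputed = attr(imp, "n_imputed"),
      pqn_quotients = pqn$quotients,
      transform = "log-center"
    )
  )
}

#' Targeted preprocessing chain
#'
#' Below-LOQ stochastic imputation followed by autoscaling.
#'
#' @inheritParams impute_below_loq
#' @return list with \code{table} and \code{report}.
#' @export
preprocess_targeted <- function(values, loq, seed = NULL,
                                censor_at_loq = FALSE) {
  imp <- impute_below_loq(values, loq, seed = seed,
                          censor_at_loq = censor_at_loq)
  out <- autoscale(imp)
  list(table = out,
       report = list(n_imputed = attr(imp, "n_imputed"),
                     transform = "autoscale"))
}
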