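#' PLS-DA stability selection with out-of-bag MCC
#'
#' Bootstrap stability selection driven by VIP ranking. For each of
#' \code{B} stratified bootstrap subsamples a PLS-DA model is fitted on the
#' in-bag samples; a feature is "selected" in that subsample when its VIP
#' exceeds \code{vip_cut}, and the out-of-bag samples are predicted by the
#' in-bag model. A feature's selection frequency is the fraction of
#' subsamples selecting it. To decide which frequencies are larger than
#' chance, the whole procedure is repeated on \code{n_null} datasets with
#' permuted class labels and the observed frequencies are compared against
#' the (1 - alpha) quantile of the pooled null frequencies: features above
#' it form the relevant set. Each sample's out-of-bag class is the majority
#' vote over the subsamples that left it out (ties broken by the mean
#' out-of-bag fitted response), and MCCoob is the Matthews correlation of
#' those votes against the true labels.
#'
#' For paired (multilevel) data pass \code{subjects}: resampling then
#' operates on whole subjects, so a sample and its mirrored within-subject
#' difference are always in-bag or out-of-bag together, and the null
#' calibration swaps the two labels within randomly chosen subjects
#' instead of permuting labels globally.
#'
#' @param table preprocessed feature table.
#' @param labels two-level labels.
#' @param A number of latent variables (default 2).
#' @param B number of bootstrap subsamples (default 200).
#' @param alpha significance level of the relevance call (default 0.05).
#' @param vip_cut VIP threshold marking a feature selected within one
#'   subsample (default 1, the mean-square level of VIP).
#' @param n_null number of label-permuted runs used to calibrate the
#'   relevance threshold (default 20).
#' @param subjects optional subject id per row for paired designs.
#' @param seed RNG seed.
#' @return object of class \code{stability_selection}: \code{frequency}
#'   (per-feature selection frequency), \code{relevant} (feature ids),
#'   \code{threshold} (calibrated frequency threshold), \code{mcc_oob},
#'   \code{oob_class} and \code{oob_votes} (per-sample), \code{B},
#'   \code{alpha}, \code{vip_cut}, \code{A}.
#' @export
stability_selection <- function(table, labels, A = 2, B = 200, alpha = 0.05,
                                vip_cut = 1, n_null = 20, subjects = NULL,
                                seed = NULL) {
  assert_feature_table(table)
  labels <- as.character(labels)
  if (B < 2) stop("`B` must be at least 2", call. = FALSE)
  assert_fraction(alpha, "alpha")
  lev <- sort(unique(labels))
  if (length(lev) != 2) stop("exactly two classes are required", call. = FALSE)
  if (!is.null(subjects) && length(subjects) != nrow(table)) {
    stop("`subjects` must have one id per sample", call. = FALSE)
  }
  with_seed(seed, {
    obs <- bootstrap_ensemble(table, labels, A, B, vip_cut, subjects,
                              collect_oob = TRUE)
    null_freq <- if (n_null > 0) {
      unlist(lapply(seq_len(n_null), function(i) {
        perm <- permute_labels(labels, subjects)
        bootstrap_ensemble(table, perm, A, B, vip_cut, subjects,
                           collect_oob = FALSE)$frequency
      }), use.names = FALSE)
    } else {
      numeric(0)
    }
    threshold <- if (length(null_freq)) {
      as.numeric(stats::quantile(null_freq, 1 - alpha, type = 1))
    } else {
      vip_cut_threshold_default(alpha)
    }
    relevant <- colnames(table)[obs$frequency > threshold]

    votes <- obs$votes
    oob_class <- apply_votes(votes, obs$resp_sum, lev)
    m <- mcc(truth = labels, pred = oob_class)
    structure(list(
      frequency = stats::setNames(obs$frequency, colnames(table)),
      relevant = relevant, threshold = threshold, null_frequencies = null_freq,
      mcc_oob = m, oob_class = oob_class,
      oob_votes = votes, B = B, alpha = alpha, vip_cut = vip_cut, A = A,
      levels = lev
    ), class = "stability_selection")
  })
}

# Fallback threshold when calibration is disabled: a fixed high frequency.
vip_cut_threshold_default <- function(alpha) 1 - alpha

# One bootstrap ensemble: selection counts and (optionally) OOB votes.
bootstrap_ensemble <- function(table, labels, A, B, vip_cut, subjects,
                               collect_oob) {
  n <- nrow(table)
  p <- ncol(table)
  lev <- sort(unique(labels))
  sel_count <- numeric(p)
  votes <- matrix(0L, n, 2, dimnames = list(rownames(table), lev))
  resp_sum <- numeric(n)
  cls_idx <- lapply(lev, function(l) which(labels == l))
  subj_split <- if (!is.null(subjects)) split(seq_len(n), subjects) else NULL

  for (b in seq_len(B)) {
    for (retry in 1:10) {
      if (is.null(subjects)) {
        inbag <- unlist(lapply(cls_idx, function(ix) {
          ix[sample.int(length(ix), length(ix), replace = TRUE)]
        }), use.names = FALSE)
      } else {
        drawn <- sample.int(length(subj_split), length(subj_split),
                            replace = TRUE)
        inbag <- unlist(subj_split[drawn], use.names = FALSE)
      }
      if (length(unique(labels[inbag])) == 2) break
      if (retry == 10) stop("bootstrap subsample kept missing a class",
                            call. = FALSE)
    }
    oob <- setdiff(seq_len(n), unique(inbag))
    A_b <- min(A, length(unique(inbag)) - 1L)
    Xi <- table[inbag, , drop = FALSE]
    rownames(Xi) <- make.unique(rownames(Xi))  # resampling duplicates rows
    fit <- fit_plsda(Xi, labels[inbag], A = A_b)
    sel_count <- sel_count + (vip(fit) > vip_cut)
    if (collect_oob && length(oob)) {
      yhat <- predict(fit, table[oob, , drop = FALSE], type = "response")
      cls <- ifelse(yhat >= 0, lev[2], lev[1])
      for (k in seq_along(oob)) {
        votes[oob[k], cls[k]] <- votes[oob[k], cls[k]] + 1L
      }
      resp_sum[oob] <- resp_sum[oob] + yhat
    }
  }
  list(frequency = sel_count / B, votes = votes, resp_sum = resp_sum)
}

# Majority OOB vote per sample; ties broken by the mean fitted response;
# samples never out-of-bag get NA.
apply_votes <- function(votes, resp_sum, lev) {
  total <- rowSums(votes)
  out <- rep(NA_character_, nrow(votes))
  maj <- votes[, 2] - votes[, 1]
  out[total > 0 & maj > 0] <- lev[2]
  out[total > 0 & maj < 0] <- lev[1]
  tie <- total > 0 & maj == 0
  out[tie] <- ifelse(resp_sum[tie] >= 0, lev[2], lev[1])
  stats::setNames(out, rownames(votes))
}

# Label permutation for the null calibration: global permutation for
# independent samples; within-subject swap for paired designs.
permute_labels <- function(labels, subjects = NULL) {
  if (is.null(subjects)) {
    return(sample(labels))
  }
  out <- labels
  for (ix in split(seq_along(labels), subjects)) {
    if (stats::runif(1) < 0.5) out[ix] <- rev(out[ix])
  }
  out
}

#' @export
print.stability_selection <- function(x, ...) {
  cat(sprintf(
    "Stability selection: B = %d, A = %d, alpha = %.2f\n  %d relevant feature(s) (frequency > %.3f); MCCoob = %.3f\n",
    x$B, x$A, x$alpha, length(x$relevant), x$threshold, x$mcc_oob))
  invisible(x)
}

#' Multilevel transform for paired two-timepoint data
#'
#' Converts a paired T0/T1 table into the signed within-subject difference
#' form used by multilevel PLS-DA: each subject contributes one row
#' \code{x_T1 - x_T0} labeled \code{"+"} and its mirror
#' \code{x_T0 - x_T1} labeled \code{"-"}. A classifier that separates the
#' two labels has found a consistent treatment direction across subjects;
#' between-subject variation cancels in the differences.
#'
#' @param table feature table containing both timepoints.
#' @param meta sample metadata (sample_id, subject_id, timepoint).
#' @return list with \code{table} (2 x n_subjects rows), \code{labels}
#'   ("+"/"-"), \code{subjects} (subject id per row).
#' @export
multilevel_transform <- function(table, meta) {
  assert_feature_table(table)
  pairs <- match_pairs(meta, rownames(table))
  d <- table[pairs$t1, , drop = FALSE] - table[pairs$t0, , drop = FALSE]
  out <- rbind(d, -d)
  rownames(out) <- c(paste0(pairs$subject_id, ".up"),
                     paste0(pairs$subject_id, ".down"))
  list(table = out,
       labels = rep(c("+", "-"), each = nrow(pairs)),
       subjects = rep(pairs$subject_id, 2))
}
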