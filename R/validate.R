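# Stratified fold assignment: each class is split as evenly as possible
# over the folds. Returns an integer fold id per sample.
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (lev in unique(labels)) {
    idx <- which(labels == lev)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Cross-validated Matthews correlation of a PLS-DA model
#'
#' Stratified k-fold cross-validation: in each split the model (including
#' its column centering) is re-estimated on the training folds only, the
#' held-out samples are predicted, and all held-out predictions are pooled
#' into a single confusion matrix whose MCC is returned.
#'
#' @param table feature table.
#' @param labels two-level labels.
#' @param A number of latent variables.
#' @param folds number of folds (default 5).
#' @param seed RNG seed controlling the fold assignment.
#' @param subjects optional subject id per row; when given, folds are
#'   assigned at the subject level so paired rows never straddle a split.
#' @return list with \code{mcc}, \code{predictions} (pooled held-out
#'   classes) and \code{fold} (assignment).
#' @export
cross_validate_mcc <- function(table, labels, A = 2, folds = 5, seed = NULL,
                               subjects = NULL) {
  assert_feature_table(table)
  labels <- as.character(labels)
  if (folds < 2) stop("`folds` must be at least 2", call. = FALSE)
  if (is.null(subjects) && any(table(labels) < folds)) {
    warning("a class has fewer members than folds; some folds will miss it",
            call. = FALSE)
  }
  with_seed(seed, {
    fold <- if (is.null(subjects)) {
      stratified_folds(labels, folds)
    } else {
      subj <- unique(subjects)
      sf <- stats::setNames(rep_len(seq_len(folds),
                                    length(subj))[sample.int(length(subj))],
                            subj)
      as.integer(sf[subjects])
    }
    pred <- rep(NA_character_, nrow(table))
    for (k in sort(unique(fold))) {
      tr <- fold != k
      # training fold can support at most n_train - 1 components
      A_k <- min(A, sum(tr) - 1L)
      fit <- fit_plsda(table[tr, , drop = FALSE], labels[tr], A = A_k)
      pred[!tr] <- predict(fit, table[!tr, , drop = FALSE])
    }
    list(mcc = mcc(truth = labels, pred = pred),
         predictions = stats::setNames(pred, rownames(table)),
         fold = fold)
  })
}

#' Permutation test for a PLS-DA model
#'
#' Tests whether the cross-validated MCC could have arisen without any
#' class structure: the labels are permuted \code{n_perm} times, the
#' cross-validated MCC recomputed each time, and the p-value is
#' \code{(1 + #(null >= observed)) / (1 + n_perm)}.
#'
#' @inheritParams cross_validate_mcc
#' @param n_perm number of label permutations (default 1000).
#' @return list with \code{p}, \code{observed} (MCCcv) and \code{null}
#'   (permutation distribution).
#' @export
permutation_test <- function(table, labels, A = 2, folds = 5, n_perm = 1000,
                             seed = NULL, subjects = NULL) {
  if (n_perm < 1) stop("`n_perm` must be at least 1", call. = FALSE)
  labels <- as.character(labels)
  with_seed(seed, {
    obs <- cross_validate_mcc(table, labels, A = A, folds = folds,
                              seed = NULL, subjects = subjects)$mcc
    null <- vapply(seq_len(n_perm), function(i) {
      cross_validate_mcc(table, permute_labels(labels, subjects), A = A,
                         folds = folds, seed = NULL,
                         subjects = subjects)$mcc
    }, numeric(1))
    list(p = (1 + sum(null >= obs)) / (1 + n_perm), observed = obs,
         null = null)
  })
}

#' Choose the number of PLS-DA latent variables by cross-validation
#'
#' Evaluates \code{cross_validate_mcc} for A in \code{1:A_max} (capped by
#' the data rank) and returns the smallest A attaining the maximal MCC.
#'
#' @inheritParams cross_validate_mcc
#' @param A_max largest number of components considered (default 5).
#' @return list with \code{A}, \code{mcc} (at the chosen A) and
#'   \code{mcc_by_A}.
#' @export
select_ncomp <- function(table, labels, A_max = 5, folds = 5, seed = NULL,
                         subjects = NULL) {
  A_max <- min(A_max, nrow(table) - ceiling(nrow(table) / folds) - 1L,
               ncol(table))
  A_max <- max(1L, A_max)
  mccs <- vapply(seq_len(A_max), function(a) {
    cross_validate_mcc(table, labels, A = a, folds = folds, seed = seed,
                       subjects = subjects)$mcc
  }, numeric(1))
  best <- which.max(mccs)  # ties resolve to the smallest A
  list(A = as.integer(best), mcc = mccs[best], mcc_by_A = mccs)
}
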