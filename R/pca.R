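#' PCA outlier screening with Hotelling T2 and Q statistics
#'
#' Fits a principal component analysis on a (single-group) feature table
#' and flags samples exceeding either the Hotelling T2 control limit in the
#' model plane or the Q (squared prediction error) limit in the residual
#' space, at significance level \code{alpha}.
#'
#' The T2 limit uses the F-distribution form
#' \eqn{A(n-1)(n+1)/(n(n-A)) \cdot F_{A, n-A, 1-\alpha}}; the Q limit uses
#' the Jackson-Mudholkar approximation from the residual eigenvalues.
#' The number of components defaults to the smallest A whose cumulative
#' explained variance reaches \code{var_explained}, capped so that the
#' residual space is nonempty.
#'
#' @param table feature table of one group (>= 3 samples).
#' @param alpha significance level of both tests (default 0.05).
#' @param A number of components; \code{NULL} (default) applies the
#'   cumulative-variance rule.
#' @param var_explained target cumulative explained variance for the
#'   automatic choice of A (default 0.8).
#' @return object of class \code{pca_screen}: \code{scores},
#'   \code{loadings}, \code{explained} (variance fractions), \code{A},
#'   \code{t2}, \code{q} (per-sample statistics), \code{t2_limit},
#'   \code{q_limit}, \code{flagged} (sample ids exceeding either limit).
#' @export
pca_outlier_screen <- function(table, alpha = 0.05, A = NULL,
                               var_explained = 0.8) {
  assert_feature_table(table)
  assert_fraction(alpha, "alpha")
  n <- nrow(table)
  if (n < 3) stop("at least 3 samples are required", call. = FALSE)
  pc <- stats::prcomp(table, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- sum(ev > max(ev) * 1e-12)
  max_A <- max(1L, rank - 1L)  # keep a residual space for the Q statistic
  if (is.null(A)) {
    cum <- cumsum(ev[seq_len(rank)]) / sum(ev[seq_len(rank)])
    A <- min(which(cum >= var_explained)[1], max_A)
    if (is.na(A)) A <- max_A
  } else {
    A <- assert_count(A, "A", min = 1)
    if (A > rank) {
      stop(sprintf("A = %d exceeds the rank of the data (%d)", A, rank),
           call. = FALSE)
    }
  }
  scores <- pc$x[, seq_len(A), drop = FALSE]
  lam <- ev[seq_len(A)]

  t2 <- rowSums(sweep(scores^2, 2, lam, `/`))
  t2_limit <- if (n > A) {
    (A * (n - 1) * (n + 1)) / (n * (n - A)) *
      stats::qf(1 - alpha, A, n - A)
  } else {
    Inf
  }

  resid <- pc$x[, -seq_len(A), drop = FALSE]
  q <- rowSums(resid^2)
  lam_res <- ev[-seq_len(A)]
  lam_res <- lam_res[lam_res > max(ev) * 1e-12]
  q_limit <- jackson_mudholkar_limit(lam_res, alpha)

  flagged <- rownames(table)[t2 > t2_limit | q > q_limit]
  structure(list(
    scores = scores, loadings = pc$rotation[, seq_len(A), drop = FALSE],
    center = pc$center, eigenvalues = ev,
    explained = ev / sum(ev), A = A, alpha = alpha,
    t2 = stats::setNames(t2, rownames(table)), t2_limit = t2_limit,
    q = stats::setNames(q, rownames(table)), q_limit = q_limit,
    flagged = flagged
  ), class = "pca_screen")
}

# Jackson-Mudholkar control limit for the squared prediction error, from
# the eigenvalues of the residual subspace.
jackson_mudholkar_limit <- function(lam_res, alpha) {
  if (length(lam_res) == 0) return(Inf)
  th1 <- sum(lam_res)
  th2 <- sum(lam_res^2)
  th3 <- sum(lam_res^3)
  h0 <- 1 - 2 * th1 * th3 / (3 * th2^2)
  if (!is.finite(h0) || h0 == 0) return(Inf)
  z <- stats::qnorm(1 - alpha)
  inner <- z * sqrt(2 * th2 * h0^2) / th1 + 1 + th2 * h0 * (h0 - 1) / th1^2
  if (inner < 0) return(0)
  th1 * inner^(1 / h0)
}

#' Score new samples against a fitted PCA screening model
#'
#' Computes the Hotelling T2 and Q statistics of new samples in the model
#' of \code{\link{pca_outlier_screen}}; the control limits stored in the
#' model are derived for exactly this use (a future observation from the
#' in-control distribution exceeds each limit with probability alpha).
#'
#' @param object \code{pca_screen} model.
#' @param newdata feature table over the model's features.
#' @param ... unused.
#' @return data.frame with sample_id, t2, q, flagged.
#' @export
predict.pca_screen <- function(object, newdata, ...) {
  newdata <- newdata[, rownames(object$loadings), drop = FALSE]
  Xc <- sweep(newdata, 2, object$center)
  scores <- Xc %*% object$loadings
  t2 <- rowSums(sweep(scores^2, 2, object$eigenvalues[seq_len(object$A)], `/`))
  resid <- Xc - tcrossprod(scores, object$loadings)
  q <- rowSums(resid^2)
  data.frame(sample_id = rownames(newdata), t2 = t2, q = q,
             flagged = t2 > object$t2_limit | q > object$q_limit,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' @export
print.pca_screen <- function(x, ...) {
  cat(sprintf("PCA outlier screen: A = %d, alpha = %.2f; %d/%d sample(s) flagged\n",
              x$A, x$alpha, length(x$flagged), length(x$t2)))
  invisible(x)
}
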