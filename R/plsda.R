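#' Fit a two-class PLS-DA model
#'
#' Partial least squares discriminant analysis for two classes: the class
#' labels are coded -1/+1 and a single-response PLS regression (NIPALS,
#' sequential component extraction with X deflation) is fitted on
#' column-centered data. A sample is assigned to the class whose side of
#' the zero threshold its fitted response falls on.
#'
#' @param table feature table (samples x features), already preprocessed.
#' @param labels two-level factor/character vector, one label per row.
#' @param A number of latent variables (1 <= A <= min(n - 1, p)).
#' @param center center the columns of \code{table} (default TRUE; disable
#'   only if the table is centered upstream).
#' @return object of class \code{plsda}, with components: \code{weights}
#'   (W, p x A), \code{loadings} (P), \code{y_loadings} (q, length A),
#'   \code{scores} (T, n x A), \code{coef} (regression vector
#'   B = W (P'W)^-1 q), class coding map, centering record, fitted
#'   responses and fitted classes.
#' @export
fit_plsda <- function(table, labels, A = 2, center = TRUE) {
  assert_feature_table(table)
  labels <- as.character(labels)
  lev <- sort(unique(labels))
  if (length(lev) != 2) {
    stop("PLS-DA requires exactly two classes, got: ",
         paste(lev, collapse = ", "), call. = FALSE)
  }
  if (any(table(labels) < 2)) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  n <- nrow(table)
  p <- ncol(table)
  A <- assert_count(A, "A", min = 1)
  if (A > min(n - 1L, p)) {
    stop(sprintf("A = %d exceeds min(n - 1, p) = %d", A, min(n - 1L, p)),
         call. = FALSE)
  }
  y <- ifelse(labels == lev[2], 1, -1)
  x_center <- if (center) colMeans(table) else rep(0, p)
  X <- sweep(table, 2, x_center)
  if (all(abs(X) < .Machine$double.eps * 1e3)) {
    stop("X has (numerically) zero variance", call. = FALSE)
  }
  y_center <- mean(y)
  yc <- y - y_center

  W <- matrix(0, p, A, dimnames = list(colnames(table), NULL))
  P <- matrix(0, p, A, dimnames = list(colnames(table), NULL))
  Tm <- matrix(0, n, A, dimnames = list(rownames(table), NULL))
  q <- numeric(A)
  Xd <- X
  yd <- yc
  for (a in seq_len(A)) {
    w <- crossprod(Xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * 1e3) {
      stop(sprintf("component %d: residual X carries no covariance with the response", a),
           call. = FALSE)
    }
    w <- w / nw
    t <- Xd %*% w
    tt <- sum(t^2)
    pvec <- crossprod(Xd, t)[, 1] / tt
    q[a] <- sum(yd * t) / tt
    Xd <- Xd - tcrossprod(t, pvec)
    yd <- yd - q[a] * t[, 1]
    W[, a] <- w
    P[, a] <- pvec
    Tm[, a] <- t
  }
  # B = W (P'W)^{-1} q maps centered X to fitted centered response
  B <- W %*% solve(crossprod(P, W), q)
  fitted <- as.numeric(X %*% B) + y_center
  model <- structure(list(
    weights = W, loadings = P, y_loadings = q, scores = Tm,
    coef = B[, 1], levels = lev, y = y, x_center = x_center,
    y_center = y_center, A = A, fitted = fitted,
    fitted_class = ifelse(fitted >= 0, lev[2], lev[1])
  ), class = "plsda")
  model
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf("PLS-DA: %d samples x %d features, A = %d (classes: %s = -1, %s = +1)\n",
              nrow(x$scores), length(x$coef), x$A, x$levels[1], x$levels[2]))
  invisible(x)
}

#' Predict from a PLS-DA model
#'
#' @param object fitted \code{\link{fit_plsda}} model.
#' @param newdata feature table with the model's features as columns.
#' @param type \code{"class"} (default), \code{"response"} (fitted numeric
#'   response) or \code{"scores"}.
#' @param ... unused.
#' @export
predict.plsda <- function(object, newdata, type = c("class", "response", "scores"),
                          ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1,
                      dimnames = list("new", names(object$coef)))
  }
  newdata <- newdata[, names(object$coef), drop = FALSE]
  Xc <- sweep(newdata, 2, object$x_center)
  if (type == "scores") {
    # scores via W* = W (P'W)^{-1}
    Wstar <- object$weights %*%
      solve(crossprod(object$loadings, object$weights))
    return(Xc %*% Wstar)
  }
  yhat <- as.numeric(Xc %*% object$coef) + object$y_center
  if (type == "response") return(yhat)
  ifelse(yhat >= 0, object$levels[2], object$levels[1])
}

#' Variable influence on projection (VIP)
#'
#' Per-feature importance of a fitted PLS-DA model:
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{aj}/\|w_a\|)^2 / \sum_a SSY_a}}
#' where \eqn{SSY_a = q_a^2 t_a^\top t_a} is the response variation
#' explained by component \eqn{a}. The mean squared VIP over features is 1,
#' so VIP > 1 marks features contributing more than average.
#'
#' @param model fitted \code{\link{fit_plsda}} model.
#' @return named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "plsda")) stop("`model` must be a plsda fit", call. = FALSE)
  ssy <- model$y_loadings^2 * colSums(model$scores^2)
  if (sum(ssy) <= 0) {
    stop("model explains no response variance; VIP undefined", call. = FALSE)
  }
  W <- model$weights
  Wn2 <- sweep(W^2, 2, colSums(W^2), `/`)   # (w_aj / ||w_a||)^2
  p <- nrow(W)
  v <- sqrt(p * as.numeric(Wn2 %*% ssy) / sum(ssy))
  stats::setNames(v, rownames(W))
}

#' Post-transform a PLS-DA model
#'
#' Rotates the A-dimensional score space of a fitted model into a single
#' predictive direction — the combination of scores with maximal covariance
#' with the coded class response — and A - 1 orthogonal directions that are
#' exactly uncorrelated with the response. The rotation is a change of
#' basis of the score space only: fitted responses and class predictions
#' are unchanged. The orthogonal components isolate structured variation
#' unrelated to the class contrast, which makes score plots directly
#' interpretable (class separation lives on one axis).
#'
#' @param model fitted \code{\link{fit_plsda}} model with A >= 2 (for A = 1
#'   the model is already in predictive form; returned as-is with a
#'   warning).
#' @return object of class \code{plsda_pt}: \code{predictive_scores} (n),
#'   \code{orthogonal_scores} (n x (A-1)), \code{rotation} (A x A
#'   orthonormal, first column = predictive direction), plus the original
#'   model.
#' @export
post_transform <- function(model) {
  if (!inherits(model, "plsda")) stop("`model` must be a plsda fit", call. = FALSE)
  Tm <- model$scores
  A <- model$A
  if (A < 2) {
    warning("A = 1: post-transformation is the identity", call. = FALSE)
    return(structure(list(
      predictive_scores = Tm[, 1], orthogonal_scores = Tm[, 0, drop = FALSE],
      rotation = matrix(1, 1, 1), model = model
    ), class = "plsda_pt"))
  }
  # cov(T v, y) = v' u with u_a = q_a t_a' t_a (scores are mutually
  # orthogonal), so the predictive direction is u/||u|| and any direction
  # orthogonal to u has exactly zero covariance with the response.
  u <- model$y_loadings * colSums(Tm^2)
  u <- u / sqrt(sum(u^2))
  R <- qr.Q(qr(cbind(u, diag(A)[, -which.max(abs(u))])))[, seq_len(A)]
  if (sum(R[, 1] * u) < 0) R[, 1] <- -R[, 1]
  TR <- Tm %*% R
  structure(list(
    predictive_scores = stats::setNames(TR[, 1], rownames(Tm)),
    orthogonal_scores = TR[, -1, drop = FALSE],
    rotation = R,
    model = model
  ), class = "plsda_pt")
}

#' @export
print.plsda_pt <- function(x, ...) {
  cat(sprintf("Post-transformed PLS-DA: 1 predictive + %d orthogonal component(s)\n",
              ncol(x$orthogonal_scores)))
  invisible(x)
}

#' Matthews correlation coefficient
#'
#' Balanced summary of a 2x2 confusion: \eqn{(TP\,TN - FP\,FN) /
#' \sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}}, in [-1, 1]. When any marginal is
#' zero the coefficient is defined as 0.
#'
#' @param tp,tn,fp,fn confusion counts; alternatively pass \code{truth} and
#'   \code{pred} label vectors (with \code{positive} naming the positive
#'   class) and the counts are tabulated.
#' @param truth,pred optional label vectors.
#' @param positive label treated as positive when tabulating.
#' @return MCC in [-1, 1].
#' @export
mcc <- function(tp = NULL, tn = NULL, fp = NULL, fn = NULL,
                truth = NULL, pred = NULL, positive = NULL) {
  if (!is.null(truth)) {
    keep <- !is.na(pred) & !is.na(truth)
    truth <- as.character(truth)[keep]
    pred <- as.character(pred)[keep]
    if (is.null(positive)) positive <- sort(unique(truth))[1]
    tp <- sum(truth == positive & pred == positive)
    tn <- sum(truth != positive & pred != positive)
    fp <- sum(truth != positive & pred == positive)
    fn <- sum(truth == positive & pred != positive)
  }
  counts <- c(tp, tn, fp, fn)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("confusion counts must be nonnegative with a positive total",
         call. = FALSE)
  }
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}
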