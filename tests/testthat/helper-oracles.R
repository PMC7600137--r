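# Independent brute-force oracles used to validate the fast implementations.

# MCC equals the Pearson correlation of the binary truth/prediction vectors;
# expanding a confusion into vectors and calling cor() is an independent
# computation path.
oracle_mcc <- function(tp, tn, fp, fn) {
  truth <- c(rep(1, tp + fn), rep(0, tn + fp))
  pred <- c(rep(1, tp), rep(0, fn), rep(0, tn), rep(1, fp))
  r <- suppressWarnings(stats::cor(truth, pred))
  if (is.na(r)) 0 else r
}

# Literal step-up scan over all ranks.
oracle_bh <- function(p, delta) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0
  for (i in seq_len(m)) {
    if (ps[i] <= i * delta / m) k <- i
  }
  reject <- logical(m)
  if (k > 0) reject[o[seq_len(k)]] <- TRUE
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[o[i]] <- min(1, min(m * ps[i:m] / (i:m)))
  }
  list(q = q, reject = reject)
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments
# (tie-free data only).
oracle_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  u_null <- apply(combs, 2, function(ix) {
    sum(r[ix]) - n1 * (n1 + 1) / 2
  })
  p_lo <- mean(u_null <= u_obs)
  p_hi <- mean(u_null >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Exact two-sided Wilcoxon signed-rank p by enumerating all sign patterns
# (nonzero, tie-free |d| only).
oracle_wsr_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_null <- as.numeric(signs %*% r)
  p_lo <- mean(v_null <= v_obs)
  p_hi <- mean(v_null >= v_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# VIP by explicit per-feature loops straight from the definition.
oracle_vip <- function(model) {
  W <- model$weights
  A <- ncol(W)
  p <- nrow(W)
  ssy <- numeric(A)
  for (a in seq_len(A)) {
    ssy[a] <- model$y_loadings[a]^2 * sum(model$scores[, a]^2)
  }
  out <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(A)) {
      acc <- acc + ssy[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    }
    out[j] <- sqrt(p * acc / sum(ssy))
  }
  out
}

# Annotation matching by a triple loop over feature x adduct x candidate.
oracle_match <- function(features, db, tol_ppm) {
  rules <- adduct_rules()
  out <- character(0)
  for (i in seq_len(nrow(features))) {
    for (r in seq_len(nrow(rules))) {
      if (rules$polarity[r] != features$polarity[i]) next
      M <- features$mz[i] + rules$offset[r]
      for (k in seq_len(nrow(db))) {
        err <- abs(M - db$monoisotopic_mass[k]) / db$monoisotopic_mass[k] * 1e6
        if (err <= tol_ppm) {
          out <- c(out, paste(features$feature_id[i], rules$adduct[r],
                              db$name[k], sep = "|"))
        }
      }
    }
  }
  sort(out)
}
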