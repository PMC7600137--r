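make_qc_table <- function(qc_vals, n_feat = 3) {
  # 2 study samples + QC rows; feature 1 carries qc_vals
  qc <- matrix(rep(10, length(qc_vals) * n_feat), length(qc_vals), n_feat)
  qc[, 1] <- qc_vals
  tab <- rbind(matrix(5, 2, n_feat), qc)
  dimnames(tab) <- list(c("a", "b", paste0("QC", seq_along(qc_vals))),
                        paste0("f", seq_len(n_feat)))
  tab
}

test_that("QC CV filter removes exactly the irreproducible features", {
  tab <- make_qc_table(c(10, 10, 10))
  out <- qc_cv_filter(tab, paste0("QC", 1:3))
  expect_equal(ncol(out$table), 3)           # CV = 0 everywhere: keep all
  expect_equal(nrow(out$report), 0)
  expect_false(any(grepl("QC", rownames(out$table))))

  tab2 <- make_qc_table(c(1, 2, 3))          # CV = 1/2 > 0.25: drop f1
  out2 <- qc_cv_filter(tab2, paste0("QC", 1:3))
  expect_equal(out2$report$feature_id, "f1")
  expect_equal(out2$report$qc_cv, 0.5)
  expect_equal(out2$report$reason, "cv_above_threshold")
  expect_false("f1" %in% colnames(out2$table))

  expect_error(qc_cv_filter(tab, "QC1"), "2 QC samples")
})

test_that("QC CV filter handles zero-mean and all-missing QC features", {
  tab <- make_qc_table(c(0, 0, 0))
  out <- qc_cv_filter(tab, paste0("QC", 1:3))
  expect_equal(out$report$reason, "zero_mean")

  tab2 <- make_qc_table(c(NA, NA, NA))
  out2 <- qc_cv_filter(tab2, paste0("QC", 1:3))
  expect_equal(out2$report$reason, "no_qc_signal")
})

test_that("QC CV filter is idempotent", {
  set.seed(4)
  tab <- exp(rand_table(12, 20) * 0.6 + 6)
  tab[9:12, 1:4] <- tab[9:12, 1:4] * matrix(runif(16, 0.2, 3), 4)
  qc_ids <- rownames(tab)[9:12]
  once <- qc_cv_filter(tab, qc_ids, drop_qc = FALSE)
  twice <- qc_cv_filter(once$table, qc_ids, drop_qc = FALSE)
  expect_identical(once$table, twice$table)
  expect_equal(nrow(twice$report), 0)
})

test_that("imputation draws strictly between zero and the feature minimum", {
  set.seed(9)
  tab <- exp(rand_table(10, 8) + 3)
  tab[sample(length(tab), 15)] <- NA
  filled <- impute_missing(tab, seed = 42)
  expect_false(anyNA(filled))
  expect_equal(attr(filled, "n_imputed"), sum(is.na(tab)))
  for (j in seq_len(ncol(tab))) {
    obs <- tab[!is.na(tab[, j]), j]
    imp <- filled[is.na(tab[, j]), j]
    expect_true(all(imp > 0 & imp < min(obs)))
    expect_identical(filled[!is.na(tab[, j]), j], obs)  # observed untouched
  }
  expect_identical(unclass(filled), unclass(impute_missing(tab, seed = 42)))
  expect_false(identical(filled, impute_missing(tab, seed = 43)))

  clean <- exp(rand_table(4, 3))
  expect_equal(unclass(impute_missing(clean, 1))[, ], clean[, ])

  allna <- tab
  allna[, 2] <- NA
  expect_error(impute_missing(allna, 1), "f2")
})

test_that("PQN matches the hand-worked quotient example", {
  tab <- rbind(s1 = c(2, 4, 8))
  colnames(tab) <- paste0("f", 1:3)
  out <- pqn_normalize(tab, reference = c(1, 2, 2))
  expect_equal(as.numeric(out$table), c(1, 2, 4))   # quotients (2,2,4), med 2
  expect_equal(unname(out$quotients), 2)

  # a sample that is a scaled copy of the reference collapses onto it
  ref <- c(1, 2, 3, 4)
  tab2 <- rbind(s1 = 2 * ref, s2 = ref)
  colnames(tab2) <- paste0("f", 1:4)
  out2 <- pqn_normalize(tab2, reference = ref)
  expect_equal(unname(out2$table["s1", ]), ref)

  # identical samples with the median-spectrum reference are unchanged
  tab3 <- matrix(rep(c(1, 5, 9), each = 4), 4, 3,
                 dimnames = list(paste0("s", 1:4), paste0("f", 1:3)))
  out3 <- pqn_normalize(tab3)
  expect_equal(out3$table, tab3)
  expect_true(all(out3$quotients == 1))
})

test_that("PQN is invariant to per-sample dilution", {
  set.seed(12)
  tab <- exp(rand_table(8, 10))
  ref <- apply(tab, 2, stats::median)
  base <- pqn_normalize(tab, reference = ref)
  diluted <- tab
  diluted[3, ] <- diluted[3, ] * 7.5
  out <- pqn_normalize(diluted, reference = ref)
  expect_equal(out$table[3, ], base$table[3, ])
})

test_that("PQN refuses incomplete or nonpositive tables", {
  tab <- exp(rand_table(3, 3))
  tab[1, 1] <- NA
  expect_error(pqn_normalize(tab), "impute")
  tab[1, 1] <- -1
  expect_error(pqn_normalize(tab), "positive")
})

test_that("log-centering matches hand values and zeroes column means", {
  tab <- rbind(s1 = c(exp(1), 4), s2 = c(exp(3), 4))
  colnames(tab) <- c("f1", "f2")
  out <- log_center(tab)
  expect_equal(unname(out[, "f1"]), c(-1, 1))
  expect_equal(unname(out[, "f2"]), c(0, 0))   # constant feature -> zeros
  set.seed(2)
  big <- exp(rand_table(20, 15))
  expect_lt(max(abs(colMeans(log_center(big)))), 1e-10)

  bad <- tab
  bad[2, 1] <- 0
  expect_error(log_center(bad), "s2.*f1")
})

test_that("autoscaling gives unit variance and drops constants", {
  tab <- rbind(s1 = c(1, 2), s2 = c(3, 2))
  colnames(tab) <- c("f1", "f2")
  expect_warning(out <- autoscale(tab), "f2")
  expect_equal(unname(out[, "f1"]), c(-1, 1) / sqrt(2))  # sd with n-1
  set.seed(6)
  big <- rand_table(15, 8)
  once <- autoscale(big)
  expect_equal(autoscale(once), once, tolerance = 1e-12)  # idempotent
  expect_lt(max(abs(colMeans(once))), 1e-12)
  expect_equal(unname(apply(once, 2, stats::sd)), rep(1, 8))
})

test_that("below-LOQ imputation fills censored cells within (0, LOQ)", {
  set.seed(8)
  vals <- abs(rand_table(6, 4)) + 0.5
  vals[cbind(c(1, 3, 5), c(2, 2, 4))] <- NA
  loq <- stats::setNames(c(0.3, 0.1, 0.2, 0.05), colnames(vals))
  out <- impute_below_loq(vals, loq, seed = 5)
  expect_false(anyNA(out))
  expect_true(all(out[c(1, 3), 2] > 0 & out[c(1, 3), 2] < 0.1))
  expect_true(all(out[5, 4] > 0 & out[5, 4] < 0.05))
  expect_identical(unclass(out), unclass(impute_below_loq(vals, loq, seed = 5)))

  clean <- abs(rand_table(3, 2)) + 1
  expect_equal(unclass(impute_below_loq(clean, 0.1, seed = 1))[, ], clean[, ])
  expect_error(impute_below_loq(vals, c(f1 = 0.3, f2 = NA, f3 = 0.2, f4 = 0.1)),
               "f2")
})

test_that("the untargeted chain enforces its stage order", {
  set.seed(10)
  tab <- exp(rand_table(8, 6))
  tab[2, 3] <- NA
  expect_error(pqn_normalize(tab), "impute")      # PQN before imputation
  expect_error(log_center(tab), "positive|missing")  # log before imputation
  full <- preprocess_untargeted(rbind(tab, pooled_qc_profile(tab, 0.05, 3, 1)),
                                paste0("QC0", 1:3), seed = 3)
  expect_false(anyNA(full$table))
  expect_lt(max(abs(colMeans(full$table))), 1e-10)
  expect_equal(full$report$n_imputed, 1)
})
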