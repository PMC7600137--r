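# Small fixtures built in code.

rand_table <- function(n, p, seed = NULL, prefix = "s") {
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(n * p), n, p,
         dimnames = list(paste0(prefix, seq_len(n)), paste0("f", seq_len(p))))
}

# Two spherical clusters separated by `sep` standard deviations along the
# first `k` features.
two_clusters <- function(n_per = 10, p = 6, sep = 6, k = 2, seed = 1) {
  set.seed(seed)
  X <- rand_table(2 * n_per, p)
  y <- rep(c("a", "b"), each = n_per)
  X[y == "b", seq_len(k)] <- X[y == "b", seq_len(k)] + sep
  list(X = X, y = y)
}

# A small paired study table: n subjects at T0 and T1.
paired_fixture <- function(n = 8, p = 5, shift = 0, seed = 1) {
  set.seed(seed)
  t0 <- rand_table(n, p, prefix = "x")
  rownames(t0) <- paste0("subj", seq_len(n), "_T0")
  t1 <- t0 + matrix(rnorm(n * p, sd = 0.5), n, p)
  t1[, 1] <- t1[, 1] + shift
  rownames(t1) <- paste0("subj", seq_len(n), "_T1")
  meta <- data.frame(
    sample_id = c(rownames(t0), rownames(t1)),
    group = "case",
    subject_id = rep(paste0("subj", seq_len(n)), 2),
    timepoint = rep(c("T0", "T1"), each = n),
    is_qc = FALSE, stringsAsFactors = FALSE
  )
  list(table = rbind(t0, t1), meta = meta)
}

# The bundled six-marker features as they appear in a relevant set.
marker_features <- function() {
  data.frame(
    feature_id = c("4.42@172.1332", "5.53@295.1543",
                   "4.92@198.1864", "2.84@371.2280", "3.12@415.2546",
                   "3.58@520.3342"),
    mz = c(172.1332, 295.1543, 198.1864, 371.2280, 415.2546, 520.3342),
    polarity = c("negative", "negative", "positive", "positive", "positive",
                 "positive"),
    expected = c("9-amino-nonanoic acid", "lactone of PGF-MUM",
                 "12-amino-dodecanoic acid", "N-linoleoyl taurine",
                 "17-phenoxy trinor PGF2alpha ethyl amide",
                 "lysoPC(18:2(9Z;12Z))"),
    stringsAsFactors = FALSE
  )
}
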