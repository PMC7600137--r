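test_that("generated study has the designed dimensions and layout", {
  cfg <- sim_config(n_case = 26, n_control = 16, n_features = 108,
                    n_qc = 5, missing_rate = 0)
  st <- generate_study(cfg)
  expect_equal(dim(st$table), c(26 * 2 + 16 + 5, 108))
  expect_equal(sum(st$meta$is_qc), 5)
  expect_equal(sum(st$meta$group == "case"), 52)
  expect_equal(sum(st$meta$group == "control"), 16)
  # cases appear once per timepoint under the same subject id
  cases <- st$meta[st$meta$group == "case", ]
  expect_true(all(table(cases$subject_id, cases$timepoint) == 1))
  # feature ids parse as time@mass
  ids <- parse_feature_ids(colnames(st$table))
  expect_false(anyNA(ids$rt_min))
  expect_false(anyNA(ids$mz))
  expect_true(all(st$table > 0, na.rm = TRUE))
})

test_that("identical configurations generate bit-identical studies", {
  cfg <- sim_config(seed = 77, effect_size = 1, n_discriminating = 5)
  a <- generate_study(cfg)
  b <- generate_study(cfg)
  expect_identical(a, b)
  d <- generate_study(sim_config(seed = 78, effect_size = 1,
                                 n_discriminating = 5))
  expect_false(identical(a$table, d$table))
})

test_that("missingness hits the requested rate reproducibly", {
  cfg <- sim_config(missing_rate = 0.1, seed = 11)
  a <- generate_study(cfg)
  frac <- mean(is.na(a$table))
  expect_gte(frac, 0.08)
  expect_lte(frac, 0.12)
  expect_identical(is.na(a$table), is.na(generate_study(cfg)$table))
})

test_that("left-censored missingness concentrates in low-intensity cells", {
  cfg <- sim_config(missing_rate = 0.15, seed = 5, censor = TRUE,
                    n_qc = 0)
  st <- generate_study(cfg)
  cfg0 <- sim_config(missing_rate = 0, seed = 5, censor = TRUE, n_qc = 0)
  full <- generate_study(cfg0)$table
  z <- scale(log(full))
  expect_lt(mean(z[is.na(st$table)]), -0.5)
})

test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(n_case = -1), "n_case")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(n_features = 10, n_discriminating = 11),
               "n_discriminating")
  expect_error(generate_study(list()), "sim_config")
})

test_that("planted shifts make univariate p-values monotone in effect size", {
  med_p <- vapply(c(0, 0.5, 1, 2), function(es) {
    ps <- vapply(1:3, function(s) {
      cfg <- sim_config(effect_size = es, n_discriminating = 10,
                        missing_rate = 0, n_qc = 0, seed = 100 + s)
      st <- generate_study(cfg)
      keep <- st$meta$group %in% c("case", "control") &
        st$meta$timepoint %in% c("T0", "none")
      tab <- log(st$table[st$meta$sample_id[keep], ])
      scr <- mann_whitney_screen(tab, st$meta$group[keep])
      stats::median(scr$result$p[scr$result$feature_id %in%
                                   st$truth$discriminating_feature_ids])
    }, numeric(1))
    mean(ps)
  }, numeric(1))
  expect_true(all(diff(med_p) <= 0))
})

test_that("pooled QC replicates converge to the target CV", {
  tab <- exp(rand_table(10, 6, seed = 3) + 8)
  qc0 <- pooled_qc_profile(tab, cv_target = 0, n_rep = 5, seed = 1)
  expect_true(all(apply(qc0, 2, stats::sd) == 0))

  cv_t <- c(0.5, rep(0.1, 5))
  qc <- pooled_qc_profile(tab, cv_target = cv_t, n_rep = 100, seed = 2)
  cv_emp <- apply(qc, 2, stats::sd) / colMeans(qc)
  expect_gte(cv_emp[1], 0.35)
  expect_lte(cv_emp[1], 0.65)

  expect_error(pooled_qc_profile(tab, 0.1, n_rep = 1), "2 QC replicates")
  expect_error(pooled_qc_profile(tab, -0.1, n_rep = 5), "cv_target")

  # CV 0.10 everywhere never trips the 0.25 filter in repeated draws
  removed <- vapply(1:20, function(s) {
    qcs <- pooled_qc_profile(tab, 0.10, n_rep = 5, seed = s)
    full <- rbind(tab, qcs)
    nrow(qc_cv_filter(full, rownames(qcs), threshold = 0.25)$report)
  }, numeric(1))
  expect_gte(mean(removed == 0), 0.95)
})

test_that("study round-trips through the CSV/JSON writers", {
  dir <- withr::local_tempdir()
  st <- generate_study(sim_config(n_case = 4, n_control = 3, n_features = 6,
                                  n_discriminating = 2, n_qc = 2,
                                  missing_rate = 0.1, seed = 2))
  paths <- write_study(st, dir)
  back <- read_feature_table(paths$table)
  expect_equal(back, st$table)
  meta <- utils::read.csv(paths$meta, stringsAsFactors = FALSE)
  expect_equal(meta$sample_id, st$meta$sample_id)
  truth <- jsonlite::read_json(paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$discriminating_feature_ids,
                  st$truth$discriminating_feature_ids)
})
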