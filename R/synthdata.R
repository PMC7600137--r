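#' Configuration for a synthetic breathomics study
#'
#' Builds the parameter set of the synthetic study generator. The defaults
#' emulate the structure of a two-group pediatric EBC study: a case group
#' sampled at two timepoints (T0, before treatment; T1, after), a control
#' group sampled once, pooled QC replicate injections, log-normal feature
#' intensities with a subject random intercept, and a planted subset of
#' group-discriminating features.
#'
#' @param n_case number of case subjects (each contributes a T0 and a T1
#'   sample).
#' @param n_control number of control subjects (one sample each).
#' @param n_features number of "time@mass" features.
#' @param n_discriminating number of features whose log-intensity mean is
#'   shifted between case and control groups.
#' @param effect_size standardized case-vs-control mean shift, in units of the
#'   total within-group log-intensity standard deviation.
#' @param paired_effect standardized T0 to T1 mean shift in the case group,
#'   applied to the same planted feature subset; 0 disables any treatment
#'   effect.
#' @param n_qc number of pooled-QC replicate injections.
#' @param missing_rate fraction of cells set missing (completely at random by
#'   default; see \code{censor}).
#' @param qc_cv_high_fraction fraction of features given a technical QC
#'   coefficient of variation above typical filter thresholds (0.40 vs the
#'   0.10 baseline).
#' @param sigma_log total within-group standard deviation on the natural-log
#'   scale.
#' @param icc intra-class correlation of repeated samples from the same
#'   subject (subject random intercept share of \code{sigma_log^2}).
#' @param censor if TRUE (default), missingness is intensity-dependent
#'   (left-censoring: low-intensity cells are preferentially missing),
#'   the mechanism assumed by the below-minimum imputation step; FALSE
#'   gives missingness completely at random.
#' @param seed RNG seed; identical configurations generate bit-identical
#'   studies.
#' @return object of class \code{sim_config}.
#' @export
sim_config <- function(n_case = 26, n_control = 16, n_features = 108,
                       n_discriminating = 10, effect_size = 0,
                       paired_effect = 0, n_qc = 5, missing_rate = 0.05,
                       qc_cv_high_fraction = 0.1, sigma_log = 0.5,
                       icc = 0.5, censor = TRUE, seed = 1L) {
  n_case <- assert_count(n_case, "n_case")
  n_control <- assert_count(n_control, "n_control")
  n_features <- assert_count(n_features, "n_features", min = 1)
  n_discriminating <- assert_count(n_discriminating, "n_discriminating")
  n_qc <- assert_count(n_qc, "n_qc")
  if (n_discriminating > n_features) {
    stop("`n_discriminating` must not exceed `n_features`", call. = FALSE)
  }
  assert_fraction(missing_rate, "missing_rate", open_hi = TRUE)
  assert_fraction(qc_cv_high_fraction, "qc_cv_high_fraction")
  assert_fraction(icc, "icc")
  if (!is.numeric(effect_size) || length(effect_size) != 1 || is.na(effect_size)) {
    stop("`effect_size` must be a single number", call. = FALSE)
  }
  if (!is.numeric(paired_effect) || length(paired_effect) != 1 || is.na(paired_effect)) {
    stop("`paired_effect` must be a single number", call. = FALSE)
  }
  if (!is.numeric(sigma_log) || length(sigma_log) != 1 || sigma_log <= 0) {
    stop("`sigma_log` must be a single positive number", call. = FALSE)
  }
  structure(list(
    n_case = n_case, n_control = n_control, n_features = n_features,
    n_discriminating = n_discriminating, effect_size = effect_size,
    paired_effect = paired_effect, n_qc = n_qc,
    missing_rate = as.numeric(missing_rate),
    qc_cv_high_fraction = as.numeric(qc_cv_high_fraction),
    sigma_log = as.numeric(sigma_log), icc = as.numeric(icc),
    censor = isTRUE(censor), seed = as.integer(seed)
  ), class = "sim_config")
}

#' Generate a synthetic breathomics study
#'
#' Draws a sample-by-feature intensity table with accompanying sample
#' metadata and the ground truth needed for parameter-recovery checks.
#'
#' The intensity model is log-normal per feature: each feature has a
#' log-scale baseline mean, every subject a random intercept (intra-class
#' correlation \code{icc}), and every injection an independent residual.
#' Exactly \code{n_discriminating} features have their case-group log mean
#' shifted by \code{effect_size * sigma_log}; for those same features the
#' case group at T1 is additionally shifted by
#' \code{paired_effect * sigma_log}. QC rows are replicate draws around a
#' fixed pooled profile, with a configurable fraction of features given a
#' high technical CV so the QC filter has something to remove. Missing
#' values are inserted completely at random (or preferentially in
#' low-intensity features when \code{censor = TRUE}).
#'
#' @param config a \code{\link{sim_config}} object.
#' @return list with elements \code{table} (intensity matrix, samples x
#'   features, NA = missing), \code{meta} (data.frame: sample_id, group,
#'   subject_id, timepoint, is_qc), and \code{truth} (list:
#'   discriminating_feature_ids, paired_shift_feature_ids, true_group,
#'   qc_cv_target).
#' @export
generate_study <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by sim_config()", call. = FALSE)
  }
  with_seed(config$seed, {
    p <- config$n_features
    # unique "time@mass" ids: retention time in minutes, mass in Da
    rt <- round(runif(p, 0.5, 12), 2)
    mz <- round(runif(p, 80, 600), 4)
    fid <- sprintf("%.2f@%.4f", rt, mz)
    while (anyDuplicated(fid)) {
      dup <- duplicated(fid)
      mz[dup] <- round(runif(sum(dup), 80, 600), 4)
      fid <- sprintf("%.2f@%.4f", rt, mz)
    }

    mu <- rnorm(p, mean = 9, sd = 1)            # log-scale feature baselines
    sigma <- config$sigma_log
    sd_subj <- sqrt(config$icc) * sigma
    sd_res <- sqrt(1 - config$icc) * sigma

    disc <- if (config$n_discriminating > 0) {
      sort(sample.int(p, config$n_discriminating))
    } else {
      integer(0)
    }
    shift_group <- config$effect_size * sigma
    shift_paired <- config$paired_effect * sigma

    case_ids <- sprintf("case%02d", seq_len(config$n_case))
    ctrl_ids <- sprintf("ctrl%02d", seq_len(config$n_control))

    sample_id <- c(paste0(case_ids, "_T0"), paste0(case_ids, "_T1"),
                   ctrl_ids,
                   if (config$n_qc > 0) sprintf("QC%02d", seq_len(config$n_qc)))
    group <- c(rep("case", 2L * config$n_case), rep("control", config$n_control),
               rep("QC", config$n_qc))
    subject <- c(case_ids, case_ids, ctrl_ids, rep(NA_character_, config$n_qc))
    timepoint <- c(rep("T0", config$n_case), rep("T1", config$n_case),
                   rep("none", config$n_control), rep("none", config$n_qc))
    meta <- data.frame(sample_id = sample_id, group = group,
                       subject_id = subject, timepoint = timepoint,
                       is_qc = group == "QC", stringsAsFactors = FALSE)

    n_study <- 2L * config$n_case + config$n_control
    logx <- matrix(rep(mu, each = n_study), nrow = n_study, ncol = p)
    # subject random intercepts shared between a case's T0 and T1 rows
    b_case <- matrix(rnorm(config$n_case * p, sd = sd_subj), config$n_case, p)
    b_ctrl <- matrix(rnorm(config$n_control * p, sd = sd_subj),
                     config$n_control, p)
    intercepts <- rbind(b_case, b_case, b_ctrl)
    logx <- logx + intercepts + matrix(rnorm(n_study * p, sd = sd_res),
                                       n_study, p)
    if (length(disc)) {
      case_rows <- seq_len(2L * config$n_case)
      logx[case_rows, disc] <- logx[case_rows, disc] + shift_group
      t1_rows <- config$n_case + seq_len(config$n_case)
      logx[t1_rows, disc] <- logx[t1_rows, disc] + shift_paired
    }
    x <- exp(logx)

    # pooled QC profile with per-feature technical CV (baseline 0.10; a
    # configurable fraction of features get CV 0.40, above common filters)
    cv_target <- rep(0.10, p)
    n_high <- round(config$qc_cv_high_fraction * p)
    if (n_high > 0) {
      cv_target[sample.int(p, n_high)] <- 0.40
    }
    if (config$n_qc > 0) {
      qc <- qc_replicates(exp(mu), cv_target, config$n_qc)
      x <- rbind(x, qc)
    }
    dimnames(x) <- list(sample_id, fid)

    # missingness over the whole table; the left-censoring mode weights the
    # draw sharply toward low-intensity cells (within-feature standardized
    # log intensity), mimicking values lost below the detection level --
    # the mechanism the below-minimum imputation rule assumes
    if (config$missing_rate > 0) {
      n_cells <- length(x)
      if (config$censor) {
        z <- scale(log(x))
        w <- exp(-3 * z)
        miss <- sample.int(n_cells, size = round(config$missing_rate * n_cells),
                           prob = w)
      } else {
        miss <- sample.int(n_cells, size = round(config$missing_rate * n_cells))
      }
      x[miss] <- NA_real_
    }

    truth <- list(
      discriminating_feature_ids = fid[disc],
      paired_shift_feature_ids = if (shift_paired != 0) fid[disc] else character(0),
      true_group = stats::setNames(group, sample_id),
      qc_cv_target = stats::setNames(cv_target, fid)
    )
    list(table = x, meta = meta, truth = truth)
  })
}

# Replicate QC rows around a fixed pooled profile with per-feature target CV.
qc_replicates <- function(profile, cv_target, n_rep) {
  p <- length(profile)
  stopifnot(length(cv_target) == p)
  sdlog <- sqrt(log(1 + cv_target^2))
  meanlog <- log(profile) - sdlog^2 / 2   # so E[X] = profile exactly
  draws <- matrix(rlnorm(n_rep * p,
                         meanlog = rep(meanlog, each = n_rep),
                         sdlog = rep(sdlog, each = n_rep)),
                  nrow = n_rep, ncol = p)
  draws
}

#' Simulate pooled-QC replicate injections
#'
#' Draws QC replicate rows around the pooled profile of a study table such
#' that the per-feature empirical coefficient of variation converges to
#' \code{cv_target} as the number of replicates grows.
#'
#' @param table feature table whose per-feature median defines the pooled
#'   profile.
#' @param cv_target per-feature target CV (scalar recycled, or vector of
#'   length \code{ncol(table)}); all values must be >= 0.
#' @param n_rep number of replicate injections (>= 2; a CV is undefined
#'   below that).
#' @param seed optional RNG seed.
#' @return feature table of QC rows (\code{n_rep} x \code{ncol(table)}).
#' @export
pooled_qc_profile <- function(table, cv_target, n_rep, seed = NULL) {
  assert_feature_table(table)
  if (n_rep < 2) {
    stop("at least 2 QC replicates are required (CV undefined otherwise)",
         call. = FALSE)
  }
  p <- ncol(table)
  cv_target <- rep_len(as.numeric(cv_target), p)
  if (any(is.na(cv_target)) || any(cv_target < 0)) {
    stop("`cv_target` must be >= 0 for every feature", call. = FALSE)
  }
  profile <- apply(table, 2, stats::median, na.rm = TRUE)
  with_seed(seed, {
    qc <- qc_replicates(profile, cv_target, n_rep)
    dimnames(qc) <- list(sprintf("QC%02d", seq_len(n_rep)), colnames(table))
    qc
  })
}

#' Write a synthetic study to disk
#'
#' Writes the intensity table and metadata as CSV and the ground truth as
#' JSON, the on-disk contract used by the rest of the workflow.
#'
#' @param study result of \code{\link{generate_study}}.
#' @param dir output directory (created if absent).
#' @return invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    table = file.path(dir, "feature_table.csv"),
    meta = file.path(dir, "sample_meta.csv"),
    truth = file.path(dir, "ground_truth.json")
  )
  write_feature_table(study$table, paths$table)
  utils::write.csv(study$meta, paths$meta, row.names = FALSE)
  jsonlite::write_json(study$truth, paths$truth, auto_unbox = FALSE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}

#' Read / write feature tables as CSV
#'
#' Rows are samples (first column \code{sample_id}), remaining columns are
#' "time@mass" features. Empty cells encode missing values.
#'
#' @param path CSV file path.
#' @return \code{read_feature_table}: numeric matrix with sample rownames.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  assert_feature_table(m)
  m
}

#' @rdname read_feature_table
#' @param table feature table matrix.
#' @export
write_feature_table <- function(table, path) {
  assert_feature_table(table)
  df <- data.frame(sample_id = rownames(table), table, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
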