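#' Default analysis configuration
#'
#' Collects every tunable of the workflow with its standard value: QC CV
#' filter threshold 0.25, FDR level 0.10 for the univariate screens,
#' significance level 0.05 for outlier tests and stability selection,
#' 200 bootstrap subsamples, 5-fold cross-validation and 1000 label
#' permutations.
#'
#' @param ... overrides of the defaults (unknown names are an error).
#' @return named list of class \code{breathdisc_config}.
#' @export
default_config <- function(...) {
  cfg <- list(
    cv_threshold = 0.25,  # QC CV feature filter
    delta = 0.10,         # FDR level of the univariate screens
    alpha = 0.05,         # outlier tests + stability relevance level
    B = 200,              # bootstrap subsamples
    folds = 5,            # cross-validation folds
    n_perm = 1000,        # label permutations
    vip_cut = 1,          # within-subsample VIP selection threshold
    n_null = 20,          # permuted runs calibrating selection frequencies
    A = NULL,             # latent variables; NULL = choose by MCCcv
    A_max = 5,            # search range for the automatic choice
    tol_ppm = 20,         # annotation mass tolerance
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "breathdisc_config")
}

#' Read a configuration file
#'
#' JSON (always available) or YAML (if the yaml package is installed)
#' files holding overrides of \code{\link{default_config}}.
#'
#' @param path file path ending in .json, .yaml or .yml.
#' @export
read_config <- function(path) {
  vals <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(default_config, vals)
}

# Resolve the rows and labels of one contrast from the sample metadata.
contrast_design <- function(meta, contrast) {
  ok <- c("T0-vs-control", "T1-vs-control", "T0-vs-T1-paired")
  if (!contrast %in% ok) {
    stop("`contrast` must be one of: ", paste(ok, collapse = ", "),
         call. = FALSE)
  }
  if (contrast == "T0-vs-T1-paired") {
    rows <- meta$sample_id[meta$group == "case" &
                             meta$timepoint %in% c("T0", "T1")]
    return(list(sample_ids = rows, labels = NULL, paired = TRUE))
  }
  tp <- sub("-vs-control", "", contrast)
  case_rows <- meta$sample_id[meta$group == "case" & meta$timepoint == tp]
  ctrl_rows <- meta$sample_id[meta$group == "control"]
  list(sample_ids = c(case_rows, ctrl_rows),
       labels = c(rep("case", length(case_rows)),
                  rep("control", length(ctrl_rows))),
       paired = FALSE)
}

#' Run one pairwise contrast of the discrimination workflow
#'
#' Executes, on a preprocessed feature table, the full comparison between
#' two sample groups: per-group PCA outlier screening (flagged samples are
#' dropped and logged), the univariate nonparametric screen with FDR
#' control, PLS-DA stability selection (plain for the unpaired contrasts,
#' multilevel on signed within-subject differences for the paired one),
#' cross-validated MCC and the label-permutation test, the merge of the
#' univariate and multivariate relevant sets, and — when a metabolite
#' table is supplied — putative annotation of the merged set.
#'
#' @param table preprocessed feature table (QC rows removed; see
#'   \code{\link{preprocess_untargeted}}).
#' @param meta sample metadata (sample_id, group, subject_id, timepoint).
#' @param contrast \code{"T0-vs-control"}, \code{"T1-vs-control"} or
#'   \code{"T0-vs-T1-paired"}.
#' @param config a \code{\link{default_config}} list.
#' @param db optional metabolite table for annotation (see
#'   \code{\link{match_features}}).
#' @param mode ionization mode of the table, \code{"negative"} or
#'   \code{"positive"}; required for annotation.
#' @param annotate annotate the merged relevant set (default TRUE when
#'   \code{db} is given).
#' @return object of class \code{comparison_result}: univariate screen,
#'   stability model, MCC summaries, merged relevant set, outliers
#'   dropped, annotation hits and full parameter provenance.
#' @export
run_contrast <- function(table, meta, contrast, config = default_config(),
                         db = NULL, mode = NULL, annotate = !is.null(db)) {
  assert_feature_table(table)
  if (!all(rownames(table) %in% meta$sample_id)) {
    stop("samples present in `table` but absent from `meta`: ",
         paste(utils::head(setdiff(rownames(table), meta$sample_id), 3),
               collapse = ", "), call. = FALSE)
  }
  design <- contrast_design(meta, contrast)
  missing_rows <- setdiff(design$sample_ids, rownames(table))
  if (length(missing_rows)) {
    stop("contrast requires sample(s) not in the table: ",
         paste(utils::head(missing_rows, 3), collapse = ", "), call. = FALSE)
  }
  sub <- table[design$sample_ids, , drop = FALSE]
  meta_sub <- meta[match(design$sample_ids, meta$sample_id), , drop = FALSE]

  # per-group PCA outlier screening; screening groups are timepoint-specific
  grp_key <- paste(meta_sub$group, meta_sub$timepoint, sep = ".")
  flagged <- character(0)
  for (g in unique(grp_key)) {
    rows <- design$sample_ids[grp_key == g]
    if (length(rows) >= 3) {
      scr <- pca_outlier_screen(sub[rows, , drop = FALSE],
                                alpha = config$alpha)
      flagged <- c(flagged, scr$flagged)
    }
  }
  if (design$paired && length(flagged)) {
    # removing one timepoint of a subject removes the subject
    bad_subj <- meta_sub$subject_id[meta_sub$sample_id %in% flagged]
    flagged <- union(flagged,
                     meta_sub$sample_id[meta_sub$subject_id %in% bad_subj])
  }
  keep <- !(design$sample_ids %in% flagged)
  sub <- sub[keep, , drop = FALSE]
  meta_sub <- meta_sub[keep, , drop = FALSE]
  labels <- design$labels[keep]

  seed <- config$seed
  if (design$paired) {
    uni <- wilcoxon_paired_screen(sub, meta_sub, delta = config$delta)
    ml <- multilevel_transform(sub, meta_sub)
    X <- ml$table
    y <- ml$labels
    subjects <- ml$subjects
  } else {
    uni <- mann_whitney_screen(sub, labels, delta = config$delta)
    X <- sub
    y <- labels
    subjects <- NULL
  }

  if (is.null(config$A)) {
    sel <- select_ncomp(X, y, A_max = config$A_max, folds = config$folds,
                        seed = seed, subjects = subjects)
    A <- sel$A
  } else {
    A <- config$A
  }
  cv <- cross_validate_mcc(X, y, A = A, folds = config$folds, seed = seed,
                           subjects = subjects)
  perm <- permutation_test(X, y, A = A, folds = config$folds,
                           n_perm = config$n_perm, seed = seed,
                           subjects = subjects)
  stab <- stability_selection(X, y, A = A, B = config$B,
                              alpha = config$alpha, vip_cut = config$vip_cut,
                              n_null = config$n_null, subjects = subjects,
                              seed = seed)

  uni_set <- uni$result$feature_id[uni$result$significant]
  multi_set <- stab$relevant
  merged <- union(uni_set, multi_set)

  hits <- NULL
  if (annotate && length(merged)) {
    if (is.null(db)) db <- example_metabolite_db()
    if (is.null(mode)) {
      stop("`mode` (ionization polarity) is required for annotation",
           call. = FALSE)
    }
    hits <- match_features(merged, db, tol_ppm = config$tol_ppm,
                           polarity = mode)
  }

  structure(list(
    contrast = contrast, mode = mode,
    outliers_dropped = flagged,
    univariate = uni,
    stability = stab,
    A = A,
    mcc_cv = cv$mcc,
    mcc_oob = stab$mcc_oob,
    permutation_p = perm$p,
    univariate_set = uni_set,
    multivariate_set = multi_set,
    merged_set = merged,
    multivariate_within_univariate = all(multi_set %in% uni_set),
    annotation = hits,
    provenance = list(
      delta = config$delta, alpha = config$alpha, B = config$B,
      folds = config$folds, n_perm = config$n_perm,
      vip_cut = config$vip_cut, n_null = config$n_null, A = A,
      seed = seed,
      steps = c("pca_outlier_screen",
                if (design$paired) "wilcoxon_paired_screen" else "mann_whitney_screen",
                if (design$paired) "multilevel_transform",
                "stability_selection", "cross_validate_mcc",
                "permutation_test",
                if (annotate) "match_features")
    )
  ), class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Contrast %s%s\n", x$contrast,
              if (!is.null(x$mode)) paste0(" (", x$mode, " mode)") else ""))
  cat(sprintf("  univariate significant: %d; multivariate relevant: %d; merged: %d\n",
              length(x$univariate_set), length(x$multivariate_set),
              length(x$merged_set)))
  cat(sprintf("  A = %d, MCCcv = %.3f, MCCoob = %.3f, permutation p = %.4g\n",
              x$A, x$mcc_cv, x$mcc_oob, x$permutation_p))
  if (length(x$outliers_dropped)) {
    cat("  outliers dropped:", paste(x$outliers_dropped, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Shared and unique relevant features between two contrasts
#'
#' @param a,b character vectors of feature ids over the same mode's
#'   feature universe (or \code{comparison_result} objects, whose merged
#'   sets are compared).
#' @return list with counts \code{shared}, \code{unique_a},
#'   \code{unique_b} and the corresponding id vectors.
#' @export
overlap <- function(a, b) {
  if (inherits(a, "comparison_result")) a <- a$merged_set
  if (inherits(b, "comparison_result")) b <- b$merged_set
  shared <- intersect(a, b)
  list(
    shared = length(shared), unique_a = length(setdiff(a, b)),
    unique_b = length(setdiff(b, a)),
    shared_ids = shared, unique_a_ids = setdiff(a, b),
    unique_b_ids = setdiff(b, a)
  )
}

#' Run a contrast on a targeted analyte panel
#'
#' Applies the targeted preprocessing (below-LOQ stochastic imputation,
#' autoscaling) and then the same univariate + multivariate engine used for
#' the untargeted tables. Annotation is skipped: targeted analytes are
#' already identified.
#'
#' @param values analyte concentration matrix (samples x analytes; NA =
#'   below LOQ).
#' @param loq per-analyte limit of quantification.
#' @param meta sample metadata as in \code{\link{run_contrast}}.
#' @param contrast contrast name.
#' @param config configuration list.
#' @return \code{comparison_result}.
#' @export
targeted_contrast <- function(values, loq, meta, contrast,
                              config = default_config()) {
  prep <- preprocess_targeted(values, loq, seed = config$seed)
  run_contrast(prep$table, meta, contrast, config = config, db = NULL,
               annotate = FALSE)
}

#' Serialize a comparison result to JSON
#'
#' @param result \code{comparison_result}.
#' @param path output file.
#' @export
write_result <- function(result, path) {
  out <- list(
    contrast = result$contrast, mode = result$mode,
    outliers_dropped = result$outliers_dropped,
    n_univariate = length(result$univariate_set),
    n_multivariate = length(result$multivariate_set),
    n_merged = length(result$merged_set),
    univariate_set = result$univariate_set,
    multivariate_set = result$multivariate_set,
    merged_set = result$merged_set,
    multivariate_within_univariate = result$multivariate_within_univariate,
    A = result$A, mcc_cv = result$mcc_cv, mcc_oob = result$mcc_oob,
    permutation_p = result$permutation_p,
    selection_frequency = as.list(result$stability$frequency),
    annotation = result$annotation,
    provenance = result$provenance
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
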