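PROTON_MASS <- 1.007276
WATER_MASS <- 18.010565
AMMONIA_MASS <- 17.026549

#' Adduct rules for neutral-mass calculation
#'
#' The ion forms commonly observed in electrospray LC-MS of breath
#' condensate: the deprotonated molecule in negative mode, and the
#' protonated molecule with optional neutral loss of water or ammonia in
#' positive mode. Each rule maps an observed m/z to the neutral
#' monoisotopic mass M.
#'
#' @return data.frame with columns \code{adduct}, \code{polarity},
#'   \code{offset} such that \code{M = mz + offset}.
#' @export
adduct_rules <- function() {
  data.frame(
    adduct = c("M-H", "M+H", "M+H-H2O", "M+H-NH3"),
    polarity = c("negative", "positive", "positive", "positive"),
    offset = c(PROTON_MASS,
               -PROTON_MASS,
               -PROTON_MASS + WATER_MASS,
               -PROTON_MASS + AMMONIA_MASS),
    stringsAsFactors = FALSE
  )
}

# Accept a few equivalent spellings of the adduct names.
normalize_adduct <- function(x) {
  key <- toupper(gsub("[[:space:]]", "", x))
  key <- gsub("−", "-", key)       # unicode minus
  key <- gsub("H2O|H₂O", "H2O", key)
  key <- gsub("NH3|NH₃", "NH3", key)
  key
}

#' Neutral monoisotopic mass from an observed m/z
#'
#' Applies the adduct algebra: \code{M-H}: M = mz + 1.007276;
#' \code{M+H}: M = mz - 1.007276; \code{M+H-H2O}: M = mz - 1.007276 +
#' 18.010565; \code{M+H-NH3}: M = mz - 1.007276 + 17.026549 (all Da).
#'
#' @param mz observed mass-to-charge ratio (Da, singly charged).
#' @param adduct one of \code{"M-H"}, \code{"M+H"}, \code{"M+H-H2O"},
#'   \code{"M+H-NH3"} (spacing-insensitive).
#' @return neutral monoisotopic mass in Da (vectorized).
#' @export
neutral_mass <- function(mz, adduct) {
  if (any(mz <= 0)) stop("m/z must be positive", call. = FALSE)
  rules <- adduct_rules()
  key <- normalize_adduct(adduct)
  idx <- match(key, normalize_adduct(rules$adduct))
  if (anyNA(idx)) {
    stop("unknown adduct rule(s): ",
         paste(unique(adduct[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  mz + rules$offset[idx]
}

#' Match features to candidate metabolites by accurate mass
#'
#' For every feature, every polarity-consistent adduct rule is applied to
#' its m/z and the resulting neutral mass is compared against each database
#' candidate; every (feature, adduct, candidate) combination within
#' \code{tol_ppm} is kept, sorted by absolute mass error. Accurate mass
#' alone cannot distinguish isomers, so hits are putative (annotation
#' level 3).
#'
#' @param features data.frame with columns \code{feature_id}, \code{mz},
#'   \code{polarity} ("negative"/"positive"); or a character vector of
#'   "time@mass" ids combined with a single \code{polarity}.
#' @param db metabolite table with columns \code{name}, \code{class},
#'   \code{monoisotopic_mass}; malformed rows are skipped with a warning.
#' @param tol_ppm mass tolerance in parts per million (default 20,
#'   typical for QTOF accuracy).
#' @param polarity used when \code{features} is a character vector.
#' @return data.frame of hits: feature_id, mz, adduct, name, class,
#'   neutral_mass, db_mass, error_mda, error_ppm, level; zero-row when
#'   nothing matches. Features without any hit are listed in attribute
#'   \code{"unannotated"}.
#' @export
match_features <- function(features, db, tol_ppm = 20, polarity = NULL) {
  if (is.character(features)) {
    ids <- parse_feature_ids(features)
    if (is.null(polarity)) {
      stop("`polarity` is required when features are given as ids",
           call. = FALSE)
    }
    features <- data.frame(feature_id = ids$feature_id, mz = ids$mz,
                           polarity = polarity, stringsAsFactors = FALSE)
  }
  stopifnot(all(c("feature_id", "mz", "polarity") %in% names(features)))
  if (!is.numeric(tol_ppm) || tol_ppm < 0) {
    stop("`tol_ppm` must be a nonnegative number", call. = FALSE)
  }
  need <- c("name", "class", "monoisotopic_mass")
  if (!all(need %in% names(db))) {
    stop("`db` must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  dbm <- suppressWarnings(as.numeric(db$monoisotopic_mass))
  bad <- is.na(dbm) | dbm <= 0 | is.na(db$name) | db$name == ""
  if (any(bad)) {
    warning(sum(bad), " malformed database row(s) skipped", call. = FALSE)
    db <- db[!bad, , drop = FALSE]
    dbm <- dbm[!bad]
  }
  rules <- adduct_rules()
  hits <- list()
  for (i in seq_len(nrow(features))) {
    fr <- features[i, ]
    use <- rules[rules$polarity == fr$polarity, , drop = FALSE]
    for (r in seq_len(nrow(use))) {
      M <- fr$mz + use$offset[r]
      err_ppm <- (M - dbm) / dbm * 1e6
      ok <- which(abs(err_ppm) <= tol_ppm)
      if (length(ok)) {
        hits[[length(hits) + 1L]] <- data.frame(
          feature_id = fr$feature_id, mz = fr$mz, adduct = use$adduct[r],
          name = db$name[ok], class = db$class[ok],
          neutral_mass = M, db_mass = dbm[ok],
          error_mda = (M - dbm[ok]) * 1e3, error_ppm = err_ppm[ok],
          level = "3", stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(hits)) do.call(rbind, hits) else data.frame(
    feature_id = character(0), mz = numeric(0), adduct = character(0),
    name = character(0), class = character(0), neutral_mass = numeric(0),
    db_mass = numeric(0), error_mda = numeric(0), error_ppm = numeric(0),
    level = character(0), stringsAsFactors = FALSE
  )
  out <- out[order(abs(out$error_ppm)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unannotated") <- setdiff(features$feature_id, out$feature_id)
  out
}

#' Bundled candidate metabolite table
#'
#' Loads the small metabolite mass table shipped with the package:
#' EBC asthma marker candidates (prostaglandins, omega-amino fatty acids,
#' N-acyl amides, lysoglycerophospholipids). Neutral masses are synthetic:
#' back-computed from reported ion masses under the stated adduct, not
#' taken from a spectral library.
#'
#' @return data.frame with columns name, class, monoisotopic_mass,
#'   polarity.
#' @export
example_metabolite_db <- function() {
  path <- system.file("extdata", "synthetic_metabolite_db.csv",
                      package = "breathdisc", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
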