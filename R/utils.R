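#' @keywords internal
#' @importFrom stats runif rnorm rlnorm
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so simulation helpers do not clobber the
# session RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# A feature table is a numeric matrix, samples in rows, features in columns,
# with unique rownames (sample ids) and unique colnames ("time@mass" ids).
assert_feature_table <- function(x, arg = "table") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("`%s` must be a numeric matrix (samples x features)", arg),
         call. = FALSE)
  }
  if (is.null(rownames(x)) || anyDuplicated(rownames(x))) {
    stop(sprintf("`%s` must have unique sample ids as rownames", arg),
         call. = FALSE)
  }
  if (is.null(colnames(x)) || anyDuplicated(colnames(x))) {
    stop(sprintf("`%s` must have unique feature ids as colnames", arg),
         call. = FALSE)
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0) {
  if (length(x) != 1 || !is.numeric(x) || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a single integer >= %d", name, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_hi = FALSE) {
  bad <- length(x) != 1 || !is.numeric(x) || is.na(x) || x < lo ||
    (if (open_hi) x >= hi else x > hi)
  if (bad) {
    stop(sprintf("`%s` must be a number in [%s, %s%s", name, lo, hi,
                 if (open_hi) ")" else "]"), call. = FALSE)
  }
  invisible(as.numeric(x))
}

# Parse "time@mass" feature ids into retention time (min) and m/z (Da).
#' Split "time@mass" feature identifiers
#'
#' Feature ids in untargeted LC-MS tables encode the retention time (minutes)
#' and the measured m/z (Da) separated by \code{"@"}.
#'
#' @param ids character vector of feature ids such as \code{"4.42@172.1332"}.
#' @return data.frame with columns \code{feature_id}, \code{rt_min},
#'   \code{mz}.
#' @export
parse_feature_ids <- function(ids) {
  parts <- strsplit(as.character(ids), "@", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed feature id(s): ", paste(ids[bad], collapse = ", "),
         call. = FALSE)
  }
  data.frame(
    feature_id = as.character(ids),
    rt_min = as.numeric(vapply(parts, `[`, "", 1L)),
    mz = as.numeric(vapply(parts, `[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
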