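#' Subject-level partially verified diagnostic data
#'
#' Constructs a `verification_data` object: one row per subject with the
#' binary diagnostic test result `test`, the verification indicator
#' `verified`, and the gold-standard disease status `disease`. Disease status
#' must be observed exactly for the verified subjects; for unverified
#' subjects it is stored as `NA` (never as a 0/1 sentinel), so that no
#' estimator can silently use it.
#'
#' @param test integer vector of 0/1 test results (1 = positive).
#' @param verified integer vector of 0/1 verification indicators (1 = the
#'   subject received the gold standard).
#' @param disease integer vector of 0/1 disease statuses, `NA` where
#'   `verified == 0`.
#' @return A data frame of class `verification_data` with integer columns
#'   `test`, `verified`, `disease`.
#' @examples
#' d <- verification_data(test = c(1, 1, 0, 0),
#'                        verified = c(1, 1, 1, 0),
#'                        disease = c(1, 0, 0, NA))
#' cell_counts(d)
#' @export
verification_data <- function(test, verified, disease) {
  x <- data.frame(test = as.integer(test),
                  verified = as.integer(verified),
                  disease = as.integer(disease))
  class(x) <- c("verification_data", "data.frame")
  viol <- validate_verification_data(x)
  if (nrow(viol) > 0L) {
    stop("invalid verification data:\n",
         paste(utils::capture.output(print(head(viol, 10L))), collapse = "\n"),
         call. = FALSE)
  }
  x
}

#' Coerce a data frame to verification data
#'
#' Accepts any data frame with columns named `test`, `verified`, `disease`
#' (any order, case-insensitive). Empty strings and the literal `"NA"` in
#' `disease` are read as missing.
#'
#' @param x a data frame.
#' @return A validated [verification_data()] object.
#' @export
as_verification_data <- function(x) {
  stopifnot(is.data.frame(x))
  nm <- tolower(names(x))
  need <- c("test", "verified", "disease")
  if (!all(need %in% nm)) {
    stop("missing required column(s): ",
         paste(setdiff(need, nm), collapse = ", "), call. = FALSE)
  }
  cols <- lapply(need, function(v) parse_binary(x[[which(nm == v)[1L]]], v))
  verification_data(test = cols[[1L]], verified = cols[[2L]],
                    disease = cols[[3L]])
}

# Tolerant 0/1 parser: "", "NA", NA -> NA; anything not 0/1 is an error
# naming the offending rows.
parse_binary <- function(v, what) {
  if (is.factor(v)) v <- as.character(v)
  if (is.character(v)) {
    v <- trimws(v)
    v[v %in% c("", "NA")] <- NA_character_
  }
  out <- suppressWarnings(as.integer(v))
  bad <- which((!is.na(v) & is.na(out)) | (!is.na(out) & !out %in% c(0L, 1L)))
  if (length(bad) > 0L) {
    stop(sprintf("column '%s': non-binary value(s) at row(s) %s", what,
                 paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  out
}

#' Validate partially verified diagnostic data
#'
#' Checks the structural invariants of a [verification_data()] layout and
#' returns the violations found (an empty data frame when the data are
#' valid). Each finding carries the offending row index and a rule name, so
#' callers can report precisely.
#'
#' Rules: every column is 0/1 (disease may be `NA`); `disease` is non-missing
#' exactly where `verified == 1`; at least one subject.
#'
#' @param x a data frame with columns `test`, `verified`, `disease`.
#' @return A data frame with columns `row` (index, `NA` for dataset-level
#'   findings) and `rule`.
#' @export
validate_verification_data <- function(x) {
  viol <- list()
  add <- function(rows, rule) {
    if (length(rows) > 0L) {
      viol[[length(viol) + 1L]] <<- data.frame(row = rows, rule = rule)
    }
  }
  if (nrow(x) < 1L) add(NA_integer_, "empty_dataset")
  add(which(!is.na(x$test) & !x$test %in% c(0L, 1L)), "test_not_binary")
  add(which(is.na(x$test)), "test_missing")
  add(which(!is.na(x$verified) & !x$verified %in% c(0L, 1L)),
      "verified_not_binary")
  add(which(is.na(x$verified)), "verified_missing")
  add(which(!is.na(x$disease) & !x$disease %in% c(0L, 1L)),
      "disease_not_binary")
  add(which(x$verified == 1L & is.na(x$disease)),
      "disease_missing_where_verified")
  add(which(x$verified == 0L & !is.na(x$disease)),
      "disease_present_where_unverified")
  if (length(viol) == 0L) {
    return(data.frame(row = integer(), rule = character()))
  }
  do.call(rbind, viol)
}

#' Reduce subject-level data to its sufficient cell counts
#'
#' All the estimators in this package are functions of six counts: the 2x2
#' table of (test, disease) among verified subjects plus the unverified
#' counts in each test stratum. `cell_counts` tabulates them.
#'
#' @param x a [verification_data()] object (or a raw data frame with the same
#'   columns), or six counts given directly.
#' @param s11,s10,s01,s00 verified counts for (T=1,D=1), (T=1,D=0), (T=0,D=1)
#'   and (T=0,D=0).
#' @param u1,u0 unverified counts in the T=1 and T=0 strata.
#' @return An object of class `cell_counts`: a list with elements `s11`,
#'   `s10`, `s01`, `s00`, `u1`, `u0`.
#' @examples
#' cell_counts(s11 = 40, s10 = 10, s01 = 5, s00 = 20, u1 = 0, u0 = 25)
#' @export
cell_counts <- function(x = NULL, s11 = 0, s10 = 0, s01 = 0, s00 = 0,
                        u1 = 0, u0 = 0) {
  if (!is.null(x)) {
    stopifnot(is.data.frame(x))
    viol <- validate_verification_data(x)
    if (nrow(viol) > 0L) {
      stop("invalid verification data: ",
           paste(unique(viol$rule), collapse = ", "),
           " (row ", paste(head(stats::na.omit(viol$row), 5L), collapse = ", "),
           ")", call. = FALSE)
    }
    v <- x$verified == 1L
    s11 <- sum(v & x$test == 1L & x$disease == 1L)
    s10 <- sum(v & x$test == 1L & x$disease == 0L)
    s01 <- sum(v & x$test == 0L & x$disease == 1L)
    s00 <- sum(v & x$test == 0L & x$disease == 0L)
    u1 <- sum(!v & x$test == 1L)
    u0 <- sum(!v & x$test == 0L)
  }
  cc <- list(s11 = as.numeric(s11), s10 = as.numeric(s10),
             s01 = as.numeric(s01), s00 = as.numeric(s00),
             u1 = as.numeric(u1), u0 = as.numeric(u0))
  if (any(unlist(cc) < 0) || any(is.na(unlist(cc)))) {
    stop("cell counts must be non-negative", call. = FALSE)
  }
  class(cc) <- "cell_counts"
  cc
}

#' @export
print.cell_counts <- function(x, ...) {
  cat("Partially verified 2x2 cell counts\n")
  m <- matrix(c(x$s11, x$s10, x$u1, x$s01, x$s00, x$u0), nrow = 2L,
              byrow = TRUE,
              dimnames = list(c("T=1", "T=0"),
                              c("D=1 (V=1)", "D=0 (V=1)", "unverified")))
  print(m)
  cat(sprintf("N = %d, verified n = %d (%.1f%% unverified)\n",
              n_total(x), n_verified(x), pct_unverified(x)))
  invisible(x)
}

#' Subject totals of a cell-count table
#'
#' @param x a `cell_counts` object.
#' @return `n_verified`: the number of complete cases; `n_total`: the total
#'   number of subjects; `pct_unverified`: percentage of unverified subjects.
#' @export
n_verified <- function(x) {
  as.integer(x$s11 + x$s10 + x$s01 + x$s00)
}

#' @rdname n_verified
#' @export
n_total <- function(x) {
  as.integer(n_verified(x) + x$u1 + x$u0)
}

#' @rdname n_verified
#' @export
pct_unverified <- function(x) {
  100 * (x$u1 + x$u0) / n_total(x)
}

#' Expand cell counts back to subject-level data
#'
#' Inverse of [cell_counts()] up to subject order: builds one row per counted
#' subject.
#'
#' @param counts a `cell_counts` object.
#' @return A [verification_data()] object.
#' @export
expand_counts <- function(counts) {
  stopifnot(inherits(counts, "cell_counts"))
  k <- c(counts$s11, counts$s10, counts$s01, counts$s00, counts$u1,
         counts$u0)
  if (max(abs(k - round(k))) > 1e-6) {
    stop("counts must be whole numbers to expand to subjects", call. = FALSE)
  }
  k <- round(k)
  verification_data(
    test = rep(c(1L, 1L, 0L, 0L, 1L, 0L), times = k),
    verified = rep(c(1L, 1L, 1L, 1L, 0L, 0L), times = k),
    disease = rep(c(1L, 0L, 1L, 0L, NA_integer_, NA_integer_), times = k))
}

#' Classic partially verified diagnostic count tables
#'
#' Two well-known teaching datasets from the verification-bias literature,
#' reconstructed as count tables from their published marginal summaries and
#' expanded to subject level in code (synthetic reconstructions; the subject
#' order carries no information):
#'
#' * `"hepatic"`: hepatic scintigraphy for liver cancer, 650 patients of whom
#'   344 were verified by pathology (47.1% unverified).
#' * `"diaphanography"`: breast transillumination for breast cancer, 900
#'   patients of whom 88 were verified by biopsy (90.2% unverified).
#'
#' @param name `"hepatic"` or `"diaphanography"`.
#' @param counts_only return the `cell_counts` table instead of subject-level
#'   data.
#' @return A [verification_data()] object, or a `cell_counts` table.
#' @export
pvb_example <- function(name = c("hepatic", "diaphanography"),
                        counts_only = FALSE) {
  name <- match.arg(name)
  cc <- switch(name,
    hepatic = cell_counts(s11 = 231, s10 = 32, s01 = 27, s00 = 54,
                          u1 = 166, u0 = 140),
    diaphanography = cell_counts(s11 = 26, s10 = 11, s01 = 7, s00 = 44,
                                 u1 = 30, u0 = 782))
  if (counts_only) cc else expand_counts(cc)
}
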