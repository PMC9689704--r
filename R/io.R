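#' Read a partially verified diagnostic dataset from CSV
#'
#' Expects header columns `disease`, `test`, `verified` (any order,
#' case-insensitive); empty cells and the literal `NA` in `disease` are
#' missing. The dataset is validated and a one-line summary (N, verified n,
#' percentage unverified to one decimal) is written to standard error.
#'
#' @param path path to the CSV file.
#' @param quiet suppress the summary message.
#' @return A [verification_data()] object.
#' @export
read_verification_csv <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) {
    stop("no data rows in ", path, call. = FALSE)
  }
  data <- as_verification_data(raw)
  if (!quiet) {
    cc <- cell_counts(data)
    message(sprintf("%s: N = %d, verified n = %d, %% unverified = %.1f%%",
                    basename(path), n_total(cc), n_verified(cc),
                    pct_unverified(cc)))
  }
  data
}

#' Write a dataset, estimate table, or simulation result to CSV
#'
#' Deterministic column order and full precision (15 significant digits), so
#' a write-then-read round trip reproduces values exactly. Attributes of the
#' resolved configuration may be embedded as comment-free extra columns by
#' the CLI; these writers emit plain tabular CSV.
#'
#' @param x a `verification_data`, `accuracy_table`, or `simulation_result`
#'   object (any data frame works).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pvb_csv <- function(x, path) {
  stopifnot(is.data.frame(x), nrow(x) > 0L)
  df <- as.data.frame(x)
  num <- vapply(df, is.double, logical(1L))
  df[num] <- lapply(df[num], function(v) {
    out <- trimws(formatC(v, digits = 15, format = "g"))
    out[is.na(v)] <- NA_character_
    out
  })
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_pvb_csv
#' @export
write_estimates <- write_pvb_csv

#' @rdname write_pvb_csv
#' @export
write_results <- write_pvb_csv

#' Read back an estimate or result CSV written by [write_pvb_csv()]
#'
#' @param path path to the CSV file.
#' @return A data frame with numeric columns restored.
#' @export
read_pvb_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df
}
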