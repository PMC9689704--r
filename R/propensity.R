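#' Estimate the verification propensity score
#'
#' The propensity score here is the verification probability given the test
#' result, PS = P(V=1|T). With a single binary covariate the logistic
#' regression of V on T is saturated, so its fitted probabilities are exactly
#' the verified fractions within each test stratum; those stratum fractions
#' are computed directly. Known probabilities can be supplied instead for
#' oracle analyses.
#'
#' @param x a [verification_data()] object or a `cell_counts` table.
#' @param known optional numeric vector `c(ps_t1, ps_t0)` of known
#'   verification probabilities; when given, no fitting is done.
#' @return A list of class `propensity_model` with elements `ps_t1`, `ps_t0`
#'   and `source` (`"fitted"` or `"known"`).
#' @examples
#' cc <- cell_counts(s11 = 40, s10 = 10, s01 = 5, s00 = 20, u1 = 0, u0 = 25)
#' fit_propensity(cc)
#' @export
fit_propensity <- function(x, known = NULL) {
  if (!is.null(known)) {
    stopifnot(length(known) == 2L, all(known > 0), all(known <= 1))
    ps <- list(ps_t1 = known[[1L]], ps_t0 = known[[2L]], source = "known")
    class(ps) <- "propensity_model"
    return(ps)
  }
  cc <- if (inherits(x, "cell_counts")) x else cell_counts(x)
  m1 <- cc$s11 + cc$s10 + cc$u1
  m0 <- cc$s01 + cc$s00 + cc$u0
  if (m1 == 0 || m0 == 0) {
    stop("both test strata must be non-empty to fit the propensity score",
         call. = FALSE)
  }
  ps_t1 <- (cc$s11 + cc$s10) / m1
  ps_t0 <- (cc$s01 + cc$s00) / m0
  if (ps_t1 <= 0 || ps_t0 <= 0) {
    stop("non-positive propensity; IPWE/IPB undefined", call. = FALSE)
  }
  ps <- list(ps_t1 = ps_t1, ps_t0 = ps_t0, source = "fitted")
  class(ps) <- "propensity_model"
  ps
}

#' @export
print.propensity_model <- function(x, ...) {
  cat(sprintf("Verification propensity (%s): P(V=1|T=1) = %.4f, P(V=1|T=0) = %.4f\n",
              x$source, x$ps_t1, x$ps_t0))
  invisible(x)
}

#' Normalized inverse-propensity resampling weights
#'
#' Computes the inverse probability bootstrap weight of each complete case,
#' proportional to 1/PS and scaled so the weights sum to one over the n
#' complete cases. Resampling the complete cases with these weights restores
#' the complete-data distribution of (T, D) in expectation.
#'
#' @param ps numeric vector of per-complete-case verification propensities,
#'   all positive.
#' @return Numeric weight vector of the same length, summing to 1.
#' @examples
#' ipb_weights(c(0.2, 0.8))   # 5:1.25 normalized -> 0.8, 0.2
#' @export
ipb_weights <- function(ps) {
  stopifnot(is.numeric(ps), length(ps) >= 1L)
  if (any(is.na(ps)) || any(ps <= 0)) {
    stop("all propensity scores must be positive", call. = FALSE)
  }
  w <- 1 / ps
  w / sum(w)
}

# Per-subject propensity vector for the complete cases of a dataset.
propensity_per_case <- function(data, ps) {
  stopifnot(inherits(data, "verification_data"),
            inherits(ps, "propensity_model"))
  t_cc <- data$test[data$verified == 1L]
  ifelse(t_cc == 1L, ps$ps_t1, ps$ps_t0)
}
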