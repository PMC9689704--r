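#' Simulation scenario for a partially verified diagnostic study
#'
#' Bundles the true parameters of one simulation cell: disease prevalence
#' `p`, true sensitivity `sn` and specificity `sp`, the MAR verification
#' probabilities given the test result, and the sample size.
#'
#' Complete data are multinomial over the four (test, disease) cells with
#' probabilities
#' \deqn{\pi_1 = Sn \cdot p,\quad \pi_2 = (1-Sn) p,\quad
#'       \pi_3 = (1-Sp)(1-p),\quad \pi_4 = Sp (1-p),}
#' and verification is then drawn Bernoulli with probability `pv1` for
#' test-positives and `pv0` for test-negatives, masking `disease` where
#' unverified.
#'
#' @param p true prevalence P(D=1), in (0,1).
#' @param sn true sensitivity P(T=1|D=1), in (0,1].
#' @param sp true specificity P(T=0|D=0), in (0,1].
#' @param pv1 verification probability P(V=1|T=1), in (0,1].
#' @param pv0 verification probability P(V=1|T=0), in \[0,1\].
#' @param N sample size per simulated dataset.
#' @return A list of class `scenario_config`.
#' @examples
#' cfg <- scenario_config(p = 0.4, sn = 0.6, sp = 0.6)
#' cell_probabilities(cfg)
#' verification_fraction(cfg)
#' @export
scenario_config <- function(p, sn, sp, pv1 = 0.8, pv0 = 0.4, N = 1000) {
  stopifnot(is.numeric(p), p > 0, p < 1,
            is.numeric(sn), sn > 0, sn <= 1,
            is.numeric(sp), sp > 0, sp <= 1,
            is.numeric(pv1), pv1 > 0, pv1 <= 1,
            is.numeric(pv0), pv0 >= 0, pv0 <= 1,
            N >= 1)
  cfg <- list(p = p, sn = sn, sp = sp, pv1 = pv1, pv0 = pv0,
              N = as.integer(N))
  class(cfg) <- "scenario_config"
  cfg
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "Scenario: p = %.3g, Sn = %.3g, Sp = %.3g, P(V=1|T=1) = %.3g, P(V=1|T=0) = %.3g, N = %d\n",
    x$p, x$sn, x$sp, x$pv1, x$pv0, x$N))
  invisible(x)
}

#' Multinomial cell probabilities of the complete data
#'
#' @param cfg a [scenario_config()].
#' @return Named numeric vector `(pi1, pi2, pi3, pi4)` for the cells
#'   (T=1,D=1), (T=0,D=1), (T=1,D=0), (T=0,D=0); sums to 1.
#' @export
cell_probabilities <- function(cfg) {
  stopifnot(inherits(cfg, "scenario_config"))
  c(pi1 = cfg$sn * cfg$p,
    pi2 = (1 - cfg$sn) * cfg$p,
    pi3 = (1 - cfg$sp) * (1 - cfg$p),
    pi4 = cfg$sp * (1 - cfg$p))
}

#' Analytic verified fraction P(V=1) of a scenario
#'
#' `pv1 * P(T=1) + pv0 * P(T=0)` with `P(T=1) = pi1 + pi3`.
#'
#' @param cfg a [scenario_config()].
#' @return The marginal verification probability.
#' @export
verification_fraction <- function(cfg) {
  pis <- cell_probabilities(cfg)
  pt1 <- pis[["pi1"]] + pis[["pi3"]]
  cfg$pv1 * pt1 + cfg$pv0 * (1 - pt1)
}

#' Simulate a fully verified diagnostic dataset
#'
#' Draws one N-trial multinomial over the four (test, disease) cells, expands
#' it to subject level and shuffles the rows (equivalent in distribution to
#' per-subject categorical draws). All subjects are verified.
#'
#' Uses the current R random number stream; call `set.seed()` first for
#' reproducibility.
#'
#' @param cfg a [scenario_config()].
#' @return A [verification_data()] object with `verified == 1` everywhere.
#' @export
simulate_complete <- function(cfg) {
  pis <- cell_probabilities(cfg)
  k <- stats::rmultinom(1L, cfg$N, pis)[, 1L]
  test <- rep(c(1L, 0L, 1L, 0L), times = k)
  disease <- rep(c(1L, 1L, 0L, 0L), times = k)
  ord <- sample.int(cfg$N)
  verification_data(test = test[ord], verified = rep(1L, cfg$N),
                    disease = disease[ord])
}

#' Apply MAR partial verification to complete data
#'
#' Each subject's verification indicator is drawn Bernoulli with probability
#' `pv1` if test-positive and `pv0` if test-negative; disease status is set
#' missing where unverified. Test results and the disease status of verified
#' subjects are untouched.
#'
#' @param data a fully verified [verification_data()] object.
#' @param pv1,pv0 verification probabilities given T=1 and T=0.
#' @return A [verification_data()] object with partially missing disease.
#' @export
apply_mar_verification <- function(data, pv1 = 0.8, pv0 = 0.4) {
  stopifnot(inherits(data, "verification_data"), all(data$verified == 1L))
  pv <- ifelse(data$test == 1L, pv1, pv0)
  v <- as.integer(stats::runif(nrow(data)) < pv)
  verification_data(test = data$test, verified = v,
                    disease = ifelse(v == 1L, data$disease, NA_integer_))
}

#' Simulate one partially verified dataset
#'
#' Convenience wrapper: [simulate_complete()] followed by
#' [apply_mar_verification()] with the scenario's verification probabilities.
#'
#' @param cfg a [scenario_config()].
#' @param seed optional integer seed set before generation.
#' @return A [verification_data()] object.
#' @export
simulate_pvb <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  apply_mar_verification(simulate_complete(cfg), cfg$pv1, cfg$pv0)
}

# Count-level fast path used by the study runner: draws the complete 2x2
# table and thins each cell binomially by its verification probability.
# Exactly equivalent in distribution to the subject-level pipeline.
simulate_counts <- function(cfg) {
  pis <- cell_probabilities(cfg)
  k <- unname(stats::rmultinom(1L, cfg$N, pis)[, 1L])  # (11, 01, 10, 00)
  full <- c(n11 = k[1L], n01 = k[2L], n10 = k[3L], n00 = k[4L])
  s11 <- stats::rbinom(1L, full[["n11"]], cfg$pv1)
  s10 <- stats::rbinom(1L, full[["n10"]], cfg$pv1)
  s01 <- stats::rbinom(1L, full[["n01"]], cfg$pv0)
  s00 <- stats::rbinom(1L, full[["n00"]], cfg$pv0)
  list(full = cell_counts(s11 = full[["n11"]], s10 = full[["n10"]],
                          s01 = full[["n01"]], s00 = full[["n00"]]),
       masked = cell_counts(s11 = s11, s10 = s10, s01 = s01, s00 = s00,
                            u1 = full[["n11"]] + full[["n10"]] - s11 - s10,
                            u0 = full[["n01"]] + full[["n00"]] - s01 - s00))
}

# Independent per-replicate seeds derived from one master seed, so each
# replicate is individually reproducible.
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(2147483646L, n)
}
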