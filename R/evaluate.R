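#' Mean, bias, and standard error of a set of estimates
#'
#' Bias is the mean estimate minus the true value; the standard error is the
#' standard deviation of the estimates across replicates (denominator B - 1).
#'
#' @param estimates numeric vector of per-replicate estimates (length >= 2).
#' @param theta_true the true parameter value.
#' @return Named vector `c(mean, bias, se)`.
#' @examples
#' compute_metrics(c(0.5, 0.7), 0.6)
#' @export
compute_metrics <- function(estimates, theta_true) {
  stopifnot(length(estimates) >= 2L)
  m <- mean(estimates)
  c(mean = m, bias = m - theta_true, se = stats::sd(estimates))
}

#' Run one Monte-Carlo simulation cell
#'
#' Simulates `B` independent partially verified datasets under a scenario and
#' evaluates the requested estimators on every one of them, reporting each
#' method's mean estimate, bias, and Monte-Carlo standard error for both
#' sensitivity and specificity.
#'
#' Per replicate, a complete multinomial dataset is generated and MAR
#' verification applied (via the exact count-level equivalents of
#' [simulate_complete()] and [apply_mar_verification()]); FDA is evaluated on
#' the complete data and every other method on the masked data, so all
#' methods share the replicate's random draw (common random numbers). A
#' replicate is redrawn until all four verified cells are non-empty, i.e.
#' until every estimator is estimable — the study conditions on estimable
#' samples; the number of redraws is reported.
#'
#' Each replicate runs on its own seed derived from `seed`, so replicates are
#' independent and individually reproducible.
#'
#' @param cfg a [scenario_config()].
#' @param methods methods to evaluate.
#' @param B number of simulation replicates (>= 2).
#' @param b bootstrap samples per replicate for IPB.
#' @param m imputations per replicate for MI.
#' @param seed master seed.
#' @param ipb_point IPB point estimator (see [estimate_ipb()]).
#' @return A data frame of class `simulation_result`: one row per method with
#'   columns `method`, `mean_sn`, `bias_sn`, `se_sn`, `mean_sp`, `bias_sp`,
#'   `se_sp`, `B`, `n_redrawn`, plus the scenario parameters.
#' @examples
#' cfg <- scenario_config(p = 0.4, sn = 0.6, sp = 0.6, N = 200)
#' run_cell(cfg, methods = c("fda", "cca", "bg"), B = 50, seed = 1)
#' @export
run_cell <- function(cfg, methods = c("fda", "cca", "bg", "ipwe", "mi", "ipb"),
                     B = 500, b = 1000, m = 100, seed = 1,
                     ipb_point = "sample") {
  stopifnot(inherits(cfg, "scenario_config"), B >= 2)
  methods <- match.arg(tolower(methods),
                       c("fda", "cca", "bg", "ipwe", "mi", "ipb"),
                       several.ok = TRUE)
  rep_seeds <- derive_seeds(seed, B)
  est <- array(NA_real_, dim = c(B, length(methods), 2L),
               dimnames = list(NULL, methods, c("sn", "sp")))
  n_redrawn <- 0L
  for (i in seq_len(B)) {
    set.seed(rep_seeds[i])
    repeat {
      sim <- simulate_counts(cfg)
      cc <- sim$masked
      if (cc$s11 > 0 && cc$s10 > 0 && cc$s01 > 0 && cc$s00 > 0) break
      n_redrawn <- n_redrawn + 1L
    }
    ps <- fit_propensity(cc)
    for (mth in methods) {
      e <- switch(mth,
        fda = estimate_fda(sim$full, ci = "none"),
        cca = estimate_cca(cc, ci = "none"),
        bg = estimate_bg(cc, ci = "none"),
        ipwe = estimate_ipwe(cc, ps = ps, ci = "none"),
        mi = estimate_mi(cc, m = m),
        ipb = estimate_ipb(cc, ps = ps, b = b, point = ipb_point,
                           warn_degenerate = FALSE))
      est[i, mth, "sn"] <- e$sn
      est[i, mth, "sp"] <- e$sp
    }
  }
  rows <- lapply(methods, function(mth) {
    msn <- compute_metrics(est[, mth, "sn"], cfg$sn)
    msp <- compute_metrics(est[, mth, "sp"], cfg$sp)
    data.frame(p = cfg$p, sn_true = cfg$sn, sp_true = cfg$sp, N = cfg$N,
               method = mth,
               mean_sn = msn[["mean"]], bias_sn = msn[["bias"]],
               se_sn = msn[["se"]],
               mean_sp = msp[["mean"]], bias_sp = msp[["bias"]],
               se_sp = msp[["se"]],
               B = B, n_redrawn = n_redrawn)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("simulation_result", "data.frame")
  attr(out, "estimates") <- est
  out
}

#' Run the full simulation study grid
#'
#' Evaluates the estimators over the default factorial grid: prevalence
#' `p` in \{0.4, 0.1\}, (Sn, Sp) in \{(0.6,0.6), (0.6,0.9), (0.9,0.6)\}, and
#' sample size `N` in \{200, 1000\}, with MAR verification probabilities 0.8
#' (test-positive) and 0.4 (test-negative). Each cell gets its own seed
#' derived from `seed`.
#'
#' @param p,snsp,N grid levels; `snsp` is a list of `c(sn, sp)` pairs.
#' @param pv1,pv0 verification probabilities.
#' @inheritParams run_cell
#' @return A long-format data frame of class `simulation_result` (one row
#'   per cell x method).
#' @export
run_study <- function(p = c(0.4, 0.1),
                      snsp = list(c(0.6, 0.6), c(0.6, 0.9), c(0.9, 0.6)),
                      N = c(200, 1000),
                      pv1 = 0.8, pv0 = 0.4,
                      methods = c("fda", "cca", "bg", "ipwe", "mi", "ipb"),
                      B = 500, b = 1000, m = 100, seed = 1,
                      ipb_point = "sample") {
  grid <- expand.grid(ip = seq_along(p), is = seq_along(snsp),
                      iN = seq_along(N))
  cell_seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(g) {
    cfg <- scenario_config(p = p[grid$ip[g]],
                           sn = snsp[[grid$is[g]]][1L],
                           sp = snsp[[grid$is[g]]][2L],
                           pv1 = pv1, pv0 = pv0, N = N[grid$iN[g]])
    run_cell(cfg, methods = methods, B = B, b = b, m = m,
             seed = cell_seeds[g], ipb_point = ipb_point)
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    attr(r, "estimates") <- NULL
    r
  }))
  rownames(out) <- NULL
  class(out) <- c("simulation_result", "data.frame")
  out
}

#' Pivot a long simulation result into the study's table layout
#'
#' One block per (N, Sn, Sp) cell with methods as rows and mean/bias/SE
#' columns for Sn and Sp, rounded to three decimals (full precision remains
#' in the long-format input).
#'
#' @param results a `simulation_result` data frame.
#' @param digits rounding for display.
#' @return A data frame in block layout.
#' @export
format_study_table <- function(results, digits = 3) {
  cols <- c("mean_sn", "bias_sn", "se_sn", "mean_sp", "bias_sp", "se_sp")
  out <- results[order(results$p, results$N, results$sn_true,
                       results$sp_true), ,
                 drop = FALSE]
  out[cols] <- lapply(out[cols], round, digits = digits)
  out$method <- toupper(out$method)
  out[c("p", "N", "sn_true", "sp_true", "method", cols)]
}
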