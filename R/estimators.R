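#' @title Accuracy estimate container
#' @description Paired sensitivity/specificity point estimates with optional
#'   standard errors and confidence intervals, labelled by method.
#' @param method method label.
#' @param sn,sp point estimates in \[0,1\].
#' @param sn_se,sp_se standard errors (or `NA`).
#' @param sn_ci,sp_ci length-2 `c(lo, hi)` intervals (or `NA`s).
#' @param alpha complement of the CI level.
#' @param extra list of method-specific diagnostics.
#' @return An object of class `accuracy_estimate`.
#' @keywords internal
accuracy_estimate <- function(method, sn, sp, sn_se = NA_real_,
                              sp_se = NA_real_, sn_ci = c(NA_real_, NA_real_),
                              sp_ci = c(NA_real_, NA_real_), alpha = 0.05,
                              extra = list()) {
  stopifnot(is.na(sn) || (sn >= 0 && sn <= 1),
            is.na(sp) || (sp >= 0 && sp <= 1))
  out <- list(method = method, sn = sn, sp = sp, sn_se = sn_se, sp_se = sp_se,
              sn_ci = sn_ci, sp_ci = sp_ci, alpha = alpha, extra = extra)
  class(out) <- "accuracy_estimate"
  out
}

#' @export
print.accuracy_estimate <- function(x, digits = 3, ...) {
  fmt <- function(est, ci) {
    s <- formatC(est, digits = digits, format = "f")
    if (!any(is.na(ci))) {
      s <- sprintf("%s (%s, %s)", s,
                   formatC(ci[1L], digits = digits, format = "f"),
                   formatC(ci[2L], digits = digits, format = "f"))
    }
    s
  }
  cat(sprintf("%s: Sn = %s, Sp = %s\n", toupper(x$method),
              fmt(x$sn, x$sn_ci), fmt(x$sp, x$sp_ci)))
  invisible(x)
}

as_counts <- function(x) {
  if (inherits(x, "cell_counts")) x else cell_counts(x)
}

# Shared Sn/Sp arithmetic on a verified (or complete) 2x2 table.
snsp_from_table <- function(s11, s10, s01, s00) {
  nd1 <- s11 + s01
  nd0 <- s10 + s00
  if (nd1 <= 0 || nd0 <= 0) {
    stop("Sn/Sp undefined: empty disease class", call. = FALSE)
  }
  list(sn = s11 / nd1, sp = s00 / nd0, nd1 = nd1, nd0 = nd0)
}

#' Full data analysis (FDA) of a fully verified dataset
#'
#' The standard sensitivity/specificity estimates `Sn = P(T=1|D=1)`,
#' `Sp = P(T=0|D=0)`, valid only when every subject is verified. In the
#' simulation study this is the ideal benchmark computed on the complete data
#' before verification is masked.
#'
#' @param x a [verification_data()] object or `cell_counts` table with no
#'   unverified subjects.
#' @param alpha complement of the CI level.
#' @param ci `"wald"` or `"none"`.
#' @return An `accuracy_estimate`.
#' @export
estimate_fda <- function(x, alpha = 0.05, ci = c("wald", "none")) {
  ci <- match.arg(ci)
  cc <- as_counts(x)
  if (cc$u1 > 0 || cc$u0 > 0) {
    stop("FDA requires fully verified data (no unverified subjects)",
         call. = FALSE)
  }
  e <- snsp_from_table(cc$s11, cc$s10, cc$s01, cc$s00)
  finish_wald("fda", e, alpha, ci)
}

#' Complete case analysis (CCA)
#'
#' Sensitivity/specificity computed from the verified subjects only,
#' `Sn = P(T=1|D=1,V=1)`, `Sp = P(T=0|D=0,V=1)`. Under preferential
#' verification of test-positives this is biased: sensitivity upward,
#' specificity downward, with large-sample limit
#' `sn pv1 / (sn pv1 + (1-sn) pv0)` (and the specificity analogue with
#' pv1/pv0 swapped).
#'
#' @inheritParams estimate_fda
#' @return An `accuracy_estimate`.
#' @export
estimate_cca <- function(x, alpha = 0.05, ci = c("wald", "none")) {
  ci <- match.arg(ci)
  cc <- as_counts(x)
  e <- snsp_from_table(cc$s11, cc$s10, cc$s01, cc$s00)
  finish_wald("cca", e, alpha, ci)
}

finish_wald <- function(method, e, alpha, ci) {
  if (ci == "wald") {
    accuracy_estimate(method, e$sn, e$sp,
                      sn_se = sqrt(e$sn * (1 - e$sn) / e$nd1),
                      sp_se = sqrt(e$sp * (1 - e$sp) / e$nd0),
                      sn_ci = wald_ci(e$sn, e$nd1, alpha),
                      sp_ci = wald_ci(e$sp, e$nd0, alpha), alpha = alpha)
  } else {
    accuracy_estimate(method, e$sn, e$sp, alpha = alpha)
  }
}

#' Begg-Greenes corrected estimates
#'
#' Bayes-theorem reassembly of sensitivity and specificity from the marginal
#' test-positive fraction (all N subjects) and the predictive values among
#' verified subjects, unbiased under MAR verification:
#' \deqn{\widehat{Sn} = \frac{\hat P(T=1)\hat P(D=1|T=1,V=1)}
#'   {\hat P(T=1)\hat P(D=1|T=1,V=1) + \hat P(T=0)\hat P(D=1|T=0,V=1)},}
#' and the analogous expression for specificity with D=0.
#'
#' @inheritParams estimate_fda
#' @param ci `"analytic"` (logit-scale delta method, see
#'   [bg_analytic_ci()]), `"boot"` (BCa over subject resampling), or
#'   `"none"`.
#' @param b bootstrap replicates when `ci = "boot"`.
#' @return An `accuracy_estimate`.
#' @examples
#' estimate_bg(pvb_example("hepatic", counts_only = TRUE))
#' @export
estimate_bg <- function(x, alpha = 0.05, ci = c("analytic", "boot", "none"),
                        b = 1000) {
  ci <- match.arg(ci)
  cc <- as_counts(x)
  n1 <- cc$s11 + cc$s10
  n0 <- cc$s01 + cc$s00
  if (n1 <= 0 || n0 <= 0) {
    stop("BG requires verified cases in both test strata", call. = FALSE)
  }
  m1 <- n1 + cc$u1
  m0 <- n0 + cc$u0
  N <- m1 + m0
  p1 <- cc$s11 / n1                      # P(D=1 | T=1, V=1)
  p0 <- cc$s01 / n0                      # P(D=1 | T=0, V=1)
  den_sn <- m1 / N * p1 + m0 / N * p0
  den_sp <- m1 / N * (1 - p1) + m0 / N * (1 - p0)
  if (den_sn <= 0 || den_sp <= 0) {
    stop("BG denominator is zero: no estimated diseased (or non-diseased) ",
         "subjects", call. = FALSE)
  }
  sn <- (m1 / N * p1) / den_sn
  sp <- (m0 / N * (1 - p0)) / den_sp
  est <- accuracy_estimate("bg", sn, sp, alpha = alpha)
  if (ci == "analytic") {
    ic <- bg_analytic_ci(cc, alpha)
    est$sn_ci <- ic$sn
    est$sp_ci <- ic$sp
  } else if (ci == "boot") {
    est <- add_count_bootstrap_ci(est, cc, b, alpha, function(c2) {
      e <- estimate_bg(c2, ci = "none")
      c(sn = e$sn, sp = e$sp)
    })
  }
  est
}

#' Inverse probability weighting estimator (IPWE)
#'
#' Horvitz-Thompson-style weighting of the verified subjects by the inverse
#' of their verification propensity:
#' \deqn{\widehat{Sn} = \frac{\sum_i T_i V_i D_i / \widehat{PS}_i}
#'   {\sum_i V_i D_i / \widehat{PS}_i},\qquad
#'  \widehat{Sp} = \frac{\sum_i (1-T_i) V_i (1-D_i) / \widehat{PS}_i}
#'   {\sum_i V_i (1-D_i) / \widehat{PS}_i}.}
#' With the saturated (stratum-proportion) propensity fit this is
#' algebraically identical to the Begg-Greenes estimator.
#'
#' @inheritParams estimate_fda
#' @param ps a `propensity_model` from [fit_propensity()]; fitted from the
#'   data when `NULL`. When `ci = "bca"` and the propensity was fitted, it is
#'   refitted inside each bootstrap resample.
#' @param ci `"bca"` (bootstrap bias-corrected accelerated, the convention
#'   for this estimator), `"normal"` (bootstrap normal) or `"none"`.
#' @param b bootstrap replicates for the interval.
#' @return An `accuracy_estimate`.
#' @export
estimate_ipwe <- function(x, ps = NULL, alpha = 0.05,
                          ci = c("bca", "normal", "none"), b = 1000) {
  ci <- match.arg(ci)
  cc <- as_counts(x)
  refit <- is.null(ps)
  if (is.null(ps)) ps <- fit_propensity(cc)
  e <- ipwe_point(cc, ps)
  est <- accuracy_estimate("ipwe", e$sn, e$sp, alpha = alpha)
  if (ci != "none") {
    stat <- function(c2) {
      ps2 <- if (refit) fit_propensity(c2) else ps
      ipwe_point(c2, ps2)[c("sn", "sp")]
    }
    est <- add_count_bootstrap_ci(est, cc, b, alpha, stat,
                                  type = if (ci == "bca") "bca" else "normal")
  }
  est
}

ipwe_point <- function(cc, ps) {
  wd1 <- cc$s11 / ps$ps_t1 + cc$s01 / ps$ps_t0   # weighted diseased mass
  wd0 <- cc$s10 / ps$ps_t1 + cc$s00 / ps$ps_t0   # weighted non-diseased mass
  if (wd1 <= 0 || wd0 <= 0) {
    stop("IPWE undefined: no weighted mass in a disease class", call. = FALSE)
  }
  list(sn = (cc$s11 / ps$ps_t1) / wd1, sp = (cc$s00 / ps$ps_t0) / wd0)
}

# Nonparametric bootstrap over the six observed cell types (equivalent to
# resampling the N subjects with replacement), with BCa acceleration from
# the leave-one-out jackknife collapsed over identical subjects.
add_count_bootstrap_ci <- function(est, cc, b, alpha, statistic,
                                   type = c("bca", "normal")) {
  type <- match.arg(type)
  k <- c(cc$s11, cc$s10, cc$s01, cc$s00, cc$u1, cc$u0)
  N <- sum(k)
  draws <- stats::rmultinom(b, N, k / N)
  reps <- apply(draws, 2L, function(d) {
    c2 <- cell_counts(s11 = d[1L], s10 = d[2L], s01 = d[3L], s00 = d[4L],
                      u1 = d[5L], u0 = d[6L])
    tryCatch(unlist(statistic(c2)), error = function(e) c(sn = NA_real_,
                                                          sp = NA_real_))
  })
  for (q in c("sn", "sp")) {
    t <- reps[q, ]
    t <- t[is.finite(t)]
    if (length(t) < 2L) next
    if (type == "normal") {
      icv <- boot_normal_ci(est[[q]], stats::sd(t), alpha)
    } else {
      jack <- vapply(which(k > 0), function(i) {
        d <- k
        d[i] <- d[i] - 1
        c2 <- cell_counts(s11 = d[1L], s10 = d[2L], s01 = d[3L], s00 = d[4L],
                          u1 = d[5L], u0 = d[6L])
        out <- tryCatch(unlist(statistic(c2))[[q]],
                        error = function(e) NA_real_)
        out
      }, numeric(1L))
      jack_full <- rep(jack, times = k[k > 0])
      jack_full <- jack_full[is.finite(jack_full)]
      icv <- boot_bca_ci(t, est[[q]], jack_full, alpha)
    }
    est[[paste0(q, "_ci")]] <- icv
    est[[paste0(q, "_se")]] <- stats::sd(t)
  }
  est
}

#' Multiple imputation of missing disease status
#'
#' Proper imputation under the logistic model
#' `logit P(D=1|T) = beta0 + beta1 T` fitted to the verified subjects: each
#' of the m imputations draws coefficients from the asymptotic normal
#' posterior of the fit and then draws each missing disease status Bernoulli
#' from the implied probability. By default the fit augments the data with
#' a small number of weighted pseudo-observations (two per class at
#' `mean(T) +/- sd(T)`, total weight 2), the standard safeguard against
#' perfect separation in imputation models; with `augment = FALSE` a
#' separated table is an error.
#'
#' @param x a [verification_data()] object or `cell_counts` table.
#' @param m number of imputations (>= 2).
#' @param augment add the anti-separation pseudo-observations (default TRUE).
#' @return An object of class `imputation_set`: per-imputation full-data
#'   sensitivity/specificity estimates `sn_j`, `sp_j` with their
#'   within-imputation variances, plus the fitted coefficients.
#' @export
impute_disease <- function(x, m = 100, augment = TRUE) {
  stopifnot(m >= 2)
  cc <- as_counts(x)
  sv <- c(cc$s11, cc$s10, cc$s01, cc$s00)
  if (!augment && any(sv == 0)) {
    stop("perfect separation in the imputation model (an empty verified ",
         "cell); use a larger sample, augment = TRUE, or another method",
         call. = FALSE)
  }
  xv <- c(1, 1, 0, 0)
  yv <- c(1, 0, 1, 0)
  wv <- sv
  if (augment) {
    N <- n_total(cc)
    mu <- (cc$s11 + cc$s10 + cc$u1) / N
    sdv <- sqrt(mu * (1 - mu) * N / max(1, N - 1))
    xv <- c(xv, mu - sdv, mu - sdv, mu + sdv, mu + sdv)
    yv <- c(yv, 0, 1, 0, 1)
    wv <- c(wv, rep(0.5, 4L))
  }
  keep <- wv > 0
  X <- cbind(1, xv[keep])
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = yv[keep], weights = wv[keep],
                   family = stats::binomial()))
  if (fit$rank < 2L) {
    stop("perfect separation in the imputation model (an empty verified ",
         "cell); use a larger sample, augment = TRUE, or another method",
         call. = FALSE)
  }
  beta <- fit$coefficients
  V <- chol2inv(fit$qr$qr[1:2, 1:2, drop = FALSE])
  L <- t(chol(V))
  sn_j <- sp_j <- sn_var <- sp_var <- numeric(m)
  for (j in seq_len(m)) {
    bj <- beta + drop(L %*% stats::rnorm(2L))
    p1 <- stats::plogis(bj[1L] + bj[2L])
    p0 <- stats::plogis(bj[1L])
    d1 <- stats::rbinom(1L, cc$u1, p1)
    d0 <- stats::rbinom(1L, cc$u0, p0)
    c11 <- cc$s11 + d1
    c01 <- cc$s01 + d0
    c10 <- cc$s10 + cc$u1 - d1
    c00 <- cc$s00 + cc$u0 - d0
    e <- snsp_from_table(c11, c10, c01, c00)
    sn_j[j] <- e$sn
    sp_j[j] <- e$sp
    sn_var[j] <- e$sn * (1 - e$sn) / e$nd1
    sp_var[j] <- e$sp * (1 - e$sp) / e$nd0
  }
  out <- list(m = m, sn_j = sn_j, sp_j = sp_j, sn_var = sn_var,
              sp_var = sp_var, beta = beta, vcov = V, augment = augment)
  class(out) <- "imputation_set"
  out
}

#' Multiple imputation estimates with Rubin pooling
#'
#' Runs [impute_disease()] (unless an `imputation_set` is supplied), takes
#' the mean of the per-imputation full-data estimates as the point estimate,
#' and pools the variances by Rubin's rules for the confidence interval.
#'
#' @param x a [verification_data()] object, `cell_counts` table, or an
#'   `imputation_set` from [impute_disease()].
#' @param m number of imputations; `"auto"` uses the percentage of
#'   incomplete cases (rounded, at least 2), the usual rule for applied
#'   analyses.
#' @param alpha complement of the CI level.
#' @param augment passed to [impute_disease()].
#' @return An `accuracy_estimate` with the `imputation_set` in `$extra`.
#' @export
estimate_mi <- function(x, m = 100, alpha = 0.05, augment = TRUE) {
  if (inherits(x, "imputation_set")) {
    imp <- x
  } else {
    cc <- as_counts(x)
    if (identical(m, "auto")) m <- max(2L, round(pct_unverified(cc)))
    imp <- impute_disease(cc, m = m, augment = augment)
  }
  pool_sn <- rubin_pool(imp$sn_j, imp$sn_var, alpha)
  pool_sp <- rubin_pool(imp$sp_j, imp$sp_var, alpha)
  accuracy_estimate("mi", pool_sn$est, pool_sp$est,
                    sn_se = pool_sn$se, sp_se = pool_sp$se,
                    sn_ci = pool_sn$ci, sp_ci = pool_sp$ci, alpha = alpha,
                    extra = list(imputations = imp,
                                 df = c(sn = pool_sn$df, sp = pool_sp$df)))
}

#' Inverse probability bootstrap (IPB) estimates
#'
#' Corrects partial verification bias by weighted resampling of the n
#' complete cases: each verified subject gets resampling weight proportional
#' to the inverse of its verification propensity ([ipb_weights()]), so a
#' bootstrap sample of size n drawn with those weights restores the
#' complete-data distribution of (test, disease) and can be analysed with the
#' standard full-data formulas.
#'
#' Three point estimators are available:
#' * `"sample"` (default): draw one weighted bootstrap sample — the debiased
#'   synthetic dataset — and report its standard Sn/Sp; the `b` ordinary
#'   bootstrap resamples of that synthetic sample provide the standard error
#'   and the bootstrap normal interval. This is the estimator whose
#'   sampling dispersion the package's simulation study tabulates; its
#'   variance adds the resampling variance to the sampling variance, the
#'   price of producing an analysable debiased dataset.
#' * `"mean"`: the mean of the standard estimates over `b` weighted bootstrap
#'   samples (smaller Monte-Carlo dispersion, same expectation).
#' * `"plugin"`: the weighted (Hajek) estimate itself, identical to
#'   [estimate_ipwe()].
#'
#' Because every complete case is one of four (test, disease) cell types,
#' weighted resampling is performed as a four-cell multinomial draw, which is
#' distributionally identical to per-subject resampling. Bootstrap replicates
#' in which Sn or Sp is undefined (no diseased, or no non-diseased, subjects
#' drawn) are excluded from that quantity's mean/SD and counted; a warning is
#' issued above 1% incidence.
#'
#' @param x a [verification_data()] object or `cell_counts` table.
#' @param ps a `propensity_model`; fitted from the data when `NULL`.
#' @param b number of bootstrap samples.
#' @param alpha complement of the CI level.
#' @param point point estimator, see Details.
#' @param max_redraw for `point = "sample"`: maximum redraws of a degenerate
#'   synthetic sample.
#' @param warn_degenerate warn when more than 1% of bootstrap replicates are
#'   degenerate (the study runner disables this, counting instead).
#' @return An `accuracy_estimate`; `$extra$replicates` holds the replicate
#'   set (valid replicate values, `b_requested`, `n_degenerate`) and, for
#'   `point = "sample"`, `$extra$synthetic` holds the synthetic sample's cell
#'   counts.
#' @export
estimate_ipb <- function(x, ps = NULL, b = 1000, alpha = 0.05,
                         point = c("sample", "mean", "plugin"),
                         max_redraw = 100, warn_degenerate = TRUE) {
  point <- match.arg(point)
  cc <- as_counts(x)
  n <- n_verified(cc)
  if (n < 2L) stop("IPB requires at least two complete cases", call. = FALSE)
  if (is.null(ps)) ps <- fit_propensity(cc)
  # weighted resampling probabilities of the four verified cell types
  q <- c(s11 = cc$s11 / ps$ps_t1, s10 = cc$s10 / ps$ps_t1,
         s01 = cc$s01 / ps$ps_t0, s00 = cc$s00 / ps$ps_t0)
  if (sum(q) <= 0) stop("no complete cases to resample", call. = FALSE)
  q <- q / sum(q)

  if (point == "sample") {
    for (i in seq_len(max_redraw)) {
      syn <- stats::rmultinom(1L, n, q)[, 1L]
      ok <- (syn[1L] + syn[3L] > 0) && (syn[2L] + syn[4L] > 0)
      if (ok) break
    }
    if (!ok) {
      stop("could not draw a non-degenerate synthetic sample", call. = FALSE)
    }
    sn0 <- syn[1L] / (syn[1L] + syn[3L])
    sp0 <- syn[4L] / (syn[2L] + syn[4L])
    reps <- snsp_replicates(stats::rmultinom(b, n, syn / n))
    extra <- list(replicates = reps,
                  synthetic = cell_counts(s11 = syn[1L], s10 = syn[2L],
                                          s01 = syn[3L], s00 = syn[4L]))
  } else {
    reps <- snsp_replicates(stats::rmultinom(b, n, q))
    extra <- list(replicates = reps)
    if (point == "mean") {
      sn0 <- mean(reps$sn_reps)
      sp0 <- mean(reps$sp_reps)
    } else {
      e <- ipwe_point(cc, ps)
      sn0 <- e$sn
      sp0 <- e$sp
    }
  }
  if (length(reps$sn_reps) == 0L || length(reps$sp_reps) == 0L) {
    stop("all bootstrap replicates degenerate", call. = FALSE)
  }
  if (warn_degenerate && max(reps$n_degenerate) > 0.01 * b) {
    warning(sprintf("%d of %d IPB bootstrap replicates were degenerate",
                    max(reps$n_degenerate), b))
  }
  sn_se <- stats::sd(reps$sn_reps)
  sp_se <- stats::sd(reps$sp_reps)
  accuracy_estimate("ipb", sn0, sp0, sn_se = sn_se, sp_se = sp_se,
                    sn_ci = boot_normal_ci(sn0, sn_se, alpha),
                    sp_ci = boot_normal_ci(sp0, sp_se, alpha),
                    alpha = alpha, extra = extra)
}

# Per-replicate Sn/Sp from a 4 x b matrix of resampled verified cell counts
# (rows: s11, s10, s01, s00). Degenerate replicates are dropped per quantity.
snsp_replicates <- function(draws) {
  sn <- draws[1L, ] / (draws[1L, ] + draws[3L, ])
  sp <- draws[4L, ] / (draws[2L, ] + draws[4L, ])
  b <- ncol(draws)
  out <- list(sn_reps = sn[is.finite(sn)], sp_reps = sp[is.finite(sp)],
              b_requested = b,
              n_degenerate = c(sn = sum(!is.finite(sn)),
                               sp = sum(!is.finite(sp))))
  class(out) <- "bootstrap_replicates"
  out
}

# Subject-level weighted resampler; the distributional reference for the
# multinomial fast path (used by the test suite).
ipb_resample_subjects <- function(data, ps = NULL, b = 100) {
  stopifnot(inherits(data, "verification_data"))
  if (is.null(ps)) ps <- fit_propensity(data)
  cc_idx <- which(data$verified == 1L)
  w <- ipb_weights(propensity_per_case(data, ps))
  t_cc <- data$test[cc_idx]
  d_cc <- data$disease[cc_idx]
  n <- length(cc_idx)
  sn <- sp <- numeric(b)
  for (j in seq_len(b)) {
    pick <- sample.int(n, n, replace = TRUE, prob = w)
    tt <- t_cc[pick]
    dd <- d_cc[pick]
    sn[j] <- sum(tt == 1L & dd == 1L) / sum(dd == 1L)
    sp[j] <- sum(tt == 0L & dd == 0L) / sum(dd == 0L)
  }
  list(sn = sn[is.finite(sn)], sp = sp[is.finite(sp)])
}

#' Estimate diagnostic accuracy under partial verification
#'
#' One-call interface running any subset of the six estimators on a dataset
#' and returning a tidy table of point estimates and confidence intervals.
#' `"fda"` is only applicable to fully verified data and is skipped (with a
#' message) otherwise. Confidence intervals follow each method's convention:
#' Wald for FDA/CCA, logit delta method for BG, BCa bootstrap for IPWE,
#' Rubin's rules for MI, bootstrap normal for IPB.
#'
#' @param data a [verification_data()] object (or coercible data frame).
#' @param method character vector of methods, or `"all"`.
#' @param b bootstrap samples for IPWE/IPB.
#' @param m imputations for MI; `"auto"` = percentage of incomplete cases.
#' @param alpha complement of the CI level.
#' @param seed optional seed set before the stochastic methods run.
#' @return A data frame of class `accuracy_table`: one row per method with
#'   columns `method`, `sn`, `sn_se`, `sn_lo`, `sn_hi`, `sp`, `sp_se`,
#'   `sp_lo`, `sp_hi`.
#' @examples
#' est <- estimate_accuracy(pvb_example("hepatic"), b = 200, seed = 1)
#' est
#' @export
estimate_accuracy <- function(data, method = "all", b = 1000, m = "auto",
                              alpha = 0.05, seed = NULL) {
  if (!inherits(data, "verification_data")) data <- as_verification_data(data)
  all_methods <- c("fda", "cca", "bg", "ipwe", "mi", "ipb")
  if (identical(method, "all")) method <- all_methods
  method <- match.arg(tolower(method), all_methods, several.ok = TRUE)
  cc <- cell_counts(data)
  if (!is.null(seed)) set.seed(seed)
  if ("fda" %in% method && (cc$u1 > 0 || cc$u0 > 0)) {
    if (length(method) == 1L) {
      stop("FDA requires fully verified data", call. = FALSE)
    }
    message("skipping FDA: data are not fully verified")
    method <- setdiff(method, "fda")
  }
  rows <- lapply(method, function(mth) {
    est <- switch(mth,
      fda = estimate_fda(cc, alpha),
      cca = estimate_cca(cc, alpha),
      bg = estimate_bg(cc, alpha),
      ipwe = estimate_ipwe(cc, alpha = alpha, b = b),
      mi = estimate_mi(cc, m = m, alpha = alpha),
      ipb = estimate_ipb(cc, b = b, alpha = alpha))
    data.frame(method = mth, sn = est$sn, sn_se = est$sn_se,
               sn_lo = est$sn_ci[[1L]], sn_hi = est$sn_ci[[2L]],
               sp = est$sp, sp_se = est$sp_se,
               sp_lo = est$sp_ci[[1L]], sp_hi = est$sp_ci[[2L]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "alpha") <- alpha
  class(out) <- c("accuracy_table", "data.frame")
  out
}

#' @export
print.accuracy_table <- function(x, digits = 3, ...) {
  fmt <- function(est, lo, hi) {
    ifelse(is.na(lo),
           formatC(est, digits = digits, format = "f"),
           sprintf("%s (%s, %s)",
                   formatC(est, digits = digits, format = "f"),
                   formatC(lo, digits = digits, format = "f"),
                   formatC(hi, digits = digits, format = "f")))
  }
  out <- data.frame(Method = toupper(x$method),
                    `Sn (95% CI)` = fmt(x$sn, x$sn_lo, x$sn_hi),
                    `Sp (95% CI)` = fmt(x$sp, x$sp_lo, x$sp_hi),
                    check.names = FALSE)
  print(out, row.names = FALSE)
  invisible(x)
}
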