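#' Wald confidence interval for a proportion
#'
#' `p_hat +/- z[1-alpha/2] * sqrt(p_hat (1 - p_hat) / n_eff)`, clipped to
#' \[0, 1\].
#'
#' @param p_hat the estimated proportion.
#' @param n_eff the effective denominator count.
#' @param alpha complement of the confidence level (default 0.05 for 95%).
#' @return Numeric vector `c(lo, hi)`.
#' @examples
#' wald_ci(0.5, 100)
#' @export
wald_ci <- function(p_hat, n_eff, alpha = 0.05) {
  stopifnot(p_hat >= 0, p_hat <= 1, alpha > 0, alpha < 1)
  if (n_eff < 1) {
    return(c(lo = NA_real_, hi = NA_real_))
  }
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(p_hat * (1 - p_hat) / n_eff)
  clip01(c(lo = p_hat - z * se, hi = p_hat + z * se))
}

#' Bootstrap normal confidence interval
#'
#' `center +/- z[1-alpha/2] * sd_rep`, where `sd_rep` is the bootstrap
#' standard error, clipped to \[0, 1\].
#'
#' @param center the point estimate.
#' @param sd_rep bootstrap standard error (non-negative).
#' @param alpha complement of the confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @export
boot_normal_ci <- function(center, sd_rep, alpha = 0.05) {
  stopifnot(sd_rep >= 0, alpha > 0, alpha < 1)
  z <- stats::qnorm(1 - alpha / 2)
  clip01(c(lo = center - z * sd_rep, hi = center + z * sd_rep))
}

#' Bias-corrected and accelerated (BCa) bootstrap interval
#'
#' Standard BCa: the bias correction z0 comes from the fraction of replicate
#' values strictly below the point estimate, the acceleration from the
#' skewness of the jackknife values, and the endpoints from the replicate
#' distribution at the adjusted quantiles. Quantile lookups interpolate
#' between order statistics on the normal-quantile scale, following the
#' convention of the classical bootstrap literature, so results agree with
#' reference implementations.
#'
#' @param replicates numeric vector of bootstrap replicate statistics.
#' @param point_est the statistic on the original data.
#' @param jackknife_estimates leave-one-out statistics used for the
#'   acceleration; acceleration is taken as
#'   `sum(u^3) / (6 sum(u^2)^(3/2))` with `u = mean(jack) - jack`.
#' @param alpha complement of the confidence level.
#' @param clip clip the interval to \[0, 1\] (for proportions).
#' @return Numeric vector `c(lo, hi)`.
#' @export
boot_bca_ci <- function(replicates, point_est, jackknife_estimates,
                        alpha = 0.05, clip = TRUE) {
  t <- replicates[is.finite(replicates)]
  if (length(unique(t)) < 2L) {
    warning("all bootstrap replicates identical; returning point interval")
    out <- c(lo = point_est, hi = point_est)
    return(if (clip) clip01(out) else out)
  }
  z0 <- stats::qnorm(sum(t < point_est) / length(t))
  if (!is.finite(z0)) {
    stop("BCa bias correction is infinite (point estimate outside the ",
         "replicate range)", call. = FALSE)
  }
  u <- mean(jackknife_estimates) - jackknife_estimates
  denom <- 6 * sum(u^2)^1.5
  a <- if (denom > 0) sum(u^3) / denom else 0
  zalpha <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  out <- c(lo = quantile_norm_inter(t, adj[1L]),
           hi = quantile_norm_inter(t, adj[2L]))
  if (clip) clip01(out) else out
}

# Interpolated order-statistic quantile on the qnorm scale (the convention
# used for bootstrap percentile endpoints).
quantile_norm_inter <- function(t, alpha) {
  R <- length(t)
  rk <- (R + 1) * alpha
  k <- trunc(rk)
  tstar <- sort(t)
  if (k <= 0) return(tstar[1L])
  if (k >= R) return(tstar[R])
  if (k == rk) return(tstar[k])
  g <- (stats::qnorm(alpha) - stats::qnorm(k / (R + 1))) /
    (stats::qnorm((k + 1) / (R + 1)) - stats::qnorm(k / (R + 1)))
  tstar[k] + g * (tstar[k + 1L] - tstar[k])
}

#' Pool multiple-imputation estimates by Rubin's rules
#'
#' The pooled estimate is the mean of the per-imputation estimates; the total
#' variance is the mean within-imputation variance W plus `(1 + 1/m)` times
#' the between-imputation variance B. The interval uses the t reference with
#' the classical degrees of freedom `(m-1) (1 + W / ((1+1/m) B))^2`; with
#' B = 0 the normal reference applies.
#'
#' @param estimates_j numeric vector of per-imputation point estimates
#'   (length m >= 2).
#' @param within_var_j per-imputation (within) variances, same length.
#' @param alpha complement of the confidence level.
#' @param clip clip the interval to \[0, 1\].
#' @return A list with `est`, `var_total`, `within`, `between`, `df`, `se`,
#'   `ci`.
#' @examples
#' rubin_pool(c(0.6, 0.8), c(0.001, 0.001))
#' @export
rubin_pool <- function(estimates_j, within_var_j, alpha = 0.05, clip = TRUE) {
  m <- length(estimates_j)
  stopifnot(m >= 2L, length(within_var_j) == m)
  qbar <- mean(estimates_j)
  w <- mean(within_var_j)
  b <- stats::var(estimates_j)
  total <- w + (1 + 1 / m) * b
  se <- sqrt(total)
  if (b > 0) {
    df <- (m - 1) * (1 + w / ((1 + 1 / m) * b))^2
    q <- stats::qt(1 - alpha / 2, df)
  } else {
    df <- Inf
    q <- stats::qnorm(1 - alpha / 2)
  }
  ci <- c(lo = qbar - q * se, hi = qbar + q * se)
  list(est = qbar, var_total = total, within = w, between = b, df = df,
       se = se, ci = if (clip) clip01(ci) else ci)
}

#' Analytic Begg-Greenes confidence interval
#'
#' Delta-method interval on the logit scale for the Bayes-theorem corrected
#' sensitivity/specificity. Writing m1, m0 for the test-stratum totals, n1,
#' n0 for the verified counts per stratum and p1 = P(D=1|T=1,V=1),
#' p0 = P(D=1|T=0,V=1), the corrected sensitivity satisfies
#' `logit(Sn) = logit(P(T=1)) + log(p1/p0)`, whose three components are
#' asymptotically independent under the two-phase design, giving
#' \deqn{Var[logit(\widehat{Sn})] = N/(m_1 m_0) + (1-p_1)/(n_1 p_1) +
#'       (1-p_0)/(n_0 p_0),}
#' and the specificity analogue with p replaced by 1-p. The interval is
#' computed on the logit scale and back-transformed.
#'
#' @param counts a `cell_counts` table.
#' @param alpha complement of the confidence level.
#' @return A list with elements `sn` and `sp`, each `c(lo, hi)`.
#' @export
bg_analytic_ci <- function(counts, alpha = 0.05) {
  cc <- counts
  n1 <- cc$s11 + cc$s10
  n0 <- cc$s01 + cc$s00
  m1 <- n1 + cc$u1
  m0 <- n0 + cc$u0
  N <- m1 + m0
  p1 <- cc$s11 / n1
  p0 <- cc$s01 / n0
  est <- estimate_bg(cc, ci = "none")
  z <- stats::qnorm(1 - alpha / 2)
  logit_ci <- function(est, v) {
    if (est <= 0 || est >= 1 || !is.finite(v)) {
      return(c(lo = NA_real_, hi = NA_real_))
    }
    l <- log(est / (1 - est)) + c(-1, 1) * z * sqrt(v)
    clip01(c(lo = stats::plogis(l[1L]), hi = stats::plogis(l[2L])))
  }
  v_sn <- N / (m1 * m0) + (1 - p1) / (n1 * p1) + (1 - p0) / (n0 * p0)
  v_sp <- N / (m1 * m0) + p1 / (n1 * (1 - p1)) + p0 / (n0 * (1 - p0))
  list(sn = logit_ci(est$sn, v_sn), sp = logit_ci(est$sp, v_sp))
}

clip01 <- function(x) {
  x[] <- pmin(1, pmax(0, x))
  x
}
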