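test_that("Wald interval matches direct arithmetic and clips", {
  expect_equal(wald_ci(0.5, 100), c(lo = 0.4020018, hi = 0.5979982),
               tolerance = 1e-6)
  expect_equal(wald_ci(1, 50), c(lo = 1, hi = 1))
  p <- 40 / 45
  z <- qnorm(0.975)
  expect_equal(unname(wald_ci(p, 45)),
               c(p - z * sqrt(p * (1 - p) / 45),
                 p + z * sqrt(p * (1 - p) / 45)))
  # width non-increasing in the denominator
  w <- sapply(c(10, 50, 250, 1000), function(n) diff(wald_ci(0.3, n)))
  expect_true(all(diff(w) < 0))
})

test_that("bootstrap normal interval is symmetric and matches arithmetic", {
  expect_equal(boot_normal_ci(0.29, 0.1176),
               c(lo = 0.059508, hi = 0.520492), tolerance = 1e-5)
  expect_equal(boot_normal_ci(0.7, 0), c(lo = 0.7, hi = 0.7))
  ci <- boot_normal_ci(0.5, 0.05)
  expect_equal(ci[["hi"]] - 0.5, 0.5 - ci[["lo"]])
})

test_that("BCa matches the boot package on identical replicates", {
  skip_if_not_installed("boot")
  set.seed(7)
  x <- rexp(40)
  bo <- boot::boot(x, function(d, i) mean(d[i]), R = 999)
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  L <- mean(jack) - jack
  mine <- boot_bca_ci(bo$t[, 1], bo$t0, jack, alpha = 0.05, clip = FALSE)
  ref <- boot::boot.ci(bo, type = "bca", L = L)$bca[4:5]
  expect_equal(unname(mine), ref, tolerance = 1e-6)
  # skewed statistic too
  bo2 <- boot::boot(x, function(d, i) exp(mean(log(d[i]))), R = 999)
  jack2 <- vapply(seq_along(x), function(i) exp(mean(log(x[-i]))), numeric(1))
  mine2 <- boot_bca_ci(bo2$t[, 1], bo2$t0, jack2, alpha = 0.1, clip = FALSE)
  ref2 <- boot::boot.ci(bo2, conf = 0.9, type = "bca",
                        L = mean(jack2) - jack2)$bca[4:5]
  expect_equal(unname(mine2), ref2, tolerance = 1e-6)
})

test_that("BCa reduces to the percentile interval when z0 = a = 0", {
  # symmetric replicate set with the point estimate at the exact median and
  # symmetric jackknife values => no correction, no acceleration
  t <- c(seq(0.1, 0.45, by = 0.01), seq(0.55, 0.9, by = 0.01))
  jack <- seq(-1, 1, length.out = 21) + 0.5
  ci <- boot_bca_ci(t, 0.5, jack, alpha = 0.1, clip = FALSE)
  perc <- c(pvboot:::quantile_norm_inter(t, 0.05),
            pvboot:::quantile_norm_inter(t, 0.95))
  expect_equal(unname(ci), perc)
})

test_that("BCa is equivariant under increasing affine maps", {
  set.seed(8)
  t <- rbeta(2000, 2, 5)
  jack <- rbeta(30, 2, 5)
  t0 <- median(t)
  a <- 3.7
  b <- -1.2
  ci <- boot_bca_ci(t, t0, jack, alpha = 0.05, clip = FALSE)
  ci_t <- boot_bca_ci(a * t + b, a * t0 + b, a * jack + b, alpha = 0.05,
                      clip = FALSE)
  expect_equal(unname(ci_t), a * unname(ci) + b, tolerance = 1e-12)
})

test_that("identical replicates collapse to a point interval with a warning", {
  expect_warning(ci <- boot_bca_ci(rep(0.4, 100), 0.4, rep(0.4, 10)),
                 "identical")
  expect_equal(unname(ci), c(0.4, 0.4))
})

test_that("Rubin pooling follows the total-variance decomposition", {
  out <- rubin_pool(c(0.6, 0.8), c(0.001, 0.001))
  expect_equal(out$est, 0.7)
  expect_equal(out$between, 0.02)
  expect_equal(out$var_total, 0.001 + 1.5 * 0.02)
  expect_equal(out$df, (1 + 0.001 / (1.5 * 0.02))^2)
  # zero between-variance: plain normal interval on the within variance
  out0 <- rubin_pool(rep(0.6, 5), rep(0.004, 5))
  z <- qnorm(0.975)
  expect_equal(unname(out0$ci), c(0.6 - z * sqrt(0.004),
                                  0.6 + z * sqrt(0.004)))
  # random inputs against an independently coded oracle
  set.seed(9)
  for (i in 1:10) {
    m <- sample(3:20, 1)
    est <- runif(m)
    wv <- runif(m, 1e-4, 1e-2)
    out <- rubin_pool(est, wv, clip = FALSE)
    qbar <- sum(est) / m
    bvar <- sum((est - qbar)^2) / (m - 1)
    tvar <- sum(wv) / m + (m + 1) / m * bvar
    df <- (m - 1) * (1 + (sum(wv) / m) / ((1 + 1 / m) * bvar))^2
    expect_equal(out$est, qbar, tolerance = 1e-12)
    expect_equal(out$var_total, tvar, tolerance = 1e-12)
    expect_equal(out$df, df, tolerance = 1e-12)
    expect_equal(unname(out$ci),
                 qbar + c(-1, 1) * qt(0.975, df) * sqrt(tvar),
                 tolerance = 1e-12)
  }
})

test_that("BG analytic and bootstrap intervals agree at large N", {
  cfg <- scenario_config(p = 0.4, sn = 0.7, sp = 0.8, N = 40000)
  cc <- expected_counts(cfg)
  cc_int <- cell_counts(s11 = round(cc$s11), s10 = round(cc$s10),
                        s01 = round(cc$s01), s00 = round(cc$s00),
                        u1 = round(cc$u1), u0 = round(cc$u0))
  analytic <- estimate_bg(cc_int, ci = "analytic")
  set.seed(10)
  booted <- estimate_bg(cc_int, ci = "boot", b = 2000)
  expect_equal(analytic$sn_ci, booted$sn_ci, tolerance = 0.15)
  expect_equal(analytic$sp_ci, booted$sp_ci, tolerance = 0.15)
  # widths within 10% of each other
  expect_lt(abs(diff(analytic$sn_ci) / diff(booted$sn_ci) - 1), 0.1)
  expect_lt(abs(diff(analytic$sp_ci) / diff(booted$sp_ci) - 1), 0.1)
})

test_that("intervals contain their point estimate after clipping", {
  set.seed(11)
  for (cc in random_counts(5)) {
    est <- estimate_bg(cc, ci = "analytic")
    if (!any(is.na(est$sn_ci))) {
      expect_true(est$sn_ci[[1]] <= est$sn && est$sn <= est$sn_ci[[2]])
    }
    if (!any(is.na(est$sp_ci))) {
      expect_true(est$sp_ci[[1]] <= est$sp && est$sp <= est$sp_ci[[2]])
    }
  }
})
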