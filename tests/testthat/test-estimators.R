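test_that("FDA and CCA are the standard 2x2 proportions", {
  full <- cell_counts(s11 = 40, s10 = 10, s01 = 10, s00 = 40)
  e <- estimate_fda(full)
  expect_equal(e$sn, 0.8)
  expect_equal(e$sp, 0.8)
  # expected-count table recovers the truth exactly
  e2 <- estimate_fda(cell_counts(s11 = 9, s10 = 36, s01 = 1, s00 = 54))
  expect_equal(e2$sn, 0.9)
  expect_equal(e2$sp, 0.6)
  expect_error(estimate_fda(toy_counts()), "fully verified")
  expect_error(estimate_fda(cell_counts(s11 = 5, s01 = 3)), "empty disease")

  cca <- estimate_cca(toy_counts())
  expect_equal(cca$sn, 40 / 45)
  expect_equal(cca$sp, 20 / 30)
  expect_equal(estimate_cca(cell_counts(s11 = 7, s10 = 0, s01 = 0,
                                        s00 = 5))$sn, 1)
})

test_that("CCA converges to its closed-form MAR limit", {
  cfg <- scenario_config(p = 0.4, sn = 0.6, sp = 0.6, N = 1000)
  cc <- expected_counts(cfg)
  e <- estimate_cca(cc, ci = "none")
  expect_equal(e$sn, cca_limit_sn(0.6, 0.8, 0.4), tolerance = 1e-12)
  expect_equal(e$sp, cca_limit_sp(0.6, 0.8, 0.4), tolerance = 1e-12)
  expect_equal(e$sn, 0.75, tolerance = 1e-12)
  expect_equal(e$sp, 3 / 7, tolerance = 1e-12)
})

test_that("BG reassembles Sn/Sp by Bayes' theorem", {
  # toy fixture: P(T=1) = .5, P(D=1|T=1,V=1) = .8, P(D=1|T=0,V=1) = .2
  cc <- cell_counts(s11 = 40, s10 = 10, s01 = 5, s00 = 20, u1 = 0, u0 = 25)
  e <- estimate_bg(cc, ci = "none")
  expect_equal(e$sn, 0.8)
  expect_equal(e$sp, 0.8)
  # full verification: identical to FDA
  full <- cell_counts(s11 = 40, s10 = 10, s01 = 10, s00 = 40)
  expect_equal(estimate_bg(full, ci = "none")$sn, estimate_fda(full)$sn)
  # expected counts under MAR invert exactly to the truth, any scenario
  set.seed(3)
  for (i in 1:10) {
    cfg <- scenario_config(runif(1, 0.1, 0.9), runif(1, 0.3, 0.95),
                           runif(1, 0.3, 0.95),
                           pv1 = runif(1, 0.5, 1), pv0 = runif(1, 0.2, 0.9),
                           N = 1000)
    e <- estimate_bg(expected_counts(cfg), ci = "none")
    expect_equal(e$sn, cfg$sn, tolerance = 1e-10)
    expect_equal(e$sp, cfg$sp, tolerance = 1e-10)
  }
  expect_error(estimate_bg(cell_counts(s01 = 3, s00 = 5, u1 = 4)),
               "both test strata")
})

test_that("BG point estimates reproduce the classic clinical analyses", {
  h <- estimate_bg(pvb_example("hepatic", counts_only = TRUE), ci = "none")
  expect_equal(round(h$sn, 3), 0.836)
  expect_equal(round(h$sp, 3), 0.738)
  d <- estimate_bg(pvb_example("diaphanography", counts_only = TRUE),
                   ci = "none")
  expect_equal(round(d$sn, 3), 0.292)
  expect_equal(round(d$sp, 3), 0.973)
  hc <- estimate_cca(pvb_example("hepatic", counts_only = TRUE))
  expect_equal(round(hc$sn, 3), 0.895)
  expect_equal(round(hc$sp, 3), 0.628)
  expect_equal(round(hc$sn_ci, 3), c(lo = 0.858, hi = 0.933))
  expect_equal(round(hc$sp_ci, 3), c(lo = 0.526, hi = 0.730))
})

test_that("IPWE weights verified cases by inverse propensity", {
  d <- toy_data()
  ps <- fit_propensity(d)
  e <- estimate_ipwe(d, ps = ps, ci = "none")
  expect_equal(e$sn, 40 / (40 + 5 / 0.5))  # 0.8
  expect_equal(e$sp, (20 / 0.5) / (10 + 20 / 0.5))  # 0.8
  # all PS = 1: unweighted, equals CCA
  e1 <- estimate_ipwe(d, ps = fit_propensity(d, known = c(1, 1)), ci = "none")
  cca <- estimate_cca(toy_counts())
  expect_equal(e1$sn, cca$sn)
  expect_equal(e1$sp, cca$sp)
})

test_that("IPWE with the saturated fit is algebraically Begg-Greenes", {
  set.seed(6)
  for (cc in random_counts(20)) {
    bg <- estimate_bg(cc, ci = "none")
    ipwe <- estimate_ipwe(cc, ci = "none")
    expect_equal(ipwe$sn, bg$sn, tolerance = 1e-12)
    expect_equal(ipwe$sp, bg$sp, tolerance = 1e-12)
  }
})

test_that("all six estimators coincide on fully verified data", {
  full <- cell_counts(s11 = 45, s10 = 12, s01 = 8, s00 = 35)
  truth <- estimate_fda(full, ci = "none")
  expect_equal(estimate_cca(full, ci = "none")$sn, truth$sn)
  expect_equal(estimate_bg(full, ci = "none")$sn, truth$sn)
  expect_equal(estimate_ipwe(full, ci = "none")$sn, truth$sn)
  expect_equal(estimate_cca(full, ci = "none")$sp, truth$sp)
  expect_equal(estimate_bg(full, ci = "none")$sp, truth$sp)
  expect_equal(estimate_ipwe(full, ci = "none")$sp, truth$sp)
  # MI with nothing to impute is exactly FDA, with a Wald-type interval
  set.seed(7)
  mi <- estimate_mi(full, m = 5)
  expect_equal(mi$sn, truth$sn)
  expect_equal(mi$sp, truth$sp)
  expect_equal(mi$extra$imputations$sn_j, rep(truth$sn, 5))
  # IPB has uniform weights here: a plain bootstrap of the complete cases
  set.seed(8)
  ipb <- estimate_ipb(full, b = 4000, point = "mean")
  expect_lt(abs(ipb$sn - truth$sn), 0.01)
  expect_lt(abs(ipb$sp - truth$sp), 0.01)
})

test_that("IPB under constant propensity reduces to the plain bootstrap", {
  cc <- toy_counts()
  ps_const <- fit_propensity(NULL, known = c(0.6, 0.6))
  set.seed(9)
  ipb <- estimate_ipb(cc, ps = ps_const, b = 20000, point = "mean")
  cca <- estimate_cca(cc, ci = "none")
  # bootstrap mean converges to the complete-case estimate
  expect_lt(abs(ipb$sn - cca$sn), 3 * ipb$sn_se / sqrt(20000) + 0.005)
  expect_lt(abs(ipb$sp - cca$sp), 3 * ipb$sp_se / sqrt(20000) + 0.005)
})

test_that("IPB resampling mass restores the debiased cell distribution", {
  # toy fixture: weighted mass splits 50/50 between test strata
  cc <- toy_counts()
  set.seed(10)
  ipb <- estimate_ipb(cc, b = 20000, point = "mean")
  reps <- ipb$extra$replicates
  expect_equal(reps$b_requested, 20000)
  expect_equal(length(reps$sn_reps) + reps$n_degenerate[["sn"]], 20000)
  expect_lt(abs(ipb$sn - 0.8), 0.01)
  # direct weighted-multinomial oracle: E[m11]/n equals the debiased mass
  q <- c(40, 10, 5 / 0.5, 20 / 0.5) / 100
  expect_equal(mean(stats::rmultinom(50000, 75, q)[1, ]) / 75, q[1],
               tolerance = 0.01)
})

test_that("count-level IPB resampler matches subject-level resampling", {
  cfg <- scenario_config(p = 0.4, sn = 0.6, sp = 0.6, N = 150)
  d <- simulate_pvb(cfg, seed = 20)
  ps <- fit_propensity(d)
  set.seed(21)
  subj <- pvboot:::ipb_resample_subjects(d, ps, b = 10000)
  set.seed(22)
  fast <- estimate_ipb(cell_counts(d), ps = ps, b = 10000,
                       point = "mean")$extra$replicates
  # two draws from the same resampling distribution: compare ECDFs
  ks <- suppressWarnings(stats::ks.test(subj$sn, fast$sn_reps))
  expect_lt(unname(ks$statistic), 0.03)
  ks2 <- suppressWarnings(stats::ks.test(subj$sp, fast$sp_reps))
  expect_lt(unname(ks2$statistic), 0.03)
})

test_that("degenerate IPB replicates are excluded and counted", {
  # tiny diseased mass: many resamples contain no diseased subject
  cc <- cell_counts(s11 = 1, s10 = 30, s01 = 1, s00 = 30, u1 = 8, u0 = 45)
  set.seed(23)
  expect_warning(ipb <- estimate_ipb(cc, b = 2000, point = "mean"),
                 "degenerate")
  reps <- ipb$extra$replicates
  expect_gt(reps$n_degenerate[["sn"]], 0)
  expect_equal(length(reps$sn_reps) + reps$n_degenerate[["sn"]], 2000)
  expect_true(all(reps$sn_reps >= 0 & reps$sn_reps <= 1))
})

test_that("imputation draws missing disease from the stratum posterior", {
  set.seed(24)
  imp <- impute_disease(toy_counts(), m = 400)
  expect_equal(imp$m, 400)
  expect_true(all(imp$sn_j >= 0 & imp$sn_j <= 1))
  # observed P(D=1|T=0,V=1) = 0.2: the pooled MI estimate should sit near
  # the MAR-consistent BG value, which uses that same stratum rate
  set.seed(25)
  mi <- estimate_mi(toy_counts(), m = 400)
  bg <- estimate_bg(toy_counts(), ci = "none")
  expect_lt(abs(mi$sn - bg$sn), 0.04)
  expect_lt(abs(mi$sp - bg$sp), 0.06)
})

test_that("bare proper imputation refuses separated tables", {
  cc <- cell_counts(s11 = 10, s10 = 40, s01 = 0, s00 = 30, u1 = 10, u0 = 40)
  expect_error(impute_disease(cc, m = 5, augment = FALSE),
               "perfect separation")
  # augmented fit handles the same table
  set.seed(26)
  imp <- impute_disease(cc, m = 5, augment = TRUE)
  expect_length(imp$sn_j, 5)
})

test_that("MI pooling follows Rubin's rules on the imputation set", {
  set.seed(27)
  imp <- impute_disease(toy_counts(), m = 30)
  mi <- estimate_mi(imp)
  pool <- rubin_pool(imp$sn_j, imp$sn_var)
  expect_equal(mi$sn, pool$est)
  expect_equal(mi$sn_se, pool$se)
  expect_equal(mi$sn_ci, pool$ci)
})

test_that("the one-call interface returns a tidy per-method table", {
  d <- toy_data()
  set.seed(28)
  suppressMessages(est <- estimate_accuracy(d, b = 300, m = 10))
  expect_s3_class(est, "accuracy_table")
  expect_setequal(est$method, c("cca", "bg", "ipwe", "mi", "ipb"))
  expect_true(all(est$sn >= 0 & est$sn <= 1))
  expect_true(all(est$sn_lo <= est$sn & est$sn <= est$sn_hi))
  expect_true(all(est$sp_lo <= est$sp & est$sp <= est$sp_hi))
  expect_error(estimate_accuracy(d, method = "fda"), "fully verified")
})
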