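# Shared fixtures, all built in code.

# Module-wide toy table: T=1 stratum fully verified (40 diseased, 10 not);
# T=0 stratum half verified (5 diseased, 20 not, 25 unverified).
toy_counts <- function() {
  cell_counts(s11 = 40, s10 = 10, s01 = 5, s00 = 20, u1 = 0, u0 = 25)
}

toy_data <- function() {
  expand_counts(toy_counts())
}

# Expected (non-integer) verified/unverified cell counts of a scenario:
# the large-sample table all MAR-consistent estimators should invert exactly.
expected_counts <- function(cfg) {
  pis <- cell_probabilities(cfg)
  N <- cfg$N
  cell_counts(s11 = N * pis[["pi1"]] * cfg$pv1,
              s10 = N * pis[["pi3"]] * cfg$pv1,
              s01 = N * pis[["pi2"]] * cfg$pv0,
              s00 = N * pis[["pi4"]] * cfg$pv0,
              u1 = N * (pis[["pi1"]] + pis[["pi3"]]) * (1 - cfg$pv1),
              u0 = N * (pis[["pi2"]] + pis[["pi4"]]) * (1 - cfg$pv0))
}

# Random strictly-positive count tables for algebraic identities.
random_counts <- function(k = 1) {
  lapply(seq_len(k), function(i) {
    cell_counts(s11 = sample(1:80, 1), s10 = sample(1:80, 1),
                s01 = sample(1:80, 1), s00 = sample(1:80, 1),
                u1 = sample(0:60, 1), u0 = sample(0:60, 1))
  })
}

# CCA large-sample limit of Sn under MAR verification (and Sp analogue).
cca_limit_sn <- function(sn, pv1, pv0) {
  sn * pv1 / (sn * pv1 + (1 - sn) * pv0)
}

cca_limit_sp <- function(sp, pv1, pv0) {
  sp * pv0 / (sp * pv0 + (1 - sp) * pv1)
}
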