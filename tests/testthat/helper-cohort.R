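# Shared helpers for the suite.

# A small, fast cohort configuration (sizes at the floor the generator
# accepts) for tests that only need the table layout.
quick_config <- function(n_building = 120, n_longitudinal = 120, ...) {
  cohort_config(n_building = n_building, n_longitudinal = n_longitudinal, ...)
}

# Brute-force Mann-Whitney AUC: all case-control pairs, half credit for
# ties. Deliberately O(m*n); the independent oracle for auc_mw().
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# Random admissible standardized loading vector: |lambda| in [lo, hi],
# random signs, first element forced positive (the canonical orientation).
random_loadings <- function(p = 4, lo = 0.3, hi = 0.95) {
  lam <- runif(p, lo, hi) * sample(c(-1, 1), p, replace = TRUE)
  if (lam[1] < 0) lam <- -lam
  names(lam) <- paste0("x", seq_len(p))
  lam
}

# A fixed complete risk-factor profile used as the perturbation base in
# monotonicity tests.
base_profile <- function(sex = "F") {
  data.frame(age = 55, sex = sex, tc = 210, hdl = 52, sbp = 130,
             treated_htn = FALSE, diabetes = FALSE, smoker = FALSE,
             stringsAsFactors = FALSE)
}
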