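#!/usr/bin/env Rscript
# Step 4 — analytic loading recovery on exact implied correlation
# matrices.
#
# With no individual-level cohort data deposited, the published
# standardized loading columns of the two covariate-free models are
# treated as inputs: each column implies an exact 4x4 correlation
# matrix (off-diagonal ij = lambda_i * lambda_j), and fitting the
# one-factor ML CFA to that matrix must return the column itself.
# Writes results/analytic_recovery.csv.

library(kidneylatent)

columns <- list(
  model_1 = c(scr = 0.757, cys = 0.597, ua = 0.597, bun = 0.638),
  model_2 = c(egfr_ckdepi_cre_2021 = 0.889, egfr_ckdepi_cys_2012 = 0.856,
              ua = -0.393, bun = -0.561)
)

rows <- list()
for (nm in names(columns)) {
  lam <- columns[[nm]]
  fit <- fit_ml(implied_covariance(lam), n = 100000)
  rows[[nm]] <- data.frame(model = nm, indicator = names(lam),
                           input_loading = unname(lam),
                           recovered = unname(fit$std_loadings),
                           abs_error = abs(unname(fit$std_loadings - lam)),
                           fml = fit$fml)
}
out <- do.call(rbind, rows)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/analytic_recovery.csv", row.names = FALSE)
print(out, row.names = FALSE, digits = 6)
cat(sprintf("\nmax |recovered - input| = %.2e (zero-discrepancy fixed point)\n",
            max(out$abs_error)))
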