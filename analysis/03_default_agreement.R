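#!/usr/bin/env Rscript
# Step 3 — quantify between-system agreement at default thresholds.
#
# Cross-tabulates the two default classifications into the four quadrants
# (both CFAE / NavX-only / CARTO-only / neither), computes Cohen's kappa,
# Spearman's rho between CFE-Mean and ICL, the Yates chi-square for the
# difference in detection proportions, and Mann-Whitney comparisons of each
# index between concordant-CFAE and the rest.

library(cfaer)

ind <- read.csv("results/indices.csv")
q <- quadrant_table(ind$navx_cfae, ind$carto_cfae, ids = ind$id,
                    ids_b = ind$id)
print(q)

rho <- spearman_rho(ind$cfe_mean_score, ind$icl)
chi <- yates_chi_square(matrix(c(sum(ind$navx_cfae), sum(!ind$navx_cfae),
                                 sum(ind$carto_cfae), sum(!ind$carto_cfae)),
                               2, byrow = TRUE))
cat(sprintf("Spearman rho(CFE-Mean, ICL) = %.3f\n", rho))
cat(sprintf("Yates chi-square for %0.f%% vs %0.f%% detection: X2 = %.1f, p = %.3g\n",
            100 * q$proportion_a, 100 * q$proportion_b,
            chi$statistic, chi$p_value))

both <- ind$navx_cfae & ind$carto_cfae
for (col in c("cfe_mean_score", "icl", "cfe_sd_score", "aci_score",
              "sci_score")) {
  mw <- mann_whitney_u(ind[[col]][both], ind[[col]][!both])
  cat(sprintf("Mann-Whitney %-15s concordant-CFAE vs rest: U = %8.0f, p = %.3g\n",
              col, mw$U, mw$p_value))
}

out <- data.frame(
  n_both_cfae = q$n_both_cfae, n_navx_only = q$n_a_only,
  n_carto_only = q$n_b_only, n_neither = q$n_neither, total = q$total,
  pct_navx = 100 * q$proportion_a, pct_carto = 100 * q$proportion_b,
  kappa = q$kappa, kappa_band = cohen_kappa(q)$band, spearman_rho = rho,
  chi_square = chi$statistic, chi_p = chi$p_value)
write.csv(out, "results/default_agreement.csv", row.names = FALSE)
cat("summary -> results/default_agreement.csv\n")
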