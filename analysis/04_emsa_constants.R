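#!/usr/bin/env Rscript
# Oligomeric DNA-binding constants from excess-zinc EMSA band fractions.
#
# Generates a synthetic protein-titration band-fraction table emulating
# the excess-zinc gels (zinc-saturated Zur titrated against 65 nM zitB
# probe), then estimates the binding constants with both species models
# and compares them with the partially zinc-loaded affinity measured
# calorimetrically.

suppressPackageStartupMessages(library(zurlink))
seed <- 404
dir.create("results", showWarnings = FALSE)

truth <- oligomer_constants("per_site", K_site = 2e9)   # Kd 0.5 nM
d <- generate_emsa_dataset(truth, seed = seed)
write_band_table_csv(d$table, "results/emsa_band_fractions.csv")

fit_ps <- fit_band_constants(d$table, "per_site")
cat("per-site model:\n")
print(fit_ps)

# stepwise fit of the same gel (the three observed bands only)
tab3 <- d$table[c("p_total_M", "f_free", "f_2to1", "f_3to1")]
fr <- as.matrix(tab3[-1])
tab3[-1] <- fr / rowSums(fr)
attr(tab3, "D_total") <- attr(d$table, "D_total")
class(tab3) <- c("band_fraction_table", "data.frame")
fit_sw <- fit_band_constants(tab3, "stepwise")
cat("\nstepwise model (free / 2:1 / 3:1 bands):\n")
print(fit_sw)

est <- data.frame(
  model = c("per_site", "stepwise_2to1", "stepwise_3to1"),
  Kd_M = c(fit_ps$constants$Kd_site, fit_sw$constants$Kd2,
           fit_sw$constants$Kd3))
write.csv(est, "results/emsa_constants.csv", row.names = FALSE)

itc_Kd <- 1 / 1.8e6
cat(sprintf("\nfitted dissociation constants: %s M\n",
            paste(signif(est$Kd_M, 3), collapse = ", ")))
cat(sprintf("partially zinc-loaded ITC Kd: %.2g M -> the zinc-saturated\n",
            itc_Kd))
cat(sprintf("affinity is %d-fold tighter (low-to-sub-nanomolar), in line\n",
            round(itc_Kd / fit_ps$constants$Kd_site)))
cat("with the ~1000-fold K6/K4 enhancement inferred from the linkage\n")
cat("model.\n")
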