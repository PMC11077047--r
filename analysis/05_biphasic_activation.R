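#!/usr/bin/env Rscript
# Two-tier simulation of the biphasic zinc activation of zitB.
#
# Clamps free zinc over eight log-decades (buffered cellular zinc) and
# solves the joint equilibrium of a 4 uM Zur pool with the three-site
# zurbox and three low-affinity upstream sites, tracking occupancies,
# the zinc-saturated Zur fraction and an expression proxy.

suppressPackageStartupMessages(library(zurlink))
dir.create("results", showWarnings = FALSE)

pm <- promoter_model()
grid <- 10^seq(-16, -8, length.out = 241)
prof <- simulate_activation_profile(pm, grid)
write_population_csv(prof, "results/activation_profile.csv")

pb <- phase_boundaries(prof)
cat(sprintf("zurbox half-saturation:   %.3g M free zinc\n", pb$zurbox_mid))
cat(sprintf("upstream half-saturation: %.3g M free zinc\n",
            pb$upstream_mid))
cat(sprintf("separation: %.0f-fold in free zinc\n", pb$ratio))

i <- findInterval(pb$zurbox_mid, prof$free_zinc_M)
cat(sprintf("zinc-saturated Zur fraction at the zurbox midpoint: %.2g\n",
            prof$frac_PL6[i]))
cat("-> phase 1: the zurbox fills while the bulk Zur pool is still\n")
cat("   almost entirely zinc-free; coupling pulls the zurbox-bound\n")
cat("   dimers into the high-occupancy state.\n")

# plateau between the phases and the phase-2 amplification
lz <- log10(grid)
dE <- diff(prof$expression_proxy) / diff(lz)
i1 <- findInterval(pb$zurbox_mid, grid)
i2 <- findInterval(pb$upstream_mid, grid)
iplat <- i1 + which.min(dE[i1:i2])
E1 <- prof$expression_proxy[iplat]
E2 <- max(prof$expression_proxy)
cat(sprintf("\nexpression proxy: basal %.2f, phase-1 plateau %.2f, full %.2f\n",
            prof$expression_proxy[1], E1, E2))
cat(sprintf("phase-2 / phase-1 ratio: %.1f (the in-vivo profile rises\n",
            E2 / E1))
cat("6- to 7-fold between the two phases)\n")

peaks <- which(diff(sign(diff(dE))) == -2) + 1
peaks <- peaks[dE[peaks] > 0.05 * max(dE)]
cat(sprintf("dE/dlog[Zn] maxima at %s M free zinc: a genuinely biphasic\n",
            paste(signif(grid[peaks + 1], 2), collapse = " and ")))
cat("response with the upstream rise only after the Zur pool saturates.\n")
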