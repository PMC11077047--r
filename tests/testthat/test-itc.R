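# the published zinc-into-apo-dimer condition used throughout these tests:
# 2.0 mM ZnCl2, 19 x 2 uL injections, 24 uM dimer, 3.0 mM EGTA
fig1a_protocol <- function(chelator = 3e-3)
  titration_protocol(syringe_conc = 2e-3, cell_conc = 24e-6,
                     chelator_conc = chelator)

dna_protocol <- function()
  titration_protocol(syringe_conc = 150e-6, cell_conc = 3e-6)

test_that("zero-enthalpy systems give exactly zero heats", {
  iso <- simulate_isotherm(single_class_system(n = 6, K = 8.6e5, dH = 0),
                           fig1a_protocol(chelator = 0))
  expect_true(all(iso$ndh_kcal_per_mol == 0))
})

test_that("single-class simulator matches the closed-form isotherm and its limits", {
  prot <- fig1a_protocol(chelator = 0)
  for (K in c(1e4, 8.6e5, 1e9)) {
    iso <- simulate_isotherm(single_class_system(n = 6, K = K, dH = -6.7),
                             prot)
    orc <- oracle_single_class_isotherm(6, K, -6.7, prot)
    expect_lt(max(abs(iso$ndh_kcal_per_mol - orc$ndh_kcal_per_mol)), 1e-9)
    expect_equal(iso$molar_ratio, orc$molar_ratio, tolerance = 1e-12)
  }
  # high c: a step isotherm, ~dH before the stoichiometric point, ~0 after
  c_val <- 6 * 1e9 * 24e-6
  expect_gt(c_val, 1e3)
  iso <- simulate_isotherm(single_class_system(n = 6, K = 1e9, dH = -6.7),
                           prot)
  expect_true(all(abs(iso$ndh_kcal_per_mol[iso$molar_ratio < 5.5] -
                        (-6.7)) < 0.01))
  # post-saturation heats are near zero (dilution-driven re-equilibration
  # leaves a small residual of the displacement bookkeeping)
  expect_true(all(abs(iso$ndh_kcal_per_mol[iso$molar_ratio > 6.5]) < 0.05))
})

test_that("heats have uniform sign until saturation and integrate to n M V0 dH", {
  prot <- fig1a_protocol(chelator = 0)
  sys <- single_class_system(n = 6, K = 8.6e5, dH = -6.7)
  iso <- simulate_isotherm(sys, prot)
  expect_true(all(iso$ndh_kcal_per_mol < 0))
  # a titration driven well past saturation recovers the full site
  # capacity n * M0 * V0 * dH. A concentrated titrant keeps the volume
  # injected before saturation (and hence the displacement loss of
  # still-unbound sites) negligible.
  prot_long <- titration_protocol(syringe_conc = 20e-3, cell_conc = 24e-6,
                                  injection_volumes = rep(1e-6, 20))
  isol <- simulate_isotherm(single_class_system(n = 6, K = 1e7, dH = -6.7),
                            prot_long)
  Qtot <- sum(isol$ndh_kcal_per_mol * isol$inj_volume_L * 20e-3)
  expect_lt(abs(Qtot / (6 * 24e-6 * 200e-6 * -6.7) - 1), 0.01)
})

test_that("competitive simulation under EGTA has its inflection near 6 zinc per dimer", {
  sys <- competitive_system(n = 6, K_int = 2.3e13, dH_int = -11,
                            K_chel = conditional_chelator_constant(),
                            dH_chel = -4.3)
  iso <- simulate_isotherm(sys, fig1a_protocol())
  # steepest heat change between consecutive injections locates the
  # inflection of the sigmoid
  drop <- diff(iso$ndh_kcal_per_mol)
  infl <- iso$molar_ratio[which.max(drop)]
  expect_gt(infl, 5)
  expect_lt(infl, 7)
})

test_that("single-class refit of the exact competitive curve recovers the apparent affinity", {
  K_chel <- conditional_chelator_constant()
  sys <- competitive_system(n = 6, K_int = 2.3e13, dH_int = -11,
                            K_chel = K_chel, dH_chel = -4.3)
  iso <- simulate_isotherm(sys, fig1a_protocol())
  fit <- fit_isotherm(iso, fig1a_protocol(), "single_class",
                      single_class_system(n = 5, K = 5e5, dH = -5))
  expect_true(fit$converged)
  # printed: 8.6 (+/- 1.9) x 10^5 M^-1 per site, stoichiometry 6 per dimer
  expect_gt(fit$parameters[["K"]], 8.6e5 - 1.9e5)
  expect_lt(fit$parameters[["K"]], 8.6e5 + 1.9e5)
  expect_equal(fit$parameters[["n"]], 6, tolerance = 0.05)
})

test_that("noise-free fits round-trip the generating parameters for every variant", {
  protc <- fig1a_protocol()
  protd <- dna_protocol()
  K_chel <- conditional_chelator_constant()

  # single_class
  truth <- single_class_system(n = 3, K = 1.8e6, dH = -5)
  fit <- fit_isotherm(simulate_isotherm(truth, protd), protd,
                      "single_class",
                      single_class_system(n = 2, K = 5e5, dH = -3))
  expect_equal(fit$parameters[["n"]], 3, tolerance = 1e-4)
  expect_equal(fit$parameters[["K"]], 1.8e6, tolerance = 1e-4)
  expect_equal(fit$parameters[["dH"]], -5, tolerance = 1e-4)

  # competitive
  truthc <- competitive_system(n = 6, K_int = 2.3e13, dH_int = -11,
                               K_chel = K_chel, dH_chel = -4.3)
  fitc <- fit_isotherm(simulate_isotherm(truthc, protc), protc,
                       "competitive",
                       competitive_system(n = 5, K_int = 1e13,
                                          dH_int = -9, K_chel = K_chel,
                                          dH_chel = -4.3))
  expect_equal(fitc$parameters[["n"]], 6, tolerance = 1e-4)
  expect_equal(fitc$parameters[["K"]], 2.3e13, tolerance = 1e-4)
  expect_equal(fitc$parameters[["dH"]], -11, tolerance = 1e-4)

  # three_site
  trutht <- three_site_system(K_classes = c(4e5, 8.6e5, 2e6),
                              dH_classes = c(-6, -7, -8))
  fitt <- fit_isotherm(simulate_isotherm(trutht, fig1a_protocol(0)),
                       fig1a_protocol(0), "three_site",
                       three_site_system(K_classes = c(3e5, 1e6, 3e6),
                                         dH_classes = c(-5, -6, -9)))
  expect_equal(as.numeric(fitt$parameters[c("K1", "K2", "K3")]),
               c(4e5, 8.6e5, 2e6), tolerance = 1e-4)

  # dna_oligomer (K_4 and dH free; ladder ratio fixed)
  lp <- linkage_params(K_Zn = 2.3e13, K_4 = 1.8e6, K_6 = 4000 * 1.8e6,
                       n_dna_sites = 3)
  truthd <- dna_oligomer_system(lp, zinc_equivalents = 4, dH = -8)
  lps <- linkage_params(K_Zn = 2.3e13, K_4 = 5e5, K_6 = 4000 * 5e5,
                        n_dna_sites = 3)
  fitd <- fit_isotherm(simulate_isotherm(truthd, protd), protd,
                       "dna_oligomer",
                       dna_oligomer_system(lps, 4, -6))
  expect_equal(fitd$parameters[["K4"]], 1.8e6, tolerance = 1e-4)
  expect_equal(fitd$parameters[["dH"]], -8, tolerance = 1e-4)
})

test_that("degenerate all-zero heats are reported as unidentifiable", {
  prot <- dna_protocol()
  iso <- simulate_isotherm(single_class_system(n = 2, K = 1e6, dH = 0),
                           prot)
  expect_error(fit_isotherm(iso, prot, "single_class",
                            single_class_system(n = 2, K = 1e6, dH = -5)),
               "unidentifiable")
})

test_that("single-class fits of the linkage forward curve recover the binding stoichiometry", {
  protd <- dna_protocol()
  # under excess zinc the zitB probe takes three dimers, znuA two
  zitb <- linkage_params(K_Zn = 2.3e13, K_4 = 1.8e6, K_6 = 4000 * 1.8e6,
                         n_dna_sites = 3)
  fit3 <- fit_isotherm(
    simulate_isotherm(dna_oligomer_system(zitb, 6.5, -8), protd), protd,
    "single_class", single_class_system(n = 2.5, K = 1e7, dH = -6))
  expect_equal(fit3$parameters[["n"]], 3, tolerance = 0.05)
  znua <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 700 * 8.7e5,
                         n_dna_sites = 2)
  fit2 <- fit_isotherm(
    simulate_isotherm(dna_oligomer_system(znua, 6.5, -8), protd), protd,
    "single_class", single_class_system(n = 2.5, K = 1e7, dH = -6))
  expect_equal(fit2$parameters[["n"]], 2, tolerance = 0.05)
  # at 4.0 equivalents (the measurement condition) the flat active ladder
  # the single-class analysis assumes still yields ~n_s within ~15%
  zitb_flat <- linkage_params(K_Zn = 2.3e13, K_4 = 1.8e6, K_6 = 1.8e6,
                              n_dna_sites = 3)
  fitf <- fit_isotherm(
    simulate_isotherm(dna_oligomer_system(zitb_flat, 4, -8), protd),
    protd, "single_class", single_class_system(n = 2.5, K = 1e6, dH = -6))
  expect_equal(fitf$parameters[["n"]], 3, tolerance = 0.15)
})

test_that("chelator correction is exact in closed form and inverts the competition", {
  K_chel <- conditional_chelator_constant()
  # conditional constant from absolute log K 12.6 and pKa 9.40 / 8.79
  expect_equal(log10(K_chel), 9.97, tolerance = 0.005)

  # printed apparent affinity corrects into the printed intrinsic window
  cc <- chelator_correction(8.6e5, 3e-3, K_chel)
  expect_gt(cc$K, 2.3e13 - 0.5e13)
  expect_lt(cc$K, 2.3e13 + 0.5e13)

  # zero chelator is the identity; to_apparent is the exact inverse
  expect_equal(chelator_correction(8.6e5, 0, K_chel)$K, 8.6e5)
  back <- chelator_correction(cc$K, 3e-3, K_chel,
                              direction = "to_apparent")
  expect_equal(back$K, 8.6e5, tolerance = 1e-12)

  # enthalpy bookkeeping: dH_int = dH_app + dH_chel
  cc2 <- chelator_correction(8.6e5, 3e-3, K_chel, dH = -6.7,
                             dH_chel = -4.3)
  expect_equal(cc2$dH, -11)
})

test_that("closed-form correction agrees with simulation+refit at chelator excess", {
  K_chel <- conditional_chelator_constant()
  K_int <- 2.3e13
  for (chel in c(3e-3, 10e-3)) {
    # chelator >= 20x total protein sites (144 uM)
    expect_gte(chel / (6 * 24e-6), 20)
    sys <- competitive_system(n = 6, K_int = K_int, dH_int = -11,
                              K_chel = K_chel, dH_chel = -4.3)
    # concentrated titrant: keeps chelator dilution over the run small,
    # so the closed form (which uses the loaded chelator concentration)
    # is comparable with the refit
    prot <- titration_protocol(syringe_conc = 8e-3, cell_conc = 24e-6,
                               injection_volumes = rep(0.5e-6, 19),
                               chelator_conc = chel)
    fit <- fit_isotherm(simulate_isotherm(sys, prot), prot,
                        "single_class",
                        single_class_system(n = 6,
                                            K = K_int / (1 + K_chel * chel),
                                            dH = -6.7))
    K_back <- chelator_correction(fit$parameters[["K"]], chel, K_chel)$K
    expect_lt(abs(K_back / K_int - 1), 0.05)
  }
})

test_that("20-fold site heterogeneity is tolerated by the monophasic curve, 1000-fold is not", {
  mb <- monophasicity_bound(fig1a_protocol(0), base_K = 8.6e5, dH = -6.7,
                            fold_spreads = c(1, 20, 1000))
  cls <- setNames(mb$table$classification, mb$table$fold_spread)
  expect_identical(cls[["1"]], "indistinguishable")
  expect_identical(cls[["20"]], "indistinguishable")
  expect_identical(cls[["1000"]], "detectable")
  expect_equal(mb$max_tolerated, 20)
  expect_error(monophasicity_bound(fig1a_protocol(0), 8.6e5, -6.7,
                                   noise_sigma = 0))
})

test_that("K is recovered within a factor of 2 under 2 percent noise across c values", {
  # seeded simulation study spanning shallow to sharp isotherms
  set.seed(2024)
  prot <- titration_protocol(syringe_conc = 2e-3, cell_conc = 24e-6)
  M_sites <- 6 * 24e-6
  n_rep <- 200
  ok <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    c_val <- 10^runif(1, 0, 3)
    K <- c_val / M_sites
    truth <- single_class_system(n = 6, K = K, dH = -6.7)
    iso <- simulate_isotherm(truth, prot)
    iso$ndh_kcal_per_mol <- iso$ndh_kcal_per_mol +
      rnorm(nrow(iso), sd = 0.02 * 6.7)
    fit <- tryCatch(
      fit_isotherm(iso, prot, "single_class",
                   single_class_system(n = 6, K = K * 2, dH = -5)),
      error = function(e) NULL)
    ok[r] <- !is.null(fit) &&
      fit$parameters[["K"]] / K < 2 && fit$parameters[["K"]] / K > 0.5
  }
  expect_gte(mean(ok), 0.95)
})
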