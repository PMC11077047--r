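#' Named presets encoding the study's titration conditions
#'
#' Each preset bundles a ground-truth binding system, the matching
#' titration protocol, and a noise level, so that every pipeline stage can
#' be exercised on data with known parameters. The zinc-into-Zur presets
#' reproduce the published experimental conditions: 2.0 mM ZnCl2 titrated
#' in 19 x 2 uL injections into dimeric apo-protein in 3.0 mM EGTA; the
#' protein concentration and the zinc stoichiometry per dimer are those
#' reported for each variant (wild type 24 uM / 6.0 equivalents; H36A
#' 40 uM / 4.0; the M-site double mutant 65 uM / 2.6; the D-site double
#' mutant 53 uM / 4.0). The Zur-into-DNA presets titrate 150 uM dimer
#' (4.0 zinc equivalents) into 3 uM DNA, with the published single-class
#' constants (znuA 2:1, K = 8.7e5; zitB 3:1, K = 1.8e6; H36A variants
#' 3.3e5 and 2.6e5 M^-1).
#'
#' Intrinsic zinc enthalpies are not printed in the source experiments;
#' the presets use dH_int = -11 kcal/mol with a chelator displacement
#' enthalpy of -4.3 kcal/mol (a literature-typical zinc-EGTA value), and
#' -8 kcal/mol for the DNA-binding enthalpies. These defaults shape the
#' curves realistically but carry no analysis weight.
#'
#' @param name one of \code{"wt_zn_egta"}, \code{"h36a_zn_egta"},
#'   \code{"msite_zn_egta"}, \code{"dsite_zn_egta"}, \code{"wt_znua_dna"},
#'   \code{"wt_zitb_dna"}, \code{"h36a_znua_dna"}, \code{"h36a_zitb_dna"}.
#' @return A list of class \code{"itc_preset"}: \code{name},
#'   \code{system}, \code{protocol}, \code{sigma_ndh} (kcal/mol).
#' @export
itc_preset <- function(name) {
  K_chel <- conditional_chelator_constant()
  zn <- function(n, cell, K_int = 2.3e13)
    list(system = competitive_system(n = n, K_int = K_int, dH_int = -11,
                                     K_chel = K_chel, dH_chel = -4.3),
         protocol = titration_protocol(syringe_conc = 2e-3,
                                       cell_conc = cell,
                                       chelator_conc = 3e-3))
  dna <- function(n, K)
    list(system = single_class_system(n = n, K = K, dH = -8),
         protocol = titration_protocol(syringe_conc = 150e-6,
                                       cell_conc = 3e-6))
  p <- switch(name,
    wt_zn_egta    = zn(6.0, 24e-6),
    h36a_zn_egta  = zn(4.0, 40e-6),
    msite_zn_egta = zn(2.6, 65e-6, K_int = 3 * 2.3e13),
    dsite_zn_egta = zn(4.0, 53e-6),
    wt_znua_dna   = dna(2, 8.7e5),
    wt_zitb_dna   = dna(3, 1.8e6),
    h36a_znua_dna = dna(2, 3.3e5),
    h36a_zitb_dna = dna(3, 2.6e5),
    stop("unknown preset: ", name))
  # default noise: 2% of the apparent per-injection amplitude
  dH_app <- if (p$system$variant == "competitive")
    p$system$dH_int - p$system$dH_chel else p$system$dH
  structure(c(list(name = name), p, list(sigma_ndh = 0.02 * abs(dH_app))),
            class = "itc_preset")
}

#' Generate a noisy synthetic ITC isotherm with known ground truth
#'
#' Simulates the preset's isotherm and adds i.i.d. Gaussian noise to the
#' normalized heats. Fully deterministic for a given (preset, seed) pair;
#' the caller's RNG state is left untouched.
#'
#' @param preset a preset name (see \code{\link{itc_preset}}) or an
#'   \code{itc_preset} object.
#' @param seed integer seed.
#' @param sigma_ndh noise s.d. on normalized heats (kcal/mol); defaults to
#'   the preset's value; 0 gives the deterministic curve.
#' @return A list of class \code{"synthetic_itc"}: \code{isotherm} (noisy),
#'   \code{truth} (the generating \code{binding_system}),
#'   \code{protocol}, \code{sigma_ndh}, \code{seed}.
#' @examples
#' d <- generate_itc_dataset("wt_zn_egta", seed = 1)
#' head(d$isotherm)
#' @export
generate_itc_dataset <- function(preset, seed, sigma_ndh = NULL) {
  if (is.character(preset)) preset <- itc_preset(preset)
  stopifnot(inherits(preset, "itc_preset"))
  if (is.null(sigma_ndh)) sigma_ndh <- preset$sigma_ndh
  iso <- simulate_isotherm(preset$system, preset$protocol)
  if (sigma_ndh > 0) {
    noise <- withr::with_seed(seed,
                              stats::rnorm(nrow(iso), sd = sigma_ndh))
    iso$ndh_kcal_per_mol <- iso$ndh_kcal_per_mol + noise
  }
  structure(list(isotherm = iso, truth = preset$system,
                 protocol = preset$protocol, sigma_ndh = sigma_ndh,
                 seed = seed, preset = preset$name),
            class = "synthetic_itc")
}

#' Generate a noisy synthetic EMSA band-fraction table
#'
#' Predicts band fractions from \code{\link{predict_band_fractions}},
#' applies multiplicative Gaussian noise, clips to [0, 1] and renormalizes
#' each row to sum to 1 (fractions quantified from band intensities are
#' compositional).
#'
#' @param constants ground-truth \code{\link{oligomer_constants}}.
#' @param design list with \code{P_grid} (total dimer concentrations, M)
#'   and \code{D_total} (M). Default: five levels from 10 nM to 1 uM
#'   around a low-nanomolar transition, 65 nM DNA (the gel conditions).
#' @param seed integer seed.
#' @param sigma_fraction relative noise on fractions; default 0.05.
#' @return A list of class \code{"synthetic_emsa"}: \code{table} (noisy
#'   \code{band_fraction_table}), \code{truth}, \code{design},
#'   \code{sigma_fraction}, \code{seed}.
#' @export
generate_emsa_dataset <- function(constants,
                                  design = list(
                                    P_grid = c(10, 30, 100, 300, 1000) *
                                      1e-9,
                                    D_total = 65e-9),
                                  seed, sigma_fraction = 0.05) {
  tab <- predict_band_fractions(constants, design$P_grid, design$D_total)
  fcols <- setdiff(names(tab), "p_total_M")
  if (sigma_fraction > 0) {
    fr <- as.matrix(tab[fcols])
    noise <- withr::with_seed(seed,
      matrix(stats::rnorm(length(fr), mean = 1, sd = sigma_fraction),
             nrow = nrow(fr)))
    fr <- pmin(pmax(fr * noise, 0), 1)
    fr <- fr / rowSums(fr)
    tab[fcols] <- fr
  }
  structure(list(table = tab, truth = constants, design = design,
                 sigma_fraction = sigma_fraction, seed = seed),
            class = "synthetic_emsa")
}
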