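#' Titration protocol for an ITC experiment
#'
#' Describes the injection schedule and cell contents of a displacement-cell
#' isothermal titration calorimetry run. All concentrations are molar and
#' volumes are litres.
#'
#' @param syringe_conc titrant concentration in the syringe (M).
#' @param cell_conc macromolecule concentration in the cell (M of dimer for
#'   zinc-into-Zur runs, M of DNA for Zur-into-DNA runs).
#' @param injection_volumes ordered vector of injection volumes (L);
#'   default 19 injections of 2 uL.
#' @param V0 active cell volume (L); default 200 uL, nominal for the
#'   instrument class used for these experiments.
#' @param chelator_conc competing chelator (EGTA) concentration in the cell
#'   (M); 0 for chelator-free runs.
#' @param temperature cell temperature (degrees C); recorded only.
#' @param discard_first drop the first injection from fitting (common
#'   practice for a diffusion-compromised first peak); default FALSE, since
#'   all 19 injections are analyzed here.
#' @return An object of class \code{"titration_protocol"}.
#' @export
titration_protocol <- function(syringe_conc, cell_conc,
                               injection_volumes = rep(2e-6, 19),
                               V0 = 200e-6, chelator_conc = 0,
                               temperature = 25, discard_first = FALSE) {
  stopifnot(V0 > 0, length(injection_volumes) >= 1,
            all(injection_volumes > 0),
            syringe_conc >= 0, cell_conc >= 0, chelator_conc >= 0)
  structure(list(syringe_conc = syringe_conc, cell_conc = cell_conc,
                 injection_volumes = injection_volumes, V0 = V0,
                 chelator_conc = chelator_conc, temperature = temperature,
                 discard_first = isTRUE(discard_first)),
            class = "titration_protocol")
}

#' Binding-system constructors for ITC simulation and fitting
#'
#' Four equilibrium models are supported:
#' \describe{
#'   \item{single_class}{n identical independent sites per macromolecule
#'     with per-site association constant K and enthalpy dH (kcal per mole
#'     of ligand bound) — the standard one-set-of-sites analysis.}
#'   \item{three_site}{three classes of two sites each (the dimer carries
#'     three pairs of regulatory sites), per-class constants and
#'     enthalpies; used for heterogeneity-tolerance analysis.}
#'   \item{competitive}{n protein sites with intrinsic constant K_int
#'     competing with a chelator (conditional constant K_chel) for the
#'     titrated metal; the exact displacement model behind the
#'     apparent-to-intrinsic correction.}
#'   \item{dna_oligomer}{the linkage model: dimeric Zur carrying a fixed
#'     zinc load titrated into DNA bearing independent dimer-sites.}
#' }
#'
#' @param n sites per macromolecule (per dimer for zinc binding).
#' @param K,K_int per-site association constant (M^-1).
#' @param dH,dH_int binding enthalpy, kcal per mole of ligand (negative =
#'   exothermic).
#' @param K_classes,dH_classes length-3 per-class constants / enthalpies.
#' @param K_chel,dH_chel conditional chelator-metal constant (M^-1) and
#'   enthalpy (kcal/mol).
#' @param params a \code{\link{linkage_params}} object (dna_oligomer).
#' @param zinc_equivalents zinc equivalents per dimer co-titrated with the
#'   protein (dna_oligomer).
#' @return A list of class \code{"binding_system"} with a \code{variant}
#'   element.
#' @name binding_system
NULL

#' @rdname binding_system
#' @export
single_class_system <- function(n, K, dH) {
  stopifnot(n > 0, K > 0)
  structure(list(variant = "single_class", n = n, K = K, dH = dH),
            class = "binding_system")
}

#' @rdname binding_system
#' @export
three_site_system <- function(K_classes, dH_classes) {
  stopifnot(length(K_classes) == 3, all(K_classes > 0),
            length(dH_classes) == 3)
  structure(list(variant = "three_site", K_classes = K_classes,
                 dH_classes = dH_classes), class = "binding_system")
}

#' @rdname binding_system
#' @export
competitive_system <- function(n, K_int, dH_int, K_chel, dH_chel = 0) {
  stopifnot(n > 0, K_int > 0, K_chel >= 0)
  structure(list(variant = "competitive", n = n, K_int = K_int,
                 dH_int = dH_int, K_chel = K_chel, dH_chel = dH_chel),
            class = "binding_system")
}

#' @rdname binding_system
#' @export
dna_oligomer_system <- function(params, zinc_equivalents, dH) {
  stopifnot(inherits(params, "linkage_params"), zinc_equivalents >= 0)
  structure(list(variant = "dna_oligomer", params = params,
                 zinc_equivalents = zinc_equivalents, dH = dH),
            class = "binding_system")
}

# Per-injection totals under the displacement-cell dilution convention:
# each injection of volume dV dilutes everything already in the cell by
# (1 - dV/(2 V0))/(1 + dV/(2 V0)) and delivers titrant
# X_s * (dV/V0)/(1 + dV/(2 V0)). Applied recursively injection by
# injection.
.injection_totals <- function(protocol) {
  V0 <- protocol$V0
  nin <- length(protocol$injection_volumes)
  M <- numeric(nin); X <- numeric(nin); C <- numeric(nin)
  m <- protocol$cell_conc; x <- 0; ch <- protocol$chelator_conc
  for (j in seq_len(nin)) {
    d <- protocol$injection_volumes[j] / V0
    phi <- (1 - d / 2) / (1 + d / 2)
    m <- m * phi; x <- x * phi; ch <- ch * phi
    x <- x + protocol$syringe_conc * d / (1 + d / 2)
    M[j] <- m; X[j] <- x; C[j] <- ch
  }
  list(M = M, X = X, chel = C)
}

# Bound ligand for n identical independent sites (total sites St, total
# ligand Xt, per-site K): the standard quadratic, written in a stable form.
.bound_single <- function(St, Xt, K) {
  if (K <= 0 || St <= 0 || Xt <= 0) return(0 * Xt)
  b <- St + Xt + 1 / K
  2 * St * Xt / (b + sqrt(b * b - 4 * St * Xt))
}

# Free ligand for a sum of independent site classes: solve
# Xt = F + sum_c S_c K_c F / (1 + K_c F), monotone in F.
.free_ligand_multi <- function(Xt, S, K) {
  if (Xt <= 0) return(0)
  f <- function(FF) FF + sum(S * K * FF / (1 + K * FF)) - Xt
  stats::uniroot(f, c(0, Xt), tol = 1e-18 * max(Xt, 1e-12),
                 maxiter = 2000L)$root
}

# Cumulative heat content of the cell (kcal) for each injection's totals.
.cell_heat <- function(system, protocol, tot) {
  V0 <- protocol$V0
  switch(system$variant,
    single_class = {
      B <- mapply(.bound_single, system$n * tot$M, tot$X,
                  MoreArgs = list(K = system$K))
      V0 * system$dH * B
    },
    three_site = {
      Q <- numeric(length(tot$X))
      for (j in seq_along(tot$X)) {
        S <- 2 * tot$M[j] * c(1, 1, 1)
        FF <- .free_ligand_multi(tot$X[j], S, system$K_classes)
        Bc <- S * system$K_classes * FF / (1 + system$K_classes * FF)
        Q[j] <- V0 * sum(system$dH_classes * Bc)
      }
      Q
    },
    competitive = {
      Q <- numeric(length(tot$X))
      for (j in seq_along(tot$X)) {
        S <- c(system$n * tot$M[j], tot$chel[j])
        K <- c(system$K_int, system$K_chel)
        FF <- .free_ligand_multi(tot$X[j], S, K)
        Bc <- S * K * FF / (1 + K * FF)
        Q[j] <- V0 * (system$dH_int * Bc[1] + system$dH_chel * Bc[2])
      }
      Q
    },
    dna_oligomer = {
      Q <- numeric(length(tot$X))
      for (j in seq_along(tot$X)) {
        st <- solve_state(system$params,
                          mixture_totals(tot$X[j], tot$M[j],
                                         system$zinc_equivalents * tot$X[j]))
        Q[j] <- V0 * system$dH * sum(st$bound_by_state)
      }
      Q
    },
    stop("unknown binding system variant"))
}

#' Simulate an integrated ITC isotherm
#'
#' Forward-simulates the normalized heat per injection for a binding system
#' under a titration protocol, using the standard displacement-cell
#' dilution bookkeeping. The injection heat is the increment of the cell
#' heat content plus the volume-displacement correction
#' \eqn{(dV/V_0)(Q_j + Q_{j-1})/2}, normalized per mole of injectant.
#'
#' For the \code{competitive} variant the heat of a matched
#' chelator-only reference titration (same protocol, no macromolecule) is
#' subtracted, emulating the blank correction applied to
#' chelator-containing experiments; disable with
#' \code{background_correct = FALSE}.
#'
#' @param system a \code{binding_system} object.
#' @param protocol a \code{\link{titration_protocol}} object.
#' @param background_correct subtract the chelator-only reference run
#'   (competitive variant only).
#' @return An object of class \code{"isotherm"}: a data frame with columns
#'   \code{injection}, \code{inj_volume_L}, \code{molar_ratio} (cumulative
#'   injectant over cell macromolecule) and \code{ndh_kcal_per_mol}.
#' @examples
#' sys <- single_class_system(n = 2, K = 8.7e5, dH = -8)
#' prot <- titration_protocol(syringe_conc = 150e-6, cell_conc = 3e-6)
#' iso <- simulate_isotherm(sys, prot)
#' head(iso)
#' @export
simulate_isotherm <- function(system, protocol, background_correct = TRUE) {
  stopifnot(inherits(system, "binding_system"),
            inherits(protocol, "titration_protocol"))
  tot <- .injection_totals(protocol)
  Q <- .cell_heat(system, protocol, tot)
  if (system$variant == "competitive" && background_correct &&
      protocol$chelator_conc > 0) {
    bg_prot <- protocol
    bg_prot$cell_conc <- 0
    bg_tot <- .injection_totals(bg_prot)
    Q <- Q - .cell_heat(system, bg_prot, bg_tot)
  }
  dV <- protocol$injection_volumes
  V0 <- protocol$V0
  Qprev <- c(0, Q[-length(Q)])
  dQ <- Q - Qprev + (dV / V0) * (Q + Qprev) / 2
  ndh <- dQ / (dV * protocol$syringe_conc)
  iso <- data.frame(injection = seq_along(dV), inj_volume_L = dV,
                    molar_ratio = tot$X / tot$M,
                    ndh_kcal_per_mol = ndh)
  if (protocol$discard_first) iso <- iso[-1, , drop = FALSE]
  class(iso) <- c("isotherm", "data.frame")
  iso
}

# --- fitting ------------------------------------------------------------

# parameter packing: every variant is fit on an unconstrained scale
# (log K, raw n and dH) via Levenberg-Marquardt.
.fit_pack <- function(variant, start) {
  switch(variant,
    single_class = c(n = start$n, lnK = log(start$K), dH = start$dH),
    competitive  = c(n = start$n, lnK = log(start$K_int), dH = start$dH_int),
    three_site   = c(lnK1 = log(start$K_classes[1]),
                     lnK2 = log(start$K_classes[2]),
                     lnK3 = log(start$K_classes[3]),
                     dH1 = start$dH_classes[1], dH2 = start$dH_classes[2],
                     dH3 = start$dH_classes[3]),
    dna_oligomer = c(lnK4 = log(start$params$K_dna[["K_4"]]),
                     dH = start$dH))
}

.fit_unpack <- function(variant, par, template) {
  switch(variant,
    single_class = single_class_system(n = par[["n"]],
                                       K = exp(par[["lnK"]]),
                                       dH = par[["dH"]]),
    competitive  = competitive_system(n = par[["n"]],
                                      K_int = exp(par[["lnK"]]),
                                      dH_int = par[["dH"]],
                                      K_chel = template$K_chel,
                                      dH_chel = template$dH_chel),
    three_site   = three_site_system(
                     K_classes = exp(c(par[["lnK1"]], par[["lnK2"]],
                                       par[["lnK3"]])),
                     dH_classes = c(par[["dH1"]], par[["dH2"]],
                                    par[["dH3"]])),
    dna_oligomer = {
      lp0 <- template$params
      r6 <- lp0$K_dna[["K_6"]] / lp0$K_dna[["K_4"]]
      K4 <- exp(par[["lnK4"]])
      lp <- linkage_params(K_Zn = lp0$K_Zn, K_4 = K4, K_6 = r6 * K4,
                           n_dna_sites = lp0$n_dna_sites,
                           K_low = lp0$K_dna[["K_0"]])
      dna_oligomer_system(lp, template$zinc_equivalents, par[["dH"]])
    })
}

#' Fit a binding model to an integrated ITC isotherm
#'
#' Nonlinear least squares (Levenberg-Marquardt, association constants fit
#' on the log scale) of the \code{\link{simulate_isotherm}} forward model
#' against observed normalized heats.
#'
#' Free parameters by variant: \code{single_class} — n, K, dH;
#' \code{competitive} — n, K_int, dH_int (chelator constants held fixed at
#' the values in \code{start}); \code{three_site} — three per-class K and
#' dH; \code{dna_oligomer} — K_4 and dH (the K_6/K_4 ratio and zinc
#' parameters held fixed at the values in \code{start}).
#'
#' @param data an \code{isotherm} (columns \code{molar_ratio},
#'   \code{ndh_kcal_per_mol}; at least 5 points).
#' @param protocol the \code{\link{titration_protocol}} used.
#' @param variant one of \code{"single_class"}, \code{"three_site"},
#'   \code{"competitive"}, \code{"dna_oligomer"}.
#' @param start a \code{binding_system} of the same variant providing the
#'   initial guess (and the fixed parameters).
#' @return An object of class \code{"itc_fit"}: \code{system} (best-fit
#'   binding system), \code{parameters}, \code{se} (standard errors, delta
#'   method for K), \code{rss}, \code{residuals}, \code{converged}.
#' @export
fit_isotherm <- function(data, protocol, variant, start) {
  stopifnot(inherits(start, "binding_system"), start$variant == variant)
  y <- data$ndh_kcal_per_mol
  if (length(y) < 5) stop("need at least 5 injections to fit")
  if (all(abs(y) < 1e-12))
    stop("all heats are (near) zero: binding parameters are unidentifiable")
  resid_fn <- function(par) {
    sys <- try(.fit_unpack(variant, par, start), silent = TRUE)
    if (inherits(sys, "try-error")) return(rep(1e6, length(y)))
    sim <- try(simulate_isotherm(sys, protocol), silent = TRUE)
    if (inherits(sim, "try-error")) return(rep(1e6, length(y)))
    y - sim$ndh_kcal_per_mol
  }
  p0 <- .fit_pack(variant, start)
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  if (!(fit$info %in% 1:4))
    warning("Levenberg-Marquardt did not report convergence (info = ",
            fit$info, ")")
  par <- stats::coef(fit)
  sys <- .fit_unpack(variant, par, start)
  rss <- sum(fit$fvec^2)
  se_raw <- tryCatch(sqrt(diag(rss / max(1, length(y) - length(par)) *
                                 solve(fit$hessian / 2))),
                     error = function(e) rep(NA_real_, length(par)))
  names(se_raw) <- names(par)
  # delta method: se(K) = K * se(ln K)
  se <- se_raw
  for (nm in grep("^lnK", names(se), value = TRUE)) {
    se[sub("^ln", "", nm)] <- exp(par[[nm]]) * se_raw[[nm]]
    se <- se[names(se) != nm]
  }
  parameters <- par
  for (nm in grep("^lnK", names(par), value = TRUE)) {
    parameters[sub("^ln", "", nm)] <- exp(par[[nm]])
    parameters <- parameters[names(parameters) != nm]
  }
  structure(list(system = sys, parameters = parameters, se = se,
                 rss = rss, residuals = as.numeric(fit$fvec),
                 converged = fit$info %in% 1:4, variant = variant),
            class = "itc_fit")
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("ITC fit (", x$variant, ")\n", sep = "")
  for (nm in names(x$parameters))
    cat(sprintf("  %-4s = %.6g (se %.3g)\n", nm, x$parameters[[nm]],
                if (nm %in% names(x$se)) x$se[[nm]] else NA))
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

#' Conditional metal-chelator stability constant at a given pH
#'
#' Converts an absolute (fully deprotonated) stability constant to the
#' conditional constant at the working pH through the protonation
#' alpha-factor of the chelator's terminal acid groups:
#' \eqn{K' = K / (1 + [H]/Ka_1 + [H]^2/(Ka_1 Ka_2))}.
#'
#' Defaults are the zinc-EGTA values used throughout: absolute log K 12.6
#' and terminal pKa 9.40 and 8.79, giving log K' = 9.97 at pH 7.8.
#'
#' @param logK_abs absolute log10 stability constant.
#' @param pKa terminal pKa values of the chelator (highest first).
#' @param pH working pH.
#' @return The conditional association constant (M^-1).
#' @examples
#' conditional_chelator_constant()   # ~9.3e9 for Zn-EGTA at pH 7.8
#' @export
conditional_chelator_constant <- function(logK_abs = 12.6,
                                          pKa = c(9.40, 8.79), pH = 7.8) {
  H <- 10^(-pH)
  Ka <- 10^(-pKa)
  alpha <- 1 + H / Ka[1] + H^2 / (Ka[1] * Ka[2])
  10^logK_abs / alpha
}

#' Chelator-competition correction of an apparent affinity
#'
#' In the presence of an excess competing chelator, the apparent metal
#' affinity measured by ITC is reduced by the factor
#' \eqn{1 + K'_{chel} [chel]}. This function converts between apparent and
#' intrinsic constants (and, when enthalpies are supplied, between apparent
#' and intrinsic enthalpies: \eqn{\Delta H_{int} = \Delta H_{app} +
#' \Delta H_{chel}}, since the observed heat is depleted by the heat of
#' metal release from the chelator).
#'
#' @param K apparent (or intrinsic) association constant (M^-1).
#' @param chelator_conc chelator concentration (M).
#' @param K_chel conditional chelator-metal constant (M^-1).
#' @param dH apparent (or intrinsic) enthalpy (kcal/mol), optional.
#' @param dH_chel chelator-metal binding enthalpy (kcal/mol).
#' @param direction \code{"to_intrinsic"} (default) or
#'   \code{"to_apparent"} (the exact inverse).
#' @return A list with \code{K} (corrected constant), \code{Kd} (its
#'   reciprocal, M) and, if \code{dH} was given, \code{dH}.
#' @examples
#' chelator_correction(8.6e5, 3e-3, conditional_chelator_constant())$K
#' @export
chelator_correction <- function(K, chelator_conc, K_chel, dH = NULL,
                                dH_chel = 0,
                                direction = c("to_intrinsic",
                                              "to_apparent")) {
  direction <- match.arg(direction)
  stopifnot(K >= 0, chelator_conc >= 0, K_chel >= 0)
  fac <- 1 + K_chel * chelator_conc
  if (direction == "to_intrinsic") {
    out <- list(K = K * fac, Kd = 1 / (K * fac))
    if (!is.null(dH)) out$dH <- dH + dH_chel
  } else {
    out <- list(K = K / fac, Kd = fac / K)
    if (!is.null(dH)) out$dH <- dH - dH_chel
  }
  out
}

#' Heterogeneity tolerance of a monophasic isotherm
#'
#' How different can the three per-class zinc binding constants of the
#' dimer be before the isotherm stops looking single-class? For each fold
#' spread, the three-site curve (classes at \eqn{K\,s^{-1/2}}, \eqn{K},
#' \eqn{K\,s^{+1/2}}, two sites each, common enthalpy) is simulated
#' noise-free under the protocol, fit with the single-class model, and the
#' systematic misfit is compared with the instrument noise by an F-test
#' with known variance: the spread is \emph{detectable} when
#' \eqn{RSS/((N-3)\sigma^2)} exceeds the upper \eqn{\alpha} quantile of
#' \eqn{F_{N-3,\infty}}.
#'
#' @param protocol a \code{\link{titration_protocol}}.
#' @param base_K central per-site association constant (M^-1) — on the
#'   apparent scale if the protocol contains a chelator.
#' @param dH per-site binding enthalpy (kcal/mol).
#' @param noise_sigma instrument noise on normalized heats (kcal/mol).
#'   Default 0.02, a typical integrated-heat repeatability for a modern
#'   automated microcalorimeter on curves of a few kcal/mol amplitude.
#' @param fold_spreads spreads (>= 1) to classify.
#' @param alpha F-test level.
#' @return A list: \code{table} (data frame with spread, rss, F statistic,
#'   p value, classification) and \code{max_tolerated} (largest spread
#'   classified indistinguishable; \code{NA} if none).
#' @export
monophasicity_bound <- function(protocol, base_K, dH, noise_sigma = 0.02,
                                fold_spreads = c(1, 3, 10, 20, 100, 1000),
                                alpha = 0.05) {
  stopifnot(noise_sigma > 0, all(fold_spreads >= 1))
  res <- lapply(fold_spreads, function(sp) {
    Kc <- base_K * sp^c(-0.5, 0, 0.5)
    truth <- three_site_system(K_classes = Kc, dH_classes = rep(dH, 3))
    iso <- simulate_isotherm(truth, protocol)
    fit <- fit_isotherm(iso, protocol, "single_class",
                        single_class_system(n = 6, K = base_K, dH = dH))
    N <- nrow(iso)
    Fstat <- (fit$rss / (N - 3)) / noise_sigma^2
    p <- stats::pf(Fstat, N - 3, Inf, lower.tail = FALSE)
    data.frame(fold_spread = sp, rss = fit$rss, F_stat = Fstat, p_value = p,
               classification = if (p < alpha) "detectable"
                                else "indistinguishable")
  })
  tab <- do.call(rbind, res)
  tol <- tab$fold_spread[tab$classification == "indistinguishable"]
  list(table = tab,
       max_tolerated = if (length(tol)) max(tol) else NA_real_)
}
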