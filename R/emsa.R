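#' Oligomeric DNA-binding constants for EMSA analysis
#'
#' Two parameterizations of the Zur-DNA species ladder observed on gels
#' under excess zinc (all Zur zinc-saturated):
#' \describe{
#'   \item{per_site}{the DNA carries \code{n_sites} identical independent
#'     dimer-sites with one per-site constant \code{K_site}; all
#'     intermediate species (including 1:1) exist with binomial weights.}
#'   \item{stepwise}{only the species seen as bands are carried: free DNA,
#'     the 2:1 complex (overall constant \code{beta2}, M^-2, for
#'     D + 2P = DP2) and the 3:1 complex (stepwise \code{K3}, M^-1, for
#'     DP2 + P = DP3).}
#' }
#'
#' @param variant \code{"per_site"} or \code{"stepwise"}.
#' @param K_site per-site association constant (M^-1), per_site variant.
#' @param beta2 overall 2:1 association constant (M^-2), stepwise variant.
#' @param K3 stepwise 3:1 association constant (M^-1), stepwise variant.
#' @param n_sites number of dimer-sites on the probe (per_site variant);
#'   3 for the zitB probe.
#' @return A list of class \code{"oligomer_constants"} including derived
#'   dissociation-constant equivalents (\code{Kd_site} or \code{Kd2}
#'   \eqn{= 1/\sqrt{\beta_2}} and \code{Kd3} \eqn{= 1/K_3}).
#' @export
oligomer_constants <- function(variant = c("per_site", "stepwise"),
                               K_site = NULL, beta2 = NULL, K3 = NULL,
                               n_sites = 3) {
  variant <- match.arg(variant)
  if (variant == "per_site") {
    stopifnot(!is.null(K_site), K_site >= 0, n_sites %in% 1:3)
    structure(list(variant = "per_site", K_site = K_site,
                   n_sites = as.integer(n_sites),
                   Kd_site = if (K_site > 0) 1 / K_site else Inf),
              class = "oligomer_constants")
  } else {
    stopifnot(!is.null(beta2), !is.null(K3), beta2 > 0, K3 > 0)
    structure(list(variant = "stepwise", beta2 = beta2, K3 = K3,
                   Kd2 = 1 / sqrt(beta2), Kd3 = 1 / K3),
              class = "oligomer_constants")
  }
}

# free dimer concentration with protein depletion: solve
# P_total = P_free + D_total * (mean dimers bound per DNA), monotone.
.emsa_free_protein <- function(constants, P_total, D_total) {
  if (P_total == 0) return(0)
  bound_per_dna <- function(Pf) {
    if (constants$variant == "per_site") {
      s <- constants$K_site * Pf
      constants$n_sites * s / (1 + s)
    } else {
      b2 <- constants$beta2
      q2 <- b2 * Pf^2; q3 <- b2 * constants$K3 * Pf^3
      (2 * q2 + 3 * q3) / (1 + q2 + q3)
    }
  }
  f <- function(Pf) Pf + D_total * bound_per_dna(Pf) - P_total
  if (f(P_total) <= 0) return(P_total)
  stats::uniroot(f, c(0, P_total), tol = 1e-16 * max(P_total, 1e-12),
                 maxiter = 2000L)$root
}

.emsa_fractions_at <- function(constants, Pf) {
  if (constants$variant == "per_site") {
    n <- constants$n_sites
    th <- constants$K_site * Pf / (1 + constants$K_site * Pf)
    fr <- choose(n, 0:n) * th^(0:n) * (1 - th)^(n - (0:n))
    stats::setNames(fr, c("f_free", paste0("f_", 1:n, "to1")))
  } else {
    q2 <- constants$beta2 * Pf^2
    q3 <- constants$beta2 * constants$K3 * Pf^3
    Q <- 1 + q2 + q3
    c(f_free = 1 / Q, f_2to1 = q2 / Q, f_3to1 = q3 / Q)
  }
}

#' Predict EMSA band fractions under excess zinc
#'
#' Computes the fractional distribution of DNA among the gel species for a
#' grid of total dimer concentrations, with protein depletion modeled
#' (the free dimer concentration is solved self-consistently, since the
#' DNA-site capacity is comparable to the protein totals on these gels).
#' All Zur is treated as zinc-saturated (the excess-zinc condition of the
#' experiment, > 6 equivalents per dimer).
#'
#' @param constants an \code{\link{oligomer_constants}} object.
#' @param P_grid vector of total dimer concentrations (M).
#' @param D_total DNA probe concentration (M).
#' @return A \code{band_fraction_table}: data frame with \code{p_total_M},
#'   \code{f_free}, \code{f_2to1}, \code{f_3to1} and (per_site variant)
#'   \code{f_1to1}; rows sum to 1. \code{D_total} is kept as an attribute.
#' @examples
#' oc <- oligomer_constants("per_site", K_site = 2e9)
#' predict_band_fractions(oc, c(10, 30, 100, 300, 1000) * 1e-9, 65e-9)
#' @export
predict_band_fractions <- function(constants, P_grid, D_total) {
  stopifnot(inherits(constants, "oligomer_constants"),
            all(P_grid >= 0), D_total >= 0)
  rows <- lapply(P_grid, function(P) {
    Pf <- .emsa_free_protein(constants, P, D_total)
    .emsa_fractions_at(constants, Pf)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(p_total_M = P_grid, out)
  attr(out, "D_total") <- D_total
  class(out) <- c("band_fraction_table", "data.frame")
  out
}

#' Estimate oligomeric DNA-binding constants from band fractions
#'
#' Weighted least squares of \code{\link{predict_band_fractions}} against
#' an observed band-fraction table (the protein-titration EMSA analysis
#' under excess zinc). Constants are fit on the log scale by
#' Levenberg-Marquardt after a coarse log-grid search for the start.
#'
#' Only fraction columns present in \code{data} enter the objective.
#' Fitting the per_site variant of a 3-site probe requires the
#' \code{f_1to1} column (the model predicts a 1:1 species and folding it
#' silently into another band would bias the fit); use the stepwise
#' variant for gels on which only free, 2:1 and 3:1 bands were resolved.
#'
#' @param data a \code{band_fraction_table} (columns \code{p_total_M},
#'   \code{f_free}, \code{f_2to1}, \code{f_3to1}, optional \code{f_1to1}
#'   and \code{sigma}); at least 4 protein concentrations spanning the
#'   binding transition.
#' @param variant \code{"per_site"} or \code{"stepwise"}.
#' @param D_total DNA probe concentration (M); defaults to the table's
#'   \code{D_total} attribute.
#' @param n_sites number of dimer-sites (per_site variant).
#' @return A list of class \code{"emsa_fit"}: \code{constants} (an
#'   \code{\link{oligomer_constants}} with best-fit values), \code{se},
#'   \code{rss}, \code{residuals}, \code{converged}.
#' @export
fit_band_constants <- function(data, variant = c("stepwise", "per_site"),
                               D_total = attr(data, "D_total"),
                               n_sites = 3) {
  variant <- match.arg(variant)
  if (is.null(D_total)) stop("D_total must be supplied (or carried as an ",
                             "attribute of the table)")
  if (nrow(data) < 4)
    stop("need at least 4 protein concentrations to fit")
  fcols <- intersect(c("f_free", "f_1to1", "f_2to1", "f_3to1"),
                     names(data))
  if (variant == "per_site" && n_sites == 3 && !("f_1to1" %in% names(data)))
    stop("per_site fitting of a 3-site probe needs the f_1to1 column; ",
         "use the stepwise variant for three-band gels")
  # transition must be bracketed: free DNA must both persist and vanish
  if (min(data$f_free) > 0.8 || max(data$f_free) < 0.2)
    stop("binding transition not bracketed by the data: ",
         "constants are unidentifiable")
  w <- if ("sigma" %in% names(data)) 1 / data$sigma else rep(1, nrow(data))
  obs <- as.matrix(data[fcols])
  make <- function(par) {
    if (variant == "per_site")
      oligomer_constants("per_site", K_site = exp(par[[1]]),
                         n_sites = n_sites)
    else
      oligomer_constants("stepwise", beta2 = exp(par[[1]]),
                         K3 = exp(par[[2]]))
  }
  resid_fn <- function(par) {
    oc <- try(make(par), silent = TRUE)
    if (inherits(oc, "try-error")) return(rep(1e6, length(obs)))
    pred <- predict_band_fractions(oc, data$p_total_M, D_total)
    as.numeric(w * (obs - as.matrix(pred[fcols])))
  }
  # coarse grid start over plausible affinity decades
  if (variant == "per_site") {
    grid <- lapply(seq(5, 13, by = 0.5), function(g) log(10^g))
  } else {
    grid <- list()
    for (g2 in seq(12, 24, by = 2)) for (g3 in seq(5, 13, by = 2))
      grid <- c(grid, list(c(log(10^g2), log(10^g3))))
  }
  rss0 <- vapply(grid, function(p) sum(resid_fn(p)^2), numeric(1))
  p0 <- grid[[which.min(rss0)]]
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14))
  par <- stats::coef(fit)
  oc <- make(par)
  rss <- sum(fit$fvec^2)
  dof <- max(1, length(obs) - length(par))
  se_log <- tryCatch(sqrt(diag(rss / dof * solve(fit$hessian / 2))),
                     error = function(e) rep(NA_real_, length(par)))
  se <- if (variant == "per_site") {
    c(K_site = oc$K_site * se_log[1])
  } else {
    c(beta2 = oc$beta2 * se_log[1], K3 = oc$K3 * se_log[2])
  }
  structure(list(constants = oc, se = se, rss = rss,
                 residuals = as.numeric(fit$fvec),
                 converged = fit$info %in% 1:4),
            class = "emsa_fit")
}

#' @export
print.emsa_fit <- function(x, ...) {
  oc <- x$constants
  cat("EMSA band-fraction fit (", oc$variant, ")\n", sep = "")
  if (oc$variant == "per_site") {
    cat(sprintf("  K_site = %.4g M^-1 (Kd = %.4g M)\n", oc$K_site,
                oc$Kd_site))
  } else {
    cat(sprintf("  beta2 = %.4g M^-2 (Kd2 = %.4g M)\n", oc$beta2, oc$Kd2))
    cat(sprintf("  K3    = %.4g M^-1 (Kd3 = %.4g M)\n", oc$K3, oc$Kd3))
  }
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}
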