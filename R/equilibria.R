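#' Linkage parameters for the coupled zinc / DNA binding model
#'
#' Bundles the parameters of the linked-equilibria model of Zur: a per-site
#' zinc association constant for the six equivalent regulatory sites of the
#' dimer, and seven DNA association constants \eqn{K_0..K_6}, one for each
#' zinc-occupancy state \eqn{PL_i} of the dimer binding a single dimer-site
#' on DNA. The znuA probe carries two independent dimer-sites, zitB three.
#'
#' When only the anchor constants are given (\code{K_low} for the inactive
#' low-occupancy states, \code{K_4} pinned to the ITC measurement at four
#' zinc equivalents per dimer, and \code{K_6} for the zinc-saturated dimer)
#' the odd states are filled by geometric interpolation:
#' \eqn{K_0 = K_1 = K_2 = K_{low}}, \eqn{K_3 = \sqrt{K_2 K_4}},
#' \eqn{K_5 = \sqrt{K_4 K_6}}. A full 7-vector \code{K_dna} overrides this
#' rule.
#'
#' @param K_Zn per-site zinc association constant (M^-1), > 0.
#' @param K_4 DNA association constant of the 4-zinc dimer (M^-1).
#' @param K_6 DNA association constant of the zinc-saturated dimer (M^-1).
#' @param n_dna_sites number of independent dimer-binding sites on the DNA
#'   probe: 2 for znuA, 3 for zitB (1 allowed for a single-site probe).
#' @param K_low DNA constant assigned to states i <= 2 (M^-1); default 1e4,
#'   the upper bound of the "subtle" affinity attributed to low-occupancy
#'   states.
#' @param K_dna optional full vector of seven constants K_0..K_6 (M^-1),
#'   non-decreasing; overrides the interpolation rule.
#' @return An object of class \code{"linkage_params"}: a list with elements
#'   \code{K_Zn}, \code{K_dna} (length 7, named \code{K_0..K_6}) and
#'   \code{n_dna_sites}.
#' @examples
#' lp <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 700 * 8.7e5,
#'                      n_dna_sites = 2)
#' lp$K_dna
#' @export
linkage_params <- function(K_Zn, K_4 = NULL, K_6 = NULL, n_dna_sites,
                           K_low = 1e4, K_dna = NULL) {
  stopifnot(is.numeric(K_Zn), length(K_Zn) == 1, is.finite(K_Zn), K_Zn > 0)
  if (!(n_dna_sites %in% 1:3))
    stop("n_dna_sites must be 1, 2 or 3 (2 for znuA, 3 for zitB)")
  if (is.null(K_dna)) {
    if (is.null(K_4) || is.null(K_6))
      stop("supply either K_dna (length 7) or both K_4 and K_6")
    stopifnot(K_4 >= 0, K_6 >= 0)
    K_dna <- c(K_low, K_low, K_low,
               sqrt(K_low * K_4), K_4, sqrt(K_4 * K_6), K_6)
  }
  if (length(K_dna) != 7 || any(!is.finite(K_dna)) || any(K_dna < 0))
    stop("K_dna must be 7 finite non-negative constants K_0..K_6")
  if (any(diff(K_dna) < 0))
    stop("K_dna must be non-decreasing in zinc occupancy (monotone activation)")
  structure(list(K_Zn = K_Zn,
                 K_dna = stats::setNames(K_dna, paste0("K_", 0:6)),
                 n_dna_sites = as.integer(n_dna_sites)),
            class = "linkage_params")
}

#' Total concentrations of the mixture
#'
#' @param P_total total dimer concentration (M).
#' @param D_total total DNA concentration (M).
#' @param zinc_mode \code{"total"} (zinc conserved; free zinc solved for) or
#'   \code{"free_clamped"} (free zinc buffered at a fixed value, as in a
#'   cell where zinc is buffered by the proteome).
#' @param L_value total zinc (M) in \code{"total"} mode, or the clamped free
#'   zinc concentration (M) in \code{"free_clamped"} mode.
#' @return A list of class \code{"mixture_totals"}.
#' @export
mixture_totals <- function(P_total, D_total, L_value,
                           zinc_mode = c("total", "free_clamped")) {
  zinc_mode <- match.arg(zinc_mode)
  vals <- c(P_total = P_total, D_total = D_total, L_value = L_value)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all concentrations must be finite and >= 0")
  structure(list(P_total = P_total, D_total = D_total,
                 zinc_mode = zinc_mode, L_value = L_value),
            class = "mixture_totals")
}

#' Solver options for the equilibrium solver
#'
#' @param rel_tol relative tolerance on the solved unknowns.
#' @param max_iter maximum iterations for the 1-D root bracketing/refinement.
#' @param log_bracket_width width (natural-log units) of the search bracket
#'   below the trivial upper bound for each log-transformed unknown.
#' @return A list of class \code{"solve_options"}.
#' @export
solve_options <- function(rel_tol = 1e-10, max_iter = 200L,
                          log_bracket_width = 120) {
  stopifnot(rel_tol > 0, max_iter >= 1, log_bracket_width > 0)
  structure(list(rel_tol = rel_tol, max_iter = as.integer(max_iter),
                 log_bracket_width = log_bracket_width),
            class = "solve_options")
}

# Zinc-occupancy state weights of the free dimer at free zinc L:
# w_i = C(6,i) (K_Zn L)^i, so that p_i = p_0 * w_i and
# sum_i w_i = (1 + K_Zn L)^6 (binomial self-check).
.state_weights <- function(K_Zn, L_free) {
  x <- K_Zn * L_free
  choose(6, 0:6) * x^(0:6)
}

# Given free zinc (through the state weights) solve dimer conservation for
# p_0 with a single class of DNA sites. Conservation reads
#   P = p_0 Z + D n s/(1+s),  s = p_0 kappa,
# with Z = sum w_i and kappa = sum K_i w_i: a quadratic in p_0, solved in a
# numerically stable form (the positive root; c < 0 guarantees one).
.solve_p0_quadratic <- function(P, D, n_sites, Z, kappa) {
  if (P == 0) return(0)
  if (kappa == 0 || D == 0) return(P / Z)
  a <- Z * kappa
  b <- Z + D * n_sites * kappa - P * kappa
  cc <- -P
  disc <- sqrt(b * b - 4 * a * cc)
  if (b >= 0) 2 * P / (b + disc) else (-b + disc) / (2 * a)
}

# Generic inner solve over >= 1 site classes (classes: list of
# list(n_sites=, K=7-vector)). Monotone in p_0; single class uses the
# closed-form quadratic, otherwise Brent on log p_0.
.solve_p0 <- function(P, D, classes, w, opts) {
  Z <- sum(w)
  kappas <- vapply(classes, function(cl) sum(cl$K * w), numeric(1))
  ns <- vapply(classes, function(cl) cl$n_sites, numeric(1))
  if (P == 0) return(0)
  if (length(classes) == 1L)
    return(.solve_p0_quadratic(P, D, ns[1], Z, kappas[1]))
  f <- function(u) {
    p0 <- exp(u)
    s <- p0 * kappas
    p0 * Z + D * sum(ns * s / (1 + s)) - P
  }
  hi <- log(P / Z)           # all protein free => upper bound on p_0
  lo <- log(P / (Z + D * sum(ns * kappas)))  # all sites would bind
  if (f(lo) > 0) return(exp(lo))
  r <- stats::uniroot(f, c(lo - 1e-9, hi + 1e-9), tol = 1e-14,
                      maxiter = 10L * opts$max_iter)
  exp(r$root)
}

# Assemble the full composition from converged (L_free, p_0) for one class.
.assemble_state <- function(params, totals, L_free, p0) {
  w <- .state_weights(params$K_Zn, L_free)
  K <- params$K_dna
  n_s <- params$n_dna_sites
  D <- totals$D_total
  p_free <- p0 * w
  s <- p0 * sum(K * w)
  theta <- s / (1 + s)
  m <- 0:n_s
  d_complex <- D * choose(n_s, m) * theta^m * (1 - theta)^(n_s - m)
  bound_total <- D * n_s * theta
  bound_by_state <- if (s > 0) bound_total * (K * p_free) / s else rep(0, 7)
  structure(list(
    L_free = L_free,
    p_free = stats::setNames(p_free, paste0("p_", 0:6)),
    d_complex = stats::setNames(d_complex, paste0("d_", m)),
    site_occupancy = theta,
    bound_by_state = stats::setNames(bound_by_state, paste0("b_", 0:6)),
    s = s,
    params = params, totals = totals), class = "species_state")
}

# Total zinc held at free zinc L (free + on free dimers + on DNA-bound dimers)
.zinc_total_at <- function(P, D, classes, K_Zn, L_free, opts) {
  w <- .state_weights(K_Zn, L_free)
  p0 <- .solve_p0(P, D, classes, w, opts)
  zn_free_dimer <- p0 * sum((0:6) * w)
  zn_dna <- 0
  for (cl in classes) {
    kap <- sum(cl$K * w)
    s <- p0 * kap
    kap2 <- sum((0:6) * cl$K * w)
    if (s > 0) zn_dna <- zn_dna + D * cl$n_sites * p0 * kap2 / (1 + s)
  }
  list(L_total = L_free + zn_free_dimer + zn_dna, p0 = p0)
}

# Core solver shared by solve_state() and the activation module: find
# (L_free, p_0) satisfying conservation for an arbitrary list of independent
# DNA site classes. In "total" mode the problem reduces to a 1-D root in
# log L_free (total zinc is strictly increasing in free zinc).
.solve_core <- function(K_Zn, classes, totals, opts) {
  P <- totals$P_total
  D <- totals$D_total
  if (totals$zinc_mode == "free_clamped") {
    L_free <- totals$L_value
  } else {
    L_tot <- totals$L_value
    if (L_tot == 0) {
      L_free <- 0
    } else {
      g <- function(v) .zinc_total_at(P, D, classes, K_Zn, exp(v), opts)$L_total - L_tot
      hi <- log(L_tot)
      lo <- hi - opts$log_bracket_width
      if (g(lo) > 0) {
        # binding too weak to matter at the bracket floor: free ~ total
        L_free <- exp(lo)
      } else {
        r <- stats::uniroot(g, c(lo, hi), tol = 1e-15,
                            maxiter = 10L * opts$max_iter)
        L_free <- exp(r$root)
      }
    }
  }
  w <- .state_weights(K_Zn, L_free)
  p0 <- .solve_p0(P, D, classes, w, opts)
  list(L_free = L_free, p0 = p0, w = w)
}

#' Solve the linked zinc / DNA binding equilibrium
#'
#' Computes the full equilibrium composition of a mixture of dimeric Zur
#' (six equivalent regulatory zinc sites), DNA carrying
#' \code{params$n_dna_sites} independent identical dimer-sites, and zinc.
#' Free-dimer states follow \eqn{p_i = p_0 C(6,i)(K_{Zn} L)^i}; the
#' DNA-site binding weight is \eqn{s = \sum_i K_i p_i} and the m-dimer
#' complexes are binomial, \eqn{d_m = D\,C(n_s,m)\,s^m/(1+s)^{n_s}}.
#'
#' @param params a \code{\link{linkage_params}} object.
#' @param totals a \code{\link{mixture_totals}} object.
#' @param opts a \code{\link{solve_options}} object.
#' @return An object of class \code{"species_state"}: free zinc
#'   \code{L_free}, free-dimer states \code{p_free} (\code{p_0..p_6}), DNA
#'   complexes \code{d_complex} (\code{d_0..d_{n_s}}), the per-site
#'   occupancy \code{site_occupancy}, and \code{bound_by_state}, the
#'   concentration of DNA-bound dimers in each zinc-occupancy state.
#' @examples
#' lp <- linkage_params(K_Zn = 2.3e13, K_4 = 8.7e5, K_6 = 700 * 8.7e5,
#'                      n_dna_sites = 2)
#' st <- solve_state(lp, mixture_totals(200e-9, 65e-9, 5e-6))
#' st$d_complex / 65e-9      # DNA species fractions
#' @export
solve_state <- function(params, totals, opts = solve_options()) {
  stopifnot(inherits(params, "linkage_params"),
            inherits(totals, "mixture_totals"),
            inherits(opts, "solve_options"))
  classes <- list(list(n_sites = params$n_dna_sites, K = params$K_dna))
  sol <- .solve_core(params$K_Zn, classes, totals, opts)
  st <- .assemble_state(params, totals, sol$L_free, sol$p0)
  .check_conservation(st)
  st
}

# Conservation self-checks on an assembled state (errors signal a solver
# failure, not bad user input).
.check_conservation <- function(st) {
  tot <- st$totals
  relerr <- function(a, b) abs(a - b) / max(abs(b), 1e-300)
  if (tot$D_total > 0 &&
      relerr(sum(st$d_complex), tot$D_total) > 1e-10)
    stop("DNA conservation violated (solver failure)")
  P_acc <- sum(st$p_free) + sum(st$bound_by_state)
  if (tot$P_total > 0 && relerr(P_acc, tot$P_total) > 1e-8)
    stop("dimer conservation violated (solver failure)")
  if (tot$zinc_mode == "total" && tot$L_value > 0) {
    L_acc <- st$L_free + sum((0:6) * st$p_free) +
      sum((0:6) * st$bound_by_state)
    if (relerr(L_acc, tot$L_value) > 1e-8)
      stop("zinc conservation violated (solver failure)")
  }
  invisible(st)
}

#' DNA species fractions as a function of zinc
#'
#' Solves the linkage model along an ascending grid of total zinc
#' concentrations at fixed protein and DNA totals, returning the fractional
#' population of free DNA and of each m:1 (dimer:DNA) complex — the
#' zinc-titration population plots of the model.
#'
#' @param params a \code{\link{linkage_params}} object.
#' @param P_total total dimer concentration (M).
#' @param D_total total DNA concentration (M).
#' @param zinc_grid ascending vector of total zinc concentrations (M).
#' @param opts solver options.
#' @return A data frame with columns \code{zinc_total_M}, \code{frac_free},
#'   \code{frac_1to1}, ..., up to \code{frac_\{n_s\}to1}; rows sum to 1.
#' @export
zinc_titration_profile <- function(params, P_total, D_total, zinc_grid,
                                   opts = solve_options()) {
  if (is.unsorted(zinc_grid)) stop("zinc_grid must be ascending")
  rows <- lapply(seq_along(zinc_grid), function(j) {
    st <- tryCatch(
      solve_state(params, mixture_totals(P_total, D_total, zinc_grid[j]),
                  opts),
      error = function(e) stop("solver failed at zinc_grid[", j, "] = ",
                               zinc_grid[j], ": ", conditionMessage(e)))
    st$d_complex / D_total
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("frac_free", paste0("frac_", seq_len(params$n_dna_sites),
                                      "to1"))
  cbind(zinc_total_M = zinc_grid, out)
}

#' DNA species fractions as a function of the Zur:DNA molar ratio
#'
#' Emulates a protein-into-DNA titration at a fixed zinc load per dimer:
#' at each molar ratio r the dimer total is r * D_total and the total zinc
#' is \code{zinc_equivalents_per_dimer} times the dimer total (zinc is
#' co-titrated with the protein, as in the DNA-binding ITC experiments).
#'
#' @param params a \code{\link{linkage_params}} object.
#' @param D_total DNA concentration (M).
#' @param zinc_equivalents_per_dimer zinc equivalents carried per dimer.
#' @param ratio_grid ascending grid of [dimer]/[DNA] molar ratios.
#' @param opts solver options.
#' @return A data frame with columns \code{molar_ratio}, \code{frac_free},
#'   \code{frac_1to1}, ...; rows sum to 1.
#' @export
protein_titration_profile <- function(params, D_total,
                                      zinc_equivalents_per_dimer,
                                      ratio_grid, opts = solve_options()) {
  if (is.unsorted(ratio_grid)) stop("ratio_grid must be ascending")
  rows <- lapply(seq_along(ratio_grid), function(j) {
    P <- ratio_grid[j] * D_total
    st <- tryCatch(
      solve_state(params,
                  mixture_totals(P, D_total,
                                 zinc_equivalents_per_dimer * P), opts),
      error = function(e) stop("solver failed at ratio_grid[", j, "] = ",
                               ratio_grid[j], ": ", conditionMessage(e)))
    st$d_complex / D_total
  })
  out <- as.data.frame(do.call(rbind, rows))
  names(out) <- c("frac_free", paste0("frac_", seq_len(params$n_dna_sites),
                                      "to1"))
  cbind(molar_ratio = ratio_grid, out)
}

#' @export
print.species_state <- function(x, ...) {
  cat("Linked-equilibrium composition\n")
  cat(sprintf("  free zinc: %.4g M   site occupancy: %.4f\n",
              x$L_free, x$site_occupancy))
  cat("  free dimer states (M):\n")
  print(signif(x$p_free, 4))
  cat("  DNA complexes (M):\n")
  print(signif(x$d_complex, 4))
  invisible(x)
}
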