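#' Two-tier promoter model for biphasic zitB activation
#'
#' Coarse-grained description of the zitB promoter used to rationalize its
#' two-phase response to zinc: a high-affinity zurbox carrying three
#' dimer-sites, plus \code{N_up} low-affinity upstream dimer-sites whose
#' occupation requires near-saturation of the bulk Zur pool. Upstream
#' sites share the zurbox zinc-state affinity ladder scaled by
#' \code{K_up / K_6}, so a dimer's zinc state modulates both tiers
#' identically.
#'
#' An expression proxy maps occupancies to a transcription-output scale:
#' \eqn{E = w_0 + w_1\,\theta_{zurbox} + w_2\,\theta_{up}}. The default
#' weights \code{c(1, 2, 20)} put the zurbox-saturated (phase-1) level at
#' 3x basal and the fully upstream-bound level 6- to 7-fold above phase 1,
#' the in-vivo dynamic range reported for zitB.
#'
#' @param zurbox a \code{\link{linkage_params}} for the zurbox (zitB:
#'   \code{n_dna_sites = 3}).
#' @param N_up number of upstream low-affinity dimer-sites (>= 1; the
#'   upstream protected region spans roughly one additional hexamer-scale
#'   footprint, hence the default 3).
#' @param K_up association constant of the zinc-saturated dimer for one
#'   upstream site (M^-1); must be < the zurbox \code{K_6}. Default
#'   \code{K_6 / 4000}, i.e. back at the partially-saturated-Zur affinity
#'   scale, which places upstream filling at bulk-pool saturation.
#' @param P_total cellular dimer concentration (M); default 4e-6, the
#'   estimated total Zur concentration in S. coelicolor.
#' @param D_total promoter concentration (M); default 1e-9 (single-copy
#'   promoter; depletion negligible).
#' @param weights expression-proxy weights \code{c(w0, w1, w2)} for
#'   (basal, zurbox occupancy, upstream occupancy).
#' @return A list of class \code{"promoter_model"}.
#' @export
promoter_model <- function(zurbox = linkage_params(K_Zn = 2.3e13,
                                                   K_4 = 1.8e6,
                                                   K_6 = 4000 * 1.8e6,
                                                   n_dna_sites = 3),
                           N_up = 3, K_up = NULL, P_total = 4e-6,
                           D_total = 1e-9, weights = c(1, 2, 20)) {
  stopifnot(inherits(zurbox, "linkage_params"), N_up >= 1,
            P_total > 0, D_total > 0, length(weights) == 3)
  K6 <- zurbox$K_dna[["K_6"]]
  if (is.null(K_up)) K_up <- K6 / 4000
  if (K_up >= K6)
    stop("K_up must be below the zurbox K_6 (upstream sites are the ",
         "low-affinity tier)")
  structure(list(zurbox = zurbox, N_up = as.integer(N_up), K_up = K_up,
                 P_total = P_total, D_total = D_total,
                 weights = stats::setNames(weights, c("w0", "w1", "w2"))),
            class = "promoter_model")
}

#' Simulate the zinc-dependent activation profile of the promoter
#'
#' Solves the joint equilibrium of the Zur pool with the zurbox and
#' upstream site classes at each point of a free-zinc grid (buffered,
#' free-clamped zinc — the in-vivo regime), and returns site occupancies,
#' the zinc-saturated fraction of the whole Zur population, and the
#' expression proxy.
#'
#' @param model a \code{\link{promoter_model}}.
#' @param zinc_grid ascending grid of free zinc concentrations (M),
#'   typically log-spaced over >= 8 decades (e.g. 1e-16 to 1e-4).
#' @param opts a \code{\link{solve_options}} object.
#' @return An \code{"activation_profile"} data frame: \code{free_zinc_M},
#'   \code{theta_zurbox}, \code{theta_up}, \code{frac_PL6},
#'   \code{expression_proxy}.
#' @examples
#' pm <- promoter_model()
#' prof <- simulate_activation_profile(pm, 10^seq(-16, -8, length.out = 49))
#' @export
simulate_activation_profile <- function(model, zinc_grid,
                                        opts = solve_options()) {
  stopifnot(inherits(model, "promoter_model"))
  if (is.unsorted(zinc_grid)) stop("zinc_grid must be ascending")
  zb <- model$zurbox
  K_up_vec <- zb$K_dna * (model$K_up / zb$K_dna[["K_6"]])
  classes <- list(list(n_sites = zb$n_dna_sites, K = zb$K_dna),
                  list(n_sites = model$N_up, K = K_up_vec))
  rows <- lapply(seq_along(zinc_grid), function(j) {
    totals <- mixture_totals(model$P_total, model$D_total, zinc_grid[j],
                             zinc_mode = "free_clamped")
    sol <- tryCatch(.solve_core(zb$K_Zn, classes, totals, opts),
                    error = function(e)
                      stop("solver failed at zinc_grid[", j, "] = ",
                           zinc_grid[j], ": ", conditionMessage(e)))
    w <- sol$w; p0 <- sol$p0
    s_z <- p0 * sum(zb$K_dna * w)
    s_u <- p0 * sum(K_up_vec * w)
    th_z <- s_z / (1 + s_z)
    th_u <- s_u / (1 + s_u)
    # PL6 fraction over the entire dimer population (free + DNA-bound)
    p_free <- p0 * w
    b_z <- if (s_z > 0)
      model$D_total * zb$n_dna_sites * th_z * (zb$K_dna * p_free) / s_z
      else rep(0, 7)
    b_u <- if (s_u > 0)
      model$D_total * model$N_up * th_u * (K_up_vec * p_free) / s_u
      else rep(0, 7)
    pop <- p_free + b_z + b_u
    c(theta_zurbox = th_z, theta_up = th_u,
      frac_PL6 = as.numeric(pop[7] / sum(pop)))
  })
  out <- as.data.frame(do.call(rbind, rows))
  w <- model$weights
  out$expression_proxy <- w[["w0"]] + w[["w1"]] * out$theta_zurbox +
    w[["w2"]] * out$theta_up
  out <- cbind(free_zinc_M = zinc_grid, out)
  attr(out, "model") <- model
  class(out) <- c("activation_profile", "data.frame")
  out
}

#' Half-saturation zinc concentrations of the two tiers
#'
#' Locates, by monotone log-linear interpolation, the free zinc at which
#' each occupancy curve reaches half of its own plateau (its value at the
#' top of the grid). Under the model invariant K_up < K_6 the zurbox
#' midpoint always precedes the upstream midpoint.
#'
#' @param profile an \code{activation_profile}.
#' @return A list: \code{zurbox_mid}, \code{upstream_mid} (M free zinc)
#'   and \code{ratio} (upstream over zurbox, > 1 except in the degenerate
#'   equal-affinity case, which warns).
#' @export
phase_boundaries <- function(profile) {
  stopifnot(inherits(profile, "activation_profile"))
  mid_of <- function(theta, what) {
    plateau <- theta[length(theta)]
    half <- plateau / 2
    if (plateau <= 0 || theta[1] > half)
      stop(what, " transition not bracketed by the profile grid")
    i <- findInterval(half, theta)  # theta non-decreasing
    if (i >= length(theta))
      stop(what, " transition not bracketed by the profile grid")
    lz <- log10(profile$free_zinc_M)
    10^(lz[i] + (half - theta[i]) / (theta[i + 1] - theta[i]) *
          (lz[i + 1] - lz[i]))
  }
  zb <- mid_of(profile$theta_zurbox, "zurbox")
  up <- mid_of(profile$theta_up, "upstream")
  if (abs(log(up / zb)) < 1e-8)
    warning("zurbox and upstream midpoints coincide (degenerate ",
            "equal-affinity profile)")
  list(zurbox_mid = zb, upstream_mid = up, ratio = up / zb)
}
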