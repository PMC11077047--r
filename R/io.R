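#' File formats
#'
#' All tables are plain CSV with a header row, '.' decimal separator and
#' concentrations in molar units. Numbers are written with 12 significant
#' digits, so write/read round trips are lossless to float-formatting
#' precision.
#'
#' @name zurlink-io
NULL

.write_csv12 <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- signif(out[[j]], 12)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.read_csv_checked <- function(path, required, optional = character(),
                              what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = TRUE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(what, " file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- c(required, intersect(optional, names(df)))
  df <- df[keep]
  for (nm in keep) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))
      stop(what, " file ", path, ": column '", nm,
           "' has non-numeric value(s) at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    if (anyNA(v))
      stop(what, " file ", path, ": column '", nm, "' has missing ",
           "value(s) at row(s) ",
           paste(utils::head(which(is.na(v)), 5), collapse = ", "))
  }
  df
}

#' @describeIn zurlink-io write an isotherm (columns \code{injection},
#'   \code{inj_volume_L}, \code{molar_ratio}, \code{ndh_kcal_per_mol}).
#' @param x object to write.
#' @param path file path.
#' @export
write_isotherm_csv <- function(x, path) {
  stopifnot(all(c("injection", "inj_volume_L", "molar_ratio",
                  "ndh_kcal_per_mol") %in% names(x)))
  .write_csv12(as.data.frame(x)[c("injection", "inj_volume_L",
                                  "molar_ratio", "ndh_kcal_per_mol")],
               path)
}

#' @describeIn zurlink-io read an isotherm; errors name any missing or
#'   malformed column and reject non-increasing molar ratios.
#' @export
read_isotherm_csv <- function(path) {
  df <- .read_csv_checked(path, c("injection", "inj_volume_L",
                                  "molar_ratio", "ndh_kcal_per_mol"),
                          what = "isotherm")
  if (any(diff(df$molar_ratio) <= 0))
    stop("isotherm file ", path, ": molar_ratio must be strictly ",
         "increasing (first violation after row ",
         which(diff(df$molar_ratio) <= 0)[1], ")")
  class(df) <- c("isotherm", "data.frame")
  df
}

#' @describeIn zurlink-io write a band-fraction table (columns
#'   \code{p_total_M}, \code{f_free}, \code{f_2to1}, \code{f_3to1},
#'   optional \code{f_1to1}, \code{sigma}).
#' @export
write_band_table_csv <- function(x, path) {
  cols <- c("p_total_M", "f_free",
            intersect("f_1to1", names(x)), "f_2to1", "f_3to1",
            intersect("sigma", names(x)))
  stopifnot(all(c("p_total_M", "f_free", "f_2to1", "f_3to1") %in%
                  names(x)))
  .write_csv12(as.data.frame(x)[cols], path)
}

#' @describeIn zurlink-io read a band-fraction table; fractions must lie
#'   in [0, 1] and each row of listed fractions must sum to 1 within 1e-6.
#' @param D_total DNA concentration (M) to attach to the table.
#' @export
read_band_table_csv <- function(path, D_total = NULL) {
  df <- .read_csv_checked(path, c("p_total_M", "f_free", "f_2to1",
                                  "f_3to1"), c("f_1to1", "sigma"),
                          what = "band-fraction")
  fcols <- intersect(c("f_free", "f_1to1", "f_2to1", "f_3to1"), names(df))
  fr <- as.matrix(df[fcols])
  if (any(fr < 0 | fr > 1))
    stop("band-fraction file ", path, ": fractions outside [0, 1] at ",
         "row(s) ", paste(utils::head(which(rowSums(fr < 0 | fr > 1) > 0),
                                      5), collapse = ", "))
  bad <- which(abs(rowSums(fr) - 1) > 1e-6)
  if (length(bad))
    stop("band-fraction file ", path, ": fractions do not sum to 1 at ",
         "row(s) ", paste(utils::head(bad, 5), collapse = ", "))
  attr(df, "D_total") <- D_total
  class(df) <- c("band_fraction_table", "data.frame")
  df
}

#' @describeIn zurlink-io write a population table (zinc- or
#'   protein-titration DNA species fractions) or an activation profile.
#' @export
write_population_csv <- function(x, path) .write_csv12(x, path)

#' @describeIn zurlink-io read a population table written by
#'   \code{write_population_csv}.
#' @export
read_population_csv <- function(path) {
  df <- utils::read.csv(path)
  axis <- intersect(c("zinc_total_M", "molar_ratio", "free_zinc_M"),
                    names(df))
  if (!length(axis))
    stop("population file ", path, " is missing its axis column ",
         "(zinc_total_M, molar_ratio or free_zinc_M)")
  df
}

#' @describeIn zurlink-io serialize an ITC fit to JSON (parameter names
#'   \code{n}, \code{K_Minv}, \code{dH_kcal_per_mol}, \code{se_*},
#'   \code{rss}, \code{converged}).
#' @param fit an \code{itc_fit} object.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "itc_fit"))
  p <- as.list(fit$parameters)
  rename <- c(K = "K_Minv", K4 = "K4_Minv", dH = "dH_kcal_per_mol")
  names(p) <- ifelse(names(p) %in% names(rename),
                     rename[names(p)], names(p))
  se <- as.list(fit$se)
  names(se) <- paste0("se_", ifelse(names(se) %in% names(rename),
                                    rename[names(se)], names(se)))
  jsonlite::write_json(c(list(variant = fit$variant), p, se,
                         list(rss = fit$rss, converged = fit$converged)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @describeIn zurlink-io read a fit-result JSON back into a list.
#' @export
read_fit_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

# --- run configuration --------------------------------------------------

.promoter_presets <- list(
  znuA = list(n_dna_sites = 2, K_4 = 8.7e5),
  zitB = list(n_dna_sites = 3, K_4 = 1.8e6))

#' Named promoter shortcuts
#'
#' The two promoter probes with their fitted single-class constants:
#' \code{znuA} (two dimer-sites, K_4 = 8.7e5 M^-1) and \code{zitB} (three
#' dimer-sites, K_4 = 1.8e6 M^-1).
#'
#' @param promoter \code{"znuA"} or \code{"zitB"}.
#' @param K6_ratio K_6 as a multiple of K_4 (defaults: the ratios at which
#'   the oligomeric complex becomes predominant, 700 for znuA and 4000 for
#'   zitB).
#' @param K_Zn per-site zinc constant (M^-1); default the intrinsic value
#'   2.3e13 (no chelator present in the gel buffer).
#' @return A \code{\link{linkage_params}} object.
#' @export
promoter_params <- function(promoter = c("znuA", "zitB"), K6_ratio = NULL,
                            K_Zn = 2.3e13) {
  promoter <- match.arg(promoter)
  p <- .promoter_presets[[promoter]]
  if (is.null(K6_ratio))
    K6_ratio <- if (promoter == "znuA") 700 else 4000
  linkage_params(K_Zn = K_Zn, K_4 = p$K_4, K_6 = K6_ratio * p$K_4,
                 n_dna_sites = p$n_dna_sites)
}

.config_schema <- list(
  model = c("type", "promoter", "K_Zn", "K_4", "K_6", "K_low", "K_dna",
            "n_dna_sites", "n", "K", "dH", "K_int", "dH_int", "K_chel",
            "dH_chel", "zinc_equivalents"),
  protocol = c("syringe_conc", "cell_conc", "injection_volumes", "V0",
               "chelator_conc", "temperature", "discard_first"),
  solver = c("rel_tol", "max_iter", "log_bracket_width"),
  noise = c("sigma_ndh", "sigma_fraction", "seed"),
  output = c("dir", "prefix"))

#' Read and validate a run configuration (YAML or JSON)
#'
#' The configuration has up to five sections — \code{model},
#' \code{protocol}, \code{solver}, \code{noise}, \code{output} — with a
#' fixed vocabulary of keys. Unknown sections or keys are rejected with a
#' message naming them, and elementary physical constraints (positive
#' association constants, non-negative concentrations) are checked before
#' any computation.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return The validated configuration as a nested list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("config must be .yaml/.yml or .json: ", path)
  unknown_sections <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown_sections))
    stop("unknown config section(s): ",
         paste(unknown_sections, collapse = ", "))
  for (sec in names(cfg)) {
    unknown <- setdiff(names(cfg[[sec]]), .config_schema[[sec]])
    if (length(unknown))
      stop("unknown key(s) in config section '", sec, "': ",
           paste(unknown, collapse = ", "))
  }
  m <- cfg$model
  for (kk in intersect(c("K_Zn", "K_4", "K_6", "K", "K_int", "K_chel"),
                       names(m)))
    if (!is.numeric(m[[kk]]) || any(m[[kk]] <= 0))
      stop("config model$", kk, " must be a positive number")
  pr <- cfg$protocol
  for (kk in intersect(c("syringe_conc", "cell_conc", "chelator_conc",
                         "V0"), names(pr)))
    if (!is.numeric(pr[[kk]]) || any(pr[[kk]] < 0))
      stop("config protocol$", kk, " must be non-negative")
  cfg
}
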