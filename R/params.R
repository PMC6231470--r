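#' Default log-scale trait baselines
#'
#' Baseline (control) trait values on the natural log scale, per trait and
#' sampling point, for a mid-salinity population. Values are in the units of
#' the measurement protocol: egg diameter and standard length in mm,
#' yolk-sac area to length ratio in mm, weight in g, HSI in percent.
#'
#' @return A tibble with columns `trait`, `point`, `log_mean`.
#' @export
default_baselines <- function() {
  out <- tibble::tribble(
    ~trait,         ~point,  ~log_mean,
    "egg_diameter", "egg",   log(1.5),
    "yolk_ratio",   "hatch", log(0.45),
    "SDL",          "dph12", log(8),
    "weight",       "dph12", log(0.004),
    "SDL",          "dph30", log(14),
    "weight",       "dph30", log(0.04),
    "HSI",          "dph30", log(2.5),
    "SDL",          "dph90", log(35),
    "weight",       "dph90", log(0.45),
    "HSI",          "dph90", log(3.2)
  )
  out$trait <- factor(out$trait, levels = .tgp_traits)
  out$point <- factor(out$point, levels = .tgp_points)
  out
}

# Canonicalise an effect specification to a 2x2 matrix
# rows = direction (increased/decreased), cols = stage (early/late).
# Accepted inputs: scalar; direction-named vector; list(early =, late =).
.effect_matrix <- function(x, what) {
  m <- matrix(0, 2, 2, dimnames = list(.tgp_directions, .tgp_stages))
  fill_dir <- function(v) {
    if (length(v) == 1 && is.null(names(v))) return(c(increased = unname(v), decreased = unname(v)))
    if (!all(names(v) %in% .tgp_directions)) {
      stop(what, ": direction names must be 'increased'/'decreased'")
    }
    out <- c(increased = 0, decreased = 0)
    out[names(v)] <- v
    out
  }
  if (is.list(x)) {
    if (!all(names(x) %in% .tgp_stages)) stop(what, ": stage names must be 'early'/'late'")
    for (s in names(x)) m[, s] <- fill_dir(x[[s]])
  } else {
    v <- fill_dir(x)
    m[, "early"] <- v
    m[, "late"] <- v
  }
  m
}

.dir_vec <- function(x, what) {
  if (length(x) == 1 && is.null(names(x))) return(c(increased = unname(x), decreased = unname(x)))
  if (!all(names(x) %in% .tgp_directions)) {
    stop(what, ": names must be 'increased'/'decreased'")
  }
  out <- c(increased = 0, decreased = 0)
  out[names(x)] <- x
  out
}

#' Simulation parameters for the synthetic split-clutch experiment
#'
#' Bundles every tunable of the generator. Treatment effects act additively
#' on the log scale of each trait, so a coefficient of -0.1 is roughly a 10%
#' trait reduction and equals the expected contribution to lnR. Effects may
#' differ between salinity directions and life stages: each of
#' `alpha_parental`, `beta_offspring`, `gamma_interaction` accepts a scalar,
#' a vector named by direction (`increased`, `decreased`), or a list named by
#' stage (`early`, `late`) of such vectors.
#'
#' The defaults encode the study conditions the package is designed to
#' emulate: negative carry-over and offspring effects under increased
#' salinity that persist into the late stage, a positive offspring effect of
#' decreased salinity that fades after the early stage (compensatory
#' growth), strongly elevated mortality between hatch and 30 dph under
#' increased salinity, and size-selective survival (`lambda_size` > 0) so
#' that mortality truncates the lower tail of the size distribution.
#'
#' @param baselines Tibble of log-scale baselines per (trait, point); see
#'   [default_baselines()].
#' @param alpha_parental Carry-over effect of parental treatment on offspring
#'   log traits.
#' @param beta_offspring Effect of the offspring's own environment.
#' @param gamma_interaction Parental x offspring interaction (adaptive TGP if
#'   it raises fitness in matched environments; negative = nonadaptive).
#' @param sd_crossing,sd_tank,sd_chamber,sd_residual Standard deviations of
#'   the Gaussian random effects (log scale): family (crossing), tank,
#'   climate chamber, and residual measurement error.
#' @param size_loading Loading of the individual's latent size z-score on
#'   every log trait; links trait values to size-selective mortality.
#' @param base_survival Named per-interval baseline survival probabilities
#'   for a control fish of average latent size, intervals `egg_hatch`,
#'   `hatch_dph12`, `dph12_dph30`, `dph30_dph90`.
#' @param hazard_offspring_env,hazard_parental_env Additive shifts on the
#'   per-interval survival log-odds for fish whose offspring (resp.
#'   parental) environment is the treatment; named by direction.
#' @param lambda_size Survival log-odds per standard deviation of latent
#'   size; 0 disables size-selective mortality.
#' @param n_families Optional integer overriding the design's per-cell
#'   family counts.
#' @param n_per_family Offspring stocked per family within each cell.
#' @param n_tanks_per_cell Rearing tanks per treatment cell; families are
#'   split across tanks.
#' @param n_measured Named vector, fish measured per treatment group at each
#'   sampling point (drawn without replacement from survivors); `Inf`
#'   measures every survivor. Defaults follow the reference protocol's
#'   average N per treatment group.
#' @param seed Integer RNG seed; the generator is fully reproducible.
#' @return A list of class `tgp_params`.
#' @export
#' @examples
#' p <- sim_params(seed = 42)
#' p$alpha_parental
sim_params <- function(baselines = default_baselines(),
                       alpha_parental = list(
                         early = c(increased = -0.06, decreased = 0.02),
                         late = c(increased = -0.007, decreased = 0)
                       ),
                       beta_offspring = list(
                         early = c(increased = -0.12, decreased = 0.08),
                         late = c(increased = -0.036, decreased = 0)
                       ),
                       gamma_interaction = list(
                         early = c(increased = -0.05, decreased = 0),
                         late = c(increased = -0.003, decreased = 0)
                       ),
                       sd_crossing = 0.01,
                       sd_tank = 0.01,
                       sd_chamber = 0.005,
                       sd_residual = 0.12,
                       size_loading = 0.07,
                       base_survival = c(egg_hatch = 0.95, hatch_dph12 = 0.90,
                                         dph12_dph30 = 0.85, dph30_dph90 = 0.96),
                       hazard_offspring_env = c(increased = -1.6, decreased = 0.4),
                       hazard_parental_env = c(increased = -0.5, decreased = 0),
                       lambda_size = 1.0,
                       n_families = NULL,
                       n_per_family = 30,
                       n_tanks_per_cell = 3,
                       n_measured = c(egg = 108, hatch = 87, dph12 = 50,
                                      dph30 = 31, dph90 = 56),
                       seed = 1) {
  stopifnot(is.data.frame(baselines),
            all(c("trait", "point", "log_mean") %in% names(baselines)))
  sds <- c(sd_crossing = sd_crossing, sd_tank = sd_tank,
           sd_chamber = sd_chamber, sd_residual = sd_residual)
  if (any(sds < 0)) stop("random-effect standard deviations must be >= 0")
  if (any(base_survival <= 0) || any(base_survival > 1)) {
    stop("base_survival probabilities must lie in (0, 1]")
  }
  if (!all(c("egg_hatch", "hatch_dph12", "dph12_dph30", "dph30_dph90") %in%
             names(base_survival))) {
    stop("base_survival must name all four sampling intervals")
  }
  if (n_per_family < 1 || n_tanks_per_cell < 1) {
    stop("n_per_family and n_tanks_per_cell must be >= 1")
  }
  if (!all(.tgp_points %in% names(n_measured))) {
    stop("n_measured must name all five sampling points")
  }
  structure(list(
    baselines = baselines,
    alpha_parental = .effect_matrix(alpha_parental, "alpha_parental"),
    beta_offspring = .effect_matrix(beta_offspring, "beta_offspring"),
    gamma_interaction = .effect_matrix(gamma_interaction, "gamma_interaction"),
    sd_crossing = sd_crossing, sd_tank = sd_tank,
    sd_chamber = sd_chamber, sd_residual = sd_residual,
    size_loading = size_loading,
    base_survival = base_survival[c("egg_hatch", "hatch_dph12",
                                    "dph12_dph30", "dph30_dph90")],
    hazard_offspring_env = .dir_vec(hazard_offspring_env, "hazard_offspring_env"),
    hazard_parental_env = .dir_vec(hazard_parental_env, "hazard_parental_env"),
    lambda_size = lambda_size,
    n_families = n_families,
    n_per_family = as.integer(n_per_family),
    n_tanks_per_cell = as.integer(n_tanks_per_cell),
    n_measured = n_measured[.tgp_points],
    seed = as.integer(seed)
  ), class = "tgp_params")
}

#' Null simulation parameters
#'
#' Convenience wrapper: all treatment effects, hazard shifts and
#' size-selectivity set to zero, so traits differ between cells only through
#' random effects and every fish survives with the baseline probabilities.
#'
#' @param ... Overrides passed on to [sim_params()].
#' @return A `tgp_params` object.
#' @export
null_params <- function(...) {
  defaults <- list(
    alpha_parental = 0, beta_offspring = 0, gamma_interaction = 0,
    hazard_offspring_env = 0, hazard_parental_env = 0, lambda_size = 0
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}

#' @export
print.tgp_params <- function(x, ...) {
  cat("<tgp_params>\n")
  cat("  effects (increased dir, early/late): alpha",
      paste(signif(x$alpha_parental["increased", ], 3), collapse = "/"),
      " beta", paste(signif(x$beta_offspring["increased", ], 3), collapse = "/"),
      " gamma", paste(signif(x$gamma_interaction["increased", ], 3), collapse = "/"), "\n")
  cat("  random-effect sds:", x$sd_crossing, x$sd_tank, x$sd_chamber, x$sd_residual, "\n")
  cat("  size_loading:", x$size_loading, " lambda_size:", x$lambda_size, "\n")
  cat("  base survival:", paste(x$base_survival, collapse = ", "), "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}
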