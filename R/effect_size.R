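#' Log response ratio
#'
#' `lnR = ln(x_t / x_c)`, the natural log of the ratio of the treatment-group
#' mean to the control-group mean. Positive values indicate increased
#' condition/fitness relative to control, negative values decreased.
#'
#' @param x_t,x_c Positive treatment- and control-group means (natural
#'   scale); vectors recycle.
#' @return Numeric vector of dimensionless effect sizes.
#' @export
#' @examples
#' compute_lnr(1.2, 1.0) # log(1.2)
compute_lnr <- function(x_t, x_c) {
  if (any(!is.finite(x_t)) || any(!is.finite(x_c)) ||
      any(x_t <= 0) || any(x_c <= 0)) {
    stop("group means must be positive and finite")
  }
  log(x_t / x_c)
}

#' Replicate means within one treatment group
#'
#' Averages trait values within a treatment group per tank and crossing,
#' the replication unit from which the group mean entering lnR is computed.
#'
#' @param measurements Measurement table (or `tgp_experiment`).
#' @param trait,point Trait and sampling-point labels.
#' @param population,experiment,mode Cell coordinates; `experiment` is
#'   ignored (with `NA` matching) for the shared C-C control.
#' @return Numeric vector with one mean per (tank x crossing) combination
#'   holding at least one measurement; empty (with a warning) if nothing was
#'   measured.
#' @export
replicate_means <- function(measurements, population, experiment, mode, trait, point) {
  meas <- as_measurements(measurements)
  sel <- meas$population == population & meas$mode == mode &
    meas$trait == trait & meas$point == point
  if (!identical(mode, "C-C")) sel <- sel & meas$experiment %in% experiment
  sub <- meas[sel & !is.na(sel), , drop = FALSE]
  if (nrow(sub) == 0) {
    warning("no measurements for ", population, " ", mode, " ", trait, " @ ", point)
    return(numeric(0))
  }
  out <- sub |>
    dplyr::group_by(.data$tank, .data$crossing) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop")
  out$m
}

# Group means per cell x point x trait: mean over (tank x crossing) means.
.group_means <- function(meas) {
  meas |>
    dplyr::group_by(.data$population, .data$experiment, .data$mode,
                    .data$direction, .data$point, .data$life_stage,
                    .data$trait, .data$tank, .data$crossing) |>
    dplyr::summarise(m = mean(.data$value), .groups = "drop") |>
    dplyr::group_by(.data$population, .data$experiment, .data$mode,
                    .data$direction, .data$point, .data$life_stage,
                    .data$trait) |>
    dplyr::summarise(x = mean(.data$m), n_replicates = dplyr::n(),
                     .groups = "drop")
}

#' Build the lnR effect-size table
#'
#' Computes one log response ratio per (experiment x acclimation mode x
#' trait x sampling point): trait values are first averaged within each
#' treatment group per tank and crossing, those replicate means are averaged
#' to a single group mean, and each treatment group's mean is divided by the
#' mean of its population's shared C-C control measured at the same trait
#' and point. Rows carry the meta-analysis factors: population, salinity
#' direction, acclimation mode, life stage and trait.
#'
#' On the complete reference design (3 populations x 2 experiments x 3 modes
#' x 10 trait-point combinations) the table has 180 rows: 72 early and 108
#' late.
#'
#' @param x A `tgp_experiment` or a tidy measurement table with columns
#'   `population`, `experiment`, `mode`, `direction`, `crossing`, `tank`,
#'   `point`, `life_stage`, `trait`, `value`.
#' @return A tibble of class `tgp_effect_table`: `population`, `experiment`,
#'   `salinity` (direction factor), `mode` (T-C/C-T/T-T), `trait`, `point`,
#'   `life_stage`, `x_t`, `x_c`, `n_t`, `n_c`, `ln_r`.
#' @export
#' @examples
#' sim <- simulate_experiment(params = sim_params(seed = 1))
#' eff <- build_effect_table(sim)
#' nrow(eff) # 180
build_effect_table <- function(x) {
  meas <- as_measurements(x)
  gm <- .group_means(meas)
  controls <- gm[gm$mode == "C-C", c("population", "point", "trait", "x", "n_replicates")]
  names(controls)[names(controls) == "x"] <- "x_c"
  names(controls)[names(controls) == "n_replicates"] <- "n_c"
  if (nrow(controls) == 0) stop("no C-C control measurements in the data")
  treat <- gm[gm$mode != "C-C", , drop = FALSE]
  pops_missing <- setdiff(unique(treat$population), unique(controls$population))
  if (length(pops_missing)) {
    stop("missing C-C control cell for population(s): ",
         paste(pops_missing, collapse = ", "))
  }
  tab <- dplyr::inner_join(treat, controls, by = c("population", "point", "trait"))
  dropped <- nrow(treat) - nrow(tab)
  if (dropped > 0) {
    message(dropped, " treatment group mean(s) had no matching control mean; rows omitted")
  }
  out <- tibble::tibble(
    population = factor(tab$population, levels = sort(unique(gm$population))),
    experiment = tab$experiment,
    salinity = factor(tab$direction, levels = .tgp_directions),
    mode = factor(as.character(tab$mode), levels = setdiff(.tgp_modes, "C-C")),
    trait = factor(as.character(tab$trait), levels = .tgp_traits),
    point = tab$point,
    life_stage = tab$life_stage,
    x_t = tab$x,
    x_c = tab$x_c,
    n_t = tab$n_replicates,
    n_c = tab$n_c,
    ln_r = compute_lnr(tab$x, tab$x_c)
  )
  out <- dplyr::arrange(out, .data$population, .data$experiment, .data$mode,
                        .data$point, .data$trait)
  class(out) <- c("tgp_effect_table", class(out))
  out
}
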