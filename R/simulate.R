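#' Simulate a split-clutch two-generation salinity experiment
#'
#' Generates individual-level data with the hierarchical structure the
#' downstream analysis assumes. Traits are lognormal: each measurement is
#' `exp(baseline + treatment effects + crossing + tank + chamber +
#' size_loading * latent_size + residual)`, with all terms on the log scale,
#' so the expected log trait of cell (p, o) is
#' `baseline + alpha * [p = T] + beta * [o = T] + gamma * [p = T & o = T]`.
#' Families (crossings) are split across the offspring environments of their
#' experiment and across tanks (split-clutch design): C-C and C-T share the
#' population's control-parent families, T-C and T-T the experiment's
#' treatment-parent families. Mortality acts between consecutive sampling
#' points with per-interval survival log-odds
#' `qlogis(base_survival) + hazard terms + lambda_size * latent_size`, so a
#' positive `lambda_size` makes death size-selective. At each sampling point
#' a subsample of survivors per treatment group is measured for the traits
#' scheduled at that point.
#'
#' @param design Treatment-cell table from [enumerate_design()].
#' @param params Parameter bundle from [sim_params()].
#' @return An object of class `tgp_experiment`: a list with elements
#'   `design`, `params`, `individuals` (one row per fish, with survival
#'   indicator columns `alive_egg` ... `alive_dph90`) and `measurements`
#'   (tidy long table, one row per fish x sampling point x measured trait).
#' @export
#' @examples
#' sim <- simulate_experiment(enumerate_design(), sim_params(seed = 7))
#' sim
simulate_experiment <- function(design = enumerate_design(), params = sim_params()) {
  stopifnot(inherits(params, "tgp_params"))
  if (!is.data.frame(design) || nrow(design) == 0) stop("`design` must be a non-empty cell table")
  req <- c("population", "experiment", "mode", "parental_env", "offspring_env",
           "direction", "offspring_psu", "n_families")
  if (!all(req %in% names(design))) {
    stop("`design` lacks columns: ", paste(setdiff(req, names(design)), collapse = ", "))
  }
  set.seed(params$seed)

  cells <- design
  if (!is.null(params$n_families)) cells$n_families <- as.integer(params$n_families)
  if (any(cells$n_families < 1)) stop("treatment cell with zero families")
  cells <- dplyr::arrange(cells, .data$population,
                          dplyr::coalesce(.data$experiment, ""), .data$mode)
  cells$mode <- factor(as.character(cells$mode), levels = .tgp_modes)

  n_tank <- params$n_tanks_per_cell
  npf <- params$n_per_family

  ind <- purrr::map_dfr(seq_len(nrow(cells)), function(i) {
    cc <- cells[i, ]
    fam <- rep(seq_len(cc$n_families), each = npf)
    within_fam <- rep(seq_len(npf), times = cc$n_families)
    crossing <- if (cc$parental_env == "C") {
      sprintf("%s_C_f%02d", cc$population, fam)
    } else {
      sprintf("%s_T_f%02d", cc$experiment, fam)
    }
    tibble::tibble(
      population = cc$population,
      experiment = cc$experiment,
      mode = cc$mode,
      parental_env = cc$parental_env,
      offspring_env = cc$offspring_env,
      direction = cc$direction,
      crossing = crossing,
      tank = sprintf("%s_%s_%s_t%d", cc$population,
                     dplyr::coalesce(cc$experiment, "CC"), cc$mode,
                     ((within_fam - 1L) %% n_tank) + 1L),
      chamber = sprintf("%s_%gpsu", cc$population, cc$offspring_psu)
    )
  })
  n <- nrow(ind)
  ind$individual_id <- sprintf("i%06d", seq_len(n))
  ind$latent_size <- rnorm(n)

  u_cross <- setNames(rnorm(length(unique(ind$crossing)), 0, params$sd_crossing),
                      sort(unique(ind$crossing)))
  u_tank <- setNames(rnorm(length(unique(ind$tank)), 0, params$sd_tank),
                     sort(unique(ind$tank)))
  u_chamber <- setNames(rnorm(length(unique(ind$chamber)), 0, params$sd_chamber),
                        sort(unique(ind$chamber)))

  treated <- ind$mode != "C-C"
  dir <- ifelse(treated, ind$direction, "increased") # placeholder for C-C, zeroed below
  h_off <- ifelse(treated & ind$offspring_env == "T",
                  params$hazard_offspring_env[dir], 0)
  h_par <- ifelse(treated & ind$parental_env == "T",
                  params$hazard_parental_env[dir], 0)

  alive <- matrix(TRUE, n, 5, dimnames = list(NULL, .tgp_points))
  for (k in 1:4) {
    eta <- qlogis(params$base_survival[k]) + h_off + h_par +
      params$lambda_size * ind$latent_size
    surv <- rbinom(n, 1L, plogis(eta)) == 1L
    alive[, k + 1] <- alive[, k] & surv
  }
  ind$alive_egg <- alive[, "egg"]
  ind$alive_hatch <- alive[, "hatch"]
  ind$alive_dph12 <- alive[, "dph12"]
  ind$alive_dph30 <- alive[, "dph30"]
  ind$alive_dph90 <- alive[, "dph90"]

  # Fixed effect on the log trait per individual and life stage
  eff_stage <- function(stage) {
    out <- numeric(n)
    tt <- which(treated)
    d <- ind$direction[tt]
    out[tt] <- params$alpha_parental[cbind(d, stage)] * (ind$parental_env[tt] == "T") +
      params$beta_offspring[cbind(d, stage)] * (ind$offspring_env[tt] == "T") +
      params$gamma_interaction[cbind(d, stage)] *
        (ind$parental_env[tt] == "T" & ind$offspring_env[tt] == "T")
    out
  }
  eff <- cbind(early = eff_stage("early"), late = eff_stage("late"))

  sched <- sampling_schedule()
  tsched <- trait_schedule()
  base_lookup <- params$baselines
  cell_key <- paste(ind$population, dplyr::coalesce(ind$experiment, "CC"), ind$mode)

  meas_list <- list()
  for (j in seq_len(nrow(sched))) {
    pt <- as.character(sched$point[j])
    stage <- as.character(sched$life_stage[j])
    cap <- params$n_measured[[pt]]
    alive_j <- which(alive[, pt])
    picked <- unlist(lapply(split(alive_j, cell_key[alive_j]), function(idx) {
      if (length(idx) <= cap) idx else sample(idx, cap)
    }), use.names = FALSE)
    if (length(picked) == 0) next
    traits_j <- as.character(tsched$trait[tsched$point == pt])
    for (tr in traits_j) {
      mu0 <- base_lookup$log_mean[base_lookup$trait == tr & base_lookup$point == pt]
      if (length(mu0) != 1) stop("no baseline for trait ", tr, " at point ", pt)
      mu <- mu0 + eff[picked, stage] +
        u_cross[ind$crossing[picked]] + u_tank[ind$tank[picked]] +
        u_chamber[ind$chamber[picked]] +
        params$size_loading * ind$latent_size[picked] +
        rnorm(length(picked), 0, params$sd_residual)
      meas_list[[length(meas_list) + 1]] <- tibble::tibble(
        individual_id = ind$individual_id[picked],
        population = ind$population[picked],
        experiment = ind$experiment[picked],
        mode = ind$mode[picked],
        parental_env = ind$parental_env[picked],
        offspring_env = ind$offspring_env[picked],
        direction = ind$direction[picked],
        crossing = ind$crossing[picked],
        tank = ind$tank[picked],
        chamber = ind$chamber[picked],
        point = pt,
        age_dph = sched$age_dph[j],
        life_stage = stage,
        trait = tr,
        value = exp(mu)
      )
    }
  }
  meas <- dplyr::bind_rows(meas_list)
  meas$point <- factor(meas$point, levels = .tgp_points)
  meas$trait <- factor(meas$trait, levels = .tgp_traits)
  meas$life_stage <- factor(meas$life_stage, levels = .tgp_stages)
  meas$mode <- factor(as.character(meas$mode), levels = .tgp_modes)
  meas <- dplyr::arrange(meas, .data$population,
                         dplyr::coalesce(.data$experiment, ""), .data$mode,
                         .data$point, .data$trait, .data$individual_id)

  structure(list(design = cells, params = params,
                 individuals = ind, measurements = meas),
            class = "tgp_experiment")
}

#' @export
print.tgp_experiment <- function(x, ...) {
  cat("<tgp_experiment>\n")
  cat(" ", nrow(x$design), "treatment cells,", nrow(x$individuals), "individuals,",
      nrow(x$measurements), "measurements\n")
  cat("  overall survival to 90 dph:",
      signif(mean(x$individuals$alive_dph90), 3), "\n")
  invisible(x)
}

# Accept either a tgp_experiment or a raw measurement table.
as_measurements <- function(x) {
  if (inherits(x, "tgp_experiment")) return(x$measurements)
  stopifnot(is.data.frame(x))
  x
}

#' Hepatosomatic index
#'
#' `HSI = 100 * liver_weight / total_weight`, a percentage proxy for liver
#' glycogen energy reserves.
#'
#' @param liver_weight,total_weight Masses in the same unit; vectors recycle.
#' @return Numeric vector of HSI values in percent.
#' @export
#' @examples
#' derive_hsi(0.02, 1.0) # 2
derive_hsi <- function(liver_weight, total_weight) {
  if (any(total_weight <= 0)) stop("total_weight must be positive")
  if (any(liver_weight < 0)) stop("liver_weight must be non-negative")
  if (any(liver_weight > total_weight)) stop("liver_weight exceeds total_weight")
  100 * liver_weight / total_weight
}

#' Yolk-sac size to length ratio
#'
#' Yolk sac area (mm^2) divided by larval length (mm).
#'
#' @param yolk_area Yolk sac area in mm^2, non-negative.
#' @param length Larval length in mm, positive.
#' @return Numeric vector (mm).
#' @export
#' @examples
#' derive_yolk_ratio(1.5, 3) # 0.5
derive_yolk_ratio <- function(yolk_area, length) {
  if (any(length <= 0)) stop("length must be positive")
  if (any(yolk_area < 0)) stop("yolk_area must be non-negative")
  yolk_area / length
}

#' Per-tank survival at a sampling point
#'
#' Mortality is analysed per tank as a ratio of alive vs dead fish. Counts
#' every stocked fish of a tank as alive or dead at the given sampling
#' point.
#'
#' @param x A `tgp_experiment` or its `individuals` table.
#' @param point Sampling point label (`"egg"` ... `"dph90"`).
#' @param by Grouping below the treatment cell: `"tank"` (default) or
#'   `c("tank", "crossing")` for the tank-by-family counts used by the
#'   survival GLMM.
#' @return A tibble with the cell coordinates, grouping columns, `stocked`,
#'   `alive`, `dead` and `rate`.
#' @export
tank_survival <- function(x, point = "dph30", by = "tank") {
  ind <- if (inherits(x, "tgp_experiment")) x$individuals else x
  point <- match.arg(point, .tgp_points)
  stopifnot(all(by %in% c("tank", "crossing")))
  alive_col <- paste0("alive_", point)
  if (!alive_col %in% names(ind)) stop("no survival column for point ", point)
  out <- ind |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c("population", "experiment", "mode", "parental_env", "offspring_env",
        "direction", "chamber", by)
    ))) |>
    dplyr::summarise(
      stocked = dplyr::n(),
      alive = sum(.data[[alive_col]]),
      dead = .data$stocked - .data$alive,
      rate = ifelse(.data$stocked > 0, .data$alive / .data$stocked, NA_real_),
      .groups = "drop"
    )
  if (any(out$stocked == 0)) warning("empty tank: survival rate undefined")
  out$point <- factor(point, levels = .tgp_points)
  out
}

#' Per-treatment-group survival rates at each sampling point
#'
#' Survival rate of every treatment group (cell) at every sampling point;
#' the input to the truncation-selection thresholds.
#'
#' @param x A `tgp_experiment` or its `individuals` table.
#' @return A tibble with `population`, `experiment`, `mode`, `direction`,
#'   `point`, `stocked`, `alive`, `rate`.
#' @export
group_survival <- function(x) {
  ind <- if (inherits(x, "tgp_experiment")) x$individuals else x
  purrr::map_dfr(.tgp_points, function(pt) {
    alive_col <- paste0("alive_", pt)
    ind |>
      dplyr::group_by(.data$population, .data$experiment, .data$mode,
                      .data$direction) |>
      dplyr::summarise(
        stocked = dplyr::n(),
        alive = sum(.data[[alive_col]]),
        rate = .data$alive / .data$stocked,
        .groups = "drop"
      ) |>
      dplyr::mutate(point = factor(pt, levels = .tgp_points), .before = "stocked")
  })
}
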