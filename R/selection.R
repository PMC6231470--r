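#' The nine counterfactual selection scenarios
#'
#' Grid of three selection strengths (weak/moderate/strong survival
#' thresholds) by three removal directions: `random` (uniform removal,
#' replicated), `small` (remove the largest values, selecting for small) and
#' `large` (remove the smallest values, selecting for large).
#'
#' @param n_random_replicates Replicates for the `random` direction
#'   (default 300); directed scenarios are deterministic and run once.
#' @return Tibble with `scenario`, `strength`, `direction`, `n_replicates`.
#' @export
selection_scenarios <- function(n_random_replicates = 300) {
  grid <- tidyr::expand_grid(
    strength = factor(c("weak", "moderate", "strong"),
                      levels = c("weak", "moderate", "strong")),
    direction = factor(c("random", "small", "large"),
                       levels = c("random", "small", "large"))
  )
  grid$scenario <- paste(grid$strength, grid$direction, sep = "-")
  grid$n_replicates <- ifelse(grid$direction == "random",
                              as.integer(n_random_replicates), 1L)
  grid[, c("scenario", "strength", "direction", "n_replicates")]
}

#' Survival thresholds for the selection strengths
#'
#' For each sampling point, the threshold survival rate to which
#' higher-surviving groups are reduced: `weak` is the upper quartile of the
#' group survival rates, `moderate` their mean, `strong` the lower quartile.
#' Quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7); the convention is recorded in the output.
#' Because the mean of a skewed rate set can fall outside the interquartile
#' range, the weak and strong thresholds are clipped at the mean so that the
#' ordering `strong <= moderate <= weak` (weaker selection keeps more fish)
#' holds by construction.
#'
#' @param survival_rates Tibble with columns `point` and `rate` (one row per
#'   treatment group per point), e.g. from [group_survival()]; or a bare
#'   numeric vector of rates for a single unnamed point.
#' @param strength Character vector of strengths to compute (default all
#'   three).
#' @return Tibble `point`, `strength`, `threshold`, with attribute
#'   `quantile_type = 7`.
#' @export
#' @examples
#' selection_thresholds(c(0.6, 0.7, 0.8, 0.9))
selection_thresholds <- function(survival_rates,
                                 strength = c("weak", "moderate", "strong")) {
  strength <- match.arg(strength, several.ok = TRUE)
  if (is.numeric(survival_rates)) {
    survival_rates <- tibble::tibble(point = "all", rate = survival_rates)
  }
  stopifnot(all(c("point", "rate") %in% names(survival_rates)))
  r <- survival_rates$rate
  if (any(r < 0 | r > 1)) stop("survival rates must lie in [0, 1]")
  counts <- table(survival_rates$point)
  if (any(counts[counts > 0] < 2)) stop("need >= 2 groups per time point")
  out <- survival_rates |>
    dplyr::group_by(.data$point) |>
    dplyr::summarise(
      weak = max(quantile(.data$rate, 0.75, type = 7, names = FALSE),
                 mean(.data$rate)),
      moderate = mean(.data$rate),
      strong = min(quantile(.data$rate, 0.25, type = 7, names = FALSE),
                   mean(.data$rate)),
      .groups = "drop"
    ) |>
    tidyr::pivot_longer(dplyr::all_of(c("weak", "moderate", "strong")),
                        names_to = "strength", values_to = "threshold")
  out <- out[out$strength %in% strength, , drop = FALSE]
  out$strength <- factor(out$strength, levels = c("weak", "moderate", "strong"))
  attr(out, "quantile_type") <- 7
  out
}

#' Number of measurements to remove from a group
#'
#' Only groups whose survival rate exceeds the threshold are reduced; the
#' kept fraction approximates `q / group_rate` so the implied survival after
#' removal matches the threshold. At least one value is always kept.
#'
#' @param n_measured Number of measured values in the group (>= 0).
#' @param group_rate The group's survival rate, in (0, 1].
#' @param q Threshold survival rate, > 0.
#' @return Integer count(s) to remove: `0` when `group_rate <= q`, otherwise
#'   `round(n_measured * (1 - q / group_rate))` capped at `n_measured - 1`.
#' @export
#' @examples
#' removal_count(20, 0.90, 0.72) # 4
removal_count <- function(n_measured, group_rate, q) {
  if (any(q <= 0)) stop("threshold q must be positive")
  if (any(group_rate <= 0 | group_rate > 1)) stop("group_rate must lie in (0, 1]")
  if (any(n_measured < 0)) stop("n_measured must be >= 0")
  m <- ifelse(group_rate <= q, 0,
              pmin(round(n_measured * (1 - q / group_rate)),
                   pmax(n_measured - 1, 0)))
  as.integer(pmax(m, 0))
}

#' Truncate a vector of trait measurements
#'
#' Emulates directional or random mortality on a group's measured values:
#' direction `"small"` removes the `n_remove` largest values (selecting for
#' small), `"large"` removes the smallest, `"random"` removes uniformly
#' without replacement. The original order of the surviving values is
#' preserved.
#'
#' @param values Numeric vector of measurements.
#' @param n_remove How many to remove; `0 <= n_remove < length(values)`.
#' @param direction `"small"`, `"large"` or `"random"`.
#' @param seed Optional integer seed for `"random"` removal.
#' @return The surviving values, in input order.
#' @export
#' @examples
#' apply_truncation(c(3, 5, 7, 9), 2, "small") # 3 5
apply_truncation <- function(values, n_remove,
                             direction = c("random", "small", "large"),
                             seed = NULL) {
  direction <- match.arg(direction)
  n <- length(values)
  if (n_remove < 0 || n_remove >= n) {
    stop("n_remove must satisfy 0 <= n_remove < length(values)")
  }
  if (n_remove == 0) return(values)
  if (direction == "random" && !is.null(seed)) set.seed(seed)
  values[-.truncation_drop_index(values, n_remove, direction)]
}

# indices of the values a truncation removes; shared by apply_truncation()
# and the dataset engine so both use identical ranking and tie handling
.truncation_drop_index <- function(values, n_remove, direction) {
  switch(direction,
    small = order(values, decreasing = TRUE)[seq_len(n_remove)],
    large = order(values)[seq_len(n_remove)],
    random = sample.int(length(values), n_remove)
  )
}

# Core engine: truncate one measurement table under one (strength, direction).
# rates: group_survival() table; thresholds: one row per point for the chosen
# strength. Groups whose survival exceeds the point's threshold lose
# measurements per removal_count()/apply_truncation(), per trait (default) or
# linked across traits by ranking on standard length.
truncate_dataset <- function(meas, rates, thresholds, direction,
                             include_controls = TRUE, linked = FALSE) {
  direction <- match.arg(direction, c("random", "small", "large"))
  thr <- thresholds[, c("point", "threshold")]
  m <- meas |>
    dplyr::left_join(rates[, c("population", "experiment", "mode", "point", "rate")],
                     by = c("population", "experiment", "mode", "point")) |>
    dplyr::left_join(thr, by = "point")
  if (!include_controls) {
    m$rate[m$mode == "C-C"] <- NA_real_
  }
  split_cols <- if (linked) {
    c("population", "experiment", "mode", "point")
  } else {
    c("population", "experiment", "mode", "point", "trait")
  }
  out <- m |>
    dplyr::group_by(dplyr::across(dplyr::all_of(split_cols))) |>
    dplyr::group_modify(function(.x, .y) {
      rate <- .x$rate[1]
      q <- .x$threshold[1]
      if (is.na(rate) || is.na(q) || rate <= q) return(.x)
      if (!linked) {
        k <- removal_count(nrow(.x), rate, q)
        if (k == 0) return(.x)
        .x[-.truncation_drop_index(.x$value, k, direction), , drop = FALSE]
      } else {
        # one removal decision per individual, ranked on standard length
        # (or the point's only trait), applied to all of its trait rows
        rank_trait <- if ("SDL" %in% .x$trait) "SDL" else as.character(.x$trait[1])
        rk <- .x[.x$trait == rank_trait, c("individual_id", "value")]
        k <- removal_count(nrow(rk), rate, q)
        if (k == 0) return(.x)
        drop_ids <- rk$individual_id[.truncation_drop_index(rk$value, k, direction)]
        .x[!.x$individual_id %in% drop_ids, , drop = FALSE]
      }
    }) |>
    dplyr::ungroup()
  out$rate <- NULL
  out$threshold <- NULL
  out
}

.child_seed <- function(seed, i) {
  as.integer((as.numeric(seed) %% 65011 * 32749 + i * 7919 + 1) %% 2147483629)
}

#' Build the counterfactual selection datasets
#'
#' Applies every scenario of the strength x direction grid to a measurement
#' table: per sampling point, treatment groups whose survival rate exceeds
#' the scenario's threshold have measurements removed (largest, smallest or
#' random values per trait) until their implied survival matches the
#' threshold. Random scenarios are replicated.
#'
#' @param x A `tgp_experiment`, or a measurement table (then `rates` is
#'   required).
#' @param scenarios Scenario grid from [selection_scenarios()].
#' @param seed Master seed; every scenario replicate gets a deterministic
#'   child seed.
#' @param rates Group survival rates from [group_survival()]; computed from
#'   `x` when it is a `tgp_experiment`.
#' @param include_controls Should C-C control groups be eligible for
#'   reduction (default `TRUE`; the selection acts on any group above
#'   threshold)?
#' @param linked Rank whole individuals by standard length and remove all
#'   their trait rows at the point, instead of truncating each trait's
#'   values independently (default `FALSE`).
#' @return An object of class `tgp_selection`: list with `thresholds`,
#'   `scenarios` (the grid) and `datasets`, a named list (one entry per
#'   scenario) of lists of truncated measurement tables.
#' @export
build_selected_datasets <- function(x, scenarios = selection_scenarios(),
                                    seed = 1, rates = NULL,
                                    include_controls = TRUE, linked = FALSE) {
  meas <- as_measurements(x)
  if (is.null(rates)) {
    if (!inherits(x, "tgp_experiment")) {
      stop("`rates` must be supplied when `x` is not a tgp_experiment")
    }
    rates <- group_survival(x)
  }
  thr <- selection_thresholds(rates)
  datasets <- vector("list", nrow(scenarios))
  names(datasets) <- scenarios$scenario
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    thr_i <- thr[thr$strength == as.character(sc$strength), ]
    reps <- vector("list", sc$n_replicates)
    for (r in seq_len(sc$n_replicates)) {
      set.seed(.child_seed(seed, i * 100000 + r))
      reps[[r]] <- truncate_dataset(meas, rates, thr_i,
                                    as.character(sc$direction),
                                    include_controls = include_controls,
                                    linked = linked)
    }
    datasets[[i]] <- reps
  }
  structure(list(thresholds = thr, scenarios = scenarios,
                 datasets = datasets, seed = seed,
                 include_controls = include_controls, linked = linked),
            class = "tgp_selection")
}

#' @export
print.tgp_selection <- function(x, ...) {
  cat("<tgp_selection>", length(x$datasets), "scenarios\n")
  print(x$thresholds)
  invisible(x)
}

#' Re-run the effect-size meta-analysis under selection counterfactuals
#'
#' For the observed dataset and each selection scenario (replicated for the
#' random direction), rebuilds the lnR effect-size table and fits the
#' per-life-stage effect-size models, returning the type-III ANOVA summary
#' per term. Replicates are summarised by the mean F statistic and the
#' fraction of replicates rejecting at `alpha`.
#'
#' @inheritParams build_selected_datasets
#' @param subsets Life-stage subsets to analyse (default early and late).
#' @param alpha Rejection level for the `reject_frac` summary.
#' @return Tibble with `scenario` (including `"observed"`), `strength`,
#'   `direction`, `subset`, `term`, `df`, `mean_F`, `reject_frac`,
#'   `n_replicates`.
#' @export
selection_analysis <- function(x, scenarios = selection_scenarios(), seed = 1,
                               rates = NULL, subsets = c("early", "late"),
                               include_controls = TRUE, linked = FALSE,
                               alpha = 0.05) {
  meas <- as_measurements(x)
  if (is.null(rates)) {
    if (!inherits(x, "tgp_experiment")) {
      stop("`rates` must be supplied when `x` is not a tgp_experiment")
    }
    rates <- group_survival(x)
  }
  thr <- selection_thresholds(rates)
  one_analysis <- function(m) {
    eff <- suppressMessages(build_effect_table(m))
    purrr::map_dfr(subsets, function(s) {
      ft <- suppressMessages(fit_effect_lm(eff, subset = s))
      out <- ft$anova
      out$subset <- s
      out
    })
  }
  obs <- one_analysis(meas)
  obs$scenario <- "observed"
  obs$replicate <- 1L
  all_rows <- list(obs)
  for (i in seq_len(nrow(scenarios))) {
    sc <- scenarios[i, ]
    thr_i <- thr[thr$strength == as.character(sc$strength), ]
    for (r in seq_len(sc$n_replicates)) {
      set.seed(.child_seed(seed, i * 100000 + r))
      tr <- truncate_dataset(meas, rates, thr_i, as.character(sc$direction),
                             include_controls = include_controls,
                             linked = linked)
      rows <- one_analysis(tr)
      rows$scenario <- sc$scenario
      rows$replicate <- r
      all_rows[[length(all_rows) + 1]] <- rows
    }
  }
  res <- dplyr::bind_rows(all_rows)
  summ <- res |>
    dplyr::group_by(.data$scenario, .data$subset, .data$term) |>
    dplyr::summarise(
      df = .data$df[1],
      mean_F = mean(.data$statistic),
      reject_frac = mean(.data$p_value < alpha),
      n_replicates = dplyr::n(),
      .groups = "drop"
    )
  summ <- dplyr::left_join(
    summ,
    rbind(scenarios[, c("scenario", "strength", "direction")],
          tibble::tibble(scenario = "observed", strength = NA, direction = NA)),
    by = "scenario"
  )
  summ[, c("scenario", "strength", "direction", "subset", "term",
           "df", "mean_F", "reject_frac", "n_replicates")]
}
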