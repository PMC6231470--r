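#' Reference populations of the Baltic salinity gradient design
#'
#' Three wild stickleback populations sampled along the Baltic salinity
#' gradient, each locally adapted to a different native salinity and each
#' exposed to two foreign salinities (one per acclimation experiment):
#' Nynäshamn (NYN, 6 PSU), Kiel (KIE, 20 PSU) and Thyborøn (THY, 33 PSU).
#'
#' @return A tibble with one row per population: `population`, `native_psu`,
#'   and a list-column `foreign_psu` holding the two foreign salinities
#'   (group 1, group 2).
#' @export
#' @examples
#' stickleback_populations()
stickleback_populations <- function() {
  tibble::tibble(
    population = c("NYN", "KIE", "THY"),
    native_psu = c(6, 20, 33),
    foreign_psu = list(c(20, 33), c(33, 6), c(6, 20))
  )
}

# Offspring-family counts per treatment cell; the shared C-C cell is assumed
# to hold for both of a population's experiments.
.default_family_counts <- function() {
  tibble::tribble(
    ~population, ~group, ~mode,  ~n_families,
    "NYN",       NA,     "C-C",  6L,
    "NYN",       1L,     "C-T",  6L,
    "NYN",       1L,     "T-C",  7L,
    "NYN",       1L,     "T-T",  7L,
    "NYN",       2L,     "C-T",  6L,
    "NYN",       2L,     "T-C",  4L,
    "NYN",       2L,     "T-T",  3L,
    "KIE",       NA,     "C-C",  6L,
    "KIE",       1L,     "C-T",  6L,
    "KIE",       1L,     "T-C",  6L,
    "KIE",       1L,     "T-T",  6L,
    "KIE",       2L,     "C-T",  6L,
    "KIE",       2L,     "T-C",  6L,
    "KIE",       2L,     "T-T",  6L,
    "THY",       NA,     "C-C",  6L,
    "THY",       1L,     "C-T",  6L,
    "THY",       1L,     "T-C",  6L,
    "THY",       1L,     "T-T",  6L,
    "THY",       2L,     "C-T",  6L,
    "THY",       2L,     "T-C",  6L,
    "THY",       2L,     "T-T",  6L
  )
}

#' Enumerate the G2 treatment cells of a factorial split-clutch design
#'
#' Expands a population table into the full set of distinct second-generation
#' (G2) treatment cells. Each population runs one acclimation experiment per
#' foreign salinity; within an experiment the parental (G1) and offspring
#' (G2) generations are each either at the native salinity ("C") or the
#' foreign salinity ("T"), giving the four acclimation modes C-C, C-T, T-C
#' and T-T. The C-C control is produced once per population and shared by
#' both of its experiments, so a two-experiment population contributes
#' 7 distinct cells and the full three-population design contributes 21.
#'
#' @param populations A tibble as returned by [stickleback_populations()]:
#'   columns `population`, `native_psu` and list-column `foreign_psu` with
#'   one or two foreign salinities per population.
#' @param family_counts Optional tibble with columns `population`, `group`
#'   (experiment number, `NA` for the shared C-C cell), `mode` and
#'   `n_families`; defaults to the reference design's offspring-family
#'   counts.
#' @return A tibble with one row per distinct treatment cell: `population`,
#'   `native_psu`, `experiment` (`NA` for the shared control), `foreign_psu`,
#'   `direction` ("increased"/"decreased" relative to native; `NA` for C-C),
#'   `mode`, `parental_env`, `offspring_env`, `parental_psu`,
#'   `offspring_psu`, `n_families`.
#' @export
#' @examples
#' design <- enumerate_design()
#' nrow(design) # 21
enumerate_design <- function(populations = stickleback_populations(),
                             family_counts = .default_family_counts()) {
  stopifnot(is.data.frame(populations), nrow(populations) >= 1)
  if (anyDuplicated(populations$population)) {
    stop("duplicate population names in `populations`")
  }
  if (any(populations$native_psu <= 0)) {
    stop("native salinities must be positive")
  }
  for (i in seq_len(nrow(populations))) {
    fp <- populations$foreign_psu[[i]]
    if (length(fp) < 1 || length(fp) > 2) {
      stop("each population needs one or two foreign salinities")
    }
    if (any(fp == populations$native_psu[i])) {
      stop("foreign salinity equal to native salinity for population ",
           populations$population[i])
    }
  }
  rows <- purrr::pmap(populations, function(population, native_psu, foreign_psu) {
    cc <- tibble::tibble(
      population = population, native_psu = native_psu,
      experiment = NA_character_, foreign_psu = NA_real_,
      direction = NA_character_, mode = "C-C",
      parental_env = "C", offspring_env = "C",
      parental_psu = native_psu, offspring_psu = native_psu
    )
    treat <- purrr::map2_dfr(foreign_psu, seq_along(foreign_psu), function(f, g) {
      tibble::tibble(
        population = population, native_psu = native_psu,
        experiment = sprintf("%s_g%d", population, g), foreign_psu = f,
        direction = if (f > native_psu) "increased" else "decreased",
        mode = c("C-T", "T-C", "T-T"),
        parental_env = c("C", "T", "T"),
        offspring_env = c("T", "C", "T"),
        parental_psu = ifelse(c("C", "T", "T") == "T", f, native_psu),
        offspring_psu = ifelse(c("T", "C", "T") == "T", f, native_psu)
      )
    })
    dplyr::bind_rows(cc, treat)
  })
  design <- dplyr::bind_rows(rows)
  if (!is.null(family_counts)) {
    fc <- family_counts
    fc$experiment <- ifelse(is.na(fc$group), NA_character_,
                            sprintf("%s_g%d", fc$population, fc$group))
    design <- dplyr::left_join(
      design,
      fc[, c("population", "experiment", "mode", "n_families")],
      by = c("population", "experiment", "mode")
    )
    design$n_families[is.na(design$n_families)] <- 6L
  } else {
    design$n_families <- 6L
  }
  design$mode <- factor(design$mode, levels = .tgp_modes)
  design
}

#' Classify ages into early and late life stages
#'
#' The border between early and late life stages is 22 days post hatch (dph):
#' from that age on juveniles possess fully developed osmoregulatory organs.
#' Ages strictly below 22 dph are "early" (this includes the egg stage at
#' -3 dph and hatch at 0 dph), ages of 22 dph and above are "late".
#'
#' @param age_dph Numeric vector of ages in days post hatch. Hatch occurs at
#'   8 days post fertilization, so the egg stage maps to negative dph; ages
#'   before fertilization (below -8 dph) are rejected.
#' @return Character vector, `"early"` or `"late"`.
#' @export
#' @examples
#' classify_life_stage(c(-3, 0, 12, 22, 30, 90))
classify_life_stage <- function(age_dph) {
  stopifnot(is.numeric(age_dph))
  if (any(age_dph < -8)) {
    stop("age before fertilization (age_dph < -8)")
  }
  ifelse(age_dph < 22, "early", "late")
}

#' Sampling schedule of the offspring generation
#'
#' Offspring are sampled as eggs (5 days post fertilization), freshly hatched
#' larvae (8 dpf = 0 dph) and at 12, 30 and 90 days post hatch. The egg and
#' hatch stages are assigned ages of -3 and 0 dph so the schedule orders
#' consistently on the dph axis.
#'
#' @return A tibble with columns `point`, `age_dpf`, `age_dph`, `life_stage`.
#' @seealso [trait_schedule()] for which traits are measured at each point.
#' @export
sampling_schedule <- function() {
  out <- tibble::tibble(
    point = factor(.tgp_points, levels = .tgp_points),
    age_dpf = c(5, 8, 20, 38, 98),
    age_dph = c(-3, 0, 12, 30, 90)
  )
  out$life_stage <- factor(classify_life_stage(out$age_dph), levels = .tgp_stages)
  out
}

#' Trait-by-sampling-point measurement schedule
#'
#' Which fitness-correlated traits are measured at each sampling point:
#' egg diameter on eggs; yolk-sac-area-to-length ratio at hatch; standard
#' length (SDL) and weight at 12, 30 and 90 dph; hepatosomatic index (HSI)
#' at 30 and 90 dph. This yields 4 early and 6 late trait-point
#' combinations.
#'
#' @return A tibble with columns `point`, `trait`, `age_dph`, `life_stage`.
#' @export
trait_schedule <- function() {
  sched <- tibble::tribble(
    ~point,  ~trait,
    "egg",   "egg_diameter",
    "hatch", "yolk_ratio",
    "dph12", "SDL",
    "dph12", "weight",
    "dph30", "SDL",
    "dph30", "weight",
    "dph30", "HSI",
    "dph90", "SDL",
    "dph90", "weight",
    "dph90", "HSI"
  )
  sched$point <- factor(sched$point, levels = .tgp_points)
  sched$trait <- factor(sched$trait, levels = .tgp_traits)
  dplyr::left_join(sched, sampling_schedule()[, c("point", "age_dph", "life_stage")],
                   by = "point")
}
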