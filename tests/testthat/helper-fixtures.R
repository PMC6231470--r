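# Small fixtures shared across test files. Everything is generated in code;
# sizes are kept small so the default suite stays fast.

# one population with a single experiment (4 cells)
one_experiment_design <- function() {
  enumerate_design(
    tibble::tibble(population = "KIE", native_psu = 20, foreign_psu = list(33)),
    family_counts = NULL
  )
}

# deterministic, fully surviving, low-noise parameter set for structural tests
quick_params <- function(...) {
  defaults <- list(
    sd_crossing = 0, sd_tank = 0, sd_chamber = 0, sd_residual = 0.05,
    size_loading = 0,
    base_survival = c(egg_hatch = 1, hatch_dph12 = 1,
                      dph12_dph30 = 1, dph30_dph90 = 1),
    n_per_family = 3, n_tanks_per_cell = 2,
    n_measured = c(egg = Inf, hatch = Inf, dph12 = Inf, dph30 = Inf, dph90 = Inf),
    seed = 1
  )
  do.call(null_params, utils::modifyList(defaults, list(...)))
}

# tiny hand-built measurement table with a C-C control and one treatment cell
toy_measurements <- function() {
  tibble::tibble(
    individual_id = sprintf("i%02d", 1:6),
    population = "POP",
    experiment = c(NA, NA, NA, "POP_g1", "POP_g1", "POP_g1"),
    mode = factor(c("C-C", "C-C", "C-C", "T-T", "T-T", "T-T"),
                  levels = c("C-C", "T-C", "C-T", "T-T")),
    parental_env = c("C", "C", "C", "T", "T", "T"),
    offspring_env = c("C", "C", "C", "T", "T", "T"),
    direction = c(NA, NA, NA, "increased", "increased", "increased"),
    crossing = c("f1", "f1", "f2", "f3", "f3", "f4"),
    tank = c("t1", "t1", "t2", "t3", "t3", "t4"),
    chamber = c("ch1", "ch1", "ch1", "ch2", "ch2", "ch2"),
    point = factor("egg", levels = c("egg", "hatch", "dph12", "dph30", "dph90")),
    age_dph = -3,
    life_stage = factor("early", levels = c("early", "late")),
    trait = factor("egg_diameter",
                   levels = c("egg_diameter", "yolk_ratio", "SDL", "weight", "HSI")),
    value = c(2, 4, 6, 2, 4, 9)
  )
}
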