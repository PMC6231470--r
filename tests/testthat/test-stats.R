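# numeric-integration oracle for the studentized range distribution:
# P(Q <= q) for k groups and df residual degrees of freedom, integrating the
# range probability over the scale distribution s ~ sqrt(chi^2_df / df)
ptukey_oracle <- function(q, k, df) {
  range_cdf <- function(w) {
    # P(range of k std normals <= w)
    f <- function(z) stats::dnorm(z) *
      (stats::pnorm(z) - stats::pnorm(z - w))^(k - 1)
    k * stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  dens_s <- function(s) 2 * s * df * stats::dchisq(s^2 * df, df)
  stats::integrate(function(s) {
    vapply(s, function(si) dens_s(si) * range_cdf(q * si), numeric(1))
  }, 0, Inf, rel.tol = 1e-9)$value
}

test_that("type-III ANOVA matches car::Anova on a full-rank model", {
  sim <- simulate_experiment(params = quick_params(sd_residual = 0.1, seed = 8))
  eff <- build_effect_table(sim)
  ft <- fit_effect_lm(eff, "early")
  cc <- car::Anova(ft$fit, type = 3)
  cc <- cc[!rownames(cc) %in% c("(Intercept)", "Residuals"), ]
  expect_equal(ft$anova$term, rownames(cc))
  expect_equal(ft$anova$statistic, cc$`F value`, tolerance = 1e-10)
  expect_equal(ft$anova$p_value, cc$`Pr(>F)`, tolerance = 1e-10)
  expect_equal(ft$residual_df, df.residual(ft$fit))
})

test_that("type-III equals sequential ANOVA on a balanced design", {
  set.seed(31)
  d <- expand.grid(a = factor(1:3), b = factor(1:4), rep = 1:5)
  d$ln_r <- rnorm(nrow(d)) + as.numeric(d$a) * 0.3
  ft <- fit_effect_lm(d, formula = ln_r ~ a * b)
  seq_tab <- anova(lm(ln_r ~ a * b, data = d))
  for (tm in c("a", "b", "a:b")) {
    expect_equal(ft$anova$statistic[ft$anova$term == tm],
                 seq_tab[tm, "F value"], tolerance = 1e-9)
  }
})

test_that("aliased terms are excluded and reported, not fatal", {
  sim <- simulate_experiment(params = quick_params(sd_residual = 0.1, seed = 9))
  eff <- build_effect_table(sim)
  expect_message(ft <- fit_effect_lm(eff, "all"), "aliased")
  expect_gt(length(ft$aliased), 0)
  expect_equal(ft$residual_df, 144)
  # the partially confounded life_stage:trait term keeps 1 estimable df
  expect_equal(ft$anova$df[ft$anova$term == "life_stage:trait"], 1L)
  expect_equal(ft$anova$df[ft$anova$term == "population:trait"], 8L)
})

test_that("a constant response yields a no-effect table", {
  sim <- simulate_experiment(params = quick_params(sd_residual = 0))
  eff <- build_effect_table(sim)
  ft <- fit_effect_lm(eff, "early")
  expect_true(all(is.na(ft$anova$p_value)))
})

test_that("mixed trait model reduces to OLS when variance components are zero", {
  p <- null_params(sd_crossing = 0, sd_tank = 0, sd_chamber = 0,
                   size_loading = 0, alpha_parental = 0.1,
                   beta_offspring = -0.2, sd_residual = 0.1,
                   base_survival = c(egg_hatch = 1, hatch_dph12 = 1,
                                     dph12_dph30 = 1, dph30_dph90 = 1),
                   n_per_family = 5, seed = 12,
                   n_measured = c(egg = Inf, hatch = Inf, dph12 = Inf,
                                  dph30 = Inf, dph90 = Inf))
  sim <- simulate_experiment(one_experiment_design(), p)
  d <- sim$measurements[sim$measurements$trait == "SDL" &
                          sim$measurements$point == "dph30", ]
  d$value <- log(d$value)
  m <- fit_trait_lmm(d)
  d2 <- d
  d2$parental_env <- factor(d2$parental_env)
  d2$offspring_env <- factor(d2$offspring_env)
  ols <- lm(value ~ parental_env * offspring_env, data = d2,
            contrasts = list(parental_env = "contr.sum",
                             offspring_env = "contr.sum"))
  expect_equal(unname(m$fixef), unname(coef(ols)), tolerance = 1e-6)
  expect_s3_class(m$anova, "tbl_df")
})

test_that("balanced one-way variance components match the closed-form ANOVA estimators", {
  set.seed(42)
  k <- 12; n <- 8
  g <- factor(rep(seq_len(k), each = n))
  y <- rep(rnorm(k, 0, 2), each = n) + rnorm(k * n)
  d <- tibble::tibble(value = y, crossing = g, chamber = "c1", tank = "t1",
                      parental_env = "C", offspring_env = "C")
  suppressMessages(m <- fit_trait_lmm(d, fixed = ~ 1))
  ms <- anova(lm(y ~ g))
  sigma2_between <- (ms["g", "Mean Sq"] - ms["Residuals", "Mean Sq"]) / n
  expect_equal(unname(m$variance["crossing"]), sigma2_between, tolerance = 1e-6)
  expect_equal(unname(m$variance["Residual"]), ms["Residuals", "Mean Sq"],
               tolerance = 1e-6)
})

test_that("a constant trait gives zero effects and zero variance", {
  d <- tibble::tibble(value = 5, crossing = rep(c("a", "b"), 10),
                      chamber = "c", tank = "t",
                      parental_env = rep(c("C", "T"), each = 10),
                      offspring_env = "C")
  m <- fit_trait_lmm(d, fixed = ~ parental_env)
  expect_true(all(m$variance == 0))
  expect_true(all(m$anova$statistic == 0))
})

test_that("mortality GLMM reduces to plain logistic regression without random variance", {
  set.seed(7)
  nt <- 40
  dd <- tibble::tibble(
    parental_env = rep(c("C", "T"), each = nt / 2),
    offspring_env = rep(c("C", "T"), nt / 2),
    crossing = rep(sprintf("f%d", 1:8), length.out = nt),
    chamber = rep(c("a", "b"), length.out = nt),
    alive = rbinom(nt, 30, 0.7)
  )
  dd$dead <- 30L - dd$alive
  gm <- fit_mortality_glmm(dd)
  d2 <- dd
  d2$parental_env <- factor(d2$parental_env)
  d2$offspring_env <- factor(d2$offspring_env)
  gl <- glm(cbind(alive, dead) ~ parental_env * offspring_env, data = d2,
            family = binomial(),
            contrasts = list(parental_env = "contr.sum",
                             offspring_env = "contr.sum"))
  expect_equal(unname(gm$fixef), unname(coef(gl)), tolerance = 1e-6)
})

test_that("equal survival between environments gives a near-zero environment effect", {
  dd <- tibble::tibble(
    parental_env = rep(c("C", "T"), each = 10),
    offspring_env = "C",
    crossing = rep(sprintf("f%d", 1:5), 4),
    chamber = rep(c("a", "b"), 10),
    alive = 21L, dead = 9L
  )
  gm <- fit_mortality_glmm(dd, fixed = ~ parental_env)
  expect_lt(gm$anova$statistic[gm$anova$term == "parental_env"], 1e-6)
})

test_that("complete separation is flagged instead of fitted", {
  dd <- tibble::tibble(parental_env = rep(c("C", "T"), each = 4),
                       offspring_env = rep(c("C", "T"), 4),
                       crossing = "f1", chamber = "a",
                       alive = 30L, dead = 0L)
  expect_message(gm <- fit_mortality_glmm(dd), "separation")
  expect_true(gm$separation)
  expect_true(all(is.na(gm$anova$statistic)))
})

test_that("backward AIC elimination drops null terms and matches exhaustive search", {
  # small crafted problem: 3 candidate main effects, one pure-noise
  set.seed(5)
  n <- 120
  d <- tibble::tibble(
    a = factor(sample(1:3, n, TRUE)),
    b = factor(sample(1:2, n, TRUE)),
    c = factor(sample(1:4, n, TRUE))
  )
  d$ln_r <- 0.8 * as.numeric(d$a) + 0.5 * (d$b == "2") + rnorm(n, 0, 0.4)
  full <- fit_effect_lm(d, formula = ln_r ~ a + b + c)
  red <- stepwise_aic(full)
  kept <- attr(terms(red$fit), "term.labels")
  # exhaustive oracle over all 8 submodels
  cands <- list(character(0), "a", "b", "c", c("a", "b"), c("a", "c"),
                c("b", "c"), c("a", "b", "c"))
  aics <- vapply(cands, function(tm) {
    f <- if (length(tm)) stats::reformulate(tm, "ln_r") else ln_r ~ 1
    AIC(lm(f, data = d))
  }, numeric(1))
  # stepAIC and AIC use different additive constants; compare selections
  ll_aics <- vapply(cands, function(tm) {
    f <- if (length(tm)) stats::reformulate(tm, "ln_r") else ln_r ~ 1
    fit <- lm(f, data = d)
    n * log(sum(fit$residuals^2) / n) + 2 * (length(coef(fit)))
  }, numeric(1))
  expect_setequal(kept, cands[[which.min(ll_aics)]])
  expect_setequal(kept, c("a", "b"))
  # a model where no drop improves AIC is returned unchanged
  red2 <- stepwise_aic(red$fit)
  expect_equal(attr(terms(red2$fit), "term.labels"), kept)
})

test_that("term elimination respects marginality and is reliable under strong signal", {
  set.seed(17)
  hits <- vapply(1:60, function(i) {
    n <- 180
    d <- tibble::tibble(a = factor(sample(1:2, n, TRUE)),
                        b = factor(sample(1:2, n, TRUE)))
    d$ln_r <- 1.5 * (d$a == "2") + rnorm(n, 0, 0.5) # b is pure noise
    red <- stepwise_aic(fit_effect_lm(d, formula = ln_r ~ a * b))
    tl <- attr(terms(red$fit), "term.labels")
    # marginality: interaction never retained without both mains
    if ("a:b" %in% tl) {
      expect_true(all(c("a", "b") %in% tl))
    }
    !"b" %in% tl || "a:b" %in% tl
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("Tukey HSD equals the pooled t-test for two groups", {
  set.seed(3)
  d <- tibble::tibble(g = factor(rep(c("x", "y"), each = 15)),
                      ln_r = rnorm(30) + rep(c(0, 0.4), each = 15))
  ft <- fit_effect_lm(d, formula = ln_r ~ g)
  th <- tukey_hsd(ft, "g")
  tt <- t.test(ln_r ~ g, data = d, var.equal = TRUE)
  expect_equal(th$p_adj, tt$p.value, tolerance = 1e-9)
  # identical group means: adjusted p ~ 1
  d2 <- d
  d2$ln_r <- rep(seq_len(15), 2) # same values in both groups
  th2 <- tukey_hsd(fit_effect_lm(d2, formula = ln_r ~ g), "g")
  expect_gt(th2$p_adj, 0.999)
})

test_that("Tukey HSD matches an independent studentized-range integration", {
  set.seed(9)
  k <- 3; n <- 5
  d <- tibble::tibble(g = factor(rep(letters[1:k], each = n)),
                      ln_r = rnorm(k * n) + rep(c(0, 0.5, 1.2), each = n))
  ft <- fit_effect_lm(d, formula = ln_r ~ g)
  th <- tukey_hsd(ft, "g")
  ms <- anova(lm(ln_r ~ g, data = d))["Residuals", "Mean Sq"]
  df <- k * n - k
  for (i in seq_len(nrow(th))) {
    qstat <- abs(th$estimate[i]) / sqrt(ms / n)
    p_oracle <- 1 - ptukey_oracle(qstat, k, df)
    expect_equal(unname(th$p_adj[i]), p_oracle, tolerance = 1e-6)
  }
})

test_that("Tukey HSD on a single-level factor returns an empty table", {
  d <- tibble::tibble(g = factor("x"), h = factor(rep(c("u", "v"), 8)),
                      ln_r = rnorm(16))
  ft <- fit_effect_lm(d, formula = ln_r ~ h)
  expect_equal(nrow(tukey_hsd(ft, "g")), 0)
})
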