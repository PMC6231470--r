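#' Type-III ANOVA for a linear model, tolerant of aliased terms
#'
#' Marginal (type-III) F tests: each term's sum of squares is the increase in
#' residual sum of squares when that term's (non-aliased) model-matrix
#' columns are removed while every other term stays in the model. Type-III
#' tests are only meaningful with sum-to-zero contrasts, which
#' [fit_effect_lm()] sets on every factor. Unlike `car::Anova(type = 3)`,
#' aliased coefficients (rank-deficient designs, e.g. partially confounded
#' trait x life-stage combinations) are tolerated: aliased columns are
#' excluded and each term is tested on its estimable degrees of freedom.
#'
#' @param fit An `lm` fit.
#' @return A list: `table` (tibble with `term`, `df`, `statistic` (F),
#'   `p_value`), `residual_df`, `residual_ss`, `aliased` (names of dropped
#'   columns).
#' @export
anova_type3 <- function(fit) {
  stopifnot(inherits(fit, "lm"))
  X <- model.matrix(fit)
  asgn <- attr(X, "assign")
  labs <- attr(terms(fit), "term.labels")
  y <- model.response(model.frame(fit))
  keep <- !is.na(coef(fit))
  aliased <- colnames(X)[!keep]
  Xk <- X[, keep, drop = FALSE]
  asgn_k <- asgn[keep]
  full <- lm.fit(Xk, y)
  rss <- sum(full$residuals^2)
  df_res <- nrow(Xk) - ncol(Xk)
  sigma2 <- rss / df_res
  degenerate <- !is.finite(sigma2) || sigma2 <= 1e-12 * (mean(y^2) + 1e-300)
  rows <- purrr::map_dfr(seq_along(labs), function(t) {
    cols <- asgn_k == t
    df_t <- sum(cols)
    if (df_t == 0) {
      return(tibble::tibble(term = labs[t], df = 0L,
                            statistic = NA_real_, p_value = NA_real_))
    }
    red <- lm.fit(Xk[, !cols, drop = FALSE], y)
    ss <- sum(red$residuals^2) - rss
    if (degenerate) {
      return(tibble::tibble(term = labs[t], df = df_t,
                            statistic = NA_real_, p_value = NA_real_))
    }
    f <- (ss / df_t) / sigma2
    tibble::tibble(term = labs[t], df = df_t, statistic = f,
                   p_value = pf(f, df_t, df_res, lower.tail = FALSE))
  })
  list(table = rows, residual_df = df_res, residual_ss = rss, aliased = aliased)
}

#' Default effect-size model formulas
#'
#' The full-table model uses the meta-analysis factor set (acclimation mode,
#' life stage, salinity direction, population, trait) with the estimable
#' two- and three-way interactions; on the complete 180-row table it has 36
#' estimable parameters, hence 144 residual df. The per-life-stage subset
#' model drops `life_stage` and the population interactions:
#' `mode * salinity * trait + population` (26 parameters on the 72-row early
#' subset, hence 46 residual df).
#'
#' @param subset `"all"`, `"early"` or `"late"`.
#' @return A formula in `ln_r`.
#' @export
effect_model_formula <- function(subset = c("all", "early", "late")) {
  subset <- match.arg(subset)
  if (subset == "all") {
    ln_r ~ mode + life_stage + salinity + population + trait +
      mode:life_stage + mode:salinity + mode:population +
      life_stage:population + life_stage:trait + population:trait +
      mode:life_stage:population + life_stage:population:trait
  } else {
    ln_r ~ mode + salinity + population + trait +
      mode:salinity + mode:trait + salinity:trait + mode:salinity:trait
  }
}

#' Fit a linear model on the lnR effect-size table
#'
#' Ordinary linear model on the effect sizes with sum-to-zero contrasts and
#' marginal (type-III) F tests; the effect-size rows are weighed equally.
#' Factors with a single observed level in the (sub)set are dropped from the
#' formula automatically.
#'
#' @param effect_table A `tgp_effect_table` (or compatible data frame with
#'   an `ln_r` column and the factor columns used by `formula`).
#' @param subset `"all"` (default), `"early"` or `"late"`; subsets by
#'   `life_stage` and picks the matching default formula.
#' @param formula Optional model formula overriding the default from
#'   [effect_model_formula()].
#' @return An object of class `tgp_effect_fit`: list with `fit` (the `lm`),
#'   `anova` (type-III table), `residual_df`, `aliased`, `subset`, `data`.
#' @export
#' @examples
#' sim <- simulate_experiment(params = sim_params(seed = 1))
#' ft <- fit_effect_lm(build_effect_table(sim), subset = "early")
#' ft$anova
fit_effect_lm <- function(effect_table, subset = c("all", "early", "late"),
                          formula = NULL) {
  subset <- match.arg(subset)
  dat <- tibble::as_tibble(effect_table)
  if (subset != "all") dat <- dat[dat$life_stage == subset, , drop = FALSE]
  if (nrow(dat) == 0) stop("no effect-size rows in subset '", subset, "'")
  dat <- droplevels(dat)
  if (is.null(formula)) formula <- effect_model_formula(subset)
  vars <- setdiff(all.vars(formula), "ln_r")
  single <- character(0)
  for (v in vars) {
    if (!v %in% names(dat)) stop("effect table lacks column ", v)
    if (!is.factor(dat[[v]])) dat[[v]] <- factor(dat[[v]])
    dat[[v]] <- droplevels(dat[[v]])
    if (nlevels(dat[[v]]) < 2) single <- c(single, v)
  }
  if (length(single)) {
    message("dropping single-level factor(s): ", paste(single, collapse = ", "))
    formula <- .drop_formula_vars(formula, single)
  }
  contr <- lapply(setdiff(vars, single), function(v) "contr.sum")
  names(contr) <- setdiff(vars, single)
  # embed the data in the call so stepAIC/update can re-evaluate the fit
  fit <- eval(bquote(lm(.(formula), data = .(dat), contrasts = .(contr))))
  an <- anova_type3(fit)
  if (length(an$aliased)) {
    message("aliased (non-estimable) coefficients excluded: ",
            paste(an$aliased, collapse = ", "))
  }
  structure(list(fit = fit, anova = an$table, residual_df = an$residual_df,
                 aliased = an$aliased, subset = subset, formula = formula,
                 data = dat),
            class = "tgp_effect_fit")
}

# remove variables (and any interaction touching them) from a formula
.drop_formula_vars <- function(formula, vars) {
  tl <- attr(terms(formula), "term.labels")
  keep <- !vapply(tl, function(t) {
    any(vars %in% strsplit(t, ":", fixed = TRUE)[[1]])
  }, logical(1))
  stats::reformulate(tl[keep], response = all.vars(formula)[1])
}

#' @export
print.tgp_effect_fit <- function(x, ...) {
  cat("<tgp_effect_fit> subset:", x$subset, "\n")
  cat("  rows:", nrow(x$data), " residual df:", x$residual_df, "\n")
  print(x$anova)
  invisible(x)
}

#' Backward model selection by AIC
#'
#' Backward elimination with `MASS::stepAIC`, respecting marginality (no
#' main effect leaves while one of its interactions remains). Operates on a
#' `tgp_effect_fit` or any `lm`.
#'
#' @param fit A `tgp_effect_fit` or `lm`.
#' @param scope Optional lower scope passed to `MASS::stepAIC`.
#' @param trace Print the elimination trace.
#' @return A list: `fit` (reduced `lm`), `anova` (type-III table of the
#'   reduced model), `residual_df`, `trace` (the stepAIC `anova`
#'   component).
#' @export
stepwise_aic <- function(fit, scope = NULL, trace = FALSE) {
  lmfit <- if (inherits(fit, "tgp_effect_fit")) fit$fit else fit
  stopifnot(inherits(lmfit, "lm"))
  args <- list(lmfit, direction = "backward", trace = trace)
  if (!is.null(scope)) args$scope <- scope
  # refits of reduced models warn that contrasts for eliminated factors are
  # unused; that is expected during elimination
  red <- withCallingHandlers(
    do.call(MASS::stepAIC, args),
    warning = function(w) {
      if (grepl("contrast will be ignored", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  an <- anova_type3(red)
  list(fit = red, anova = an$table, residual_df = an$residual_df,
       trace = red$anova)
}

#' Tukey HSD post hoc contrasts
#'
#' All pairwise contrasts of a factor (or interaction) with studentized-range
#' ("honest significant difference") adjusted p-values, via an `aov` refit of
#' the model.
#'
#' @param fit A `tgp_effect_fit` or `lm`.
#' @param term Name of the factor or interaction (e.g. `"mode:salinity"`).
#' @param conf.level Confidence level for the interval columns.
#' @return Tibble with `term`, `contrast`, `estimate`, `conf.low`,
#'   `conf.high`, `p_adj`; empty if the factor has fewer than two levels.
#' @export
tukey_hsd <- function(fit, term, conf.level = 0.95) {
  if (inherits(fit, "tgp_effect_fit")) {
    dat <- fit$data
    formula <- formula(fit$fit)
  } else {
    stopifnot(inherits(fit, "lm"))
    dat <- model.frame(fit)
    formula <- formula(fit)
  }
  vars <- strsplit(term, ":", fixed = TRUE)[[1]]
  for (v in vars) {
    if (!v %in% names(dat)) stop("unknown factor ", v)
    if (nlevels(factor(dat[[v]])) < 2) {
      return(tibble::tibble(term = character(0), contrast = character(0),
                            estimate = numeric(0), conf.low = numeric(0),
                            conf.high = numeric(0), p_adj = numeric(0)))
    }
  }
  av <- eval(bquote(aov(.(formula), data = .(dat))))
  th <- TukeyHSD(av, which = term, conf.level = conf.level)
  m <- th[[term]]
  tibble::tibble(term = term, contrast = rownames(m),
                 estimate = m[, "diff"], conf.low = m[, "lwr"],
                 conf.high = m[, "upr"], p_adj = m[, "p adj"])
}
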