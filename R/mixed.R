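#' Gaussian mixed model for a raw trait
#'
#' REML linear mixed model for trait values of one experiment (treatment
#' cell set): fixed effects `parental_env * offspring_env`, random
#' intercepts for crossing and for tank nested within climate chamber.
#' Term significance is summarised with a type-III Wald chi-square table
#' (sum-to-zero contrasts). Grouping factors with fewer than two observed
#' levels are dropped with a message; if no grouping factor survives, an
#' ordinary linear model is fitted instead.
#'
#' @param data Measurement rows (one trait at one sampling point works best):
#'   needs `parental_env`, `offspring_env`, `crossing`, `tank`, `chamber`
#'   and the response column.
#' @param response Name of the response column (default `"value"`).
#' @param fixed One-sided formula of fixed effects
#'   (default `~ parental_env * offspring_env`).
#' @return A list of class `tgp_lmm`: `fit`, `anova` (tibble `term`, `df`,
#'   `statistic`, `p_value`, Wald chi-square unless the `lm` fallback was
#'   used), `singular`, `dropped` (random terms removed), `variance`
#'   (named vector of variance components).
#' @export
fit_trait_lmm <- function(data, response = "value",
                          fixed = ~ parental_env * offspring_env) {
  dat <- tibble::as_tibble(data)
  stopifnot(response %in% names(dat))
  fvars <- all.vars(fixed)
  for (v in fvars) dat[[v]] <- droplevels(factor(dat[[v]]))
  y <- dat[[response]]
  if (var(y) == 0) {
    # constant response: every contrast is exactly zero, nothing to fit
    tl <- attr(terms(fixed), "term.labels")
    return(structure(list(
      fit = NULL, singular = TRUE, dropped = character(0),
      variance = c(crossing = 0, tank = 0, chamber = 0, residual = 0),
      fixef = setNames(numeric(length(tl)), tl),
      anova = tibble::tibble(term = tl, df = NA_integer_,
                             statistic = 0, p_value = 1)
    ), class = "tgp_lmm"))
  }
  groupings <- c(crossing = "(1 | crossing)",
                 chamber = "(1 | chamber)",
                 tank = "(1 | chamber:tank)")
  present <- vapply(c("crossing", "chamber", "tank"), function(v) {
    v %in% names(dat) && length(unique(dat[[v]])) >= 2
  }, logical(1))
  dropped <- names(groupings)[!present]
  if (length(dropped)) {
    message("dropping random term(s) with <2 levels: ",
            paste(dropped, collapse = ", "))
  }
  contr <- lapply(fvars, function(v) "contr.sum")
  names(contr) <- fvars
  fixed_part <- paste(deparse(fixed[[2]]), collapse = " ")
  if (!any(present)) {
    f <- as.formula(paste(response, "~", fixed_part))
    fit <- eval(bquote(lm(.(f), data = .(dat), contrasts = .(contr))))
    an <- anova_type3(fit)
    return(structure(list(fit = fit, anova = an$table, singular = FALSE,
                          dropped = dropped, variance = NULL,
                          fixef = coef(fit)),
                     class = "tgp_lmm"))
  }
  f <- as.formula(paste(response, "~", fixed_part, "+",
                        paste(groupings[present], collapse = " + ")))
  fit <- lme4::lmer(f, data = dat, REML = TRUE, contrasts = contr,
                    control = lme4::lmerControl(check.conv.singular = "ignore"))
  singular <- lme4::isSingular(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  variance <- setNames(vc$vcov, vc$grp)
  aw <- suppressWarnings(car::Anova(fit, type = 3))
  an <- tibble::tibble(term = rownames(aw), df = aw$Df,
                       statistic = aw$Chisq, p_value = aw$`Pr(>Chisq)`)
  an <- an[an$term != "(Intercept)", , drop = FALSE]
  structure(list(fit = fit, anova = an, singular = singular,
                 dropped = dropped, variance = variance,
                 fixef = lme4::fixef(fit)),
            class = "tgp_lmm")
}

#' @export
print.tgp_lmm <- function(x, ...) {
  cat("<tgp_lmm>", if (x$singular) "(singular fit)" else "", "\n")
  print(x$anova)
  invisible(x)
}

#' Binomial mixed model for tank survival
#'
#' Logit-link binomial GLMM for alive/dead counts, fixed effects
#' `parental_env * offspring_env`, random intercepts for crossing and
#' climate chamber, with a type-III Wald chi-square table. Complete
#' separation (every unit fully alive or fully dead) is flagged and no model
#' is fitted: the environment terms are not estimable from such data.
#'
#' @param counts Count table as from
#'   `tank_survival(x, point, by = c("tank", "crossing"))`: columns `alive`,
#'   `dead`, `parental_env`, `offspring_env`, `crossing`, `chamber`.
#' @param fixed One-sided fixed-effects formula.
#' @return A list of class `tgp_glmm`: `fit`, `anova`, `separation`,
#'   `dropped`, `fixef`.
#' @export
fit_mortality_glmm <- function(counts, fixed = ~ parental_env * offspring_env) {
  dat <- tibble::as_tibble(counts)
  stopifnot(all(c("alive", "dead") %in% names(dat)))
  fvars <- all.vars(fixed)
  for (v in fvars) dat[[v]] <- droplevels(factor(dat[[v]]))
  rate <- dat$alive / (dat$alive + dat$dead)
  if (all(rate %in% c(0, 1))) {
    message("complete separation: all units fully alive or fully dead; ",
            "environment terms not estimable")
    tl <- attr(terms(fixed), "term.labels")
    return(structure(list(
      fit = NULL, separation = TRUE, dropped = character(0), fixef = NULL,
      anova = tibble::tibble(term = tl, df = NA_integer_,
                             statistic = NA_real_, p_value = NA_real_)
    ), class = "tgp_glmm"))
  }
  groupings <- c(crossing = "(1 | crossing)", chamber = "(1 | chamber)")
  present <- vapply(names(groupings), function(v) {
    v %in% names(dat) && length(unique(dat[[v]])) >= 2
  }, logical(1))
  dropped <- names(groupings)[!present]
  if (length(dropped)) {
    message("dropping random term(s) with <2 levels: ",
            paste(dropped, collapse = ", "))
  }
  contr <- lapply(fvars, function(v) "contr.sum")
  names(contr) <- fvars
  fixed_part <- paste(deparse(fixed[[2]]), collapse = " ")
  if (var(rate) == 0) present[] <- FALSE # constant response: no estimable RE
  if (any(present)) {
    f <- as.formula(paste("cbind(alive, dead) ~", fixed_part, "+",
                          paste(groupings[present], collapse = " + ")))
    fit <- suppressMessages(lme4::glmer(
      f, data = dat, family = stats::binomial(), contrasts = contr,
      control = lme4::glmerControl(check.conv.singular = "ignore")
    ))
    aw <- suppressWarnings(car::Anova(fit, type = 3))
    an <- tibble::tibble(term = rownames(aw), df = aw$Df,
                         statistic = aw$Chisq, p_value = aw$`Pr(>Chisq)`)
    fe <- lme4::fixef(fit)
  } else {
    f <- as.formula(paste("cbind(alive, dead) ~", fixed_part))
    fit <- stats::glm(f, data = dat, family = stats::binomial(),
                      contrasts = contr)
    aw <- suppressWarnings(car::Anova(fit, type = 3, test.statistic = "Wald"))
    an <- tibble::tibble(term = rownames(aw), df = aw$Df,
                         statistic = aw$Chisq, p_value = aw$`Pr(>Chisq)`)
    fe <- coef(fit)
  }
  an <- an[an$term != "(Intercept)", , drop = FALSE]
  structure(list(fit = fit, anova = an, separation = FALSE,
                 dropped = dropped, fixef = fe),
            class = "tgp_glmm")
}

#' @export
print.tgp_glmm <- function(x, ...) {
  cat("<tgp_glmm>", if (x$separation) "(complete separation)" else "", "\n")
  print(x$anova)
  invisible(x)
}
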