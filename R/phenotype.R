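# Phenotyping of necrosis trajectories: daily descriptors, impact classes,
# the PCA fitness proxy, Box-Cox normalisation, fixed/mixed response models,
# the per-factor variance-contribution statistic, and the field-survey ANOVA.

validate_panel <- function(panel) {
  stopifnot(is.data.frame(panel))
  need <- c("colony_id", "population", "year", "day", "necrosis_pct")
  if (!all(need %in% names(panel))) {
    stop("panel must have columns ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(panel) == 0L) stop("panel is empty", call. = FALSE)
  if (any(panel$necrosis_pct %% 5 != 0 | panel$necrosis_pct < 0 |
          panel$necrosis_pct > 100)) {
    stop("necrosis_pct must lie on the 0,5,...,100 grid", call. = FALSE)
  }
  panel
}

#' Daily group-level necrosis descriptors
#'
#' Summarises a necrosis panel into the three standard assay descriptors per
#' population x year x day: the mean extent of injury (with its standard
#' error over colonies), the percentage of affected colonies (necrosis above
#' 10\%), and the percentage of dead colonies (necrosis equal to 100\%).
#' Population-year groups absent from the panel are omitted, not zero-filled.
#'
#' @param panel a necrosis panel (`colony_id`, `population`, `year`, `day`,
#'   `necrosis_pct`).
#' @return a `data.frame` with columns `population`, `year`, `day`, `n`,
#'   `mean_extent`, `se_extent`, `pct_affected`, `pct_dead`.
#' @export
compute_daily_descriptors <- function(panel) {
  panel <- validate_panel(panel)
  key <- list(population = panel$population, year = panel$year, day = panel$day)
  agg <- function(f) aggregate(panel$necrosis_pct, key, f)$x
  out <- aggregate(panel$necrosis_pct, key, length)
  names(out)[4] <- "n"
  out$mean_extent <- agg(mean)
  out$se_extent <- agg(function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_)
  out$pct_affected <- agg(function(v) 100 * mean(v > 10))
  out$pct_dead <- agg(function(v) 100 * mean(v == 100))
  out <- out[order(out$population, out$year, out$day), ]
  rownames(out) <- NULL
  out
}

#' Classify necrosis extent into impact classes
#'
#' Bins percentage necrosis into the standard assay impact classes:
#' below 10\% is "none", 10-30\% "low", above 30 up to 60\% "moderate", and
#' above 60\% "severe".
#'
#' @param necrosis_pct numeric vector of percentages in `[0, 100]`.
#' @return an ordered factor with levels none < low < moderate < severe.
#' @export
classify_impact <- function(necrosis_pct) {
  if (any(!is.finite(necrosis_pct)) ||
      any(necrosis_pct < 0 | necrosis_pct > 100)) {
    stop("necrosis_pct must be finite and within [0, 100]", call. = FALSE)
  }
  cut(necrosis_pct, breaks = c(-Inf, 10, 30, 60, Inf),
      labels = c("none", "low", "moderate", "severe"),
      right = FALSE, ordered_result = TRUE) ->
    cls
  # boundaries: 10 and 30 belong to "low" (10-30%), 60 to "moderate" (>30-60%)
  cls[necrosis_pct == 10] <- "low"
  cls[necrosis_pct == 30] <- "low"
  cls[necrosis_pct == 60] <- "moderate"
  cls
}

panel_to_wide <- function(panel) {
  panel <- validate_panel(panel)
  panel$case <- paste(panel$colony_id, panel$year, sep = "|")
  days <- sort(unique(panel$day))
  wide <- stats::reshape(
    panel[c("case", "day", "necrosis_pct")],
    idvar = "case", timevar = "day", direction = "wide"
  )
  mat <- as.matrix(wide[, -1, drop = FALSE])
  colnames(mat) <- sub("^necrosis_pct\\.", "day", colnames(mat))
  mat <- mat[, paste0("day", days), drop = FALSE]
  rownames(mat) <- wide$case
  meta <- unique(panel[c("case", "colony_id", "population", "year")])
  meta <- meta[match(rownames(mat), meta$case), ]
  list(mat = mat, meta = meta, days = days)
}

scaled_pca <- function(mat) {
  keep <- apply(mat, 2, stats::sd) > 0
  if (sum(keep) < 2L) stop("fewer than 2 non-constant day columns", call. = FALSE)
  p <- stats::prcomp(mat[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  var_expl <- 100 * p$sdev^2 / sum(p$sdev^2)
  list(pca = p, var_explained = var_expl, dropped_constant = colnames(mat)[!keep])
}

#' PCA fitness proxy from necrosis trajectories
#'
#' Cases are colony x year trajectories, variables the daily necrosis
#' percentages. An exploratory correlation-matrix PCA over all days is
#' reported; the definitive PCA drops the early days (before
#' `trim_before_day`, where trajectories barely separate) and its PC1 score
#' is the individual fitness proxy. PC1 is oriented so that it correlates
#' positively with final-day necrosis (high score = strong necrosis
#' development). Cases with any missing retained day are dropped with a
#' warning (complete-case PCA).
#'
#' @param panel a necrosis panel.
#' @param trim_before_day first day retained in the definitive PCA
#'   (default 10).
#' @return an object of class `fitness_scores`: a list with `scores`
#'   (`colony_id`, `population`, `year`, `pc1`), `var_explained` (definitive
#'   PCA, per component, percent), `exploratory_var_explained`, `loadings`
#'   (PC1 loadings per retained day), `trim_before_day`, `n_dropped`.
#' @export
fit_fitness_pca <- function(panel, trim_before_day = 10L) {
  w <- panel_to_wide(panel)
  complete <- stats::complete.cases(w$mat)
  n_dropped <- sum(!complete)
  if (n_dropped > 0) {
    warning(sprintf("dropping %d case(s) with incomplete daily trajectories", n_dropped))
  }
  mat <- w$mat[complete, , drop = FALSE]
  meta <- w$meta[complete, , drop = FALSE]
  if (nrow(mat) < 3L) stop("need at least 3 complete cases for the PCA", call. = FALSE)
  retained <- w$days[w$days >= trim_before_day]
  if (length(retained) < 2L) {
    stop("fewer than 2 day columns retained after trimming", call. = FALSE)
  }

  explor <- scaled_pca(mat)
  defin <- scaled_pca(mat[, paste0("day", retained), drop = FALSE])

  pc1 <- defin$pca$x[, 1]
  lastday <- mat[, ncol(mat)]
  orient <- stats::cor(pc1, lastday)
  if (is.finite(orient) && orient < 0) {
    pc1 <- -pc1
    defin$pca$rotation[, 1] <- -defin$pca$rotation[, 1]
  }
  scores <- data.frame(colony_id = meta$colony_id, population = meta$population,
                       year = meta$year, pc1 = as.numeric(pc1),
                       stringsAsFactors = FALSE)
  rownames(scores) <- NULL
  structure(list(scores = scores,
                 var_explained = defin$var_explained,
                 exploratory_var_explained = explor$var_explained,
                 loadings = defin$pca$rotation[, 1],
                 trim_before_day = trim_before_day,
                 n_dropped = n_dropped),
            class = "fitness_scores")
}

#' @export
print.fitness_scores <- function(x, ...) {
  cat(sprintf("fitness_scores: %d cases; PC1 explains %.2f%% (exploratory PC1: %.2f%%)\n",
              nrow(x$scores), x$var_explained[1], x$exploratory_var_explained[1]))
  invisible(x)
}

scores_df <- function(scores) {
  if (inherits(scores, "fitness_scores")) scores$scores else as.data.frame(scores)
}

#' Box-Cox normalisation of fitness scores
#'
#' Shifts the PC1 scores to strict positivity (by default `1 - min(score)`;
#' the shift used is recorded so results are auditable) and picks the Box-Cox
#' exponent by profile maximum likelihood under the fixed-effect model
#' `score ~ population * year`. Shapiro-Wilk normality and Levene
#' homoscedasticity diagnostics of the transformed model residuals are
#' reported.
#'
#' @param scores a [fit_fitness_pca()] result or a data frame with columns
#'   `pc1`, `population`, `year` (and `colony_id`).
#' @param shift positive shift added before transforming; `NULL` (default)
#'   uses `1 - min(pc1)`.
#' @param lambda_grid grid over which the profile likelihood is evaluated.
#' @return an object of class `boxcox_scores`: list with `scores` (input
#'   columns plus `fitness_t`), `lambda`, `shift`, `shapiro_p`, `levene_p`.
#' @export
boxcox_transform <- function(scores, shift = NULL,
                             lambda_grid = seq(-2, 2, by = 0.01)) {
  df <- scores_df(scores)
  stopifnot(all(c("pc1", "population", "year") %in% names(df)))
  if (stats::sd(df$pc1) == 0) stop("scores are constant: Box-Cox undefined", call. = FALSE)
  if (!all(is.finite(df$pc1))) stop("scores must be finite", call. = FALSE)
  shift <- shift %||% (1 - min(df$pc1))
  y <- df$pc1 + shift
  if (any(y <= 0)) stop("shifted scores must be strictly positive", call. = FALSE)
  df$population <- factor(df$population)
  df$year <- factor(df$year)
  dat <- df
  dat$y <- y
  fit <- stats::lm(y ~ population * year, data = dat, y = TRUE, qr = TRUE)
  bc <- MASS::boxcox(fit, lambda = lambda_grid, plotit = FALSE)
  lambda <- bc$x[which.max(bc$y)]
  trans <- if (abs(lambda) < 1e-8) log(y) else (y^lambda - 1) / lambda
  df$fitness_t <- trans
  dat$t <- trans
  tf <- stats::lm(t ~ population * year, data = dat)
  shap <- stats::shapiro.test(stats::residuals(tf))$p.value
  lev <- car::leveneTest(t ~ population:year, data = dat)[["Pr(>F)"]][1]
  structure(list(scores = df, lambda = lambda, shift = shift,
                 profile = data.frame(lambda = bc$x, loglik = bc$y),
                 shapiro_p = shap, levene_p = lev),
            class = "boxcox_scores")
}

tscores_df <- function(tscores) {
  df <- if (inherits(tscores, "boxcox_scores")) tscores$scores else as.data.frame(tscores)
  stopifnot(all(c("fitness_t", "population", "year", "colony_id") %in% names(df)))
  df$population <- factor(df$population)
  df$year <- factor(df$year)
  df$colony_id <- factor(df$colony_id)
  df
}

# keep colonies observed in >= 2 years (the common-garden inclusion rule)
apply_inclusion_rule <- function(df, min_years = 2L) {
  tab <- tapply(df$year, df$colony_id, function(y) length(unique(y)))
  drop <- names(tab)[tab < min_years]
  if (length(drop) > 0) {
    warning(sprintf("excluding %d colony(ies) observed in fewer than %d years",
                    length(drop), min_years))
    df <- df[!(df$colony_id %in% drop), , drop = FALSE]
    df$colony_id <- droplevels(df$colony_id)
  }
  df
}

#' Fixed and mixed response models for transformed fitness scores
#'
#' Fits model 1, `fitness_t ~ population * year` (fixed effects only), and
#' model 2, the same plus a per-colony random intercept, both by maximum
#' likelihood so their log-likelihoods and AICs are directly comparable.
#' Reports the model comparison (logLik, df, AIC, likelihood-ratio test of
#' the random intercept), per-fixed-factor deviance (LRT) tests on model 2,
#' Tukey-style pairwise year contrasts on model-based year means (asymptotic
#' z reference), and the per-colony random intercepts ("nec-int", the
#' individual thermotolerance baseline used as a fitness proxy downstream).
#'
#' @param tscores a [boxcox_transform()] result or data frame with columns
#'   `fitness_t`, `population`, `year`, `colony_id`.
#' @return an object of class `model_comparison`: list with `comparison`
#'   (per-model logLik/df/AIC), `lrt`, `fixed_tests`, `tukey_year`,
#'   `nec_int` (named vector), `singular` flag and the fitted `model1`,
#'   `model2`.
#' @export
fit_response_models <- function(tscores) {
  df <- apply_inclusion_rule(tscores_df(tscores))
  if (nlevels(df$population) < 2L || nlevels(df$year) < 2L) {
    stop("need at least 2 levels of population and year", call. = FALSE)
  }
  m1 <- stats::lm(fitness_t ~ population * year, data = df)
  m2 <- lme4::lmer(fitness_t ~ population * year + (1 | colony_id),
                   data = df, REML = FALSE)
  ll1 <- stats::logLik(m1); ll2 <- stats::logLik(m2)
  comparison <- data.frame(
    model = c("fixed (population * year)",
              "mixed (population * year + colony random intercept)"),
    logLik = c(as.numeric(ll1), as.numeric(ll2)),
    df = c(attr(ll1, "df"), attr(ll2, "df")),
    AIC = c(stats::AIC(m1), stats::AIC(m2))
  )
  chi2 <- 2 * (as.numeric(ll2) - as.numeric(ll1))
  df_diff <- attr(ll2, "df") - attr(ll1, "df")
  lrt <- data.frame(chi2 = chi2, df = df_diff,
                    p = stats::pchisq(chi2, df_diff, lower.tail = FALSE))

  drop_fit <- function(formula) {
    lme4::lmer(formula, data = df, REML = FALSE)
  }
  m_no_year <- drop_fit(fitness_t ~ population + (1 | colony_id))
  m_no_pop <- drop_fit(fitness_t ~ year + (1 | colony_id))
  m_no_int <- drop_fit(fitness_t ~ population + year + (1 | colony_id))
  lrt_row <- function(reduced, label) {
    llr <- stats::logLik(reduced)
    d <- attr(ll2, "df") - attr(llr, "df")
    x2 <- 2 * (as.numeric(ll2) - as.numeric(llr))
    data.frame(factor = label, chi2 = x2, df = d,
               p = stats::pchisq(x2, d, lower.tail = FALSE))
  }
  fixed_tests <- rbind(lrt_row(m_no_year, "year"),
                       lrt_row(m_no_pop, "population"),
                       lrt_row(m_no_int, "population:year"))

  emm <- emmeans::emmeans(m2, "year", lmer.df = "asymptotic")
  tukey <- as.data.frame(summary(
    emmeans::contrast(emm, method = "pairwise", adjust = "tukey")))

  re <- lme4::ranef(m2)$colony_id
  nec_int <- stats::setNames(re[, 1], rownames(re))
  singular <- lme4::isSingular(m2)
  if (singular) warning("mixed-model fit is singular (random-intercept variance at 0)")

  structure(list(comparison = comparison, lrt = lrt, fixed_tests = fixed_tests,
                 tukey_year = tukey, nec_int = nec_int, singular = singular,
                 sigma_individual = sqrt(lme4::VarCorr(m2)$colony_id[1, 1]),
                 model1 = m1, model2 = m2),
            class = "model_comparison")
}

#' Per-factor variance-contribution statistic
#'
#' Quantifies the contribution of the year, individual, population and
#' population-by-year factors to the response as the log-likelihood lost when
#' the factor is removed from the full mixed model, divided by the change in
#' parameter count: `C_f = (logLik_full - logLik_without_f) / (df_full -
#' df_without_f)`. All models are fitted by maximum likelihood on the same
#' cases. Raw contributions are floored at zero and normalised to percentages
#' summing to 100.
#'
#' @param tscores a [boxcox_transform()] result or a data frame as in
#'   [fit_response_models()].
#' @return a `data.frame` of class `variance_partition` with columns `factor`,
#'   `delta_loglik`, `delta_df`, `raw` and `contribution_pct`.
#' @export
variance_partition <- function(tscores) {
  df <- apply_inclusion_rule(tscores_df(tscores))
  full <- lme4::lmer(fitness_t ~ population * year + (1 | colony_id),
                     data = df, REML = FALSE)
  wo <- list(
    year = lme4::lmer(fitness_t ~ population + (1 | colony_id),
                      data = df, REML = FALSE),
    individual = stats::lm(fitness_t ~ population * year, data = df),
    population = lme4::lmer(fitness_t ~ year + (1 | colony_id),
                            data = df, REML = FALSE),
    `population:year` = lme4::lmer(fitness_t ~ population + year + (1 | colony_id),
                                   data = df, REML = FALSE)
  )
  ll_full <- stats::logLik(full)
  rows <- lapply(names(wo), function(f) {
    ll <- stats::logLik(wo[[f]])
    ddf <- attr(ll_full, "df") - attr(ll, "df")
    if (ddf <= 0) stop("reduced model is not nested in the full model", call. = FALSE)
    dll <- as.numeric(ll_full) - as.numeric(ll)
    data.frame(factor = f, delta_loglik = dll, delta_df = ddf,
               raw = max(0, dll / ddf))
  })
  out <- do.call(rbind, rows)
  total <- sum(out$raw)
  out$contribution_pct <- if (total > 0) 100 * out$raw / total else rep(NA_real_, nrow(out))
  rownames(out) <- NULL
  structure(out, class = c("variance_partition", "data.frame"))
}

#' One-way ANOVA of a field necrosis survey
#'
#' Parametric one-way ANOVA of percentage tissue necrosis with population as
#' the factor, followed by Tukey HSD pairwise contrasts, plus per-population
#' means and SDs.
#'
#' @param survey a `data.frame` with columns `population`, `necrosis_pct`;
#'   at least two groups with two observations each.
#' @return a list of class `survey_anova`: `F`, `p`, `tukey` (Tukey HSD
#'   table), `group_stats` and the fitted `aov` object.
#' @export
survey_anova <- function(survey) {
  stopifnot(is.data.frame(survey),
            all(c("population", "necrosis_pct") %in% names(survey)))
  survey$population <- factor(survey$population)
  counts <- table(survey$population)
  if (length(counts) < 2L) stop("need at least two populations", call. = FALSE)
  if (any(counts < 2L)) stop("every population needs at least 2 observations", call. = FALSE)
  fit <- stats::aov(necrosis_pct ~ population, data = survey)
  s <- summary(fit)[[1]]
  gs <- aggregate(necrosis_pct ~ population, data = survey,
                  FUN = function(v) c(n = length(v), mean = mean(v), sd = stats::sd(v)))
  gs <- data.frame(population = gs$population, as.data.frame(gs$necrosis_pct))
  structure(list(F = s[["F value"]][1], p = s[["Pr(>F)"]][1],
                 tukey = as.data.frame(stats::TukeyHSD(fit)$population),
                 group_stats = gs, fit = fit),
            class = "survey_anova")
}
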