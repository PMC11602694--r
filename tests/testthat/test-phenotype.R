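test_that("daily descriptors match hand arithmetic on a 3-colony toy", {
  vals <- list(c1 = list(`2015` = c(0, 0)), c2 = list(`2015` = c(10, 15)),
               c3 = list(`2015` = c(95, 100)))
  # colonies must appear in >= 2 years for panel semantics elsewhere, but
  # descriptors operate on any panel rows; day 27-28 toy
  panel <- toy_panel(vals, days = 27:28)
  d <- compute_daily_descriptors(panel)
  d28 <- d[d$day == 28, ]
  expect_equal(d28$mean_extent, mean(c(0, 15, 100)))
  expect_equal(d28$se_extent, sd(c(0, 15, 100)) / sqrt(3))
  expect_equal(d28$pct_affected, 100 * 2 / 3)
  expect_equal(d28$pct_dead, 100 * 1 / 3)
  # all-zero panel
  z <- toy_panel(list(a = list(`2015` = c(0, 0)), b = list(`2015` = c(0, 0))),
                 days = 1:2)
  dz <- compute_daily_descriptors(z)
  expect_true(all(dz$mean_extent == 0 & dz$pct_affected == 0 & dz$pct_dead == 0))
})

test_that("impact classes respect the 10/30/60 boundaries", {
  x <- c(0, 5, 9.9, 10, 15, 30, 30.1, 45, 60, 60.1, 75, 100)
  got <- as.character(classify_impact(x))
  expect_equal(got, c("none", "none", "none", "low", "low", "low", "moderate",
                      "moderate", "moderate", "severe", "severe", "severe"))
  expect_error(classify_impact(101), "within")
  expect_error(classify_impact(-1), "within")
})

test_that("PCA on a shift-structured panel is rank-1 and matches eigen oracle", {
  # necrosis(i, d) = 5 * (i + d - 10): columns are shifts of one template,
  # so all retained-day columns correlate perfectly
  days <- 1:24
  vals <- list()
  for (i in 1:4) {
    v <- pmax(0, 5 * (i + days - 10)) * (days >= 10)
    vals[[paste0("c", i)]] <- list(`2015` = v)
  }
  panel <- toy_panel(vals, days = days)
  fs <- fit_fitness_pca(panel, trim_before_day = 10)
  expect_gt(fs$var_explained[1], 99.999)
  # oracle: eigendecomposition of the correlation matrix of retained days
  mat <- matrix(unlist(lapply(vals, function(l) l$`2015`[10:24])),
                nrow = 4, byrow = TRUE)
  ev <- eigen(cor(mat))$values
  expect_equal(fs$var_explained[1], 100 * ev[1] / sum(ev), tolerance = 1e-8)
  # scores ordered with the multiplier and positively tied to final necrosis
  sc <- fs$scores$pc1[order(fs$scores$colony_id)]
  expect_true(all(diff(sc) > 0))
})

test_that("PC1 orientation is positive towards final-day necrosis", {
  panel <- simulate_necrosis_panel(sim_config(seed = 4))
  fs <- fit_fitness_pca(panel)
  d28 <- panel[panel$day == max(panel$day), ]
  key <- paste(d28$colony_id, d28$year)
  skey <- paste(fs$scores$colony_id, fs$scores$year)
  expect_gt(cor(fs$scores$pc1, d28$necrosis_pct[match(skey, key)]), 0)
})

test_that("Box-Cox recovers lambda ~ 1 for normal and ~ 0 for log-normal scores", {
  set.seed(42)
  df <- expand.grid(colony_id = sprintf("c%02d", 1:40), year = 2015:2017,
                    stringsAsFactors = FALSE)
  df$population <- rep(c("p1", "p2"), length.out = nrow(df))
  df$pc1 <- rnorm(nrow(df))
  bc1 <- boxcox_transform(df)
  expect_lt(abs(bc1$lambda - 1), 0.35)
  # near-affine transform: standardized scores essentially unchanged
  z0 <- as.numeric(scale(df$pc1 + bc1$shift))
  z1 <- as.numeric(scale(bc1$scores$fitness_t))
  expect_gt(cor(z0, z1), 0.995)

  df$pc1 <- exp(rnorm(nrow(df)))
  bc0 <- boxcox_transform(df, shift = 0)
  expect_lt(abs(bc0$lambda), 0.25)

  df$pc1 <- rep(1, nrow(df))
  expect_error(boxcox_transform(df), "constant")
})

test_that("response models prefer the random intercept when colonies differ", {
  panel <- simulate_necrosis_panel(sim_config(seed = 5))
  bc <- boxcox_transform(fit_fitness_pca(panel))
  m <- suppressMessages(suppressWarnings(fit_response_models(bc)))
  expect_lt(m$comparison$AIC[2], m$comparison$AIC[1])
  expect_lt(m$lrt$p, 0.001)
  # AIC identity for every reported model
  expect_equal(m$comparison$AIC, 2 * m$comparison$df - 2 * m$comparison$logLik)
  # year is the significant fixed factor under the default conditions
  ft <- m$fixed_tests
  expect_lt(ft$p[ft$factor == "year"], 1e-6)
  # nec-int: centred over colonies
  expect_lt(abs(mean(m$nec_int)), 0.15 * sd(m$nec_int) + 1e-8)
  # Tukey year contrasts: all pairs involving the catastrophic year stand out
  tk <- m$tukey_year
  hot <- grepl("2017", tk$contrast)
  expect_true(all(tk$p.value[hot] < 0.01))
})

test_that("random-intercept LRT is calibrated when colonies are exchangeable", {
  ps <- vapply(1:30, function(s) {
    cfg <- sim_config(seed = s, n_colonies_per_pop = 8, sigma_individual = 0,
                      year_effects = c(0, 0.3, 0.6))
    bc <- boxcox_transform(fit_fitness_pca(simulate_necrosis_panel(cfg)))
    df <- heatgarden:::apply_inclusion_rule(heatgarden:::tscores_df(bc))
    m1 <- lm(fitness_t ~ population * year, data = df)
    m2 <- suppressMessages(suppressWarnings(
      lme4::lmer(fitness_t ~ population * year + (1 | colony_id),
                 data = df, REML = FALSE)))
    pchisq(2 * (as.numeric(logLik(m2)) - as.numeric(logLik(m1))), 1,
           lower.tail = FALSE)
  }, numeric(1))
  # boundary LRT with a 1-df reference is conservative: rejections stay rare
  expect_lte(mean(ps < 0.05), 0.15)
})

test_that("variance partition matches an analytic fixed-effects likelihood oracle", {
  # no colony effect: the mixed fits collapse to the fixed models, whose ML
  # log-likelihood has the closed form -n/2 (log(2 pi RSS/n) + 1)
  set.seed(9)
  df <- expand.grid(colony_id = sprintf("c%02d", 1:30), year = factor(2015:2017))
  df$population <- factor(rep(c("p1", "p2", "p3"), each = 10)[
    match(df$colony_id, sprintf("c%02d", 1:30))])
  df$fitness_t <- 2 * (df$year == "2016") + 5 * (df$year == "2017") +
    0.8 * (df$population == "p2") + rnorm(nrow(df), 0, 1)
  vp <- suppressMessages(suppressWarnings(variance_partition(df)))
  expect_equal(sum(vp$contribution_pct), 100, tolerance = 0.01)

  ll_hat <- function(form) {
    rss <- sum(residuals(lm(form, data = df))^2)
    n <- nrow(df)
    -n / 2 * (log(2 * pi * rss / n) + 1)
  }
  ll_full <- ll_hat(fitness_t ~ population * year)
  oracle <- c(
    year = max(0, (ll_full - ll_hat(fitness_t ~ population)) / 6),
    individual = 0,
    population = max(0, (ll_full - ll_hat(fitness_t ~ year)) / 6),
    `population:year` = max(0, (ll_full - ll_hat(fitness_t ~ population + year)) / 4)
  )
  oracle_pct <- 100 * oracle / sum(oracle)
  got <- setNames(vp$contribution_pct, vp$factor)[names(oracle_pct)]
  expect_equal(unname(got), unname(oracle_pct), tolerance = 0.5)
})

test_that("a year-effects-only response attributes almost all contribution to year", {
  shares <- vapply(1:10, function(s) {
    cfg <- sim_config(seed = s, n_colonies_per_pop = 10, sigma_individual = 0,
                      sigma_population = 0)
    bc <- boxcox_transform(fit_fitness_pca(simulate_necrosis_panel(cfg)))
    vp <- suppressMessages(suppressWarnings(variance_partition(bc)))
    vp$contribution_pct[vp$factor == "year"]
  }, numeric(1))
  expect_gt(median(shares), 95)
})

test_that("survey ANOVA matches hand-computed mean squares and rejects bad input", {
  sv <- data.frame(population = rep(c("a", "b", "c"), each = 3),
                   necrosis_pct = c(1, 2, 3, 2, 3, 4, 6, 7, 8))
  res <- survey_anova(sv)
  expect_equal(res$F, 21)  # MSB = 42/2, MSW = 6/6
  expect_equal(nrow(res$tukey), 3)
  expect_error(survey_anova(data.frame(population = "a", necrosis_pct = 1:5)),
               "two populations")
})

test_that("survey ANOVA p-values are uniform when populations are identical", {
  cfg0 <- sim_config(seed = 1, survey_zero_prob = 0.2,
                     survey_beta_shape1 = 0.5, survey_beta_shape2 = 1)
  ps <- vapply(1:200, function(s) {
    cfg <- cfg0; cfg$seed <- s
    survey_anova(simulate_field_survey(cfg))$p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})
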