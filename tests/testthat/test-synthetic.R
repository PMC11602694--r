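test_that("necrosis trajectories are on-grid, monotone and absorbing at 100", {
  for (s in 1:6) {
    panel <- simulate_necrosis_panel(sim_config(seed = s))
    expect_true(all(panel$necrosis_pct %in% seq(0, 100, by = 5)))
    by_case <- split(panel$necrosis_pct, paste(panel$colony_id, panel$year))
    expect_true(all(vapply(by_case, function(v) all(diff(v) >= 0), logical(1))))
    # absorption: once at 100, stays at 100
    expect_true(all(vapply(by_case, function(v) {
      hit <- which(v == 100)
      length(hit) == 0L || all(v[hit[1]:length(v)] == 100)
    }, logical(1))))
    # inclusion rule: every colony in >= 2 years
    ny <- tapply(panel$year, panel$colony_id, function(y) length(unique(y)))
    expect_true(all(ny >= 2))
  }
})

test_that("with all effects and noise off, trajectories are identical everywhere", {
  cfg <- sim_config(seed = 1, year_effects = c(0, 0, 0), sigma_individual = 0,
                    sigma_population = 0, sigma_residual = 0,
                    missing_year_fraction = 0)
  panel <- simulate_necrosis_panel(cfg)
  ref <- panel$necrosis_pct[panel$colony_id == panel$colony_id[1] &
                              panel$year == panel$year[1]]
  by_case <- split(panel$necrosis_pct, paste(panel$colony_id, panel$year))
  expect_true(all(vapply(by_case, identical, logical(1), y = ref)))
})

test_that("a far-elevated year has the highest final necrosis in every population", {
  panel <- simulate_necrosis_panel(sim_config(seed = 11))
  d28 <- panel[panel$day == max(panel$day), ]
  m <- tapply(d28$necrosis_pct, list(d28$year, d28$population), mean)
  expect_true(all(apply(m, 2, which.max) == nrow(m)))  # last year = hot year
  # catastrophic year: everyone dead well before the assay end
  hot <- panel[panel$year == 2017 & panel$day == 24, ]
  expect_true(all(hot$necrosis_pct == 100))
})

test_that("config validation rejects impossible designs", {
  expect_error(sim_config(n_days = 8), "n_days")
  expect_error(sim_config(sigma_individual = -1), "sigma_individual")
  expect_error(sim_config(theta_target = 1), "theta_target")
  expect_error(sim_config(alleles_per_locus = c(1, 4)), "alleles_per_locus")
  expect_error(sim_config(injected_events = list(list(start = "2015-01-01",
                                                      duration = 0, fold = 1))),
               "durations")
  expect_error(simulate_temperature_series(sim_config(n_temp_years = 1)),
               "2 full years")
})

test_that("panmictic genotypes give near-zero global theta on average", {
  th <- vapply(1:40, function(s) {
    gm <- simulate_genotypes(sim_config(seed = s, theta_target = 0))
    wc_fst(gm, n_permutations = 0)$global_theta
  }, numeric(1))
  expect_lt(abs(mean(th)), 0.01)
})

test_that("strong simulated structure is recovered as K = 3 with clean assignments", {
  hits <- 0L
  for (s in 1:5) {
    gm <- simulate_genotypes(sim_config(seed = s, theta_target = 0.2))
    d <- dapc_clusters(gm, seed = s)
    if (d$chosen_k == 3L) {
      # assignments match true populations up to label permutation,
      # allowing a few stragglers
      tab <- d$cluster_by_population
      acc <- sum(apply(tab, 1, max)) / sum(tab)
      hits <- hits + as.integer(acc >= 0.85)
      expect_gt(d$mean_membership, 0.8)
    }
  }
  expect_gte(hits, 4L)
})

test_that("overlapping injected thermal events are rejected", {
  cfg <- sim_config(seed = 1, injected_events = list(
    list(start = "2016-06-01", duration = 10, fold = 1.5),
    list(start = "2016-06-08", duration = 5, fold = 1.5)))
  expect_error(simulate_temperature_series(cfg), "overlap")
})

test_that("temperature ground-truth event windows are recorded exactly", {
  cfg <- sim_config(seed = 2, injected_events = list(
    list(start = "2016-06-10", duration = 7, fold = 1.5)))
  ts <- simulate_temperature_series(cfg)
  tr <- attr(ts, "events")
  expect_equal(tr$start, as.Date("2016-06-10"))
  expect_equal(tr$end, as.Date("2016-06-16"))
  expect_equal(tr$duration, 7L)
})

test_that("survey mixture yields heavy-tailed impacted populations", {
  sv <- simulate_field_survey(sim_config(seed = 3, survey_n_per_pop = 200))
  st <- aggregate(necrosis_pct ~ population, sv,
                  function(v) c(mean = mean(v), sd = sd(v)))
  st <- data.frame(population = st$population, as.data.frame(st$necrosis_pct))
  # the two heavily impacted populations: SD exceeds the mean
  expect_true(all(st$sd[2:3] > st$mean[2:3]))
  expect_true(any(sv$necrosis_pct == 0))
  expect_true(all(sv$necrosis_pct %in% seq(0, 100, 5)))
})
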