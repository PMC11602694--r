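#' Simulation configuration for the synthetic common-garden study
#'
#' Bundles every parameter of the synthetic-data generator. The defaults
#' emulate the design of the motivating field study: three source populations
#' of 30 tagged colonies assayed in three yearly common gardens of 28 days,
#' necrosis variance dominated by the year effect (one catastrophic year) with
#' individual random intercepts, 14 microsatellite loci with weak population
#' differentiation, and a multi-year daily temperature series with a seasonal
#' cycle, AR(1) noise and optionally injected warm anomalies.
#'
#' @param seed integer; global seed from which all sub-generators derive
#'   deterministic child seeds (see [derive_seed()]).
#' @param n_populations,n_colonies_per_pop design size.
#' @param years vector of year labels for the common gardens.
#' @param n_days assay duration in days (must be >= 10 so the trimmed PCA has
#'   day columns to work with).
#' @param year_effects per-year shift of the latent necrosis propensity
#'   (logit-scale units); one value per year. The default makes the last year
#'   catastrophic (all colonies reach 100\% necrosis before the end), the
#'   first two moderate.
#' @param mu baseline latent propensity (logit scale) at day 1.
#' @param day_slope deterministic daily increase of the latent propensity.
#' @param sigma_individual SD of the per-colony random intercept.
#' @param sigma_population SD of the population effect (near zero by default:
#'   the emulated study found a negligible population component).
#' @param sigma_residual SD of the day-level latent noise.
#' @param missing_year_fraction probability that a colony misses exactly one
#'   (uniformly chosen) year; completely at random, applied only when three or
#'   more gardens exist so every colony still satisfies the two-garden
#'   inclusion rule.
#' @param n_loci,alleles_per_locus microsatellite panel size; `alleles_per_locus`
#'   is a length-2 range from which each locus' allele count is drawn.
#' @param theta_target drift parameter of the Balding-Nichols model; equals
#'   the expected Weir-Cockerham F_ST, which is what makes it a closed-form
#'   calibration target.
#' @param temp_baseline named vector `c(mean, amplitude, peak_doy)`: annual
#'   mean temperature (deg C), seasonal semi-amplitude (deg C) and day of year
#'   of the seasonal maximum.
#' @param ar1_phi,ar1_sigma AR(1) parameters of the daily temperature noise.
#' @param first_temp_year,n_temp_years span of the simulated daily series.
#' @param injected_events list of warm anomalies, each a list with elements
#'   `start` ("YYYY-MM-DD"), `duration` (days, >= 1) and `fold` (peak
#'   exceedance in units of the local iT90 - climatological-mean width).
#'   Overlapping events are rejected.
#' @param survey_n_per_pop colonies surveyed per population in the field
#'   survey.
#' @param survey_zero_prob per-population probability of an unimpacted (0\%)
#'   colony.
#' @param survey_beta_shape1,survey_beta_shape2 per-population Beta shape
#'   parameters of the impacted-colony necrosis fraction; the defaults give
#'   one mildly impacted population and two with heavy right tails (SD
#'   exceeding the mean, as observed in situ).
#'
#' @return an object of class `sim_config` (a validated list).
#' @seealso [simulate_necrosis_panel()], [simulate_genotypes()],
#'   [simulate_temperature_series()], [simulate_field_survey()]
#' @export
sim_config <- function(seed = 1L,
                       n_populations = 3L,
                       n_colonies_per_pop = 30L,
                       years = c(2015L, 2016L, 2017L),
                       n_days = 28L,
                       year_effects = c(0, 0.5, 7),
                       mu = -5,
                       day_slope = 0.12,
                       sigma_individual = 0.35,
                       sigma_population = 0.05,
                       sigma_residual = 0.8,
                       missing_year_fraction = 0.15,
                       n_loci = 14L,
                       alleles_per_locus = c(3L, 8L),
                       theta_target = 0.015,
                       temp_baseline = c(mean = 17.5, amplitude = 5, peak_doy = 227),
                       ar1_phi = 0.8,
                       ar1_sigma = 0.4,
                       first_temp_year = 2010L,
                       n_temp_years = 8L,
                       injected_events = list(),
                       survey_n_per_pop = 20L,
                       survey_zero_prob = c(0.30, 0.15, 0.20),
                       survey_beta_shape1 = c(1.0, 0.30, 0.35),
                       survey_beta_shape2 = c(11, 0.62, 0.75)) {
  assert_scalar_number(n_days, "n_days", min = 10)
  assert_scalar_number(sigma_individual, "sigma_individual", min = 0)
  assert_scalar_number(sigma_population, "sigma_population", min = 0)
  assert_scalar_number(sigma_residual, "sigma_residual", min = 0)
  assert_scalar_number(ar1_sigma, "ar1_sigma", min = 0)
  assert_scalar_number(theta_target, "theta_target", min = 0)
  if (theta_target >= 1) stop("`theta_target` must be < 1", call. = FALSE)
  assert_scalar_number(missing_year_fraction, "missing_year_fraction", 0, 1)
  if (length(year_effects) != length(years)) {
    stop("`year_effects` must have one value per year", call. = FALSE)
  }
  if (length(alleles_per_locus) != 2L || any(alleles_per_locus < 2L)) {
    stop("`alleles_per_locus` must be a range with minimum >= 2", call. = FALSE)
  }
  for (ev in injected_events) {
    if (is.null(ev$start) || is.null(ev$duration) || is.null(ev$fold)) {
      stop("each injected event needs `start`, `duration` and `fold`", call. = FALSE)
    }
    if (ev$duration < 1) stop("injected event durations must be >= 1 day", call. = FALSE)
  }
  cfg <- list(
    seed = as.integer(seed),
    n_populations = as.integer(n_populations),
    n_colonies_per_pop = as.integer(n_colonies_per_pop),
    years = years, n_days = as.integer(n_days),
    year_effects = year_effects, mu = mu, day_slope = day_slope,
    sigma_individual = sigma_individual, sigma_population = sigma_population,
    sigma_residual = sigma_residual,
    missing_year_fraction = missing_year_fraction,
    n_loci = as.integer(n_loci),
    alleles_per_locus = as.integer(alleles_per_locus),
    theta_target = theta_target,
    temp_baseline = temp_baseline, ar1_phi = ar1_phi, ar1_sigma = ar1_sigma,
    first_temp_year = as.integer(first_temp_year),
    n_temp_years = as.integer(n_temp_years),
    injected_events = injected_events,
    survey_n_per_pop = as.integer(survey_n_per_pop),
    survey_zero_prob = rep(survey_zero_prob, length.out = n_populations),
    survey_beta_shape1 = rep(survey_beta_shape1, length.out = n_populations),
    survey_beta_shape2 = rep(survey_beta_shape2, length.out = n_populations)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate a daily necrosis panel
#'
#' Generates one 28-day necrosis trajectory per colony x year from a latent
#' cumulative-propensity model: `L(i, y, d) = mu + beta_year + pi_pop + u_i +
#' day_slope * (d - 1) + eps(i, y, d)`, made monotone by a running maximum and
#' mapped to the visual 5\%-step scoring grid through
#' `100 * plogis(L)`. Monotone non-decrease and absorption at 100\% hold by
#' construction. A completely-at-random single-year dropout emulates colonies
#' that could not be retrieved for one garden; with three or more gardens every
#' colony still satisfies the "present in at least two gardens" inclusion rule.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `necrosis_panel` with columns `colony_id`,
#'   `population`, `year`, `day`, `necrosis_pct`, carrying the generative
#'   ground truth (colony intercepts, population and year effects) in
#'   `attr(, "truth")`.
#' @export
simulate_necrosis_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 1L))
  pops <- paste0("pop", seq_len(config$n_populations))
  pop_eff <- stats::rnorm(config$n_populations, 0, config$sigma_population)
  names(pop_eff) <- pops
  n_years <- length(config$years)
  days <- seq_len(config$n_days)

  rows <- vector("list", config$n_populations * config$n_colonies_per_pop)
  u_all <- numeric(0)
  k <- 0L
  for (p in seq_along(pops)) {
    for (i in seq_len(config$n_colonies_per_pop)) {
      k <- k + 1L
      id <- sprintf("%s_c%02d", pops[p], i)
      u_i <- stats::rnorm(1, 0, config$sigma_individual)
      u_all[id] <- u_i
      present <- rep(TRUE, n_years)
      if (n_years >= 3L &&
          stats::runif(1) < config$missing_year_fraction) {
        present[sample.int(n_years, 1L)] <- FALSE
      }
      traj <- vector("list", sum(present))
      j <- 0L
      for (y in which(present)) {
        j <- j + 1L
        eps <- stats::rnorm(config$n_days, 0, config$sigma_residual)
        lat <- config$mu + config$year_effects[y] + pop_eff[p] + u_i +
          config$day_slope * (days - 1) + eps
        lat <- cummax(lat)
        nec <- snap_to_grid(100 * stats::plogis(lat))
        traj[[j]] <- data.frame(
          colony_id = id, population = pops[p], year = config$years[y],
          day = days, necrosis_pct = nec, stringsAsFactors = FALSE
        )
      }
      rows[[k]] <- do.call(rbind, traj)
    }
  }
  panel <- do.call(rbind, rows)
  rownames(panel) <- NULL
  structure(panel,
            class = c("necrosis_panel", "data.frame"),
            truth = list(year_effects = stats::setNames(config$year_effects,
                                                        config$years),
                         population_effects = pop_eff,
                         colony_intercepts = u_all,
                         mu = config$mu, day_slope = config$day_slope,
                         sigma_residual = config$sigma_residual))
}

#' Simulate diploid microsatellite genotypes
#'
#' Draws per-population allele frequencies from a Balding-Nichols drift model
#' around ancestral frequencies: at each locus the ancestral frequency vector
#' `p` is Dirichlet(1), and each population's frequencies are
#' `Dirichlet(p * (1 - theta) / theta)` so that the expected Weir-Cockerham
#' F_ST equals `theta_target`. Genotypes are then drawn under within-population
#' Hardy-Weinberg proportions. `theta_target = 0` collapses to panmixia (all
#' populations share the ancestral frequencies).
#'
#' @param config a [sim_config()].
#' @return a [genotype_matrix()] whose individual IDs match the colony IDs of
#'   [simulate_necrosis_panel()] under the same configuration.
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 2L))
  pops <- paste0("pop", seq_len(config$n_populations))
  ids <- as.vector(vapply(pops, function(p) {
    sprintf("%s_c%02d", p, seq_len(config$n_colonies_per_pop))
  }, character(config$n_colonies_per_pop)))
  population <- rep(pops, each = config$n_colonies_per_pop)
  n_ind <- length(ids)
  loci <- sprintf("loc%02d", seq_len(config$n_loci))

  rdirichlet1 <- function(alpha) {
    g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
    if (all(g == 0)) g[which.max(alpha)] <- 1
    g / sum(g)
  }

  calls <- array(NA_integer_, dim = c(n_ind, config$n_loci, 2L),
                 dimnames = list(ids, loci, c("a1", "a2")))
  for (l in seq_len(config$n_loci)) {
    n_all <- sample(seq(config$alleles_per_locus[1], config$alleles_per_locus[2]), 1L)
    anc <- rdirichlet1(rep(1, n_all))
    for (p in seq_along(pops)) {
      if (config$theta_target == 0) {
        freq <- anc
      } else {
        th <- config$theta_target
        freq <- rdirichlet1(anc * (1 - th) / th)
      }
      idx <- which(population == pops[p])
      draws <- sample.int(n_all, size = 2L * length(idx), replace = TRUE, prob = freq)
      calls[idx, l, 1L] <- draws[seq_along(idx)]
      calls[idx, l, 2L] <- draws[length(idx) + seq_along(idx)]
    }
  }
  genotype_matrix(calls, ids = ids, populations = population, loci = loci)
}

#' Simulate a daily seawater temperature series
#'
#' Daily mean temperatures are a sinusoidal seasonal cycle plus stationary
#' AR(1) noise, with an additive warm anomaly over each injected event window.
#' Injected anomalies are expressed in "folds" of the local climatological
#' threshold width (iT90 minus climatological mean), the same scale the event
#' detector uses for severity categories, so a `fold = 1.5` injection peaks in
#' the "Moderate" band. The generator builds the climatology of its own
#' noise-free-plus-noise base series to convert folds to deg C; if that width
#' is degenerate (constant series) a 0.5 deg C fallback width is used.
#'
#' @param config a [sim_config()]; events in `config$injected_events` must not
#'   overlap.
#' @return a `data.frame` of class `temperature_series` with columns `date`
#'   and `temp_c`; the exact injected windows are recorded in
#'   `attr(, "events")` as ground truth for tests.
#' @export
simulate_temperature_series <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_temp_years < 2L) {
    stop("at least 2 full years are required so a climatology exists", call. = FALSE)
  }
  set.seed(derive_seed(config$seed, 3L))
  d0 <- as.Date(sprintf("%d-01-01", config$first_temp_year))
  d1 <- as.Date(sprintf("%d-12-31", config$first_temp_year + config$n_temp_years - 1L))
  dates <- seq(d0, d1, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  tb <- config$temp_baseline
  seasonal <- tb[["mean"]] +
    tb[["amplitude"]] * cos(2 * pi * (doy - tb[["peak_doy"]]) / 365.25)
  noise <- numeric(n)
  if (config$ar1_sigma > 0) {
    marg <- config$ar1_sigma / sqrt(1 - config$ar1_phi^2)
    noise[1] <- stats::rnorm(1, 0, marg)
    innov <- stats::rnorm(n - 1, 0, config$ar1_sigma)
    for (t in 2:n) noise[t] <- config$ar1_phi * noise[t - 1] + innov[t - 1]
  }
  temp <- seasonal + noise

  events <- config$injected_events
  truth <- data.frame(start = as.Date(character(0)), end = as.Date(character(0)),
                      duration = integer(0), fold = numeric(0))
  if (length(events) > 0) {
    base <- data.frame(date = dates, temp_c = temp)
    class(base) <- c("temperature_series", "data.frame")
    clim <- build_climatology(base)
    width <- clim$it90 - clim$clim_mean
    width <- pmax(width, 0.5 * (max(width) <= 1e-9))  # fallback for constant series
    windows <- lapply(events, function(ev) {
      s <- as.Date(ev$start)
      seq(s, s + ev$duration - 1L, by = "day")
    })
    all_days <- do.call(c, windows)
    if (anyDuplicated(all_days)) {
      stop("injected events overlap", call. = FALSE)
    }
    for (j in seq_along(events)) {
      idx <- match(windows[[j]], dates)
      if (anyNA(idx)) stop("injected event outside the simulated date range", call. = FALSE)
      temp[idx] <- temp[idx] + events[[j]]$fold * width[match(doy[idx], clim$doy)]
    }
    truth <- data.frame(
      start = as.Date(vapply(events, function(e) e$start, character(1))),
      duration = vapply(events, function(e) as.integer(e$duration), integer(1)),
      fold = vapply(events, function(e) e$fold, numeric(1))
    )
    truth$end <- truth$start + truth$duration - 1L
    truth <- truth[c("start", "end", "duration", "fold")]
  }
  structure(data.frame(date = dates, temp_c = temp),
            class = c("temperature_series", "data.frame"),
            events = truth)
}

#' Simulate an in-situ necrosis field survey
#'
#' Per-colony percentage necrosis is drawn from a population-specific
#' zero-inflated Beta mixture: a point mass at 0 (unimpacted colonies) and a
#' Beta-distributed graded impact otherwise, rounded to the 5\% visual grid.
#' The default shapes make one population mildly impacted and two heavily
#' right-tailed (standard deviation larger than the mean), the pattern seen in
#' post-heatwave surveys.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` of class `survey_table` with columns `colony_id`,
#'   `population`, `necrosis_pct`.
#' @export
simulate_field_survey <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(derive_seed(config$seed, 4L))
  pops <- paste0("pop", seq_len(config$n_populations))
  rec <- function(p) {
    n <- config$survey_n_per_pop
    zero <- stats::rbinom(n, 1, config$survey_zero_prob[[p]]) == 1
    x <- 100 * stats::rbeta(n, config$survey_beta_shape1[[p]],
                            config$survey_beta_shape2[[p]])
    x[zero] <- 0
    data.frame(colony_id = sprintf("%s_s%02d", pops[p], seq_len(n)),
               population = pops[p],
               necrosis_pct = snap_to_grid(x),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(seq_along(pops), rec))
  rownames(out) <- NULL
  structure(out, class = c("survey_table", "data.frame"))
}
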