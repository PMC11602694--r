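# End-to-end orchestration: one config in, per-stage artifacts and a
# consolidated machine-readable report out.

#' Pipeline configuration
#'
#' Collects the inputs and stage parameters of a full run. Inputs are either
#' file paths (`necrosis`, `genepop`, `temperature`, `survey` CSV/GENEPOP
#' files as written by [write_report()]) or a `simulate` block (a
#' [sim_config()]) from which all four inputs are generated.
#'
#' @param simulate a [sim_config()], or `NULL` when paths are given.
#' @param paths named list with elements `necrosis`, `genepop`, `temperature`,
#'   `survey`, or `NULL` when simulating.
#' @param seed global seed; every stochastic stage derives its own seed from
#'   it, so a run is reproducible from the config alone.
#' @param trim_before_day first day retained in the definitive PCA.
#' @param n_permutations permutations for the F_ST differentiation and
#'   heterosis tests.
#' @param n_randomizations randomizations for the slope null distribution.
#' @param max_k,max_pcs DAPC-style clustering parameters.
#' @param baseline_years optional climatology baseline years.
#' @param min_duration MHW minimum duration in days.
#' @param t_threshold extreme-heat-day threshold (deg C).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulate = NULL, paths = NULL, seed = 1L,
                            trim_before_day = 10L, n_permutations = 1000L,
                            n_randomizations = 10000L, max_k = 3L,
                            max_pcs = 100L, baseline_years = NULL,
                            min_duration = 5L, t_threshold = 23.0) {
  if (is.null(simulate) == is.null(paths)) {
    stop("give exactly one of `simulate` or `paths`", call. = FALSE)
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  if (!is.null(paths)) {
    need <- c("necrosis", "genepop", "temperature", "survey")
    if (!all(need %in% names(paths))) {
      stop("`paths` needs elements ", paste(need, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(simulate = simulate, paths = paths, seed = as.integer(seed),
                 trim_before_day = trim_before_day,
                 n_permutations = as.integer(n_permutations),
                 n_randomizations = as.integer(n_randomizations),
                 max_k = as.integer(max_k), max_pcs = as.integer(max_pcs),
                 baseline_years = baseline_years,
                 min_duration = as.integer(min_duration),
                 t_threshold = t_threshold),
            class = "pipeline_config")
}

load_inputs <- function(config) {
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    list(panel = simulate_necrosis_panel(sc),
         genotypes = simulate_genotypes(sc),
         temperature = simulate_temperature_series(sc),
         survey = simulate_field_survey(sc))
  } else {
    p <- config$paths
    list(panel = utils::read.csv(p$necrosis, stringsAsFactors = FALSE),
         genotypes = read_genepop(p$genepop),
         temperature = transform(utils::read.csv(p$temperature,
                                                 stringsAsFactors = FALSE),
                                 date = as.Date(date)),
         survey = utils::read.csv(p$survey, stringsAsFactors = FALSE))
  }
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes every stage in order: input generation/loading, necrosis
#' phenotyping (descriptors, PCA fitness proxy, Box-Cox, response models,
#' variance partition), population genetics (diversity, F_ST, DAPC-style
#' clustering, sMLH, heterosis against nec-int), thermal regime (climatology,
#' MHW/MHS events, summer statistics), genotype-by-environment sensitivity
#' (environmental values, slopes with null-based categories, randomization
#' null), and the field-survey ANOVA. All stochastic stages are seeded from
#' the config's global seed, so two runs of the same config are identical.
#'
#' @param config a [pipeline_config()].
#' @return an object of class `report_bundle`: a nested list with elements
#'   `inputs`, `phenotype`, `popgen`, `thermal`, `gxe`, `survey` and `meta`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed
  inputs <- run_stage("inputs", load_inputs(config))

  phenotype <- run_stage("phenotype", {
    descriptors <- compute_daily_descriptors(inputs$panel)
    pca <- fit_fitness_pca(inputs$panel, trim_before_day = config$trim_before_day)
    bc <- boxcox_transform(pca)
    models <- fit_response_models(bc)
    vp <- variance_partition(bc)
    list(descriptors = descriptors, pca = pca, boxcox = bc,
         models = models, variance_partition = vp)
  })

  popgen <- run_stage("popgen", {
    div <- diversity_summary(inputs$genotypes)
    fst <- wc_fst(inputs$genotypes, n_permutations = config$n_permutations,
                  seed = derive_seed(seed, 11L))
    dapc <- dapc_clusters(inputs$genotypes, max_k = config$max_k,
                          max_pcs = config$max_pcs,
                          seed = derive_seed(seed, 12L))
    smlh <- compute_smlh(inputs$genotypes)
    het <- heterosis_test(phenotype$models$nec_int, smlh,
                          n_perm = config$n_permutations,
                          seed = derive_seed(seed, 13L))
    list(diversity = div, fst = fst, dapc = dapc, smlh = smlh, heterosis = het)
  })

  thermal <- run_stage("thermal", {
    clim <- build_climatology(inputs$temperature,
                              baseline_years = config$baseline_years)
    events <- detect_thermal_events(inputs$temperature, clim,
                                    min_duration = config$min_duration)
    summer <- summer_statistics(inputs$temperature, events,
                                t_threshold = config$t_threshold)
    list(climatology = clim, events = events, summer = summer)
  })

  gxe <- run_stage("gxe", {
    env <- environmental_values(phenotype$pca)
    null <- null_slope_distribution(phenotype$pca, env,
                                    n_randomizations = config$n_randomizations,
                                    seed = derive_seed(seed, 14L))
    slopes <- sensitivity_slopes(phenotype$pca, env,
                                 zero_band = null$central_interval)
    list(environmental_values = env, slopes = slopes, null = null)
  })

  survey <- run_stage("survey", survey_anova(inputs$survey))

  structure(list(inputs = inputs, phenotype = phenotype, popgen = popgen,
                 thermal = thermal, gxe = gxe, survey = survey,
                 meta = list(seed = seed, schema_version = "1.0",
                             package_version = as.character(
                               utils::packageVersion("heatgarden")))),
            class = "report_bundle")
}

bundle_to_report <- function(bundle) {
  ph <- bundle$phenotype
  pg <- bundle$popgen
  list(
    schema_version = bundle$meta$schema_version,
    seed = bundle$meta$seed,
    package_version = bundle$meta$package_version,
    phenotype = list(
      pc1_var_explained = ph$pca$var_explained[1],
      exploratory_pc1_var_explained = ph$pca$exploratory_var_explained[1],
      boxcox_lambda = ph$boxcox$lambda,
      boxcox_shift = ph$boxcox$shift,
      shapiro_p = ph$boxcox$shapiro_p,
      levene_p = ph$boxcox$levene_p,
      model_comparison = ph$models$comparison,
      lrt = ph$models$lrt,
      fixed_tests = ph$models$fixed_tests,
      tukey_year = ph$models$tukey_year,
      variance_partition = as.data.frame(ph$variance_partition)
    ),
    popgen = list(
      global_fst = pg$fst$global_theta,
      global_fst_p = pg$fst$global_p,
      pairwise_fst = pg$fst$pairwise,
      pairwise_fst_p = pg$fst$pairwise_p,
      dapc_chosen_k = pg$dapc$chosen_k,
      dapc_bic = pg$dapc$bic_curve,
      dapc_mean_membership = pg$dapc$mean_membership,
      smlh_range = range(pg$smlh$smlh),
      heterosis_slope = pg$heterosis$observed_slope,
      heterosis_p = pg$heterosis$p_value,
      n_permutations = pg$fst$n_permutations
    ),
    thermal = list(
      events = as.data.frame(bundle$thermal$events),
      summer = as.data.frame(bundle$thermal$summer)
    ),
    gxe = list(
      environmental_values = as.data.frame(bundle$gxe$environmental_values),
      n_common = attr(bundle$gxe$environmental_values, "n_common"),
      mean_slope = mean(bundle$gxe$slopes$slope),
      slope_range = range(bundle$gxe$slopes$slope),
      null_mean = bundle$gxe$null$null_mean,
      null_central_interval = bundle$gxe$null$central_interval,
      exceedance_fraction = bundle$gxe$null$exceedance_fraction,
      n_randomizations = bundle$gxe$null$n_randomizations
    ),
    survey = list(F = bundle$survey$F, p = bundle$survey$p,
                  group_stats = bundle$survey$group_stats,
                  tukey = bundle$survey$tukey)
  )
}

#' Write pipeline artifacts to disk
#'
#' Writes the consolidated JSON report plus CSV exports of every tabular
#' artifact (necrosis panel, survey, temperature series, PCA scores,
#' descriptors, diversity, sMLH, events, summer statistics, sensitivity
#' slopes) and the genotypes as a GENEPOP file. The JSON is deterministic
#' for a fixed-seed run.
#'
#' @param bundle a [run_pipeline()] result.
#' @param outdir output directory (created if missing).
#' @return the report path, invisibly.
#' @export
write_report <- function(bundle, outdir) {
  stopifnot(inherits(bundle, "report_bundle"))
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE)) {
    stop("cannot create output directory ", outdir, call. = FALSE)
  }
  wcsv <- function(x, name) {
    utils::write.csv(as.data.frame(x), file.path(outdir, name), row.names = FALSE)
  }
  wcsv(bundle$inputs$panel, "necrosis_panel.csv")
  wcsv(bundle$inputs$survey, "survey.csv")
  wcsv(bundle$inputs$temperature, "temperature.csv")
  write_genepop(bundle$inputs$genotypes, file.path(outdir, "genotypes.gen"))
  wcsv(bundle$phenotype$descriptors, "daily_descriptors.csv")
  wcsv(bundle$phenotype$boxcox$scores, "fitness_scores.csv")
  wcsv(bundle$phenotype$variance_partition, "variance_partition.csv")
  wcsv(bundle$popgen$diversity, "diversity.csv")
  wcsv(bundle$popgen$smlh, "smlh.csv")
  wcsv(bundle$thermal$events, "thermal_events.csv")
  wcsv(bundle$thermal$summer, "summer_stats.csv")
  wcsv(bundle$gxe$slopes, "sensitivity_slopes.csv")
  report_path <- file.path(outdir, "report.json")
  jsonlite::write_json(bundle_to_report(bundle), report_path,
                       auto_unbox = TRUE, digits = 10, pretty = TRUE,
                       na = "null")
  invisible(report_path)
}
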