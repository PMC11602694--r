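# Genotype-by-environment sensitivity: yearly environmental values, per-
# genotype Finlay-Wilkinson regression slopes with qualitative categories,
# and the randomization null distribution of slopes.

# complete genotype x year score matrix (genotypes with a score in every year)
complete_score_matrix <- function(scores, value = "pc1") {
  df <- scores_df(scores)
  stopifnot(all(c("colony_id", "year", value) %in% names(df)))
  years <- sort(unique(df$year))
  if (length(years) < 2L) stop("need scores from at least 2 years", call. = FALSE)
  wide <- stats::reshape(df[c("colony_id", "year", value)],
                         idvar = "colony_id", timevar = "year",
                         direction = "wide")
  mat <- as.matrix(wide[, -1, drop = FALSE])
  rownames(mat) <- wide$colony_id
  colnames(mat) <- sub(paste0("^", value, "\\."), "", colnames(mat))
  mat <- mat[, as.character(years), drop = FALSE]
  complete <- mat[stats::complete.cases(mat), , drop = FALSE]
  if (nrow(complete) == 0L) {
    stop("no genotype has a score in every year: environmental values undefined",
         call. = FALSE)
  }
  complete
}

#' Yearly environmental values
#'
#' The environmental value of a year is the mean phenotype (PC1 fitness
#' score) over the common genotype set, i.e. the genotypes scored in every
#' year, so that the same set defines every year's value. These are the
#' x-values of the Finlay-Wilkinson sensitivity regressions.
#'
#' @param scores a [fit_fitness_pca()] result or a data frame with columns
#'   `colony_id`, `year` and the score column.
#' @param value name of the score column (default `"pc1"`).
#' @return a `data.frame` of class `environmental_values` with columns
#'   `year`, `e_value`, `sd`, plus attributes `n_common` and `common_ids`.
#' @export
environmental_values <- function(scores, value = "pc1") {
  mat <- complete_score_matrix(scores, value)
  out <- data.frame(year = colnames(mat),
                    e_value = colMeans(mat),
                    sd = apply(mat, 2, stats::sd))
  rownames(out) <- NULL
  structure(out, class = c("environmental_values", "data.frame"),
            n_common = nrow(mat), common_ids = rownames(mat))
}

#' Per-genotype environmental-sensitivity slopes
#'
#' Regresses each genotype's yearly phenotype on the yearly environmental
#' values (ordinary least squares through the few yearly points; the
#' Finlay-Wilkinson sensitivity). When slopes are computed over the same
#' complete genotype set that defines the environmental values, their mean is
#' exactly 1 (an algebraic identity: the average regression of the parts
#' equals the regression of the mean, which is the identity line).
#'
#' Genotypes are optionally categorised with a qualitative scheme: a slope
#' inside `zero_band` (e.g. the central 95\% interval of the randomization
#' null) counts as "flat"; flat genotypes are "resistant" if their first-year
#' score is below the first-year median and "hypersensitive" if above;
#' genotypes with a slope above the band are "sensitive"; slopes below the
#' band are flagged "atypical". Without `zero_band` no category is assigned.
#'
#' @param scores as in [environmental_values()].
#' @param env an [environmental_values()] result (recomputed from `scores`
#'   when omitted).
#' @param zero_band optional length-2 numeric: the slope interval treated as
#'   "no sensitivity".
#' @param value score column name.
#' @return a `data.frame` of class `sensitivity_profile` with columns
#'   `colony_id`, `slope`, `intercept`, `first_year_score`, `category`.
#' @export
sensitivity_slopes <- function(scores, env = NULL, zero_band = NULL,
                               value = "pc1") {
  mat <- complete_score_matrix(scores, value)
  env <- env %||% environmental_values(scores, value)
  stopifnot(inherits(env, "environmental_values"))
  e <- env$e_value[match(colnames(mat), as.character(env$year))]
  if (anyNA(e)) stop("environmental values do not cover the panel years", call. = FALSE)
  if (stats::var(e) == 0) stop("environmental values have zero variance", call. = FALSE)
  ce <- e - mean(e)
  slopes <- as.numeric(mat %*% ce) / sum(ce^2)
  intercepts <- rowMeans(mat) - slopes * mean(e)
  first <- mat[, 1]
  category <- rep(NA_character_, nrow(mat))
  if (!is.null(zero_band)) {
    stopifnot(length(zero_band) == 2L)
    low_first <- first < stats::median(first)
    flat <- slopes >= zero_band[1] & slopes <= zero_band[2]
    category[flat & low_first] <- "resistant"
    category[flat & !low_first] <- "hypersensitive"
    category[!flat & slopes > zero_band[2]] <- "sensitive"
    category[!flat & slopes < zero_band[1]] <- "atypical"
  }
  out <- data.frame(colony_id = rownames(mat), slope = slopes,
                    intercept = intercepts, first_year_score = first,
                    category = category, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("sensitivity_profile", "data.frame"),
            env_years = colnames(mat))
}

#' Randomization null distribution of sensitivity slopes
#'
#' Builds the null distribution of per-genotype slopes under "no structure":
#' each randomization shuffles the pooled PC scores across all
#' (genotype, year) cells of the complete panel, pairs them with the observed
#' yearly environmental values, and refits every per-genotype slope. The
#' null mean converges to 0 as randomizations grow, and with only a few
#' points per genotype the null slopes are heavy-tailed, which is why
#' individual-slope significance is reported as the fraction of observed
#' slopes exceeding the null mean rather than as p-values.
#'
#' A `recompute_env = TRUE` variant recomputes the environmental values from
#' each shuffled panel; note that variant is degenerate as a null for the
#' mean slope, because the mean slope of any panel against its own yearly
#' means is exactly 1 (the same identity that pins the observed mean to 1),
#' so it is not the default.
#'
#' @param scores,env,value as in [sensitivity_slopes()].
#' @param n_randomizations number of randomizations (default 10000; fewer
#'   than 100 triggers a warning).
#' @param seed optional integer seed.
#' @param recompute_env recompute environmental values from each shuffled
#'   panel instead of holding the observed ones fixed (default `FALSE`; see
#'   above).
#' @return an object of class `null_slope_distribution`: list with
#'   `null_slopes` (pooled over genotypes and randomizations), `null_mean`,
#'   `central_interval` (2.5\%/97.5\% quantiles), `observed_slopes`,
#'   `exceedance_fraction` (share of observed slopes above the null mean),
#'   `n_randomizations`, `recompute_env`.
#' @export
null_slope_distribution <- function(scores, env = NULL,
                                    n_randomizations = 10000L, seed = NULL,
                                    recompute_env = FALSE, value = "pc1") {
  if (n_randomizations < 100L) {
    warning("fewer than 100 randomizations: null summaries will be unstable")
  }
  if (!is.null(seed)) set.seed(seed)
  mat <- complete_score_matrix(scores, value)
  env <- env %||% environmental_values(scores, value)
  e_obs <- env$e_value[match(colnames(mat), as.character(env$year))]
  obs <- sensitivity_slopes(scores, env, value = value)$slope

  n_g <- nrow(mat); n_y <- ncol(mat)
  pool <- as.numeric(mat)
  null <- matrix(NA_real_, n_g, n_randomizations)
  for (b in seq_len(n_randomizations)) {
    pm <- matrix(sample(pool), n_g, n_y)
    e <- if (recompute_env) colMeans(pm) else e_obs
    ce <- e - mean(e)
    ss <- sum(ce^2)
    null[, b] <- if (ss > 0) as.numeric(pm %*% ce) / ss else NA_real_
  }
  null <- as.numeric(null)
  null <- null[is.finite(null)]
  nm <- mean(null)
  structure(list(null_slopes = null, null_mean = nm,
                 central_interval = stats::quantile(null, c(0.025, 0.975),
                                                    names = FALSE),
                 observed_slopes = obs,
                 exceedance_fraction = mean(obs > nm),
                 n_randomizations = as.integer(n_randomizations),
                 recompute_env = recompute_env),
            class = "null_slope_distribution")
}
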