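# Thermal-regime characterisation: day-of-year percentile climatology,
# marine heatwave (MHW, >= 5 d) / heat spike (MHS, < 5 d) detection, severity
# categories, and summer statistics including the T23 extreme-heat-day count.

md_365 <- function() {
  format(seq(as.Date("2001-01-01"), by = "day", length.out = 365L), "%m-%d")
}

# circular moving average of a length-365 day-of-year curve
smooth_circular <- function(x, width) {
  if (width <= 1L) return(x)
  k <- width %/% 2L
  xx <- c(x[(length(x) - k + 1L):length(x)], x, x[1:k])
  sm <- stats::filter(xx, rep(1 / (2 * k + 1), 2 * k + 1), sides = 2)
  as.numeric(sm[(k + 1L):(k + length(x))])
}

validate_series <- function(series) {
  stopifnot(is.data.frame(series), all(c("date", "temp_c") %in% names(series)))
  d <- as.Date(series$date)
  if (any(diff(as.integer(d)) <= 0)) {
    stop("temperature series dates must be strictly increasing", call. = FALSE)
  }
  if (any(series$temp_c < -2 | series$temp_c > 35, na.rm = TRUE)) {
    warning("temperatures outside the [-2, 35] degC sanity bounds")
  }
  data.frame(date = d, temp_c = as.numeric(series$temp_c))
}

#' Build a day-of-year percentile climatology
#'
#' For every day of year, values within `window_halfwidth` days (across all
#' baseline years, window wrapping around the year boundary) are pooled; the
#' pool mean gives the climatological mean and its 90th percentile the
#' interannual iT90 threshold. Both curves are then smoothed with a circular
#' moving average. This is the standard daily-climatology construction used in
#' marine heatwave detection. Feb 29 is handled by interpolation between
#' Feb 28 and Mar 1 at lookup time.
#'
#' @param series a `data.frame` with columns `date`, `temp_c` (daily means).
#' @param window_halfwidth half-width (days) of the day-of-year pooling
#'   window.
#' @param smooth_width width (days) of the moving-average smoother applied to
#'   both curves.
#' @param baseline_years optional integer vector restricting the climatology
#'   baseline; default uses all years in the series.
#' @return a `data.frame` of class `climatology` with columns `doy` (1-365),
#'   `clim_mean`, `it90`; baseline years are kept in `attr(, "baseline_years")`.
#' @export
build_climatology <- function(series, window_halfwidth = 5L, smooth_width = 31L,
                              baseline_years = NULL) {
  series <- validate_series(series)
  yr <- as.integer(format(series$date, "%Y"))
  if (!is.null(baseline_years)) {
    keep <- yr %in% baseline_years
    if (!any(keep)) stop("no data in the requested baseline years", call. = FALSE)
    series <- series[keep, , drop = FALSE]
  } else {
    baseline_years <- sort(unique(yr))
  }
  md <- format(series$date, "%m-%d")
  doy <- match(md, md_365())            # NA for Feb 29: excluded from pools
  ok <- !is.na(doy) & !is.na(series$temp_c)
  doy <- doy[ok]
  val <- series$temp_c[ok]

  clim_mean <- numeric(365L)
  it90 <- numeric(365L)
  for (d in 1:365) {
    win <- ((d - window_halfwidth):(d + window_halfwidth) - 1L) %% 365L + 1L
    pool <- val[doy %in% win]
    if (length(pool) == 0L) {
      stop(sprintf("no data in the day-of-year window around doy %d", d),
           call. = FALSE)
    }
    clim_mean[d] <- mean(pool)
    it90[d] <- stats::quantile(pool, 0.9, names = FALSE, type = 7)
  }
  clim_mean <- smooth_circular(clim_mean, smooth_width)
  it90 <- smooth_circular(it90, smooth_width)
  structure(data.frame(doy = 1:365, clim_mean = clim_mean, it90 = it90),
            class = c("climatology", "data.frame"),
            baseline_years = baseline_years,
            window_halfwidth = window_halfwidth, smooth_width = smooth_width)
}

# per-date climatology values, Feb 29 interpolated between Feb 28 and Mar 1
clim_lookup <- function(clim, dates) {
  md <- format(dates, "%m-%d")
  doy <- match(md, md_365())
  cm <- clim$clim_mean[doy]
  th <- clim$it90[doy]
  feb29 <- is.na(doy)
  if (any(feb29)) {
    cm[feb29] <- mean(clim$clim_mean[c(59L, 60L)])
    th[feb29] <- mean(clim$it90[c(59L, 60L)])
  }
  data.frame(clim_mean = cm, it90 = th)
}

#' Detect marine heatwaves and heat spikes
#'
#' Segments the series into maximal runs of days with temperature strictly
#' above the iT90 threshold. Runs lasting at least `min_duration` days are
#' classed as marine heatwaves (MHW), shorter runs as marine heat spikes
#' (MHS). Severity is assigned from the peak anomaly fold
#' `f = (temp - clim_mean) / (it90 - clim_mean)`: Moderate for `1 <= f < 2`,
#' Strong for `2 <= f < 3`, Severe for `3 <= f < 4`, Extreme for `f >= 4`
#' (sub-threshold days, fold < 1, never form events). Runs never bridge gaps
#' in the date sequence; optionally, runs separated by at most `join_gap`
#' below-threshold days are merged.
#'
#' @param series a `data.frame` with columns `date`, `temp_c`.
#' @param clim a [build_climatology()] result covering the series' days of
#'   year.
#' @param min_duration minimum run length (days) for an event to count as a
#'   MHW rather than a MHS.
#' @param join_gap merge events separated by at most this many days (0
#'   disables merging, the default, so that short spikes stay distinct).
#' @return a `data.frame` of class `thermal_events` with one row per event:
#'   `start`, `end`, `duration`, `type` ("MHW"/"MHS"), `category`,
#'   `max_anomaly` (deg C above the climatological mean) and `peak_fold`.
#' @export
detect_thermal_events <- function(series, clim, min_duration = 5L, join_gap = 0L) {
  series <- validate_series(series)
  stopifnot(inherits(clim, "climatology"))
  cl <- clim_lookup(clim, series$date)
  width <- cl$it90 - cl$clim_mean
  # small tolerance absorbs floating-point jitter from climatology smoothing
  exceed <- series$temp_c > cl$it90 + 1e-8
  if (any(exceed & width <= 1e-9, na.rm = TRUE)) {
    stop("iT90 equals the climatological mean on exceedance days: ",
         "anomaly fold is undefined (degenerate climatology)", call. = FALSE)
  }
  exceed[is.na(exceed)] <- FALSE

  # break runs at calendar gaps by treating gap boundaries as run breaks
  block <- cumsum(c(1L, diff(as.integer(series$date)) != 1L))
  runs <- list()
  for (b in unique(block)) {
    idx <- which(block == b)
    r <- rle(exceed[idx])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      runs[[length(runs) + 1L]] <- idx[starts[j]]:idx[ends[j]]
    }
  }
  if (join_gap > 0L && length(runs) > 1L) {
    merged <- list(runs[[1L]])
    for (j in 2L:length(runs)) {
      prev <- merged[[length(merged)]]
      gap <- runs[[j]][1L] - prev[length(prev)] - 1L
      same_block <- block[runs[[j]][1L]] == block[prev[length(prev)]]
      if (same_block && gap <= join_gap) {
        merged[[length(merged)]] <- prev[1L]:runs[[j]][length(runs[[j]])]
      } else {
        merged[[length(merged) + 1L]] <- runs[[j]]
      }
    }
    runs <- merged
  }
  if (length(runs) == 0L) {
    out <- data.frame(start = as.Date(character(0)), end = as.Date(character(0)),
                      duration = integer(0), type = character(0),
                      category = character(0), max_anomaly = numeric(0),
                      peak_fold = numeric(0))
    return(structure(out, class = c("thermal_events", "data.frame")))
  }
  ev <- lapply(runs, function(idx) {
    anom <- series$temp_c[idx] - cl$clim_mean[idx]
    fold <- anom / width[idx]
    data.frame(start = series$date[idx[1L]],
               end = series$date[idx[length(idx)]],
               duration = length(idx),
               max_anomaly = max(anom),
               peak_fold = max(fold))
  })
  out <- do.call(rbind, ev)
  out$type <- ifelse(out$duration >= min_duration, "MHW", "MHS")
  out$category <- cut(out$peak_fold, c(-Inf, 1, 2, 3, 4, Inf),
                      labels = c("Low", "Moderate", "Strong", "Severe", "Extreme"),
                      right = FALSE)
  out$category <- as.character(out$category)
  out <- out[c("start", "end", "duration", "type", "category",
               "max_anomaly", "peak_fold")]
  rownames(out) <- NULL
  structure(out, class = c("thermal_events", "data.frame"))
}

#' Summer thermal statistics per year
#'
#' Computes, for every year of the series with data in the summer window,
#' the mean, SD and maximum daily temperature, the T23 count of extreme heat
#' days (daily mean at or above `t_threshold` deg C, an ecological threshold
#' for *Paramuricea clavata*), and the number of MHW/MHS events overlapping
#' the window.
#'
#' @param series a `data.frame` with columns `date`, `temp_c`.
#' @param events an optional [detect_thermal_events()] table; event counts are
#'   NA when omitted.
#' @param months integer months defining the summer window (default Jun-Aug).
#' @param t_threshold extreme-heat-day threshold in deg C (default 23).
#' @return a `data.frame` of class `summer_stats` with one row per year:
#'   `year`, `mean_c`, `sd_c`, `max_c`, `t23_days`, `n_days`, `n_missing`,
#'   `n_mhw`, `n_mhs`.
#' @export
summer_statistics <- function(series, events = NULL, months = 6:8,
                              t_threshold = 23.0) {
  series <- validate_series(series)
  mo <- as.integer(format(series$date, "%m"))
  keep <- mo %in% months
  if (!any(keep)) stop("no data in the requested summer window", call. = FALSE)
  ss <- series[keep, , drop = FALSE]
  yr <- as.integer(format(ss$date, "%Y"))
  out <- lapply(sort(unique(yr)), function(y) {
    v <- ss$temp_c[yr == y]
    expected <- sum(as.integer(format(
      seq(as.Date(sprintf("%d-01-01", y)), as.Date(sprintf("%d-12-31", y)),
          by = "day"), "%m")) %in% months)
    n_mhw <- n_mhs <- NA_integer_
    if (!is.null(events)) {
      win0 <- min(ss$date[yr == y]); win1 <- max(ss$date[yr == y])
      ov <- !(events$end < win0 | events$start > win1)
      n_mhw <- sum(ov & events$type == "MHW")
      n_mhs <- sum(ov & events$type == "MHS")
    }
    data.frame(year = y, mean_c = mean(v), sd_c = stats::sd(v), max_c = max(v),
               t23_days = sum(v >= t_threshold), n_days = length(v),
               n_missing = expected - length(v), n_mhw = n_mhw, n_mhs = n_mhs)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  structure(out, class = c("summer_stats", "data.frame"))
}
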