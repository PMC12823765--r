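#' Build a dormancy-season series from hourly temperatures
#'
#' Extracts one dormancy season (by default 1 September of the previous
#' calendar year through 30 June of the harvest year) from an hourly
#' temperature table and attaches the calendar map used to report bloom
#' dates.
#'
#' @param hourly Data frame with columns `date` (Date or ISO string),
#'   `hour` (0-23) and `temp` (degC), or `timestamp` and `temp`.
#' @param season Harvest year (integer): the calendar year in which bloom
#'   is expected.
#' @param window_start,window_end Month-day strings ("MM-DD") bounding
#'   the season; the start belongs to `season - 1`.
#' @return An object of class `season_series` with elements `season`,
#'   `temps`, `dates` (Date per hour) and `doy` (day of year counted in
#'   the harvest year; dates before 1 January are non-positive).
#' @export
season_series <- function(hourly, season, window_start = "09-01",
                          window_end = "06-30") {
  if (!is.null(hourly$timestamp) && is.null(hourly$date)) {
    ts <- as.POSIXct(hourly$timestamp, tz = "UTC")
    hourly$date <- as.Date(ts, tz = "UTC")
    hourly$hour <- as.integer(format(ts, "%H"))
  }
  hourly$date <- as.Date(hourly$date)
  start <- as.Date(sprintf("%d-%s", season - 1, window_start))
  end <- as.Date(sprintf("%d-%s", season, window_end))
  sel <- hourly$date >= start & hourly$date <= end
  sub <- hourly[sel, , drop = FALSE]
  sub <- sub[order(sub$date, sub$hour), , drop = FALSE]
  ndays <- as.integer(end - start) + 1L
  if (nrow(sub) != 24L * ndays || any(!is.finite(sub$temp)))
    stop(sprintf(
      "season %d: hourly coverage of %s..%s incomplete (have %d of %d hours)",
      season, format(start), format(end), sum(sel & is.finite(hourly$temp)),
      24L * ndays))
  jan1 <- as.Date(sprintf("%d-01-01", season))
  structure(list(
    season = as.integer(season),
    temps = as.numeric(sub$temp),
    dates = sub$date,
    doy = as.numeric(sub$date - jan1) + 1
  ), class = "season_series")
}

#' @export
print.season_series <- function(x, ...) {
  cat(sprintf("Dormancy season %d: %d hours (%s .. %s)\n", x$season,
              length(x$temps), format(min(x$dates)), format(max(x$dates))))
  invisible(x)
}

#' Chill-dependent heat effectiveness
#'
#' Logistic gate on forcing: `1 / (1 + exp(-s1 * (y - yc)))`. Equals 0.5
#' when accumulated chill `y` meets the chill requirement `yc`; larger
#' `s1` sharpens the transition towards strictly sequential chill and
#' heat phases.
#'
#' @param y Accumulated chill (nonnegative).
#' @param req A [cultivar_requirements()] object.
#' @return Weight(s) in (0, 1).
#' @export
heat_effectiveness <- function(y, req) {
  stopifnot(inherits(req, "cultivar_requirements"))
  stats::plogis(req$s1 * (y - req$yc))
}

#' Simulate one dormancy season and predict bloom
#'
#' Runs the coupled hourly loop: chill kinetics update, chill-gated heat
#' accumulation, bloom at the first hour the weighted heat sum reaches
#' the heat requirement `zc`. If the requirement is not met by the end of
#' the season the model records a failure to bloom.
#'
#' @param season A [season_series()] object.
#' @param chill A [chill_params()] object.
#' @param heat A [heat_params()] object.
#' @param req A [cultivar_requirements()] object.
#' @param trajectories If `TRUE`, attach hourly chill and heat
#'   trajectories for diagnostics.
#' @return A list of class `bloom_prediction` with `season`, `status`
#'   ("bloom" or "no_bloom"), `bloom_doy` and `bloom_date` (NA when no
#'   bloom), and optionally `chill`/`heat` trajectories.
#' @export
simulate_season <- function(season, chill, heat, req, trajectories = FALSE) {
  stopifnot(inherits(season, "season_series"),
            inherits(chill, "chill_params"), inherits(heat, "heat_params"),
            inherits(req, "cultivar_requirements"))
  if (length(season$temps) < 30 * 24)
    stop("season window shorter than 30 days is degenerate")
  res <- cpp_simulate_season(season$temps, chill$E0, chill$E1, chill$A0,
                             chill$A1, chill$Tf, chill$slope, heat$Tb,
                             heat$Tu, heat$Tc, req$yc, req$zc, req$s1,
                             trajectories)
  hr <- res$bloom_hour
  out <- list(season = season$season,
              status = if (is.na(hr)) "no_bloom" else "bloom",
              bloom_doy = if (is.na(hr)) NA_real_ else season$doy[hr],
              bloom_date = if (is.na(hr)) as.Date(NA) else season$dates[hr])
  if (trajectories) {
    out$chill <- res$chill
    out$heat <- res$heat
  }
  structure(out, class = "bloom_prediction")
}

#' @export
print.bloom_prediction <- function(x, ...) {
  if (x$status == "bloom")
    cat(sprintf("Season %d: bloom on %s (DOY %g)\n", x$season,
                format(x$bloom_date), x$bloom_doy))
  else
    cat(sprintf("Season %d: failure to bloom\n", x$season))
  invisible(x)
}

#' Temperature response diagnostics
#'
#' Exposes the chill and heat submodels to long spells (default 1200 h)
#' of constant temperature across a fine grid and records the accumulated
#' output, visualizing the temperature ranges the fitted parameters treat
#' as effective. The heat curve is rescaled to a maximum of 1.0
#' (arbitrary heat units) so curves are comparable across parameter sets.
#'
#' @param chill A [chill_params()] object.
#' @param heat A [heat_params()] object.
#' @param hours Exposure length in hours (default 1200).
#' @param temps Temperature grid in degC (default -5 to 50 by 0.1: 551
#'   points).
#' @return Data frame with columns `temperature`, `chill_response`
#'   (Chill Portions accumulated over `hours`) and
#'   `heat_response_normalized`.
#' @export
temperature_response_curves <- function(chill, heat, hours = 1200,
                                        temps = seq(-5, 50, by = 0.1)) {
  stopifnot(inherits(chill, "chill_params"), inherits(heat, "heat_params"))
  chill_resp <- vapply(temps, function(tc) {
    y <- cpp_chill_accumulate(rep(tc, hours), chill$E0, chill$E1, chill$A0,
                              chill$A1, chill$Tf, chill$slope)
    y[hours]
  }, numeric(1))
  heat_raw <- hours * gdh_hour(temps, heat)
  data.frame(temperature = temps,
             chill_response = chill_resp,
             heat_response_normalized = heat_raw / max(heat_raw))
}
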