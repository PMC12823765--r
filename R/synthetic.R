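#' Synthetic daily weather configuration
#'
#' Describes an idealized station climate: a sinusoidal annual cycle in
#' the daily mean temperature (coldest in mid-January by default for the
#' Northern Hemisphere) with AR(1) day-to-day noise, and a fixed diurnal
#' range splitting the mean into tmin and tmax.
#'
#' @param latitude Station latitude (decimal degrees).
#' @param years Number of harvest years (dormancy seasons) to cover.
#' @param annual_mean Annual mean temperature (degC).
#' @param annual_amplitude Half peak-to-trough amplitude of the annual
#'   cycle (degC).
#' @param diurnal_range tmax - tmin (degC), constant.
#' @param ar1 AR(1) coefficient of the daily noise, in `[0, 1)`.
#' @param noise_sd Innovation standard deviation of the AR(1) noise
#'   (degC).
#' @param seed Integer seed.
#' @param start_year First harvest year.
#' @param coldest_doy Day of year of the coldest day (default 15).
#' @param station_id Station label.
#' @return Object of class `weather_gen_config`.
#' @export
weather_gen_config <- function(latitude = 40, years = 25, annual_mean = 12,
                               annual_amplitude = 11, diurnal_range = 8,
                               ar1 = 0.6, noise_sd = 1.5, seed = 1L,
                               start_year = 1998L, coldest_doy = 15,
                               station_id = "synthetic") {
  if (diurnal_range <= 0) stop("diurnal_range must be positive")
  if (abs(latitude) > 90) stop("latitude must lie in [-90, 90]")
  if (ar1 < 0 || ar1 >= 1) stop("ar1 must lie in [0, 1)")
  structure(list(latitude = latitude, years = years,
                 annual_mean = annual_mean,
                 annual_amplitude = annual_amplitude,
                 diurnal_range = diurnal_range, ar1 = ar1,
                 noise_sd = noise_sd, seed = as.integer(seed),
                 start_year = as.integer(start_year),
                 coldest_doy = coldest_doy, station_id = station_id),
            class = "weather_gen_config")
}

#' Generate synthetic daily weather
#'
#' Daily mean temperature = annual mean minus the annual amplitude times
#' a cosine centered on the coldest day, plus AR(1) noise;
#' `tmin`/`tmax` = mean -/+ half the diurnal range. The series runs from
#' 1 July before the first harvest year through 30 June of the last, so
#' every dormancy season window is fully covered. Deterministic in the
#' seed.
#'
#' @param config A [weather_gen_config()] object.
#' @return Daily data frame (`station_id`, `date`, `tmin`, `tmax`) with
#'   the latitude in the `latitude` attribute (and column).
#' @export
generate_weather <- function(config) {
  stopifnot(inherits(config, "weather_gen_config"))
  start <- as.Date(sprintf("%d-07-01", config$start_year - 1L))
  end <- as.Date(sprintf("%d-06-30", config$start_year + config$years - 1L))
  dates <- seq(start, end, by = "day")
  n <- length(dates)
  doy <- as.integer(format(dates, "%j"))
  seasonal <- config$annual_mean -
    config$annual_amplitude * cos(2 * pi * (doy - config$coldest_doy) / 365)
  set.seed(config$seed)
  eps <- numeric(n)
  if (config$noise_sd > 0) {
    eps[1] <- rnorm(1, 0, config$noise_sd / sqrt(1 - config$ar1^2))
    innov <- rnorm(n - 1, 0, config$noise_sd)
    for (i in 2:n) eps[i] <- config$ar1 * eps[i - 1] + innov[i - 1]
  }
  mean_t <- seasonal + eps
  out <- data.frame(station_id = config$station_id, date = dates,
                    tmin = mean_t - config$diurnal_range / 2,
                    tmax = mean_t + config$diurnal_range / 2,
                    latitude = config$latitude)
  attr(out, "latitude") <- config$latitude
  attr(out, "config") <- config
  out
}

#' Ground-truth specification for synthetic bloom observations
#'
#' Species-shared submodel parameters in intermediate form plus
#' per-cultivar requirements, and the bloom-date observation noise.
#'
#' @param intermediate An [intermediate_chill_params()] object.
#' @param Tf,slope Conversion parameters of the chill submodel.
#' @param Tb,Tu Heat submodel cardinal temperatures (`Tc` fixed at 36).
#' @param requirements Named list of [cultivar_requirements()], one per
#'   cultivar.
#' @param noise_sd_days Observation noise standard deviation (days);
#'   noise is rounded to whole days.
#' @param species Species label.
#' @return Object of class `truth_spec`.
#' @export
truth_spec <- function(intermediate, Tf, slope, Tb, Tu, requirements,
                       noise_sd_days = 1, species = "synthetic_species") {
  stopifnot(inherits(intermediate, "intermediate_chill_params"),
            is.list(requirements), length(requirements) >= 1,
            !is.null(names(requirements)))
  b <- default_bounds()
  chk <- c(theta_c = intermediate$theta_c, tau = intermediate$tau,
           pie_c = intermediate$pie_c, Tf = Tf, slope = slope, Tb = Tb,
           Tu = Tu)
  for (p in names(chk))
    if (chk[[p]] < b[p, "lower"] || chk[[p]] > b[p, "upper"])
      stop("truth parameter ", p, " outside admissible bounds")
  for (r in requirements) {
    stopifnot(inherits(r, "cultivar_requirements"))
    for (p in c("yc", "zc", "s1"))
      if (r[[p]] < b[p, "lower"] || r[[p]] > b[p, "upper"])
        stop("truth requirement ", p, " outside admissible bounds")
  }
  structure(list(intermediate = intermediate, Tf = Tf, slope = slope,
                 Tb = Tb, Tu = Tu, requirements = requirements,
                 noise_sd_days = noise_sd_days, species = species),
            class = "truth_spec")
}

#' Default recovery-experiment ground truth
#'
#' One synthetic species with three cultivars of well-separated chill
#' and heat requirements, mirroring the data shape of a combined-fit
#' calibration (several cultivars sharing one species' submodels).
#'
#' @param noise_sd_days Observation noise in days (default 1).
#' @return A [truth_spec()] object.
#' @export
default_truth_spec <- function(noise_sd_days = 1) {
  truth_spec(
    intermediate = intermediate_chill_params(theta_c = 286.6, tau = 28,
                                             pie_c = 30),
    Tf = 4, slope = 2, Tb = 7, Tu = 24,
    requirements = list(
      early = cultivar_requirements(yc = 40, zc = 400, s1 = 0.8),
      mid = cultivar_requirements(yc = 50, zc = 500, s1 = 1.0),
      late = cultivar_requirements(yc = 60, zc = 600, s1 = 1.1)),
    noise_sd_days = noise_sd_days)
}

#' Materialize the chill/heat submodels of a truth specification
#'
#' @param truth A [truth_spec()] object.
#' @return List with `chill` ([chill_params()]) and `heat`
#'   ([heat_params()]).
#' @export
truth_submodels <- function(truth) {
  stopifnot(inherits(truth, "truth_spec"))
  list(chill = intermediate_to_canonical(truth$intermediate, Tf = truth$Tf,
                                         slope = truth$slope),
       heat = heat_params(Tb = truth$Tb, Tu = truth$Tu))
}

#' Build dormancy-season series from a daily weather table
#'
#' Converts daily records to hourly temperatures and slices them into
#' one [season_series()] per harvest year fully covered by the data.
#'
#' @param weather Daily data frame (`date`, `tmin`, `tmax`), gap-free.
#' @param latitude Latitude (taken from the weather attribute or column
#'   when omitted).
#' @param window_start,window_end Season window month-day strings.
#' @return Named list of [season_series()] keyed by harvest year.
#' @export
build_seasons <- function(weather, latitude = NULL, window_start = "09-01",
                          window_end = "06-30") {
  if (is.null(latitude))
    latitude <- attr(weather, "latitude")
  if (is.null(latitude) && !is.null(weather$latitude))
    latitude <- weather$latitude[1]
  if (is.null(latitude)) stop("latitude must be supplied")
  hourly <- daily_to_hourly(weather, latitude)
  dates <- as.Date(weather$date)
  years <- sort(unique(as.integer(format(dates, "%Y"))))
  out <- list()
  for (yr in years) {
    start <- as.Date(sprintf("%d-%s", yr - 1, window_start))
    end <- as.Date(sprintf("%d-%s", yr, window_end))
    if (min(dates) <= start && max(dates) >= end)
      out[[as.character(yr)]] <- season_series(hourly, yr, window_start,
                                               window_end)
  }
  if (length(out) == 0) stop("weather covers no complete dormancy season")
  out
}

#' Generate synthetic bloom observations with known ground truth
#'
#' Simulates every cultivar's bloom in every covered season under the
#' truth parameters, then adds integer-rounded Gaussian observation
#' noise. Seasons in which a cultivar fails to bloom are emitted with a
#' `no_bloom` status and missing bloom date.
#'
#' @param weather Daily weather data frame (e.g. from
#'   [generate_weather()]).
#' @param truth A [truth_spec()] object.
#' @param seed Integer seed for the observation noise.
#' @param location Location label for the phenology records.
#' @return Phenology data frame: `location`, `species`, `cultivar`,
#'   `season`, `status`, `bloom_doy`, `bloom_date`. The season list used
#'   for simulation is attached as the `seasons` attribute.
#' @export
generate_bloom_observations <- function(weather, truth, seed = 1L,
                                        location = "synthetic_orchard") {
  stopifnot(inherits(truth, "truth_spec"))
  seasons <- build_seasons(weather)
  sub <- truth_submodels(truth)
  set.seed(seed)
  rows <- list()
  for (cv in names(truth$requirements)) {
    req <- truth$requirements[[cv]]
    for (key in names(seasons)) {
      p <- simulate_season(seasons[[key]], sub$chill, sub$heat, req)
      if (p$status == "bloom") {
        doy <- p$bloom_doy + round(rnorm(1, 0, truth$noise_sd_days))
        jan1 <- as.Date(sprintf("%s-01-01", key))
        rows[[length(rows) + 1]] <- data.frame(
          location = location, species = truth$species, cultivar = cv,
          season = as.integer(key), status = "bloom", bloom_doy = doy,
          bloom_date = jan1 + doy - 1)
      } else {
        rows[[length(rows) + 1]] <- data.frame(
          location = location, species = truth$species, cultivar = cv,
          season = as.integer(key), status = "no_bloom",
          bloom_doy = NA_real_, bloom_date = as.Date(NA))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "seasons") <- seasons
  attr(out, "truth") <- truth
  out
}

#' Combined-fit parameter-recovery experiment
#'
#' The "virtual ecologist" experiment: synthetic bloom observations are
#' generated from known parameters (three cultivars sharing one
#' species' submodels, 25 dormancy seasons each, 1-day observation
#' noise by default), the combined-fit scheme is calibrated on those 25
#' seasons, and the fitted model is validated on additional held-out
#' seasons generated from the same climate. Reports the relative errors
#' of the recovered chill and heat requirements against the ground
#' truth.
#'
#' @param seed Integer seed governing weather, observation noise and
#'   the optimizer.
#' @param truth A [truth_spec()] object (default
#'   [default_truth_spec()]).
#' @param n_calibration_seasons Seasons per cultivar used for
#'   calibration (default 25).
#' @param n_validation_seasons Additional held-out seasons (default 8).
#' @param budget Optimizer budget overrides passed to
#'   [calibration_problem()].
#' @return List with the fitted `model`, `requirement_errors` (data
#'   frame of per-cultivar relative errors in percent), `validation`
#'   (the held-out `metric_report`) and `calibration_rmse`.
#' @export
recovery_experiment <- function(seed = 1L, truth = default_truth_spec(),
                                n_calibration_seasons = 25,
                                n_validation_seasons = 8,
                                budget = list()) {
  years <- n_calibration_seasons + n_validation_seasons
  w <- generate_weather(weather_gen_config(years = years, seed = seed))
  obs <- generate_bloom_observations(w, truth, seed = seed + 1)
  seasons <- attr(obs, "seasons")
  obs <- obs[obs$status == "bloom", , drop = FALSE]
  cut <- sort(unique(obs$season))[n_calibration_seasons]
  cal <- obs[obs$season <= cut, , drop = FALSE]
  val <- obs[obs$season > cut, , drop = FALSE]
  problem <- calibration_problem("combined_fit", cal, seasons,
                                 budget = budget, seed = seed)
  model <- calibrate(problem)
  errs <- do.call(rbind, lapply(names(truth$requirements), function(cv) {
    tr <- truth$requirements[[cv]]
    fit <- model$cultivars[[cv]]$requirements
    data.frame(cultivar = cv,
               yc_true = tr$yc, yc_fit = fit$yc,
               yc_rel_error_pct = 100 * abs(fit$yc - tr$yc) / tr$yc,
               zc_true = tr$zc, zc_fit = fit$zc,
               zc_rel_error_pct = 100 * abs(fit$zc - tr$zc) / tr$zc)
  }))
  list(model = model,
       requirement_errors = errs,
       validation = evaluate_model(model, val, seasons),
       calibration_rmse = model$objective,
       n_calibration = nrow(cal), n_validation = nrow(val))
}
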