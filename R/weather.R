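#' Read a daily weather CSV
#'
#' Expected columns: `station_id`, `date` (ISO-8601), `tmin`, `tmax`;
#' empty cells are missing values. A `latitude` column is carried through
#' when present.
#'
#' @param path File path.
#' @return Data frame of daily records ordered by date.
#' @export
read_daily_weather <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("station_id", "date", "tmin", "tmax")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("daily weather CSV missing column(s): ", paste(miss, collapse = ", "))
  df$date <- as.Date(df$date)
  if (anyNA(df$date)) stop("unparseable date in daily weather CSV")
  df$tmin <- as.numeric(df$tmin)
  df$tmax <- as.numeric(df$tmax)
  bad <- !is.na(df$tmin) & !is.na(df$tmax) & df$tmax < df$tmin
  if (any(bad))
    stop("tmax < tmin on ", paste(format(df$date[bad]), collapse = ", "))
  df[order(df$station_id, df$date), , drop = FALSE]
}

#' Write a daily weather CSV
#' @param daily Data frame with `station_id`, `date`, `tmin`, `tmax`.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_daily_weather <- function(daily, path) {
  out <- daily
  out$date <- format(as.Date(out$date))
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

.shared_window_bias <- function(target_v, aux_v, dates, gap_date, half) {
  inwin <- abs(as.numeric(dates - gap_date)) <= half
  shared <- inwin & !is.na(target_v) & !is.na(aux_v)
  n <- sum(shared)
  if (n == 0) return(list(n = 0, bias = NA_real_, sd = NA_real_))
  diffs <- aux_v[shared] - target_v[shared]
  list(n = n, bias = mean(diffs), sd = if (n > 1) stats::sd(diffs) else 0)
}

#' Fill gaps in a daily series using a bias-corrected auxiliary station
#'
#' For every missing value in the target series, the auxiliary station's
#' observation on that day is corrected by the mean difference
#' (auxiliary minus target) over shared observation days inside a moving
#' window centered on the missing day, and the corrected value fills the
#' gap. `tmin` and `tmax` are filled independently with their own bias
#' estimates. When several auxiliary stations are supplied, the one with
#' the most shared days in the window is used, ties broken by smaller
#' absolute bias.
#'
#' @param target Daily data frame (`date`, `tmin`, `tmax`), one station.
#' @param aux Daily data frame for one auxiliary station, or a list of
#'   such data frames.
#' @param window_days Odd window width in days (default 15).
#' @return The filled target with provenance columns `tmin_src` /
#'   `tmax_src` ("observed" or "aux-filled"), plus a `qc` attribute: one
#'   row per gap with the shared-day count, bias, bias standard
#'   deviation, the chosen auxiliary station (with its distance in km
#'   when both stations carry latitude/longitude columns) and a flag
#'   raised when
#'   |bias| > 3 degC or sd > 3 degC (or when the gap could not be
#'   filled).
#' @export
fill_gaps_bias_corrected <- function(target, aux, window_days = 15) {
  if (window_days %% 2 != 1) stop("window_days must be odd")
  if (is.data.frame(aux)) aux <- list(aux)
  half <- (window_days - 1) / 2
  target <- target[order(target$date), , drop = FALSE]
  target$date <- as.Date(target$date)
  aux <- lapply(aux, function(a) {
    a$date <- as.Date(a$date)
    a
  })
  aux_ids <- vapply(seq_along(aux), function(i) {
    id <- aux[[i]]$station_id[1]
    if (is.null(id) || is.na(id)) paste0("aux", i) else as.character(id)
  }, character(1))
  # station separation is screening metadata, recorded when coordinates
  # are present, never enforced
  coords <- function(d) if (!is.null(d$latitude) && !is.null(d$longitude))
    c(d$longitude[1], d$latitude[1]) else NULL
  tco <- coords(target)
  aux_dist <- vapply(aux, function(a) {
    aco <- coords(a)
    if (is.null(tco) || is.null(aco)) NA_real_
    else geosphere::distHaversine(tco, aco) / 1000
  }, numeric(1))
  qc <- list()
  for (var in c("tmin", "tmax")) {
    src <- ifelse(is.na(target[[var]]), NA_character_, "observed")
    gaps <- which(is.na(target[[var]]))
    for (g in gaps) {
      gd <- target$date[g]
      cand <- lapply(aux, function(a) {
        m <- match(target$date, a$date)
        av <- a[[var]][m]
        c(.shared_window_bias(target[[var]], av, target$date, gd, half),
          list(value = av[g]))
      })
      usable <- vapply(cand, function(cc) cc$n > 0 && !is.na(cc$value),
                       logical(1))
      if (!any(usable)) {
        qc[[length(qc) + 1]] <- data.frame(
          date = gd, variable = var, aux_station = NA_character_,
          aux_distance_km = NA_real_, n_shared = 0L, bias = NA_real_,
          bias_sd = NA_real_, filled = FALSE, flagged = TRUE)
        next
      }
      ns <- vapply(cand, function(cc) cc$n, numeric(1))
      ns[!usable] <- -Inf
      best <- which(ns == max(ns))
      if (length(best) > 1) {
        ab <- vapply(cand[best], function(cc) abs(cc$bias), numeric(1))
        best <- best[which.min(ab)]
      } else best <- best[1]
      cc <- cand[[best]]
      target[[var]][g] <- cc$value - cc$bias
      src[g] <- "aux-filled"
      qc[[length(qc) + 1]] <- data.frame(
        date = gd, variable = var, aux_station = aux_ids[best],
        aux_distance_km = aux_dist[best], n_shared = cc$n, bias = cc$bias,
        bias_sd = cc$sd, filled = TRUE,
        flagged = abs(cc$bias) > 3 || (!is.na(cc$sd) && cc$sd > 3))
    }
    target[[paste0(var, "_src")]] <- src
  }
  attr(target, "qc") <- if (length(qc)) do.call(rbind, qc) else
    data.frame(date = as.Date(character()), variable = character(),
               aux_station = character(), aux_distance_km = numeric(),
               n_shared = integer(), bias = numeric(), bias_sd = numeric(),
               filled = logical(), flagged = logical())
  target
}

#' Linearly interpolate remaining gaps in a daily series
#'
#' Interior gaps in `tmin` and `tmax` are filled by linear interpolation
#' in the day index; leading and trailing gaps are left missing and
#' reported in the `unfilled` attribute.
#'
#' @param series Daily data frame (`date`, `tmin`, `tmax`).
#' @return The series with interior gaps filled and provenance columns
#'   updated to "interpolated" where filling occurred.
#' @export
interpolate_linear <- function(series) {
  series <- series[order(series$date), , drop = FALSE]
  if (all(is.na(series$tmin)) && all(is.na(series$tmax)))
    stop("station unusable: all values missing")
  unfilled <- list()
  for (var in c("tmin", "tmax")) {
    x <- series[[var]]
    if (all(is.na(x))) stop("station unusable: all ", var, " missing")
    was_na <- is.na(x)
    filled <- zoo::na.approx(x, x = as.numeric(as.Date(series$date)),
                             na.rm = FALSE)
    series[[var]] <- filled
    srccol <- paste0(var, "_src")
    if (is.null(series[[srccol]]))
      series[[srccol]] <- ifelse(was_na, NA_character_, "observed")
    series[[srccol]][was_na & !is.na(filled)] <- "interpolated"
    left <- was_na & is.na(filled)
    if (any(left))
      unfilled[[var]] <- as.Date(series$date)[left]
  }
  attr(series, "unfilled") <- unfilled
  series
}

# Solar geometry: sunrise/sunset in local solar hours from latitude and
# day of year, via the standard declination / hour-angle equations.
daylight_hours <- function(latitude, doy) {
  decl <- -23.44 * cos(2 * pi * (doy + 10) / 365) * pi / 180
  lat <- latitude * pi / 180
  cosH <- pmin(1, pmax(-1, -tan(lat) * tan(decl)))
  acos(cosH) * 24 / pi
}

#' Convert daily tmin/tmax records to hourly temperatures
#'
#' Uses the idealized diurnal curve standard in horticultural chill
#' modelling: a sine rise from the minimum at sunrise to the day's
#' maximum at an afternoon peak, a cosine decline to sunset, and a
#' logarithmic decline overnight towards the next day's minimum.
#' Sunrise and sunset come from latitude and day of year via the solar
#' declination and hour-angle equations. The afternoon peak is snapped
#' to the sampled integer-hour grid, so each day's hourly maximum equals
#' that day's `tmax` exactly.
#'
#' @param series Daily data frame (`station_id` optional, `date`, `tmin`,
#'   `tmax`), gap-free.
#' @param latitude Latitude in decimal degrees, in `[-90, 90]`.
#' @return Hourly data frame with `station_id`, `date`, `hour`, `temp`
#'   and `provenance`.
#' @export
daily_to_hourly <- function(series, latitude) {
  if (!is.finite(latitude) || abs(latitude) > 90)
    stop("latitude must lie in [-90, 90]")
  series <- series[order(series$date), , drop = FALSE]
  series$date <- as.Date(series$date)
  bad <- is.na(series$tmin) | is.na(series$tmax)
  if (any(bad))
    stop("missing tmin/tmax on ",
         paste(format(series$date[bad]), collapse = ", "),
         "; fill gaps before hourly conversion")
  n <- nrow(series)
  doy <- as.integer(format(series$date, "%j"))
  dl <- daylight_hours(latitude, doy)
  sr <- 12 - dl / 2
  ss <- 12 + dl / 2
  # afternoon peak, snapped to the hour grid, strictly inside (sr, ss)
  pk <- pmin(pmax(round(sr + (dl + 4) / 2), ceiling(sr) + 1), floor(ss))
  temp <- matrix(NA_real_, nrow = 24, ncol = n)
  day_curve <- function(d, h) {
    amp <- series$tmax[d] - series$tmin[d]
    ifelse(h <= pk[d],
           series$tmin[d] + amp * sin((pi / 2) * (h - sr[d]) / (pk[d] - sr[d])),
           series$tmin[d] + amp * cos((pi / 2) * (h - pk[d]) / (ss[d] + 4 - pk[d])))
  }
  for (d in seq_len(n)) {
    hrs <- ceiling(sr[d]):floor(ss[d])
    temp[hrs + 1, d] <- day_curve(d, hrs)
  }
  night_fill <- function(d_from, Ts, ss_h, tmin_next, sr_next) {
    # hours after sunset of day d_from until sunrise of the next day
    night_len <- 24 - ss_h + sr_next
    decline <- function(t) Ts - (Ts - tmin_next) * log1p(t) / log1p(night_len)
    if (floor(ss_h) + 1 <= 23) {
      hrs_evening <- (floor(ss_h) + 1):23
      temp[hrs_evening + 1, d_from] <<- decline(hrs_evening - ss_h)
    }
    if (d_from + 1 <= n && ceiling(sr_next) >= 1) {
      hrs_morning <- 0:(ceiling(sr_next) - 1)
      temp[hrs_morning + 1, d_from + 1] <<- decline(hrs_morning + 24 - ss_h)
    }
  }
  for (d in seq_len(n)) {
    Ts <- day_curve(d, ss[d])
    nxt <- min(d + 1, n)
    night_fill(d, Ts, ss[d], series$tmin[nxt], sr[nxt])
  }
  # hours before the first sunrise: previous night approximated by the
  # first day's own night parameters
  if (ceiling(sr[1]) >= 1) {
    first_morning <- 0:(ceiling(sr[1]) - 1)
    Ts1 <- day_curve(1, ss[1])
    nl1 <- 24 - ss[1] + sr[1]
    temp[first_morning + 1, 1] <-
      Ts1 - (Ts1 - series$tmin[1]) * log1p(first_morning + 24 - ss[1]) / log1p(nl1)
  }
  out <- data.frame(
    station_id = if (is.null(series$station_id)) "station" else
      rep(series$station_id, each = 24),
    date = rep(series$date, each = 24),
    hour = rep(0:23, n),
    temp = as.vector(temp))
  prov <- rep("observed-derived", n)
  for (var in c("tmin_src", "tmax_src")) {
    if (!is.null(series[[var]])) {
      prov[series[[var]] == "aux-filled"] <- "aux-filled"
      prov[series[[var]] == "interpolated"] <- "interpolated"
    }
  }
  out$provenance <- rep(prov, each = 24)
  out
}

#' Write an hourly weather CSV
#' @param hourly Data frame from [daily_to_hourly()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_hourly_weather <- function(hourly, path) {
  out <- data.frame(
    station_id = hourly$station_id,
    timestamp = sprintf("%sT%02d:00:00", format(as.Date(hourly$date)),
                        hourly$hour),
    temp = hourly$temp,
    provenance = hourly$provenance)
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}
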