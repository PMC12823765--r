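# A small noise-free fixture: three short seasons, default submodels,
# known requirements. Built once per test file.
fixture_seasons <- function(n = 6, days = 200, cold_days = 100) {
  seasons <- list()
  set.seed(99)
  for (i in seq_len(n)) {
    yr <- 2000 + i
    start <- as.Date(sprintf("%d-09-01", yr - 1))
    base <- c(rep(6, 24 * cold_days), rep(14, 24 * (days - cold_days))) +
      rnorm(24 * days, 0, 1)
    hourly <- data.frame(date = rep(start + 0:(days - 1), each = 24),
                         hour = rep(0:23, days), temp = base)
    seasons[[as.character(yr)]] <- season_series(
      hourly, yr, window_end = format(start + days - 1, "%m-%d"))
  }
  seasons
}

fixture_observations <- function(seasons, reqs) {
  chill <- default_chill_params()
  heat <- default_heat_params()
  rows <- list()
  for (cv in names(reqs)) {
    for (key in names(seasons)) {
      p <- simulate_season(seasons[[key]], chill, heat, reqs[[cv]])
      stopifnot(p$status == "bloom")
      rows[[length(rows) + 1]] <- data.frame(
        cultivar = cv, season = as.integer(key), bloom_doy = p$bloom_doy)
    }
  }
  do.call(rbind, rows)
}

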