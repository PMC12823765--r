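# Independent straight-line reference implementations of the hourly
# accumulators, written against the model definitions only. They are the
# oracles the package implementation is checked against and must stay
# free of any package internals.

oracle_chill_trajectory <- function(temp_C, p) {
  x <- 0
  y <- 0
  TfK <- p$Tf + 273
  out <- numeric(length(temp_C))
  for (i in seq_along(temp_C)) {
    TK <- temp_C[i] + 273
    xs <- (p$A0 / p$A1) * exp((p$E1 - p$E0) / TK)
    k1 <- p$A1 * exp(-p$E1 / TK)
    xt <- xs - (xs - x) * exp(-k1)
    if (xt >= 1) {
      s <- exp(p$slope * TfK * (TK - TfK) / TK)
      xi <- if (is.finite(s)) s / (1 + s) else 1
      y <- y + xi * xt
      x <- xt * (1 - xi)
    } else {
      x <- xt
    }
    out[i] <- y
  }
  out
}

oracle_gdh_hour <- function(t, p) {
  if (t <= p$Tb || t >= p$Tc) return(0)
  if (t <= p$Tu)
    return((p$Tu - p$Tb) / 2 * (1 + cos(pi + pi * (t - p$Tb) / (p$Tu - p$Tb))))
  (p$Tu - p$Tb) * (1 + cos(pi / 2 + (pi / 2) * (t - p$Tu) / (p$Tc - p$Tu)))
}

oracle_gdh_trajectory <- function(temp_C, p, weights = rep(1, length(temp_C))) {
  z <- numeric(length(temp_C))
  acc <- 0
  for (i in seq_along(temp_C)) {
    acc <- acc + weights[i] * oracle_gdh_hour(temp_C[i], p)
    z[i] <- acc
  }
  z
}

# Full season reference loop; returns the 1-based bloom hour or NA.
oracle_bloom_hour <- function(temp_C, chill, heat, req) {
  x <- 0
  y <- 0
  z <- 0
  TfK <- chill$Tf + 273
  for (i in seq_along(temp_C)) {
    TK <- temp_C[i] + 273
    xs <- (chill$A0 / chill$A1) * exp((chill$E1 - chill$E0) / TK)
    k1 <- chill$A1 * exp(-chill$E1 / TK)
    xt <- xs - (xs - x) * exp(-k1)
    if (xt >= 1) {
      s <- exp(chill$slope * TfK * (TK - TfK) / TK)
      xi <- if (is.finite(s)) s / (1 + s) else 1
      y <- y + xi * xt
      x <- xt * (1 - xi)
    } else {
      x <- xt
    }
    w <- 1 / (1 + exp(-req$s1 * (y - req$yc)))
    z <- z + w * oracle_gdh_hour(temp_C[i], heat)
    if (z >= req$zc) return(i)
  }
  NA_integer_
}

# Random admissible parameter draws for property tests.
random_chill_params <- function() {
  ip <- intermediate_chill_params(theta_c = runif(1, 286, 287),
                                  tau = runif(1, 16, 48),
                                  pie_c = runif(1, 24, 50))
  intermediate_to_canonical(ip, Tf = runif(1, 2, 10),
                            slope = runif(1, 1.2, 5))
}

random_heat_params <- function() {
  heat_params(Tb = runif(1, 0, 10), Tu = runif(1, 15, 30), Tc = 36)
}

random_requirements <- function() {
  cultivar_requirements(yc = runif(1, 5, 80), zc = runif(1, 100, 700),
                        s1 = runif(1, 0.1, 1.2))
}

# A short synthetic hourly winter: cooling then warming, with noise.
random_season_temps <- function(n_hours = 1500) {
  base <- 12 - 8 * sin(seq(0, pi, length.out = n_hours))
  diurnal <- 4 * sin(2 * pi * seq_len(n_hours) / 24)
  pmax(-10, base + diurnal + rnorm(n_hours, 0, 1.5))
}

# Small daily weather table used by weather-prep tests.
make_daily <- function(dates, tmin, tmax, station_id = "T1") {
  data.frame(station_id = station_id, date = as.Date(dates),
             tmin = tmin, tmax = tmax)
}
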