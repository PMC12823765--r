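#' Read a phenology CSV
#'
#' Required headers: `location`, `cultivar`, `species`, `season`,
#' `bloom_date` (ISO-8601). The bloom day of year is derived, never read
#' from the file. Rows with unparseable dates are rejected and collected
#' (with line numbers) in the `rejected` attribute; duplicate
#' (cultivar, season, location) combinations are an error.
#'
#' @param path File path.
#' @return Data frame of validated records with derived `bloom_doy`.
#' @export
read_phenology <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("location", "cultivar", "species", "season", "bloom_date")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenology CSV missing column(s): ", paste(miss, collapse = ", "))
  dates <- as.Date(df$bloom_date, format = "%Y-%m-%d")
  season <- suppressWarnings(as.integer(df$season))
  bad <- is.na(dates) | is.na(season)
  rejected <- if (any(bad))
    data.frame(line = which(bad) + 1L, reason = ifelse(
      is.na(dates[bad]), "unparseable bloom_date", "unparseable season"))
  else data.frame(line = integer(), reason = character())
  df <- df[!bad, , drop = FALSE]
  dates <- dates[!bad]
  df$season <- season[!bad]
  key <- paste(df$cultivar, df$season, df$location, sep = "|")
  if (anyDuplicated(key))
    stop("duplicate (cultivar, season, location) record(s): ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  jan1 <- as.Date(sprintf("%d-01-01", df$season))
  df$bloom_date <- dates
  df$bloom_doy <- as.numeric(dates - jan1) + 1
  attr(df, "rejected") <- rejected
  if (nrow(rejected))
    warning(nrow(rejected), " malformed phenology row(s) rejected")
  df
}

#' Write a phenology CSV
#' @param phenology Data frame with the phenology columns.
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_phenology <- function(phenology, path) {
  out <- phenology
  out$bloom_date <- format(as.Date(out$bloom_date))
  out$bloom_doy <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write model parameters as JSON
#'
#' @param params A list with any of `chill` ([chill_params()] or
#'   [intermediate_chill_params()]), `heat` ([heat_params()]) and
#'   `requirements` ([cultivar_requirements()]).
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_params_json <- function(params, path) {
  enc <- list()
  if (!is.null(params$chill)) {
    enc$parameterization <- if (inherits(params$chill,
                                         "intermediate_chill_params"))
      "intermediate" else "canonical"
    enc$chill <- unclass(params$chill)
  }
  if (!is.null(params$heat)) enc$heat <- unclass(params$heat)
  if (!is.null(params$requirements))
    enc$requirements <- unclass(params$requirements)
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read model parameters from JSON
#'
#' @param path File path written by [write_params_json()] (or following
#'   the same layout).
#' @return List with `chill`, `heat`, `requirements` (entries NULL when
#'   absent); an intermediate chill set is converted to canonical form
#'   using the `Tf`/`slope` stored alongside it (defaults 4 / 1.6).
#' @export
read_params_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- list(chill = NULL, heat = NULL, requirements = NULL)
  if (!is.null(raw$chill)) {
    if (identical(raw$parameterization, "intermediate")) {
      ip <- intermediate_chill_params(
        theta_c = raw$chill$theta_c, tau = raw$chill$tau,
        pie_c = raw$chill$pie_c,
        theta_star = if (is.null(raw$chill$theta_star)) 279 else
          raw$chill$theta_star)
      out$chill <- intermediate_to_canonical(
        ip, Tf = if (is.null(raw$chill$Tf)) 4 else raw$chill$Tf,
        slope = if (is.null(raw$chill$slope)) 1.6 else raw$chill$slope)
      out$intermediate <- ip
    } else {
      out$chill <- chill_params(E0 = raw$chill$E0, E1 = raw$chill$E1,
                                A0 = raw$chill$A0, A1 = raw$chill$A1,
                                Tf = raw$chill$Tf, slope = raw$chill$slope)
    }
  }
  if (!is.null(raw$heat))
    out$heat <- heat_params(Tb = raw$heat$Tb, Tu = raw$heat$Tu,
                            Tc = if (is.null(raw$heat$Tc)) 36 else
                              raw$heat$Tc)
  if (!is.null(raw$requirements))
    out$requirements <- cultivar_requirements(yc = raw$requirements$yc,
                                              zc = raw$requirements$zc,
                                              s1 = raw$requirements$s1)
  out
}

#' Write a fitted model as JSON
#'
#' Serializes scheme, constants, seed, objective and per-cultivar
#' parameters (requirements plus canonical and, where applicable,
#' intermediate submodel parameters). Deterministic: identical models
#' produce byte-identical files.
#'
#' @param model A `fitted_model` from [calibrate()].
#' @param path File path.
#' @return Invisibly, `path`.
#' @export
write_fitted_model <- function(model, path) {
  stopifnot(inherits(model, "fitted_model"))
  enc <- list(
    scheme = model$scheme,
    constants = model$constants,
    seed = model$seed,
    objective = model$objective,
    converged = model$converged,
    vector = as.list(model$vector),
    cultivars = lapply(model$cultivars, function(cv) list(
      requirements = unclass(cv$requirements),
      chill = unclass(cv$chill),
      intermediate = if (is.null(cv$intermediate)) NULL else
        unclass(cv$intermediate),
      heat = unclass(cv$heat))))
  jsonlite::write_json(enc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a fitted model from JSON
#'
#' @param path File written by [write_fitted_model()].
#' @return A `fitted_model` object.
#' @export
read_fitted_model <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cultivars <- lapply(raw$cultivars, function(cv) list(
    requirements = do.call(cultivar_requirements, cv$requirements),
    chill = do.call(chill_params, cv$chill),
    intermediate = if (is.null(cv$intermediate)) NULL else
      do.call(intermediate_chill_params, cv$intermediate),
    heat = do.call(heat_params, cv$heat)))
  structure(list(scheme = raw$scheme, constants = raw$constants,
                 cultivars = cultivars,
                 vector = unlist(raw$vector),
                 objective = raw$objective, seed = raw$seed,
                 trace = NULL, converged = raw$converged),
            class = "fitted_model")
}

#' Read a pipeline/CLI configuration file
#'
#' YAML with fields such as `scheme`, `seed`, `budget`
#' (`pop`/`generations`/`polish_iter`), `split`
#' (`mode`/`fraction`/`count`), `weather` (generator settings),
#' `out_dir` and `window_start`/`window_end`.
#'
#' @param path YAML file path.
#' @return Named list.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$scheme) &&
      !cfg$scheme %in% c("baseline", "cultivar_fit", "combined_fit"))
    stop("unknown calibration scheme: ", cfg$scheme)
  cfg
}

.config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(cfg, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

#' Run the full synthetic pipeline
#'
#' simulate -> split -> calibrate -> evaluate -> response curves, writing
#' every artifact plus a manifest (package version, seeds, config hash,
#' stages run) to the output directory. Deterministic given the
#' configuration: a rerun produces byte-identical fitted-model JSON.
#'
#' @param config Named list (or path to a YAML file) with `out_dir` and
#'   optional `seed`, `scheme`, `weather`, `noise_sd_days`, `split` and
#'   `budget` entries.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_config(config)
  if (is.null(config$out_dir)) stop("config must name an out_dir")
  scheme <- if (is.null(config$scheme)) "combined_fit" else config$scheme
  if (!scheme %in% c("baseline", "cultivar_fit", "combined_fit"))
    stop("unknown calibration scheme: ", scheme)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(f) file.path(config$out_dir, f)
  stages <- character(0)

  wcfg <- do.call(weather_gen_config,
                  c(list(seed = seed), config$weather))
  weather <- generate_weather(wcfg)
  truth <- default_truth_spec(
    noise_sd_days = if (is.null(config$noise_sd_days)) 1 else
      config$noise_sd_days)
  phen <- generate_bloom_observations(weather, truth, seed = seed)
  seasons <- attr(phen, "seasons")
  write_daily_weather(weather[, c("station_id", "date", "tmin", "tmax")],
                      pth("weather.csv"))
  write_phenology(phen, pth("phenology.csv"))
  stages <- c(stages, "simulate")

  obs <- phen[phen$status == "bloom", , drop = FALSE]
  split_cfg <- utils::modifyList(list(mode = "full", fraction = 0.75,
                                      count = 10), as.list(config$split))
  sp <- split_observations(obs, mode = split_cfg$mode,
                           fraction = split_cfg$fraction,
                           count = split_cfg$count, seed = seed)
  problem <- calibration_problem(scheme, sp$calibration, seasons,
                                 budget = as.list(config$budget),
                                 seed = seed)
  model <- calibrate(problem)
  write_fitted_model(model, pth("fitted_model.json"))
  stages <- c(stages, "calibrate")

  metrics <- list()
  preds <- list()
  for (subset in c("calibration", "validation")) {
    rep <- evaluate_model(model, sp[[subset]], seasons)
    pr <- attr(rep, "predictions")
    pr$subset <- subset
    preds[[subset]] <- pr
    metrics[[subset]] <- data.frame(
      species = truth$species, scheme = scheme, subset = subset,
      n = rep$n, rmse = rep$rmse, rpiq = rep$rpiq,
      mean_bias = rep$mean_bias, prop_large_error = rep$prop_large_error,
      n_no_bloom = rep$n_no_bloom)
  }
  allpred <- do.call(rbind, preds)
  allpred$bloom_date <- NULL
  utils::write.csv(allpred, pth("predictions.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(do.call(rbind, metrics), pth("metrics.csv"),
                   row.names = FALSE, na = "")
  stages <- c(stages, "evaluate")

  first <- model$cultivars[[1]]
  rc <- temperature_response_curves(first$chill, first$heat)
  utils::write.csv(rc, pth("response_curves.csv"), row.names = FALSE)
  stages <- c(stages, "response_curves")

  manifest <- list(
    package = "bloomcast",
    version = as.character(utils::packageVersion("bloomcast")),
    seed = seed, scheme = scheme, stages = stages,
    config_hash = .config_hash(config))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
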