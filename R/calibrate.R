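#' Default optimization bounds
#'
#' Box constraints for every free parameter, in calibration-vector
#' units: requirement parameters (`yc`, `zc`, `s1`), intermediate chill
#' parameters (`theta_c`, `tau`, `pie_c`), conversion parameters (`Tf`,
#' `slope`) and heat cardinal temperatures (`Tb`, `Tu`). `theta_star`
#' (279 K) and `Tc` (36 degC) are held constant and listed in the
#' `constants` attribute.
#'
#' @return Data frame with rownames naming the parameters and columns
#'   `lower` and `upper`; attribute `constants` holds the fixed values.
#' @export
default_bounds <- function() {
  b <- data.frame(
    lower = c(yc = 5, zc = 100, s1 = 0.1, theta_c = 286, tau = 16,
              pie_c = 24, Tf = 2, slope = 1.2, Tb = 0, Tu = 15),
    upper = c(yc = 80, zc = 700, s1 = 1.2, theta_c = 287, tau = 48,
              pie_c = 50, Tf = 10, slope = 5.0, Tb = 10, Tu = 30))
  attr(b, "constants") <- list(theta_star = 279, Tc = 36)
  b
}

.SUBMODEL_PARS <- c("theta_c", "tau", "pie_c", "Tf", "slope", "Tb", "Tu")
.REQ_PARS <- c("yc", "zc", "s1")

#' Define a calibration problem
#'
#' Binds observations, their dormancy seasons, the calibration scheme
#' and the optimizer settings into one object that owns the flat
#' parameter-vector layout.
#'
#' @param scheme One of "baseline" (default submodels, only `yc`, `zc`,
#'   `s1` per cultivar), "cultivar_fit" (all ten free parameters per
#'   cultivar) or "combined_fit" (seven submodel parameters shared across
#'   the species, `yc`, `zc`, `s1` per cultivar).
#' @param observations Data frame with columns `cultivar`, `season`,
#'   `bloom_doy`, and optionally `species` and `season_key` (defaults to
#'   `as.character(season)`).
#' @param seasons Named list of [season_series()] objects keyed by
#'   `season_key`.
#' @param bounds Bounds table as from [default_bounds()].
#' @param budget List controlling the optimizer: `pop` (population
#'   size; default scales with dimension), `generations` and
#'   `polish_iter`.
#' @param seed Integer seed controlling every stochastic step.
#' @return Object of class `calibration_problem`.
#' @export
calibration_problem <- function(scheme = c("baseline", "cultivar_fit",
                                           "combined_fit"),
                                observations, seasons,
                                bounds = default_bounds(),
                                budget = list(), seed = 1L) {
  scheme <- match.arg(scheme)
  need <- c("cultivar", "season", "bloom_doy")
  miss <- setdiff(need, names(observations))
  if (length(miss))
    stop("observations missing column(s): ", paste(miss, collapse = ", "))
  if (is.null(observations$season_key))
    observations$season_key <- as.character(observations$season)
  if (scheme == "combined_fit" && !is.null(observations$species) &&
      length(unique(observations$species)) > 1)
    stop("combined_fit shares submodels within one species; run one ",
         "calibration per species")
  have <- observations$season_key %in% names(seasons)
  if (any(!have)) {
    warning(sum(!have), " observation(s) dropped: no matching weather season")
    observations <- observations[have, , drop = FALSE]
  }
  if (nrow(observations) == 0) stop("no observations with matching seasons")
  cultivars <- sort(unique(as.character(observations$cultivar)))
  sim <- lapply(cultivars, function(cv) {
    rows <- observations[observations$cultivar == cv, , drop = FALSE]
    ss <- seasons[rows$season_key]
    list(temps = lapply(ss, `[[`, "temps"),
         doys = lapply(ss, `[[`, "doy"),
         observed = as.numeric(rows$bloom_doy),
         end_doy = vapply(ss, function(s) max(s$doy), numeric(1)))
  })
  names(sim) <- cultivars
  budget <- utils::modifyList(list(pop = NULL, generations = 200,
                                   polish_iter = 400), budget)
  structure(list(scheme = scheme, observations = observations,
                 seasons = seasons, cultivars = cultivars, sim = sim,
                 bounds = bounds, constants = attr(bounds, "constants"),
                 budget = budget, seed = as.integer(seed)),
            class = "calibration_problem")
}

#' @export
print.calibration_problem <- function(x, ...) {
  cat(sprintf("Calibration problem: scheme %s, %d cultivar(s), %d observations\n",
              x$scheme, length(x$cultivars), nrow(x$observations)))
  invisible(x)
}

#' Flat parameter-vector layout for a calibration problem
#'
#' Baseline: 3 entries per cultivar (`yc`, `zc`, `s1`). Cultivar-fit: 10
#' per cultivar (the 3 requirements plus `theta_c`, `tau`, `pie_c`,
#' `Tf`, `slope`, `Tb`, `Tu`). Combined-fit: 3 per cultivar followed by
#' the 7 shared submodel parameters. `theta_star` and `Tc` never enter
#' the vector.
#'
#' @param problem A [calibration_problem()] object.
#' @return List with `layout` (data frame: `name`, `param`, `cultivar`
#'   with NA for shared entries), `lower`, `upper`, and a deterministic
#'   `init` vector at the box midpoint.
#' @export
build_parameter_vector <- function(problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  b <- problem$bounds
  per_cv <- switch(problem$scheme,
                   baseline = .REQ_PARS,
                   cultivar_fit = c(.REQ_PARS, .SUBMODEL_PARS),
                   combined_fit = .REQ_PARS)
  rows <- do.call(rbind, lapply(problem$cultivars, function(cv)
    data.frame(name = paste0(per_cv, "[", cv, "]"), param = per_cv,
               cultivar = cv)))
  if (problem$scheme == "combined_fit")
    rows <- rbind(rows, data.frame(name = .SUBMODEL_PARS,
                                   param = .SUBMODEL_PARS,
                                   cultivar = NA_character_))
  rows$index <- seq_len(nrow(rows))
  lower <- b[rows$param, "lower"]
  upper <- b[rows$param, "upper"]
  names(lower) <- names(upper) <- rows$name
  list(layout = rows, lower = lower, upper = upper,
       init = (lower + upper) / 2)
}

# Decode a flat vector into per-cultivar model parts. Returns list with
# per-cultivar requirements and chill/heat parameter objects.
decode_parameter_vector <- function(vector, problem) {
  pv <- build_parameter_vector(problem)
  lay <- pv$layout
  if (length(vector) != nrow(lay))
    stop("parameter vector has length ", length(vector), ", expected ",
         nrow(lay))
  val <- function(param, cv = NA) {
    i <- which(lay$param == param &
                 (is.na(cv) & is.na(lay$cultivar) |
                    !is.na(cv) & !is.na(lay$cultivar) & lay$cultivar == cv))
    vector[i]
  }
  submodels_for <- function(cv) {
    if (problem$scheme == "baseline")
      return(list(chill = default_chill_params(),
                  heat = default_heat_params(),
                  intermediate = NULL))
    src <- if (problem$scheme == "cultivar_fit") cv else NA
    ip <- intermediate_chill_params(theta_c = val("theta_c", src),
                                    tau = val("tau", src),
                                    pie_c = val("pie_c", src),
                                    theta_star = problem$constants$theta_star)
    list(chill = intermediate_to_canonical(ip, Tf = val("Tf", src),
                                           slope = val("slope", src)),
         heat = heat_params(Tb = val("Tb", src), Tu = val("Tu", src),
                            Tc = problem$constants$Tc),
         intermediate = ip)
  }
  shared <- if (problem$scheme == "combined_fit") submodels_for(NA) else NULL
  out <- lapply(problem$cultivars, function(cv) {
    sm <- if (problem$scheme == "combined_fit") shared else submodels_for(cv)
    list(requirements = cultivar_requirements(yc = val("yc", cv),
                                              zc = val("zc", cv),
                                              s1 = val("s1", cv)),
         chill = sm$chill, heat = sm$heat, intermediate = sm$intermediate)
  })
  names(out) <- problem$cultivars
  out
}

# Inverse of decode: rebuild the flat vector from decoded parts.
encode_parameter_vector <- function(decoded, problem) {
  pv <- build_parameter_vector(problem)
  lay <- pv$layout
  v <- numeric(nrow(lay))
  for (i in seq_len(nrow(lay))) {
    p <- lay$param[i]
    cv <- lay$cultivar[i]
    part <- if (is.na(cv)) decoded[[1]] else decoded[[cv]]
    v[i] <- if (p %in% .REQ_PARS) part$requirements[[p]]
    else if (p %in% c("theta_c", "tau", "pie_c")) part$intermediate[[p]]
    else if (p %in% c("Tf", "slope")) part$chill[[p]]
    else part$heat[[p]]
  }
  names(v) <- lay$name
  v
}

.PENALTY <- 1e6

#' Bloom-date RMSE objective
#'
#' Decodes the flat parameter vector, simulates every observation's
#' season and returns the root-mean-square error of predicted minus
#' observed bloom day of year, pooled over all cultivars. A season that
#' fails to bloom contributes a penalty residual of
#' `season-end DOY - observed DOY + 30` days, which dominates ordinary
#' residuals, stays finite and shrinks as the model approaches
#' blooming. Any decoding or simulation failure yields a large finite
#' penalty rather than an error.
#'
#' @param vector Flat parameter vector (see
#'   [build_parameter_vector()]).
#' @param problem A [calibration_problem()] object.
#' @return RMSE in days (scalar).
#' @export
objective_rmse <- function(vector, problem) {
  dec <- tryCatch(decode_parameter_vector(vector, problem),
                  error = function(e) NULL)
  if (is.null(dec)) return(.PENALTY)
  res <- unlist(lapply(problem$cultivars, function(cv) {
    d <- dec[[cv]]
    s <- problem$sim[[cv]]
    pred <- cpp_predict_bloom(s$temps, s$doys, d$chill$E0, d$chill$E1,
                              d$chill$A0, d$chill$A1, d$chill$Tf,
                              d$chill$slope, d$heat$Tb, d$heat$Tu,
                              d$heat$Tc, d$requirements$yc,
                              d$requirements$zc, d$requirements$s1)
    nb <- is.na(pred)
    pred[nb] <- s$end_doy[nb] + 30
    pred - s$observed
  }), use.names = FALSE)
  if (any(!is.finite(res))) return(.PENALTY)
  sqrt(mean(res^2))
}

# Differential evolution (rand/1/bin) with bound reflection; the seeded
# global stage of calibrate().
.de_optimize <- function(fn, lower, upper, pop, generations) {
  d <- length(lower)
  X <- matrix(runif(pop * d, lower, upper), nrow = pop, byrow = TRUE)
  f <- apply(X, 1, fn)
  trace <- numeric(generations)
  CR <- 0.9
  for (g in seq_len(generations)) {
    Fw <- runif(1, 0.5, 1)   # dithered amplification factor
    for (i in seq_len(pop)) {
      r <- sample(setdiff(seq_len(pop), i), 3)
      v <- X[r[1], ] + Fw * (X[r[2], ] - X[r[3], ])
      # reflect into the box
      v <- ifelse(v < lower, pmin(upper, 2 * lower - v), v)
      v <- ifelse(v > upper, pmax(lower, 2 * upper - v), v)
      jr <- sample.int(d, 1)
      mask <- runif(d) < CR
      mask[jr] <- TRUE
      trial <- ifelse(mask, v, X[i, ])
      ft <- fn(trial)
      if (ft <= f[i]) {
        X[i, ] <- trial
        f[i] <- ft
      }
    }
    trace[g] <- min(f)
  }
  best <- which.min(f)
  list(par = X[best, ], value = f[best], trace = trace)
}

.calibrate_single <- function(problem, lower, upper, fn, budget) {
  d <- length(lower)
  pop <- budget$pop
  if (is.null(pop)) pop <- max(20L, min(60L, 5L * d))
  if (all(upper == lower)) {
    return(list(par = lower, value = fn(lower), trace = numeric(0),
                converged = TRUE))
  }
  de <- .de_optimize(fn, lower, upper, pop, budget$generations)
  clamp <- function(v) pmin(pmax(v, lower), upper)
  pol <- stats::optim(de$par, function(v) fn(clamp(v)),
                      method = "Nelder-Mead",
                      control = list(maxit = budget$polish_iter))
  par <- clamp(pol$par)
  value <- fn(par)
  if (value > de$value) {
    par <- de$par
    value <- de$value
  }
  n <- length(de$trace)
  tail_gain <- if (n >= 10)
    de$trace[ceiling(0.8 * n)] - de$trace[n] else Inf
  list(par = par, value = value, trace = de$trace,
       converged = is.finite(tail_gain) && tail_gain < 0.05)
}

# Alternating block refinement for the combined-fit layout: Nelder-Mead
# on the shared submodel block with requirements fixed, then on each
# cultivar's 3 requirement parameters, repeated. Purely local; part of
# the single calibration run.
.block_refine <- function(par, fn, lower, upper, layout, rounds = 2,
                          maxit = 150) {
  clamp <- function(v) pmin(pmax(v, lower), upper)
  blocks <- c(list(shared = which(is.na(layout$cultivar))),
              lapply(split(seq_len(nrow(layout)), layout$cultivar),
                     identity))
  blocks <- Filter(length, blocks)
  best <- fn(par)
  for (r in seq_len(rounds)) {
    for (idx in blocks) {
      sub <- function(v) {
        w <- par
        w[idx] <- v
        fn(clamp(w))
      }
      res <- stats::optim(par[idx], sub, method = "Nelder-Mead",
                          control = list(maxit = maxit))
      cand <- par
      cand[idx] <- res$par
      cand <- clamp(cand)
      fc <- fn(cand)
      if (fc <= best) {
        par <- cand
        best <- fc
      }
    }
  }
  list(par = par, value = best)
}

#' Calibrate a phenology model
#'
#' Seeded global search (differential evolution within the bounds)
#' followed by derivative-free local polish (Nelder-Mead, clamped to the
#' box). A single run per problem; no multi-start. For the baseline and
#' cultivar-fit schemes, each cultivar's subproblem is searched
#' independently (their objectives are separable) and the results are
#' concatenated into the joint vector; the combined-fit scheme searches
#' the full joint vector, followed by alternating block refinement of
#' the shared submodel block and each cultivar's requirement block.
#'
#' @param problem A [calibration_problem()] object.
#' @return Object of class `fitted_model`: scheme, constants,
#'   per-cultivar parameters, objective value at the optimum, seed,
#'   optimizer trace summary and a convergence flag.
#' @export
calibrate <- function(problem) {
  stopifnot(inherits(problem, "calibration_problem"))
  pv <- build_parameter_vector(problem)
  set.seed(problem$seed)
  if (problem$scheme %in% c("baseline", "cultivar_fit") &&
      length(problem$cultivars) > 1) {
    parts <- lapply(problem$cultivars, function(cv) {
      sub <- problem
      sub$cultivars <- cv
      sub$sim <- problem$sim[cv]
      spv <- build_parameter_vector(sub)
      .calibrate_single(sub, spv$lower, spv$upper,
                        function(v) objective_rmse(v, sub), problem$budget)
    })
    par <- unlist(lapply(parts, `[[`, "par"))
    names(par) <- pv$layout$name
    value <- objective_rmse(par, problem)
    trace <- lapply(parts, `[[`, "trace")
    converged <- all(vapply(parts, `[[`, logical(1), "converged"))
  } else {
    fn <- function(v) objective_rmse(v, problem)
    res <- .calibrate_single(problem, pv$lower, pv$upper, fn,
                             problem$budget)
    par <- res$par
    value <- res$value
    if (problem$scheme == "combined_fit" && length(problem$cultivars) > 1) {
      ref <- .block_refine(par, fn, pv$lower, pv$upper, pv$layout)
      if (ref$value <= value) {
        par <- ref$par
        value <- ref$value
      }
    }
    names(par) <- pv$layout$name
    trace <- res$trace
    converged <- res$converged
  }
  decoded <- decode_parameter_vector(par, problem)
  structure(list(scheme = problem$scheme, constants = problem$constants,
                 cultivars = decoded, vector = par, objective = value,
                 seed = problem$seed, trace = trace,
                 converged = converged),
            class = "fitted_model")
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("Fitted %s model (%d cultivar(s)): calibration RMSE %.2f days%s\n",
              x$scheme, length(x$cultivars), x$objective,
              if (x$converged) "" else " [convergence warning]"))
  for (cv in names(x$cultivars)) {
    r <- x$cultivars[[cv]]$requirements
    cat(sprintf("  %s: yc = %.1f, zc = %.0f, s1 = %.2f\n", cv, r$yc, r$zc,
                r$s1))
  }
  invisible(x)
}

#' Predict bloom dates for observations with a fitted model
#'
#' @param model A `fitted_model` from [calibrate()].
#' @param observations Data frame with `cultivar`, `season` and
#'   optionally `season_key`.
#' @param seasons Named list of [season_series()] keyed by `season_key`.
#' @return The observations with columns `predicted_doy` (NA on failure
#'   to bloom) and `status` appended.
#' @export
predict_bloom <- function(model, observations, seasons) {
  stopifnot(inherits(model, "fitted_model"))
  if (is.null(observations$season_key))
    observations$season_key <- as.character(observations$season)
  pred <- rep(NA_real_, nrow(observations))
  for (cv in unique(as.character(observations$cultivar))) {
    if (!cv %in% names(model$cultivars)) {
      warning("no fitted parameters for cultivar ", cv)
      next
    }
    d <- model$cultivars[[cv]]
    idx <- which(observations$cultivar == cv)
    ss <- seasons[observations$season_key[idx]]
    if (anyNA(names(ss)) || any(!observations$season_key[idx] %in% names(seasons)))
      stop("missing weather season for some observations of ", cv)
    pred[idx] <- cpp_predict_bloom(lapply(ss, `[[`, "temps"),
                                   lapply(ss, `[[`, "doy"),
                                   d$chill$E0, d$chill$E1, d$chill$A0,
                                   d$chill$A1, d$chill$Tf, d$chill$slope,
                                   d$heat$Tb, d$heat$Tu, d$heat$Tc,
                                   d$requirements$yc, d$requirements$zc,
                                   d$requirements$s1)
  }
  observations$predicted_doy <- pred
  observations$status <- ifelse(is.na(pred), "no_bloom", "bloom")
  observations
}
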