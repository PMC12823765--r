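test_that("default bounds reproduce the admissible parameter box", {
  b <- default_bounds()
  expect_equal(unlist(b["yc", ]), c(lower = 5, upper = 80))
  expect_equal(unlist(b["tau", ]), c(lower = 16, upper = 48))
  expect_equal(unlist(b["zc", ]), c(lower = 100, upper = 700))
  expect_equal(unlist(b["theta_c", ]), c(lower = 286, upper = 287))
  expect_equal(unlist(b["pie_c", ]), c(lower = 24, upper = 50))
  expect_equal(unlist(b["s1", ]), c(lower = 0.1, upper = 1.2))
  expect_identical(attr(b, "constants"), list(theta_star = 279, Tc = 36))
})

test_that("vector layouts count 3K, 10 per cultivar, and 3K + 7", {
  seasons <- fixture_seasons(2)
  reqs <- list(a = cultivar_requirements(20, 300, 0.5))
  obs1 <- fixture_observations(seasons, reqs)
  p1 <- calibration_problem("cultivar_fit", obs1, seasons)
  expect_length(build_parameter_vector(p1)$init, 10)

  reqs3 <- list(a = cultivar_requirements(20, 300, 0.5),
                b = cultivar_requirements(30, 400, 0.7),
                c = cultivar_requirements(40, 500, 0.9))
  obs3 <- fixture_observations(seasons, reqs3)
  p3 <- calibration_problem("combined_fit", obs3, seasons)
  expect_length(build_parameter_vector(p3)$init, 16)
  lay <- build_parameter_vector(p3)$layout
  expect_identical(sum(is.na(lay$cultivar)), 6L + 1L)  # 7 shared entries

  reqs6 <- setNames(rep(reqs, 6), letters[1:6])
  obs6 <- fixture_observations(seasons, reqs6)
  p6 <- calibration_problem("baseline", obs6, seasons)
  expect_length(build_parameter_vector(p6)$init, 18)
})

test_that("combined fitting across species is refused", {
  seasons <- fixture_seasons(2)
  obs <- fixture_observations(seasons,
                              list(a = cultivar_requirements(20, 300, 0.5),
                                   b = cultivar_requirements(30, 400, 0.7)))
  obs$species <- ifelse(obs$cultivar == "a", "sp1", "sp2")
  expect_error(calibration_problem("combined_fit", obs, seasons),
               "per species")
  expect_silent(calibration_problem("baseline", obs, seasons))
})

test_that("encode and decode are inverse for every layout", {
  seasons <- fixture_seasons(2)
  obs <- fixture_observations(seasons,
                              list(a = cultivar_requirements(20, 300, 0.5),
                                   b = cultivar_requirements(30, 400, 0.7)))
  set.seed(31)
  for (scheme in c("baseline", "cultivar_fit", "combined_fit")) {
    prob <- calibration_problem(scheme, obs, seasons)
    pv <- build_parameter_vector(prob)
    v <- runif(length(pv$lower), pv$lower, pv$upper)
    names(v) <- pv$layout$name
    dec <- bloomcast:::decode_parameter_vector(v, prob)
    back <- bloomcast:::encode_parameter_vector(dec, prob)
    expect_equal(back, v, tolerance = 1e-12)
  }
})

test_that("the objective is zero at truth and matches a hand recompute", {
  seasons <- fixture_seasons(4)
  reqs <- list(a = cultivar_requirements(25, 350, 0.6),
               b = cultivar_requirements(35, 450, 0.8))
  obs <- fixture_observations(seasons, reqs)
  prob <- calibration_problem("baseline", obs, seasons)
  truth_v <- c(25, 350, 0.6, 35, 450, 0.8)
  expect_equal(objective_rmse(truth_v, prob), 0)
  # single observation with a five-day miss gives RMSE 5
  one <- obs[1, , drop = FALSE]
  one$bloom_doy <- one$bloom_doy + 5
  prob1 <- calibration_problem("baseline", one, seasons)
  expect_equal(objective_rmse(c(25, 350, 0.6), prob1), 5)
  # hand recompute on a perturbed vector
  v <- c(28, 380, 0.6, 35, 450, 0.8)
  dec <- bloomcast:::decode_parameter_vector(v, prob)
  res <- c()
  for (cv in c("a", "b")) {
    rows <- obs[obs$cultivar == cv, ]
    for (j in seq_len(nrow(rows))) {
      p <- simulate_season(seasons[[as.character(rows$season[j])]],
                           dec[[cv]]$chill, dec[[cv]]$heat,
                           dec[[cv]]$requirements)
      res <- c(res, p$bloom_doy - rows$bloom_doy[j])
    }
  }
  expect_equal(objective_rmse(v, prob), sqrt(mean(res^2)), tolerance = 1e-12)
})

test_that("failure to bloom incurs a finite dominating penalty", {
  # short chill phase: ~35 Chill Portions accumulate, so a requirement
  # of 80 is never met and heat stays gated
  seasons <- fixture_seasons(2, days = 150, cold_days = 40)
  obs <- fixture_observations(seasons,
                              list(a = cultivar_requirements(25, 350, 0.6)))
  prob <- calibration_problem("baseline", obs, seasons)
  val <- objective_rmse(c(80, 700, 1.2), prob)
  expect_true(is.finite(val))
  expect_gt(val, 30)
  expect_lt(val, bloomcast:::.PENALTY + 1)
})

test_that("calibration recovers a noise-free baseline problem", {
  seasons <- fixture_seasons(6)
  reqs <- list(a = cultivar_requirements(25, 350, 0.6))
  obs <- fixture_observations(seasons, reqs)
  prob <- calibration_problem("baseline", obs, seasons, seed = 4,
                              budget = list(pop = 20, generations = 40,
                                            polish_iter = 150))
  fit <- calibrate(prob)
  expect_lte(fit$objective, 1)
  # determinism: the same seed reproduces the model exactly
  fit2 <- calibrate(prob)
  expect_identical(fit$vector, fit2$vector)
  expect_identical(fit$objective, fit2$objective)
})

test_that("degenerate bounds collapse the search to a point", {
  seasons <- fixture_seasons(2)
  obs <- fixture_observations(seasons,
                              list(a = cultivar_requirements(25, 350, 0.6)))
  b <- default_bounds()
  b["yc", ] <- c(25, 25)
  b["zc", ] <- c(350, 350)
  b["s1", ] <- c(0.6, 0.6)
  attr(b, "constants") <- list(theta_star = 279, Tc = 36)
  prob <- calibration_problem("baseline", obs, seasons, bounds = b)
  fit <- calibrate(prob)
  expect_equal(unname(fit$vector), c(25, 350, 0.6))
  expect_equal(fit$objective, 0)
})

test_that("richer schemes fit the calibration data at least as well", {
  seasons <- fixture_seasons(6)
  reqs <- list(a = cultivar_requirements(25, 350, 0.6),
               b = cultivar_requirements(40, 500, 0.9))
  obs <- fixture_observations(seasons, reqs)
  set.seed(12)
  obs$bloom_doy <- obs$bloom_doy + round(rnorm(nrow(obs), 0, 2))
  budget <- list(pop = 30, generations = 80, polish_iter = 200)
  fits <- lapply(c("baseline", "combined_fit", "cultivar_fit"),
                 function(s) calibrate(
                   calibration_problem(s, obs, seasons, budget = budget,
                                       seed = 7)))
  objs <- vapply(fits, `[[`, numeric(1), "objective")
  expect_lte(objs[3], objs[2] + 0.5)  # cultivar-fit <= combined-fit
  expect_lte(objs[2], objs[1] + 0.5)  # combined-fit <= baseline
})
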