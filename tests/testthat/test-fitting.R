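# small DE settings used throughout the unit tests; the package default
# (pop 30, maxiter 500) is exercised in the acceptance suite
fast_de <- de_settings(pop_size = 20, maxiter = 150, steptol = 25)

test_that("holdout split takes the configured fraction per group", {
  ev <- rbind(toy_events(1:30, species = "a"),
              toy_events(1:31 + 100, species = "b"))
  sp <- holdout_split(ev, 0.20, seed = 99)
  expect_identical(sum(sp$test$species == "a"), 6L)  # 0.2 * 30
  expect_identical(sum(sp$test$species == "b"), 6L)  # round-half-even(6.2)
  expect_identical(nrow(sp$train) + nrow(sp$test), nrow(ev))
  # train and test are disjoint
  key <- function(d) paste(d$species, d$individual_id, d$doy)
  expect_length(intersect(key(sp$train), key(sp$test)), 0L)
  # deterministic given the seed
  sp2 <- holdout_split(ev, 0.20, seed = 99)
  expect_identical(sp, sp2)
  sp3 <- holdout_split(ev, 0.20, seed = 100)
  expect_false(identical(sp$test, sp3$test))
  expect_error(holdout_split(toy_events(1:4), 0.2, seed = 1), "fewer than 5")
})

test_that("the RMSE objective penalises no-event predictions", {
  env <- environment_data(constant_series(10))
  ev <- toy_events(c(10, 10))
  # perfect prediction: constant 10 C, F* = 100 crosses on DOY 10
  expect_equal(rmse_objective(c(f_star = 100), "fixed_gdd", ev, env), 0)
  # residuals [3, -4] -> sqrt(25/2)
  ev2 <- toy_events(c(10 - 3, 10 + 4))
  expect_equal(rmse_objective(c(f_star = 100), "fixed_gdd", ev2, env),
               sqrt(25 / 2))
  # an unreachable requirement gives the 1000-day penalty
  expect_equal(rmse_objective(c(f_star = 1e5), "fixed_gdd",
                              toy_events(10), env), 1000)
  expect_error(rmse_objective(c(f_star = 1), "fixed_gdd",
                              toy_events(10)[0, ], env), "empty")
})

test_that("differential evolution recovers analytic optima", {
  env <- environment_data(constant_series(10))
  # the RMSE-optimal naive model is the mean of the observations
  fit <- fit_model("naive", toy_events(c(100, 110, 120)), env, seed = 5,
                   settings = fast_de)
  expect_equal(unname(fit$par["mean_doy"]), 110, tolerance = 1e-3)
  expect_equal(fit$value, sqrt(200 / 3), tolerance = 1e-3)
  # reproducible bit-for-bit given the seed
  fit2 <- fit_model("naive", toy_events(c(100, 110, 120)), env, seed = 5,
                    settings = fast_de)
  expect_identical(fit$par, fit2$par)
  expect_error(fit_model("naive", toy_events(100), env), "seed")
})

test_that("DE matches a grid-search oracle for the fixed GDD model", {
  # noise-free events generated by F* = 200 across heterogeneous sites
  cfg <- synthetic_config(n_sites_intensive = 2, n_sites_broad = 6,
                          years = 2012:2014, n_species = 1,
                          species_spread = 0, event_noise_sd = 0,
                          true_params = c(f_star = 200), seed = 31)
  sim <- simulate_dataset(cfg)
  truth <- rbind(sim$truth_intensive, sim$truth_broad)
  fit <- fit_model("fixed_gdd", truth, sim$env, seed = 8,
                   settings = fast_de)
  # 1-D grid search over F* at 0.25-unit resolution
  grid <- seq(150, 250, by = 0.25)
  obj <- vapply(grid, function(f)
    rmse_objective(c(f_star = f), "fixed_gdd", truth, sim$env), 1)
  f_grid <- grid[which.min(obj)]
  expect_lt(abs(unname(fit$par) - f_grid), 2)
  expect_lte(fit$value, min(obj) + fast_de$tol)
  # and the optimum is close to the generating truth
  expect_lt(abs(unname(fit$par) - 200), 10)
})

test_that("generate-and-refit reaches sub-day RMSE on noise-free data", {
  cfg <- synthetic_config(n_sites_intensive = 2, n_sites_broad = 6,
                          years = 2012:2014, n_species = 1,
                          species_spread = 0, event_noise_sd = 0,
                          generative_model = "gdd",
                          true_params = c(t1 = 10, t_base = 5,
                                          f_star = 150),
                          seed = 17)
  sim <- simulate_dataset(cfg)
  truth <- rbind(sim$truth_intensive, sim$truth_broad)
  fit <- fit_model("gdd", truth, sim$env, seed = 3)
  # parameters may trade off along the identifiability ridge, but the
  # training error must still collapse
  expect_lt(fit$value, 1)
})

test_that("bootstrap refits are reproducible and sized as configured", {
  env <- environment_data(constant_series(10))
  ev <- toy_events(c(8, 10, 12, 9, 11, 10))
  bf <- bootstrap_fit("fixed_gdd", ev, env, seed = 21, reps = 10,
                      settings = fast_de)
  expect_s3_class(bf, "fitted_model")
  expect_identical(dim(bf$bootstrap_params), c(10L, 1L))
  expect_identical(bf$n_failed, 0L)
  expect_true(all(bf$bootstrap_params >= bf$bounds["lower", ] &
                    bf$bootstrap_params <= bf$bounds["upper", ]))
  bf2 <- bootstrap_fit("fixed_gdd", ev, env, seed = 21, reps = 10,
                       settings = fast_de)
  expect_identical(bf$bootstrap_params, bf2$bootstrap_params)
})

test_that("degenerate data give zero bootstrap spread", {
  env <- environment_data(constant_series(10))
  ev <- toy_events(rep(12, 8))  # identical repeated observations
  bf <- bootstrap_fit("fixed_gdd", ev, env, seed = 4, reps = 12,
                      settings = fast_de)
  # every n-of-n resample of identical rows is the same dataset
  expect_equal(unname(apply(bf$bootstrap_params, 2, sd)), 0)
  s <- env[[1]]$series
  expect_identical(
    predict_mean_of_bootstraps(bf, s, env[[1]]$covariates),
    predict_event("fixed_gdd", bf$point_params, s))
})

test_that("bootstrap parameter spread shrinks with sample size", {
  spread_at <- function(n_ind, seed) {
    cfg <- synthetic_config(n_sites_intensive = 2, n_sites_broad = 2,
                            years = 2012:2013, n_species = 1,
                            species_spread = 0, event_noise_sd = 3,
                            n_individuals_intensive = n_ind,
                            n_individuals_broad = n_ind, seed = seed)
    sim <- simulate_dataset(cfg)
    truth <- rbind(sim$truth_intensive, sim$truth_broad)
    bf <- bootstrap_fit("fixed_gdd", truth, sim$env, seed = 1, reps = 15,
                        settings = fast_de)
    sd(bf$bootstrap_params[, 1])
  }
  expect_lt(spread_at(40, 2), spread_at(4, 2))
})

test_that("mean-of-bootstrap predictions follow the exclusion rule", {
  env <- environment_data(constant_series(10))
  s <- env[[1]]$series
  bf <- bootstrap_fit("fixed_gdd", toy_events(c(9, 10, 11)), env,
                      seed = 2, reps = 4, settings = fast_de)
  # {100, 100, NO_EVENT}-style mixtures: the no-event member is excluded
  bf$bootstrap_params <- matrix(c(95, 105, 1e6), ncol = 1,
                                dimnames = list(NULL, "f_star"))
  p95 <- predict_event("fixed_gdd", c(f_star = 95), s)
  p105 <- predict_event("fixed_gdd", c(f_star = 105), s)
  expect_true(is.na(predict_event("fixed_gdd", c(f_star = 1e6), s)))
  expect_equal(predict_mean_of_bootstraps(bf, s), mean(c(p95, p105)))
  # all-no-event propagates the marker
  bf$bootstrap_params <- matrix(c(1e6, 2e6), ncol = 1,
                                dimnames = list(NULL, "f_star"))
  expect_true(is.na(predict_mean_of_bootstraps(bf, s)))
  bf$bootstrap_params <- matrix(NA_real_, 2, 1,
                                dimnames = list(NULL, "f_star"))
  expect_error(predict_mean_of_bootstraps(bf, s), "no usable")
})

test_that("fitted models serialise to JSON and CSV", {
  dir <- withr::local_tempdir()
  env <- environment_data(constant_series(10))
  bf <- bootstrap_fit("fixed_gdd", toy_events(c(9, 10, 11)), env,
                      seed = 2, reps = 3, settings = fast_de)
  jf <- file.path(dir, "fit.json"); cf <- file.path(dir, "boot.csv")
  write_fitted_model(bf, jf, cf)
  meta <- jsonlite::read_json(jf)
  expect_identical(meta$model, "fixed_gdd")
  expect_identical(meta$bootstrap_reps, 3L)
  expect_equal(meta$point_params$f_star, unname(bf$point_params))
  expect_identical(nrow(read.csv(cf)), 3L)
})
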