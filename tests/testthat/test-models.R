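test_that("model registry matches the published parameterisations", {
  counts <- c(naive = 1, linear = 2, gdd = 3, fixed_gdd = 1,
              alternating = 3, uniforc = 4, m1 = 4, msb = 4)
  for (m in names(counts)) {
    spec <- model_spec(m)
    expect_length(spec$parameter_names, counts[[m]])
    expect_true(all(spec$bounds["lower", ] <= spec$bounds["upper", ]))
  }
  # uniforc's sigmoid slope is constrained negative so warmth forces
  expect_lt(model_spec("uniforc")$bounds["upper", "b"], 0)
  expect_error(model_spec("unichill"))
})

test_that("naive and linear predictors are pure arithmetic", {
  s1 <- constant_series(10)
  s2 <- random_test_series(1)
  expect_equal(predict_event("naive", c(mean_doy = 110), s1), 110)
  expect_equal(predict_naive(c(mean_doy = 95.5)), 95.5)
  expect_equal(predict_event("naive", c(mean_doy = 80), s1),
               predict_event("naive", c(mean_doy = 80), s2))
  expect_equal(predict_linear(c(beta1 = 100, beta2 = -2), 5), 90)
  expect_equal(predict_linear(c(beta1 = 100, beta2 = 0), 17.3), 100)
  expect_equal(predict_linear(c(beta1 = 100, beta2 = -2), 0), 100)
  expect_error(predict_linear(c(beta1 = 1, beta2 = 1), Inf), "finite")
})

test_that("forcing accumulation is a running sum from the start day", {
  s <- constant_series(10, doy = 1:50)
  acc <- accumulate_forcing(s, function(ti) rep(1, length(ti)), 1)
  expect_equal(unname(acc), 1:50)
  acc5 <- accumulate_forcing(s, function(ti) rep(1, length(ti)), 5)
  expect_identical(names(acc5)[1], "5")
  expect_equal(unname(acc5), 1:46)
  expect_error(accumulate_forcing(s, identity, 0), "outside series range")
  # brute-force day-by-day loop agrees on random series
  for (seed in 1:25) {
    rs <- random_test_series(seed)
    acc <- accumulate_forcing(rs, function(ti) pmax(ti - 3, 0), -10)
    ref <- numeric(0); tot <- 0
    for (d in -10:250) {
      tot <- tot + max(temp_at(rs, d) - 3, 0)
      ref <- c(ref, tot)
    }
    expect_equal(unname(acc), ref)
  }
})

test_that("GDD-family spec examples hold", {
  expect_equal(predict_event("gdd", c(t1 = 1, t_base = 0, f_star = 100),
                             constant_series(10)), 10)
  expect_equal(predict_event("fixed_gdd", c(f_star = 50),
                             constant_series(5)), 10)
  # frozen series: no event when forcing never accrues
  expect_true(is.na(predict_event("gdd", c(t1 = 1, t_base = 0, f_star = 10),
                                  constant_series(-5))))
  # alternating temperatures, brute-force value
  s <- temperature_series("ALT", 2015, 1:20, rep(c(-10, 20), 10), 40)
  expect_equal(predict_event("fixed_gdd", c(f_star = 60), s), 6)
  # sigmoid midpoint: half a forcing unit per day at Ti = c
  expect_equal(predict_event("uniforc", c(t1 = 1, b = -2, c = 10, f_star = 5),
                             constant_series(10)), 10)
  # saturation: strongly negative b and warm days give ~1 unit/day
  expect_equal(predict_event("uniforc", c(t1 = 3, b = -15, c = 0, f_star = 7),
                             constant_series(20)), 9)
  # alternating with no chill days: requirement collapses to a + b
  expect_equal(predict_event("alternating", c(a = 50, b = 50, c = -0.01),
                             constant_series(10)), 20)
  # msb spring correction shifts the requirement by d * Tmean
  expect_equal(predict_event("msb", c(a = 50, b = 50, c = -0.01, d = -5),
                             constant_series(10)), 10)
})

test_that("every forcing predictor matches the day-by-day oracle", {
  models <- c("gdd", "fixed_gdd", "alternating", "uniforc", "m1", "msb")
  n_ok <- setNames(integer(length(models)), models)
  for (seed in 1:200) {
    rs <- random_test_series(seed, lat = runif(1, -60, 60))
    cov <- compute_covariates(rs)
    for (m in models) {
      p <- random_test_params(m, seed * 131 + match(m, models))
      got <- predict_event(m, p, rs, cov)
      want <- ref_predict(m, p, rs$doy_start:rs$doy_end, rs$tmean,
                          lat = rs$latitude)
      expect_identical(got, want)
      if (!is.na(got)) n_ok[m] <- n_ok[m] + 1L
    }
  }
  # the draw produces a healthy mix of event and no-event cases
  expect_true(all(n_ok > 20))
  expect_true(all(n_ok < 200))
})

test_that("limit identities tie the model family together", {
  for (seed in 1:40) {
    rs <- random_test_series(seed)
    cov <- compute_covariates(rs)
    t1 <- round(runif(1, -30, 120)); tb <- runif(1, -10, 15)
    fs <- runif(1, 5, 400); a <- runif(1, 5, 400)
    # M1 with k = 0 is GDD
    expect_identical(
      predict_event("m1", c(t1 = t1, t_base = tb, f_star = fs, k = 0),
                    rs, cov),
      predict_event("gdd", c(t1 = t1, t_base = tb, f_star = fs), rs, cov))
    # MSB with d = 0 is Alternating
    b <- runif(1, 0, 500); cc <- runif(1, -2, 0)
    expect_identical(
      predict_event("msb", c(a = a, b = b, c = cc, d = 0), rs, cov),
      predict_event("alternating", c(a = a, b = b, c = cc), rs, cov))
    # Alternating with b = 0 is GDD with t1 = 1, Tbase = 5, F* = a
    expect_identical(
      predict_event("alternating", c(a = a, b = 0, c = cc), rs, cov),
      predict_event("gdd", c(t1 = 1, t_base = 5, f_star = a), rs, cov))
    # Fixed GDD is GDD with t1 = 1, Tbase = 0
    expect_identical(
      predict_event("fixed_gdd", c(f_star = fs), rs, cov),
      predict_event("gdd", c(t1 = 1, t_base = 0, f_star = fs), rs, cov))
  }
})

test_that("warming never delays and larger requirements never hasten", {
  for (seed in 1:20) {
    rs <- random_test_series(seed)
    warm <- temperature_series(rs$site_id, rs$year,
                               rs$doy_start:rs$doy_end,
                               pmin(rs$tmean + 3, 60), rs$latitude)
    for (m in c("gdd", "fixed_gdd", "uniforc")) {
      p <- random_test_params(m, seed + 991)
      if ("b" %in% names(p)) p[["b"]] <- -abs(p[["b"]])
      d0 <- predict_event(m, p, rs)
      d1 <- predict_event(m, p, warm)
      if (!is.na(d0)) expect_true(!is.na(d1) && d1 <= d0)
      p2 <- p
      p2[["f_star"]] <- p[["f_star"]] * 1.5
      d2 <- predict_event(m, p2, rs)
      if (!is.na(d2) && !is.na(d0)) expect_gte(d2, d0)
      if (is.na(d0)) expect_true(is.na(d2))
    }
  }
})

test_that("no-event is a marker, never a day", {
  s <- constant_series(-5)
  p <- predict_event("fixed_gdd", c(f_star = 10), s)
  expect_true(is.na(p))
  expect_type(p, "double")
  # a real prediction always lies within the series range
  for (seed in 1:30) {
    rs <- random_test_series(seed)
    d <- predict_event("fixed_gdd", c(f_star = runif(1, 1, 800)), rs)
    if (!is.na(d)) {
      expect_gte(d, rs$doy_start)
      expect_lte(d, rs$doy_end)
    }
  }
})

test_that("the M1 printed-formula variant is available as an option", {
  rs <- random_test_series(77)
  p <- c(t1 = 1, t_base = 0, f_star = 300, k = 2)
  default <- predict_event("m1", p, rs)
  floored <- predict_event("m1", p, rs,
                           control = list(m1_forcing_floor = 5))
  want <- ref_predict("m1", p, rs$doy_start:rs$doy_end, rs$tmean,
                      lat = rs$latitude, m1_floor = 5)
  expect_identical(floored, want)
  # the 5-unit floor accumulates at least as fast as the 0 floor
  if (!is.na(default)) expect_lte(floored, default)
})

test_that("event tables are predicted via their site-year series", {
  s1 <- constant_series(10, site = "A")
  s2 <- constant_series(20, site = "B")
  env <- environment_data(list(s1, s2))
  ev <- data.frame(site_id = c("A", "B", "A"), year = 2015L,
                   doy = c(100, 100, 100))
  got <- predict_events("fixed_gdd", c(f_star = 100), ev, env)
  expect_equal(got, c(10, 5, 10))
  expect_error(predict_events("fixed_gdd", c(f_star = 1),
                              data.frame(site_id = "Z", year = 2015L,
                                         doy = 1), env),
               "no temperature series")
  # the cached fixed-GDD path agrees with the generic predictor
  for (seed in 1:20) {
    rs <- random_test_series(seed, lat = 44)
    env1 <- environment_data(list(rs))
    fs <- runif(1, 1, 700)
    ev1 <- data.frame(site_id = rs$site_id, year = rs$year, doy = 1)
    expect_identical(
      predict_events("fixed_gdd", c(f_star = fs), ev1, env1),
      predict_fixed_gdd(rs, c(f_star = fs)))
  }
})
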