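# Independent day-by-day reference implementations used as oracles.
# These deliberately share no code with the package: each predictor is a
# plain loop over days that recomputes its running sums and the daily
# requirement from scratch.

ref_predict <- function(model, params, doy, tmean, lat = 40,
                        m1_floor = 0) {
  p <- as.list(params)
  start <- switch(model,
                  gdd = round(p$t1), uniforc = round(p$t1),
                  m1 = round(p$t1), 1L)
  tmean_spring <- mean(tmean[match(1:90, doy)])
  acc <- 0
  ncd <- 0
  for (i in seq_along(doy)) {
    d <- doy[i]
    ti <- tmean[i]
    if (d >= 1 && ti < 0) ncd <- ncd + 1
    if (d < start) next
    acc <- acc + switch(model,
      gdd = max(ti - p$t_base, 0),
      fixed_gdd = max(ti, 0),
      alternating = max(ti - 5, 0),
      msb = max(ti - 5, 0),
      uniforc = 1 / (1 + exp(p$b * (ti - p$c))),
      m1 = max(ti - p$t_base, m1_floor)
    )
    req <- switch(model,
      gdd = p$f_star,
      fixed_gdd = p$f_star,
      uniforc = p$f_star,
      alternating = p$a + p$b * exp(p$c * ncd),
      msb = p$a + p$b * exp(p$c * ncd) + p$d * tmean_spring,
      m1 = (ref_daylength(lat, d) / 24)^p$k * p$f_star
    )
    if (!is.na(req) && acc >= req) return(as.numeric(d))
  }
  NA_real_
}

# CBM day length, written out independently for the oracle
ref_daylength <- function(lat, d) {
  d <- ((d - 1) %% 365) + 1
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (d - 186)))
  phi <- asin(0.39795 * cos(theta))
  x <- sin(lat * pi / 180) * sin(phi) / (cos(lat * pi / 180) * cos(phi))
  24 - (24 / pi) * acos(max(-1, min(1, x)))
}

# Random seasonal-ish temperature series for oracle comparisons
random_test_series <- function(seed, doy = -90:250, lat = NULL) {
  set.seed(seed)
  if (is.null(lat)) lat <- runif(1, -60, 60)
  base <- runif(1, -5, 15)
  amp <- runif(1, 5, 18)
  tm <- base + amp * cos(2 * pi * (doy - 200) / 365) + rnorm(length(doy), 0, 4)
  temperature_series(paste0("rand", seed), 2000L, doy,
                     pmin(60, pmax(-60, tm)), lat)
}

# Random in-bounds parameter draw for a model
random_test_params <- function(model, seed) {
  set.seed(seed)
  b <- model_spec(model)$bounds
  p <- runif(ncol(b), b["lower", ], b["upper", ])
  names(p) <- colnames(b)
  # keep thresholds in a range where events sometimes do / don't occur
  if ("f_star" %in% names(p)) p[["f_star"]] <- runif(1, 5, 600)
  if ("a" %in% names(p)) p[["a"]] <- runif(1, 5, 500)
  if ("b" %in% names(p) && model %in% c("alternating", "msb")) {
    p[["b"]] <- runif(1, 0, 500)
  }
  p
}

constant_series <- function(temp, doy = -90:250, lat = 40, site = "CONST",
                            year = 2015L) {
  temperature_series(site, year, doy, rep(temp, length(doy)), lat)
}

# tiny event table on a fixed environment, for fitting tests
toy_events <- function(doys, site = "CONST", year = 2015L,
                       species = "sp", phenophase_class = "budburst") {
  data.frame(species = species, phenophase_class = phenophase_class,
             site_id = site, individual_id = paste0("i", seq_along(doys)),
             year = year, doy = doys, stringsAsFactors = FALSE)
}
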