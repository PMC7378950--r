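# Deterministic sub-stream seed from a master seed and a mix of
# integer/character tags (FNV-style accumulation, kept below 2^31).
substream_seed <- function(seed, ...) {
  ids <- list(...)
  h <- as.numeric(seed) %% 2147483629
  for (v in ids) {
    if (is.character(v)) v <- sum(utf8ToInt(v) * seq_along(utf8ToInt(v)))
    h <- (h * 1000003 + as.numeric(v) %% 2147483629) %% 2147483629
  }
  as.integer(h + 1)
}

#' Configuration of the synthetic phenology study
#'
#' Defines a synthetic cross-scale study: a small set of intensively
#' monitored sites (regular 3--7 day revisits of many individuals, long
#' site fidelity) against a larger set of broad-scale sites (few
#' individuals, sparse irregular visits, yearly dropout), all driven by a
#' shared site-latitude temperature climatology and a known generative
#' phenology model.
#'
#' Species differ in their required forcing total (the threshold-like
#' parameter is scaled by `species_spread` across species); sites can
#' additionally vary around the species value via `param_spatial_sd`,
#' which is the knob that makes single-site parameter estimates diverge
#' from the range-wide ones.
#'
#' @param n_sites_intensive,n_sites_broad Number of sites per campaign
#'   style.
#' @param years Event-season calendar years.
#' @param latitude_range Range from which site latitudes are drawn.
#' @param temp_params List: `annual_mean_at_ref_lat` (degrees C),
#'   `ref_lat`, `lapse_per_degree_lat` (degrees C per degree latitude),
#'   `amplitude` (seasonal half-range, degrees C), `peak_doy` (warmest
#'   day), `daily_noise_sd` (degrees C).
#' @param generative_model Name of the model generating true events.
#' @param true_params Base (species-average) parameter vector of the
#'   generative model.
#' @param n_species Number of species.
#' @param species_spread Relative spread of the threshold parameter
#'   across species (species s gets the base value scaled by an evenly
#'   spaced factor in `1 +/- species_spread`).
#' @param param_spatial_sd Named numeric: across-site standard deviation
#'   of each parameter (0 = spatially invariant truth).
#' @param event_noise_sd Individual-level noise on the realised event day
#'   (days).
#' @param n_individuals_intensive,n_individuals_broad Monitored
#'   individuals per species at each site.
#' @param intensive_interval_range Integer range of the regular revisit
#'   interval (days) at intensive sites.
#' @param broad_visit_rate Daily visit probability at broad-scale sites.
#' @param broad_dropout_prob Probability that a broad-scale individual is
#'   not monitored at all in a given year.
#' @param seed Master seed; every stream the generator uses derives from
#'   it.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_sites_intensive = 2,
                             n_sites_broad = 20,
                             years = 2010:2015,
                             latitude_range = c(32, 45),
                             temp_params = list(),
                             generative_model = "fixed_gdd",
                             true_params = c(f_star = 200),
                             n_species = 4,
                             species_spread = 0.3,
                             param_spatial_sd = numeric(0),
                             event_noise_sd = 2,
                             n_individuals_intensive = 15,
                             n_individuals_broad = 3,
                             intensive_interval_range = c(3L, 7L),
                             broad_visit_rate = 1 / 14,
                             broad_dropout_prob = 0.3,
                             seed = 1) {
  tp_default <- list(annual_mean_at_ref_lat = 12, ref_lat = 40,
                     lapse_per_degree_lat = -0.8, amplitude = 12,
                     peak_doy = 200, daily_noise_sd = 3)
  unknown <- setdiff(names(temp_params), names(tp_default))
  if (length(unknown)) {
    stop("unknown temp_params field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  tp <- utils::modifyList(tp_default, temp_params)
  spec <- model_spec(generative_model)
  true_params <- param_vector(true_params, spec)
  names(true_params) <- spec$parameter_names
  if (length(param_spatial_sd)) {
    bad <- setdiff(names(param_spatial_sd), spec$parameter_names)
    if (length(bad)) {
      stop("param_spatial_sd names not parameters of ", spec$name, ": ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    if (any(param_spatial_sd < 0)) {
      stop("param_spatial_sd must be >= 0", call. = FALSE)
    }
  }
  stopifnot(event_noise_sd >= 0, tp$daily_noise_sd >= 0,
            n_sites_intensive >= 1, n_sites_broad >= 1, n_species >= 1,
            species_spread >= 0, broad_visit_rate > 0,
            broad_visit_rate <= 1, broad_dropout_prob >= 0,
            broad_dropout_prob < 1,
            all(intensive_interval_range >= 1))
  structure(
    list(n_sites_intensive = as.integer(n_sites_intensive),
         n_sites_broad = as.integer(n_sites_broad),
         years = as.integer(years),
         latitude_range = as.numeric(latitude_range),
         temp_params = tp,
         generative_model = spec$name,
         true_params = true_params,
         n_species = as.integer(n_species),
         species_spread = species_spread,
         param_spatial_sd = param_spatial_sd,
         event_noise_sd = event_noise_sd,
         n_individuals_intensive = as.integer(n_individuals_intensive),
         n_individuals_broad = as.integer(n_individuals_broad),
         intensive_interval_range = as.integer(intensive_interval_range),
         broad_visit_rate = broad_visit_rate,
         broad_dropout_prob = broad_dropout_prob,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

# Threshold-like parameter that varies across species: the required
# forcing total where the model has one, else the requirement intercept.
threshold_param <- function(model_name) {
  switch(model_name,
    naive = "mean_doy", linear = "beta1",
    alternating = "a", msb = "a",
    "f_star"
  )
}

#' Species-level true parameters of a synthetic study
#'
#' @param config A [synthetic_config()].
#' @return Named list (one element per species) of parameter vectors.
#' @export
species_true_params <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  tp <- threshold_param(config$generative_model)
  scales <- if (config$n_species == 1L) 1 else {
    seq(1 - config$species_spread, 1 + config$species_spread,
        length.out = config$n_species)
  }
  out <- lapply(seq_len(config$n_species), function(s) {
    p <- config$true_params
    p[tp] <- p[tp] * scales[s]
    p
  })
  names(out) <- sprintf("species_%02d", seq_len(config$n_species))
  out
}

#' Site table of a synthetic study
#'
#' @param config A [synthetic_config()].
#' @return Data frame `site_id, latitude, longitude, style`.
#' @export
generate_sites <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  n <- config$n_sites_intensive + config$n_sites_broad
  set.seed(substream_seed(config$seed, "sites"))
  lat <- stats::runif(n, config$latitude_range[1], config$latitude_range[2])
  lon <- stats::runif(n, -120, -70)
  data.frame(
    site_id = c(sprintf("INT%02d", seq_len(config$n_sites_intensive)),
                sprintf("BRD%02d", seq_len(config$n_sites_broad))),
    latitude = round(lat, 3),
    longitude = round(lon, 3),
    style = rep(c("intensive", "broad"),
                c(config$n_sites_intensive, config$n_sites_broad)),
    stringsAsFactors = FALSE
  )
}

#' Generate one site-year daily temperature series
#'
#' Daily mean temperature is a latitude-shifted sinusoidal climatology
#' plus white noise: `M(lat) + A * cos(2 * pi * (d - peak_doy) / 365) +
#' N(0, daily_noise_sd)`, over DOY -90..250 so that forcing may start in
#' the preceding autumn. Reproducible per (seed, site, year).
#'
#' @param config A [synthetic_config()].
#' @param site One row of [generate_sites()] (or any list with `site_id`
#'   and `latitude`).
#' @param year Season year.
#' @return A [temperature_series()].
#' @export
generate_temperature <- function(config, site, year) {
  stopifnot(inherits(config, "synthetic_config"))
  tp <- config$temp_params
  doy <- -90:250
  m <- tp$annual_mean_at_ref_lat +
    tp$lapse_per_degree_lat * (site$latitude - tp$ref_lat)
  clim <- m + tp$amplitude * cos(2 * pi * (doy - tp$peak_doy) / 365)
  set.seed(substream_seed(config$seed, "temp", site$site_id, year))
  noise <- if (tp$daily_noise_sd > 0) {
    stats::rnorm(length(doy), 0, tp$daily_noise_sd)
  } else 0
  temperature_series(site$site_id, year, doy,
                     pmin(60, pmax(-60, clim + noise)), site$latitude)
}

#' Site-level true parameters (species truth plus spatial variation)
#'
#' Each site's parameters for each species are the species truth plus
#' independent Normal deviates with `param_spatial_sd` (drawn once per
#' site-species, clamped to the model's bounds).
#'
#' @param config A [synthetic_config()].
#' @param sites Site table from [generate_sites()].
#' @return Nested list `[[species]][[site_id]]` of parameter vectors.
#' @export
site_true_params <- function(config, sites) {
  sp_par <- species_true_params(config)
  spec <- model_spec(config$generative_model)
  out <- lapply(seq_along(sp_par), function(s) {
    per_site <- lapply(seq_len(nrow(sites)), function(i) {
      p <- sp_par[[s]]
      if (length(config$param_spatial_sd)) {
        set.seed(substream_seed(config$seed, "spatial",
                                sites$site_id[i], s))
        for (pn in names(config$param_spatial_sd)) {
          p[pn] <- p[pn] + stats::rnorm(1, 0, config$param_spatial_sd[pn])
          p[pn] <- min(max(p[pn], spec$bounds["lower", pn]),
                       spec$bounds["upper", pn])
        }
      }
      p
    })
    names(per_site) <- sites$site_id
    per_site
  })
  names(out) <- names(sp_par)
  out
}

#' True phenology events of a synthetic study
#'
#' For every species, site, year and individual, the true event day is
#' the generative model's prediction under the site-level parameters plus
#' individual Normal noise, rounded to a whole day. Site-years where the
#' generative model predicts no event are skipped and counted.
#'
#' @param config A [synthetic_config()].
#' @param sites Site table.
#' @param env A `pheno_env` covering every site-year (see
#'   [simulate_dataset()]).
#' @return Event-table data frame (`species, phenophase_class, site_id,
#'   individual_id, year, doy`) of true events, with attribute
#'   `n_no_event` (skipped site-years) and `site_params`.
#' @export
generate_true_events <- function(config, sites, env) {
  stopifnot(inherits(config, "synthetic_config"))
  site_par <- site_true_params(config, sites)
  spec <- model_spec(config$generative_model)
  rows <- list()
  n_no_event <- 0L
  for (sp in names(site_par)) {
    for (i in seq_len(nrow(sites))) {
      site <- sites[i, ]
      n_ind <- if (site$style == "intensive") {
        config$n_individuals_intensive
      } else {
        config$n_individuals_broad
      }
      for (yr in config$years) {
        e <- env_lookup(env, site$site_id, yr)
        true_doy <- predict_event(spec, site_par[[sp]][[site$site_id]],
                                  e$series, e$covariates)
        if (is.na(true_doy)) {
          n_no_event <- n_no_event + 1L
          next
        }
        set.seed(substream_seed(config$seed, "events", sp,
                                site$site_id, yr))
        noise <- if (config$event_noise_sd > 0) {
          stats::rnorm(n_ind, 0, config$event_noise_sd)
        } else 0
        doys <- pmax(1, round(true_doy + noise))
        rows[[length(rows) + 1L]] <- data.frame(
          species = sp, phenophase_class = "budburst",
          site_id = site$site_id,
          individual_id = sprintf("%s_%s_ind%02d", site$site_id, sp,
                                  seq_len(n_ind)),
          year = yr, doy = doys, stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_no_event") <- n_no_event
  attr(out, "site_params") <- site_par
  out
}

#' Observation campaign over true events
#'
#' Turns true event days into status records by simulating visits.
#' Intensive campaigns revisit each individual at a regular interval
#' drawn from `intensive_interval_range` (one draw per individual-year);
#' broad-scale campaigns visit on random days (daily probability
#' `broad_visit_rate`) and skip whole individual-years with probability
#' `broad_dropout_prob`. Every visit before the true day yields a "no",
#' every visit on or after it a "yes".
#'
#' @param config A [synthetic_config()].
#' @param true_events True event table from [generate_true_events()].
#' @param style `"intensive"` or `"broad"`.
#' @return Status-record data frame (`individual_id, site_id, species,
#'   phenophase, date, status`).
#' @export
generate_campaign <- function(config, true_events,
                              style = c("intensive", "broad")) {
  stopifnot(inherits(config, "synthetic_config"))
  style <- match.arg(style)
  rows <- vector("list", nrow(true_events))
  for (i in seq_len(nrow(true_events))) {
    ev <- true_events[i, ]
    set.seed(substream_seed(config$seed, "campaign", style,
                            ev$individual_id, ev$year))
    if (style == "intensive") {
      rng <- config$intensive_interval_range
      interval <- sample(seq(rng[1], rng[2]), 1L)
      offset <- sample(seq_len(interval), 1L)
      visits <- seq(offset, 250L, by = interval)
    } else {
      if (stats::runif(1) < config$broad_dropout_prob) next
      visits <- which(stats::runif(250L) < config$broad_visit_rate)
      if (length(visits) == 0L) next
    }
    rows[[i]] <- data.frame(
      individual_id = ev$individual_id, site_id = ev$site_id,
      species = ev$species, phenophase = "breaking_leaf_buds",
      date = as.Date(visits - 1, origin = sprintf("%d-01-01", ev$year)),
      status = ifelse(visits >= ev$doy, "yes", "no"),
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(individual_id = character(), site_id = character(),
                      species = character(), phenophase = character(),
                      date = as.Date(character()), status = character(),
                      stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Simulate a full cross-scale phenology study
#'
#' Generates sites, per site-year temperature series, true events for
#' both campaign styles, and the two status-record tables. Everything is
#' a deterministic function of `config$seed`.
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_dataset`: `sites`, `env` (a
#'   `pheno_env`), `truth_intensive`, `truth_broad`,
#'   `records_intensive`, `records_broad`, `config`.
#' @export
simulate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  sites <- generate_sites(config)
  series <- list()
  for (i in seq_len(nrow(sites))) {
    for (yr in config$years) {
      series[[length(series) + 1L]] <-
        generate_temperature(config, sites[i, ], yr)
    }
  }
  env <- environment_data(series)
  truth <- generate_true_events(config, sites, env)
  int_sites <- sites$site_id[sites$style == "intensive"]
  truth_int <- truth[truth$site_id %in% int_sites, , drop = FALSE]
  truth_brd <- truth[!truth$site_id %in% int_sites, , drop = FALSE]
  structure(
    list(sites = sites, env = env,
         truth_intensive = truth_int, truth_broad = truth_brd,
         records_intensive = generate_campaign(config, truth_int,
                                               "intensive"),
         records_broad = generate_campaign(config, truth_brd, "broad"),
         config = config),
    class = "synthetic_dataset"
  )
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(
    "<synthetic_dataset> %d intensive + %d broad sites, %d season(s)\n",
    x$config$n_sites_intensive, x$config$n_sites_broad,
    length(x$config$years)))
  cat(sprintf("  true events: %d intensive, %d broad; records: %d / %d\n",
              nrow(x$truth_intensive), nrow(x$truth_broad),
              nrow(x$records_intensive), nrow(x$records_broad)))
  invisible(x)
}

#' Write a simulated study to CSV files
#'
#' Writes the two status tables, the temperature table, the site table
#' and the withheld truth tables as plain CSV under `dir`.
#'
#' @param sim A `synthetic_dataset`.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the named vector of file paths.
#' @export
write_simulated_csv <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  temps <- do.call(rbind, lapply(sim$env, function(e) {
    s <- e$series
    data.frame(
      site_id = s$site_id,
      date = as.Date(s$doy_start:s$doy_end - 1,
                     origin = sprintf("%d-01-01", s$year)),
      tmean_c = round(s$tmean, 2), stringsAsFactors = FALSE)
  }))
  temps <- unique(temps[order(temps$site_id, temps$date), ])
  paths <- c(
    status_intensive = file.path(dir, "status_intensive.csv"),
    status_broad = file.path(dir, "status_broad.csv"),
    temperature = file.path(dir, "temperature.csv"),
    sites = file.path(dir, "sites.csv"),
    truth_intensive = file.path(dir, "truth_intensive.csv"),
    truth_broad = file.path(dir, "truth_broad.csv")
  )
  utils::write.csv(sim$records_intensive, paths["status_intensive"],
                   row.names = FALSE)
  utils::write.csv(sim$records_broad, paths["status_broad"],
                   row.names = FALSE)
  utils::write.csv(temps, paths["temperature"], row.names = FALSE)
  utils::write.csv(sim$sites, paths["sites"], row.names = FALSE)
  utils::write.csv(sim$truth_intensive, paths["truth_intensive"],
                   row.names = FALSE)
  utils::write.csv(sim$truth_broad, paths["truth_broad"],
                   row.names = FALSE)
  invisible(paths)
}
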