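# Polynomial rolling hash of the serialised configuration, used to stamp
# artifacts so reruns can be matched to their exact settings.
config_hash <- function(config) {
  s <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                        force = TRUE)
  h <- 17
  for (b in utf8ToInt(as.character(s))) {
    h <- (h * 31 + b) %% 2147483647
  }
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' Assembles and validates the configuration of a full cross-scale run:
#' the synthetic study (or input file paths), the cleaning filters, the
#' models to fit, the optimiser and bootstrap settings, and the master
#' seed. Unknown keys are rejected rather than ignored.
#'
#' @param config A named list, or path to a YAML/JSON file containing
#'   one. Recognised keys: `seed`; `synthetic` (list of
#'   [synthetic_config()] arguments) or `inputs` (list with
#'   `status_intensive`, `status_broad`, `temperature`, `sites` CSV
#'   paths); `models` (character vector of model names);
#'   `max_gap_days` (30 or 15); `budburst_cutoff`; `flowers_cutoff`;
#'   `min_n`; `min_n_rule`; `holdout_fraction`; `bootstrap_reps`;
#'   `de` (list of [de_settings()] arguments); `prediction_method`
#'   (`"bootstrap_mean"` or `"point"`); `m1_forcing_floor`;
#'   `output_dir`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    seed = 1L, synthetic = list(), inputs = NULL,
    models = c("naive", "linear", "gdd", "fixed_gdd"),
    max_gap_days = 30, budburst_cutoff = 172, flowers_cutoff = 213,
    min_n = 30, min_n_rule = "gte", holdout_fraction = 0.20,
    bootstrap_reps = 250, de = list(),
    prediction_method = "bootstrap_mean", m1_forcing_floor = 0,
    output_dir = NULL
  )
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg <- utils::modifyList(defaults, config, keep.null = TRUE)
  cfg$models <- vapply(cfg$models, function(m) model_spec(m)$name, "")
  cfg$de <- do.call(de_settings, cfg$de)
  if (is.null(cfg$inputs)) {
    syn_args <- cfg$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- cfg$seed
    cfg$synthetic <- do.call(synthetic_config, syn_args)
  }
  stopifnot(cfg$max_gap_days >= 1, cfg$holdout_fraction > 0,
            cfg$holdout_fraction < 1, cfg$bootstrap_reps >= 1)
  cfg$prediction_method <- match.arg(cfg$prediction_method,
                                     c("bootstrap_mean", "point"))
  structure(cfg, class = "pipeline_config")
}

# Fit one collection: a fitted_model per (group key, model name).
fit_collection <- function(groups, models, env, seed, reps, settings,
                           control) {
  out <- list()
  for (g in names(groups)) {
    ev <- groups[[g]]
    out[[g]] <- list()
    for (m in models) {
      out[[g]][[m]] <- bootstrap_fit(
        m, ev, env, seed = substream_seed(seed, "fit", g, m),
        reps = reps, settings = settings, control = control)
    }
  }
  out
}

#' Run the full cross-scale comparison pipeline
#'
#' Executes the study end to end: simulate (or load) the two observation
#' campaigns, clean the status records into events, hold out a test
#' fraction per species-phenophase group, fit every configured model to
#' the intensive and the broad-scale training events separately (with
#' bootstrap), and compare the two collections by (1) bootstrap-mean
#' parameters, (2) paired holdout predictions per evaluation site class,
#' and (3) paired holdout RMSE differences with t tests, evaluated
#' separately on intensive-site and broad-site holdouts.
#'
#' The intensive collection is fitted per species x phenophase x
#' intensive site (a species monitored at two intensive sites contributes
#' two separate comparisons); the broad collection is fitted per species
#' x phenophase across all broad-scale sites and paired with every
#' intensive fit of that species.
#'
#' @param config A [pipeline_config()] (or list/path coercible to one).
#' @return A list of class `pipeline_result`: `events_intensive`,
#'   `events_broad`, `split_intensive`, `split_broad`, `collections`,
#'   `parameter_comparison`, `prediction_comparison`,
#'   `rmse_local` / `rmse_broadscale` (difference tests on intensive and
#'   broad holdouts), `config`, `config_hash`, `seed`. When
#'   `config$output_dir` is set, the comparison tables are also written
#'   as CSV plus a JSON summary.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (!inherits(config, "pipeline_config")) {
    config <- pipeline_config(config)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  # --- data ---------------------------------------------------------
  if (is.null(config$inputs)) {
    sim <- stage("simulate", simulate_dataset(config$synthetic))
    records_int <- sim$records_intensive
    records_brd <- sim$records_broad
    env <- sim$env
    sites <- sim$sites
  } else {
    sim <- NULL
    records_int <- stage("load", check_status_records(
      utils::read.csv(config$inputs$status_intensive,
                      stringsAsFactors = FALSE)))
    records_brd <- stage("load", check_status_records(
      utils::read.csv(config$inputs$status_broad,
                      stringsAsFactors = FALSE)))
    env <- stage("load", environment_data(read_temperature_csv(
      config$inputs$temperature, config$inputs$sites)))
    sites <- utils::read.csv(config$inputs$sites,
                             stringsAsFactors = FALSE)
    if (!"style" %in% names(sites)) {
      stop("site CSV needs a `style` column (intensive/broad)",
           call. = FALSE)
    }
  }
  site_classes <- stats::setNames(sites$style, sites$site_id)

  # --- prepare ------------------------------------------------------
  ev_int <- stage("prepare", prepare_events(
    records_int, max_gap_days = config$max_gap_days,
    budburst_cutoff = config$budburst_cutoff,
    flowers_cutoff = config$flowers_cutoff,
    min_n = config$min_n, min_n_rule = config$min_n_rule))
  ev_brd <- stage("prepare", prepare_events(
    records_brd, max_gap_days = config$max_gap_days,
    budburst_cutoff = config$budburst_cutoff,
    flowers_cutoff = config$flowers_cutoff,
    min_n = config$min_n, min_n_rule = config$min_n_rule))

  # --- split --------------------------------------------------------
  split_int <- stage("split", holdout_split(
    ev_int, config$holdout_fraction,
    seed = substream_seed(config$seed, "split", "intensive")))
  split_brd <- stage("split", holdout_split(
    ev_brd, config$holdout_fraction,
    seed = substream_seed(config$seed, "split", "broad")))

  # --- group keys ---------------------------------------------------
  # intensive: species | phenophase | site; broad: species | phenophase
  # (the broad fit of a species is paired with each of its intensive
  # fits, so both collections share the intensive keys)
  int_key <- function(ev) paste(ev$species, ev$phenophase_class,
                                ev$site_id, sep = "|")
  brd_key <- function(ev) paste(ev$species, ev$phenophase_class,
                                sep = "|")
  groups_int <- split(split_int$train, int_key(split_int$train))
  groups_brd <- split(split_brd$train, brd_key(split_brd$train))

  control <- list(m1_forcing_floor = config$m1_forcing_floor)
  coll_int <- stage("fit", fit_collection(
    groups_int, config$models, env,
    seed = substream_seed(config$seed, "intensive"),
    reps = config$bootstrap_reps, settings = config$de,
    control = control))
  coll_brd_base <- stage("fit", fit_collection(
    groups_brd, config$models, env,
    seed = substream_seed(config$seed, "broad"),
    reps = config$bootstrap_reps, settings = config$de,
    control = control))
  # re-key the broad fits onto the intensive group keys
  coll_brd <- stats::setNames(lapply(names(coll_int), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    coll_brd_base[[paste(parts[1], parts[2], sep = "|")]]
  }), names(coll_int))
  keep <- !vapply(coll_brd, is.null, TRUE)
  coll_int <- coll_int[keep]
  coll_brd <- coll_brd[keep]
  if (length(coll_int) == 0L) {
    stop("pipeline stage 'fit' failed: no species-phenophase group is ",
         "present in both campaigns", call. = FALSE)
  }

  # --- holdout tables ----------------------------------------------
  ho_int <- split_int$test
  ho_int$group <- int_key(ho_int)
  ho_int <- ho_int[ho_int$group %in% names(coll_int), , drop = FALSE]
  # each broad holdout event is predicted by every intensive fit of its
  # species-phenophase, one comparison per intensive site
  ho_brd <- do.call(rbind, lapply(names(coll_int), function(k) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    sub <- split_brd$test[brd_key(split_brd$test) ==
                            paste(parts[1], parts[2], sep = "|"), ,
                          drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    sub$group <- k
    sub
  }))

  # --- compare ------------------------------------------------------
  par_cmp <- stage("compare", compare_parameters(coll_int, coll_brd))
  ho_all <- rbind(ho_int, ho_brd)
  pred_cmp <- stage("compare", compare_predictions(
    coll_int, coll_brd, ho_all, env, site_classes,
    method = config$prediction_method, control = control))
  rmse_local <- stage("compare", rmse_difference_tests(
    coll_int, coll_brd, ho_int, env,
    method = config$prediction_method, control = control))
  rmse_broad <- stage("compare", rmse_difference_tests(
    coll_int, coll_brd, ho_brd, env,
    method = config$prediction_method, control = control))

  result <- structure(
    list(events_intensive = ev_int, events_broad = ev_brd,
         split_intensive = split_int, split_broad = split_brd,
         collections = list(intensive = coll_int, broad = coll_brd),
         parameter_comparison = par_cmp,
         prediction_comparison = pred_cmp,
         rmse_local = rmse_local, rmse_broadscale = rmse_broad,
         sim = sim, config = config, config_hash = config_hash(config),
         seed = config$seed),
    class = "pipeline_result"
  )
  if (!is.null(config$output_dir)) {
    write_pipeline_result(result, config$output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> seed %d, config %s\n", x$seed,
              x$config_hash))
  cat(sprintf("  events: %d intensive, %d broad; %d comparison group(s)\n",
              nrow(x$events_intensive), nrow(x$events_broad),
              length(x$collections$intensive)))
  cat(sprintf("  models: %s\n", paste(x$config$models, collapse = ", ")))
  cat(sprintf(
    "  mean holdout RMSE diff (intensive - broad model): %+.2f d %s, %+.2f d %s\n",
    mean(x$rmse_local$diffs$rmse_diff), "on intensive holdouts",
    mean(x$rmse_broadscale$diffs$rmse_diff), "on broad holdouts"))
  invisible(x)
}

#' Write pipeline comparison artifacts
#'
#' Writes the parameter comparison, the prediction pairs and R2 tables,
#' and the RMSE-difference tables as CSV, plus a JSON summary stamped
#' with the seed and configuration hash.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory.
#' @return Invisibly, the vector of file paths.
#' @export
write_pipeline_result <- function(result, dir) {
  stopifnot(inherits(result, "pipeline_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    parameters = file.path(dir, "parameter_comparison.csv"),
    prediction_pairs = file.path(dir, "prediction_pairs.csv"),
    prediction_r2 = file.path(dir, "prediction_r2.csv"),
    rmse_local = file.path(dir, "rmse_diff_intensive_holdouts.csv"),
    rmse_broadscale = file.path(dir, "rmse_diff_broad_holdouts.csv"),
    summary = file.path(dir, "summary.json")
  )
  utils::write.csv(result$parameter_comparison, paths["parameters"],
                   row.names = FALSE)
  utils::write.csv(result$prediction_comparison$pairs,
                   paths["prediction_pairs"], row.names = FALSE)
  utils::write.csv(result$prediction_comparison$r2,
                   paths["prediction_r2"], row.names = FALSE)
  utils::write.csv(result$rmse_local$diffs, paths["rmse_local"],
                   row.names = FALSE)
  utils::write.csv(result$rmse_broadscale$diffs, paths["rmse_broadscale"],
                   row.names = FALSE)
  summary <- list(
    seed = result$seed,
    config_hash = result$config_hash,
    models = result$config$models,
    n_events = list(intensive = nrow(result$events_intensive),
                    broad = nrow(result$events_broad)),
    rmse_tests = list(
      intensive_holdouts = result$rmse_local$tests,
      broad_holdouts = result$rmse_broadscale$tests
    )
  )
  jsonlite::write_json(summary, paths["summary"], auto_unbox = TRUE,
                       digits = NA, dataframe = "rows")
  invisible(paths)
}
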