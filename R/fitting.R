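NO_EVENT_PENALTY_DAYS <- 1000

#' Differential-evolution settings
#'
#' Optimiser hyperparameters for [fit_model()]. The defaults use a
#' population of 30 candidate vectors, mutation scale dithered per vector
#' in \[0.5, 1.0\], crossover probability 0.7, and at most 500 generations
#' with a relative-improvement stop of `tol` over `steptol` generations.
#'
#' @param pop_size Population size (number of candidate vectors).
#' @param mutation Length-2 numeric: dither range for the mutation scale F.
#' @param recombination Crossover probability CR in \[0, 1\].
#' @param maxiter Maximum generations.
#' @param tol Relative convergence tolerance on the objective (days).
#' @param steptol Generations without sufficient improvement before stop.
#' @return A list of class `de_settings`.
#' @export
de_settings <- function(pop_size = 30, mutation = c(0.5, 1.0),
                        recombination = 0.7, maxiter = 500, tol = 1e-3,
                        steptol = 50) {
  stopifnot(pop_size >= 4, length(mutation) == 2, mutation[1] <= mutation[2],
            recombination >= 0, recombination <= 1, maxiter >= 1)
  structure(
    list(pop_size = pop_size, mutation = as.numeric(mutation),
         recombination = recombination, maxiter = as.integer(maxiter),
         tol = tol, steptol = as.integer(steptol)),
    class = "de_settings"
  )
}

#' Hold out a random test fraction per species-phenophase group
#'
#' Splits an event table into training and test sets, sampling the test
#' fraction uniformly without replacement within each species x phenophase
#' group. The test count is `round(fraction * n)` (banker's rounding) with
#' a minimum of one event.
#'
#' @param events Event data frame.
#' @param fraction Test fraction (default 0.20).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A list of class `split_dataset` with `train`, `test`,
#'   `fraction_test` and `seed`.
#' @export
holdout_split <- function(events, fraction = 0.20, seed) {
  stopifnot(fraction > 0, fraction < 1)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  grp <- paste(events$species, events$phenophase_class, sep = "\r")
  sizes <- table(grp)
  if (any(sizes < 5L)) {
    small <- names(sizes)[sizes < 5L]
    stop("group(s) with fewer than 5 events cannot be split: ",
         paste(gsub("\r", " / ", small), collapse = "; "), call. = FALSE)
  }
  set.seed(as.integer(seed))
  test_idx <- integer(0)
  for (g in sort(unique(grp))) {
    idx <- which(grp == g)
    n_test <- max(1L, as.integer(round(fraction * length(idx))))
    test_idx <- c(test_idx, sort(sample(idx, n_test)))
  }
  train <- events[-test_idx, , drop = FALSE]
  test <- events[test_idx, , drop = FALSE]
  rownames(train) <- rownames(test) <- NULL
  structure(
    list(train = train, test = test, fraction_test = fraction,
         seed = as.integer(seed)),
    class = "split_dataset"
  )
}

#' Root-mean-square error of model predictions on an event table
#'
#' The fitting objective: RMSE in days between predicted and observed
#' event DOY. A no-event prediction (the model never accumulates enough
#' forcing within the series range) contributes a fixed residual of 1000
#' days, which keeps the objective finite while pushing the optimiser away
#' from degenerate parameters.
#'
#' @param params Parameter vector for `model`.
#' @param model A [model_spec()] or model name.
#' @param events Event data frame with observed `doy`.
#' @param env A `pheno_env` from [environment_data()].
#' @param control Passed to [predict_event()].
#' @return RMSE in days.
#' @export
rmse_objective <- function(params, model, events, env, control = list()) {
  if (nrow(events) == 0L) stop("empty training set", call. = FALSE)
  pred <- predict_events(model, params, events, env, control)
  res <- pred - events$doy
  res[is.na(pred)] <- NO_EVENT_PENALTY_DAYS
  sqrt(mean(res^2))
}

#' Fit a phenology model by differential evolution
#'
#' Global minimisation of the training RMSE over the model's parameter
#' box (the registry bounds, overridable). Differential evolution searches
#' with a population of candidate parameter vectors; runs are reproducible
#' given `seed`. A candidate whose objective is non-finite is rejected by
#' assigning it a very large value, never by aborting the search.
#'
#' @param model A [model_spec()] or model name.
#' @param events Training event data frame.
#' @param env A `pheno_env` from [environment_data()].
#' @param seed Integer seed.
#' @param settings A [de_settings()] list.
#' @param bounds Optional bounds matrix (rows `lower`, `upper`) replacing
#'   the registry defaults.
#' @param control Passed to [predict_event()].
#' @return A list of class `de_fit` with `par` (named optimum), `value`
#'   (training RMSE, days), `model`, `seed`, `settings`, `bounds`.
#' @export
fit_model <- function(model, events, env, seed, settings = de_settings(),
                      bounds = NULL, control = list()) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  if (nrow(events) == 0L) stop("empty training set", call. = FALSE)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  if (is.null(bounds)) bounds <- spec$bounds
  if (!all(is.finite(bounds))) stop("bounds must be finite", call. = FALSE)

  obj <- function(p) {
    v <- tryCatch(
      rmse_objective(p, spec, events, env, control),
      error = function(e) Inf
    )
    if (!is.finite(v)) 1e9 else v
  }

  set.seed(as.integer(seed))
  de_ctl <- DEoptim::DEoptim.control(
    NP = settings$pop_size,
    F = settings$mutation[1],
    CR = settings$recombination,
    itermax = settings$maxiter,
    strategy = 4L,  # rand/1/bin with per-vector dither of F up to 1
    reltol = settings$tol,
    steptol = settings$steptol,
    trace = FALSE
  )
  # the population default (30) is deliberate for all models; silence
  # DEoptim's NP >= 10 * n_par advisory
  fit <- withCallingHandlers(
    DEoptim::DEoptim(obj, lower = bounds["lower", ],
                     upper = bounds["upper", ], control = de_ctl),
    warning = function(w) {
      if (grepl("ten times", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  par <- as.numeric(fit$optim$bestmem)
  names(par) <- spec$parameter_names
  structure(
    list(par = par, value = fit$optim$bestval, model = spec$name,
         n_train = nrow(events), seed = as.integer(seed),
         settings = settings, bounds = bounds),
    class = "de_fit"
  )
}

#' Fit with bootstrap parameter distributions
#'
#' Refits the model on `reps` resamples of the training events (n-out-of-n
#' with replacement); each resample has its own seed derived from the
#' master seed, so the whole ensemble is reproducible. A resample whose
#' fit fails is retried once with a fresh resample, then recorded as a
#' missing row and excluded from downstream means.
#'
#' @inheritParams fit_model
#' @param reps Number of bootstrap refits (250 by default).
#' @return A list of class `fitted_model`: `model_name`, `point_params`,
#'   `bootstrap_params` (matrix `reps` x n_par, `NA` rows for failures),
#'   `rmse_train` (days), `n_train`, `seed`, `settings`, `bounds` and
#'   `n_failed`.
#' @export
bootstrap_fit <- function(model, events, env, seed, reps = 250,
                          settings = de_settings(), bounds = NULL,
                          control = list()) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  if (missing(seed)) stop("`seed` is required", call. = FALSE)
  point <- fit_model(spec, events, env, seed = seed, settings = settings,
                     bounds = bounds, control = control)

  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max, reps)
  retry_seeds <- sample.int(.Machine$integer.max, reps)
  # one optimiser seed shared across refits: a refit is then a pure
  # function of its resampled dataset, so identical resamples give
  # bit-identical parameter vectors
  de_seed <- sample.int(.Machine$integer.max, 1L)

  npar <- length(spec$parameter_names)
  boot <- matrix(NA_real_, nrow = reps, ncol = npar,
                 dimnames = list(NULL, spec$parameter_names))
  n <- nrow(events)
  n_failed <- 0L
  for (r in seq_len(reps)) {
    one <- function(s) {
      set.seed(s)
      idx <- sample.int(n, n, replace = TRUE)
      fit_model(spec, events[idx, , drop = FALSE], env, seed = de_seed,
                settings = settings, bounds = point$bounds,
                control = control)$par
    }
    par <- tryCatch(one(rep_seeds[r]), error = function(e) NULL)
    if (is.null(par)) {
      par <- tryCatch(one(retry_seeds[r]), error = function(e) NULL)
    }
    if (is.null(par)) {
      n_failed <- n_failed + 1L
    } else {
      boot[r, ] <- par
    }
  }
  if (n_failed > 0L) {
    message(sprintf("bootstrap_fit(%s): %d of %d refits failed; %s",
                    spec$name, n_failed, reps,
                    "missing rows excluded from bootstrap means"))
  }
  structure(
    list(model_name = spec$name, point_params = point$par,
         bootstrap_params = boot, rmse_train = point$value,
         n_train = nrow(events), seed = as.integer(seed),
         settings = settings, bounds = point$bounds, n_failed = n_failed),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s: n_train = %d, training RMSE = %.2f d\n",
              x$model_name, x$n_train, x$rmse_train))
  cat("  point:    ",
      paste(sprintf("%s = %.3g", names(x$point_params), x$point_params),
            collapse = ", "), "\n")
  bm <- bootstrap_means(x)
  cat(sprintf("  bootstrap (%d reps): ",
              nrow(x$bootstrap_params) - x$n_failed),
      paste(sprintf("%s = %.3g", names(bm), bm), collapse = ", "), "\n")
  invisible(x)
}

#' Bootstrap-mean parameter values of a fitted model
#'
#' @param fitted A `fitted_model` from [bootstrap_fit()].
#' @return Named numeric vector: mean of each parameter over the usable
#'   bootstrap refits.
#' @export
bootstrap_means <- function(fitted) {
  stopifnot(inherits(fitted, "fitted_model"))
  colMeans(fitted$bootstrap_params, na.rm = TRUE)
}

#' Predict an event day as the mean over bootstrap refits
#'
#' Evaluates every usable bootstrap parameter vector on the series and
#' averages the predicted days. Bootstrap members predicting no event are
#' excluded from the mean when at least one member predicts a day; if all
#' members predict no event the result is `NA_real_`.
#'
#' @param fitted A `fitted_model`.
#' @param series A [temperature_series()].
#' @param covariates Optional `covariate_bundle`.
#' @param control Passed to [predict_event()].
#' @return Mean predicted DOY, or `NA_real_`.
#' @export
predict_mean_of_bootstraps <- function(fitted, series, covariates = NULL,
                                       control = list()) {
  stopifnot(inherits(fitted, "fitted_model"))
  boot <- fitted$bootstrap_params[
    !apply(is.na(fitted$bootstrap_params), 1L, any), , drop = FALSE]
  if (nrow(boot) == 0L) {
    stop("no usable bootstrap parameter vectors", call. = FALSE)
  }
  spec <- model_spec(fitted$model_name)
  preds <- apply(boot, 1L, function(p) {
    predict_event(spec, p, series, covariates, control)
  })
  if (all(is.na(preds))) return(NA_real_)
  mean(preds, na.rm = TRUE)
}

#' Predict an event table from a fitted model
#'
#' @param fitted A `fitted_model`.
#' @param events Event data frame with `site_id` and `year`.
#' @param env A `pheno_env`.
#' @param method `"bootstrap_mean"` (default: mean of per-bootstrap
#'   predictions, as used for reported predictions) or `"point"` (the
#'   single best-fit vector).
#' @param control Passed to [predict_event()].
#' @return Numeric vector of predicted DOY (NA for no-event), one per row.
#' @export
predict_fitted <- function(fitted, events, env,
                           method = c("bootstrap_mean", "point"),
                           control = list()) {
  stopifnot(inherits(fitted, "fitted_model"))
  method <- match.arg(method)
  if (method == "point") {
    return(predict_events(fitted$model_name, fitted$point_params, events,
                          env, control))
  }
  keys <- series_key(events$site_id, events$year)
  uk <- unique(keys)
  per_key <- vapply(uk, function(k) {
    e <- env[[k]]
    if (is.null(e)) stop("no temperature series for ", k, call. = FALSE)
    predict_mean_of_bootstraps(fitted, e$series, e$covariates, control)
  }, numeric(1))
  unname(per_key[match(keys, uk)])
}

#' Serialise a fitted model
#'
#' Writes the fit metadata (model, point parameters, bounds, seed,
#' optimiser settings) as JSON and the bootstrap parameter matrix as CSV.
#'
#' @param fitted A `fitted_model`.
#' @param json_file,csv_file Output paths (either may be `NULL` to skip).
#' @return Invisibly, the JSON string.
#' @export
write_fitted_model <- function(fitted, json_file = NULL, csv_file = NULL) {
  stopifnot(inherits(fitted, "fitted_model"))
  meta <- list(
    model = fitted$model_name,
    point_params = as.list(fitted$point_params),
    bounds = list(lower = as.list(fitted$bounds["lower", ]),
                  upper = as.list(fitted$bounds["upper", ])),
    rmse_train = fitted$rmse_train,
    n_train = fitted$n_train,
    seed = fitted$seed,
    settings = unclass(fitted$settings),
    bootstrap_reps = nrow(fitted$bootstrap_params),
    bootstrap_failed = fitted$n_failed
  )
  js <- jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(json_file)) writeLines(js, json_file)
  if (!is.null(csv_file)) {
    utils::write.csv(as.data.frame(fitted$bootstrap_params), csv_file,
                     row.names = FALSE)
  }
  invisible(js)
}
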