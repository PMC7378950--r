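#' Phenology model registry
#'
#' Returns the specification of one of the eight supported spring phenology
#' models: its ordered parameter names, default fitting bounds, and the
#' covariates it requires. Six of the models share a thermal-forcing
#' skeleton: daily mean temperature is transformed into forcing units,
#' accumulated from a start day, and the event is the first day on which
#' the accumulation reaches a required total.
#'
#' * `naive` — constant mean day of year (1 parameter).
#' * `linear` — regression of event DOY on mean spring temperature
#'   (intercept `beta1`, slope `beta2`).
#' * `gdd` — growing degree days: forcing `max(Ti - Tbase, 0)` accumulated
#'   from fitted start day `t1` until total `Fstar`.
#' * `fixed_gdd` — GDD with `t1 = 1` (1 January) and `Tbase = 0` fixed;
#'   only `Fstar` is fitted.
#' * `alternating` — forcing `max(Ti - 5, 0)` from DOY 1 against a
#'   requirement `a + b * exp(c * NCD(t))` that declines with the running
#'   number of chill days NCD.
#' * `uniforc` — sigmoid forcing `1 / (1 + exp(b * (Ti - c)))` from fitted
#'   `t1` until total `Fstar` (`b` constrained negative so warmth forces).
#' * `m1` — GDD whose required total is scaled by day length:
#'   `(L(t) / 24)^k * Fstar`.
#' * `msb` — Alternating plus a mean-spring-temperature correction
#'   `d * Tmean` on the requirement.
#'
#' @param name Model name, one of `"naive"`, `"linear"`, `"gdd"`,
#'   `"fixed_gdd"`, `"alternating"`, `"uniforc"`, `"m1"`, `"msb"`.
#' @return A list of class `model_spec` with elements `name`,
#'   `parameter_names`, `bounds` (matrix with rows `lower`/`upper`) and
#'   `requires`.
#' @export
#' @examples
#' model_spec("gdd")$parameter_names
model_spec <- function(name) {
  name <- match.arg(name, pheno_model_names())
  spec <- .model_registry[[name]]
  structure(
    list(
      name = name,
      parameter_names = colnames(spec$bounds),
      bounds = spec$bounds,
      requires = spec$requires
    ),
    class = "model_spec"
  )
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<model_spec> %s (%d parameter%s)\n", x$name,
              length(x$parameter_names),
              if (length(x$parameter_names) == 1L) "" else "s"))
  b <- x$bounds
  for (p in colnames(b)) {
    cat(sprintf("  %-9s in [%g, %g]\n", p, b["lower", p], b["upper", p]))
  }
  invisible(x)
}

#' Names of the supported phenology models
#' @return Character vector of model names.
#' @export
pheno_model_names <- function() names(.model_registry)

.model_bounds <- function(...) {
  v <- list(...)
  m <- vapply(v, as.numeric, numeric(2))
  rownames(m) <- c("lower", "upper")
  m
}

.model_registry <- list(
  naive = list(
    bounds = .model_bounds(mean_doy = c(1, 250)),
    requires = "none"
  ),
  linear = list(
    bounds = .model_bounds(beta1 = c(0, 250), beta2 = c(-20, 20)),
    requires = "tmean_spring"
  ),
  gdd = list(
    bounds = .model_bounds(t1 = c(-30, 120), t_base = c(-10, 15),
                           f_star = c(0, 1000)),
    requires = "temperature"
  ),
  fixed_gdd = list(
    bounds = .model_bounds(f_star = c(0, 1000)),
    requires = "temperature"
  ),
  alternating = list(
    bounds = .model_bounds(a = c(0, 1000), b = c(0, 2000), c = c(-2, 0)),
    requires = c("temperature", "ncd")
  ),
  uniforc = list(
    bounds = .model_bounds(t1 = c(-30, 120), b = c(-20, -0.1),
                           c = c(-10, 25), f_star = c(0, 200)),
    requires = "temperature"
  ),
  m1 = list(
    bounds = .model_bounds(t1 = c(-30, 120), t_base = c(-10, 15),
                           f_star = c(0, 1000), k = c(0, 50)),
    requires = c("temperature", "photoperiod")
  ),
  msb = list(
    bounds = .model_bounds(a = c(0, 1000), b = c(0, 2000), c = c(-2, 0),
                           d = c(-200, 200)),
    requires = c("temperature", "ncd", "tmean_spring")
  )
)

param_vector <- function(params, spec) {
  pn <- spec$parameter_names
  if (is.null(names(params))) {
    if (length(params) != length(pn)) {
      stop(sprintf("model '%s' needs %d parameters (%s), got %d",
                   spec$name, length(pn), paste(pn, collapse = ", "),
                   length(params)), call. = FALSE)
    }
    names(params) <- pn
  }
  missing <- setdiff(pn, names(params))
  if (length(missing)) {
    stop(sprintf("model '%s' missing parameter(s): %s", spec$name,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  as.numeric(params[pn])
}

#' Accumulate daily forcing units along a temperature series
#'
#' Running sum of a daily forcing transformation from a start day to the
#' end of the series range. This is the shared accumulation step of the
#' thermal-forcing models.
#'
#' @param series A [temperature_series()].
#' @param forcing_fn Function mapping a vector of daily mean temperatures
#'   to daily forcing units.
#' @param start_doy Integer DOY at which accumulation begins; must lie
#'   within the series range.
#' @return Numeric vector of cumulative forcing, named by DOY, from
#'   `start_doy` to the end of the series. Days with missing temperature
#'   propagate `NA`.
#' @export
accumulate_forcing <- function(series, forcing_fn, start_doy) {
  stopifnot(inherits(series, "temperature_series"))
  start_doy <- as.integer(round(start_doy))
  if (start_doy < series$doy_start || start_doy > series$doy_end) {
    stop(sprintf("start DOY %d outside series range %d..%d", start_doy,
                 series$doy_start, series$doy_end), call. = FALSE)
  }
  temps <- series_window(series, start_doy, series$doy_end,
                         allow_gaps = TRUE)
  acc <- cumsum(forcing_fn(temps))
  names(acc) <- start_doy:series$doy_end
  acc
}

# First DOY at which cumulative forcing meets a (possibly day-varying)
# requirement. `threshold` is a scalar or a vector aligned with `acc`.
# Returns NA_real_ (the no-event marker) when the requirement is never met.
first_threshold_crossing <- function(acc, threshold) {
  hit <- which(!is.na(acc) & !is.na(threshold) & acc >= threshold)
  if (length(hit) == 0L) return(NA_real_)
  as.numeric(names(acc)[hit[1L]])
}

#' Predict an event day with one phenology model
#'
#' Evaluates one of the eight model predictors for a given parameter
#' vector, temperature series and covariates. An event that never occurs
#' within the series range is reported as `NA_real_`, the package's
#' no-event marker (the fitting objective maps it to a fixed large
#' residual; it is never silently treated as a day).
#'
#' @param model A [model_spec()] or model name.
#' @param params Named (or correctly ordered) numeric parameter vector.
#' @param series A [temperature_series()]; ignored by `naive`.
#' @param covariates A `covariate_bundle` from [compute_covariates()];
#'   required by `linear`, `alternating`, `m1` and `msb`. Computed from
#'   `series` on the fly when omitted.
#' @param control List of prediction options; `m1_forcing_floor` (default
#'   0) sets the lower clamp of the M1 forcing function `max(Ti - Tbase,
#'   floor)`.
#' @return Predicted event DOY as a single numeric value, or `NA_real_`
#'   if the model predicts no event within the series range.
#' @export
#' @examples
#' ts <- temperature_series("A", 2015, -90:250, rep(10, 341), latitude = 42)
#' predict_event("gdd", c(t1 = 1, t_base = 0, f_star = 100), ts)
predict_event <- function(model, params, series = NULL, covariates = NULL,
                          control = list()) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  p <- param_vector(params, spec)
  names(p) <- spec$parameter_names
  if (spec$name != "naive" && is.null(series)) {
    stop("model '", spec$name, "' requires a temperature series",
         call. = FALSE)
  }
  needs_cov <- any(spec$requires %in% c("tmean_spring", "ncd", "photoperiod"))
  if (needs_cov && is.null(covariates)) {
    covariates <- compute_covariates(series)
  }
  switch(spec$name,
    naive = predict_naive(p),
    linear = predict_linear(p, covariates$tmean_spring),
    gdd = predict_gdd(series, p),
    fixed_gdd = predict_fixed_gdd(series, p),
    alternating = predict_alternating(series, p, covariates),
    uniforc = predict_uniforc(series, p),
    m1 = predict_m1(series, p, covariates, control),
    msb = predict_msb(series, p, covariates)
  )
}

#' Naive model: historical mean day of year
#'
#' Predicts the mean DOY of prior observations regardless of climate.
#' @param params Named vector with `mean_doy`.
#' @return Predicted DOY.
#' @export
predict_naive <- function(params) {
  as.numeric(params[["mean_doy"]])
}

#' Linear model: event day regressed on spring temperature
#'
#' `DOY = beta1 + beta2 * Tmean`, with Tmean the 1 January--31 March mean
#' daily temperature.
#' @param params Named vector with `beta1`, `beta2`.
#' @param tmean_spring Mean spring temperature in degrees C.
#' @return Predicted DOY.
#' @export
predict_linear <- function(params, tmean_spring) {
  if (!is.finite(tmean_spring)) {
    stop("`tmean_spring` must be finite", call. = FALSE)
  }
  as.numeric(params[["beta1"]] + params[["beta2"]] * tmean_spring)
}

#' Growing-degree-day model
#'
#' Forcing `max(Ti - Tbase, 0)` accumulates from start day `t1`; the event
#' is the first DOY with accumulation `>= Fstar`. `t1` is rounded to the
#' nearest integer day (optimisers propose continuous values).
#'
#' @param series A [temperature_series()].
#' @param params Named vector with `t1`, `t_base`, `f_star` (`f_star >= 0`).
#' @return Predicted DOY or `NA_real_` if the requirement is never met.
#' @export
predict_gdd <- function(series, params) {
  f_star <- params[["f_star"]]
  if (f_star < 0) stop("`f_star` must be >= 0", call. = FALSE)
  acc <- accumulate_forcing(
    series,
    function(ti) pmax(ti - params[["t_base"]], 0),
    round(params[["t1"]])
  )
  first_threshold_crossing(acc, f_star)
}

#' Fixed growing-degree-day model
#'
#' GDD with the start day fixed at 1 January and the base temperature at
#' 0 degrees C; only the required total `Fstar` is free.
#'
#' @inheritParams predict_gdd
#' @param params Named vector with `f_star`.
#' @return Predicted DOY or `NA_real_`.
#' @export
predict_fixed_gdd <- function(series, params) {
  predict_gdd(series, c(t1 = 1, t_base = 0, f_star = params[["f_star"]]))
}

#' Alternating model: forcing requirement declines with chill days
#'
#' Forcing `max(Ti - 5, 0)` accumulates from DOY 1; on each day `t` the
#' requirement is `a + b * exp(c * NCD(t))`, where `NCD(t)` is the number
#' of chill days (daily mean below 0 C) in DOY 1..t. The event is the
#' first day whose accumulation meets that day's requirement. A requirement
#' that overflows to infinity simply cannot be met that day.
#'
#' @inheritParams predict_gdd
#' @param params Named vector with `a`, `b`, `c`.
#' @param covariates Optional `covariate_bundle` (its `ncd` curve is used
#'   when present).
#' @return Predicted DOY or `NA_real_`.
#' @export
predict_alternating <- function(series, params, covariates = NULL) {
  acc <- accumulate_forcing(series, function(ti) pmax(ti - 5, 0), 1L)
  ncd <- if (!is.null(covariates)) {
    covariates$ncd[seq_along(acc)]
  } else {
    chill_day_curve(series, series$doy_end)
  }
  thr <- params[["a"]] + params[["b"]] * exp(params[["c"]] * ncd)
  first_threshold_crossing(acc, thr)
}

#' Uniforc model: sigmoid forcing accumulation
#'
#' Daily forcing `1 / (1 + exp(b * (Ti - c)))` accumulates from `t1` until
#' total `Fstar`. With `b < 0` the sigmoid rises with temperature, 0.5 at
#' `Ti = c`, saturating at one forcing unit per warm day.
#'
#' @inheritParams predict_gdd
#' @param params Named vector with `t1`, `b`, `c`, `f_star`.
#' @return Predicted DOY or `NA_real_`.
#' @export
predict_uniforc <- function(series, params) {
  f_star <- params[["f_star"]]
  if (f_star < 0) stop("`f_star` must be >= 0", call. = FALSE)
  acc <- accumulate_forcing(
    series,
    function(ti) 1 / (1 + exp(params[["b"]] * (ti - params[["c"]]))),
    round(params[["t1"]])
  )
  first_threshold_crossing(acc, f_star)
}

#' M1 model: GDD with a day-length scaled requirement
#'
#' As [predict_gdd()] but the daily requirement is
#' `(L(t) / 24)^k * Fstar` with `L(t)` the photoperiod in hours on day
#' `t`. With `k = 0` the model reduces exactly to GDD. The forcing
#' function is `max(Ti - Tbase, floor)` with `floor = 0` by default;
#' `control$m1_forcing_floor = 5` reproduces a published variant that
#' clamps daily forcing at 5 units.
#'
#' @inheritParams predict_alternating
#' @param params Named vector with `t1`, `t_base`, `f_star`, `k`.
#' @param control List; see `m1_forcing_floor` above.
#' @return Predicted DOY or `NA_real_`.
#' @export
predict_m1 <- function(series, params, covariates = NULL, control = list()) {
  f_star <- params[["f_star"]]
  if (f_star < 0) stop("`f_star` must be >= 0", call. = FALSE)
  floor_val <- control$m1_forcing_floor %||% 0
  acc <- accumulate_forcing(
    series,
    function(ti) pmax(ti - params[["t_base"]], floor_val),
    round(params[["t1"]])
  )
  doys <- as.integer(names(acc))
  photo <- if (!is.null(covariates)) {
    unname(covariates$photoperiod[as.character(doys)])
  } else {
    photoperiod_hours(series$latitude, doys)
  }
  thr <- (photo / 24)^params[["k"]] * f_star
  first_threshold_crossing(acc, thr)
}

#' MSB model: Alternating with a spring-temperature correction
#'
#' As [predict_alternating()] with the daily requirement shifted by
#' `d * Tmean`, where Tmean is the mean spring (1 January--31 March)
#' temperature of the site-year. With `d = 0` it reduces exactly to the
#' Alternating model.
#'
#' @inheritParams predict_alternating
#' @param params Named vector with `a`, `b`, `c`, `d`.
#' @return Predicted DOY or `NA_real_`.
#' @export
predict_msb <- function(series, params, covariates = NULL) {
  if (is.null(covariates)) covariates <- compute_covariates(series)
  acc <- accumulate_forcing(series, function(ti) pmax(ti - 5, 0), 1L)
  ncd <- covariates$ncd[seq_along(acc)]
  thr <- params[["a"]] + params[["b"]] * exp(params[["c"]] * ncd) +
    params[["d"]] * covariates$tmean_spring
  first_threshold_crossing(acc, thr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict event days for a table of observations
#'
#' Vectorised prediction over an event table: each row is matched to its
#' site-year temperature series in `env`, and each unique site-year is
#' evaluated once.
#'
#' @param model A [model_spec()] or model name.
#' @param params Parameter vector (see [predict_event()]).
#' @param events Data frame with at least `site_id` and `year` columns.
#' @param env A `pheno_env` from [environment_data()].
#' @param control Passed to [predict_event()].
#' @return Numeric vector of predicted DOY, `NA_real_` for no-event, one
#'   per row of `events`.
#' @export
predict_events <- function(model, params, events, env, control = list()) {
  spec <- if (inherits(model, "model_spec")) model else model_spec(model)
  keys <- series_key(events$site_id, events$year)
  uk <- unique(keys)
  p <- param_vector(params, spec)
  names(p) <- spec$parameter_names
  per_key <- vapply(uk, function(k) {
    e <- env[[k]]
    if (is.null(e)) {
      stop("no temperature series for ", k, call. = FALSE)
    }
    if (spec$name == "fixed_gdd" && !is.null(e$forcing_cache$gdd0)) {
      return(first_threshold_crossing(e$forcing_cache$gdd0,
                                      p[["f_star"]]))
    }
    predict_event(spec, p, e$series, e$covariates, control)
  }, numeric(1))
  unname(per_key[match(keys, uk)])
}
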