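#' Coefficient of determination about the 1:1 line
#'
#' Agreement of paired values with the identity line:
#' `1 - sum((y - x)^2) / sum((y - mean(y))^2)`. Unlike a regression R2 it
#' can be negative — the pairs then agree with the 1:1 line less well than
#' a constant at the mean of `y` would. Used to compare parameter values
#' and predictions between two model collections.
#'
#' @param x Values from the reference collection (plotted on the x axis).
#' @param y Paired values from the other collection; must not be constant.
#' @return A single numeric value, at most 1, unbounded below.
#' @export
#' @examples
#' identity_line_r2(c(1, 2, 3), c(0, 2, 4)) # 0.75
identity_line_r2 <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) {
    stop("need at least 3 finite pairs", call. = FALSE)
  }
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    stop("`y` has zero variance; identity-line R2 undefined", call. = FALSE)
  }
  1 - sum((y - x)^2) / ss_tot
}

#' Pearson correlation between predictions and observations
#'
#' @param predictions,observations Paired numeric vectors, each with at
#'   least 3 finite values and nonzero variance.
#' @return Pearson r.
#' @export
pearson_correlation <- function(predictions, observations) {
  ok <- is.finite(predictions) & is.finite(observations)
  x <- predictions[ok]; y <- observations[ok]
  if (length(x) < 3L) stop("need at least 3 finite pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("constant input; Pearson correlation undefined", call. = FALSE)
  }
  stats::cor(x, y)
}

# A model collection is a nested named list: collection[[group]][[model]]
# is a fitted_model, where `group` keys a species-phenophase combination
# (for duplicated species at two intensive sites, the site is part of the
# group key so the pairs stay separate).
collection_models <- function(collection) {
  unique(unlist(lapply(collection, names)))
}

#' Compare bootstrap-mean parameters between two model collections
#'
#' For every model fitted in both collections for at least 3 shared
#' groups, pairs the bootstrap-mean parameter values across groups and
#' computes the identity-line R2 per parameter. Collection A anchors the
#' x axis; the R2 denominator uses the variance of collection B's values
#' (`r2_ab`), with the reversed anchoring also reported (`r2_ba`).
#'
#' @param collection_a,collection_b Nested lists `[[group]][[model]]` of
#'   `fitted_model` objects (A = intensive, B = broad-scale, by
#'   convention).
#' @return Data frame with columns `model, parameter, n_groups, r2_ab,
#'   r2_ba`.
#' @export
compare_parameters <- function(collection_a, collection_b) {
  rows <- list()
  for (m in collection_models(collection_a)) {
    groups <- intersect(
      names(collection_a)[vapply(collection_a, function(g)
        m %in% names(g), TRUE)],
      names(collection_b)[vapply(collection_b, function(g)
        m %in% names(g), TRUE)]
    )
    if (length(groups) < 3L) {
      message("compare_parameters: model '", m,
              "' has fewer than 3 shared groups; skipped")
      next
    }
    pa <- do.call(rbind, lapply(groups, function(g)
      bootstrap_means(collection_a[[g]][[m]])))
    pb <- do.call(rbind, lapply(groups, function(g)
      bootstrap_means(collection_b[[g]][[m]])))
    for (p in colnames(pa)) {
      r2_ab <- tryCatch(identity_line_r2(pa[, p], pb[, p]),
                        error = function(e) NA_real_)
      r2_ba <- tryCatch(identity_line_r2(pb[, p], pa[, p]),
                        error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        model = m, parameter = p, n_groups = length(groups),
        r2_ab = r2_ab, r2_ba = r2_ba, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(model = character(), parameter = character(),
                      n_groups = integer(), r2_ab = numeric(),
                      r2_ba = numeric(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Compare held-out predictions between two model collections
#'
#' For every holdout event, computes the predicted day from the matching
#' group's model in each collection and the identity-line R2 of the
#' paired predictions, separately per evaluation site class (intensive
#' vs broad-scale sites). Events where either collection predicts no
#' event are excluded pairwise.
#'
#' @inheritParams compare_parameters
#' @param holdout_events Event data frame (held out from fitting) with a
#'   `group` column naming the collection group of each event.
#' @param env A `pheno_env`.
#' @param site_classes Named character vector mapping `site_id` to
#'   `"intensive"` or `"broad"`.
#' @param method Prediction method, see [predict_fitted()].
#' @param control Passed to predictors.
#' @return List with `pairs` (data frame of per-event paired predictions)
#'   and `r2` (data frame `model, site_class, n, r2_ab, r2_ba,
#'   n_dropped_no_event`).
#' @export
compare_predictions <- function(collection_a, collection_b, holdout_events,
                                env, site_classes,
                                method = c("bootstrap_mean", "point"),
                                control = list()) {
  method <- match.arg(method)
  stopifnot("group" %in% names(holdout_events))
  pair_rows <- list()
  for (m in collection_models(collection_a)) {
    for (g in unique(holdout_events$group)) {
      fa <- collection_a[[g]][[m]]
      fb <- collection_b[[g]][[m]]
      if (is.null(fa) || is.null(fb)) next
      ev <- holdout_events[holdout_events$group == g, , drop = FALSE]
      pa <- predict_fitted(fa, ev, env, method = method, control = control)
      pb <- predict_fitted(fb, ev, env, method = method, control = control)
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        model = m, group = g, site_id = ev$site_id, year = ev$year,
        site_class = unname(site_classes[ev$site_id]),
        observed = ev$doy, pred_a = pa, pred_b = pb,
        stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, pair_rows)
  r2_rows <- list()
  if (!is.null(pairs)) {
    for (m in unique(pairs$model)) {
      for (cl in unique(pairs$site_class)) {
        sub <- pairs[pairs$model == m & pairs$site_class == cl, ]
        ok <- is.finite(sub$pred_a) & is.finite(sub$pred_b)
        n_drop <- sum(!ok)
        if (n_drop > 0L) {
          message(sprintf(
            "compare_predictions: %s/%s: %d no-event pair(s) excluded",
            m, cl, n_drop))
        }
        sub <- sub[ok, ]
        r2_ab <- tryCatch(identity_line_r2(sub$pred_a, sub$pred_b),
                          error = function(e) NA_real_)
        r2_ba <- tryCatch(identity_line_r2(sub$pred_b, sub$pred_a),
                          error = function(e) NA_real_)
        r2_rows[[length(r2_rows) + 1L]] <- data.frame(
          model = m, site_class = cl, n = nrow(sub), r2_ab = r2_ab,
          r2_ba = r2_ba, n_dropped_no_event = n_drop,
          stringsAsFactors = FALSE)
      }
    }
  }
  r2 <- do.call(rbind, r2_rows)
  rownames(r2) <- NULL
  list(pairs = pairs, r2 = r2)
}

#' Paired out-of-sample RMSE differences between two model collections
#'
#' For every model and group, computes the holdout RMSE of each
#' collection's fit on the same holdout events and their difference
#' (collection A minus collection B: negative values mean the A-derived
#' model predicts these holdouts better). Per model, a one-sample
#' two-sided t test asks whether the mean difference departs from zero.
#' Zero variance across groups makes the t statistic undefined; such
#' models are reported as degenerate with the mean difference only.
#'
#' @inheritParams compare_predictions
#' @return List with `diffs` (data frame `model, group, n_events, rmse_a,
#'   rmse_b, rmse_diff`) and `tests` (data frame `model, n_groups,
#'   mean_diff, t_stat, df, p_value, degenerate`).
#' @export
rmse_difference_tests <- function(collection_a, collection_b,
                                  holdout_events, env,
                                  method = c("bootstrap_mean", "point"),
                                  control = list()) {
  method <- match.arg(method)
  stopifnot("group" %in% names(holdout_events))
  diff_rows <- list()
  for (m in collection_models(collection_a)) {
    for (g in unique(holdout_events$group)) {
      fa <- collection_a[[g]][[m]]
      fb <- collection_b[[g]][[m]]
      if (is.null(fa) || is.null(fb)) next
      ev <- holdout_events[holdout_events$group == g, , drop = FALSE]
      pa <- predict_fitted(fa, ev, env, method = method, control = control)
      pb <- predict_fitted(fb, ev, env, method = method, control = control)
      ra <- pa - ev$doy; ra[is.na(pa)] <- NO_EVENT_PENALTY_DAYS
      rb <- pb - ev$doy; rb[is.na(pb)] <- NO_EVENT_PENALTY_DAYS
      rmse_a <- sqrt(mean(ra^2)); rmse_b <- sqrt(mean(rb^2))
      diff_rows[[length(diff_rows) + 1L]] <- data.frame(
        model = m, group = g, n_events = nrow(ev), rmse_a = rmse_a,
        rmse_b = rmse_b, rmse_diff = rmse_a - rmse_b,
        stringsAsFactors = FALSE)
    }
  }
  diffs <- do.call(rbind, diff_rows)
  if (is.null(diffs)) stop("no comparable model/group pairs", call. = FALSE)
  rownames(diffs) <- NULL
  tests <- do.call(rbind, lapply(unique(diffs$model), function(m) {
    d <- diffs$rmse_diff[diffs$model == m]
    if (length(d) < 3L) {
      return(data.frame(model = m, n_groups = length(d),
                        mean_diff = mean(d), t_stat = NA_real_,
                        df = NA_real_, p_value = NA_real_,
                        degenerate = TRUE, stringsAsFactors = FALSE))
    }
    if (stats::sd(d) == 0) {
      data.frame(model = m, n_groups = length(d), mean_diff = mean(d),
                 t_stat = NA_real_, df = NA_real_, p_value = NA_real_,
                 degenerate = TRUE, stringsAsFactors = FALSE)
    } else {
      tt <- stats::t.test(d, mu = 0)
      data.frame(model = m, n_groups = length(d), mean_diff = mean(d),
                 t_stat = unname(tt$statistic), df = unname(tt$parameter),
                 p_value = tt$p.value, degenerate = FALSE,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(tests) <- NULL
  list(diffs = diffs, tests = tests)
}
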