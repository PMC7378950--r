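#' Map a monitored phenophase to its analysis class
#'
#' The three leaf-out phenophases (breaking leaf buds for deciduous
#' broadleafs, breaking needle buds for conifers, emerging needles for
#' pines) are pooled as "budburst"; fully open flowers are "flowers".
#'
#' @param phenophase Character vector of phenophase codes.
#' @return Character vector of `"budburst"` / `"flowers"`.
#' @export
#' @examples
#' classify_phenophase(c("breaking_leaf_buds", "open_flowers"))
classify_phenophase <- function(phenophase) {
  map <- c(
    breaking_leaf_buds = "budburst",
    breaking_needle_buds = "budburst",
    emerging_needles = "budburst",
    open_flowers = "flowers"
  )
  out <- unname(map[as.character(phenophase)])
  if (anyNA(out)) {
    bad <- unique(phenophase[is.na(out)])
    stop("unknown phenophase(s): ", paste(bad, collapse = ", "),
         "; accepted values: ", paste(names(map), collapse = ", "),
         call. = FALSE)
  }
  out
}

check_status_records <- function(records) {
  need <- c("individual_id", "site_id", "species", "phenophase", "date",
            "status")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    stop("status records missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  records$date <- as.Date(records$date)
  if (anyNA(records$date)) {
    stop("unparseable dates in status records", call. = FALSE)
  }
  bad <- !records$status %in% c("yes", "no", "unsure")
  if (any(bad)) {
    stop("invalid status value(s): ",
         paste(unique(records$status[bad]), collapse = ", "),
         " (must be yes/no/unsure)", call. = FALSE)
  }
  records
}

#' Infer phenology event days from status records
#'
#' Converts repeated yes/no monitoring of individual plants into one event
#' per individual, phenophase and year. For each individual-phenophase-year
#' the first "yes" record is taken; an event is emitted only if the most
#' recent preceding "no" lies within `max_gap_days`, and its day of year is
#' the midpoint of the two dates (half-integers are kept — censoring by the
#' visit schedule makes the true day uncertain within the gap). "unsure"
#' records are dropped first; duplicate records on one date resolve to
#' "yes". Individuals are never pooled to a site-level record.
#'
#' @param records Data frame of status records with columns
#'   `individual_id, site_id, species, phenophase, date, status`.
#' @param max_gap_days Maximum days between the preceding "no" and the
#'   first "yes" for the pair to define an event (30 by default; 15 is the
#'   stricter variant).
#' @return Data frame of events with columns `species, phenophase_class,
#'   site_id, individual_id, year, doy`, with attributes `n_yes_unmatched`
#'   (first-yes records with no qualifying prior "no") and `n_tie_days`
#'   (duplicate same-date yes/no conflicts resolved to yes).
#' @export
infer_events <- function(records, max_gap_days = 30) {
  records <- check_status_records(records)
  stopifnot(is.numeric(max_gap_days), max_gap_days >= 1)
  records <- records[records$status != "unsure", , drop = FALSE]

  # resolve duplicate individual-phenophase-date records; yes wins ties
  key <- paste(records$individual_id, records$phenophase, records$date,
               sep = "\r")
  ord <- order(key, records$status == "yes", decreasing = c(FALSE, TRUE),
               method = "radix")
  records <- records[ord, , drop = FALSE]
  dup <- duplicated(key[ord])
  n_ties <- 0L
  if (any(dup)) {
    # ties = dates where the same individual has both a yes and a no record
    both <- tapply(records$status, key[ord],
                   function(s) length(unique(s)) > 1L)
    n_ties <- sum(both)
    records <- records[!dup, , drop = FALSE]
  }

  records$year <- as.integer(format(records$date, "%Y"))
  grp <- paste(records$individual_id, records$phenophase, records$year,
               sep = "\r")
  pieces <- split(records, grp)

  n_unmatched <- 0L
  rows <- lapply(pieces, function(g) {
    g <- g[order(g$date), , drop = FALSE]
    yes_idx <- which(g$status == "yes")
    if (length(yes_idx) == 0L) return(NULL)
    first_yes <- yes_idx[1L]
    no_idx <- which(g$status == "no" & g$date < g$date[first_yes])
    if (length(no_idx) == 0L) {
      n_unmatched <<- n_unmatched + 1L
      return(NULL)
    }
    last_no <- no_idx[length(no_idx)]
    gap <- as.numeric(g$date[first_yes] - g$date[last_no])
    if (gap > max_gap_days) {
      n_unmatched <<- n_unmatched + 1L
      return(NULL)
    }
    jan1 <- as.Date(sprintf("%d-01-01", g$year[first_yes]))
    doy_yes <- as.numeric(g$date[first_yes] - jan1) + 1
    doy_no <- as.numeric(g$date[last_no] - jan1) + 1
    data.frame(
      species = g$species[first_yes],
      phenophase_class = classify_phenophase(g$phenophase[first_yes]),
      site_id = g$site_id[first_yes],
      individual_id = g$individual_id[first_yes],
      year = g$year[first_yes],
      doy = (doy_no + doy_yes) / 2,
      stringsAsFactors = FALSE
    )
  })
  rows <- Filter(Negate(is.null), rows)
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (is.null(out)) {
    out <- data.frame(species = character(), phenophase_class = character(),
                      site_id = character(), individual_id = character(),
                      year = integer(), doy = numeric(),
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$species, out$phenophase_class, out$site_id,
                   out$individual_id, out$year), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_yes_unmatched") <- n_unmatched
  attr(out, "n_tie_days") <- n_ties
  out
}

#' Drop late-season events past the phenophase cutoffs
#'
#' Budburst events past DOY 172 and flowering events past DOY 213 are
#' removed to limit the influence of outliers (events on the cutoff day
#' itself are kept).
#'
#' @param events Event data frame from [infer_events()].
#' @param budburst_cutoff,flowers_cutoff Latest retained DOY per class.
#' @return The filtered event data frame.
#' @export
apply_doy_cutoffs <- function(events, budburst_cutoff = 172,
                              flowers_cutoff = 213) {
  cutoff <- ifelse(events$phenophase_class == "flowers",
                   flowers_cutoff, budburst_cutoff)
  out <- events[events$doy <= cutoff, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep only well-observed species-phenophase groups
#'
#' Groups (species x phenophase class) with too few events carry little
#' information for model fitting and are dropped. The default keeps groups
#' with at least `min_n` events; `rule = "gt"` requires strictly more.
#'
#' @param events Event data frame.
#' @param min_n Minimum group size (30 by default).
#' @param rule `"gte"` (keep n >= min_n, default) or `"gt"` (keep
#'   n > min_n).
#' @return The filtered event data frame.
#' @export
apply_minimum_count <- function(events, min_n = 30,
                                rule = c("gte", "gt")) {
  rule <- match.arg(rule)
  grp <- paste(events$species, events$phenophase_class, sep = "\r")
  n <- table(grp)[grp]
  keep <- if (rule == "gte") n >= min_n else n > min_n
  out <- events[as.vector(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Convert numeric monitoring metrics to yes/no status records
#'
#' Intensive monitoring protocols record numeric metrics (percent of buds
#' open, count of open flowers, ...) rather than yes/no status. A metric
#' strictly above `threshold` becomes "yes", otherwise "no".
#'
#' @param table Data frame with the status-record columns except `status`,
#'   plus a numeric metric column.
#' @param threshold Numeric threshold (default 0: any positive metric is a
#'   "yes").
#' @param metric_col Name of the metric column (default `"metric"`).
#' @return A status-record data frame (metric column replaced by `status`).
#' @export
binarize_intensive_metrics <- function(table, threshold = 0,
                                       metric_col = "metric") {
  if (!metric_col %in% names(table)) {
    stop("no column '", metric_col, "' in table", call. = FALSE)
  }
  m <- table[[metric_col]]
  if (!is.numeric(m)) {
    m2 <- suppressWarnings(as.numeric(m))
    if (anyNA(m2) & !all(is.na(m2) == is.na(m))) {
      bad <- which(is.na(m2) & !is.na(m))
      stop("non-numeric metric value at row(s): ",
           paste(utils::head(bad, 5L), collapse = ", "), call. = FALSE)
    }
    m <- m2
  }
  if (anyNA(m)) {
    stop("missing metric value at row(s): ",
         paste(utils::head(which(is.na(m)), 5L), collapse = ", "),
         call. = FALSE)
  }
  table$status <- ifelse(m > threshold, "yes", "no")
  table[[metric_col]] <- NULL
  table
}

#' Full status-record cleaning pipeline
#'
#' Runs [infer_events()], [apply_doy_cutoffs()] and [apply_minimum_count()]
#' in sequence (the minimum-count filter is applied after the cutoffs, so
#' group sizes are counted on retained events) and records the in/out
#' counts of every step.
#'
#' @param records Status-record data frame.
#' @param max_gap_days Passed to [infer_events()].
#' @param budburst_cutoff,flowers_cutoff Passed to [apply_doy_cutoffs()].
#' @param min_n,min_n_rule Passed to [apply_minimum_count()].
#' @param verbose Print the audit counts?
#' @return The cleaned event data frame, with a `filter_log` attribute
#'   (named integer vector of record/event counts after each stage).
#' @export
prepare_events <- function(records, max_gap_days = 30,
                           budburst_cutoff = 172, flowers_cutoff = 213,
                           min_n = 30, min_n_rule = "gte",
                           verbose = FALSE) {
  ev <- infer_events(records, max_gap_days = max_gap_days)
  log <- c(records_in = nrow(records), events_inferred = nrow(ev))
  ev2 <- apply_doy_cutoffs(ev, budburst_cutoff, flowers_cutoff)
  log <- c(log, after_doy_cutoffs = nrow(ev2))
  ev3 <- apply_minimum_count(ev2, min_n = min_n, rule = min_n_rule)
  log <- c(log, after_minimum_count = nrow(ev3))
  if (verbose) {
    message(paste(sprintf("%s: %d", names(log), log), collapse = "; "))
  }
  attr(ev3, "filter_log") <- log
  attr(ev3, "n_yes_unmatched") <- attr(ev, "n_yes_unmatched")
  ev3
}

#' Read and write event tables
#'
#' Plain-CSV serialisation of the event table (`species, phenophase_class,
#' site_id, individual_id, year, doy`).
#'
#' @param file Path to a CSV file.
#' @param events Event data frame.
#' @return `read_events_csv` returns the event data frame.
#' @export
read_events_csv <- function(file) {
  ev <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("species", "phenophase_class", "site_id", "individual_id",
            "year", "doy")
  missing <- setdiff(need, names(ev))
  if (length(missing)) {
    stop("event CSV missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  ev
}

#' @rdname read_events_csv
#' @export
write_events_csv <- function(events, file) {
  utils::write.csv(events, file, row.names = FALSE)
  invisible(file)
}
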