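#' Define a time grid
#'
#' The grid discretises the study window into `n_intervals` contiguous,
#' half-open intervals of equal duration: interval i covers
#' `[start + (i-1)*resolution, start + i*resolution)`. Any resolution works
#' (a day, an hour, 30 minutes, a minute); the choice sets the granularity of
#' the NTask trajectories.
#'
#' @param start Grid start: a `POSIXct` or an ISO-8601 string.
#' @param resolution Interval length: numeric seconds or a string understood
#'   by [lubridate::duration()], e.g. `"30 mins"`, `"1 hour"`.
#' @param n_intervals Positive integer number of intervals (N).
#' @param tz Timezone used when `start` is given as a string (default UTC).
#' @return An object of class `rn_time_grid`.
#' @examples
#' time_grid("2024-03-04 07:00:00", "30 mins", 24)
#' @export
time_grid <- function(start, resolution, n_intervals, tz = "UTC") {
  if (is.character(start)) start <- lubridate::ymd_hms(start, tz = tz)
  stopifnot(inherits(start, "POSIXct"), length(start) == 1L, !is.na(start))
  res_s <- if (is.numeric(resolution)) as.numeric(resolution) else
    as.numeric(lubridate::duration(resolution))
  if (!is.finite(res_s) || res_s <= 0) stop("resolution must be > 0", call. = FALSE)
  n_intervals <- as.integer(n_intervals)
  if (is.na(n_intervals) || n_intervals < 1L) {
    stop("n_intervals must be a positive integer", call. = FALSE)
  }
  structure(list(start = start, resolution = res_s, n_intervals = n_intervals),
            class = "rn_time_grid")
}

#' @export
print.rn_time_grid <- function(x, ...) {
  cat("<time grid: ", x$n_intervals, " x ", x$resolution, " s from ",
      format(x$start, "%Y-%m-%d %H:%M:%S %Z"), ">\n", sep = "")
  invisible(x)
}

grid_end <- function(grid) grid$start + grid$resolution * grid$n_intervals

#' Audit-log CSV dialect
#'
#' Describes how a raw audit-event extract maps onto the neutral event model:
#' which columns hold the nurse id, timestamp, action, EHR section and
#' workstation location, the field delimiter, and the timestamp format.
#'
#' @param nurse_id,timestamp,action,section,location_id Column names in the
#'   source file.
#' @param delim Field delimiter.
#' @param ts_format Timestamp format string for [strptime()], or `NULL` to
#'   parse ISO-8601 via [lubridate::ymd_hms()].
#' @param tz Timezone applied to parsed timestamps.
#' @return A list of class `rn_dialect`.
#' @export
audit_dialect <- function(nurse_id = "nurse_id", timestamp = "timestamp",
                          action = "action", section = "section",
                          location_id = "location_id", delim = ",",
                          ts_format = NULL, tz = "UTC") {
  structure(list(nurse_id = nurse_id, timestamp = timestamp, action = action,
                 section = section, location_id = location_id, delim = delim,
                 ts_format = ts_format, tz = tz),
            class = "rn_dialect")
}

#' Read a raw audit-event table
#'
#' Parses a delimited audit-log extract into the canonical event tibble
#' (`nurse_id`, `timestamp`, `action`, `section`, `location_id`), sorted by
#' nurse and time. Rows with unparseable timestamps or missing ids are either
#' fatal (`on_error = "stop"`, the default) or dropped with a warning that
#' reports their line numbers (`on_error = "drop"`).
#'
#' @param path Path to the delimited file (header row required).
#' @param dialect An [audit_dialect()].
#' @param on_error `"stop"` or `"drop"` for malformed rows.
#' @return A tibble of audit events sorted by (`nurse_id`, `timestamp`).
#' @export
read_audit_log <- function(path, dialect = audit_dialect(),
                           on_error = c("stop", "drop")) {
  on_error <- match.arg(on_error)
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- c(dialect$nurse_id, dialect$timestamp, dialect$action)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("audit log is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  get_col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))
  ev <- tibble::tibble(
    nurse_id = suppressWarnings(as.integer(raw[[dialect$nurse_id]])),
    timestamp = parse_ts(raw[[dialect$timestamp]], dialect),
    action = raw[[dialect$action]],
    section = get_col(dialect$section),
    location_id = get_col(dialect$location_id)
  )
  bad <- which(is.na(ev$nurse_id) | is.na(ev$timestamp) | is.na(ev$action))
  if (length(bad)) {
    lines <- bad + 1L  # header occupies line 1
    msg <- paste0(length(bad), " malformed row(s) at line(s) ",
                  paste(utils::head(lines, 10L), collapse = ", "),
                  if (length(bad) > 10L) ", ...")
    if (on_error == "stop") stop(msg, call. = FALSE)
    warning(msg, "; dropped", call. = FALSE)
    ev <- ev[-bad, ]
  }
  if (nrow(ev) == 0L) warning("audit log contains no events", call. = FALSE)
  dplyr::arrange(ev, .data$nurse_id, .data$timestamp)
}

parse_ts <- function(x, dialect) {
  if (is.null(dialect$ts_format)) {
    suppressWarnings(lubridate::ymd_hms(x, tz = dialect$tz, quiet = TRUE))
  } else {
    as.POSIXct(strptime(x, format = dialect$ts_format, tz = dialect$tz))
  }
}

#' Assign events to grid intervals
#'
#' Adds an `interval` column: interval i holds events with
#' `start + (i-1)*res <= t < start + i*res` (half-open, so a timestamp exactly
#' on a boundary belongs to the later interval). Events outside the grid get
#' `NA` and are counted in the `n_excluded` attribute; they are reported, not
#' fatal, because real audit extracts overhang study windows.
#'
#' @param events Event tibble (any number of nurses).
#' @param grid An [time_grid()].
#' @return `events` with an integer `interval` column (`NA` = out of grid) and
#'   attribute `n_excluded`.
#' @export
assign_events_to_intervals <- function(events, grid) {
  stopifnot(inherits(grid, "rn_time_grid"))
  off <- as.numeric(difftime(events$timestamp, grid$start, units = "secs"))
  idx <- floor(off / grid$resolution) + 1
  idx[off < 0 | idx > grid$n_intervals] <- NA
  events$interval <- as.integer(idx)
  n_excluded <- sum(is.na(events$interval))
  if (n_excluded > 0L) {
    message(n_excluded, " event(s) fall outside the ", grid$n_intervals,
            "-interval grid and were excluded")
  }
  attr(events, "n_excluded") <- n_excluded
  events
}

#' Resolve one task code for an interval
#'
#' The temporal model stores a single task code per interval. An empty
#' interval is the idle code ("no EHR interaction"); an interval with events
#' takes the code of the highest-priority action observed. The default
#' priority puts data input above data review, reflecting the documentation
#' focus of the model.
#'
#' @param actions Character vector of action labels observed in the interval
#'   (may be empty).
#' @param task_vs Task value set.
#' @param priority Labels ordered from highest to lowest priority; must cover
#'   every non-idle label of `task_vs`.
#' @param idle_label Label of the idle state (defaults to the label of code 1).
#' @return The integer task code for the interval.
#' @export
resolve_interval_code <- function(actions, task_vs,
                                  priority = default_priority(task_vs),
                                  idle_label = vs_decode(task_vs, 1L)) {
  if (length(actions) == 0L) return(vs_encode(task_vs, idle_label))
  unknown <- setdiff(unique(actions), task_vs$label)
  if (length(unknown)) {
    stop("action label(s) not in task value set: ",
         paste(shQuote(unknown), collapse = ", "), call. = FALSE)
  }
  uncovered <- setdiff(setdiff(task_vs$label, idle_label), priority)
  if (length(uncovered)) {
    stop("priority order does not cover label(s): ",
         paste(shQuote(uncovered), collapse = ", "), call. = FALSE)
  }
  hit <- priority[priority %in% actions][1]
  if (is.na(hit)) return(vs_encode(task_vs, idle_label))  # only idle observed
  vs_encode(task_vs, hit)
}

#' @rdname resolve_interval_code
#' @export
default_priority <- function(task_vs) {
  # highest code first: input > read for the default task set
  vs_decode(task_vs, rev(setdiff(sort(task_vs$code), 1L)))
}

#' Build the NTask vector for one nurse
#'
#' Encodes a nurse's event stream onto the grid as a length-N sequence of
#' task codes: one code per interval, idle where no event falls. The nurse id
#' is carried alongside the payload (it is not part of the mathematical
#' vector); [to_printed_tuple()] renders the conventional display form
#' `(id, v1, ..., vN)`.
#'
#' @param events Event tibble for a single nurse (may be empty).
#' @param grid An [time_grid()].
#' @param task_vs Task value set.
#' @param nurse_id Nurse identifier; defaults to the single id present in
#'   `events`.
#' @param priority Action priority passed to [resolve_interval_code()].
#' @return An object of class `rn_ntask`: list with `nurse_id`, `codes`
#'   (integer length N) and `grid`.
#' @examples
#' vs <- default_task_value_set()
#' g <- time_grid("2024-03-04 07:00:00", "1 hour", 5)
#' ev <- tibble::tibble(
#'   nurse_id = 55L,
#'   timestamp = g$start + c(600, 4 * 3600 + 600),
#'   action = c("read EHR data", "input EHR data"),
#'   section = c("flowsheet", "notes"), location_id = "OR-WS1"
#' )
#' to_printed_tuple(build_ntask(ev, g, vs))
#' @export
build_ntask <- function(events, grid, task_vs = default_task_value_set(),
                        nurse_id = NULL, priority = default_priority(task_vs)) {
  stopifnot(inherits(grid, "rn_time_grid"))
  if (is.null(nurse_id)) {
    ids <- unique(events$nurse_id)
    if (length(ids) != 1L) {
      stop("events must belong to exactly one nurse (or pass nurse_id)",
           call. = FALSE)
    }
    nurse_id <- ids
  } else if (nrow(events) && !all(events$nurse_id == nurse_id)) {
    stop("events contain nurse ids other than ", nurse_id, call. = FALSE)
  }
  ev <- suppressMessages(assign_events_to_intervals(events, grid))
  ev <- ev[!is.na(ev$interval), ]
  codes <- vapply(seq_len(grid$n_intervals), function(i) {
    resolve_interval_code(ev$action[ev$interval == i], task_vs, priority)
  }, integer(1))
  new_ntask(nurse_id, codes, grid)
}

new_ntask <- function(nurse_id, codes, grid) {
  structure(list(nurse_id = as.integer(nurse_id), codes = as.integer(codes),
                 grid = grid),
            class = "rn_ntask")
}

#' @export
print.rn_ntask <- function(x, ...) {
  cat("<NTask ", to_printed_tuple(x), ">\n", sep = "")
  invisible(x)
}

#' Encode trajectories for a whole cohort of nurses
#'
#' Vectorised form of [build_ntask()]: one row per (nurse, interval).
#'
#' @inheritParams build_ntask
#' @param events Event tibble covering any number of nurses.
#' @return A long tibble (`nurse_id`, `interval`, `code`) with one row per
#'   nurse and interval, ordered by nurse then interval.
#' @export
encode_trajectories <- function(events, grid, task_vs = default_task_value_set(),
                                priority = default_priority(task_vs)) {
  ids <- sort(unique(events$nurse_id))
  purrr::map_dfr(ids, function(id) {
    nt <- build_ntask(events[events$nurse_id == id, ], grid, task_vs, id, priority)
    tibble::tibble(nurse_id = nt$nurse_id,
                   interval = seq_along(nt$codes), code = nt$codes)
  })
}

#' Average hours worked per week, derived from the audit log
#'
#' For each calendar day (in the log's timezone) the daily span is the time
#' between the nurse's first and last EHR interactions; daily spans are
#' summed within ISO weeks, and the result is the mean weekly total over
#' weeks containing at least one event. A lower-bound proxy for hours worked:
#' it sees only documented activity.
#'
#' @param events Event tibble for one nurse (at least one event).
#' @return Mean weekly hours, a number in `[0, 168]`.
#' @export
derive_hours_per_week <- function(events) {
  if (nrow(events) == 0L) {
    stop("cannot derive hours per week from an empty event stream", call. = FALSE)
  }
  tz <- attr(events$timestamp, "tzone") %||% "UTC"
  days <- events |>
    dplyr::mutate(day = lubridate::as_date(.data$timestamp, tz = tz)) |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(
      span_h = as.numeric(difftime(max(.data$timestamp), min(.data$timestamp),
                                   units = "hours")),
      .groups = "drop")
  weekly <- days |>
    dplyr::mutate(iso = paste0(lubridate::isoyear(.data$day), "-W",
                               lubridate::isoweek(.data$day))) |>
    dplyr::group_by(.data$iso) |>
    dplyr::summarise(total_h = sum(.data$span_h), .groups = "drop")
  mean(weekly$total_h)
}

#' Primary assignment, derived from workstation locations
#'
#' Infers the unit a nurse primarily practices in from where documentation
#' happens: the unit whose workstations account for the most events. Ties go
#' to the lexicographically smallest unit label so the result is
#' deterministic; events at unmapped workstations are ignored.
#'
#' @param events Event tibble for one nurse.
#' @param location_map Tibble with columns `location_id`, `unit`.
#' @return The unit label, or `NA_character_` (with a warning) if no event has
#'   a mappable location.
#' @export
derive_primary_location <- function(events, location_map) {
  stopifnot(all(c("location_id", "unit") %in% names(location_map)))
  unit <- location_map$unit[match(events$location_id, location_map$location_id)]
  unit <- unit[!is.na(unit)]
  if (length(unit) == 0L) {
    warning("no event has a mappable workstation location; ",
            "primary assignment is missing", call. = FALSE)
    return(NA_character_)
  }
  counts <- sort(table(unit), decreasing = TRUE)
  top <- names(counts)[counts == max(counts)]
  sort(top)[1]
}
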