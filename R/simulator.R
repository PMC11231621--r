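#' Define a nurse archetype for the simulator
#'
#' An archetype is a generative recipe for one recurring activity pattern: a
#' first-order Markov chain over the task states drives the per-interval
#' charting dynamics, an optional burst rule forces a terminal block of
#' documentation (the "charting in a block at end of shift" pattern), and the
#' static draws (home unit, outcome probabilities, absence intensity) tie the
#' pattern to nurse characteristics and outcomes.
#'
#' @param name Archetype name.
#' @param transition Row-stochastic matrix over the task states, with row and
#'   column names equal to the task value-set labels.
#' @param burst Optional list `list(f = <fraction>, state = <label>)`: the
#'   final `ceiling(f * N)` intervals are forced to `state` (0 < f < 1).
#' @param home_unit Unit label the nurse primarily works in.
#' @param outcome_rates Named numeric vector of Bernoulli probabilities for
#'   the boolean outcome elements.
#' @param missed_days_mean Poisson mean for distinct absence days.
#' @return An object of class `rn_archetype`.
#' @export
archetype <- function(name, transition, burst = NULL, home_unit,
                      outcome_rates, missed_days_mean = 0) {
  transition <- as.matrix(transition)
  if (is.null(rownames(transition)) || !identical(rownames(transition),
                                                  colnames(transition))) {
    stop("transition matrix needs matching row and column state names",
         call. = FALSE)
  }
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9)) {
    stop("transition rows must be nonnegative and sum to 1", call. = FALSE)
  }
  if (!is.null(burst)) {
    stopifnot(is.list(burst), burst$f > 0, burst$f < 1,
              burst$state %in% rownames(transition))
  }
  if (any(outcome_rates < 0 | outcome_rates > 1)) {
    stop("outcome rates must be probabilities in [0, 1]", call. = FALSE)
  }
  stopifnot(missed_days_mean >= 0)
  structure(list(name = name, transition = transition, burst = burst,
                 home_unit = home_unit, outcome_rates = outcome_rates,
                 missed_days_mean = missed_days_mean),
            class = "rn_archetype")
}

#' Default simulated archetypes
#'
#' Two contrasting charting styles over the idle/read/input task states:
#' \describe{
#'   \item{continuous_charter}{documents throughout the shift (input-dominant
#'     transition rows, home unit ICU).}
#'   \item{block_charter}{mostly reads or is away from the EHR during the
#'     shift, then charts in a forced input block over the final 20% of
#'     intervals (home unit OR).}
#' }
#' The resignation probabilities (0.60 for block charters vs 0.05 for
#' continuous charters) plant a strong outcome contrast between the styles;
#' the remaining rates are milder illustrative contrasts.
#'
#' @return Named list of two `rn_archetype` objects.
#' @export
default_archetypes <- function() {
  states <- default_task_value_set()$label
  continuous <- matrix(c(0.20, 0.30, 0.50,
                         0.10, 0.30, 0.60,
                         0.05, 0.15, 0.80),
                       nrow = 3, byrow = TRUE, dimnames = list(states, states))
  block <- matrix(c(0.80, 0.15, 0.05,
                    0.60, 0.35, 0.05,
                    0.50, 0.30, 0.20),
                  nrow = 3, byrow = TRUE, dimnames = list(states, states))
  list(
    continuous_charter = archetype(
      "continuous_charter", continuous, burst = NULL, home_unit = "ICU",
      outcome_rates = c(salary_increase = 0.40, resignation = 0.05,
                        promotion = 0.15),
      missed_days_mean = 1.5),
    block_charter = archetype(
      "block_charter", block,
      burst = list(f = 0.2, state = "input EHR data"), home_unit = "OR",
      outcome_rates = c(salary_increase = 0.20, resignation = 0.60,
                        promotion = 0.05),
      missed_days_mean = 4)
  )
}

#' Stationary distribution of a Markov chain
#'
#' Solves pi = pi P by the eigen decomposition of t(P); used to start
#' simulated shifts in steady state and to check chain calibration.
#'
#' @param transition Row-stochastic matrix.
#' @return Named probability vector.
#' @export
stationary_distribution <- function(transition) {
  e <- eigen(t(transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- v / sum(v)
  stats::setNames(pmax(v, 0) / sum(pmax(v, 0)), rownames(transition))
}

#' Simulate one shift's task-state sequence
#'
#' Runs the archetype's Markov chain for `n_intervals` steps, then applies
#' the burst rule (if any): the final `ceiling(f * n)` states are forced to
#' the burst state. Uses the current RNG stream, so results are reproducible
#' under a fixed seed.
#'
#' @param arch An [archetype()].
#' @param n_intervals Sequence length.
#' @param start Optional start state label; default draws from the chain's
#'   stationary distribution.
#' @return Character vector of state labels, length `n_intervals`.
#' @export
simulate_shift_sequence <- function(arch, n_intervals, start = NULL) {
  states <- rownames(arch$transition)
  seqv <- character(n_intervals)
  seqv[1] <- if (!is.null(start)) {
    stopifnot(start %in% states)
    start
  } else {
    sample(states, 1, prob = stationary_distribution(arch$transition))
  }
  for (i in seq_len(n_intervals - 1L)) {
    seqv[i + 1L] <- sample(states, 1, prob = arch$transition[seqv[i], ])
  }
  if (!is.null(arch$burst)) {
    n_burst <- min(n_intervals, ceiling(arch$burst$f * n_intervals))
    seqv[(n_intervals - n_burst + 1L):n_intervals] <- arch$burst$state
  }
  seqv
}

#' Default workstation-to-unit map
#'
#' Three workstations per unit, named `<UNIT>-WS<j>`.
#' @param units Character vector of unit labels.
#' @param per_unit Workstations per unit.
#' @return Tibble (`location_id`, `unit`).
#' @export
default_location_map <- function(units = c("ICU", "MedSurg", "OR"),
                                 per_unit = 3L) {
  tidyr::expand_grid(unit = units, ws = seq_len(per_unit)) |>
    dplyr::transmute(location_id = paste0(.data$unit, "-WS", .data$ws),
                     unit = .data$unit)
}

#' Emit audit events realising a task-state sequence
#'
#' Each non-idle interval emits `1 + Poisson(rate - 1)` events carrying that
#' interval's action label, with timestamps uniform within the interval
#' (sorted) and workstations drawn with probability `home_mass` from the
#' nurse's home unit. Idle intervals emit nothing, so encoding the emitted
#' events on the same grid recovers the generating sequence exactly.
#'
#' @param states Character state-label sequence (length = grid N).
#' @param grid The [time_grid()].
#' @param rate Mean events per active interval (>= 1).
#' @param home_unit Home unit label.
#' @param nurse_id Nurse id stamped on the events.
#' @param idle_label State label that emits no events.
#' @param location_map Workstation map (see [default_location_map()]).
#' @param home_mass Probability an event's workstation is in the home unit.
#' @return Event tibble in the canonical audit dialect.
#' @export
emit_events <- function(states, grid, rate = 2, home_unit, nurse_id,
                        idle_label = "no EHR interaction",
                        location_map = default_location_map(),
                        home_mass = 0.9) {
  stopifnot(rate >= 1, length(states) == grid$n_intervals)
  sections <- c("flowsheet", "mar", "notes", "orders")
  units <- unique(location_map$unit)
  unit_prob <- stats::setNames(rep((1 - home_mass) / max(1, length(units) - 1),
                                   length(units)), units)
  unit_prob[home_unit] <- if (length(units) == 1L) 1 else home_mass
  active <- which(states != idle_label)
  rows <- purrr::map(active, function(i) {
    n_ev <- 1L + stats::rpois(1, rate - 1)
    t0 <- grid$start + (i - 1) * grid$resolution
    offs <- sort(stats::runif(n_ev, 0, grid$resolution))
    unit <- sample(units, n_ev, replace = TRUE, prob = unit_prob[units])
    ws <- vapply(unit, function(u) {
      sample(location_map$location_id[location_map$unit == u], 1)
    }, character(1))
    tibble::tibble(nurse_id = as.integer(nurse_id), timestamp = t0 + offs,
                   action = states[i],
                   section = sample(sections, n_ev, replace = TRUE),
                   location_id = ws)
  })
  if (length(rows) == 0L) {
    return(tibble::tibble(nurse_id = integer(), timestamp = grid$start[0],
                          action = character(), section = character(),
                          location_id = character()))
  }
  dplyr::bind_rows(rows)
}

#' Draw static attributes and outcomes for one simulated nurse
#'
#' Employment length and accreditation are drawn from fixed marginal
#' distributions; the home unit is copied from the archetype; boolean
#' outcomes are Bernoulli draws at the archetype's rates and missed days are
#' Poisson, realised as dated HR event records inside the outcome window so
#' the encoding path can rebuild them. The archetype name is returned as the
#' ground-truth label (for evaluation only).
#'
#' @param arch An [archetype()].
#' @param nurse_id Nurse id.
#' @param window Outcome window `c(start, end)` (Dates).
#' @return List with `hr` (one-row tibble), `hr_events`, `adt`, `truth`.
#' @export
attach_static <- function(arch, nurse_id, window) {
  window <- as.Date(window)
  days <- seq(window[1], window[2], by = "day")
  hr <- tibble::tibble(
    nurse_id = as.integer(nurse_id),
    employment_years = 1L + stats::rpois(1, 5),
    accreditation = sample(c("LPN", "RN", "NP"), 1, prob = c(0.15, 0.75, 0.10))
  )
  yes <- names(arch$outcome_rates)[
    stats::runif(length(arch$outcome_rates)) < arch$outcome_rates]
  n_miss <- min(length(days), stats::rpois(1, arch$missed_days_mean))
  hr_events <- dplyr::bind_rows(
    tibble::tibble(nurse_id = as.integer(nurse_id),
                   date = sample(days, length(yes), replace = TRUE),
                   kind = yes),
    tibble::tibble(nurse_id = as.integer(nurse_id),
                   date = if (n_miss > 0) sort(sample(days, n_miss)) else
                     as.Date(character()),
                   kind = rep("absence", n_miss))
  )
  n_er <- stats::rpois(1, 1); n_or <- stats::rpois(1, 1)
  n_dis <- stats::rpois(1, 2)
  adt <- tibble::tibble(
    nurse_id = as.integer(nurse_id),
    patient = paste0("p", nurse_id, "_", seq_len(n_er + n_or + n_dis)),
    kind = rep(c("admit_er", "admit_or", "discharge_home"),
               c(n_er, n_or, n_dis)),
    los = c(rep(NA_real_, n_er + n_or),
            round(stats::rgamma(n_dis, shape = 2, scale = 2), 1))
  )
  list(hr = hr, hr_events = hr_events, adt = adt,
       truth = tibble::tibble(nurse_id = as.integer(nurse_id),
                              archetype = arch$name))
}

#' Simulator configuration
#'
#' Defaults describe a cohort of 60 nurses, an even two-archetype mixture,
#' one 12-hour shift on a 24 x 30-minute grid, 2 events per active interval,
#' and a 28-day outcome window starting on the shift date.
#'
#' @param n_nurses Number of nurses (>= 1).
#' @param weights Mixture weights over `archetypes` (must sum to 1).
#' @param grid The shared [time_grid()].
#' @param rate Mean events per active interval.
#' @param archetypes Named list of [archetype()]s.
#' @param location_map Workstation map.
#' @param window Outcome window (Dates); default 28 days from the grid start.
#' @param seed Integer seed driving the whole bundle.
#' @return A list of class `rn_sim_config`.
#' @export
sim_config <- function(n_nurses = 60L, weights = c(0.5, 0.5),
                       grid = time_grid("2024-03-04 07:00:00", "30 mins", 24),
                       rate = 2, archetypes = default_archetypes(),
                       location_map = default_location_map(),
                       window = NULL, seed = 1L) {
  stopifnot(n_nurses >= 1L, length(weights) == length(archetypes))
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("archetype mixture weights must sum to 1", call. = FALSE)
  }
  if (is.null(window)) {
    d0 <- lubridate::as_date(grid$start)
    window <- c(d0, d0 + 27)
  }
  structure(list(n_nurses = as.integer(n_nurses), weights = weights,
                 grid = grid, rate = rate, archetypes = archetypes,
                 location_map = location_map, window = as.Date(window),
                 seed = as.integer(seed)),
            class = "rn_sim_config")
}

#' Simulate a full cohort bundle
#'
#' Draws one archetype per nurse from the mixture, simulates each shift
#' sequence, emits audit events, and draws the auxiliary HR/ADT tables plus
#' ground-truth labels. Fully deterministic given `config$seed`. The planted
#' state sequences are returned so tests can verify that encoding the events
#' reproduces them exactly.
#'
#' @param config A [sim_config()].
#' @return A list of class `rn_sim_bundle` with elements `events`, `hr`,
#'   `hr_events`, `adt`, `truth`, `states` (long tibble of planted state
#'   labels) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "rn_sim_config"))
  withr::with_seed(config$seed, {
    arch_names <- names(config$archetypes)
    assigned <- sample(arch_names, config$n_nurses, replace = TRUE,
                       prob = config$weights)
    per_nurse <- purrr::map(seq_len(config$n_nurses), function(id) {
      arch <- config$archetypes[[assigned[id]]]
      states <- simulate_shift_sequence(arch, config$grid$n_intervals)
      events <- emit_events(states, config$grid, config$rate, arch$home_unit,
                            id, location_map = config$location_map)
      static <- attach_static(arch, id, config$window)
      c(list(events = events,
             states = tibble::tibble(nurse_id = as.integer(id),
                                     interval = seq_along(states),
                                     state = states)),
        static)
    })
    pull <- function(nm) dplyr::bind_rows(purrr::map(per_nurse, nm))
    structure(list(events = pull("events"), hr = pull("hr"),
                   hr_events = pull("hr_events"), adt = pull("adt"),
                   truth = pull("truth"), states = pull("states"),
                   config = config),
              class = "rn_sim_bundle")
  })
}

#' @export
print.rn_sim_bundle <- function(x, ...) {
  cat("<simulated bundle: ", x$config$n_nurses, " nurses, ",
      nrow(x$events), " audit events, seed ", x$config$seed, ">\n", sep = "")
  print(dplyr::count(x$truth, .data$archetype))
  invisible(x)
}

#' Write a simulated bundle to disk
#'
#' Writes `audit.csv` (canonical audit dialect), `hr.csv`, `hr_events.csv`,
#' `adt.csv`, `truth.csv` and `sim_config.json` (grid, weights, rates, seed)
#' into `dir`.
#'
#' @param bundle An `rn_sim_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ev <- bundle$events
  ev$timestamp <- format(ev$timestamp, "%Y-%m-%dT%H:%M:%OS3")
  readr::write_csv(ev, file.path(dir, "audit.csv"))
  readr::write_csv(bundle$hr, file.path(dir, "hr.csv"))
  readr::write_csv(bundle$hr_events, file.path(dir, "hr_events.csv"))
  readr::write_csv(bundle$adt, file.path(dir, "adt.csv"))
  readr::write_csv(bundle$truth, file.path(dir, "truth.csv"))
  cfg <- bundle$config
  jsonlite::write_json(
    list(n_nurses = cfg$n_nurses, weights = cfg$weights, seed = cfg$seed,
         rate = cfg$rate,
         archetypes = names(cfg$archetypes),
         grid = list(start = format(cfg$grid$start, "%Y-%m-%dT%H:%M:%S"),
                     tz = attr(cfg$grid$start, "tzone") %||% "UTC",
                     resolution_s = cfg$grid$resolution,
                     n_intervals = cfg$grid$n_intervals),
         window = format(cfg$window)),
    file.path(dir, "sim_config.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
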