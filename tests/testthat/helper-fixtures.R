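# Shared fixtures built in code.

task_vs <- default_task_value_set()

# The five-period scenario: nurse 55 reads in period 1, idles in 2-4,
# writes a note in period 5, on an hourly grid.
worked_grid <- function() time_grid("2024-03-04 07:00:00", "1 hour", 5)

worked_events <- function(grid = worked_grid()) {
  tibble::tibble(
    nurse_id = 55L,
    timestamp = grid$start + c(600, 4 * 3600 + 600),
    action = c("read EHR data", "input EHR data"),
    section = c("flowsheet", "notes"),
    location_id = c("OR-WS1", "OR-WS2")
  )
}

# Trajectories made of b identical blocks of n_each copies each; block j is
# the constant sequence of code j (codes must exist in the task set).
block_trajectories <- function(n_each, n_intervals, codes = c(1L, 3L)) {
  purrr::imap_dfr(codes, function(code, j) {
    tidyr::expand_grid(nurse_id = (j - 1L) * n_each + seq_len(n_each),
                       interval = seq_len(n_intervals)) |>
      dplyr::mutate(code = code)
  })
}

# Ground-truth labels of a simulated bundle as integer clusters.
truth_labels <- function(bundle) {
  tibble::tibble(nurse_id = bundle$truth$nurse_id,
                 cluster = as.integer(factor(bundle$truth$archetype)))
}

# Independent Hamming-distance oracle: plain double loop over a wide matrix.
brute_force_distances <- function(trajectories) {
  wide <- trajectories |>
    dplyr::arrange(nurse_id, interval) |>
    tidyr::pivot_wider(names_from = interval, values_from = code)
  m <- as.matrix(wide[-1])
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(wide$nurse_id, wide$nurse_id))
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- sum(m[i, ] != m[j, ])
  D
}

# Independent two-sided Fisher oracle: enumerate every table with the
# observed margins and sum hypergeometric probabilities <= observed.
fisher_enum_p <- function(tab) {
  a <- tab[1, 1]; r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  xs <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- stats::dhyper(xs, c1, n - c1, r1)
  p_obs <- stats::dhyper(a, c1, n - c1, r1)
  min(1, sum(probs[probs <= p_obs + 1e-12]))
}

# Independent BH oracle: step-up definition with running minimum.
bh_stepup <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / (m:1)))[ro]
}

# Simulate, encode and cluster one default cohort; returns pieces for
# recovery checks.
simulate_and_cluster <- function(seed, n_nurses = 60L, k = 2L, ...) {
  cfg <- sim_config(n_nurses = n_nurses, seed = seed, ...)
  bundle <- simulate_cohort(cfg)
  traj <- encode_trajectories(bundle$events, cfg$grid)
  cl <- cluster_trajectories(trajectory_distances(traj), k, seed = seed)
  list(bundle = bundle, trajectories = traj, clustering = cl)
}
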