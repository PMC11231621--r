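test_that("contingency tables tally in/out by YES/NO and drop missings", {
  labels <- tibble::tibble(nurse_id = 1:10,
                           cluster = rep(c(1L, 2L), c(4L, 6L)))
  values <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE)
  tab <- contingency_table(labels, values, 1L)
  expect_equal(unname(tab), matrix(c(3, 1, 1, 5), nrow = 2, byrow = TRUE))
  expect_identical(sum(tab), 10L)

  values[10] <- NA
  expect_identical(sum(contingency_table(labels, values, 1L)), 9L)
  expect_error(contingency_table(labels, values, 3L), "empty")
  expect_error(contingency_table(labels, rep(NA, 10), 1L), "all property values")
})

test_that("Fisher p-values match hand-enumerable tables", {
  expect_equal(fisher_exact_p(matrix(c(1, 1, 1, 1), 2)), 1)
  # margins (5,5,5,5): the two extreme tables each have probability 1/C(10,5)
  expect_equal(fisher_exact_p(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_error(fisher_exact_p(matrix(c(-1, 1, 1, 1), 2)), "nonnegative")
  # row/column swap invariance
  withr::with_seed(15, {
    for (rep in 1:10) {
      tab <- matrix(sample(0:8, 4, replace = TRUE), 2)
      p <- fisher_exact_p(tab)
      expect_equal(fisher_exact_p(tab[2:1, ]), p, tolerance = 1e-10)
      expect_equal(fisher_exact_p(tab[, 2:1]), p, tolerance = 1e-10)
      expect_equal(p, fisher_enum_p(tab), tolerance = 1e-9)
    }
  })
})

test_that("the permutation test is exact-style, seeded, and enumerable at n = 6", {
  # identical constant values: the statistic is zero everywhere
  expect_equal(permutation_test_numeric(rep(2, 8), rep(c(TRUE, FALSE), 4),
                                        n_perm = 99, seed = 1), 1)
  # {0,0,0} vs {10,10,10}: only 2 of the C(6,3) = 20 splits reach |diff| = 10
  vals <- c(0, 0, 0, 10, 10, 10)
  flags <- rep(c(TRUE, FALSE), each = 3)
  exact <- mean(apply(utils::combn(6, 3), 2, function(idx) {
    abs(mean(vals[idx]) - mean(vals[-idx])) >= 10 - 1e-12
  }))
  expect_equal(exact, 2 / 20)
  p_hat <- permutation_test_numeric(vals, flags, n_perm = 9999, seed = 5)
  expect_lt(abs(p_hat - exact), 0.02)
  # deterministic given the seed
  expect_identical(permutation_test_numeric(vals, flags, 999, seed = 3),
                   permutation_test_numeric(vals, flags, 999, seed = 3))
  expect_error(permutation_test_numeric(1:5, c(TRUE, rep(FALSE, 4)), 99, 1),
               "at least 2")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  withr::with_seed(27, {
    for (rep in 1:10) {
      p <- runif(sample(1:20, 1))
      q <- bh_adjust(p)
      expect_equal(q, bh_stepup(p), tolerance = 1e-12)
      expect_true(all(q >= p - 1e-12))
      expect_true(all(q <= 1))
    }
  })
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("enrichment reports recover a planted outcome association", {
  run <- simulate_and_cluster(seed = 101, n_nurses = 60)
  bundle <- run$bundle
  cohort <- suppressMessages(encode_cohort(
    bundle$events, bundle$config$grid, hr = bundle$hr,
    hr_events = bundle$hr_events, adt = bundle$adt,
    window = bundle$config$window))
  enr <- enrichment_report(run$clustering, cohort, n_perm = 499, seed = 1)
  expect_s3_class(enr, "rn_enrichment")
  # q is monotone above p and the table is sorted by q
  ok <- !is.na(enr$q)
  expect_true(all(enr$q[ok] >= enr$p[ok] - 1e-12))
  expect_false(is.unsorted(enr$q[ok]))

  # identify the cluster dominated by block charters; resignation must be
  # significantly enriched there
  truth <- truth_labels(bundle)
  joined <- dplyr::inner_join(run$clustering$labels, bundle$truth,
                              by = "nurse_id")
  block_cl <- joined |>
    dplyr::filter(archetype == "block_charter") |>
    dplyr::count(cluster) |>
    dplyr::slice_max(n, n = 1) |>
    dplyr::pull(cluster)
  res <- enr[enr$cluster == block_cl & enr$family == "noutcome" &
               enr$element == "resignation", ]
  expect_identical(res$direction, "enriched")
  expect_lt(res$q, 0.05)
})

test_that("constant properties and shuffled labels yield null results", {
  traj <- block_trajectories(10, 8, codes = c(1L, 3L))
  g <- time_grid("2024-03-04 07:00:00", "1 hour", 8)
  ntype <- purrr::map_dfr(1:20, function(id) {
    static_table(list(build_ntype(list(accreditation = "RN"), nurse_id = id)))
  })
  cohort <- suppressMessages(assemble_cohort(traj, ntype = ntype, grid = g))
  fit <- cluster_trajectories(trajectory_distances(cohort), 2)
  enr <- enrichment_report(fit, cohort, n_perm = 99, seed = 1)
  const <- enr[enr$element == "accreditation" & !is.na(enr$p), ]
  expect_true(all(const$p == 1))
  expect_true(all(const$effect == 0))
  expect_true(all(const$direction == "enriched"))  # stated zero-effect tie rule

  # labels shuffled against the statics: (almost) nothing passes the screen
  bundle <- simulate_cohort(sim_config(n_nurses = 60, seed = 303))
  cohort2 <- suppressMessages(encode_cohort(
    bundle$events, bundle$config$grid, hr = bundle$hr,
    hr_events = bundle$hr_events, adt = bundle$adt,
    window = bundle$config$window))
  ids <- sort(unique(cohort2$trajectories$nurse_id))
  shuffled <- withr::with_seed(5, tibble::tibble(
    nurse_id = ids, cluster = sample(rep(1:2, length.out = length(ids)))))
  fake <- structure(list(labels = shuffled,
                         medoids = tibble::tibble(cluster = 1:2,
                                                  nurse_id = ids[1:2]),
                         k = 2L, seed = 5L), class = "rn_clustering")
  enr2 <- enrichment_report(fake, cohort2, n_perm = 199, seed = 7)
  expect_lte(sum(enr2$q < 0.05, na.rm = TRUE), 1L)
})

test_that("cluster-conditional rates form the baseline predictor", {
  labels <- tibble::tibble(nurse_id = 1:20, cluster = rep(1:2, each = 10L))
  fit <- structure(list(labels = labels,
                        medoids = tibble::tibble(cluster = 1:2,
                                                 nurse_id = c(1L, 11L)),
                        k = 2L, seed = 1L), class = "rn_clustering")
  traj <- block_trajectories(10, 4, codes = c(1L, 3L))
  noutcome <- purrr::map_dfr(1:20, function(id) {
    static_table(list(build_noutcome(
      if (id <= 6) tibble::tibble(date = as.Date("2024-03-05"),
                                  kind = "resignation")
      else tibble::tibble(date = as.Date(character()), kind = character()),
      nurse_id = id, window = as.Date(c("2024-03-01", "2024-03-28")))))
  })
  cohort <- suppressMessages(assemble_cohort(
    traj, noutcome = noutcome, grid = time_grid("2024-03-04 07:00:00",
                                                "1 hour", 4)))
  rates <- cluster_conditional_rates(fit, cohort, "resignation")
  expect_equal(rates$rate, c(0.6, 0))
  expect_equal(rates$n, c(10L, 10L))
  expect_equal(rates$ci_lo[2], 0)
  expect_true(all(rates$ci_hi >= rates$rate & rates$ci_lo <= rates$rate))
})

test_that("rates recover the simulator's configured outcome probabilities", {
  bundle <- simulate_cohort(sim_config(n_nurses = 400, seed = 909))
  cohort <- suppressMessages(encode_cohort(
    bundle$events, bundle$config$grid, hr = bundle$hr,
    hr_events = bundle$hr_events, adt = bundle$adt,
    window = bundle$config$window))
  truth <- truth_labels(bundle)
  fit <- structure(list(labels = truth,
                        medoids = tibble::tibble(cluster = 1:2,
                                                 nurse_id = truth$nurse_id[1:2]),
                        k = 2L, seed = 1L), class = "rn_clustering")
  rates <- cluster_conditional_rates(fit, cohort, "resignation")
  configured <- vapply(
    sort(unique(bundle$truth$archetype)),
    function(a) bundle$config$archetypes[[a]]$outcome_rates[["resignation"]],
    numeric(1))
  expect_true(all(abs(rates$rate - configured) < 0.1))
})
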