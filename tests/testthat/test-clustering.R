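test_that("Hamming distance counts mismatching positions", {
  expect_identical(hamming_distance(c(2, 1, 1, 1, 3), c(2, 1, 1, 1, 3)), 0L)
  expect_identical(hamming_distance(c(2, 1, 1, 1, 3), c(3, 1, 1, 1, 3)), 1L)
  expect_identical(hamming_distance(rep(1L, 7), rep(2L, 7)), 7L)
  expect_error(hamming_distance(1:3, 1:4), "length")
})

test_that("the distance matrix matches a brute-force recomputation", {
  withr::with_seed(13, {
    traj <- tidyr::expand_grid(nurse_id = 1:5, interval = 1:12) |>
      dplyr::mutate(code = sample(1:3, dplyr::n(), replace = TRUE))
  })
  D <- trajectory_distances(traj)
  expect_equal(D, brute_force_distances(traj))
  expect_true(all(D == t(D)))
  expect_true(all(diag(D) == 0))

  one <- trajectory_distances(traj[traj$nurse_id == 1, ])
  expect_identical(dim(one), c(1L, 1L))
  expect_identical(one[1, 1], 0)

  dup <- dplyr::bind_rows(traj[traj$nurse_id == 1, ],
                          dplyr::mutate(traj[traj$nurse_id == 1, ],
                                        nurse_id = 99L))
  expect_identical(trajectory_distances(dup)[1, 2], 0)
})

test_that("k-medoids matches brute-force optima on small problems", {
  # k = 1: the medoid is the point minimising total distance to all others
  withr::with_seed(19, {
    traj <- tidyr::expand_grid(nurse_id = 1:7, interval = 1:10) |>
      dplyr::mutate(code = sample(1:3, dplyr::n(), replace = TRUE))
  })
  D <- trajectory_distances(traj)
  fit1 <- cluster_trajectories(D, 1)
  expect_identical(fit1$medoids$nurse_id, unname(which.min(colSums(D))))
  expect_equal(fit1$objective, min(colSums(D)))

  # k = 2 on n <= 8: objective equals the exhaustive optimum over all pairs
  for (seed in c(2, 4, 6)) {
    withr::with_seed(seed, {
      traj <- tidyr::expand_grid(nurse_id = 1:8, interval = 1:10) |>
        dplyr::mutate(code = sample(1:3, dplyr::n(), replace = TRUE))
    })
    D <- trajectory_distances(traj)
    best <- min(apply(utils::combn(8, 2), 2, function(pair) {
      sum(pmin(D[, pair[1]], D[, pair[2]]))
    }))
    expect_equal(cluster_trajectories(D, 2)$objective, best)
  }
  expect_error(cluster_trajectories(D, 9), "k must be")
})

test_that("identical planted blocks are recovered exactly and swaps never hurt", {
  traj <- block_trajectories(5, 8, codes = c(1L, 3L))
  D <- trajectory_distances(traj)
  fit <- cluster_trajectories(D, 2)
  expect_equal(fit$objective, 0)
  lab <- fit$labels
  expect_identical(length(unique(lab$cluster[lab$nurse_id <= 5])), 1L)
  expect_identical(length(unique(lab$cluster[lab$nurse_id > 5])), 1L)
  expect_false(unique(lab$cluster[lab$nurse_id <= 5]) ==
                 unique(lab$cluster[lab$nurse_id > 5]))

  # the final objective never exceeds the greedy seed's objective
  withr::with_seed(41, {
    traj <- tidyr::expand_grid(nurse_id = 1:20, interval = 1:15) |>
      dplyr::mutate(code = sample(1:3, dplyr::n(), replace = TRUE))
  })
  D <- trajectory_distances(traj)
  m1 <- unname(which.min(colSums(D)))
  joint <- vapply(seq_len(nrow(D)), function(h) {
    if (h == m1) Inf else sum(pmin(D[, m1], D[, h]))
  }, numeric(1))
  seed_obj <- min(joint)  # objective at the greedy two-medoid seed
  expect_lte(cluster_trajectories(D, 2)$objective, seed_obj)
})

test_that("clustering is invariant to nurse order up to relabeling", {
  bundle <- simulate_cohort(sim_config(n_nurses = 20, seed = 55))
  traj <- encode_trajectories(bundle$events, bundle$config$grid)
  fit <- cluster_trajectories(trajectory_distances(traj), 2, seed = 1)
  shuffled <- withr::with_seed(7, traj[sample(nrow(traj)), ])
  fit2 <- cluster_trajectories(trajectory_distances(shuffled), 2, seed = 1)
  expect_equal(adjusted_rand_index(fit$labels, fit2$labels), 1)
})

test_that("silhouette-based selection finds planted block counts", {
  D2 <- trajectory_distances(block_trajectories(6, 10, codes = c(1L, 3L)))
  expect_identical(as.integer(select_k(D2, 2:5)), 2L)

  D3 <- trajectory_distances(block_trajectories(5, 12, codes = c(1L, 2L, 3L)))
  expect_identical(as.integer(select_k(D3, 2:6)), 3L)

  # three separated simulated archetype blocks with within-block noise
  withr::with_seed(61, {
    base <- list(rep(1L, 15), rep(2L, 15), rep(3L, 15))
    traj <- purrr::map_dfr(1:18, function(i) {
      codes <- base[[(i - 1) %/% 6 + 1]]
      flip <- sample(15, 2)
      codes[flip] <- sample(1:3, 2, replace = TRUE)
      tibble::tibble(nurse_id = i, interval = 1:15, code = codes)
    })
  })
  expect_identical(as.integer(select_k(trajectory_distances(traj), 2:6)), 3L)

  Dz <- trajectory_distances(block_trajectories(6, 10, codes = c(2L, 2L)))
  expect_warning(kz <- select_k(Dz, 2:4), "degenerate|identical")
  expect_identical(as.integer(kz), 2L)
  expect_error(select_k(D2, integer()), "empty")
  expect_error(select_k(D2, 2:50), "within")
})

test_that("silhouette agrees with the reference implementation", {
  skip_if_not_installed("cluster")
  withr::with_seed(23, {
    traj <- tidyr::expand_grid(nurse_id = 1:15, interval = 1:12) |>
      dplyr::mutate(code = sample(1:3, dplyr::n(), replace = TRUE))
    D <- trajectory_distances(traj)
    for (k in 2:4) {
      lab <- sample(seq_len(k), 15, replace = TRUE)
      lab[seq_len(k)] <- seq_len(k)  # ensure every cluster occupied
      ref <- mean(cluster::silhouette(lab, dmatrix = D)[, "sil_width"])
      expect_equal(silhouette_score(D, lab), ref, tolerance = 1e-12)
    }
  })
})

test_that("the adjusted Rand index matches its pair-counting formula", {
  a <- tibble::tibble(nurse_id = 1:6, cluster = c(1L, 1L, 2L, 2L, 3L, 3L))
  expect_equal(adjusted_rand_index(a, a), 1)
  relab <- dplyr::mutate(a, cluster = c(3L, 3L, 1L, 1L, 2L, 2L))
  expect_equal(adjusted_rand_index(a, relab), 1)

  b <- tibble::tibble(nurse_id = 1:6, cluster = c(1L, 1L, 1L, 2L, 2L, 2L))
  # direct evaluation of (sum_ij C(n_ij,2) - E) / (max - E) for this table
  tab <- table(a$cluster, b$cluster)
  sum_ij <- sum(choose(tab, 2)); sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2)); E <- sum_a * sum_b / choose(6, 2)
  expect_equal(adjusted_rand_index(a, b),
               (sum_ij - E) / ((sum_a + sum_b) / 2 - E))

  skip_if_not_installed("mclust")
  withr::with_seed(3, {
    for (rep in 1:10) {
      x <- sample(1:3, 12, replace = TRUE)
      y <- sample(1:3, 12, replace = TRUE)
      expect_equal(adjusted_rand_index(stats::setNames(x, 1:12),
                                       stats::setNames(y, 1:12)),
                   mclust::adjustedRandIndex(x, y), tolerance = 1e-12)
    }
  })
  expect_error(adjusted_rand_index(a, dplyr::mutate(b, nurse_id = 7:12)),
               "different nurse ids")
})

test_that("tidy and glance summarise a clustering", {
  fit <- cluster_trajectories(trajectory_distances(
    block_trajectories(4, 8, codes = c(1L, 3L))), 2)
  td <- tidy(fit)
  expect_identical(nrow(td), 8L)
  expect_identical(sum(td$is_medoid), 2L)
  gl <- glance(fit)
  expect_identical(gl$k, 2L)
  expect_identical(gl$n, 8L)
})
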