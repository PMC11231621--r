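test_that("NType vectors place validated values in schema order", {
  v <- build_ntype(list(employment_years = 5, accreditation = "RN",
                        avg_hours_per_week = 48, primary_assignment = "OR"),
                   nurse_id = 55)
  expect_identical(v$values$employment_years, 5L)
  expect_identical(v$values$accreditation, "RN")
  expect_identical(v$values$primary_assignment, "OR")
  expect_identical(to_printed_tuple(v), "(55, 5, RN, 48, OR)")

  all_missing <- build_ntype(list(), nurse_id = 1)
  expect_true(all(vapply(all_missing$values, is.na, logical(1))))
  expect_error(build_ntype(list(employment_years = "five"), nurse_id = 1),
               "employment_years.*integer")
  expect_error(build_ntype(list(shoe_size = 40), nurse_id = 1),
               "not in schema")
  expect_error(build_ntype(list(accreditation = "MD"), nurse_id = 1),
               "outside its value set")
})

test_that("NPanel aggregates ADT flow and averages recorded LOS", {
  adt <- tibble::tibble(patient = c("p1", "p2", "p3"),
                        kind = c("admit_or", "discharge_home", "discharge_home"),
                        los = c(NA, 3, 5))
  v <- build_npanel(adt, nurse_id = 55)
  expect_identical(unname(unlist(v$values)), c(0L, 1L, 2L, 4L))
  expect_identical(to_printed_tuple(v), "(55, 0, 1, 2, 4)")

  empty <- build_npanel(adt[0, ], nurse_id = 1)
  expect_identical(unname(unlist(empty$values[1:3])), c(0L, 0L, 0L))
  expect_true(is.na(empty$values$avg_los))

  er_only <- build_npanel(tibble::tibble(patient = paste0("p", 1:3),
                                         kind = "admit_er", los = NA_real_),
                          nurse_id = 1)
  expect_identical(unname(unlist(er_only$values[1:3])), c(3L, 0L, 0L))
  expect_true(is.na(er_only$values$avg_los))
  expect_error(build_npanel(tibble::tibble(patient = "p", kind = "transfer",
                                           los = NA_real_), nurse_id = 1),
               "unknown ADT event kind")
})

test_that("NOutcome marks in-window events and counts distinct absence dates", {
  window <- as.Date(c("2024-03-01", "2024-03-31"))
  hr <- tibble::tibble(date = as.Date("2024-03-01") + c(1:6, 6),
                       kind = "absence")  # one duplicated date
  v <- build_noutcome(hr, nurse_id = 55, window = window)
  expect_identical(to_printed_tuple(v), "(55, NO, NO, NO, 6)")

  none <- build_noutcome(hr[0, ], nurse_id = 1, window = window)
  expect_identical(to_printed_tuple(none), "(1, NO, NO, NO, 0)")

  mixed <- tibble::tibble(
    date = as.Date(c("2024-03-10", "2024-04-02", "2024-03-11")),
    kind = c("resignation", "promotion", "absence"))
  expect_message(v2 <- build_noutcome(mixed, nurse_id = 2, window = window),
                 "outside the outcome window")
  expect_true(v2$values$resignation)
  expect_false(v2$values$promotion)  # event after the window is ignored
  expect_identical(v2$values$missed_days, 1L)
})

test_that("printed tuples round-trip through parsing for all families", {
  g <- worked_grid()
  nt <- build_ntask(worked_events(), g, task_vs)
  back <- parse_printed_tuple(to_printed_tuple(nt), grid = g)
  expect_identical(back$nurse_id, nt$nurse_id)
  expect_identical(back$codes, nt$codes)

  withr::with_seed(21, {
    for (rep in 1:5) {
      v <- build_ntype(list(employment_years = sample(1:30, 1),
                            accreditation = sample(c("LPN", "RN", "NP"), 1),
                            avg_hours_per_week = round(runif(1, 20, 60), 1),
                            primary_assignment = sample(c("ICU", "MedSurg",
                                                          "OR"), 1)),
                       nurse_id = sample(1:99, 1))
      back <- parse_printed_tuple(to_printed_tuple(v), default_ntype_schema())
      expect_identical(back$values, v$values)
      expect_identical(back$nurse_id, v$nurse_id)
    }
  })
  out <- build_noutcome(tibble::tibble(date = as.Date("2024-03-02"),
                                       kind = "salary_increase"),
                        nurse_id = 3,
                        window = as.Date(c("2024-03-01", "2024-03-31")))
  back <- parse_printed_tuple(to_printed_tuple(out), default_noutcome_schema())
  expect_identical(back$values, out$values)
})

test_that("cohorts are id-aligned on the trajectory spine", {
  g <- time_grid("2024-03-04 07:00:00", "1 hour", 3)
  traj <- block_trajectories(2, 3)  # nurses 1:4
  ntype <- static_table(list(build_ntype(list(employment_years = 3),
                                         nurse_id = 1)))
  cohort <- suppressMessages(assemble_cohort(traj, ntype = ntype, grid = g))
  expect_identical(cohort_size(cohort), 4L)
  expect_identical(nrow(cohort$ntype), 4L)          # flagged-missing rows added
  expect_true(all(is.na(cohort$ntype$accreditation)))
  expect_true(all(is.na(cohort$npanel$admit_er)))   # whole family absent

  orphan <- static_table(list(build_ntype(list(), nurse_id = 99)))
  expect_error(assemble_cohort(traj, ntype = orphan, grid = g),
               "without a task trajectory")
  dup <- dplyr::bind_rows(ntype, ntype)
  expect_error(assemble_cohort(traj, ntype = dup, grid = g), "duplicate nurse_id")

  g2 <- time_grid("2024-03-04 07:00:00", "1 hour", 4)
  nts <- list(build_ntask(worked_events()[0, ], g, task_vs, nurse_id = 1),
              build_ntask(worked_events()[0, ], g2, task_vs, nurse_id = 2))
  expect_error(assemble_cohort(nts, grid = g), "share the cohort grid")
})

test_that("cohort bundles round-trip losslessly through disk", {
  bundle <- simulate_cohort(sim_config(n_nurses = 8, seed = 5))
  cohort <- suppressMessages(encode_cohort(
    bundle$events, bundle$config$grid, hr = bundle$hr,
    hr_events = bundle$hr_events, adt = bundle$adt,
    window = bundle$config$window))
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  back <- suppressMessages(read_cohort(dir))
  expect_equal(back$trajectories, cohort$trajectories)
  expect_equal(back$ntype, cohort$ntype)
  expect_equal(back$npanel, cohort$npanel)
  expect_equal(back$noutcome, cohort$noutcome)
  expect_equal(back$grid$resolution, cohort$grid$resolution)
  expect_true(back$grid$start == cohort$grid$start)
  expect_equal(as.data.frame(back$task_vs), as.data.frame(cohort$task_vs))

  file.remove(file.path(dir, "model.json"))
  expect_error(read_cohort(dir), "sidecar")
})

test_that("an empty cohort writes and reads back as empty", {
  g <- time_grid("2024-03-04 07:00:00", "1 hour", 3)
  empty <- assemble_cohort(tibble::tibble(nurse_id = integer(),
                                          interval = integer(),
                                          code = integer()), grid = g)
  dir <- withr::local_tempdir()
  write_cohort(empty, dir)
  back <- read_cohort(dir)
  expect_identical(cohort_size(back), 0L)
})

test_that("numeric export contains only numbers", {
  bundle <- simulate_cohort(sim_config(n_nurses = 6, seed = 9))
  cohort <- suppressMessages(encode_cohort(
    bundle$events, bundle$config$grid, hr = bundle$hr,
    hr_events = bundle$hr_events, adt = bundle$adt,
    window = bundle$config$window))
  num <- cohort_to_numeric(cohort)
  for (fam in c("ntype", "npanel", "noutcome")) {
    expect_true(all(vapply(num[[fam]], is.numeric, logical(1))),
                info = fam)
  }
  # boolean encoding is the canonical NO=0 / YES=1 table
  expect_setequal(stats::na.omit(unique(num$noutcome$resignation)), c(0L, 1L))
})
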