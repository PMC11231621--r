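#' Encode a cohort from raw tables
#'
#' The encode boundary of the pipeline: consumes an audit-event table plus
#' optional auxiliary HR/ADT tables (the same dialects the simulator writes,
#' or real extracts mapped to them) and produces the id-aligned cohort.
#' NType combines HR attributes with two audit-log-derived elements
#' (average weekly hours, primary assignment); NPanel aggregates ADT flow;
#' NOutcome is rebuilt from dated HR events over the outcome window. Nurses
#' absent from an auxiliary table carry explicitly missing vectors.
#'
#' @param events Audit-event tibble (all nurses).
#' @param grid The [time_grid()].
#' @param hr Optional tibble (`nurse_id`, `employment_years`, `accreditation`).
#' @param hr_events Optional tibble (`nurse_id`, `date`, `kind`).
#' @param adt Optional tibble (`nurse_id`, `patient`, `kind`, `los`).
#' @param window Outcome window `c(start, end)`; required when `hr_events`
#'   given.
#' @param task_vs,schemas,priority,location_map Model configuration (defaults
#'   ship with the package).
#' @return An `rn_cohort`.
#' @export
encode_cohort <- function(events, grid, hr = NULL, hr_events = NULL,
                          adt = NULL, window = NULL,
                          task_vs = default_task_value_set(),
                          schemas = list(ntype = default_ntype_schema(),
                                         npanel = default_npanel_schema(),
                                         noutcome = default_noutcome_schema()),
                          priority = default_priority(task_vs),
                          location_map = default_location_map()) {
  traj <- encode_trajectories(events, grid, task_vs, priority)
  ids <- sort(unique(traj$nurse_id))

  ntype <- purrr::map_dfr(ids, function(id) {
    ev <- events[events$nurse_id == id, ]
    attrs <- list(
      avg_hours_per_week = derive_hours_per_week(ev),
      primary_assignment = suppressWarnings(
        derive_primary_location(ev, location_map))
    )
    if (!is.null(hr) && id %in% hr$nurse_id) {
      row <- hr[hr$nurse_id == id, ]
      attrs$employment_years <- row$employment_years[1]
      attrs$accreditation <- row$accreditation[1]
    }
    static_table(list(build_ntype(attrs, schemas$ntype, id)))
  })

  npanel <- if (!is.null(adt)) {
    purrr::map_dfr(intersect(ids, unique(adt$nurse_id)), function(id) {
      static_table(list(build_npanel(adt[adt$nurse_id == id, ],
                                     schemas$npanel, id)))
    })
  }
  noutcome <- if (!is.null(hr_events)) {
    if (is.null(window)) stop("window is required to encode outcomes", call. = FALSE)
    purrr::map_dfr(ids, function(id) {
      static_table(list(build_noutcome(hr_events[hr_events$nurse_id == id, ],
                                       schemas$noutcome, id, window)))
    })
  }
  assemble_cohort(traj, ntype, npanel, noutcome, grid, task_vs, schemas)
}

#' Run pipeline stages on disk
#'
#' Stage-wise commands mirroring the modelling pipeline
#' (simulate -> encode -> cluster -> enrich -> report), each reading its
#' predecessor's directory and writing plain-text artifacts stamped with the
#' seed and a config hash. Real audit data can replace the simulator at the
#' encode boundary.
#'
#' @param config For `run_simulate()`, a [sim_config()].
#' @param out_dir Output directory.
#' @return The output directory, invisibly.
#' @export
run_simulate <- function(config = sim_config(), out_dir) {
  bundle <- simulate_cohort(config)
  write_sim_bundle(bundle, out_dir)
  write_stamp(out_dir, config$seed, config[c("n_nurses", "weights", "rate", "seed")])
  message("simulated ", config$n_nurses, " nurses, ", nrow(bundle$events),
          " audit events -> ", out_dir)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param in_dir Directory holding the previous stage's outputs.
#' @param grid Grid for encoding; when `NULL`, read from `sim_config.json` in
#'   `in_dir`.
#' @param window Outcome window; when `NULL`, read from `sim_config.json`.
#' @export
run_encode <- function(in_dir, out_dir, grid = NULL, window = NULL) {
  need <- file.path(in_dir, "audit.csv")
  if (!file.exists(need)) {
    stop("no audit.csv in ", in_dir, "; run the simulate stage (or point ",
         "in_dir at a real extract) first", call. = FALSE)
  }
  if (is.null(grid) || is.null(window)) {
    cfg_path <- file.path(in_dir, "sim_config.json")
    if (!file.exists(cfg_path)) {
      stop("pass grid and window explicitly when in_dir has no sim_config.json",
           call. = FALSE)
    }
    cfg <- jsonlite::read_json(cfg_path, simplifyVector = FALSE)
    if (is.null(grid)) {
      grid <- time_grid(lubridate::ymd_hms(cfg$grid$start, tz = cfg$grid$tz),
                        cfg$grid$resolution_s, cfg$grid$n_intervals)
    }
    if (is.null(window)) window <- as.Date(unlist(cfg$window))
  }
  events <- read_audit_log(need)
  read_aux <- function(name, types) {
    p <- file.path(in_dir, name)
    if (file.exists(p)) readr::read_csv(p, col_types = types, progress = FALSE)
  }
  cohort <- encode_cohort(
    events, grid,
    hr = read_aux("hr.csv", "iic"),
    hr_events = read_aux("hr_events.csv", "iDc"),
    adt = read_aux("adt.csv", "iccd"),
    window = window)
  write_cohort(cohort, out_dir)
  write_stamp(out_dir, NA, list(in_dir = in_dir,
                                n_nurses = cohort_size(cohort)))
  message("encoded ", cohort_size(cohort), " nurses -> ", out_dir)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param k Number of clusters; give either `k` or `k_range`.
#' @param k_range Candidate k values for silhouette-based selection.
#' @param seed Seed recorded with the clustering.
#' @export
run_cluster <- function(in_dir, out_dir, k = NULL, k_range = NULL, seed = 1L) {
  cohort <- read_cohort(in_dir)
  D <- trajectory_distances(cohort)
  if (is.null(k)) {
    if (is.null(k_range)) stop("give k or k_range", call. = FALSE)
    k <- select_k(D, k_range, seed = seed)
  }
  cl <- cluster_trajectories(D, k, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cl$labels, file.path(out_dir, "clusters.csv"))
  readr::write_csv(cl$medoids, file.path(out_dir, "medoids.csv"))
  jsonlite::write_json(list(k = cl$k, objective = cl$objective,
                            silhouette = cl$silhouette, seed = cl$seed),
                       file.path(out_dir, "metrics.json"), auto_unbox = TRUE,
                       digits = NA)
  write_stamp(out_dir, seed, list(k = cl$k, in_dir = in_dir))
  message("clustered into k = ", cl$k, " -> ", out_dir)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param cohort_dir Directory with the encoded cohort bundle.
#' @param n_perm Permutations for numeric enrichment tests.
#' @export
run_enrich <- function(cohort_dir, in_dir, out_dir, n_perm = 999L, seed = 1L) {
  cohort <- read_cohort(cohort_dir)
  cl_path <- file.path(in_dir, "clusters.csv")
  if (!file.exists(cl_path)) {
    stop("no clusters.csv in ", in_dir, "; run the cluster stage first",
         call. = FALSE)
  }
  labels <- readr::read_csv(cl_path, col_types = "ii", progress = FALSE)
  medoids <- readr::read_csv(file.path(in_dir, "medoids.csv"),
                             col_types = "ii", progress = FALSE)
  cl <- structure(list(labels = labels, medoids = medoids,
                       k = max(labels$cluster), seed = seed),
                  class = "rn_clustering")
  enr <- enrichment_report(cl, cohort, n_perm = n_perm, seed = seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tidy(enr), file.path(out_dir, "enrichment.csv"))
  rates <- purrr::map_dfr(
    cohort$schemas$noutcome$elements$element[
      cohort$schemas$noutcome$elements$type == "boolean"],
    function(el) dplyr::mutate(
      cluster_conditional_rates(cl, cohort, el), element = el,
      .before = 1))
  readr::write_csv(rates, file.path(out_dir, "rates.csv"))
  write_stamp(out_dir, seed, list(n_perm = n_perm))
  message(sum(enr$q < 0.05, na.rm = TRUE), " enrichment(s) at q < 0.05 -> ",
          out_dir)
  invisible(out_dir)
}

#' @rdname run_simulate
#' @param enrich_dir Directory with the enrichment stage outputs.
#' @param cluster_dir Directory with the cluster stage outputs.
#' @param top Number of top enrichments to show.
#' @export
run_report <- function(cohort_dir, cluster_dir, enrich_dir, out_dir, top = 10L) {
  cohort <- read_cohort(cohort_dir)
  labels <- readr::read_csv(file.path(cluster_dir, "clusters.csv"),
                            col_types = "ii", progress = FALSE)
  medoids <- readr::read_csv(file.path(cluster_dir, "medoids.csv"),
                             col_types = "ii", progress = FALSE)
  enr <- readr::read_csv(file.path(enrich_dir, "enrichment.csv"),
                         col_types = readr::cols(), progress = FALSE)
  lines <- c(
    "Cohort trajectory report",
    "========================",
    paste0("nurses: ", cohort_size(cohort), "; intervals: ",
           cohort$grid$n_intervals, " x ", cohort$grid$resolution, " s"),
    "",
    "Cluster sizes:",
    paste0("  cluster ", sort(unique(labels$cluster)), ": ",
           table(labels$cluster), " nurses"),
    "",
    "Medoid trajectories (archetypical patterns):")
  for (i in seq_len(nrow(medoids))) {
    codes <- cohort$trajectories$code[
      cohort$trajectories$nurse_id == medoids$nurse_id[i]]
    lines <- c(lines, paste0("  cluster ", medoids$cluster[i], ": ",
                             to_printed_tuple(new_ntask(medoids$nurse_id[i],
                                                        codes, cohort$grid))))
  }
  shown <- utils::head(enr[!is.na(enr$q), ], top)
  lines <- c(lines, "", paste0("Top ", nrow(shown), " enrichments (by q):"),
             sprintf("  cluster %d %s %s%s: effect %+.3f (%s), p = %.3g, q = %.3g",
                     shown$cluster, shown$family, shown$element,
                     ifelse(is.na(shown$level), "", paste0("=", shown$level)),
                     shown$effect, shown$direction, shown$p, shown$q))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(lines, file.path(out_dir, "report.txt"))
  write_stamp(out_dir, NA, list(cohort_dir = cohort_dir, top = top))
  message("report -> ", file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

write_stamp <- function(dir, seed, config) {
  jsonlite::write_json(
    list(seed = seed, config_hash = rlang::hash(config),
         package_version = as.character(utils::packageVersion("rnteract"))),
    file.path(dir, "stamp.json"), auto_unbox = TRUE, null = "null")
  invisible(NULL)
}
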