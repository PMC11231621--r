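#' Build a static NType vector
#'
#' NType holds intrinsic and situational characteristics of the nurse
#' (employment length, accreditation, average weekly hours, primary
#' assignment, ...) placed in schema order. The families are deliberately
#' time-independent: their variation is much slower than the interval-level
#' NTask signal, so the cohort stores exactly one tuple per nurse per family.
#' Missing elements are kept as explicit `NA`s, never imputed — auxiliary HR
#' or scheduling sources are often absent.
#'
#' @param attributes Named list/vector of attribute values; names must match
#'   schema element names. Omitted elements are flagged missing.
#' @param schema The family's [attribute_schema()].
#' @param nurse_id Positive integer nurse id.
#' @return An object of class `rn_static` (and `rn_ntype`).
#' @examples
#' build_ntype(
#'   list(employment_years = 5, accreditation = "RN",
#'        avg_hours_per_week = 48, primary_assignment = "OR"),
#'   default_ntype_schema(), 55
#' )
#' @export
build_ntype <- function(attributes, schema = default_ntype_schema(), nurse_id) {
  new_static(attributes, schema, nurse_id, "rn_ntype")
}

new_static <- function(attributes, schema, nurse_id, subclass) {
  stopifnot(inherits(schema, "rn_schema"))
  attributes <- as.list(attributes)
  extra <- setdiff(names(attributes), schema$elements$element)
  if (length(extra)) {
    stop("attribute(s) not in schema '", schema$name, "': ",
         paste(shQuote(extra), collapse = ", "), call. = FALSE)
  }
  values <- purrr::pmap(schema$elements, function(element, type, value_set) {
    coerce_value(attributes[[element]], type, value_set, element)
  })
  names(values) <- schema$elements$element
  structure(list(nurse_id = as.integer(nurse_id), values = values,
                 schema = schema),
            class = c(subclass, "rn_static"))
}

coerce_value <- function(x, type, value_set, element) {
  if (is.null(x) || (length(x) == 1L && is.na(x))) {
    return(switch(type, integer = NA_integer_, real = NA_real_,
                  categorical = NA_character_, boolean = NA))
  }
  stopifnot(length(x) == 1L)
  switch(type,
    integer = {
      if (is.character(x) || (is.numeric(x) && abs(x - round(x)) > 1e-8)) {
        stop("element '", element, "' must be an integer; got ",
             deparse(x), call. = FALSE)
      }
      as.integer(round(x))
    },
    real = {
      if (!is.numeric(x)) {
        stop("element '", element, "' must be numeric; got ", deparse(x),
             call. = FALSE)
      }
      as.numeric(x)
    },
    categorical = {
      x <- as.character(x)
      if (!is.null(value_set) && !x %in% value_set$label) {
        stop("element '", element, "' has level ", shQuote(x),
             " outside its value set (",
             paste(shQuote(value_set$label), collapse = ", "), ")",
             call. = FALSE)
      }
      x
    },
    boolean = {
      if (is.logical(x)) return(x)
      if (is.character(x) && toupper(x) %in% c("YES", "NO")) {
        return(toupper(x) == "YES")
      }
      stop("element '", element, "' must be boolean (TRUE/FALSE or YES/NO)",
           call. = FALSE)
    })
}

#' @export
print.rn_static <- function(x, ...) {
  cat("<", x$schema$name, " ", to_printed_tuple(x), ">\n", sep = "")
  invisible(x)
}

#' Build a static NPanel vector from ADT records
#'
#' NPanel summarises the flow and acuity of the patient panel assigned to a
#' nurse: counts of admissions and discharges by kind, and average length of
#' stay over patients with a recorded LOS. The default schema stores the
#' average as an integer (rounded half-to-even); with no LOS on record the
#' element is flagged missing.
#'
#' @param adt_records Tibble with columns `patient`, `kind` (one of
#'   `admit_er`, `admit_or`, `discharge_home`) and `los` (length of stay in
#'   days; `NA` unless recorded at discharge).
#' @param schema The NPanel [attribute_schema()].
#' @param nurse_id Positive integer nurse id.
#' @return An `rn_static` (and `rn_npanel`) object.
#' @examples
#' adt <- tibble::tibble(
#'   patient = c("p1", "p2", "p3"),
#'   kind = c("admit_or", "discharge_home", "discharge_home"),
#'   los = c(NA, 3, 5)
#' )
#' build_npanel(adt, nurse_id = 55)
#' @export
build_npanel <- function(adt_records, schema = default_npanel_schema(), nurse_id) {
  count_kinds <- setdiff(schema$elements$element, "avg_los")
  if (nrow(adt_records)) {
    unknown <- setdiff(unique(adt_records$kind), count_kinds)
    if (length(unknown)) {
      stop("unknown ADT event kind(s): ", paste(shQuote(unknown), collapse = ", "),
           call. = FALSE)
    }
  }
  attrs <- as.list(stats::setNames(
    vapply(count_kinds, function(k) sum(adt_records$kind == k), numeric(1)),
    count_kinds))
  los <- adt_records$los[!is.na(adt_records$los)]
  if ("avg_los" %in% schema$elements$element) {
    los_type <- schema$elements$type[schema$elements$element == "avg_los"]
    attrs$avg_los <- if (length(los) == 0L) NA else {
      m <- mean(los)
      if (los_type == "integer") round(m) else m  # round() is half-to-even
    }
  }
  new_static(attrs, schema, nurse_id, "rn_npanel")
}

#' Build a static NOutcome vector from dated HR records
#'
#' NOutcome records long-term changes in the status of the nurse over a study
#' window: boolean elements become YES iff a matching event falls in the
#' window, and `missed_days` counts distinct absence dates in the window.
#' Events outside the window are ignored (and counted in a message).
#'
#' @param hr_records Tibble with columns `date` (Date) and `kind` (an element
#'   name of the boolean outcomes, or `"absence"`).
#' @param schema The NOutcome [attribute_schema()].
#' @param nurse_id Positive integer nurse id.
#' @param window Closed date range `c(start, end)` (Dates).
#' @return An `rn_static` (and `rn_noutcome`) object.
#' @export
build_noutcome <- function(hr_records, schema = default_noutcome_schema(),
                           nurse_id, window) {
  stopifnot(length(window) == 2L)
  window <- as.Date(window)
  hr_records$date <- as.Date(hr_records$date)
  out_of_window <- hr_records$date < window[1] | hr_records$date > window[2]
  if (any(out_of_window)) {
    message(sum(out_of_window), " HR record(s) outside the outcome window ignored")
  }
  recs <- hr_records[!out_of_window, , drop = FALSE]
  bool_elems <- schema$elements$element[schema$elements$type == "boolean"]
  unknown <- setdiff(unique(recs$kind), c(bool_elems, "absence"))
  if (length(unknown)) {
    stop("unknown HR event kind(s): ", paste(shQuote(unknown), collapse = ", "),
         call. = FALSE)
  }
  attrs <- as.list(stats::setNames(
    lapply(bool_elems, function(k) any(recs$kind == k)), bool_elems))
  if ("missed_days" %in% schema$elements$element) {
    attrs$missed_days <- length(unique(recs$date[recs$kind == "absence"]))
  }
  new_static(attrs, schema, nurse_id, "rn_noutcome")
}

#' Printed-tuple display form
#'
#' Renders a vector in the conventional display format `(id, v1, ..., vn)`:
#' booleans as YES/NO, categoricals by label, numbers as printed.
#' [parse_printed_tuple()] inverts it given the family's schema (or the task
#' value set for trajectories).
#'
#' @param x An `rn_ntask` or `rn_static` vector.
#' @return A string like `"(55, 2, 1, 1, 1, 3)"`.
#' @export
to_printed_tuple <- function(x) UseMethod("to_printed_tuple")

#' @export
to_printed_tuple.rn_ntask <- function(x) {
  paste0("(", paste(c(x$nurse_id, x$codes), collapse = ", "), ")")
}

#' @export
to_printed_tuple.rn_static <- function(x) {
  shown <- purrr::map2_chr(x$values, x$schema$elements$type, format_value)
  paste0("(", paste(c(x$nurse_id, shown), collapse = ", "), ")")
}

format_value <- function(v, type) {
  if (length(v) != 1L || is.na(v)) return("NA")
  switch(type,
    boolean = if (isTRUE(v)) "YES" else "NO",
    categorical = as.character(v),
    format(v, trim = TRUE, scientific = FALSE, drop0trailing = TRUE))
}

#' @rdname to_printed_tuple
#' @param s A printed-tuple string.
#' @param schema For static families, the [attribute_schema()]; leave `NULL`
#'   for task trajectories.
#' @param grid For task trajectories, the [time_grid()] the codes live on.
#' @export
parse_printed_tuple <- function(s, schema = NULL, grid = NULL) {
  body <- stringr::str_match(stringr::str_trim(s), "^\\((.*)\\)$")[, 2]
  if (is.na(body)) stop("not a printed tuple: ", shQuote(s), call. = FALSE)
  parts <- stringr::str_trim(stringr::str_split_1(body, ","))
  nurse_id <- as.integer(parts[1])
  vals <- parts[-1]
  if (is.null(schema)) {
    if (is.null(grid)) grid <- time_grid(lubridate::origin, 3600, length(vals))
    return(new_ntask(nurse_id, as.integer(vals), grid))
  }
  if (length(vals) != schema_dim(schema)) {
    stop("tuple has ", length(vals), " elements; schema '", schema$name,
         "' expects ", schema_dim(schema), call. = FALSE)
  }
  attrs <- purrr::map2(vals, schema$elements$type, function(v, type) {
    if (v == "NA") return(NA)
    switch(type, integer = as.integer(v), real = as.numeric(v),
           boolean = v, categorical = v)
  })
  names(attrs) <- schema$elements$element
  new_static(attrs, schema, nurse_id,
             paste0("rn_", schema$name))
}

#' Collect static vectors into a tidy table
#'
#' @param vectors A list of `rn_static` objects sharing one schema.
#' @return A tibble with `nurse_id` plus one column per schema element.
#' @export
static_table <- function(vectors) {
  stopifnot(length(vectors) > 0L)
  schema <- vectors[[1]]$schema
  purrr::map_dfr(vectors, function(v) {
    stopifnot(identical(v$schema$elements$element, schema$elements$element))
    tibble::as_tibble(c(list(nurse_id = v$nurse_id),
                        lapply(v$values, function(x) x %||% NA)))
  })
}

#' Assemble an id-aligned cohort
#'
#' The task trajectories are the spine: every nurse appearing in a static
#' family must have a trajectory, all trajectories share one grid, and nurses
#' missing a static family carry fully `NA` rows (explicitly flagged, never
#' imputed).
#'
#' @param trajectories Long tibble (`nurse_id`, `interval`, `code`) as
#'   produced by [encode_trajectories()], or a list of `rn_ntask` objects.
#' @param ntype,npanel,noutcome Tibbles from [static_table()] (or `NULL`).
#' @param grid The shared [time_grid()].
#' @param task_vs Task value set used for the codes.
#' @param schemas Named list of the three family schemas.
#' @return An object of class `rn_cohort`.
#' @export
assemble_cohort <- function(trajectories, ntype = NULL, npanel = NULL,
                            noutcome = NULL, grid,
                            task_vs = default_task_value_set(),
                            schemas = list(ntype = default_ntype_schema(),
                                           npanel = default_npanel_schema(),
                                           noutcome = default_noutcome_schema())) {
  if (is.list(trajectories) && !is.data.frame(trajectories)) {
    grids_ok <- vapply(trajectories, function(nt) {
      identical(nt$grid$resolution, grid$resolution) &&
        identical(nt$grid$n_intervals, grid$n_intervals) &&
        nt$grid$start == grid$start
    }, logical(1))
    if (!all(grids_ok)) stop("all NTask vectors must share the cohort grid", call. = FALSE)
    trajectories <- purrr::map_dfr(trajectories, function(nt) {
      tibble::tibble(nurse_id = nt$nurse_id, interval = seq_along(nt$codes),
                     code = nt$codes)
    })
  }
  trajectories <- tibble::as_tibble(trajectories)
  ids <- sort(unique(trajectories$nurse_id))
  per_nurse <- dplyr::count(trajectories, .data$nurse_id)
  if (any(per_nurse$n != grid$n_intervals)) {
    stop("every trajectory must have exactly n_intervals = ", grid$n_intervals,
         " rows per nurse", call. = FALSE)
  }
  if (!all(trajectories$code %in% task_vs$code)) {
    stop("trajectory codes outside the task value set", call. = FALSE)
  }
  statics <- list(ntype = ntype, npanel = npanel, noutcome = noutcome)
  statics <- purrr::imap(statics, function(tbl, fam) {
    align_static(tbl, schemas[[fam]], ids, fam)
  })
  structure(list(trajectories = dplyr::arrange(trajectories, .data$nurse_id,
                                               .data$interval),
                 ntype = statics$ntype, npanel = statics$npanel,
                 noutcome = statics$noutcome,
                 grid = grid, task_vs = task_vs, schemas = schemas),
            class = "rn_cohort")
}

align_static <- function(tbl, schema, ids, fam) {
  empty <- tibble::as_tibble(c(
    list(nurse_id = ids),
    stats::setNames(purrr::map(schema$elements$type, function(tp) {
      rep(switch(tp, integer = NA_integer_, real = NA_real_,
                 categorical = NA_character_, boolean = NA), length(ids))
    }), schema$elements$element)))
  if (is.null(tbl)) return(empty)
  tbl <- tibble::as_tibble(tbl)
  if (anyDuplicated(tbl$nurse_id)) {
    stop("duplicate nurse_id in ", fam, " table", call. = FALSE)
  }
  orphans <- setdiff(tbl$nurse_id, ids)
  if (length(orphans)) {
    stop("nurse id(s) in ", fam, " without a task trajectory: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(schema$elements$element, names(tbl))
  if (length(missing_cols)) {
    stop(fam, " table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- dplyr::rows_update(empty, tbl[c("nurse_id", schema$elements$element)],
                            by = "nurse_id")
  n_missing <- length(ids) - nrow(tbl)
  if (n_missing > 0L) {
    message(n_missing, " nurse(s) without ", fam, " attributes (flagged missing)")
  }
  out
}

#' @export
print.rn_cohort <- function(x, ...) {
  n <- length(unique(x$trajectories$nurse_id))
  cat("<cohort: ", n, " nurses, ", x$grid$n_intervals, " intervals of ",
      x$grid$resolution, " s>\n", sep = "")
  for (fam in c("ntype", "npanel", "noutcome")) {
    cov <- mean(stats::complete.cases(x[[fam]][-1]))
    cat("  ", fam, ": ", sprintf("%.0f%%", 100 * cov), " complete\n", sep = "")
  }
  invisible(x)
}

#' Number of nurses in a cohort
#' @param cohort An `rn_cohort`.
#' @return Integer.
#' @export
cohort_size <- function(cohort) length(unique(cohort$trajectories$nurse_id))

#' Numeric export of a cohort
#'
#' Applies the table transformation to every categorical and boolean static
#' element (booleans as NO=0/YES=1; categoricals through their value set's
#' codes, or a first-seen-order table when no value set is declared) so the
#' static families contain only numbers and are consumable by any numeric ML
#' method.
#'
#' @param cohort An `rn_cohort`.
#' @return Named list of tibbles `ntype`, `npanel`, `noutcome` with all-numeric
#'   non-id columns, plus `trajectories` (already numeric).
#' @export
cohort_to_numeric <- function(cohort) {
  numify <- function(tbl, schema) {
    for (i in seq_len(schema_dim(schema))) {
      el <- schema$elements$element[i]
      type <- schema$elements$type[i]
      if (type == "boolean") {
        tbl[[el]] <- table_transform(ifelse(is.na(tbl[[el]]), NA,
                                            ifelse(tbl[[el]], "YES", "NO")),
                                     c(NO = 0L, YES = 1L))
      } else if (type == "categorical") {
        vs <- schema$elements$value_set[[i]]
        mapping <- if (!is.null(vs)) stats::setNames(vs$code, vs$label) else {
          lv <- unique(stats::na.omit(tbl[[el]]))
          stats::setNames(seq_along(lv), lv)
        }
        tbl[[el]] <- table_transform(tbl[[el]], mapping)
      }
    }
    tbl
  }
  list(trajectories = cohort$trajectories,
       ntype = numify(cohort$ntype, cohort$schemas$ntype),
       npanel = numify(cohort$npanel, cohort$schemas$npanel),
       noutcome = numify(cohort$noutcome, cohort$schemas$noutcome))
}

#' Write / read a cohort bundle
#'
#' The bundle is plain text: `trajectories.csv` (long format), one CSV per
#' static family, and a `model.json` sidecar carrying the grid, the task
#' value set and the three schemas, so the round trip is lossless.
#'
#' @param cohort An `rn_cohort`.
#' @param dir Directory (created if needed).
#' @return `write_cohort()` returns `dir` invisibly; `read_cohort()` returns
#'   the reconstructed `rn_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(cohort$trajectories, file.path(dir, "trajectories.csv"))
  for (fam in c("ntype", "npanel", "noutcome")) {
    tbl <- cohort[[fam]]
    bools <- cohort$schemas[[fam]]$elements$element[
      cohort$schemas[[fam]]$elements$type == "boolean"]
    for (b in bools) tbl[[b]] <- ifelse(is.na(tbl[[b]]), NA,
                                        ifelse(tbl[[b]], "YES", "NO"))
    readr::write_csv(tbl, file.path(dir, paste0(fam, ".csv")), na = "")
  }
  sidecar <- list(
    grid = list(start = format(cohort$grid$start, "%Y-%m-%dT%H:%M:%S"),
                tz = attr(cohort$grid$start, "tzone") %||% "UTC",
                resolution_s = cohort$grid$resolution,
                n_intervals = cohort$grid$n_intervals),
    task_value_set = list(name = attr(cohort$task_vs, "name"),
                          kind = attr(cohort$task_vs, "kind"),
                          entries = as.data.frame(cohort$task_vs)),
    schemas = purrr::map(cohort$schemas, schema_to_list)
  )
  jsonlite::write_json(sidecar, file.path(dir, "model.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

schema_to_list <- function(schema) {
  list(name = schema$name,
       elements = purrr::pmap(schema$elements, function(element, type, value_set) {
         e <- list(element = element, type = type)
         if (!is.null(value_set)) {
           e$value_set <- list(name = attr(value_set, "name"),
                               kind = attr(value_set, "kind"),
                               entries = as.data.frame(value_set))
         }
         e
       }))
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  sidecar_path <- file.path(dir, "model.json")
  if (!file.exists(sidecar_path)) {
    stop("cohort bundle at ", dir, " has no model.json sidecar", call. = FALSE)
  }
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = FALSE)
  grid <- time_grid(lubridate::ymd_hms(sc$grid$start, tz = sc$grid$tz),
                    sc$grid$resolution_s, sc$grid$n_intervals)
  task_vs <- value_set(sc$task_value_set$name, sc$task_value_set$kind,
                       entries_from_json(sc$task_value_set$entries))
  schemas <- purrr::map(sc$schemas, schema_from_json)
  traj <- readr::read_csv(file.path(dir, "trajectories.csv"),
                          col_types = "iii", progress = FALSE)
  statics <- purrr::imap(schemas, function(schema, fam) {
    path <- file.path(dir, paste0(fam, ".csv"))
    if (!file.exists(path)) stop("bundle is missing ", fam, ".csv", call. = FALSE)
    spec <- paste0("i", paste(vapply(schema$elements$type, function(tp)
      switch(tp, integer = "i", real = "d", "c"), character(1)), collapse = ""))
    tbl <- readr::read_csv(path, col_types = spec, na = c("", "NA"),
                           progress = FALSE)
    if (!identical(names(tbl), c("nurse_id", schema$elements$element))) {
      stop(fam, ".csv columns do not match the sidecar schema", call. = FALSE)
    }
    bools <- schema$elements$element[schema$elements$type == "boolean"]
    for (b in bools) tbl[[b]] <- dplyr::case_when(
      is.na(tbl[[b]]) ~ NA, tbl[[b]] == "YES" ~ TRUE, tbl[[b]] == "NO" ~ FALSE)
    tbl
  })
  assemble_cohort(traj, statics$ntype, statics$npanel, statics$noutcome,
                  grid, task_vs, schemas)
}

schema_from_json <- function(x) {
  elements <- purrr::map_dfr(x$elements, function(e) {
    vs <- if (!is.null(e$value_set))
      value_set(e$value_set$name, e$value_set$kind,
                entries_from_json(e$value_set$entries))
    tibble::tibble(element = e$element, type = e$type, value_set = list(vs))
  })
  attribute_schema(x$name, elements)
}

entries_from_json <- function(entries) {
  purrr::map_dfr(entries, function(e) {
    tibble::tibble(code = as.integer(e$code), label = e$label,
                   description = e$description %||% NA_character_)
  })
}
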