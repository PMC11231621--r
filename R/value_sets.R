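#' Define a value set
#'
#' A value set is an ordered code/label mapping that fixes the semantics of
#' one vector family's entries: task codes for the temporal NTask vectors, or
#' level codes for a categorical attribute. Task value sets must use
#' consecutive integer codes starting at 1, so that the idle/no-interaction
#' state is always code 1 and the codes form the range `1..length(entries)`.
#'
#' @param name Name of the value set.
#' @param kind Either `"task"` (codes are consecutive integers starting at 1)
#'   or `"attribute"` (arbitrary positive integer codes; entry order defines
#'   vector position).
#' @param entries A data frame with columns `code` (positive integer),
#'   `label` (non-empty string) and optionally `description`.
#' @return An object of class `rn_value_set`: a tibble of entries with
#'   `name` and `kind` attributes.
#' @examples
#' vs <- value_set(
#'   "ehr_tasks", "task",
#'   data.frame(
#'     code = 1:3,
#'     label = c("no EHR interaction", "read EHR data", "input EHR data")
#'   )
#' )
#' vs_encode(vs, "input EHR data")
#' @export
value_set <- function(name, kind = c("task", "attribute"), entries) {
  kind <- match.arg(kind)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  entries <- tibble::as_tibble(entries)
  if (nrow(entries) == 0L) {
    stop("value set '", name, "' must have at least one entry", call. = FALSE)
  }
  if (!all(c("code", "label") %in% names(entries))) {
    stop("entries must have columns 'code' and 'label'", call. = FALSE)
  }
  if (!"description" %in% names(entries)) entries$description <- NA_character_
  entries <- entries[c("code", "label", "description")]
  entries$code <- vctrs::vec_cast(entries$code, integer())
  entries$label <- as.character(entries$label)
  if (anyNA(entries$code) || any(entries$code < 1L)) {
    stop("codes must be positive integers", call. = FALSE)
  }
  if (any(!nzchar(entries$label)) || anyNA(entries$label)) {
    stop("labels must be non-empty strings", call. = FALSE)
  }
  dup_code <- entries$code[duplicated(entries$code)]
  if (length(dup_code)) {
    stop("duplicate code(s) in value set '", name, "': ",
         paste(unique(dup_code), collapse = ", "), call. = FALSE)
  }
  dup_lab <- entries$label[duplicated(entries$label)]
  if (length(dup_lab)) {
    stop("duplicate label(s) in value set '", name, "': ",
         paste(unique(dup_lab), collapse = ", "), call. = FALSE)
  }
  if (kind == "task" && !identical(sort(entries$code), seq_len(nrow(entries)))) {
    stop("task value set codes must be the consecutive integers 1..",
         nrow(entries), "; got: ", paste(entries$code, collapse = ", "),
         call. = FALSE)
  }
  structure(entries, name = name, kind = kind,
            class = c("rn_value_set", class(entries)))
}

#' @export
print.rn_value_set <- function(x, ...) {
  cat("<value set '", attr(x, "name"), "' (", attr(x, "kind"), "), ",
      nrow(x), " entries>\n", sep = "")
  for (i in seq_len(nrow(x))) cat("  ", x$code[i], " = ", x$label[i], "\n", sep = "")
  invisible(x)
}

#' Default task value set
#'
#' The three-level EHR-interaction taxonomy: 1 = no EHR interaction,
#' 2 = read EHR data, 3 = input EHR data. This is the default granularity at
#' which nurse-EHR interactions are encoded; callers studying specific
#' workflows can define finer task sets.
#'
#' @return An `rn_value_set` of kind `"task"`.
#' @export
default_task_value_set <- function() {
  value_set(
    "ehr_tasks", "task",
    tibble::tibble(
      code = 1:3,
      label = c("no EHR interaction", "read EHR data", "input EHR data"),
      description = c("no audit-log activity in the interval",
                      "data review (chart access without documentation)",
                      "documentation entered into the record")
    )
  )
}

#' Encode labels to codes / decode codes to labels
#'
#' `vs_encode()` maps labels to their integer codes; `vs_decode()` is its
#' inverse. Both are vectorised and fail loudly on unknown values.
#'
#' @param vs An `rn_value_set`.
#' @param labels Character vector of labels present in `vs`.
#' @param codes Integer vector of codes present in `vs`.
#' @return Integer codes (`vs_encode`) or character labels (`vs_decode`).
#' @export
vs_encode <- function(vs, labels) {
  stopifnot(inherits(vs, "rn_value_set"))
  idx <- match(labels, vs$label)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop("unknown label(s) in value set '", attr(vs, "name"), "': ",
         paste(shQuote(bad), collapse = ", "),
         "; available: ", paste(shQuote(vs$label), collapse = ", "),
         call. = FALSE)
  }
  vs$code[idx]
}

#' @rdname vs_encode
#' @export
vs_decode <- function(vs, codes) {
  stopifnot(inherits(vs, "rn_value_set"))
  idx <- match(codes, vs$code)
  if (anyNA(idx)) {
    bad <- unique(codes[is.na(idx)])
    stop("unknown code(s) in value set '", attr(vs, "name"), "': ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  vs$label[idx]
}

#' Table transformation of categorical values
#'
#' Renders a categorical variable numeric by elementwise substitution through
#' an injective label-to-integer table, so static vectors become consumable by
#' numeric ML methods. `inverse_table_transform()` restores the original
#' labels exactly.
#'
#' @param values Character (or factor) vector of categorical values.
#' @param mapping Named integer vector: `c(RN = 2, OR = 7)` maps label to code.
#'   Must be injective (no repeated codes).
#' @param codes Integer vector previously produced by `table_transform()`.
#' @return Integer vector (`table_transform`) or character vector
#'   (`inverse_table_transform`). `NA` values pass through as `NA`.
#' @examples
#' table_transform(c("NO", "NO", "YES"), c(NO = 0, YES = 1))
#' @export
table_transform <- function(values, mapping) {
  mapping <- check_mapping(mapping)
  values <- as.character(values)
  idx <- match(values, names(mapping))
  bad <- unique(values[is.na(idx) & !is.na(values)])
  if (length(bad)) {
    stop("value(s) not in mapping table: ", paste(shQuote(bad), collapse = ", "),
         call. = FALSE)
  }
  unname(mapping[idx])
}

#' @rdname table_transform
#' @export
inverse_table_transform <- function(codes, mapping) {
  mapping <- check_mapping(mapping)
  idx <- match(codes, mapping)
  bad <- unique(codes[is.na(idx) & !is.na(codes)])
  if (length(bad)) {
    stop("code(s) not in mapping table: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  names(mapping)[idx]
}

check_mapping <- function(mapping) {
  if (is.null(names(mapping)) || any(!nzchar(names(mapping)))) {
    stop("mapping must be a named integer vector (label -> integer)", call. = FALSE)
  }
  mapping <- vapply(mapping, function(x) as.integer(x), integer(1))
  if (anyDuplicated(names(mapping))) {
    stop("mapping has duplicate labels", call. = FALSE)
  }
  if (anyDuplicated(mapping)) {
    stop("mapping is not injective: repeated integer code(s) ",
         paste(unique(mapping[duplicated(mapping)]), collapse = ", "),
         call. = FALSE)
  }
  mapping
}

#' Define an attribute schema
#'
#' An attribute schema fixes the order, names and types of the elements of
#' one static vector family (NType, NPanel or NOutcome). The number of
#' elements is the family's dimension (M, O or P).
#'
#' @param name Schema (family) name, e.g. `"ntype"`.
#' @param elements A data frame with columns `element` (unique names),
#'   `type` (one of `"integer"`, `"real"`, `"categorical"`, `"boolean"`) and
#'   optionally `value_set` (a list column of `rn_value_set` or `NULL` for
#'   categorical elements).
#' @return An object of class `rn_schema`.
#' @export
attribute_schema <- function(name, elements) {
  elements <- tibble::as_tibble(elements)
  stopifnot(all(c("element", "type") %in% names(elements)))
  if (!"value_set" %in% names(elements)) {
    elements$value_set <- vector("list", nrow(elements))
  }
  ok_types <- c("integer", "real", "categorical", "boolean")
  if (!all(elements$type %in% ok_types)) {
    stop("element types must be one of: ", paste(ok_types, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(elements$element)) {
    stop("duplicate element names in schema '", name, "'", call. = FALSE)
  }
  structure(list(name = name, elements = elements), class = "rn_schema")
}

#' @export
print.rn_schema <- function(x, ...) {
  cat("<attribute schema '", x$name, "', dimension ", nrow(x$elements), ">\n",
      sep = "")
  cat(paste0("  ", x$elements$element, ": ", x$elements$type, collapse = "\n"), "\n")
  invisible(x)
}

#' Schema dimension
#' @param schema An `rn_schema`.
#' @return Integer number of elements.
#' @export
schema_dim <- function(schema) {
  stopifnot(inherits(schema, "rn_schema"))
  nrow(schema$elements)
}

#' Default static-vector schemas
#'
#' Shipped schemas for the three static families:
#' \describe{
#'   \item{NType}{`employment_years` (integer), `accreditation` (categorical:
#'     LPN/RN/NP), `avg_hours_per_week` (real, derivable from the audit log),
#'     `primary_assignment` (categorical unit, derivable from workstation
#'     locations).}
#'   \item{NPanel}{`admit_er`, `admit_or`, `discharge_home` (integer counts),
#'     `avg_los` (integer, average length of stay in days, rounded
#'     half-to-even).}
#'   \item{NOutcome}{`salary_increase`, `resignation`, `promotion` (boolean),
#'     `missed_days` (integer).}
#' }
#' @return An `rn_schema`.
#' @export
default_ntype_schema <- function() {
  accred <- value_set("accreditation", "attribute",
                      tibble::tibble(code = 1:3, label = c("LPN", "RN", "NP")))
  unit <- value_set("unit", "attribute",
                    tibble::tibble(code = 1:3, label = c("ICU", "MedSurg", "OR")))
  attribute_schema("ntype", tibble::tibble(
    element = c("employment_years", "accreditation", "avg_hours_per_week",
                "primary_assignment"),
    type = c("integer", "categorical", "real", "categorical"),
    value_set = list(NULL, accred, NULL, unit)
  ))
}

#' @rdname default_ntype_schema
#' @export
default_npanel_schema <- function() {
  attribute_schema("npanel", tibble::tibble(
    element = c("admit_er", "admit_or", "discharge_home", "avg_los"),
    type = c("integer", "integer", "integer", "integer")
  ))
}

#' @rdname default_ntype_schema
#' @export
default_noutcome_schema <- function() {
  attribute_schema("noutcome", tibble::tibble(
    element = c("salary_increase", "resignation", "promotion", "missed_days"),
    type = c("boolean", "boolean", "boolean", "integer")
  ))
}

#' Read / write value-set definition files
#'
#' Value sets are serialised as small YAML documents
#' `{name, kind, entries: [{code, label, description}]}` so a model can be
#' reconfigured without touching code.
#'
#' @param vs An `rn_value_set`.
#' @param path File path.
#' @return `read_value_set()` returns an `rn_value_set`; `write_value_set()`
#'   returns `path` invisibly.
#' @export
write_value_set <- function(vs, path) {
  stopifnot(inherits(vs, "rn_value_set"))
  doc <- list(
    name = attr(vs, "name"), kind = attr(vs, "kind"),
    entries = purrr::pmap(vs, function(code, label, description) {
      e <- list(code = code, label = label)
      if (!is.na(description)) e$description <- description
      e
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_value_set
#' @export
read_value_set <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!all(c("name", "kind", "entries") %in% names(doc))) {
    stop("value-set file must contain fields name, kind, entries", call. = FALSE)
  }
  entries <- purrr::map_dfr(doc$entries, function(e) {
    tibble::tibble(code = as.integer(e$code), label = e$label,
                   description = e$description %||% NA_character_)
  })
  value_set(doc$name, doc$kind, entries)
}
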