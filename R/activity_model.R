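# Activities, areas, and the discrete attribute schema the decision engine
# splits on. Everything is config-driven: the shipped defaults cover the three
# attributes a user enters when weighing two everyday tasks (which life area
# the task belongs to, how close its deadline is, and who asked for it).

#' Deadline urgency buckets, most urgent first
#'
#' Free-form calendar deadlines are discretised into five ordered buckets so
#' the tree induction only ever sees finite attribute domains. The order is
#' total: `overdue > today > within_week > later > none`.
#'
#' @format Character vector of the five bucket labels in decreasing urgency.
#' @export
DEADLINE_BUCKETS <- c("overdue", "today", "within_week", "later", "none")

#' Requester precedence used by the default weight policy
#' @format Character vector of requester labels in decreasing precedence.
#' @export
REQUESTER_LEVELS <- c("father", "mother", "someone_else", "nobody")

#' Construct an attribute schema
#'
#' A schema is an ordered set of named discrete attributes (each with a
#' duplicate-free domain of at least two values) plus the configured set of
#' activity areas. The decision engine splits only on schema attributes and
#' the quiz engine samples only configured areas.
#'
#' @param attributes Named list; each element is a character vector giving
#'   the ordered value domain of one attribute.
#' @param areas Character vector of valid area names. Defaults to the value
#'   domain of the `area` attribute when present.
#' @return An object of class `priority_schema`.
#' @examples
#' sch <- new_schema(list(
#'   area = c("academic", "leisure"),
#'   deadline_bucket = DEADLINE_BUCKETS
#' ))
#' @export
new_schema <- function(attributes, areas = NULL) {
  if (!is.list(attributes) || length(attributes) == 0) {
    abort_schema("schema must define at least one attribute")
  }
  nm <- names(attributes)
  if (is.null(nm) || any(!nzchar(nm))) {
    abort_schema("every schema attribute must be named")
  }
  if (anyDuplicated(nm)) {
    abort_schema("duplicate attribute name: %s", nm[duplicated(nm)][1])
  }
  for (a in nm) {
    dom <- attributes[[a]]
    if (!is.character(dom) || length(dom) < 2) {
      abort_schema("attribute '%s' needs a character domain with >= 2 values", a)
    }
    if (anyDuplicated(dom)) {
      abort_schema("attribute '%s' has duplicate domain values", a)
    }
  }
  if (is.null(areas)) areas <- attributes[["area"]]
  if (is.null(areas) || length(areas) == 0 || any(!nzchar(areas))) {
    abort_schema("schema must configure a non-empty set of areas")
  }
  structure(
    list(attributes = attributes, areas = as.character(areas)),
    class = "priority_schema"
  )
}

#' The default activity schema
#'
#' Three attributes: `area` (academic, personal, family, leisure),
#' `deadline_bucket` (see [DEADLINE_BUCKETS]) and `requested_by`
#' (father, mother, someone_else, nobody). Shipped as an editable JSON
#' config in `inst/extdata/default_schema.json`.
#'
#' @return A `priority_schema`.
#' @export
default_schema <- function() {
  read_schema(system.file("extdata", "default_schema.json",
    package = "prioritree", mustWork = TRUE
  ))
}

#' Read a schema from a JSON config file
#'
#' The document holds an `attributes` object (attribute name -> array of
#' domain values, order significant) and an `areas` array.
#'
#' @param path Path to a JSON schema document.
#' @return A `priority_schema`.
#' @export
read_schema <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$attributes)) abort_schema("schema file lacks 'attributes'")
  new_schema(as.list(doc$attributes), areas = doc$areas)
}

#' Write a schema to JSON
#' @param schema A `priority_schema`.
#' @param path Output file path.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "priority_schema"))
  jsonlite::write_json(
    list(attributes = schema$attributes, areas = schema$areas),
    path,
    auto_unbox = FALSE, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.priority_schema <- function(x, ...) {
  cat("<priority_schema>\n")
  cat("  areas:", paste(x$areas, collapse = ", "), "\n")
  for (a in names(x$attributes)) {
    cat(sprintf("  %s: {%s}\n", a, paste(x$attributes[[a]], collapse = ", ")))
  }
  invisible(x)
}

#' Construct an activity
#'
#' An activity is an everyday task with a unique id, a display name, and an
#' assignment of a value to every schema attribute.
#'
#' @param id Unique string identifier.
#' @param name Free-text name.
#' @param ... Attribute assignments, e.g. `area = "academic"`.
#' @param assignment Alternatively, a named list of assignments.
#' @return An object of class `activity`.
#' @examples
#' new_activity("a1", "maths homework",
#'   area = "academic", deadline_bucket = "today", requested_by = "mother"
#' )
#' @export
new_activity <- function(id, name = id, ..., assignment = NULL) {
  if (!is.character(id) || length(id) != 1 || !nzchar(id)) {
    abort_input("activity id must be a non-empty string")
  }
  asg <- assignment %||% list(...)
  asg <- lapply(asg, as.character)
  structure(
    list(id = id, name = as.character(name), assignment = asg),
    class = "activity"
  )
}

#' @export
print.activity <- function(x, ...) {
  cat(sprintf(
    "<activity %s: %s | %s>\n", x$id, x$name,
    paste(names(x$assignment), unlist(x$assignment), sep = "=", collapse = ", ")
  ))
  invisible(x)
}

#' Validate an activity against a schema
#'
#' Checks that every schema attribute is assigned exactly one value from its
#' domain. Returns a data frame of violations, one row per problem; a
#' zero-row result means the activity conforms and the decision engine will
#' never raise a domain error on it.
#'
#' @param activity An [new_activity()] object.
#' @param schema A `priority_schema`.
#' @return Data frame with columns `type` (`missing_attribute`,
#'   `unknown_attribute`, `unknown_value`), `attribute`, `value`, `message`.
#' @export
validate_activity <- function(activity, schema) {
  if (!inherits(schema, "priority_schema")) {
    abort_schema("schema must be a 'priority_schema' object")
  }
  if (!inherits(activity, "activity")) {
    abort_input("activity must be an 'activity' object")
  }
  v <- list()
  asg <- activity$assignment
  for (a in names(schema$attributes)) {
    if (is.null(asg[[a]]) || is.na(asg[[a]])) {
      v[[length(v) + 1L]] <- data.frame(
        type = "missing_attribute", attribute = a, value = NA_character_,
        message = sprintf("attribute '%s' is not assigned", a)
      )
    } else if (!asg[[a]] %in% schema$attributes[[a]]) {
      v[[length(v) + 1L]] <- data.frame(
        type = "unknown_value", attribute = a, value = asg[[a]],
        message = sprintf("value '%s' not in the domain of '%s'", asg[[a]], a)
      )
    }
  }
  for (a in setdiff(names(asg), names(schema$attributes))) {
    v[[length(v) + 1L]] <- data.frame(
      type = "unknown_attribute", attribute = a, value = asg[[a]],
      message = sprintf("attribute '%s' is not in the schema", a)
    )
  }
  if (length(v) == 0) {
    data.frame(
      type = character(), attribute = character(),
      value = character(), message = character()
    )
  } else {
    do.call(rbind, v)
  }
}

assert_valid_activity <- function(activity, schema) {
  viol <- validate_activity(activity, schema)
  if (nrow(viol) > 0) {
    abort_input(
      "activity '%s' does not conform to the schema: %s",
      activity$id, paste(viol$message, collapse = "; ")
    )
  }
  invisible(activity)
}

#' Discretise a calendar deadline into an urgency bucket
#'
#' Maps a deadline relative to a reference date onto one of the five
#' [DEADLINE_BUCKETS]: absent deadlines map to `none`; dates before the
#' reference to `overdue`; the reference day itself to `today`; the half-open
#' week `(reference, reference + 7]` to `within_week`; anything later to
#' `later`. The mapping is total and deterministic: exactly one bucket per
#' input.
#'
#' @param deadline A `Date`, an ISO-8601 date string, or `NA`/`NULL` for "no
#'   deadline".
#' @param reference The `Date` (or ISO-8601 string) "today" is measured from.
#' @return One of the five bucket labels.
#' @examples
#' bucket_deadline("2026-01-05", reference = "2026-01-02") # "within_week"
#' bucket_deadline(NA, reference = Sys.Date()) # "none"
#' @export
bucket_deadline <- function(deadline, reference = Sys.Date()) {
  ref <- as_iso_date(reference, what = "reference date")
  if (is.null(deadline) || (length(deadline) == 1 && is.na(deadline))) {
    return("none")
  }
  d <- as_iso_date(deadline, what = "deadline")
  delta <- as.integer(d - ref)
  if (delta < 0L) {
    "overdue"
  } else if (delta == 0L) {
    "today"
  } else if (delta <= 7L) {
    "within_week"
  } else {
    "later"
  }
}

as_iso_date <- function(x, what = "date") {
  if (inherits(x, "Date")) {
    if (length(x) != 1 || is.na(x)) abort_input("%s must be a single valid date", what)
    return(x)
  }
  if (!is.character(x) || length(x) != 1) {
    abort_input("%s must be a Date or an ISO-8601 string", what)
  }
  d <- tryCatch(as.Date(x, format = "%Y-%m-%d"), error = function(e) NA)
  if (is.na(d)) abort_input("invalid %s: '%s' (expected YYYY-MM-DD)", what, x)
  d
}

#' Read activities from CSV or JSON
#'
#' CSV files need columns `id`, `name` and one column per schema attribute;
#' JSON files hold an array of `{id, name, assignment}` objects.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @param schema Optional schema; when given, every activity is validated and
#'   a non-conforming file raises an input error.
#' @return List of `activity` objects.
#' @export
read_activities <- function(path, schema = NULL) {
  acts <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    lapply(doc, function(o) {
      new_activity(o$id, o$name %||% o$id,
        assignment = lapply(o$assignment, as.character)
      )
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    if (!all(c("id", "name") %in% names(df))) {
      abort_input("activity CSV needs 'id' and 'name' columns")
    }
    attr_cols <- setdiff(names(df), c("id", "name"))
    lapply(seq_len(nrow(df)), function(i) {
      new_activity(df$id[i], df$name[i],
        assignment = as.list(df[i, attr_cols, drop = FALSE])
      )
    })
  }
  if (!is.null(schema)) {
    for (a in acts) assert_valid_activity(a, schema)
  }
  acts
}

#' The default activity bank shipped with the package
#'
#' Sixteen everyday activities (four per area) used by the quiz examples and
#' the simulators; see `inst/extdata/activity_bank.csv`.
#'
#' @param schema Schema to validate against (default: [default_schema()]).
#' @return List of `activity` objects.
#' @export
default_activity_bank <- function(schema = default_schema()) {
  read_activities(
    system.file("extdata", "activity_bank.csv",
      package = "prioritree", mustWork = TRUE
    ),
    schema = schema
  )
}
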