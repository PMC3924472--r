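# Supervisor layer: an append-only log of queries and quiz answers with
# timestamps, per-area difficulty reports, and supervisor-authored custom
# questions. Persistence is JSON Lines (one record per line) with a CSV
# export for supervisors; no database required.

#' Create an empty history store
#'
#' Holds the ordered record log and the bank of supervisor-injected custom
#' questions.
#'
#' @return A `history_store`.
#' @export
new_history_store <- function() {
  structure(
    list(records = list(), custom_questions = list()),
    class = "history_store"
  )
}

#' Construct a query/quiz log record
#'
#' One timestamped entry of the supervisor history: either a balance query
#' (`kind = "query"`) or a graded quiz answer (`kind = "quiz"`). The
#' `correct` flag is present exactly for quiz records.
#'
#' @param user User id.
#' @param kind `"query"` or `"quiz"`.
#' @param activity_ids Character vector of the two activity ids involved.
#' @param winner_id Id the engine (or answer key) declared the winner.
#' @param area Area of the activities.
#' @param rationale Short text trace of the rule applied.
#' @param correct Logical flag (quiz records only; must be `NA` for queries).
#' @param timestamp ISO-8601 string or POSIXct; stored in UTC.
#' @return A `query_record`.
#' @export
new_query_record <- function(user, kind = c("query", "quiz"), activity_ids,
                             winner_id, area, rationale = "",
                             correct = NA, timestamp = Sys.time()) {
  kind <- match.arg(kind)
  if (length(activity_ids) != 2) abort_input("activity_ids must name exactly two activities")
  if (kind == "quiz" && is.na(correct)) {
    abort_input("quiz records must carry a 'correct' flag")
  }
  if (kind == "query" && !is.na(correct)) {
    abort_input("query records must not carry a 'correct' flag")
  }
  structure(
    list(
      user = as.character(user), timestamp = format_utc(timestamp),
      kind = kind, activity_ids = as.character(activity_ids),
      winner_id = as.character(winner_id), rationale = as.character(rationale),
      correct = if (kind == "quiz") isTRUE(correct) else NA,
      area = as.character(area)
    ),
    class = "query_record"
  )
}

#' Append a record to a history store
#'
#' Validates the record, then appends it; insertion order is preserved and
#' the record count grows by exactly one.
#'
#' @param store A `history_store`.
#' @param record A `query_record`.
#' @return The updated store.
#' @export
append_record <- function(store, record) {
  stopifnot(inherits(store, "history_store"))
  if (!inherits(record, "query_record")) {
    abort_input("record must be a 'query_record'")
  }
  parse_timestamp(record$timestamp) # re-validates on the way in
  if (!record$kind %in% c("query", "quiz")) {
    abort_input("unknown record kind '%s'", record$kind)
  }
  store$records[[length(store$records) + 1L]] <- record
  store
}

#' Per-area difficulty report for one user
#'
#' Counts attempts and errors over the user's quiz records only (queries
#' carry no correctness) and reports each area's error rate. An area with
#' zero attempts reports rate 0 and is ignored by hardest-area selection;
#' among attempted areas the hardest is the maximal error rate, ties broken
#' lexicographically. The attempts column always sums to the user's
#' quiz-record count.
#'
#' @param store A `history_store`.
#' @param user User id (unknown users yield an empty report).
#' @param areas Areas to report on; defaults to those seen in the user's
#'   quiz records.
#' @return An `area_report`: data frame (`area`, `attempts`, `errors`,
#'   `error_rate`) with attribute `hardest` (NA when nothing was attempted)
#'   and `user`.
#' @export
area_report <- function(store, user, areas = NULL) {
  stopifnot(inherits(store, "history_store"))
  quiz <- Filter(
    function(r) r$kind == "quiz" && r$user == user,
    store$records
  )
  seen <- vapply(quiz, function(r) r$area, character(1))
  if (is.null(areas)) areas <- sort(unique(seen))
  df <- data.frame(
    area = as.character(areas),
    attempts = vapply(areas, function(a) sum(seen == a), integer(1)),
    stringsAsFactors = FALSE
  )
  df$errors <- vapply(areas, function(a) {
    sum(vapply(quiz, function(r) r$area == a && !r$correct, logical(1)))
  }, integer(1))
  df$error_rate <- ifelse(df$attempts > 0, df$errors / pmax(df$attempts, 1L), 0)
  attempted <- df[df$attempts > 0, , drop = FALSE]
  hardest <- if (nrow(attempted) == 0) {
    NA_character_
  } else {
    cand <- attempted[attempted$error_rate == max(attempted$error_rate), "area"]
    sort(cand)[1]
  }
  structure(df, hardest = hardest, user = user, class = c("area_report", "data.frame"))
}

#' @export
print.area_report <- function(x, ...) {
  cat(sprintf("<area_report for user '%s'>\n", attr(x, "user")))
  print.data.frame(x, row.names = FALSE)
  cat("hardest area:", attr(x, "hardest"), "\n")
  invisible(x)
}

#' Add a supervisor-authored question to the store's quiz bank
#'
#' Supervisors can target a user's specific weak skills by injecting custom
#' pairwise questions; these carry `source = "supervisor"` and are served to
#' the targeted user ahead of generated questions (see
#' [pending_custom_questions()] and [gen_quiz_session()]). Both activities
#' must validate against the schema.
#'
#' @param store A `history_store`.
#' @param question A `quiz_question` with `source = "supervisor"`.
#' @param schema Schema the activities must conform to.
#' @return The updated store.
#' @export
add_custom_question <- function(store, question, schema) {
  stopifnot(inherits(store, "history_store"))
  if (!inherits(question, "quiz_question") || question$source != "supervisor") {
    abort_input("question must be a 'quiz_question' with source = 'supervisor'")
  }
  assert_valid_activity(question$a, schema)
  assert_valid_activity(question$b, schema)
  store$custom_questions[[length(store$custom_questions) + 1L]] <- question
  store
}

#' Custom questions pending for a user
#'
#' Supervisor questions with no target user apply to everyone.
#'
#' @param store A `history_store`.
#' @param user User id.
#' @return List of `quiz_question` objects, in insertion order.
#' @export
pending_custom_questions <- function(store, user) {
  stopifnot(inherits(store, "history_store"))
  Filter(
    function(q) is.null(q$user) || identical(q$user, user),
    store$custom_questions
  )
}

record_to_list <- function(r) {
  out <- list(
    user = r$user, timestamp = r$timestamp, kind = r$kind,
    activity_ids = as.list(r$activity_ids), winner_id = r$winner_id,
    rationale = r$rationale, area = r$area
  )
  if (r$kind == "quiz") out$correct <- r$correct
  out
}

record_from_list <- function(x) {
  new_query_record(
    user = x$user, kind = x$kind,
    activity_ids = unlist(x$activity_ids, use.names = FALSE),
    winner_id = x$winner_id, area = x$area,
    rationale = x$rationale %||% "",
    correct = if (identical(x$kind, "quiz")) isTRUE(x$correct) else NA,
    timestamp = x$timestamp
  )
}

activity_to_list <- function(a) {
  list(id = a$id, name = a$name, assignment = a$assignment)
}

activity_from_list <- function(x) {
  new_activity(x$id, x$name %||% x$id, assignment = lapply(x$assignment, as.character))
}

question_to_list <- function(q) {
  list(
    id = q$id, area = q$area, source = q$source, user = q$user,
    a = activity_to_list(q$a), b = activity_to_list(q$b),
    answer = unclass(q$answer)
  )
}

question_from_list <- function(x) {
  ans <- structure(x$answer, class = "priority_decision")
  new_quiz_question(
    id = x$id, a = activity_from_list(x$a), b = activity_from_list(x$b),
    area = x$area, answer = ans, source = x$source, user = x$user
  )
}

#' Write a history store as JSON Lines
#'
#' One JSON object per line; record lines carry `line_type = "record"`,
#' custom-question lines `line_type = "custom_question"`. The round trip
#' through [read_history()] is lossless on all fields.
#'
#' @param store A `history_store`.
#' @param path Output path (conventionally `.jsonl`).
#' @export
write_history <- function(store, path) {
  stopifnot(inherits(store, "history_store"))
  lines <- c(
    vapply(store$records, function(r) {
      jsonlite::toJSON(c(list(line_type = "record"), record_to_list(r)),
        auto_unbox = TRUE, null = "null", digits = NA
      )
    }, character(1)),
    vapply(store$custom_questions, function(q) {
      jsonlite::toJSON(c(list(line_type = "custom_question"), question_to_list(q)),
        auto_unbox = TRUE, null = "null", digits = NA
      )
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a history store from JSON Lines
#' @param path Path written by [write_history()].
#' @return A `history_store`.
#' @export
read_history <- function(path) {
  store <- new_history_store()
  for (line in readLines(path, warn = FALSE)) {
    if (!nzchar(trimws(line))) next
    x <- jsonlite::fromJSON(line, simplifyVector = FALSE)
    if (identical(x$line_type, "record")) {
      store$records[[length(store$records) + 1L]] <- record_from_list(x)
    } else if (identical(x$line_type, "custom_question")) {
      store$custom_questions[[length(store$custom_questions) + 1L]] <-
        question_from_list(x)
    } else {
      abort_input("unknown line type in '%s'", path)
    }
  }
  store
}

#' Export the record log as CSV (for supervisors)
#'
#' @param store A `history_store`.
#' @param path Output CSV path, or `""` for standard output.
#' @return The exported data frame, invisibly.
#' @export
export_history_csv <- function(store, path) {
  stopifnot(inherits(store, "history_store"))
  df <- history_as_df(store)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}

history_as_df <- function(store) {
  if (length(store$records) == 0) {
    return(data.frame(
      user = character(), timestamp = character(), kind = character(),
      activity_a = character(), activity_b = character(),
      winner_id = character(), correct = logical(), area = character(),
      rationale = character()
    ))
  }
  do.call(rbind, lapply(store$records, function(r) {
    data.frame(
      user = r$user, timestamp = r$timestamp, kind = r$kind,
      activity_a = r$activity_ids[1], activity_b = r$activity_ids[2],
      winner_id = r$winner_id, correct = r$correct, area = r$area,
      rationale = r$rationale, stringsAsFactors = FALSE
    )
  }))
}

#' @export
print.history_store <- function(x, ...) {
  cat(sprintf(
    "<history_store: %d records, %d custom questions>\n",
    length(x$records), length(x$custom_questions)
  ))
  invisible(x)
}
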