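# The training quiz: pairwise prioritisation questions whose selection
# adapts toward the areas where the user errs most. Adaptation uses a
# Laplace-smoothed per-area error rate, so unseen areas keep positive
# selection probability (cold start needs no minimum-history threshold).

#' Create an empty per-area difficulty profile
#'
#' Tracks attempts and errors per area. The smoothing constant `alpha`
#' regularises the error-rate estimate: each area starts as if it had seen
#' `alpha` errors in `2*alpha` attempts, so the empty profile yields a
#' uniform selection distribution and `alpha -> Inf` keeps it uniform
#' forever.
#'
#' @param areas Character vector of area names.
#' @param alpha Positive smoothing constant (default 1).
#' @return A `difficulty_profile`.
#' @export
new_difficulty_profile <- function(areas, alpha = 1) {
  if (length(areas) == 0) abort_input("areas must be non-empty")
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0) {
    abort_input("alpha must be a positive number")
  }
  structure(
    list(
      counts = data.frame(
        area = as.character(areas),
        attempts = 0L, errors = 0L,
        stringsAsFactors = FALSE
      ),
      alpha = alpha
    ),
    class = "difficulty_profile"
  )
}

#' @export
print.difficulty_profile <- function(x, ...) {
  cat(sprintf("<difficulty_profile (alpha=%g)>\n", x$alpha))
  print(x$counts, row.names = FALSE)
  invisible(x)
}

profile_row <- function(profile, area) {
  i <- match(area, profile$counts$area)
  if (is.na(i)) abort_input("area '%s' is not tracked by this profile", area)
  i
}

#' Area selection probabilities from a difficulty profile
#'
#' Each area's raw score is its Laplace-smoothed error rate
#' `(errors + alpha) / (attempts + 2*alpha)`; the probabilities are the raw
#' scores normalised to sum 1. All probabilities are strictly positive, an
#' empty history yields the uniform distribution, and (at equal attempts)
#' more errors mean strictly more probability — the quiz drifts toward the
#' areas that cause the most difficulty.
#'
#' @param profile A `difficulty_profile`.
#' @param areas Areas to distribute over (default: all tracked areas).
#' @return Named numeric vector of probabilities summing to 1.
#' @export
selection_distribution <- function(profile, areas = profile$counts$area) {
  stopifnot(inherits(profile, "difficulty_profile"))
  if (length(areas) == 0) abort_input("areas must be non-empty")
  idx <- vapply(as.character(areas), function(a) profile_row(profile, a), integer(1))
  cts <- profile$counts[idx, , drop = FALSE]
  raw <- (cts$errors + profile$alpha) / (cts$attempts + 2 * profile$alpha)
  stats::setNames(raw / sum(raw), cts$area)
}

bank_by_area <- function(bank) {
  areas <- vapply(bank, function(a) a$assignment[["area"]] %||% NA_character_,
    character(1))
  split(bank, areas)
}

#' Generate one quiz question
#'
#' Samples an area from [selection_distribution()] (restricted to areas
#' where the bank holds at least two activities), then a distinct activity
#' pair uniformly within that area. The correct answer is the decision
#' engine's verdict on the pair, so it is always reproducible from the
#' current tree. Identical seeds reproduce identical questions.
#'
#' @param bank List of `activity` objects (at least one area must hold two).
#' @param profile A `difficulty_profile`.
#' @param tree A weighted `decision_tree`.
#' @param seed Integer seed, or `NULL` to draw from the caller's RNG stream
#'   (used by session simulators that seed once for a whole session).
#' @return A `quiz_question`: id, the activity pair, area, the engine's
#'   `priority_decision` as `answer`, and `source = "generated"`.
#' @export
generate_question <- function(bank, profile, tree, seed = NULL) {
  stopifnot(inherits(profile, "difficulty_profile"), inherits(tree, "decision_tree"))
  groups <- bank_by_area(bank)
  groups <- groups[vapply(groups, length, integer(1)) >= 2]
  eligible <- intersect(profile$counts$area, names(groups))
  if (length(eligible) == 0) {
    abort_input("no area holds at least two activities")
  }
  draw <- function() {
    p <- selection_distribution(profile, eligible)
    area <- sample(names(p), 1, prob = p)
    pair <- sample(groups[[area]], 2)
    a <- pair[[1]]
    b <- pair[[2]]
    new_quiz_question(
      id = paste0("q_", area, "_", a$id, "_", b$id),
      a = a, b = b, area = area,
      answer = prioritise(tree, a, b),
      source = "generated"
    )
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Construct a quiz question
#'
#' Mostly called by [generate_question()]; supervisors use it to author
#' custom questions (`source = "supervisor"`) that [add_custom_question()]
#' injects into a user's bank. When `answer` is omitted it is computed from
#' `tree`, so supervisor questions defer to the engine by default but may
#' carry their own key.
#'
#' @param id Question identifier.
#' @param a,b The activity pair.
#' @param area Area the question exercises.
#' @param answer A `priority_decision`; computed from `tree` when `NULL`.
#' @param tree Weighted tree used when `answer` is `NULL`.
#' @param source `"generated"` or `"supervisor"`.
#' @param user Optional target user id (supervisor questions).
#' @return A `quiz_question`.
#' @export
new_quiz_question <- function(id, a, b, area, answer = NULL, tree = NULL,
                              source = c("generated", "supervisor"),
                              user = NULL) {
  source <- match.arg(source)
  if (is.null(answer)) {
    if (is.null(tree)) abort_input("either 'answer' or 'tree' must be given")
    answer <- prioritise(tree, a, b)
  }
  stopifnot(inherits(answer, "priority_decision"))
  structure(
    list(
      id = id, a = a, b = b, area = area,
      answer = answer, source = source, user = user
    ),
    class = "quiz_question"
  )
}

#' @export
print.quiz_question <- function(x, ...) {
  cat(sprintf(
    "<quiz_question %s [%s/%s]: '%s' vs '%s'>\n",
    x$id, x$area, x$source, x$a$name, x$b$name
  ))
  invisible(x)
}

#' Grade a quiz answer and update the difficulty profile
#'
#' The answer is correct iff the chosen activity is the question's winner.
#' The question's area gets one more attempt and, on a wrong answer, one
#' more error. The input profile is not modified; an updated copy is
#' returned.
#'
#' @param question A `quiz_question`.
#' @param chosen_id Id of the activity the user picked (must be one of the
#'   pair).
#' @param profile The user's `difficulty_profile`.
#' @param timestamp Answer time (default `Sys.time()`), stored as UTC.
#' @return List with `graded` (id, chosen id, `correct` flag, timestamp) and
#'   `profile` (the updated copy).
#' @export
grade_answer <- function(question, chosen_id, profile, timestamp = Sys.time()) {
  stopifnot(inherits(question, "quiz_question"), inherits(profile, "difficulty_profile"))
  if (!chosen_id %in% c(question$a$id, question$b$id)) {
    abort_input("chosen id '%s' is not part of question '%s'", chosen_id, question$id)
  }
  correct <- identical(chosen_id, question$answer$winner_id)
  i <- profile_row(profile, question$area)
  profile$counts$attempts[i] <- profile$counts$attempts[i] + 1L
  if (!correct) profile$counts$errors[i] <- profile$counts$errors[i] + 1L
  list(
    graded = structure(
      list(
        question_id = question$id, chosen_id = chosen_id,
        correct = correct, timestamp = format_utc(timestamp)
      ),
      class = "graded_answer"
    ),
    profile = profile
  )
}

format_utc <- function(t) {
  if (is.character(t)) t <- parse_timestamp(t)
  format(t, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
}

parse_timestamp <- function(x) {
  t <- tryCatch(
    as.POSIXct(x, tz = "UTC", tryFormats = c(
      "%Y-%m-%dT%H:%M:%OSZ", "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
      "%Y-%m-%d"
    )),
    error = function(e) NA
  )
  if (length(t) != 1 || is.na(t)) abort_input("unparseable timestamp: '%s'", x)
  t
}
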