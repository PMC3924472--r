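# Fixture and cohort generators. Every generator is a pure function of its
# spec and seed: labelled example tables for tree induction, simulated quiz
# sessions from per-area competence profiles, and Likert cohorts calibrated
# to printed group means/SDs — so the whole pipeline is testable without
# human subjects.

#' Enumerate the full attribute grid of a schema
#'
#' @param schema A `priority_schema`.
#' @return Data frame with one row per combination of attribute values.
#' @export
attribute_grid <- function(schema) {
  stopifnot(inherits(schema, "priority_schema"))
  g <- expand.grid(schema$attributes,
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  g[, names(schema$attributes), drop = FALSE]
}

row_activity <- function(row, id) {
  new_activity(id, id, assignment = as.list(row))
}

#' Generate labelled training examples from a ground-truth tree
#'
#' Samples attribute assignments uniformly over the schema grid, labels
#' each with the truth tree's classification, and flips each label
#' independently with probability `noise_rate`. Identical seeds give
#' identical tables.
#'
#' @param truth_tree A weighted `decision_tree` providing the ground truth.
#' @param n Number of examples (>= 1).
#' @param noise_rate Label-flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Data frame of examples (attribute columns + `label`), ready for
#'   [induce_tree()].
#' @export
gen_labeled_examples <- function(truth_tree, n, noise_rate = 0, seed = 1L) {
  stopifnot(inherits(truth_tree, "decision_tree"))
  if (!is.numeric(n) || n < 1) abort_input("n must be >= 1")
  if (!is.numeric(noise_rate) || noise_rate < 0 || noise_rate > 1) {
    abort_input("noise_rate must lie in [0, 1]")
  }
  grid <- attribute_grid(truth_tree$schema)
  withr::with_seed(seed, {
    rows <- sample.int(nrow(grid), n, replace = TRUE)
    ex <- grid[rows, , drop = FALSE]
    rownames(ex) <- NULL
    ex$label <- vapply(seq_len(n), function(i) {
      classify(truth_tree, row_activity(ex[i, names(grid)], sprintf("g%d", i)),
        validate = FALSE
      )$label
    }, character(1))
    flip <- stats::runif(n) < noise_rate
    ex$label[flip] <- ifelse(ex$label[flip] == "priority", "non_priority", "priority")
    ex
  })
}

#' Construct a simulated user competence profile
#'
#' @param user_id User id string.
#' @param accuracy Named numeric vector: per-area probability of answering
#'   a quiz question correctly, each in `[0, 1]`.
#' @return A `user_profile`.
#' @export
new_user_profile <- function(user_id, accuracy) {
  if (any(accuracy < 0) || any(accuracy > 1)) {
    abort_input("accuracies must lie in [0, 1]")
  }
  if (is.null(names(accuracy)) || any(!nzchar(names(accuracy)))) {
    abort_input("accuracy must be a named (per-area) vector")
  }
  structure(list(user_id = user_id, accuracy = accuracy), class = "user_profile")
}

#' Simulate a quiz session for a synthetic user
#'
#' Generates `n_questions` adaptive questions, answers each correctly with
#' the user's per-area accuracy, grades it (updating the difficulty profile
#' that drives the adaptation), and logs a timestamped quiz record per
#' question. Pure under `(arguments, seed)`.
#'
#' @param profile A [new_user_profile()] competence profile.
#' @param n_questions Number of questions to simulate.
#' @param bank List of `activity` objects.
#' @param tree A weighted `decision_tree`.
#' @param seed Integer seed.
#' @param alpha Smoothing constant of the adaptive selection (default 1).
#' @param custom Optional list of supervisor `quiz_question`s served (in
#'   order) before generated questions.
#' @param start_time Timestamp of the first record; one minute between
#'   records.
#' @return List: `records` (list of `query_record`), `difficulty` (the final
#'   `difficulty_profile`), `questions` (the questions asked).
#' @export
gen_quiz_session <- function(profile, n_questions, bank, tree, seed = 1L,
                             alpha = 1, custom = list(),
                             start_time = as.POSIXct("2026-01-01 09:00:00", tz = "UTC")) {
  stopifnot(inherits(profile, "user_profile"), inherits(tree, "decision_tree"))
  if (n_questions < 1) abort_input("n_questions must be >= 1")
  areas <- tree$schema$areas
  missing_acc <- setdiff(areas, names(profile$accuracy))
  if (length(missing_acc) > 0) {
    abort_input("profile lacks accuracy for area(s): %s", paste(missing_acc, collapse = ", "))
  }
  diff_prof <- new_difficulty_profile(areas, alpha = alpha)
  records <- vector("list", n_questions)
  questions <- vector("list", n_questions)
  withr::with_seed(seed, {
    for (i in seq_len(n_questions)) {
      q <- if (i <= length(custom)) {
        custom[[i]]
      } else {
        generate_question(bank, diff_prof, tree, seed = NULL)
      }
      correct <- stats::runif(1) < profile$accuracy[[q$area]]
      chosen <- if (correct) q$answer$winner_id else q$answer$loser_id
      g <- grade_answer(q, chosen, diff_prof, timestamp = start_time + 60 * (i - 1))
      diff_prof <- g$profile
      records[[i]] <- new_query_record(
        user = profile$user_id, kind = "quiz",
        activity_ids = c(q$a$id, q$b$id), winner_id = q$answer$winner_id,
        area = q$area, rationale = q$answer$rationale,
        correct = g$graded$correct, timestamp = g$graded$timestamp
      )
      questions[[i]] <- q
    }
  })
  list(records = records, difficulty = diff_prof, questions = questions)
}

#' Cohort specification for questionnaire generators
#'
#' @param groups List of group specs, each a list with `label`, `n`,
#'   `mean`, and optional `sd` (SUS) or per-factor `means` (TMBQ).
#' @param instrument `"sus"` or `"tmbq"`.
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
new_cohort_spec <- function(groups, instrument = c("sus", "tmbq"), seed = 1L) {
  instrument <- match.arg(instrument)
  if (length(groups) == 0) abort_input("spec needs at least one group")
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n) || g$n < 1) {
      abort_input("every group needs a label and n >= 1")
    }
  }
  structure(
    list(groups = groups, instrument = instrument, seed = seed),
    class = "cohort_spec"
  )
}

#' Read a cohort spec from JSON
#' @param path JSON path (`{instrument, seed, groups: [...]}`).
#' @return A `cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  new_cohort_spec(
    groups = lapply(doc$groups, function(g) {
      g$means <- if (!is.null(g$means)) lapply(g$means, as.numeric)
      g
    }),
    instrument = doc$instrument, seed = doc$seed %||% 1L
  )
}

#' The default SUS cohort spec
#'
#' Two age groups whose printed means and standard deviations the generator
#' is calibrated to: 7 respondents averaging 73.93 (sd 4.97) and 9
#' averaging 82.5 (sd 4.68) — 16 scored responses in all, pooling to
#' mean 78.75. Shipped as `inst/extdata/sus_cohort_spec.json`.
#'
#' @param seed Integer seed.
#' @return A `cohort_spec`.
#' @export
default_sus_cohort_spec <- function(seed = 1L) {
  spec <- read_cohort_spec(system.file("extdata", "sus_cohort_spec.json",
    package = "prioritree", mustWork = TRUE
  ))
  spec$seed <- seed
  spec
}

# Split an integer total into n parts, each within [lo, hi], as evenly as
# possible; the r remainder units land on a seeded random subset of parts.
split_total <- function(total, n, lo, hi) {
  total <- as.integer(round(total))
  n <- as.integer(n)
  base <- total %/% n
  r <- total %% n
  parts <- rep(base, n)
  if (r > 0) {
    bump <- sample.int(n, r)
    parts[bump] <- parts[bump] + 1L
  }
  stopifnot(all(parts >= lo), all(parts <= hi))
  parts
}

# Spread unit mass between users (keeping the sum fixed) until the sample sd
# is as close to the target as single-unit transfers allow; best-effort,
# bounded iterations.
spread_to_sd <- function(units, target_sd, unit_value, lo, hi, max_iter = 4000L) {
  if (is.null(target_sd) || is.na(target_sd) || length(units) < 2) {
    return(units)
  }
  for (iter in seq_len(max_iter)) {
    gap <- target_sd - stats::sd(units * unit_value)
    if (gap <= 0) break
    give <- which(units < hi)
    take <- which(units > lo)
    if (length(give) == 0 || length(take) == 0) break
    i <- give[sample.int(length(give), 1)]
    j <- take[sample.int(length(take), 1)]
    if (i == j || units[i] < units[j]) next # only ever widen the spread
    cand <- units
    cand[i] <- cand[i] + 1L
    cand[j] <- cand[j] - 1L
    if (abs(target_sd - stats::sd(cand * unit_value)) < gap) units <- cand else break
  }
  units
}

# Turn a SUS score expressed in contribution units (0..40) into a 10-item
# response vector via the positional scoring rule, distributing the units
# over items at random.
sus_units_to_items <- function(units) {
  contrib <- split_total(units, 10L, 0L, 4L)
  items <- integer(10)
  odd <- c(1, 3, 5, 7, 9)
  even <- c(2, 4, 6, 8, 10)
  items[odd] <- contrib[odd] + 1L
  items[even] <- 5L - contrib[even]
  items
}

#' Generate a SUS cohort calibrated to group means
#'
#' Works in score space: each group's target total is the nearest multiple
#' of 2.5 to `n * mean` (a feasibility error is raised if that total does
#' not reproduce the target mean to 2 decimal places, or the mean is off
#' scale). Per-user scores on the 2.5 grid are then spread around the
#' target (best-effort toward the group's `sd`, when given) and inverted
#' into item vectors through the positional scoring rule, so scoring the
#' generated responses reproduces the group means exactly at 2 dp.
#' Deterministic under the spec's seed.
#'
#' @param spec A `cohort_spec` with `instrument = "sus"`; group entries
#'   carry `label`, `n`, `mean` and optional `sd`.
#' @return Data frame: `group` column + `item_1..item_10`, one row per
#'   respondent.
#' @examples
#' spec <- new_cohort_spec(
#'   groups = list(
#'     list(label = "under15", n = 7, mean = 73.93, sd = 4.97),
#'     list(label = "over16", n = 9, mean = 82.5, sd = 4.68)
#'   ),
#'   instrument = "sus", seed = 42
#' )
#' cohort <- gen_sus_cohort(spec)
#' @export
gen_sus_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$instrument != "sus") abort_input("spec instrument must be 'sus'")
  withr::with_seed(spec$seed, {
    rows <- lapply(spec$groups, function(g) {
      if (g$mean < 0 || g$mean > 100) {
        abort_feasibility(
          "group '%s': target mean %.2f is outside the SUS range [0, 100]",
          g$label, g$mean
        )
      }
      target_sum <- round(g$n * g$mean / 2.5) * 2.5
      if (round(target_sum / g$n, 2) != round(g$mean, 2)) {
        abort_feasibility(
          "group '%s': n x mean = %.2f is not within rounding of a 2.5-grid total",
          g$label, g$n * g$mean
        )
      }
      units_total <- as.integer(round(target_sum / 2.5)) # per-cohort units, 0..40n
      units <- split_total(units_total, g$n, 0L, 40L)
      units <- spread_to_sd(units, g$sd %||% NULL, 2.5, 0L, 40L)
      items <- t(vapply(units, sus_units_to_items, integer(10)))
      df <- as.data.frame(items)
      names(df) <- paste0("item_", 1:10)
      cbind(data.frame(group = rep(g$label, g$n), stringsAsFactors = FALSE), df)
    })
    do.call(rbind, rows)
  })
}

#' Generate a TMBQ cohort calibrated to per-factor means
#'
#' For each group and factor, the total item mass `round(n * k * target)`
#' (k = items in the factor) is distributed over the `n x k` item cells as
#' evenly as possible, with remainder units placed at seeded random cells —
#' so every generated factor mean sits within half a unit of the target
#' (at most 0.05 off for factors with >= 10 cells, and exact for integer
#' targets). Deterministic under the spec's seed.
#'
#' @param spec A `cohort_spec` with `instrument = "tmbq"`; group entries
#'   carry `label`, `n`, and `means` — a named list/vector of per-factor
#'   target means in `[1, 5]`.
#' @param mapping Item-to-factor mapping (default [default_tmbq_mapping()]).
#' @return Data frame: `group` column + `item_1..item_34`.
#' @export
gen_tmbq_cohort <- function(spec, mapping = default_tmbq_mapping()) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (spec$instrument != "tmbq") abort_input("spec instrument must be 'tmbq'")
  mapping <- validate_tmbq_mapping(mapping)
  withr::with_seed(spec$seed, {
    rows <- lapply(spec$groups, function(g) {
      means <- unlist(g$means)
      missing_f <- setdiff(unique(mapping), names(means))
      if (length(missing_f) > 0) {
        abort_input("group '%s' lacks target means for: %s",
          g$label, paste(missing_f, collapse = ", "))
      }
      if (any(means < 1 | means > 5)) {
        abort_feasibility(
          "group '%s': factor targets must lie in [1, 5]", g$label
        )
      }
      m <- matrix(NA_integer_, nrow = g$n, ncol = 34)
      for (f in unique(mapping)) {
        cols <- which(mapping == f)
        cells <- g$n * length(cols)
        total <- as.integer(round(cells * means[[f]]))
        total <- max(cells, min(5L * cells, total))
        vals <- split_total(total, cells, 1L, 5L)
        m[, cols] <- matrix(vals, nrow = g$n)
      }
      df <- as.data.frame(m)
      names(df) <- paste0("item_", 1:34)
      cbind(data.frame(group = rep(g$label, g$n), stringsAsFactors = FALSE), df)
    })
    do.call(rbind, rows)
  })
}

#' Score every row of a generated cohort
#'
#' Convenience wrapper: applies [score_sus()] or [score_tmbq()] row-wise to
#' a cohort data frame as produced by the generators (or read from CSV).
#'
#' @param cohort Data frame with a `group` column and item columns.
#' @param instrument `"sus"` or `"tmbq"`.
#' @param mapping TMBQ mapping (ignored for SUS).
#' @return For SUS: data frame (`group`, `score`). For TMBQ: data frame
#'   (`group`, one column per factor).
#' @export
score_cohort <- function(cohort, instrument = c("sus", "tmbq"),
                         mapping = default_tmbq_mapping()) {
  instrument <- match.arg(instrument)
  item_cols <- grep("^item_", names(cohort), value = TRUE)
  items <- as.matrix(cohort[, item_cols, drop = FALSE])
  if (instrument == "sus") {
    data.frame(
      group = cohort$group,
      score = apply(items, 1, score_sus),
      stringsAsFactors = FALSE
    )
  } else {
    fs <- t(apply(items, 1, score_tmbq, mapping = mapping))
    cbind(data.frame(group = cohort$group, stringsAsFactors = FALSE),
      as.data.frame(fs))
  }
}
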