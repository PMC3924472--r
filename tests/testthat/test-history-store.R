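quiz_rec <- function(user, area, correct, ts = "2026-02-01T10:00:00Z") {
  new_query_record(
    user = user, kind = "quiz", activity_ids = c("x1", "x2"),
    winner_id = "x1", area = area, correct = correct, timestamp = ts
  )
}

test_that("records append in order and malformed records are rejected", {
  st <- new_history_store()
  st <- append_record(st, quiz_rec("u1", "academic", TRUE))
  expect_length(st$records, 1)

  st <- append_record(st, quiz_rec("u1", "leisure", FALSE, "2026-02-01T10:01:00Z"))
  st <- append_record(st, quiz_rec("u1", "family", TRUE, "2026-02-01T10:02:00Z"))
  expect_identical(
    vapply(st$records, function(r) r$area, character(1)),
    c("academic", "leisure", "family")
  )

  expect_error(
    quiz_rec("u1", "academic", TRUE, ts = "yesterday"),
    class = "prioritree_input_error"
  )
  # the correct flag is present iff the record is a quiz record
  expect_error(
    new_query_record("u1",
      kind = "quiz", activity_ids = c("a", "b"),
      winner_id = "a", area = "academic"
    ),
    class = "prioritree_input_error"
  )
  expect_error(
    new_query_record("u1",
      kind = "query", activity_ids = c("a", "b"),
      winner_id = "a", area = "academic", correct = TRUE
    ),
    class = "prioritree_input_error"
  )
})

test_that("the area report counts quiz records only and names the hardest area", {
  st <- new_history_store()
  # fixture: 4 academic attempts with 2 errors, 2 leisure with none
  for (ok in c(TRUE, TRUE, FALSE, FALSE)) st <- append_record(st, quiz_rec("u1", "academic", ok))
  for (ok in c(TRUE, TRUE)) st <- append_record(st, quiz_rec("u1", "leisure", ok))
  # noise that must not count: another user, and a plain query
  st <- append_record(st, quiz_rec("u2", "academic", FALSE))
  st <- append_record(st, new_query_record("u1",
    kind = "query", activity_ids = c("x1", "x2"), winner_id = "x1",
    area = "academic"
  ))

  rep <- area_report(st, "u1")
  expect_identical(rep$attempts[rep$area == "academic"], 4L)
  expect_identical(rep$errors[rep$area == "academic"], 2L)
  expect_equal(rep$error_rate[rep$area == "academic"], 0.5)
  expect_equal(rep$error_rate[rep$area == "leisure"], 0)
  expect_identical(attr(rep, "hardest"), "academic")
  expect_identical(sum(rep$attempts), 6L) # = u1's quiz-record count

  empty <- area_report(new_history_store(), "nobody")
  expect_identical(nrow(empty), 0L)
  expect_true(is.na(attr(empty, "hardest")))
})

test_that("attempts are conserved and reports change only in the appended area", {
  withr::with_seed(88, {
    st <- new_history_store()
    areas <- c("academic", "personal", "family", "leisure")
    for (k in 1:40) {
      st <- append_record(st, quiz_rec("u1", sample(areas, 1), sample(c(TRUE, FALSE), 1)))
    }
    rep <- area_report(st, "u1", areas = areas)
    expect_identical(sum(rep$attempts), 40L)

    before <- area_report(st, "u1", areas = areas)
    st2 <- append_record(st, quiz_rec("u1", "family", FALSE))
    after <- area_report(st2, "u1", areas = areas)
    untouched <- after$area != "family"
    expect_identical(after$attempts[untouched], before$attempts[untouched])
    expect_identical(after$errors[untouched], before$errors[untouched])
    expect_identical(after$attempts[!untouched], before$attempts[!untouched] + 1L)
  })
})

test_that("supervisor questions join the bank and grade like any other", {
  schema <- default_schema()
  tree <- default_tree(schema)
  st <- new_history_store()
  q <- new_quiz_question(
    id = "sup1",
    a = act("s1", "academic", "today", "mother"),
    b = act("s2", "academic", "none", "nobody"),
    area = "academic", tree = tree, source = "supervisor", user = "u1"
  )
  st <- add_custom_question(st, q, schema)
  expect_length(st$custom_questions, 1)
  expect_identical(st$custom_questions[[1]]$source, "supervisor")
  expect_identical(pending_custom_questions(st, "u1")[[1]]$id, "sup1")
  expect_length(pending_custom_questions(st, "someone_else"), 0)

  # a session that starts with the custom question grades it uniformly
  up <- new_user_profile("u1", stats::setNames(rep(1, 4), schema$areas))
  ses <- gen_quiz_session(up, 3, default_activity_bank(schema), tree,
    seed = 2, custom = pending_custom_questions(st, "u1")
  )
  expect_identical(ses$questions[[1]]$id, "sup1")
  expect_true(ses$records[[1]]$correct)

  bad <- new_quiz_question(
    id = "sup2",
    a = new_activity("s3", area = "sports", deadline_bucket = "today", requested_by = "mother"),
    b = act("s4"), area = "academic",
    answer = q$answer, source = "supervisor"
  )
  expect_error(add_custom_question(st, bad, schema), class = "prioritree_input_error")
  expect_error(add_custom_question(st, "not a question", schema),
    class = "prioritree_input_error"
  )
})

test_that("the JSON Lines round trip is lossless", {
  schema <- default_schema()
  tree <- default_tree(schema)
  st <- new_history_store()
  st <- append_record(st, quiz_rec("u1", "academic", TRUE))
  st <- append_record(st, new_query_record("u2",
    kind = "query", activity_ids = c("p", "q"), winner_id = "q",
    area = "leisure", rationale = "label: priority beats non_priority",
    timestamp = "2026-02-02T08:30:00Z"
  ))
  st <- add_custom_question(st, new_quiz_question(
    id = "sup1", a = act("s1"), b = act("s2", deadline = "none"),
    area = "academic", tree = tree, source = "supervisor", user = "u1"
  ), schema)

  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_history(st, tmp)
  back <- read_history(tmp)
  expect_equal(back, st)

  # CSV export carries every record with its flags
  csv <- withr::local_tempfile(fileext = ".csv")
  export_history_csv(st, csv)
  df <- utils::read.csv(csv, stringsAsFactors = FALSE)
  expect_identical(nrow(df), 2L)
  expect_identical(df$kind, c("quiz", "query"))
  expect_true(is.na(df$correct[2]))
})
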