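test_that("entropy matches its closed forms", {
  expect_identical(entropy(c(priority = 4, non_priority = 4)), 1)
  expect_identical(entropy(c(priority = 8, non_priority = 0)), 0)
  expect_equal(entropy(c(priority = 1, non_priority = 3)), 0.811278, tolerance = 1e-6)
  # label permutation invariance and the uniform k-label ceiling
  expect_equal(entropy(c(a = 2, b = 7)), entropy(c(b = 7, a = 2)))
  expect_equal(entropy(rep(5, 4)), log2(4))
  expect_error(entropy(c(0, 0)), class = "prioritree_input_error")
  expect_error(entropy(numeric(0)), class = "prioritree_input_error")
})

test_that("information gain agrees with the direct-evaluation oracle", {
  # explicit 4-example fixture, two attributes
  df <- data.frame(
    x = c("a", "a", "b", "b"),
    y = c("p", "q", "p", "q"),
    label = c("priority", "priority", "non_priority", "non_priority"),
    stringsAsFactors = FALSE
  )
  expect_equal(information_gain(df, "x"), oracle_gain(df, "x")) # perfect: 1 bit
  expect_equal(information_gain(df, "x"), entropy(table(df$label)))
  expect_equal(information_gain(df, "y"), oracle_gain(df, "y")) # useless: 0 bits
  expect_identical(information_gain(df, "y"), 0)

  df$z <- "const"
  expect_identical(information_gain(df, "z"), 0)
  expect_error(information_gain(df, "nope"), class = "prioritree_input_error")

  # non-negativity over random small tables
  withr::with_seed(404, {
    for (rep in 1:25) {
      tb <- random_table(3, 3, sample(5:30, 1))
      for (a in setdiff(names(tb$df), "label")) {
        g <- information_gain(tb$df, a)
        expect_gte(g, 0)
        expect_equal(g, oracle_gain(tb$df, a), tolerance = 1e-12)
      }
    }
  })
})

test_that("induction handles the degenerate stopping rules", {
  schema <- tiny_schema()
  pure <- data.frame(
    area = c("academic", "leisure"), deadline_bucket = c("today", "none"),
    requested_by = c("mother", "nobody"),
    label = c("priority", "priority"), stringsAsFactors = FALSE
  )
  tr <- induce_tree(pure, schema)
  expect_identical(tr$root$type, "leaf")
  expect_identical(tr$root$label, "priority")

  # duplicated assignments with conflicting labels end in a majority leaf
  clash <- data.frame(
    area = "academic", deadline_bucket = "today", requested_by = "mother",
    label = c("priority", "non_priority", "non_priority"),
    stringsAsFactors = FALSE
  )
  tr <- induce_tree(clash, schema)
  leaves <- prioritree:::collect_leaves(tr$root)
  expect_true(all(vapply(leaves, function(l) l$type == "leaf", logical(1))))
  a <- act("c1", "academic", "today", "mother")
  expect_identical(classify(assign_weights(tr), a)$label, "non_priority")

  expect_error(induce_tree(pure[0, ], schema), class = "prioritree_input_error")
})

test_that("a single perfectly separating attribute yields a depth-1 tree", {
  schema <- tiny_schema()
  df <- expand.grid(
    area = schema$attributes$area,
    deadline_bucket = schema$attributes$deadline_bucket,
    requested_by = schema$attributes$requested_by,
    stringsAsFactors = FALSE
  )
  df$label <- ifelse(df$deadline_bucket == "today", "priority", "non_priority")
  # oracle confirms deadline_bucket uniquely maximises gain at the root
  gains <- vapply(
    c("area", "deadline_bucket", "requested_by"),
    function(a) oracle_gain(df, a), numeric(1)
  )
  expect_identical(names(which.max(gains)), "deadline_bucket")
  expect_gt(gains["deadline_bucket"], max(gains[c("area", "requested_by")]))

  tr <- induce_tree(df, schema)
  expect_identical(tr$root$type, "split")
  expect_identical(tr$root$attribute, "deadline_bucket")
  expect_true(all(vapply(
    tr$root$children, function(ch) ch$type == "leaf", logical(1)
  )))
})

test_that("induction equals the brute-force greedy oracle on random tables", {
  withr::with_seed(2024, {
    for (rep in 1:40) {
      tb <- random_table(
        n_attrs = sample(2:5, 1), n_vals = sample(2:3, 1),
        n_rows = sample(4:40, 1)
      )
      got <- induce_tree(tb$df, tb$schema)
      want <- oracle_id3(tb$df, setdiff(names(tb$df), "label"), tb$schema)
      expect_true(same_tree(got$root, want))
    }
  })
})

test_that("consistent examples are reproduced exactly (resubstitution = 100%)", {
  withr::with_seed(77, {
    for (rep in 1:10) {
      tb <- random_table(3, 3, 30)
      # make labels a deterministic function of the attributes -> consistent
      key <- do.call(paste, tb$df[setdiff(names(tb$df), "label")])
      rule <- stats::setNames(
        sample(c("priority", "non_priority"), length(unique(key)), replace = TRUE),
        unique(key)
      )
      tb$df$label <- unname(rule[key])
      tr <- induce_tree(tb$df, tb$schema)
      pred <- vapply(seq_len(nrow(tb$df)), function(i) {
        tree_predict(tr, tb$df[i, setdiff(names(tb$df), "label")])
      }, character(1))
      expect_identical(pred, tb$df$label)
    }
  })
})

test_that("leaf weights are a distinct permutation of 1..n_leaves", {
  schema <- default_schema()
  tr <- default_tree(schema)
  leaves <- prioritree:::collect_leaves(tr$root)
  ws <- vapply(leaves, function(l) l$weight, integer(1))
  expect_setequal(ws, seq_along(leaves))

  withr::with_seed(9, {
    for (rep in 1:10) {
      tb <- random_table(3, 3, 25)
      wt <- assign_weights(induce_tree(tb$df, tb$schema))
      ws <- vapply(
        prioritree:::collect_leaves(wt$root), function(l) l$weight, integer(1)
      )
      expect_setequal(ws, seq_along(ws))
    }
  })
})

test_that("the default weight policy ranks priority and urgency first", {
  schema <- tiny_schema()
  df <- expand.grid(
    area = schema$attributes$area,
    deadline_bucket = schema$attributes$deadline_bucket,
    requested_by = schema$attributes$requested_by,
    stringsAsFactors = FALSE
  )
  df$label <- ifelse(df$deadline_bucket == "today", "priority", "non_priority")
  tr <- assign_weights(induce_tree(df, schema))
  expect_identical(n_leaves(tr), 2L)
  today <- classify(tr, act("t", deadline = "today"))
  none <- classify(tr, act("n", deadline = "none"))
  expect_identical(today$label, "priority")
  expect_identical(today$weight, 2L) # the today/priority leaf outranks
  expect_identical(none$weight, 1L)

  # single-leaf tree carries weight 1 and answers every conforming activity
  single <- assign_weights(induce_tree(
    data.frame(
      area = "academic", deadline_bucket = "today", requested_by = "mother",
      label = "priority", stringsAsFactors = FALSE
    ),
    schema
  ))
  expect_identical(classify(single, act("x", "leisure", "none", "nobody"))$weight, 1L)
})

test_that("classification walks the path and falls back gracefully on schema drift", {
  schema <- tiny_schema()
  df <- expand.grid(
    area = schema$attributes$area,
    deadline_bucket = schema$attributes$deadline_bucket,
    requested_by = schema$attributes$requested_by,
    stringsAsFactors = FALSE
  )
  df$label <- ifelse(df$deadline_bucket == "today", "priority", "non_priority")
  tr <- assign_weights(induce_tree(df, schema))

  res <- classify(tr, act("a", deadline = "today"))
  expect_identical(res$label, "priority")
  expect_false(res$fallback_used)
  expect_identical(res$path[[1]], c("deadline_bucket", "today"))

  drifted <- new_activity("d",
    area = "academic", deadline_bucket = "tomorrow", requested_by = "nobody"
  )
  expect_warning(
    res <- classify(tr, drifted, validate = FALSE),
    "routed to majority branch"
  )
  expect_true(res$fallback_used)
  expect_true(res$label %in% c("priority", "non_priority"))
})

test_that("pairwise prioritisation follows label, then weight, then id", {
  tr <- default_tree()
  pri <- act("a", "academic", "today", "mother")
  non <- act("b", "leisure", "none", "nobody")

  d <- prioritise(tr, pri, non)
  expect_identical(d$winner_id, "a")
  expect_identical(d$winner_label, "priority")
  expect_false(d$tie_break_used)

  # both priority: greater weight wins and the tie-break is flagged
  p1 <- act("a", "academic", "overdue", "nobody")
  p2 <- act("b", "academic", "within_week", "mother")
  d <- prioritise(tr, p1, p2)
  expect_identical(d$winner_id, "a")
  expect_true(d$tie_break_used)
  expect_gt(d$winner_weight, d$loser_weight)

  # identical assignments: deterministic id tie-break, flagged
  twin1 <- act("alpha", "family", "today", "father")
  twin2 <- act("beta", "family", "today", "father")
  d <- prioritise(tr, twin1, twin2)
  expect_identical(d$winner_id, "alpha")
  expect_true(d$tie_break_used)
  expect_match(d$rationale, "id")

  expect_error(
    prioritise(tr, act("ok"), new_activity("bad", area = "sports")),
    class = "prioritree_input_error"
  )
})

test_that("prioritisation is antisymmetric and total over a full grid", {
  schema <- tiny_schema()
  df <- expand.grid(
    area = schema$attributes$area,
    deadline_bucket = schema$attributes$deadline_bucket,
    requested_by = schema$attributes$requested_by,
    stringsAsFactors = FALSE
  )
  df$label <- ifelse(
    df$deadline_bucket == "today" | df$requested_by == "mother",
    "priority", "non_priority"
  )
  tr <- assign_weights(induce_tree(df, schema))
  grid <- attribute_grid(schema)
  acts <- lapply(seq_len(nrow(grid)), function(i) {
    new_activity(sprintf("g%02d", i), assignment = as.list(grid[i, ]))
  })
  for (i in seq_along(acts)) {
    for (j in seq_along(acts)) {
      if (i >= j) next
      fwd <- prioritise(tr, acts[[i]], acts[[j]])
      rev <- prioritise(tr, acts[[j]], acts[[i]])
      expect_identical(fwd$winner_id, rev$winner_id)
      expect_identical(fwd$loser_id, rev$loser_id)
    }
  }
})

test_that("trees survive the JSON round trip", {
  tr <- default_tree()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_tree(tr, tmp)
  back <- read_tree(tmp)
  expect_identical(n_leaves(back), n_leaves(tr))
  expect_identical(back$schema$attributes, tr$schema$attributes)
  grid <- attribute_grid(tr$schema)
  for (i in seq_len(nrow(grid))) {
    a <- new_activity(paste0("g", i), assignment = as.list(grid[i, ]))
    expect_identical(classify(back, a), classify(tr, a))
  }
})
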