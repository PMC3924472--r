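# Fixtures built in code and independent oracles the implementation is
# checked against. The oracles deliberately share no code with R/: entropy
# via table proportions, greedy induction re-derived from first principles,
# and the Mann-Whitney exact p by full enumeration of label assignments.

tiny_schema <- function() {
  new_schema(list(
    area = c("academic", "leisure"),
    deadline_bucket = c("today", "none"),
    requested_by = c("mother", "nobody")
  ))
}

act <- function(id, area = "academic", deadline = "today", req = "nobody") {
  new_activity(id, id,
    area = area, deadline_bucket = deadline, requested_by = req
  )
}

# label proportions -> bits, written as a direct transliteration of the
# closed form (no shared code path with entropy())
oracle_entropy <- function(labels) {
  p <- as.numeric(prop.table(table(labels)))
  p <- p[p > 0]
  sum(vapply(p, function(x) -x * log2(x), numeric(1)))
}

oracle_gain <- function(df, attribute) {
  n <- nrow(df)
  rest <- 0
  for (v in unique(df[[attribute]])) {
    part <- df$label[df[[attribute]] == v]
    rest <- rest + (length(part) / n) * oracle_entropy(part)
  }
  oracle_entropy(df$label) - rest
}

oracle_majority <- function(labels) {
  np <- sum(labels == "priority")
  if (np >= length(labels) - np) "priority" else "non_priority"
}

# Independent greedy ID3: recompute every gain exhaustively at every node,
# same published stopping and tie-break rules. Returns a plain nested list.
oracle_id3 <- function(df, attrs, schema, parent_majority = oracle_majority(df$label)) {
  if (nrow(df) == 0) {
    return(list(leaf = parent_majority))
  }
  if (length(unique(df$label)) == 1) {
    return(list(leaf = df$label[1]))
  }
  if (length(attrs) == 0) {
    return(list(leaf = oracle_majority(df$label)))
  }
  attrs <- sort(attrs)
  gains <- vapply(attrs, function(a) oracle_gain(df, a), numeric(1))
  best <- attrs[which.max(gains)]
  kids <- list()
  for (v in schema$attributes[[best]]) {
    kids[[v]] <- oracle_id3(
      df[df[[best]] == v, , drop = FALSE], setdiff(attrs, best), schema,
      parent_majority = oracle_majority(df$label)
    )
  }
  list(split = best, children = kids)
}

# structural equality between the package tree and the oracle tree
same_tree <- function(node, oracle) {
  if (node$type == "leaf") {
    return(!is.null(oracle$leaf) && identical(node$label, oracle$leaf))
  }
  if (is.null(oracle$split) || !identical(node$attribute, oracle$split)) {
    return(FALSE)
  }
  if (!identical(sort(names(node$children)), sort(names(oracle$children)))) {
    return(FALSE)
  }
  all(vapply(
    names(node$children),
    function(v) same_tree(node$children[[v]], oracle$children[[v]]),
    logical(1)
  ))
}

# random labelled table over a random discrete schema
random_table <- function(n_attrs, n_vals, n_rows) {
  attrs <- stats::setNames(
    lapply(seq_len(n_attrs), function(i) paste0("v", seq_len(n_vals))),
    paste0("x", seq_len(n_attrs))
  )
  schema <- new_schema(attrs, areas = "dummy")
  df <- as.data.frame(
    lapply(attrs, function(dom) sample(dom, n_rows, replace = TRUE)),
    stringsAsFactors = FALSE
  )
  df$label <- sample(c("priority", "non_priority"), n_rows, replace = TRUE)
  list(schema = schema, df = df)
}

tree_predict <- function(tree, row) {
  classify(tree, new_activity("tmp", assignment = as.list(row)),
    validate = FALSE
  )$label
}

# exact two-sided Mann-Whitney p by enumerating all C(n, na) group
# assignments of the pooled values (tie-free inputs only)
oracle_mw_exact <- function(a, b) {
  pooled <- c(a, b)
  na <- length(a)
  u_of <- function(idx) {
    sum(rank(pooled)[idx]) - na * (na + 1) / 2
  }
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(length(pooled), na), 2, u_of)
  p_le <- mean(us <= u_obs)
  p_ge <- mean(us >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

expect_no_violations <- function(activity, schema) {
  expect_identical(nrow(validate_activity(activity, schema)), 0L)
}
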