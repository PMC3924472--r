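# ID3 induction with Shannon entropy over discrete activity attributes.
# Leaves carry unique positive integer weights; pairwise prioritisation is
# decided first by label (priority beats non_priority) and then by weight.

PRIORITY_LABELS <- c("priority", "non_priority")

#' Shannon entropy of a label count vector
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i} over the labels with positive count,
#' where \eqn{p_i} is the count fraction. Measured in bits; 0 for a pure
#' set, \eqn{\log_2 k} for a uniform k-label set.
#'
#' @param counts Named (or unnamed) vector of non-negative label counts with
#'   at least one positive entry.
#' @return Entropy in bits.
#' @examples
#' entropy(c(priority = 4, non_priority = 4)) # 1
#' entropy(c(priority = 8, non_priority = 0)) # 0
#' @export
entropy <- function(counts) {
  if (length(counts) == 0 || any(counts < 0) || any(is.na(counts))) {
    abort_input("counts must be non-negative and non-missing")
  }
  total <- sum(counts)
  if (total == 0) abort_input("entropy undefined: all counts are zero")
  p <- counts[counts > 0] / total
  -sum(p * log2(p))
}

#' Information gain of splitting labelled examples on one attribute
#'
#' The ID3 split criterion: entropy of the label column minus the
#' example-count-weighted mean entropy of the subsets induced by the
#' attribute's values. Always non-negative; exactly 0 when the attribute is
#' constant over the examples.
#'
#' @param examples Data frame with one column per attribute plus a `label`
#'   column (values `priority` / `non_priority`).
#' @param attribute Name of the attribute column to evaluate.
#' @return Gain in bits.
#' @export
information_gain <- function(examples, attribute) {
  if (!is.data.frame(examples) || nrow(examples) == 0) {
    abort_input("examples must be a non-empty data frame")
  }
  if (!"label" %in% names(examples)) abort_input("examples need a 'label' column")
  if (!attribute %in% names(examples) || attribute == "label") {
    abort_input("unknown attribute '%s'", attribute)
  }
  h <- entropy(table(examples$label))
  n <- nrow(examples)
  cond <- 0
  for (v in unique(examples[[attribute]])) {
    sub <- examples$label[examples[[attribute]] == v]
    cond <- cond + length(sub) / n * entropy(table(sub))
  }
  h - cond
}

majority_label <- function(labels) {
  # ties resolved in favour of "priority": the query tool should rather
  # over-flag than silently drop a task
  counts <- c(
    priority = sum(labels == "priority"),
    non_priority = sum(labels == "non_priority")
  )
  if (counts[["priority"]] >= counts[["non_priority"]]) "priority" else "non_priority"
}

#' Induce a decision tree from labelled examples (ID3)
#'
#' Greedy recursion: at each node the attribute with maximal information
#' gain splits the examples (gain ties broken by lexicographic attribute
#' name, so builds are deterministic). Recursion stops at pure label sets,
#' when attributes are exhausted (majority label; ties go to `priority`),
#' and on empty branches (parent majority). Every split fans out over the
#' attribute's full schema domain, so classification never falls off the
#' tree for schema-conformant activities. On consistent examples the tree
#' reproduces every training label.
#'
#' @param examples Data frame of labelled examples: one column per schema
#'   attribute plus `label` in `{priority, non_priority}`.
#' @param schema A `priority_schema`; defines the split domains.
#' @return A `decision_tree` (unweighted; see [assign_weights()]).
#' @export
induce_tree <- function(examples, schema) {
  if (!inherits(schema, "priority_schema")) {
    abort_schema("schema must be a 'priority_schema' object")
  }
  if (!is.data.frame(examples) || nrow(examples) == 0) {
    abort_input("cannot induce a tree from an empty example set")
  }
  if (!"label" %in% names(examples)) abort_input("examples need a 'label' column")
  bad <- setdiff(unique(examples$label), PRIORITY_LABELS)
  if (length(bad) > 0) abort_input("unknown label(s): %s", paste(bad, collapse = ", "))
  attrs <- intersect(names(schema$attributes), names(examples))
  if (length(attrs) == 0) abort_input("examples share no attribute with the schema")
  for (a in attrs) {
    out <- setdiff(unique(examples[[a]]), schema$attributes[[a]])
    if (length(out) > 0) {
      abort_input("examples carry out-of-domain value(s) for '%s': %s",
        a, paste(out, collapse = ", "))
    }
  }
  root <- id3_node(examples, sort(attrs), schema,
    parent_majority = majority_label(examples$label), path = list()
  )
  structure(list(root = root, schema = schema), class = "decision_tree")
}

id3_node <- function(examples, attrs, schema, parent_majority, path) {
  make_leaf <- function(label, n_pri, n_non) {
    list(
      type = "leaf", label = label, weight = NA_integer_,
      n_priority = n_pri, n_non_priority = n_non, path = path
    )
  }
  if (nrow(examples) == 0) {
    return(make_leaf(parent_majority, 0L, 0L))
  }
  labs <- examples$label
  n_pri <- sum(labs == "priority")
  n_non <- sum(labs == "non_priority")
  if (n_pri == 0L || n_non == 0L || length(attrs) == 0) {
    lab <- if (length(attrs) == 0) majority_label(labs) else labs[1]
    return(make_leaf(lab, n_pri, n_non))
  }
  gains <- vapply(attrs, function(a) information_gain(examples, a), numeric(1))
  best <- attrs[which.max(gains)] # attrs sorted => lexicographic tie-break
  dom <- schema$attributes[[best]]
  children <- list()
  sizes <- integer(length(dom))
  maj <- majority_label(labs)
  for (i in seq_along(dom)) {
    v <- dom[i]
    sub <- examples[examples[[best]] == v, , drop = FALSE]
    sizes[i] <- nrow(sub)
    children[[v]] <- id3_node(
      sub, setdiff(attrs, best), schema,
      parent_majority = maj, path = c(path, list(c(best, v)))
    )
  }
  list(
    type = "split", attribute = best, children = children,
    fallback = dom[which.max(sizes)] # densest branch hosts unseen values
  )
}

collect_leaves <- function(node) {
  if (node$type == "leaf") {
    return(list(node))
  }
  do.call(c, lapply(node$children, collect_leaves))
}

#' Number of leaves in a decision tree
#' @param tree A `decision_tree`.
#' @return Integer leaf count.
#' @export
n_leaves <- function(tree) {
  length(collect_leaves(tree$root))
}

path_value <- function(path, attribute) {
  for (p in path) if (p[1] == attribute) return(p[2])
  NA_character_
}

#' Default leaf-ranking policy for weight assignment
#'
#' Ranks leaves by: label (`priority` before `non_priority`), then deadline
#' urgency along the path (see [DEADLINE_BUCKETS]; paths without a deadline
#' test rank last), then requester precedence ([REQUESTER_LEVELS]), then the
#' lexicographic path string. Returns a numeric rank key matrix usable by
#' [assign_weights()]; lower rows rank earlier (and receive larger weights).
#'
#' @param leaves List of leaf nodes (as collected from a tree).
#' @return Integer vector: the ordering permutation of the leaves.
#' @export
rank_leaves_default <- function(leaves) {
  k1 <- vapply(leaves, function(l) match(l$label, PRIORITY_LABELS), numeric(1))
  k2 <- vapply(leaves, function(l) {
    v <- path_value(l$path, "deadline_bucket")
    if (is.na(v)) length(DEADLINE_BUCKETS) + 1 else match(v, DEADLINE_BUCKETS)
  }, numeric(1))
  k3 <- vapply(leaves, function(l) {
    v <- path_value(l$path, "requested_by")
    if (is.na(v)) length(REQUESTER_LEVELS) + 1 else match(v, REQUESTER_LEVELS)
  }, numeric(1))
  k4 <- vapply(leaves, function(l) {
    paste(vapply(l$path, paste, character(1), collapse = "="), collapse = "/")
  }, character(1))
  order(k1, k2, k3, k4)
}

#' Attach unique priority weights to a tree's leaves
#'
#' Every leaf receives a distinct positive integer weight; taken together the
#' weights are a permutation of `1..n_leaves`. Under the default policy the
#' leaves are ranked by [rank_leaves_default()] and weights assigned in
#' strictly decreasing order from `n_leaves` down to 1, so the most urgent
#' priority leaf carries the largest weight. The policy is swappable: any
#' function mapping a list of leaves to an ordering permutation works.
#'
#' @param tree A `decision_tree`.
#' @param policy Ranking function, default [rank_leaves_default()].
#' @return The tree with all leaf weights set.
#' @export
assign_weights <- function(tree, policy = rank_leaves_default) {
  stopifnot(inherits(tree, "decision_tree"))
  leaves <- collect_leaves(tree$root)
  ord <- policy(leaves)
  n <- length(leaves)
  weights_by_rank <- integer(n)
  weights_by_rank[ord] <- seq(n, 1L) # rank 1 -> weight n
  idx <- 0L
  set_w <- function(node) {
    if (node$type == "leaf") {
      idx <<- idx + 1L
      node$weight <- weights_by_rank[idx]
      return(node)
    }
    node$children <- lapply(node$children, set_w)
    node
  }
  tree$root <- set_w(tree$root)
  tree
}

#' Classify one activity with a weighted tree
#'
#' Walks attribute tests from the root to a leaf and returns that leaf's
#' label, weight and path. An attribute value missing from a split's
#' children (possible only if the schema drifted after induction) is routed
#' to the branch that held the training majority and flagged with a warning,
#' so a query never dead-ends.
#'
#' @param tree A weighted `decision_tree`.
#' @param activity An `activity` conforming to the tree's schema.
#' @param validate Validate the activity first (default TRUE).
#' @return List with `label`, `weight`, `path` (list of `(attribute, value)`
#'   pairs) and `fallback_used` flag.
#' @export
classify <- function(tree, activity, validate = TRUE) {
  stopifnot(inherits(tree, "decision_tree"))
  if (validate) assert_valid_activity(activity, tree$schema)
  node <- tree$root
  fallback <- FALSE
  while (node$type == "split") {
    v <- activity$assignment[[node$attribute]]
    if (is.null(v) || !v %in% names(node$children)) {
      warning(sprintf(
        "activity '%s': value '%s' unseen for '%s'; routed to majority branch '%s'",
        activity$id, v %||% "<missing>", node$attribute, node$fallback
      ), call. = FALSE)
      v <- node$fallback
      fallback <- TRUE
    }
    node <- node$children[[v]]
  }
  list(
    label = node$label, weight = node$weight,
    path = node$path, fallback_used = fallback
  )
}

#' Decide which of two activities takes priority
#'
#' The pairwise rule of the query tool: if exactly one activity is labelled
#' `priority` it wins outright. When both carry the same label (both
#' priority, or both non-priority — the balance always answers), the greater
#' leaf weight wins and `tie_break_used` is flagged. If both land on the
#' same leaf the lexicographically smaller id wins, also flagged. Swapping
#' the two activities swaps winner and loser.
#'
#' @param tree A weighted `decision_tree`.
#' @param a,b `activity` objects conforming to the tree's schema.
#' @return A `priority_decision`: winner/loser ids, their labels and
#'   weights, `tie_break_used`, and a `rationale` string naming the rule.
#' @export
prioritise <- function(tree, a, b) {
  stopifnot(inherits(tree, "decision_tree"))
  assert_valid_activity(a, tree$schema)
  assert_valid_activity(b, tree$schema)
  ca <- classify(tree, a, validate = FALSE)
  cb <- classify(tree, b, validate = FALSE)
  if (any(is.na(c(ca$weight, cb$weight)))) {
    abort_input("tree has unweighted leaves; call assign_weights() first")
  }
  decide <- function(winner, loser, cw, cl, tie, why) {
    structure(
      list(
        winner_id = winner$id, loser_id = loser$id,
        winner_label = cw$label, winner_weight = cw$weight,
        loser_label = cl$label, loser_weight = cl$weight,
        tie_break_used = tie, rationale = why
      ),
      class = "priority_decision"
    )
  }
  if (ca$label != cb$label) {
    if (ca$label == "priority") {
      decide(a, b, ca, cb, FALSE, "label: priority beats non_priority")
    } else {
      decide(b, a, cb, ca, FALSE, "label: priority beats non_priority")
    }
  } else if (ca$weight != cb$weight) {
    why <- sprintf(
      "both %s: greater leaf weight wins (%d vs %d)",
      ca$label, max(ca$weight, cb$weight), min(ca$weight, cb$weight)
    )
    if (ca$weight > cb$weight) {
      decide(a, b, ca, cb, TRUE, why)
    } else {
      decide(b, a, cb, ca, TRUE, why)
    }
  } else {
    why <- "identical leaf: lexicographically smaller id wins"
    if (a$id <= b$id) {
      decide(a, b, ca, cb, TRUE, why)
    } else {
      decide(b, a, cb, ca, TRUE, why)
    }
  }
}

#' @export
print.priority_decision <- function(x, ...) {
  cat(sprintf(
    "<priority_decision: %s beats %s (%s w=%d vs %s w=%d)%s>\n  %s\n",
    x$winner_id, x$loser_id, x$winner_label, x$winner_weight,
    x$loser_label, x$loser_weight,
    if (x$tie_break_used) " [tie-break]" else "", x$rationale
  ))
  invisible(x)
}

#' @export
print.decision_tree <- function(x, ...) {
  cat(sprintf("<decision_tree: %d leaves>\n", n_leaves(x)))
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(sprintf(
        "%s-> %s (w=%s, n=%d/%d)\n", pad, node$label,
        ifelse(is.na(node$weight), "?", node$weight),
        node$n_priority, node$n_non_priority
      ))
    } else {
      for (v in names(node$children)) {
        child <- node$children[[v]]
        if (child$type == "leaf") {
          cat(sprintf(
            "%s%s=%s -> %s (w=%s)\n", pad, node$attribute, v, child$label,
            ifelse(is.na(child$weight), "?", child$weight)
          ))
        } else {
          cat(sprintf("%s%s=%s:\n", pad, node$attribute, v))
          show(child, indent + 1)
        }
      }
    }
  }
  show(x$root, 1)
  invisible(x)
}

node_to_list <- function(node) {
  if (node$type == "leaf") {
    list(
      type = "leaf", label = node$label,
      weight = if (is.na(node$weight)) NULL else node$weight,
      n_priority = node$n_priority, n_non_priority = node$n_non_priority,
      path = lapply(node$path, function(p) list(attribute = p[1], value = p[2]))
    )
  } else {
    list(
      type = "split", attribute = node$attribute, fallback = node$fallback,
      children = lapply(node$children, node_to_list)
    )
  }
}

node_from_list <- function(x, path = list()) {
  if (x$type == "leaf") {
    list(
      type = "leaf", label = x$label,
      weight = if (is.null(x$weight)) NA_integer_ else as.integer(x$weight),
      n_priority = as.integer(x$n_priority %||% 0L),
      n_non_priority = as.integer(x$n_non_priority %||% 0L),
      path = path
    )
  } else {
    kids <- list()
    for (v in names(x$children)) {
      kids[[v]] <- node_from_list(
        x$children[[v]],
        path = c(path, list(c(x$attribute, v)))
      )
    }
    list(type = "split", attribute = x$attribute, fallback = x$fallback,
         children = kids)
  }
}

#' Serialise a decision tree to JSON
#'
#' The document carries the full node structure (splits, leaves, weights,
#' training counts) plus the schema, so a tree induced once can be reused
#' across runs and machines. [read_tree()] restores it losslessly.
#'
#' @param tree A `decision_tree`.
#' @param path Output file path.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "decision_tree"))
  jsonlite::write_json(
    list(
      format = "prioritree/decision_tree/v1",
      schema = list(attributes = tree$schema$attributes, areas = tree$schema$areas),
      root = node_to_list(tree$root)
    ),
    path,
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a decision tree from JSON
#' @param path Path to a document written by [write_tree()].
#' @return A `decision_tree`.
#' @export
read_tree <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(doc$root) || is.null(doc$schema)) {
    abort_input("'%s' is not a serialised decision tree", path)
  }
  schema <- new_schema(
    lapply(doc$schema$attributes, function(d) unlist(d, use.names = FALSE)),
    areas = unlist(doc$schema$areas, use.names = FALSE)
  )
  structure(
    list(root = node_from_list(doc$root), schema = schema),
    class = "decision_tree"
  )
}

#' Read labelled training examples from CSV or JSON
#'
#' CSV: header = attribute names + `label`. JSON: array of objects with an
#' `assignment` object and a `label` field (or flat objects whose keys are
#' the attribute names plus `label`).
#'
#' @param path File path.
#' @return Data frame of examples, ready for [induce_tree()].
#' @export
read_examples <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    doc <- jsonlite::read_json(path, simplifyVector = FALSE)
    rows <- lapply(doc, function(o) {
      if (!is.null(o$assignment)) {
        as.data.frame(c(o$assignment, list(label = o$label)),
          stringsAsFactors = FALSE
        )
      } else {
        as.data.frame(o, stringsAsFactors = FALSE)
      }
    })
    do.call(rbind, rows)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  }
}

#' The default weighted tree shipped with the package
#'
#' Induced from the labelled example table in
#' `inst/extdata/training_examples.csv` (the full attribute grid labelled by
#' a simple urgency rule: overdue/today tasks are priorities, as are
#' within-week tasks requested by a parent) and weighted with the default
#' policy.
#'
#' @param schema Schema to induce under (default: [default_schema()]).
#' @return A weighted `decision_tree`.
#' @export
default_tree <- function(schema = default_schema()) {
  ex <- read_examples(system.file("extdata", "training_examples.csv",
    package = "prioritree", mustWork = TRUE
  ))
  assign_weights(induce_tree(ex, schema))
}
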