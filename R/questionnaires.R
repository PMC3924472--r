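# Scoring for the two evaluation instruments: the 10-item System Usability
# Scale (0-100, alternating item polarity) and the 34-item Time Management
# Behavior Questionnaire (four factor means on the 1-5 Likert scale), plus
# pooled group summaries and the Mann-Whitney U comparison used on small
# cohorts.

check_likert <- function(items, n, instrument) {
  if (length(items) != n) {
    abort_input("%s needs exactly %d item responses, got %d", instrument, n, length(items))
  }
  if (any(is.na(items)) || any(items != as.integer(items)) ||
    any(items < 1) || any(items > 5)) {
    abort_input("%s items must be integers in 1..5", instrument)
  }
  as.integer(items)
}

#' Score one SUS response
#'
#' Positional scoring of the 10-item System Usability Scale: odd items
#' (1, 3, 5, 7, 9) contribute `value - 1`, even items (2, 4, 6, 8, 10)
#' contribute `5 - value`, and the summed contributions are multiplied by
#' 2.5, giving a score in `[0, 100]` on the 2.5 grid. The maximal pattern
#' `(5,1,5,1,5,1,5,1,5,1)` scores exactly 100, and item-wise complementing a
#' response (`6 - r`) complements its score (`score(r) + score(6-r) = 100`).
#'
#' @param items Integer vector of 10 Likert responses in 1..5, positionally
#'   indexed.
#' @return SUS score in `[0, 100]`, always a multiple of 2.5.
#' @examples
#' score_sus(c(5, 1, 5, 1, 5, 1, 5, 1, 5, 1)) # 100
#' score_sus(rep(3, 10)) # 50
#' @export
score_sus <- function(items) {
  items <- check_likert(items, 10L, "SUS")
  odd <- items[c(1, 3, 5, 7, 9)] - 1L
  even <- 5L - items[c(2, 4, 6, 8, 10)]
  2.5 * sum(odd, even)
}

#' The default TMBQ item-to-factor mapping
#'
#' The instrument's published item-level factor assignment is configuration,
#' not code: this default (F1 items 1-10, F2 items 11-21, F3 items 22-29,
#' F4 items 30-34 — 10/11/8/5 items) ships as an editable JSON document in
#' `inst/extdata/tmbq_factors.json` and stands in for the validated Spanish
#' mapping, which is not publicly printed. Factor readings: F1 goal/priority
#' setting, F2 time-management mechanics, F3 preference for disorganisation,
#' F4 perceived control of time.
#'
#' @return Character vector of length 34; element i names the factor of
#'   item i.
#' @export
default_tmbq_mapping <- function() {
  read_tmbq_mapping(system.file("extdata", "tmbq_factors.json",
    package = "prioritree", mustWork = TRUE
  ))
}

#' Read a TMBQ factor mapping from JSON
#'
#' The document maps factor names to arrays of 1-based item indices; the
#' arrays must partition 1..34 and every factor must be non-empty.
#'
#' @param path Path to the JSON mapping.
#' @return Character vector of length 34 (item index -> factor).
#' @export
read_tmbq_mapping <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_tmbq_mapping(doc)
}

validate_tmbq_mapping <- function(mapping) {
  if (is.character(mapping) && length(mapping) == 34) {
    mapping <- split(seq_len(34), mapping)
  }
  if (!is.list(mapping) || length(mapping) == 0 || is.null(names(mapping))) {
    abort_schema("TMBQ mapping must assign item indices to named factors")
  }
  idx <- unlist(mapping, use.names = FALSE)
  if (length(idx) != 34 || anyDuplicated(idx) || !setequal(idx, seq_len(34))) {
    abort_schema("TMBQ mapping must partition items 1..34 exactly once each")
  }
  if (any(vapply(mapping, length, integer(1)) == 0)) {
    abort_schema("every TMBQ factor must contain at least one item")
  }
  out <- character(34)
  for (f in names(mapping)) out[unlist(mapping[[f]])] <- f
  out
}

#' Score one TMBQ response into factor means
#'
#' Each factor's score is the arithmetic mean of its mapped item values on
#' the raw 1-5 scale; no items are reverse-coded (high F3 reads as a
#' preference for a disorganised environment, so raw scoring is the
#' intended direction). Factor means are invariant to item order within a
#' factor and always lie in `[1, 5]`.
#'
#' @param items Integer vector of 34 Likert responses in 1..5.
#' @param mapping Item-to-factor mapping: a character vector of length 34,
#'   or a named list of index vectors as read by [read_tmbq_mapping()].
#'   Default: [default_tmbq_mapping()].
#' @return Named numeric vector of factor means (factors in mapping order).
#' @examples
#' score_tmbq(rep(3, 34)) # every factor 3
#' @export
score_tmbq <- function(items, mapping = default_tmbq_mapping()) {
  items <- check_likert(items, 34L, "TMBQ")
  mapping <- validate_tmbq_mapping(mapping)
  means <- tapply(items, mapping, mean)
  out <- as.numeric(means)
  names(out) <- names(means)
  out[unique(mapping)] # mapping order, not alphabetical
}

#' Summarise scores per group and pooled
#'
#' Per-group and pooled n / mean / sample standard deviation (n-1
#' denominator throughout). The pooled values are computed from the raw
#' scores; they coincide with combining the per-group statistics through
#' the sum-of-squares identity (see [pool_group_summaries()]), which is
#' how printed subgroup statistics can be pooled without raw data.
#'
#' @param scores Numeric vector of scores.
#' @param groups Group label per score; `NULL` treats all scores as one
#'   group.
#' @return A `cohort_summary`: `$groups` data frame (`group`, `n`, `mean`,
#'   `sd`) and `$pooled` list (`n`, `mean`, `sd`). `sd` is `NA` for n < 2.
#' @export
cohort_summary <- function(scores, groups = NULL) {
  if (length(scores) == 0 || !is.numeric(scores)) {
    abort_input("scores must be a non-empty numeric vector")
  }
  if (is.null(groups)) groups <- rep("all", length(scores))
  if (length(groups) != length(scores)) {
    abort_input("groups must be as long as scores")
  }
  gs <- lapply(split(scores, groups), function(s) {
    list(n = length(s), mean = mean(s), sd = if (length(s) >= 2) stats::sd(s) else NA_real_)
  })
  df <- data.frame(
    group = names(gs),
    n = vapply(gs, `[[`, integer(1), "n"),
    mean = vapply(gs, `[[`, numeric(1), "mean"),
    sd = vapply(gs, `[[`, numeric(1), "sd"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  structure(
    list(
      groups = df,
      pooled = list(
        n = length(scores), mean = mean(scores),
        sd = if (length(scores) >= 2) stats::sd(scores) else NA_real_
      )
    ),
    class = "cohort_summary"
  )
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("<cohort_summary>\n")
  print(x$groups, row.names = FALSE)
  cat(sprintf(
    "pooled: n=%d mean=%.2f sd=%s\n", x$pooled$n, x$pooled$mean,
    ifelse(is.na(x$pooled$sd), "NA", sprintf("%.2f", x$pooled$sd))
  ))
  invisible(x)
}

#' Pool printed subgroup statistics without raw data
#'
#' Combines per-group (n, mean, sd) triples into the pooled mean and pooled
#' sample standard deviation via the sum-of-squares identity: the total SS
#' is the within-group SS, `sum((n_i - 1) sd_i^2)`, plus the between-group
#' SS, `sum(n_i (mean_i - mean)^2)`, divided by `N - 1`. With exact inputs
#' this reproduces `sd()` over the concatenated raw scores; with printed
#' (rounded) subgroup statistics it reconstructs the pooled figures a study
#' reports.
#'
#' @param n Integer vector of group sizes.
#' @param mean Numeric vector of group means.
#' @param sd Numeric vector of group sample standard deviations (n-1
#'   denominator); groups of size 1 may pass `NA` (they contribute no
#'   within-group SS).
#' @return List `(n, mean, sd)` for the pooled cohort.
#' @examples
#' pool_group_summaries(n = c(7, 9), mean = c(73.93, 82.5), sd = c(4.97, 4.68))
#' @export
pool_group_summaries <- function(n, mean, sd) {
  if (length(n) == 0 || length(n) != length(mean) || length(n) != length(sd)) {
    abort_input("n, mean, sd must be equal-length and non-empty")
  }
  if (any(n < 1)) abort_input("every group needs n >= 1")
  N <- sum(n)
  m <- sum(n * mean) / N
  within <- ifelse(n >= 2, (n - 1) * sd^2, 0)
  if (any(n >= 2 & is.na(sd))) abort_input("sd required for every group with n >= 2")
  between <- n * (mean - m)^2
  s <- if (N >= 2) sqrt(sum(within, between) / (N - 1)) else NA_real_
  list(n = N, mean = m, sd = s)
}

#' Mann-Whitney U test for two independent samples
#'
#' Computes the rank-sum U statistic with midranks for ties (so
#' `U_a + U_b = n_a * n_b` always holds) and a two-sided p-value: exact by
#' enumeration of label assignments when `n_a + n_b <= 12` and the data are
#' tie-free, otherwise the normal approximation with tie and continuity
#' corrections. Intended for the small cohorts this toolkit evaluates.
#'
#' @param a,b Non-empty numeric vectors.
#' @param exact Force (`TRUE`) or suppress (`FALSE`) the exact p-value;
#'   default `NULL` applies the rule above.
#' @return List with `U` (for sample `a`), `p` (two-sided), and `method`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4)) # U = 0, p = 1/3
#' @export
mann_whitney_u <- function(a, b, exact = NULL) {
  if (length(a) == 0 || length(b) == 0) {
    abort_input("both groups must be non-empty")
  }
  r <- rank(c(a, b))
  na <- length(a)
  nb <- length(b)
  u_a <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0
  if (is.null(exact)) exact <- (na + nb <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE, alternative = "two.sided")
  )
  list(
    U = u_a,
    p = unname(wt$p.value),
    method = if (grepl("continuity", wt$method)) "normal_approx" else "exact"
  )
}

#' Read questionnaire responses from CSV
#'
#' One row per respondent; item columns are every column except an optional
#' `group` (and optional `id`) column, taken in file order. Validates the
#' item count for the requested instrument.
#'
#' @param path CSV path.
#' @param instrument `"sus"` (10 items) or `"tmbq"` (34 items).
#' @return List with `items` (integer matrix, one row per respondent) and
#'   `groups` (character vector or `NULL`).
#' @export
read_responses <- function(path, instrument = c("sus", "tmbq")) {
  instrument <- match.arg(instrument)
  want <- if (instrument == "sus") 10L else 34L
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  groups <- if ("group" %in% names(df)) as.character(df$group) else NULL
  item_cols <- setdiff(names(df), c("group", "id"))
  if (length(item_cols) != want) {
    abort_input(
      "%s responses need %d item columns, found %d",
      toupper(instrument), want, length(item_cols)
    )
  }
  m <- as.matrix(df[, item_cols, drop = FALSE])
  storage.mode(m) <- "integer"
  for (i in seq_len(nrow(m))) check_likert(m[i, ], want, toupper(instrument))
  list(items = m, groups = groups)
}
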