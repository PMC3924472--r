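---
title: "Methods: decision-tree prioritisation, adaptive quizzing, and questionnaire scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-tree prioritisation, adaptive quizzing, and questionnaire scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prioritree)
```

prioritree is a desk-scale toolkit for task-prioritisation training of the
kind used in serious games for health: adolescents (the motivating
population is ADHD, though the methods are population-agnostic) weigh two
everyday activities against each other, and the system both answers the
question ("which should come first?") and trains the skill through an
adaptive quiz supervised by a therapist or parent. This vignette is the
package's own account of the models and the design choices behind them.

## The activity model

An activity is a task with a unique id and a value for each attribute of a
configurable discrete schema. The default schema has three attributes:

* `area` — which part of life the task belongs to (`academic`, `personal`,
  `family`, `leisure`); the set is configuration, not code, because real
  deployments add areas.
* `deadline_bucket` — five ordered urgency levels (`overdue`, `today`,
  `within_week`, `later`, `none`). Calendar deadlines are free-form, so
  `bucket_deadline()` discretises them: dates strictly before the reference
  day are `overdue`, the reference day is `today`, the half-open week
  `(reference, reference + 7]` is `within_week`, everything beyond is
  `later`, and a missing deadline is `none`. The week boundary is a design
  choice: one week is the natural planning horizon for homework-scale
  tasks, and a half-open interval keeps the buckets a partition (every
  input lands in exactly one bucket). Dates are ISO-8601 calendar dates
  with no time-of-day component.
* `requested_by` — who asked for the task (`father`, `mother`,
  `someone_else`, `nobody`); requests from a parent carry social weight
  that the training data can encode.

`validate_activity()` returns one violation descriptor per problem rather
than failing fast, because the supervisor UI workflow wants all problems at
once. A clean validation is a guarantee: classification can then never
raise a domain error.

## The decision engine

The core is classic ID3 over the discrete schema. Split quality is Shannon
entropy in bits,

$$H(S) = -\sum_i p_i \log_2 p_i,$$

and the split criterion is information gain
$H(S) - \sum_v \tfrac{|S_v|}{|S|} H(S_v)$. Induction recurses greedily:
the maximal-gain attribute splits the node, recursion stops at pure label
sets, at exhausted attribute lists (majority label), and on empty branches
(parent majority). Labels are binary — `priority` / `non_priority` — and
three deliberate choices make builds deterministic and total:

* **Gain ties** are broken by lexicographic attribute name.
* **Majority ties** resolve to `priority`: for a prioritisation aid,
  over-flagging a task is the safer failure mode than dropping it.
* **Every split fans out over the attribute's full schema domain**, so a
  value unseen in training still has a branch (labelled by the parent's
  majority). If, after schema drift, a value is missing entirely,
  `classify()` routes to the branch that held the training majority and
  records a warning instead of dead-ending the user.

There is no pruning, no gain ratio, and no continuous-threshold handling:
the attribute grids are tiny by construction (the default grid has 80
cells) and the training tables are authored or generated, not mined.

### Leaf weights and the pairwise rule

Every leaf carries a distinct positive integer weight; across a tree the
weights are a permutation of `1..n_leaves`. Weights exist to break ties:
when both activities in a query receive the same label, the greater leaf
weight wins. The default ranking policy orders leaves by

1. label (`priority` before `non_priority`),
2. deadline urgency along the leaf's path (paths that never test the
   deadline rank after all five buckets),
3. requester precedence (`father`, `mother`, `someone_else`, `nobody`),
4. lexicographic path string,

and assigns weights decreasing from `n_leaves` to 1. The policy is a
plain R function and can be swapped wholesale (`assign_weights(tree,
policy = ...)`); the ranking above encodes the intuition that urgency
dominates and parental requests outrank third parties. `prioritise()`
then decides: label first, weight second (flagged as a tie-break), and —
for two activities landing on the very same leaf — the lexicographically
smaller id, flagged, so the function is total and antisymmetric even on
symmetric inputs. Both-non-priority pairs are still resolved by weight:
the balance always answers.

## The adaptive quiz

A difficulty profile tracks per-area attempts and errors. Question
selection samples an area from the Laplace-smoothed error rate

$$P(\text{area } a) \propto \frac{e_a + \alpha}{t_a + 2\alpha}, \qquad \alpha = 1,$$

then a distinct activity pair uniformly within the area. The smoothing
constant is the one genuinely free parameter: $\alpha = 1$ (one
pseudo-error in two pseudo-attempts per area) keeps every area's
probability strictly positive, makes the empty profile exactly uniform,
and needs no cold-start threshold; $\alpha \to \infty$ recovers the
uniform quiz. Adaptation is per-area rather than per-question because the
difficulty signal the supervisor reads is per-area. The question's correct
answer is always the engine's own verdict on the pair, so quiz content
can never contradict the query tool; supervisor-authored questions may
carry their own key but defer to the tree by default.

All randomness flows through explicit seeds (`withr::with_seed`); a
session generator seeds once and draws questions from the running stream,
so identical `(inputs, seed)` reproduce identical sessions byte for byte.

## The supervisor layer

The history store is an append-only log — persisted as JSON Lines with a
CSV export — of query and quiz records (user, UTC ISO-8601 timestamp,
activity pair, decision, correctness for quiz records only). Reports count
quiz records per area; an area's error rate is `errors/attempts` with 0
reported at zero attempts, and the hardest area is the maximal rate among
*attempted* areas with lexicographic tie-breaking. Supervisors can inject
custom questions targeted at one user (or all users); simulated sessions
serve pending custom questions before generated ones.

## Questionnaire scoring

**SUS.** The ten-item System Usability Scale is scored positionally: odd
items contribute `value − 1`, even items `5 − value`, and the summed
contributions are multiplied by 2.5, giving `[0, 100]` on a 2.5 grid.
Two consequences are useful as tests: the most favourable pattern
`(5,1,5,1,5,1,5,1,5,1)` scores exactly 100, and item-wise complementing a
response complements its score (`score(r) + score(6 − r) = 100`).

**TMBQ.** The 34-item Time Management Behavior Questionnaire is scored as
per-factor means of the raw 1–5 item values over a four-factor partition
(goal/priority setting; time-management mechanics; preference for
disorganisation; perceived control of time). No item is reverse-coded:
the disorganisation factor is interpreted so that high raw scores mean a
disorganised preference, which is the direction raw scoring already
yields. The item-to-factor assignment of the validated Spanish instrument
is not publicly printed, so the mapping ships as an editable JSON config;
the default splits items 1–10 / 11–21 / 22–29 / 30–34 (10/11/8/5 items)
and is a documented placeholder, not a claim about the instrument.

**Group statistics.** `cohort_summary()` reports per-group and pooled
n/mean/sd with the sample (n−1) standard deviation throughout — the
convention under which pooled figures printed in small usability studies
are exactly recoverable from their subgroup statistics.
`pool_group_summaries()` performs that recovery without raw data through
the sum-of-squares identity

$$ (N-1)\,s^2 \;=\; \sum_g (n_g - 1) s_g^2 \;+\; \sum_g n_g (\bar x_g - \bar x)^2 . $$

**Mann-Whitney U.** For the small two-group comparisons this toolkit
meets, `mann_whitney_u()` computes the rank-sum U with midranks (so
$U_a + U_b = n_a n_b$ always) and takes its two-sided p-value from
`stats::wilcox.test`: exact when the pooled sample is at most 12 and
tie-free, otherwise the normal approximation with tie and continuity
corrections. The tests check the approximation against full enumeration
of label assignments for groups of 3–6.

## The synthetic-data generators

Every generator is a pure function of its spec and seed, and everything it
emits passes the consuming module's validators.

* `gen_labeled_examples()` samples assignments uniformly over the
  attribute grid, labels them with a ground-truth tree, and flips each
  label independently with a given noise rate — the fixture source for
  induction tests.
* `gen_quiz_session()` simulates a user with per-area answer accuracy
  working through the adaptive quiz, threading the difficulty profile so
  the adaptation loop itself is exercised.
* `gen_sus_cohort()` calibrates responses to target group means. It works
  in score space: a group's target total is the nearest 2.5-grid multiple
  of `n × mean` (infeasible targets — off-scale means, or totals that
  cannot reproduce the mean at two decimals — raise a feasibility error
  naming the constraint), per-user scores are spread around the mean, and
  each score is inverted into an item vector through the positional rule.
  Working in score space avoids integer programming over items. A target
  sd, when given, is approached by seeded single-unit transfers and is
  best-effort: on a 2.5 grid with small n the reachable sds are quantised,
  so the generator stops at the closest achievable value rather than
  guaranteeing two decimals (only means carry that guarantee).
* `gen_tmbq_cohort()` distributes each factor's total item mass
  `round(n k \bar x)` over its `n × k` item cells as evenly as possible,
  giving factor means within half a unit of target — at most 0.05 off for
  factors with at least ten cells, exact for integer targets.

The default SUS cohort spec encodes the study conditions the package is
evaluated against: 16 scored respondents in two age groups of 7 (mean
73.93, sd 4.97) and 9 (mean 82.5, sd 4.68), pooling to mean 78.75 — the
7/9 split is the unique integer split of 16 consistent with those three
means. What the generators deliberately do **not** model: demographic
structure beyond group labels, item-level response correlation,
response times, and dropout (a dropout is just a smaller n). Passing
calibration tests therefore shows the pipeline arithmetic is right, not
that real adolescents behave like the simulator.

## Problem sizes and numerical choices

The shipped training table is the full 80-cell default grid labelled by an
urgency rule (overdue/today tasks are priorities, as are within-week tasks
requested by a parent), which induces an 8-leaf tree. The test suite
checks induction against a brute-force greedy oracle on 200 random tables
of up to 5 attributes × 3 values × 40 examples, prioritisation
antisymmetry on all 3160 grid pairs, quiz selection frequencies over
10,000 draws (within 3 binomial standard errors), competence recovery over
500-question sessions (central 95% binomial acceptance region on the error
count), and the Mann-Whitney approximation against enumeration for all
group sizes 3–6. Entropy needs no numerical care beyond excluding
zero-count labels from the sum; probabilities are compared at 1e-12 only
where exact arithmetic is expected (normalised distributions), and
two-decimal rounding happens at the reporting layer, never inside a
computation.

## Known limitations

* ID3 only: no continuous attributes, no pruning, no multi-class labels —
  adequate for authored desk-scale schemas, wrong for mined data.
* The default TMBQ mapping is a placeholder for an unpublished validated
  mapping; factor-level conclusions depend on supplying the real one.
* The SUS sd calibration is best-effort (quantised score grid).
* The history store is a single-process file log; there is no
  authentication or concurrent-writer story — "supervisor" is an API
  role, not a security boundary.
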