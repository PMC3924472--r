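Package: prioritree
Title: Weighted Decision-Tree Task Prioritisation, Adaptive Quizzing, and
    Usability Questionnaire Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for serious-games-for-health style task
    prioritisation training. Induces ID3 decision trees with Shannon
    entropy over discrete activity attributes, attaches unique priority
    weights to leaves, and resolves pairwise "which activity first?"
    queries by label and weight. An adaptive quiz engine targets the
    activity areas where a user makes the most errors, a supervisor
    history layer logs sessions and reports per-area difficulty, and
    exact scorers are provided for the System Usability Scale (SUS) and
    the Time Management Behavior Questionnaire (TMBQ), together with
    pooled group summaries and the Mann-Whitney U comparison. A
    synthetic-data module generates labelled training tables, simulated
    quiz sessions, and Likert cohorts calibrated to target group
    statistics so the whole pipeline is testable without human subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
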