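cohort_test_cols <- function()
  c(TMT_A = "tmt_a", TMT_B = "tmt_b", DST = "dst",
    WORDLIST_LEARNING = "wordlist_learning",
    WORDLIST_RECALL = "wordlist_recall",
    PEGBOARD_DOM = "pegboard_dom", PEGBOARD_NONDOM = "pegboard_nondom")

cohort_q_cols <- function()
  c(memory_loss = "q_memory", slowed_thinking = "q_slowed",
    attention = "q_attention", prospective_memory = "q_prospective",
    informant_remarks = "q_informant",
    interest = "q_interest", mood = "q_mood")

#' Analysis configuration
#'
#' Collects every tunable of the screening analysis, with defaults that
#' reproduce the published rules end-to-end: z cutoff -1.0, screen positive
#' at deficits in 2 or more of the 4 domains, complainer at "often" or worse
#' on the memory-loss or attention item, depression at "more than half the
#' days" on either mood item, 95% exact confidence intervals.
#'
#' @param norms_path optional path to a norms CSV; `NULL` means the shipped
#'   demonstration norms.
#' @param cutoff z cutoff for an individually pathological test result.
#' @param min_domains number of pathological domains at which the screen
#'   turns positive.
#' @param sci_threshold,sci_items complainer rule, see [score_sci()].
#' @param depression_threshold see [score_depression()].
#' @param alpha two-sided level for confidence intervals.
#' @param seed integer seed recorded for simulation runs.
#' @return a list of class `screen_config`.
#' @export
screen_config <- function(norms_path = NULL, cutoff = -1, min_domains = 2,
                          sci_threshold = "often",
                          sci_items = c("memory_loss", "attention"),
                          depression_threshold = "more_than_half",
                          alpha = 0.05, seed = NULL) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1,
            min_domains >= 1, alpha > 0, alpha < 1)
  sci_threshold <- match.arg(sci_threshold, sci_levels())
  depression_threshold <- match.arg(depression_threshold,
                                    depression_levels())
  sci_items <- match.arg(sci_items, sci_item_names(), several.ok = TRUE)
  structure(list(norms_path = norms_path, cutoff = cutoff,
                 min_domains = as.integer(min_domains),
                 sci_threshold = sci_threshold, sci_items = sci_items,
                 depression_threshold = depression_threshold,
                 alpha = alpha, seed = seed),
            class = "screen_config")
}

#' @rdname screen_config
#' @param path file path for the YAML serialization.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "screen_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname screen_config
#' @param config a `screen_config` object.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(screen_config, raw)
}

#' Read and validate a cohort CSV
#'
#' One row per patient. Required columns: `patient_id`, `age`, the seven raw
#' test scores (`tmt_a`, `tmt_b`, `dst`, `wordlist_learning`,
#' `wordlist_recall`, `pegboard_dom`, `pegboard_nondom`), the questionnaire
#' columns (`q_memory`, `q_slowed`, `q_attention`, `q_prospective`,
#' `q_informant` on the never..always scale; `q_interest`, `q_mood` on the
#' not_at_all..nearly_every_day scale), and `diagnosis`
#' (`NORMAL`/`ANI`/`MND`/`HAD`). Optional: `education`, `efavirenz`.
#' Validation failures are collected and reported with row numbers and
#' column names.
#'
#' @param path path to the CSV (UTF-8, comma separator, dot decimals).
#' @return a `hand_cohort` data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(df)
}

#' @rdname read_cohort
#' @param df a data.frame with the cohort columns, e.g. built in code.
#' @export
validate_cohort <- function(df) {
  req <- c("patient_id", "age", unname(cohort_test_cols()),
           unname(cohort_q_cols()), "diagnosis")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("cohort lacks required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) {
    warning("cohort file contains a header but no rows", call. = FALSE)
    class(df) <- c("hand_cohort", "data.frame")
    return(df)
  }
  problems <- character(0)
  note <- function(row, col, what)
    sprintf("row %d, column %s: %s", row, col, what)
  for (col in c("age", unname(cohort_test_cols()))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & is.na(v))
    problems <- c(problems,
                  vapply(bad, note, character(1), col = col,
                         what = "not numeric"))
    df[[col]] <- v
  }
  vocab <- list(
    c(unname(cohort_q_cols()[1:5])), c(unname(cohort_q_cols()[6:7])))
  scales <- list(sci_levels(), depression_levels())
  for (s in 1:2) for (col in vocab[[s]]) {
    bad <- which(!is.na(df[[col]]) & !(df[[col]] %in% scales[[s]]))
    problems <- c(problems,
                  vapply(bad, function(r)
                    note(r, col, paste0("invalid response '", df[[col]][r],
                                        "'")), character(1)))
  }
  badd <- which(!toupper(df$diagnosis) %in% hand_categories())
  problems <- c(problems,
                vapply(badd, function(r)
                  note(r, "diagnosis",
                       paste0("unknown label '", df$diagnosis[r], "'")),
                  character(1)))
  if (length(problems))
    stop("invalid cohort file:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  df$diagnosis <- toupper(df$diagnosis)
  if ("efavirenz" %in% names(df)) df$efavirenz <- as.logical(df$efavirenz)
  class(df) <- c("hand_cohort", "data.frame")
  df
}

#' @rdname read_cohort
#' @param cohort a `hand_cohort` data.frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Score one cohort: z-scores, domain flags, and per-patient decisions
#'
#' Applies the normative scoring and all decision rules to every patient,
#' without the accuracy evaluation. The workhorse behind [run_pipeline()].
#'
#' @param cohort a `hand_cohort` data.frame.
#' @param norms a `hand_norms` table.
#' @param config a [screen_config()].
#' @return a list with `z` (patients x tests matrix), `domain_flags`
#'   (patients x domains logical matrix), and per-patient vectors `screen`,
#'   `complainer`, `depressive`, `combined`, plus `unevaluable` (list of
#'   domains without scores, per patient).
#' @export
score_cohort <- function(cohort, norms = demo_norms(),
                         config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  n <- nrow(cohort)
  tests <- hand_tests()
  tcols <- cohort_test_cols()
  map <- check_domain_map(default_domain_map())

  # z-scores, vectorized per test over the age-banded norms (equivalent to
  # standard_score() patient by patient; that equivalence is under test)
  z <- matrix(NA_real_, n, length(tests), dimnames = list(NULL, tests))
  for (t in tests) {
    raw <- cohort[[tcols[[t]]]]
    if (any(!is.na(raw) & (!is.finite(raw) | raw < 0)))
      stop("non-finite or negative raw score for test ", t, call. = FALSE)
    nb <- norms[norms$test == t, , drop = FALSE]
    nb <- nb[order(nb$age_min), , drop = FALSE]
    if (nrow(nb) == 0)
      stop("norms contain no entry for test ", t, call. = FALSE)
    band <- findInterval(cohort$age, nb$age_min)
    uncovered <- !is.na(raw) &
      (band == 0 | cohort$age > nb$age_max[pmax(band, 1)])
    if (any(uncovered))
      stop("no normative age band covers test ", t, " for patient(s) ",
           paste(utils::head(cohort$patient_id[uncovered], 5),
                 collapse = ", "),
           " (age ", paste(utils::head(cohort$age[uncovered], 5),
                           collapse = ", "), ")", call. = FALSE)
    m <- nb$mean[pmax(band, 1)]; s <- nb$sd[pmax(band, 1)]
    z[, t] <- if (test_direction(t) == "higher_worse")
      (m - raw) / s else (raw - m) / s
  }

  # domain rule: a domain is flagged iff any member test is flagged; a
  # domain with no scored member test is unevaluable, never pathological
  test_flag <- z < config$cutoff
  dflags <- matrix(FALSE, n, 4, dimnames = list(NULL, hand_domains()))
  unev <- matrix(FALSE, n, 4, dimnames = list(NULL, hand_domains()))
  for (d in hand_domains()) {
    member <- test_flag[, map[[d]], drop = FALSE]
    dflags[, d] <- rowSums(member, na.rm = TRUE) > 0
    unev[, d] <- rowSums(!is.na(member)) == 0
  }
  unevaluable <- lapply(seq_len(n), function(i) hand_domains()[unev[i, ]])
  n_unev <- sum(rowSums(unev) > 0)
  if (n_unev > 0)
    warning(n_unev, " patient(s) have unevaluable domain(s) (no scored ",
            "test); those domains were treated as not pathological",
            call. = FALSE)
  screen <- rowSums(dflags) >= config$min_domains

  # questionnaire flags, vectorized over the ordinal scales
  qcols <- cohort_q_cols()
  endorsed <- function(col, threshold, levels) {
    v <- cohort[[col]]
    bad <- !is.na(v) & !v %in% levels
    if (any(bad))
      stop("invalid response '", v[bad][1], "' in column ", col,
           call. = FALSE)
    !is.na(v) & match(v, levels) >= match(threshold, levels)
  }
  complainer <- Reduce(`|`, lapply(config$sci_items, function(it)
    endorsed(qcols[[it]], config$sci_threshold, sci_levels())))
  depressive <- endorsed(qcols[["interest"]], config$depression_threshold,
                         depression_levels()) |
    endorsed(qcols[["mood"]], config$depression_threshold,
             depression_levels())

  list(z = z, domain_flags = dflags, screen = screen,
       complainer = complainer, depressive = depressive,
       combined = combined_decision(screen, complainer),
       unevaluable = unevaluable)
}

#' Run the full screening analysis
#'
#' End-to-end evaluation of the screening battery on a cohort with
#' reference-standard diagnoses: normative scoring, domain classification,
#' screen/complainer/combined decisions, 2x2 tables and accuracy metrics
#' with exact confidence intervals (overall, complaint-stratified, and for
#' the combined criterion), and a descriptive comparison of screen-positive
#' versus screen-negative patients. Deterministic given its inputs.
#'
#' @param cohort a `hand_cohort` data.frame (see [read_cohort()]).
#' @param norms a `hand_norms` table; default the shipped demonstration
#'   norms.
#' @param config a [screen_config()]; defaults reproduce the published
#'   analysis.
#' @return an object of class `hand_screen_eval` with components `scores`
#'   (the [score_cohort()] result), `crosstab`, `accuracy`
#'   (a `stratified_accuracy` list), `sci_accuracy` (complaint alone as the
#'   index test), `comparison` (screen-positive vs negative descriptives),
#'   `cohort`, and `config`.
#' @examples
#' fit <- run_pipeline(reference_cohort())
#' fit
#' summary(fit)
#' @export
run_pipeline <- function(cohort, norms = demo_norms(),
                         config = screen_config()) {
  if (!is.null(config$norms_path)) norms <- read_norms(config$norms_path)
  scores <- score_cohort(cohort, norms, config)
  diagnosis <- cohort$diagnosis
  ct <- crosstab(scores$screen, diagnosis)
  acc <- stratified_evaluation(scores$screen, scores$complainer, diagnosis,
                               config$alpha)
  sci_acc <- accuracy_metrics(crosstab(scores$complainer, diagnosis),
                              config$alpha)
  cont <- intersect(c("age", "education"), names(cohort))
  cat_vars <- intersect(c("efavirenz"), names(cohort))
  comparison <- compare_groups(
    cbind(as.data.frame(cohort),
          complainer = scores$complainer, depressive = scores$depressive),
    scores$screen, continuous = cont,
    categorical = c(cat_vars, "complainer", "depressive"))
  structure(list(scores = scores, crosstab = ct, accuracy = acc,
                 sci_accuracy = sci_acc, comparison = comparison,
                 cohort = cohort, config = config, norms = norms),
            class = "hand_screen_eval")
}

#' @export
print.hand_screen_eval <- function(x, ...) {
  n <- nrow(x$cohort)
  npos <- sum(x$scores$screen)
  nhand <- sum(hand_positive(x$cohort$diagnosis))
  cat(sprintf("Screening battery evaluation: %d patients, %d (%.0f%%) HAND,",
              n, nhand, 100 * nhand / n),
      sprintf("%d (%.0f%%) screen-positive\n", npos, 100 * npos / n))
  print(x$crosstab)
  print(x$accuracy$overall)
  invisible(x)
}

#' @export
summary.hand_screen_eval <- function(object, ...) {
  x <- object
  n <- nrow(x$cohort)
  dx <- table(factor(x$cohort$diagnosis, hand_categories()))
  nhand <- sum(dx[c("ANI", "MND", "HAD")])
  cat("=== Cohort ===\n")
  cat(sprintf("  n = %d; HAND %d (%.0f%%): ANI %d, MND %d, HAD %d\n",
              n, nhand, 100 * nhand / n, dx[["ANI"]], dx[["MND"]],
              dx[["HAD"]]))
  cat(sprintf("  complainers: %d (%d among HAND, %.0f%% of HAND)\n",
              sum(x$scores$complainer),
              sum(x$scores$complainer & hand_positive(x$cohort$diagnosis)),
              100 * sum(x$scores$complainer &
                          hand_positive(x$cohort$diagnosis)) / nhand))
  cat("\n=== Complaint alone as index test ===\n")
  print(x$sci_accuracy)
  cat("\n=== Screen against reference standard ===\n")
  print(x$crosstab)
  print(x$accuracy)
  cat("\n=== Characteristics by screen result ===\n")
  print(x$comparison)
  invisible(x)
}

#' @export
plot.hand_screen_eval <- function(x, ...) {
  reports <- Filter(Negate(is.null), unclass(x$accuracy))
  labs <- c(overall = "overall", non_complainers = "non-compl.",
            complainers = "compl.", combined = "combined")
  metrics <- c("sensitivity", "specificity", "ppv", "npv")
  k <- 0
  est <- lo <- hi <- numeric(0); lab <- character(0)
  for (s in names(reports)) for (m in metrics) {
    r <- reports[[s]][reports[[s]]$metric == m, ]
    if (is.na(r$estimate)) next
    k <- k + 1
    est[k] <- r$estimate; lo[k] <- r$lower; hi[k] <- r$upper
    lab[k] <- paste(labs[[s]], m)
  }
  old <- graphics::par(mar = c(4, 10, 2, 1)); on.exit(graphics::par(old))
  graphics::plot(est, seq_len(k), xlim = c(0, 1), yaxt = "n",
                 xlab = "proportion (exact 95% CI)", ylab = "",
                 pch = 19, main = "Screen accuracy")
  graphics::segments(lo, seq_len(k), hi, seq_len(k))
  graphics::axis(2, at = seq_len(k), labels = lab, las = 1, cex.axis = 0.7)
  invisible(x)
}

#' Per-patient JSON screen report
#'
#' Serializes an evaluation to JSON: the rule parameters used and, per
#' patient, the z-scores, domain flags, and screen/complainer/combined
#' decisions — an audit trail of which test fired which domain.
#'
#' @param eval a `hand_screen_eval` object.
#' @param path optional file path; when given the JSON is written there.
#' @return the JSON string, invisibly when written to file.
#' @export
screen_report <- function(eval, path = NULL) {
  stopifnot(inherits(eval, "hand_screen_eval"))
  patients <- lapply(seq_len(nrow(eval$cohort)), function(i) list(
    patient_id = eval$cohort$patient_id[i],
    z = as.list(round(eval$scores$z[i, ], 3)),
    domain_flags = as.list(eval$scores$domain_flags[i, ]),
    unevaluable_domains = eval$scores$unevaluable[[i]],
    screen_positive = eval$scores$screen[i],
    complainer = eval$scores$complainer[i],
    depressive = eval$scores$depressive[i],
    combined_positive = eval$scores$combined[i]
  ))
  obj <- list(config = unclass(eval$config), patients = patients)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE, null = "null")
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
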