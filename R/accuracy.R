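hand_categories <- function() c("NORMAL", "ANI", "MND", "HAD")

#' Is a diagnosis HAND-positive?
#'
#' HAND (HIV-associated neurocognitive disorder) subsumes ANI, MND and HAD;
#' `NORMAL` is the only HAND-negative category.
#'
#' @param diagnosis character vector of categories `NORMAL`, `ANI`, `MND`,
#'   `HAD` (or a logical vector, returned unchanged).
#' @return logical vector.
#' @export
hand_positive <- function(diagnosis) {
  if (is.logical(diagnosis)) return(diagnosis)
  diagnosis <- toupper(as.character(diagnosis))
  bad <- setdiff(diagnosis[!is.na(diagnosis)], hand_categories())
  if (length(bad))
    stop("unknown diagnosis label(s): ", paste(unique(bad), collapse = ", "),
         call. = FALSE)
  diagnosis %in% c("ANI", "MND", "HAD")
}

#' Cross-tabulate screen result against the reference standard
#'
#' Counts the 2x2 table of screen result (positive/negative) against the
#' reference-standard diagnosis (HAND / normal cognition).
#'
#' @param screen logical vector of screen results.
#' @param diagnosis diagnosis labels (`NORMAL`/`ANI`/`MND`/`HAD`) or a
#'   logical HAND indicator, aligned with `screen`.
#' @return an object of class `hand_crosstab`: a list with integer counts
#'   `tp` (screen+, HAND), `fp` (screen+, normal), `fn` (screen-, HAND),
#'   `tn` (screen-, normal).
#' @examples
#' ct <- crosstab(c(TRUE, TRUE, FALSE), c("ANI", "NORMAL", "MND"))
#' as.matrix(ct)
#' @export
crosstab <- function(screen, diagnosis) {
  if (length(screen) != length(diagnosis))
    stop("screen and diagnosis differ in length", call. = FALSE)
  disease <- hand_positive(diagnosis)
  if (anyNA(screen) || anyNA(disease))
    stop("missing screen result or diagnosis label", call. = FALSE)
  structure(list(tp = sum(screen & disease),
                 fp = sum(screen & !disease),
                 fn = sum(!screen & disease),
                 tn = sum(!screen & !disease)),
            class = "hand_crosstab")
}

#' @export
as.matrix.hand_crosstab <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), nrow = 2,
              dimnames = list(screen = c("positive", "negative"),
                              reference = c("HAND", "normal")))
  m
}

#' @export
print.hand_crosstab <- function(x, ...) {
  m <- as.matrix(x)
  m <- cbind(m, total = rowSums(m))
  m <- rbind(m, total = colSums(m))
  cat("Screen result x reference standard\n")
  print(m)
  invisible(x)
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval for a binomial proportion, in the beta-quantile
#' form: lower = qbeta(alpha/2; k, n-k+1), upper = qbeta(1-alpha/2; k+1, n-k),
#' with lower = 0 when k = 0 and upper = 1 when k = n. Equivalent to
#' inverting the exact binomial test.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @param alpha two-sided significance level in (0, 1), default `0.05`.
#' @return numeric vector `c(lower, upper)` of proportions.
#' @examples
#' clopper_pearson(16, 25)  # the screen's sensitivity CI, 42-82%
#' @export
clopper_pearson <- function(k, n, alpha = 0.05) {
  if (!is.numeric(k) || !is.numeric(n) || length(k) != 1 || length(n) != 1 ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stop("require integer counts with 0 <= k <= n and n >= 1", call. = FALSE)
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1", call. = FALSE)
  lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  c(lower = lower, upper = upper)
}

binom_ci <- function(k, n, alpha) {
  if (is.na(n) || n == 0)
    return(c(estimate = NA_real_, lower = NA_real_, upper = NA_real_))
  ci <- clopper_pearson(k, n, alpha)
  c(estimate = k / n, lower = unname(ci[1]), upper = unname(ci[2]))
}

#' Accuracy metrics with exact confidence intervals
#'
#' Sensitivity, specificity, positive and negative predictive value from a
#' 2x2 table, each with its Clopper-Pearson interval computed on the metric's
#' own numerator and denominator. A metric whose denominator is zero is
#' reported as undefined (`NA`), never as 0 — with strata of a handful of
#' patients this is a live possibility, and silently coercing it to a number
#' would corrupt downstream summaries.
#'
#' @param ct a `hand_crosstab` (or a list with fields `tp`, `fp`, `fn`,
#'   `tn`).
#' @param alpha two-sided level for the intervals, default `0.05`.
#' @return an object of class `accuracy_report`: a data.frame with one row
#'   per metric and columns `metric`, `estimate`, `lower`, `upper`, `k`, `n`.
#' @examples
#' accuracy_metrics(crosstab(rep(c(TRUE, FALSE), c(17, 13)),
#'                           rep(c("ANI", "NORMAL", "ANI", "NORMAL"),
#'                               c(16, 1, 9, 4))))
#' @export
accuracy_metrics <- function(ct, alpha = 0.05) {
  for (f in c("tp", "fp", "fn", "tn"))
    if (is.null(ct[[f]]) || ct[[f]] < 0 || ct[[f]] != round(ct[[f]]))
      stop("contingency table needs non-negative integer counts tp/fp/fn/tn",
           call. = FALSE)
  num <- c(sensitivity = ct$tp, specificity = ct$tn,
           ppv = ct$tp, npv = ct$tn)
  den <- c(sensitivity = ct$tp + ct$fn, specificity = ct$tn + ct$fp,
           ppv = ct$tp + ct$fp, npv = ct$tn + ct$fn)
  rows <- lapply(names(num), function(m) {
    est <- binom_ci(num[[m]], den[[m]], alpha)
    data.frame(metric = m, estimate = est[["estimate"]],
               lower = est[["lower"]], upper = est[["upper"]],
               k = num[[m]], n = den[[m]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "alpha") <- alpha
  attr(out, "crosstab") <- ct
  class(out) <- c("accuracy_report", "data.frame")
  out
}

#' Round a proportion to an integer percentage, half away from zero
#'
#' The convention used for reporting: 16/17 prints as 94, 4/13 as 31.
#' (Base R's `round()` rounds half to even, which would print 0.125 as 12;
#' clinical tables round half up.)
#'
#' @param p proportion(s) in `[0, 1]`, `NA` allowed.
#' @return integer percentage(s).
#' @export
pct <- function(p) {
  ifelse(is.na(p), NA_real_, floor(100 * p + 0.5))
}

#' @export
print.accuracy_report <- function(x, ...) {
  a <- attr(x, "alpha")
  cat(sprintf("Diagnostic accuracy (%.0f%% exact CIs)\n", 100 * (1 - a)))
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-11s undefined (denominator 0)\n", x$metric[i]))
    } else {
      cat(sprintf("  %-11s %3.0f%% (%d/%d, CI %.0f-%.0f%%)\n",
                  x$metric[i], pct(x$estimate[i]), x$k[i], x$n[i],
                  pct(x$lower[i]), pct(x$upper[i])))
    }
  }
  invisible(x)
}

#' Complaint-stratified and combined-criterion evaluation
#'
#' Evaluates the screen against the reference standard (i) in the whole
#' cohort, (ii) among non-complainers, (iii) among complainers, and (iv) for
#' the combined criterion (screen positive OR complainer) in the whole
#' cohort. An empty stratum yields a report marked empty rather than an
#' error.
#'
#' @param screen logical screen results.
#' @param complainer logical SCI flags, aligned.
#' @param diagnosis diagnosis labels or logical HAND indicator, aligned.
#' @param alpha CI level, default `0.05`.
#' @return a list of class `stratified_accuracy` with elements `overall`,
#'   `non_complainers`, `complainers`, `combined`, each an
#'   `accuracy_report` (or `NULL` with an `empty_strata` attribute when a
#'   stratum has no patients).
#' @export
stratified_evaluation <- function(screen, complainer, diagnosis,
                                  alpha = 0.05) {
  n <- length(screen)
  if (length(complainer) != n || length(diagnosis) != n)
    stop("screen, complainer and diagnosis must be aligned", call. = FALSE)
  if (anyNA(screen) || anyNA(complainer))
    stop("screen and complainer flags must be complete", call. = FALSE)
  eval_subset <- function(idx, flags) {
    if (!length(idx)) return(NULL)
    accuracy_metrics(crosstab(flags[idx], diagnosis[idx]), alpha)
  }
  out <- list(
    overall = eval_subset(seq_len(n), screen),
    non_complainers = eval_subset(which(!complainer), screen),
    complainers = eval_subset(which(complainer), screen),
    combined = eval_subset(seq_len(n), combined_decision(screen, complainer))
  )
  attr(out, "empty_strata") <- names(out)[vapply(out, is.null, logical(1))]
  attr(out, "n") <- c(overall = n,
                      non_complainers = sum(!complainer),
                      complainers = sum(complainer), combined = n)
  class(out) <- "stratified_accuracy"
  out
}

#' @export
print.stratified_accuracy <- function(x, ...) {
  n <- attr(x, "n")
  labs <- c(overall = "Whole cohort, screen alone",
            non_complainers = "Non-complainers, screen alone",
            complainers = "Complainers, screen alone",
            combined = "Whole cohort, screen OR complaint")
  for (s in names(x)) {
    cat(sprintf("-- %s (n = %d)\n", labs[[s]], n[[s]]))
    if (is.null(x[[s]])) cat("   empty stratum\n") else print(x[[s]])
  }
  invisible(x)
}

#' Descriptive comparison of two screen-result groups
#'
#' Compares baseline variables between screen-positive and screen-negative
#' patients: continuous variables by median (IQR) and a two-sided
#' Mann-Whitney test, binary variables by count (%) and Fisher's exact test
#' when any expected 2x2 cell is below 5, chi-square otherwise. A variable
#' that is constant overall, or a group of size zero, gives an `NA` p-value
#' with a note.
#'
#' @param cohort a data.frame of patient records.
#' @param group logical grouping flag (typically the screen result), aligned
#'   with the rows of `cohort`.
#' @param continuous names of numeric columns to compare.
#' @param categorical names of logical (or two-level) columns to compare.
#' @return a data.frame of class `group_comparison` with one row per
#'   variable: summaries per group, the test used, and the two-sided p.
#' @export
compare_groups <- function(cohort, group,
                           continuous = character(0),
                           categorical = character(0)) {
  stopifnot(is.logical(group), length(group) == nrow(cohort))
  g1 <- which(group); g0 <- which(!group)
  summarize_cont <- function(v, idx) {
    if (!length(idx)) return("-")
    q <- stats::quantile(v[idx], c(.25, .5, .75), na.rm = TRUE, names = FALSE)
    sprintf("%.1f (%.1f-%.1f)", q[2], q[1], q[3])
  }
  rows <- list()
  for (v in continuous) {
    x <- cohort[[v]]
    note <- ""; p <- NA_real_; test <- "mann_whitney"
    if (!length(g1) || !length(g0)) {
      note <- "empty group; comparison skipped"
      warning("empty group: skipping comparison for ", v, call. = FALSE)
    } else if (length(unique(stats::na.omit(x))) < 2) {
      note <- "constant variable; p undefined"
    } else {
      # plain normal-approximation Mann-Whitney without continuity
      # correction (ranksum convention): identical groups give p = 1
      p <- stats::wilcox.test(x[g1], x[g0], exact = FALSE,
                              correct = FALSE)$p.value
    }
    rows[[v]] <- data.frame(
      variable = v, type = "continuous",
      group_pos = summarize_cont(x, g1), group_neg = summarize_cont(x, g0),
      test = test, p = p, note = note, stringsAsFactors = FALSE)
  }
  summarize_bin <- function(x, idx) {
    if (!length(idx)) return("-")
    k <- sum(x[idx], na.rm = TRUE)
    sprintf("%d/%d (%.0f%%)", k, length(idx), 100 * k / length(idx))
  }
  for (v in categorical) {
    x <- cohort[[v]]
    if (!is.logical(x)) x <- as.logical(x)
    note <- ""; p <- NA_real_; test <- NA_character_
    if (!length(g1) || !length(g0)) {
      note <- "empty group; comparison skipped"
      warning("empty group: skipping comparison for ", v, call. = FALSE)
    } else if (length(unique(stats::na.omit(x))) < 2) {
      note <- "constant variable; p undefined"
    } else {
      tab <- table(factor(group, c(FALSE, TRUE)), factor(x, c(FALSE, TRUE)))
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      if (any(expected < 5)) {
        test <- "fisher_exact"
        p <- stats::fisher.test(tab)$p.value
      } else {
        test <- "chi_square"
        p <- stats::chisq.test(tab, correct = FALSE)$p.value
      }
    }
    rows[[v]] <- data.frame(
      variable = v, type = "categorical",
      group_pos = summarize_bin(x, g1), group_neg = summarize_bin(x, g0),
      test = test, p = p, note = note, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("Characteristics by screen result (positive vs negative)\n")
  df <- as.data.frame(x)
  df$p <- ifelse(is.na(df$p), "-", sprintf("%.3f", df$p))
  print(df, row.names = FALSE)
  invisible(x)
}
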