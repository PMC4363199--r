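#' The seven screening tests
#'
#' Identifiers of the seven neuropsychological tests in the battery, and the
#' direction in which a raw score worsens.
#'
#' Timed tests (Trail Making A and B, Grooved Pegboard dominant and
#' non-dominant hand) worsen as the raw score (seconds) increases; count-based
#' tests (Digit Symbol, wordlist learning and delayed recall) worsen as the
#' raw score (correct items) decreases. [standard_score()] folds this
#' direction into one convention: negative z always means worse performance.
#'
#' @return `hand_tests()` returns the character vector of the seven test
#'   identifiers. `test_direction()` returns, for each test, either
#'   `"higher_worse"` or `"lower_worse"`.
#' @examples
#' hand_tests()
#' test_direction("TMT_A")
#' @export
hand_tests <- function() {
  c("TMT_A", "TMT_B", "DST", "WORDLIST_LEARNING", "WORDLIST_RECALL",
    "PEGBOARD_DOM", "PEGBOARD_NONDOM")
}

#' @rdname hand_tests
#' @param test character vector of test identifiers.
#' @export
test_direction <- function(test) {
  test <- match_test(test)
  dir <- c(TMT_A = "higher_worse", TMT_B = "higher_worse",
           DST = "lower_worse",
           WORDLIST_LEARNING = "lower_worse", WORDLIST_RECALL = "lower_worse",
           PEGBOARD_DOM = "higher_worse", PEGBOARD_NONDOM = "higher_worse")
  unname(dir[test])
}

match_test <- function(test) {
  test <- toupper(as.character(test))
  bad <- setdiff(test, hand_tests())
  if (length(bad))
    stop("unknown test identifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  test
}

#' Read a normative table
#'
#' Reads a CSV of age-banded normative means and standard deviations, one row
#' per (test, age band). Expected header: `test,age_min,age_max,mean,sd`,
#' optionally followed by `education_min,education_max` (recorded but not used
#' by the default scoring, which stratifies by age only).
#'
#' Age bands are closed integer intervals; for a given test they must not
#' overlap. The normative values themselves are site configuration — the
#' package ships an illustrative table (see [demo_norms()]) whose Trail Making
#' A band for ages 40-49 (mean 31 s, SD 9 s) places the pathological cutoff at
#' 40 seconds.
#'
#' @param path path to the norms CSV.
#' @return a `data.frame` of class `hand_norms`.
#' @seealso [standard_score()], [raw_cutoff()], [nurse_lookup()]
#' @export
read_norms <- function(path) {
  if (!file.exists(path)) stop("norms file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_hand_norms(df)
}

#' @rdname read_norms
#' @param df a data.frame with the norms columns, e.g. built in code.
#' @export
as_hand_norms <- function(df) {
  req <- c("test", "age_min", "age_max", "mean", "sd")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("norms table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0)
    stop("norms table is empty: at least one normative entry is required",
         call. = FALSE)
  df$test <- match_test(df$test)
  for (col in c("age_min", "age_max", "mean", "sd")) {
    df[[col]] <- as.numeric(df[[col]])
    if (anyNA(df[[col]]))
      stop("non-numeric value in norms column '", col, "'", call. = FALSE)
  }
  if (any(df$sd <= 0)) {
    i <- which(df$sd <= 0)[1]
    stop(sprintf("norms: sd must be > 0 (test %s, band %d-%d)",
                 df$test[i], df$age_min[i], df$age_max[i]), call. = FALSE)
  }
  if (any(df$age_min > df$age_max)) {
    i <- which(df$age_min > df$age_max)[1]
    stop(sprintf("norms: empty age band for test %s (%d-%d)",
                 df$test[i], df$age_min[i], df$age_max[i]), call. = FALSE)
  }
  for (t in unique(df$test)) {
    b <- df[df$test == t, , drop = FALSE]
    b <- b[order(b$age_min), , drop = FALSE]
    if (nrow(b) > 1 && any(b$age_min[-1] <= b$age_max[-nrow(b)])) {
      j <- which(b$age_min[-1] <= b$age_max[-nrow(b)])[1]
      stop(sprintf("norms: overlapping age bands for test %s (%d-%d and %d-%d)",
                   t, b$age_min[j], b$age_max[j],
                   b$age_min[j + 1], b$age_max[j + 1]), call. = FALSE)
    }
  }
  class(df) <- c("hand_norms", "data.frame")
  df
}

#' @export
print.hand_norms <- function(x, ...) {
  cat("Normative table:", length(unique(x$test)), "test(s),",
      nrow(x), "age band(s)\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Illustrative normative table shipped with the package
#'
#' Age-banded demonstration norms for the seven tests, covering ages 20-79 in
#' five bands. They are illustrative values of plausible magnitude, not any
#' published normative dataset; their Trail Making A band for ages 40-49
#' (mean 31, SD 9) reproduces the 40-second pathological cutoff used as the
#' worked example of the nurse lookup table.
#'
#' @return a `hand_norms` table.
#' @export
demo_norms <- function() {
  path <- system.file("extdata", "demo_norms.csv", package = "handscreen")
  read_norms(path)
}

find_norm <- function(norms, test, age) {
  test <- match_test(test)
  hit <- norms$test == test & norms$age_min <= age & age <= norms$age_max
  if (!any(hit))
    stop(sprintf("no normative age band covers test %s at age %s", test, age),
         call. = FALSE)
  norms[which(hit)[1], , drop = FALSE]
}

#' Convert a raw test score to a normative standard score
#'
#' Looks up the normative mean and SD for the subject's age band and returns
#' the standard score z, oriented so that negative z means worse performance
#' regardless of the test's raw direction: for timed tests
#' z = (mean - raw) / sd, for count tests z = (raw - mean) / sd. Under this
#' convention "a standard score below -1.0" always denotes impairment.
#'
#' @param raw raw score (seconds or correct items); finite and non-negative.
#' @param test a test identifier, see [hand_tests()].
#' @param age age in whole years.
#' @param norms a `hand_norms` table.
#' @return the standard score z (numeric scalar).
#' @examples
#' norms <- as_hand_norms(data.frame(test = "TMT_A", age_min = 40,
#'                                   age_max = 49, mean = 31, sd = 9))
#' standard_score(41, "TMT_A", 45, norms)  # slower than the 40 s cutoff
#' @export
standard_score <- function(raw, test, age, norms) {
  stopifnot(is.numeric(raw), length(raw) == 1)
  if (!is.finite(raw) || raw < 0)
    stop("raw score must be finite and non-negative", call. = FALSE)
  entry <- find_norm(norms, test, age)
  if (test_direction(test) == "higher_worse")
    (entry$mean - raw) / entry$sd
  else
    (raw - entry$mean) / entry$sd
}

#' Flag an individually pathological test result
#'
#' A single test result is pathological when its standard score lies strictly
#' below the cutoff (default -1.0). The boundary value z = cutoff is not
#' pathological.
#'
#' @param z standard score(s), oriented negative-is-worse.
#' @param cutoff dimensionless cutoff, default `-1`.
#' @return logical vector; `NA` stays `NA` (missing test).
#' @export
flag_test <- function(z, cutoff = -1) {
  stopifnot(is.numeric(z))
  z < cutoff
}

#' Raw-score threshold corresponding to the z cutoff
#'
#' Inverts the standard-score transform: the raw value at which z equals the
#' cutoff, together with the direction of pathological exceedance. For a
#' timed test the result is pathological when it takes *more* than the
#' threshold seconds; for a count test, when *fewer* than the threshold items
#' are correct. This is what the nurse-facing lookup table prints.
#'
#' @inheritParams standard_score
#' @param cutoff dimensionless z cutoff, default `-1`.
#' @return a list with `threshold` (raw units) and `direction`
#'   (`"more_than"` or `"fewer_than"`).
#' @examples
#' norms <- as_hand_norms(data.frame(test = "TMT_A", age_min = 40,
#'                                   age_max = 49, mean = 31, sd = 9))
#' raw_cutoff("TMT_A", 45, norms)  # pathological if more than 40 seconds
#' @export
raw_cutoff <- function(test, age, norms, cutoff = -1) {
  entry <- find_norm(norms, test, age)
  if (test_direction(test) == "higher_worse")
    list(threshold = entry$mean - cutoff * entry$sd, direction = "more_than")
  else
    list(threshold = entry$mean + cutoff * entry$sd, direction = "fewer_than")
}

#' Nurse-facing lookup table of raw cutoffs
#'
#' Expands a normative table into one row per (test, age band) with the raw
#' threshold at the z cutoff and the direction of pathological exceedance —
#' the printed form handed to the administering nurses.
#'
#' @param norms a `hand_norms` table.
#' @param cutoff z cutoff, default `-1`.
#' @param path optional path; if given the table is also written as CSV.
#' @return a data.frame with columns
#'   `test,age_min,age_max,direction,raw_cutoff`.
#' @export
nurse_lookup <- function(norms, cutoff = -1, path = NULL) {
  out <- data.frame(
    test = norms$test,
    age_min = norms$age_min,
    age_max = norms$age_max,
    direction = test_direction(norms$test),
    raw_cutoff = ifelse(test_direction(norms$test) == "higher_worse",
                        norms$mean - cutoff * norms$sd,
                        norms$mean + cutoff * norms$sd),
    stringsAsFactors = FALSE
  )
  out$direction <- ifelse(out$direction == "higher_worse",
                          "more_than", "fewer_than")
  if (!is.null(path)) utils::write.csv(out, path, row.names = FALSE)
  out
}
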