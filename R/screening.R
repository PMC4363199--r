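#' The four cognitive domains and the test-to-domain map
#'
#' The battery evaluates four domains — cognitive speed, memory, executive
#' function and motor speed. Several tests serve more than one domain: a slow
#' Trail Making A, for instance, counts against both cognitive speed and
#' motor speed.
#'
#' @return `hand_domains()` returns the four domain identifiers;
#'   `default_domain_map()` returns the default assignment as a named list of
#'   test-identifier vectors.
#' @examples
#' default_domain_map()
#' @export
hand_domains <- function() {
  c("COGNITIVE_SPEED", "MEMORY", "EXECUTIVE", "MOTOR_SPEED")
}

#' @rdname hand_domains
#' @export
default_domain_map <- function() {
  list(
    COGNITIVE_SPEED = c("TMT_A", "TMT_B", "DST"),
    MEMORY = c("WORDLIST_LEARNING", "WORDLIST_RECALL"),
    EXECUTIVE = "TMT_B",
    MOTOR_SPEED = c("DST", "PEGBOARD_DOM", "PEGBOARD_NONDOM", "TMT_A", "TMT_B")
  )
}

check_domain_map <- function(map) {
  if (!setequal(names(map), hand_domains()))
    stop("domain map must name exactly the four domains: ",
         paste(hand_domains(), collapse = ", "), call. = FALSE)
  for (d in names(map)) {
    if (length(map[[d]]) == 0)
      stop("domain ", d, " has no tests assigned", call. = FALSE)
    map[[d]] <- match_test(map[[d]])
  }
  map
}

#' Classify the four domains from standard scores
#'
#' A domain is pathological if at least one of its constituent tests has a
#' standard score strictly below the cutoff. A domain whose tests were all
#' missing cannot be evaluated: it is reported unflagged and listed in the
#' `"unevaluable"` attribute (conservative; a missing test never counts as
#' impaired).
#'
#' @param z named numeric vector of standard scores, names from
#'   [hand_tests()]; `NA` marks a missing test. At most one score per test.
#' @param map a domain map, default [default_domain_map()].
#' @param cutoff z cutoff, default `-1`.
#' @return named logical vector over the four domains, with attribute
#'   `unevaluable` listing domains with no scored test.
#' @examples
#' z <- c(TMT_A = -1.2, TMT_B = 0, DST = 0, WORDLIST_LEARNING = 0,
#'        WORDLIST_RECALL = 0, PEGBOARD_DOM = 0, PEGBOARD_NONDOM = 0)
#' classify_domains(z)  # cognitive speed and motor speed flagged
#' @export
classify_domains <- function(z, map = default_domain_map(), cutoff = -1) {
  stopifnot(is.numeric(z))
  if (is.null(names(z)) || any(!nzchar(names(z))))
    stop("scores must be named by test identifier", call. = FALSE)
  names(z) <- match_test(names(z))
  if (anyDuplicated(names(z)))
    stop("duplicate score for test ",
         names(z)[duplicated(names(z))][1], call. = FALSE)
  map <- check_domain_map(map)
  covered <- unlist(map, use.names = FALSE)
  orphan <- setdiff(names(z), covered)
  if (length(orphan))
    stop("test(s) not assigned to any domain: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  test_flag <- flag_test(z, cutoff)
  flags <- logical(length(map))
  names(flags) <- names(map)
  unevaluable <- character(0)
  for (d in names(map)) {
    f <- test_flag[intersect(map[[d]], names(z))]
    if (length(f) == 0 || all(is.na(f))) {
      flags[d] <- FALSE
      unevaluable <- c(unevaluable, d)
    } else {
      flags[d] <- any(f, na.rm = TRUE)
    }
  }
  structure(flags, unevaluable = unevaluable)
}

#' Overall screen decision from domain flags
#'
#' The screen is positive when the number of pathological domains reaches
#' `min_domains` (default 2, the "deficits in two or more domains" rule).
#'
#' @param domain_flags named logical vector over the four domains, as
#'   returned by [classify_domains()].
#' @param min_domains positive integer, default `2`.
#' @return single logical.
#' @export
screen_decision <- function(domain_flags, min_domains = 2) {
  stopifnot(is.logical(domain_flags), length(domain_flags) == 4,
            min_domains >= 1)
  sum(domain_flags, na.rm = TRUE) >= min_domains
}

sci_levels <- function() c("never", "rarely", "sometimes", "often", "always")
depression_levels <- function()
  c("not_at_all", "several_days", "more_than_half", "nearly_every_day")

sci_item_names <- function()
  c("memory_loss", "slowed_thinking", "attention",
    "prospective_memory", "informant_remarks")

get_item <- function(resp, name) {
  if (is.null(resp) || !name %in% names(resp)) NULL else resp[[name]]
}

ordinal_at_least <- function(resp, threshold, levels) {
  if (is.null(resp) || is.na(resp)) return(NA)
  resp <- as.character(resp)
  if (!resp %in% levels)
    stop("unknown ordinal response '", resp, "' (expected one of ",
         paste(levels, collapse = ", "), ")", call. = FALSE)
  match(resp, levels) >= match(match.arg(threshold, levels), levels)
}

#' Score the subjective cognitive impairment (SCI) questionnaire
#'
#' Five items on a never/rarely/sometimes/often/always scale probe memory
#' loss, slowed thinking, attention, prospective memory, and remarks by
#' friends or family. A patient is a "complainer" when any of the configured
#' items (default: memory loss or attention, mirroring "memory loss or
#' difficulties to concentrate") is endorsed at or above the threshold level
#' (default "often"). The two robustness items (prospective memory, informant
#' remarks) are recorded but excluded from the default rule. A missing item
#' counts as not endorsed.
#'
#' @param resp named list or character vector of item responses; recognised
#'   names: `memory_loss`, `slowed_thinking`, `attention`,
#'   `prospective_memory`, `informant_remarks`.
#' @param threshold level at or above which an item counts as endorsed,
#'   default `"often"`.
#' @param items which items enter the rule, default
#'   `c("memory_loss", "attention")`.
#' @return single logical: complainer or not.
#' @examples
#' score_sci(list(memory_loss = "often", attention = "rarely"))
#' @export
score_sci <- function(resp, threshold = "often",
                      items = c("memory_loss", "attention")) {
  items <- match.arg(items, sci_item_names(), several.ok = TRUE)
  hit <- vapply(items, function(it)
    isTRUE(ordinal_at_least(get_item(resp, it), threshold, sci_levels())),
    logical(1))
  any(hit)
}

#' Score the two depression items
#'
#' Two items on a not-at-all / several-days / more-than-half-the-days /
#' nearly-every-day scale (loss of interest, depressed mood over the past two
#' weeks). The flag is raised when either item reaches the threshold (default
#' "more_than_half"). Used for cohort description only; it never enters the
#' screen decision. Both items missing makes the flag unevaluable (`NA`).
#'
#' @param resp named list or character vector with items `interest` and
#'   `mood`.
#' @param threshold default `"more_than_half"`.
#' @return single logical or `NA`.
#' @export
score_depression <- function(resp, threshold = "more_than_half") {
  a <- ordinal_at_least(get_item(resp, "interest"), threshold, depression_levels())
  b <- ordinal_at_least(get_item(resp, "mood"), threshold, depression_levels())
  if (is.na(a) && is.na(b)) return(NA)
  isTRUE(a) || isTRUE(b)
}

#' Combined screen-or-complaint criterion
#'
#' Positive when either the cognitive screen or the complaint questionnaire
#' is positive (logical OR) — the "either one or both tests positive"
#' combination.
#'
#' @param screen_positive logical screen flag.
#' @param complainer logical SCI flag.
#' @return logical.
#' @export
combined_decision <- function(screen_positive, complainer) {
  stopifnot(is.logical(screen_positive), is.logical(complainer))
  screen_positive | complainer
}
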