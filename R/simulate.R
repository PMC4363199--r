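#' Simulation parameters for a synthetic screening cohort
#'
#' Bundles and validates the parameters of the cohort simulator. The defaults
#' are the study conditions of the pilot cohort the package models: 30
#' patients, HAND prevalence 25/30 (~83%) with severity mix 16:8:1
#' (ANI:MND:HAD), and complaint rates weakly coupled to true impairment —
#' 9/25 (36%) of impaired patients complain while 3/5 (60%) of cognitively
#' normal ones do, the key miscalibration that motivates screening over
#' self-report.
#'
#' @param n cohort size.
#' @param prevalence probability of HAND, in `[0, 1]`.
#' @param severity_mix probabilities of (ANI, MND, HAD) given HAND; sums
#'   to 1.
#' @param domain_shift named non-negative mean z-decrements per domain under
#'   HAND at ANI severity. A test inherits the largest shift among the
#'   domains it serves. Defaults are moderate subclinical deficits (0.6-0.8
#'   SD).
#' @param severity_scale multipliers applied to `domain_shift` for ANI, MND
#'   and HAD (deficits deepen with severity).
#' @param test_correlation within-subject equicorrelation of the seven test
#'   z-scores, in `[0, 1)` (shared-factor model, always positive definite).
#' @param complaint_rate_impaired P(complainer | HAND).
#' @param complaint_rate_normal P(complainer | normal cognition).
#' @param depression_rate P(depressive symptoms), independent annotation.
#' @param seed integer RNG seed; `NULL` leaves the RNG state alone.
#' @return a validated list of class `sim_params`.
#' @export
sim_params <- function(n = 30,
                       prevalence = 25 / 30,
                       severity_mix = c(ANI = 16 / 25, MND = 8 / 25,
                                        HAD = 1 / 25),
                       domain_shift = c(COGNITIVE_SPEED = 0.8, MEMORY = 0.8,
                                        EXECUTIVE = 0.6, MOTOR_SPEED = 0.7),
                       severity_scale = c(ANI = 1, MND = 1.5, HAD = 2.5),
                       test_correlation = 0.3,
                       complaint_rate_impaired = 9 / 25,
                       complaint_rate_normal = 3 / 5,
                       depression_rate = 0.1,
                       seed = NULL) {
  stopifnot(n >= 1, prevalence >= 0, prevalence <= 1,
            complaint_rate_impaired >= 0, complaint_rate_impaired <= 1,
            complaint_rate_normal >= 0, complaint_rate_normal <= 1,
            depression_rate >= 0, depression_rate <= 1)
  if (!setequal(names(severity_mix), c("ANI", "MND", "HAD")) ||
      abs(sum(severity_mix) - 1) > 1e-8 || any(severity_mix < 0))
    stop("severity_mix must be probabilities over ANI, MND, HAD summing to 1",
         call. = FALSE)
  if (!setequal(names(domain_shift), hand_domains()) || any(domain_shift < 0))
    stop("domain_shift must be non-negative and name the four domains",
         call. = FALSE)
  if (!setequal(names(severity_scale), c("ANI", "MND", "HAD")) ||
      any(severity_scale < 0))
    stop("severity_scale must be non-negative over ANI, MND, HAD",
         call. = FALSE)
  if (test_correlation < 0 || test_correlation >= 1)
    stop("test_correlation must lie in [0, 1) for a positive-definite ",
         "covariance", call. = FALSE)
  structure(list(n = as.integer(n), prevalence = prevalence,
                 severity_mix = severity_mix[c("ANI", "MND", "HAD")],
                 domain_shift = domain_shift[hand_domains()],
                 severity_scale = severity_scale[c("ANI", "MND", "HAD")],
                 test_correlation = test_correlation,
                 complaint_rate_impaired = complaint_rate_impaired,
                 complaint_rate_normal = complaint_rate_normal,
                 depression_rate = depression_rate,
                 seed = seed),
            class = "sim_params")
}

# Per-test mean z-decrement at ANI severity: a test inherits the largest
# shift among the domains it serves.
test_shifts <- function(domain_shift, map = default_domain_map()) {
  vapply(hand_tests(), function(t) {
    in_dom <- vapply(map, function(tests) t %in% tests, logical(1))
    max(domain_shift[names(map)[in_dom]])
  }, numeric(1))
}

likert_below <- function(n, levels, top) {
  # responses strictly below `top` on an ordinal scale, mild skew to low end
  k <- match(top, levels) - 1
  levels[sample.int(k, n, replace = TRUE, prob = rev(seq_len(k)))]
}

raw_from_z <- function(z, test, age, norms) {
  entry <- find_norm(norms, test, age)
  raw <- if (test_direction(test) == "higher_worse")
    entry$mean - z * entry$sd
  else
    entry$mean + z * entry$sd
  max(round(raw, 1), 0)
}

#' Simulate a synthetic screening cohort
#'
#' Generates per-patient records with the statistical structure the screen
#' evaluation assumes: a latent HAND diagnosis drawn from the prevalence and
#' severity mix; seven test z-scores from an equicorrelated Gaussian
#' (shared-factor) model whose means are depressed, per domain and severity,
#' under HAND; raw scores back-transformed through a normative table for the
#' patient's age; and a complaint flag drawn Bernoulli conditional on
#' diagnosis — so that, as in the clinic, most impaired patients do not
#' complain. Ages are drawn around a median of 52.5 years (IQR about 47-64)
#' and truncated to the normative coverage.
#'
#' @param params a [sim_params()] object.
#' @param norms a `hand_norms` table used to back-transform z to raw scores;
#'   default [demo_norms()].
#' @return a data.frame of class `hand_cohort`, one row per patient, with the
#'   columns accepted by [read_cohort()].
#' @seealso [analytic_operating_characteristics()] for the closed-form
#'   operating characteristics under independence.
#' @export
simulate_cohort <- function(params = sim_params(), norms = demo_norms()) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  n <- params$n
  diagnosis <- ifelse(stats::runif(n) < params$prevalence,
                      sample(c("ANI", "MND", "HAD"), n, replace = TRUE,
                             prob = params$severity_mix),
                      "NORMAL")
  age_lo <- min(norms$age_min); age_hi <- max(norms$age_max)
  age <- pmin(pmax(round(stats::rnorm(n, 52.5, 12.6)), age_lo), age_hi)
  education <- pmin(pmax(round(stats::rnorm(n, 12.5, 2)), 8), 20)

  shifts_ani <- test_shifts(params$domain_shift)
  rho <- params$test_correlation
  shared <- stats::rnorm(n)
  tests <- hand_tests()
  z <- matrix(NA_real_, n, length(tests), dimnames = list(NULL, tests))
  for (j in seq_along(tests)) {
    eps <- stats::rnorm(n)
    noise <- sqrt(rho) * shared + sqrt(1 - rho) * eps
    shift <- ifelse(diagnosis == "NORMAL", 0,
                    shifts_ani[j] * params$severity_scale[diagnosis])
    z[, j] <- noise - shift
  }
  # back-transform z to raw through the age-banded norms, vectorized per
  # test; full precision (no rounding), clamped at the physiologic floor 0
  raw <- z
  for (j in seq_along(tests)) {
    nb <- norms[norms$test == tests[j], , drop = FALSE]
    nb <- nb[order(nb$age_min), , drop = FALSE]
    band <- findInterval(age, nb$age_min)
    if (any(band == 0 | age > nb$age_max[pmax(band, 1)]))
      stop("norms do not cover all simulated ages for test ", tests[j],
           call. = FALSE)
    m <- nb$mean[band]; s <- nb$sd[band]
    raw[, j] <- if (test_direction(tests[j]) == "higher_worse")
      m - z[, j] * s else m + z[, j] * s
    raw[, j] <- pmax(raw[, j], 0)
  }

  p_complain <- ifelse(diagnosis == "NORMAL",
                       params$complaint_rate_normal,
                       params$complaint_rate_impaired)
  complainer <- stats::runif(n) < p_complain
  lv <- sci_levels()
  q_memory <- ifelse(complainer, sample(c("often", "always"), n, TRUE),
                     likert_below(n, lv, "often"))
  q_attention <- ifelse(complainer,
                        sample(lv, n, TRUE),
                        likert_below(n, lv, "often"))
  depressive <- stats::runif(n) < params$depression_rate
  dep_lv <- depression_levels()
  q_mood <- ifelse(depressive,
                   sample(c("more_than_half", "nearly_every_day"), n, TRUE),
                   likert_below(n, dep_lv, "more_than_half"))

  out <- data.frame(
    patient_id = sprintf("S%03d", seq_len(n)),
    age = age, education = education,
    tmt_a = raw[, "TMT_A"], tmt_b = raw[, "TMT_B"], dst = raw[, "DST"],
    wordlist_learning = raw[, "WORDLIST_LEARNING"],
    wordlist_recall = raw[, "WORDLIST_RECALL"],
    pegboard_dom = raw[, "PEGBOARD_DOM"],
    pegboard_nondom = raw[, "PEGBOARD_NONDOM"],
    q_memory = q_memory,
    q_slowed = likert_below(n, lv, "often"),
    q_attention = q_attention,
    q_prospective = sample(lv, n, TRUE),
    q_informant = sample(lv, n, TRUE),
    q_interest = likert_below(n, dep_lv, "more_than_half"),
    q_mood = q_mood,
    diagnosis = diagnosis,
    efavirenz = stats::runif(n) < 7 / 30,
    stringsAsFactors = FALSE
  )
  class(out) <- c("hand_cohort", "data.frame")
  out
}

#' Closed-form operating characteristics of the screen under independence
#'
#' For uncorrelated test z-scores, the screen's exact sensitivity and
#' specificity follow by enumerating all 2^7 pathology patterns of the seven
#' tests. Each test is individually pathological with probability
#' P(z < cutoff) = Phi(cutoff + shift) — shift 0 for normal cognition,
#' the severity-scaled per-test shift under HAND — and each pattern is mapped
#' through the domain rule and the k-of-4 screen decision. Sensitivity
#' averages over the severity mix. Serves as the independent oracle for
#' [simulate_cohort()]; correlated parameterizations have no closed form
#' here and are rejected.
#'
#' @param params a [sim_params()] object with `test_correlation = 0`.
#' @param cutoff z cutoff, default `-1`.
#' @param min_domains screen rule threshold, default `2`.
#' @param map domain map, default [default_domain_map()].
#' @return list with `sensitivity`, `specificity`, and
#'   `p_positive_by_status` (named vector over NORMAL/ANI/MND/HAD).
#' @export
analytic_operating_characteristics <- function(params = sim_params(test_correlation = 0),
                                               cutoff = -1, min_domains = 2,
                                               map = default_domain_map()) {
  stopifnot(inherits(params, "sim_params"))
  if (params$test_correlation != 0)
    stop("closed form available only for test_correlation = 0; ",
         "use Monte-Carlo simulation for correlated tests", call. = FALSE)
  shifts_ani <- test_shifts(params$domain_shift, map)
  p_positive <- function(shift_vec) {
    p_flag <- stats::pnorm(cutoff + shift_vec)
    total <- 0
    for (pattern in 0:(2^7 - 1)) {
      flagged <- as.logical(bitwAnd(bitwShiftR(pattern, 0:6), 1L))
      prob <- prod(ifelse(flagged, p_flag, 1 - p_flag))
      dom <- vapply(map, function(tests)
        any(flagged[match(tests, hand_tests())]), logical(1))
      if (sum(dom) >= min_domains) total <- total + prob
    }
    total
  }
  p_by_status <- c(
    NORMAL = p_positive(rep(0, 7)),
    ANI = p_positive(shifts_ani * params$severity_scale[["ANI"]]),
    MND = p_positive(shifts_ani * params$severity_scale[["MND"]]),
    HAD = p_positive(shifts_ani * params$severity_scale[["HAD"]])
  )
  sens <- sum(params$severity_mix * p_by_status[c("ANI", "MND", "HAD")])
  list(sensitivity = sens,
       specificity = 1 - p_by_status[["NORMAL"]],
       p_positive_by_status = p_by_status)
}
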