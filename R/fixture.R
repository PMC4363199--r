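#' Deterministic 30-patient synthetic reference cohort
#'
#' Reconstructs, from published marginal counts alone, a cohort whose joint
#' cross-classification of (diagnosis, complainer, screen result) is the one
#' those margins force. The arithmetic, row by row:
#'
#' * 25 of 30 have HAND (16 ANI, 8 MND, 1 HAD); 5 are cognitively normal.
#' * 9 of the 25 HAND patients complain of memory loss or concentration
#'   difficulty; 2 of the 5 normals do not (so 3 normals complain) —
#'   12 complainers, 18 non-complainers.
#' * The screen is positive in 16 HAND patients and 1 normal (the 2x2 table
#'   16/1/9/4). Among complainers, sensitivity 4/9 and specificity 2/3 force
#'   4 complainer-HAND screen-positives and the lone false positive to be a
#'   complainer; among non-complainers, sensitivity 12/16 and specificity
#'   2/2 force the remaining 12 HAND positives and no normal positives.
#'
#' Within those forced cells the row-level details (which severity goes with
#' which complaint/screen cell, ages, raw scores) are not published; this
#' fixture fixes them deterministically and synthesizes raw test scores and
#' questionnaire answers that route every row through the full scoring
#' pipeline — under the shipped demonstration norms and default rules — to
#' its required flags. Screen-positive rows carry deficits in two or more
#' domains (via Trail Making A, Trail Making B, Digit Symbol + recall, or
#' pegboard + learning patterns; the HAD row is globally impaired at z = -2);
#' false-negative HAND rows carry a single-domain deficit (memory or motor)
#' the two-domain rule cannot see; normal screen-negative rows sit within
#' half a standard deviation of the norms. Ages reproduce a median of 52.5
#' (IQR 47-64).
#'
#' The same cohort ships as a CSV at
#' `system.file("extdata", "synthetic_reference_cohort.csv",
#' package = "handscreen")` for diffing; this function is the source of
#' truth.
#'
#' @param norms normative table used to back-transform target z-scores to
#'   raw scores; default [demo_norms()]. The forced flags are guaranteed
#'   under the default norms.
#' @return a `hand_cohort` data.frame with 30 rows.
#' @examples
#' cohort <- reference_cohort()
#' table(cohort$diagnosis)
#' @export
reference_cohort <- function(norms = demo_norms()) {
  tests <- hand_tests()

  # group layout: diagnosis, complainer, required screen result
  diagnosis <- c(
    rep("ANI", 7), "MND", rep("MND", 3), "HAD",      # 1-12  non-compl, screen+
    rep("ANI", 3), "MND",                            # 13-16 non-compl, screen-
    "ANI", "ANI", "MND", "MND",                      # 17-20 complainer, screen+
    rep("ANI", 4), "MND",                            # 21-25 complainer, screen-
    "NORMAL",                                        # 26    complainer, screen+
    "NORMAL", "NORMAL",                              # 27-28 complainer, screen-
    "NORMAL", "NORMAL"                               # 29-30 non-compl, screen-
  )
  complainer <- c(rep(FALSE, 16), rep(TRUE, 12), FALSE, FALSE)
  screen_target <- c(rep(TRUE, 12), rep(FALSE, 4), rep(TRUE, 4),
                     rep(FALSE, 5), TRUE, rep(FALSE, 4))

  # ages: fixed permutation of a list with median 52.5 and quartiles 47 / 64
  age <- c(55, 47, 61, 44, 66, 49, 53, 70, 45, 64, 52, 58,
           48, 67, 42, 56, 51, 64, 46, 69, 47, 65, 41, 54,
           72, 50, 68, 43, 46, 52)

  education <- c(10, 11, 11, 11, 12, 12, 12, 12, 12, 13, 13, 13,
                 12, 12, 12, 13, 13, 13, 14, 11, 13, 13, 12, 13,
                 14, 12, 12, 13, 13, 12)

  # deficit profiles: named target z-scores overriding a mild filler
  profile_A <- c(TMT_A = -1.5)                                # speed + motor
  profile_B <- c(TMT_B = -1.8)                                # speed + exec + motor
  profile_C <- c(DST = -1.3, WORDLIST_RECALL = -1.5)          # speed + motor + memory
  profile_D <- c(PEGBOARD_DOM = -1.4, WORDLIST_LEARNING = -1.2) # motor + memory
  memory_only <- c(WORDLIST_RECALL = -1.4)
  motor_only_d <- c(PEGBOARD_DOM = -1.3)
  motor_only_n <- c(PEGBOARD_NONDOM = -1.2)
  none <- numeric(0)
  profiles <- list(
    profile_A, profile_B, profile_C, profile_D,    # 1-4
    profile_A, profile_B, profile_C, profile_D,    # 5-8
    profile_A, profile_B, profile_C,               # 9-11
    stats::setNames(rep(-2, 7), tests),            # 12: HAD, global impairment
    memory_only, motor_only_d, none, memory_only,  # 13-16 false negatives
    profile_A, profile_B, profile_C, profile_D,    # 17-20
    memory_only, motor_only_n, none, memory_only,  # 21-24
    none,                                          # 25
    profile_A,                                     # 26: the false positive
    none, none, none, none                         # 27-30
  )

  filler_z <- function(i, j) (((i * 3 + j * 5) %% 11) - 5) / 10  # in [-0.5, 0.5]
  raw <- matrix(NA_real_, 30, 7, dimnames = list(NULL, tests))
  for (i in 1:30) {
    z <- vapply(seq_along(tests), function(j) filler_z(i, j), numeric(1))
    names(z) <- tests
    z[names(profiles[[i]])] <- profiles[[i]]
    for (j in seq_along(tests))
      raw[i, j] <- raw_from_z(z[j], tests[j], age[i], norms)
  }

  lowlv <- c("never", "rarely", "sometimes")
  q_memory <- ifelse(complainer,
                     rep(c("often", "always"), length.out = 30),
                     lowlv[(seq_len(30) %% 3) + 1])
  q_attention <- lowlv[((seq_len(30) + 1) %% 3) + 1]
  q_attention[complainer & seq_len(30) %% 2 == 0] <- "often"

  # depressive symptoms: 2 screen-positive rows, 1 screen-negative row
  q_mood <- rep("not_at_all", 30)
  q_mood[c(5, 18, 21)] <- "more_than_half"
  q_interest <- rep(c("not_at_all", "several_days"), length.out = 30)

  # efavirenz: 5 ANI + 1 MND + 1 HAD + 1 normal; 6 screen-positive, 2 negative
  efavirenz <- rep(FALSE, 30)
  efavirenz[c(1, 2, 3, 8, 12, 17, 13, 29)] <- TRUE

  out <- data.frame(
    patient_id = sprintf("P%02d", 1:30),
    age = age, education = education,
    tmt_a = raw[, "TMT_A"], tmt_b = raw[, "TMT_B"], dst = raw[, "DST"],
    wordlist_learning = raw[, "WORDLIST_LEARNING"],
    wordlist_recall = raw[, "WORDLIST_RECALL"],
    pegboard_dom = raw[, "PEGBOARD_DOM"],
    pegboard_nondom = raw[, "PEGBOARD_NONDOM"],
    q_memory = q_memory,
    q_slowed = lowlv[((seq_len(30) + 2) %% 3) + 1],
    q_attention = q_attention,
    q_prospective = c("sometimes", "rarely")[(seq_len(30) %% 2) + 1],
    q_informant = c("never", "rarely")[(seq_len(30) %% 2) + 1],
    q_interest = q_interest,
    q_mood = q_mood,
    diagnosis = diagnosis,
    efavirenz = efavirenz,
    stringsAsFactors = FALSE
  )
  attr(out, "screen_target") <- screen_target
  class(out) <- c("hand_cohort", "data.frame")
  out
}
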