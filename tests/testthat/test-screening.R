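zeros <- function() setNames(rep(0, 7), hand_tests())

test_that("domain classification follows the test-to-domain map", {
  z <- zeros(); z["TMT_A"] <- -1.2
  flags <- classify_domains(z)
  expect_true(flags[["COGNITIVE_SPEED"]])
  expect_true(flags[["MOTOR_SPEED"]])
  expect_false(flags[["MEMORY"]])
  expect_false(flags[["EXECUTIVE"]])

  expect_false(any(classify_domains(zeros())))

  z <- zeros(); z["WORDLIST_RECALL"] <- -2.5
  flags <- classify_domains(z)
  expect_identical(unname(c(flags)), c(FALSE, TRUE, FALSE, FALSE))
})

test_that("missing tests make domains unevaluable, never pathological", {
  z <- zeros()
  z["WORDLIST_LEARNING"] <- NA; z["WORDLIST_RECALL"] <- NA
  flags <- classify_domains(z)
  expect_false(flags[["MEMORY"]])
  expect_identical(attr(flags, "unevaluable"), "MEMORY")
  # a partially missing domain is still evaluable from the scored test
  z["WORDLIST_LEARNING"] <- -1.5
  flags <- classify_domains(z)
  expect_true(flags[["MEMORY"]])
  expect_length(attr(flags, "unevaluable"), 0)
})

test_that("malformed score sets are rejected", {
  expect_error(classify_domains(c(TMT_A = -1, TMT_A = 0,
                                  zeros()[-1])), "duplicate")
  expect_error(classify_domains(setNames(0, "TMT_C")), "unknown test")
  expect_error(classify_domains(0.5), "named")
})

test_that("the screen turns positive at min_domains flagged domains", {
  f <- c(COGNITIVE_SPEED = TRUE, MEMORY = FALSE, EXECUTIVE = FALSE,
         MOTOR_SPEED = TRUE)
  expect_true(screen_decision(f))
  expect_false(screen_decision(c(f[1], MEMORY = FALSE, EXECUTIVE = FALSE,
                                 MOTOR_SPEED = FALSE)))
  expect_true(screen_decision(setNames(rep(TRUE, 4), hand_domains())))
  # boundary rules: 1 flags on any deficit; 5 can never be met
  expect_true(screen_decision(c(f[1], MEMORY = FALSE, EXECUTIVE = FALSE,
                                MOTOR_SPEED = FALSE), min_domains = 1))
  expect_false(screen_decision(setNames(!logical(4), hand_domains()),
                               min_domains = 5))
})

test_that("screen rule matches the exhaustive 2^7 truth-table oracle", {
  for (pattern in all_test_patterns()) {
    z <- ifelse(pattern, -2, 0)
    names(z) <- names(pattern)
    got <- screen_decision(classify_domains(z))
    expect_identical(got, brute_force_screen(pattern),
                     info = paste(names(pattern)[pattern], collapse = "+"))
    # and with min_domains = 1: positive iff any test pathological
    expect_identical(
      screen_decision(classify_domains(z), min_domains = 1),
      any(pattern))
  }
})

test_that("complainer rule: any configured item at or above threshold", {
  expect_true(score_sci(list(memory_loss = "often", attention = "rarely")))
  expect_false(score_sci(list(memory_loss = "never", attention = "never",
                              slowed_thinking = "never")))
  expect_false(score_sci(list(memory_loss = "sometimes",
                              attention = "sometimes")))
  expect_true(score_sci(list(memory_loss = "never", attention = "always")))
  # robustness items are excluded from the default rule...
  expect_false(score_sci(list(memory_loss = "never", attention = "never",
                              prospective_memory = "always")))
  # ...but can be configured in
  expect_true(score_sci(list(prospective_memory = "always"),
                        items = c("memory_loss", "attention",
                                  "prospective_memory")))
  # missing items are treated as not endorsed
  expect_false(score_sci(list()))
  # threshold is configurable
  expect_true(score_sci(list(memory_loss = "sometimes"),
                        threshold = "sometimes"))
  expect_error(score_sci(list(memory_loss = "frequently")), "frequently")
})

test_that("depression flag: either item at threshold; both missing is NA", {
  expect_true(score_depression(list(interest = "more_than_half",
                                    mood = "not_at_all")))
  expect_false(score_depression(list(interest = "not_at_all",
                                     mood = "not_at_all")))
  expect_false(score_depression(list(interest = "several_days",
                                     mood = "several_days")))
  expect_true(score_depression(list(mood = "nearly_every_day")))
  expect_true(is.na(score_depression(list())))
})

test_that("combined criterion is the logical OR", {
  expect_true(combined_decision(FALSE, TRUE))
  expect_true(combined_decision(TRUE, FALSE))
  expect_true(combined_decision(TRUE, TRUE))
  expect_false(combined_decision(FALSE, FALSE))
  expect_identical(combined_decision(c(TRUE, FALSE), c(FALSE, FALSE)),
                   c(TRUE, FALSE))
})

test_that("flagging more tests is monotone through domains and screen", {
  set.seed(42)
  for (rep in 1:100) {
    z <- setNames(runif(7, -2.5, 1), hand_tests())
    flags <- classify_domains(z)
    positive <- screen_decision(flags)
    # knock one more test below the cutoff
    ok <- which(z >= -1)
    if (!length(ok)) next
    z2 <- z
    z2[sample(ok, 1)] <- -1.5
    flags2 <- classify_domains(z2)
    expect_true(all(flags2 >= flags))               # flags only added
    expect_gte(screen_decision(flags2), positive)   # screen never un-flips
    # combined decision dominates the screen for any complaint status
    for (compl in c(TRUE, FALSE))
      expect_gte(combined_decision(screen_decision(flags2), compl),
                 screen_decision(flags2))
  }
})
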