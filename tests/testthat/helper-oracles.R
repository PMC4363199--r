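# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exact binomial CI by direct inversion of the binomial CDF: the smallest /
# largest p whose two-sided exact test retains k at level alpha.
cdf_inversion_ci <- function(k, n, alpha = 0.05) {
  lower <- if (k == 0) 0 else
    uniroot(function(p) 1 - pbinom(k - 1, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  upper <- if (k == n) 1 else
    uniroot(function(p) pbinom(k, n, p) - alpha / 2,
            c(1e-12, 1 - 1e-12), tol = 1e-12)$root
  c(lower, upper)
}

# Two-sided Fisher exact p by full hypergeometric enumeration over all
# tables with the observed margins: sum the probabilities of tables no more
# probable than the observed one (with the customary relative tolerance
# against floating-point ties).
fisher_enumeration_p <- function(a, b, c, d) {
  m <- a + c; nn <- b + d; kk <- a + b
  support <- max(0, kk - nn):min(kk, m)
  probs <- dhyper(support, m, nn, kk)
  obs <- dhyper(a, m, nn, kk)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Truth table of the screen over all 2^7 test-pathology patterns, derived
# directly from the published test-to-domain assignment (hand-transcribed
# here, independent of default_domain_map()).
brute_force_screen <- function(pattern, min_domains = 2) {
  # pattern: named logical over the seven tests, TRUE = pathological result
  cognitive_speed <- pattern[["TMT_A"]] || pattern[["TMT_B"]] ||
    pattern[["DST"]]
  memory <- pattern[["WORDLIST_LEARNING"]] || pattern[["WORDLIST_RECALL"]]
  executive <- pattern[["TMT_B"]]
  motor_speed <- pattern[["DST"]] || pattern[["PEGBOARD_DOM"]] ||
    pattern[["PEGBOARD_NONDOM"]] || pattern[["TMT_A"]] || pattern[["TMT_B"]]
  sum(cognitive_speed, memory, executive, motor_speed) >= min_domains
}

all_test_patterns <- function() {
  tests <- c("TMT_A", "TMT_B", "DST", "WORDLIST_LEARNING", "WORDLIST_RECALL",
             "PEGBOARD_DOM", "PEGBOARD_NONDOM")
  lapply(0:127, function(bits) {
    p <- as.logical(bitwAnd(bitwShiftR(bits, 0:6), 1L))
    names(p) <- tests
    p
  })
}

# small norms table used by many unit tests; the TMT_A band reproduces the
# 40-second worked example
tiny_norms <- function() {
  as_hand_norms(data.frame(
    test = c("TMT_A", "DST"),
    age_min = c(40, 40), age_max = c(49, 49),
    mean = c(31, 50), sd = c(9, 10)))
}

write_temp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
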