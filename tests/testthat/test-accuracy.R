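reference_crosstab <- function() {
  # the published 2x2: 16 true positives, 1 false positive, 9 false
  # negatives, 4 true negatives
  screen <- rep(c(TRUE, TRUE, FALSE, FALSE), c(16, 1, 9, 4))
  dx <- rep(c("ANI", "NORMAL", "MND", "NORMAL"), c(16, 1, 9, 4))
  crosstab(screen, dx)
}

test_that("crosstab partitions the cohort into the 2x2 cells", {
  ct <- reference_crosstab()
  expect_identical(unclass(ct)[c("tp", "fp", "fn", "tn")],
                   list(tp = 16L, fp = 1L, fn = 9L, tn = 4L))
  m <- as.matrix(ct)
  expect_equal(sum(m), 30)

  empty <- crosstab(logical(0), character(0))
  expect_true(all(unlist(empty) == 0))

  allpos <- crosstab(rep(TRUE, 5), rep("HAD", 5))
  expect_identical(unlist(unclass(allpos)), c(tp = 5L, fp = 0L, fn = 0L,
                                              tn = 0L))
  expect_error(crosstab(TRUE, c("ANI", "MND")), "length")
  expect_error(crosstab(c(TRUE, NA), c("ANI", "MND")), "missing")
  expect_error(crosstab(TRUE, "HIV"), "unknown diagnosis")
})

test_that("clopper_pearson equals the binomial-CDF-inversion oracle for
           all n <= 30", {
  for (n in 1:30) for (k in 0:n) {
    got <- clopper_pearson(k, n)
    want <- cdf_inversion_ci(k, n)
    expect_equal(unname(got), want, tolerance = 1e-9,
                 info = sprintf("k=%d n=%d", k, n))
  }
  # and agrees with the exact test's interval on a few spot checks
  for (kn in list(c(16, 25), c(4, 5), c(2, 7), c(0, 10), c(13, 13))) {
    expect_equal(unname(clopper_pearson(kn[1], kn[2])),
                 as.numeric(binom.test(kn[1], kn[2])$conf.int),
                 tolerance = 1e-12)
  }
})

test_that("clopper_pearson boundary and argument behaviour", {
  expect_identical(clopper_pearson(0, 10)[["lower"]], 0)
  expect_identical(clopper_pearson(10, 10)[["upper"]], 1)
  # specificity 4/5 prints as 80% (28-99%)
  ci <- clopper_pearson(4, 5)
  expect_equal(pct(ci[["lower"]]), 28)
  expect_lte(abs(pct(ci[["upper"]]) - 99), 1)
  expect_error(clopper_pearson(5, 4), "0 <= k <= n")
  expect_error(clopper_pearson(-1, 4), "0 <= k <= n")
  expect_error(clopper_pearson(2.5, 4), "0 <= k <= n")
  expect_error(clopper_pearson(1, 4, alpha = 1.2), "alpha")
})

test_that("exact intervals cover at least the nominal level", {
  # exact coverage by summing binomial probabilities, no Monte Carlo needed
  for (n in c(5, 13, 25)) for (p in seq(0.1, 0.9, by = 0.1)) {
    covered <- vapply(0:n, function(k) {
      ci <- clopper_pearson(k, n)
      ci[["lower"]] <= p && p <= ci[["upper"]]
    }, logical(1))
    expect_gte(sum(dbinom(0:n, n, p) * covered), 0.95)
  }
})

test_that("accuracy metrics reproduce the published headline numbers", {
  rep_ <- accuracy_metrics(reference_crosstab())
  est <- setNames(rep_$estimate, rep_$metric)
  expect_identical(pct(est[["sensitivity"]]), 64)
  expect_identical(pct(est[["specificity"]]), 80)
  expect_identical(pct(est[["ppv"]]), 94)
  expect_identical(pct(est[["npv"]]), 31)
  # sensitivity * (tp+fn) and specificity * (tn+fp) recover integer counts
  expect_equal(est[["sensitivity"]] * 25, 16, tolerance = 1e-12)
  expect_equal(est[["specificity"]] * 5, 4, tolerance = 1e-12)
  expect_true(all(rep_$lower <= rep_$estimate & rep_$estimate <= rep_$upper))
})

test_that("zero denominators give undefined metrics, not zeros", {
  rep_ <- accuracy_metrics(list(tp = 0, fp = 0, fn = 0, tn = 10))
  est <- setNames(rep_$estimate, rep_$metric)
  expect_identical(est[["specificity"]], 1)
  expect_identical(est[["npv"]], 1)
  expect_true(is.na(est[["sensitivity"]]))
  expect_true(is.na(est[["ppv"]]))

  rep_ <- accuracy_metrics(list(tp = 1, fp = 1, fn = 1, tn = 1))
  expect_true(all(rep_$estimate == 0.5))
  expect_error(accuracy_metrics(list(tp = -1, fp = 0, fn = 0, tn = 0)),
               "non-negative")
})

test_that("stratified evaluation returns the four reports and flags empty
           strata", {
  screen <- c(TRUE, TRUE, FALSE, FALSE)
  compl <- c(TRUE, FALSE, TRUE, FALSE)
  dx <- c("ANI", "NORMAL", "MND", "NORMAL")
  out <- stratified_evaluation(screen, compl, dx)
  expect_named(out, c("overall", "non_complainers", "complainers",
                      "combined"))
  expect_length(attr(out, "empty_strata"), 0)
  # nobody complains: the complainer stratum is empty, not an error
  out <- stratified_evaluation(screen, rep(FALSE, 4), dx)
  expect_null(out$complainers)
  expect_identical(attr(out, "empty_strata"), "complainers")
  expect_error(stratified_evaluation(screen, compl[1:2], dx), "aligned")
})

test_that("Fisher p matches full hypergeometric enumeration on all small
           tables", {
  # every 2x2 table with total <= 16, plus a deterministic sample up to 30
  for (N in c(2:16, 30)) {
    tables <- expand.grid(a = 0:N, b = 0:N, c = 0:N)
    tables <- tables[rowSums(tables) <= N, ]
    tables$d <- N - rowSums(tables)
    if (N == 30) {
      set.seed(N)
      tables <- tables[sample(nrow(tables), 300), ]
    }
    for (i in seq_len(nrow(tables))) {
      t <- tables[i, ]
      if ((t$a + t$b) == 0 || (t$c + t$d) == 0 ||
          (t$a + t$c) == 0 || (t$b + t$d) == 0) next
      got <- fisher.test(matrix(c(t$a, t$c, t$b, t$d), 2))$p.value
      want <- fisher_enumeration_p(t$a, t$b, t$c, t$d)
      expect_equal(got, want, tolerance = 1e-10,
                   info = sprintf("%d %d %d %d", t$a, t$b, t$c, t$d))
    }
  }
  # the cross-checked mid-size example
  expect_equal(fisher.test(matrix(c(5, 7, 12, 6), 2))$p.value,
               fisher_enumeration_p(5, 12, 7, 6), tolerance = 1e-12)
})

test_that("group comparison: tests, conventions and degenerate inputs", {
  cohort <- data.frame(
    age = c(50, 60, 55, 45, 52, 58, 49, 61),
    flag = c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE),
    const = rep(TRUE, 8),
    cage = rep(33, 8))
  group <- rep(c(TRUE, FALSE), 4)
  out <- compare_groups(cohort, group, continuous = c("age", "cage"),
                        categorical = c("flag", "const"))
  expect_s3_class(out, "group_comparison")
  # small counts route through Fisher's exact test
  expect_identical(out$test[out$variable == "flag"], "fisher_exact")
  # constant variables have undefined p with a note
  expect_true(is.na(out$p[out$variable == "const"]))
  expect_match(out$note[out$variable == "cage"], "constant")

  # identical value distributions: Mann-Whitney p = 1 under the uncorrected
  # normal-approximation convention
  cohort2 <- data.frame(v = rep(c(1, 2, 3), 2))
  out2 <- compare_groups(cohort2, rep(c(TRUE, FALSE), each = 3),
                         continuous = "v")
  expect_equal(out2$p, 1, tolerance = 1e-12)

  # an empty group skips the comparison with a warning
  expect_warning(
    out3 <- compare_groups(cohort, rep(TRUE, 8), continuous = "age"),
    "empty group")
  expect_true(is.na(out3$p))

  # large balanced counts route through chi-square
  big <- data.frame(flag = rep(c(TRUE, FALSE), 30))
  outb <- compare_groups(big, rep(c(TRUE, FALSE), each = 30),
                         categorical = "flag")
  expect_identical(outb$test, "chi_square")
})
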