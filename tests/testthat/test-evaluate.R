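test_that("exact intervals match the binomial-tail oracle for all n <= 30", {
  for (n in 1:30) {
    for (k in 0:n) {
      got <- clopper_pearson(k, n, 0.95)
      oracle <- binom.test(k, n)$conf.int * 100  # stats' exact CP interval
      expect_equal(unname(got), as.numeric(oracle), tolerance = 1e-8,
                   info = sprintf("k=%d n=%d", k, n))
    }
  }
})

test_that("exact intervals reproduce the published bounds to one decimal", {
  r1 <- function(v) round(v, 1)
  expect_equal(r1(clopper_pearson(20, 20)), c(lower = 83.2, upper = 100))
  expect_equal(r1(clopper_pearson(30, 30)), c(lower = 88.4, upper = 100))
  expect_equal(r1(clopper_pearson(27, 27)), c(lower = 87.2, upper = 100))
  expect_equal(r1(clopper_pearson(13, 17)), c(lower = 50.1, upper = 93.2))
  expect_equal(unname(clopper_pearson(0, 12)[1]), 0)
  expect_error(clopper_pearson(1, 0), "trials")
  expect_error(clopper_pearson(5, 3), "successes")
})

test_that("intervals bracket the estimate and widen with confidence", {
  set.seed(41)
  for (i in 1:25) {
    n <- sample(1:200, 1); k <- sample(0:n, 1)
    ci <- clopper_pearson(k, n, 0.95)
    p <- 100 * k / n
    expect_lte(ci[["lower"]], p)
    expect_gte(ci[["upper"]], p)
    wide <- clopper_pearson(k, n, 0.99)
    expect_lte(wide[["lower"]], ci[["lower"]])
    expect_gte(wide[["upper"]], ci[["upper"]])
  }
})

test_that("packaged cohort fixtures load with the expected shape", {
  s1 <- series1_calls()
  expect_s3_class(s1, "call_matrix")
  expect_equal(length(s1$cases), 44L)
  expect_equal(sort(s1$loci),
               sort(c("BAT25", "BAT26", "D5S346", "BAT34c4", "D18S55")))
  expect_true(all(is.na(s1$pcr[, "BAT34c4"])))
  s2 <- series2_calls()
  expect_equal(length(s2$cases), 6L)
  expect_equal(sort(s2$loci), c("BAT25", "BAT26"))
})

test_that("locus-vs-locus comparison reproduces the marker error counts", {
  s1 <- series1_calls()
  d5 <- locus_vs_locus(s1, "D5S346")
  expect_equal(d5$fn, 3L)
  expect_equal(d5$fp, 2L)
  expect_equal(d5$tp + d5$fn, 9L)   # unstable loci by the comparator
  expect_equal(d5$tn + d5$fp, 35L)  # stable loci by the comparator
  expect_equal(round(d5$sensitivity, 1), 66.7)
  expect_equal(round(d5$specificity, 1), 94.3)
  for (locus in c("BAT25", "BAT26")) {
    cf <- locus_vs_locus(s1, locus)
    expect_equal(cf$sensitivity, 100)
    expect_equal(cf$specificity, 100)
    expect_equal(cf$tp + cf$fp + cf$tn + cf$fn, 44L)
  }
  expect_error(locus_vs_locus(s1, "BAT34c4"), "not.*possible|not-comparable")
  expect_error(locus_vs_locus(s1, "NR21"), "not in matrix")
})

test_that("locus-vs-overall comparison reproduces the marker accuracies", {
  s1 <- series1_calls(); s2 <- series2_calls()
  for (locus in c("BAT25", "BAT26")) {
    cf <- locus_vs_overall(list(s1, s2), locus)
    expect_equal(cf$sensitivity, 100)
    expect_equal(cf$specificity, 100)
    expect_equal(cf$tp, 20L)  # pooled MSI-H cases
    expect_equal(cf$tn, 30L)
    expect_equal(round(cf$sens_ci[["lower"]], 1), 83.2)
    expect_equal(round(cf$spec_ci[["lower"]], 1), 88.4)
  }
  b34 <- locus_vs_overall(s1, "BAT34c4")
  expect_equal(round(b34$sensitivity, 1), 76.5)
  expect_equal(b34$specificity, 100)
  expect_equal(round(b34$sens_ci[["lower"]], 1), 50.1)
  expect_equal(round(b34$sens_ci[["upper"]], 1), 93.2)
  expect_equal(round(b34$spec_ci[["lower"]], 1), 87.2)
  d18 <- locus_vs_overall(s1, "D18S55")
  expect_equal(round(d18$sensitivity, 1), 58.8)
  expect_equal(round(d18$specificity, 1), 96.3)
  expect_equal(round(d18$sens_ci[["lower"]], 1), 32.9)
  expect_equal(round(d18$sens_ci[["upper"]], 1), 81.6)
  expect_equal(round(d18$spec_ci[["lower"]], 1), 81.0)
  expect_equal(round(d18$spec_ci[["upper"]], 1), 99.9)
  d5 <- locus_vs_overall(s1, "D5S346")
  expect_equal(round(d5$sensitivity, 1), 47.1)
  expect_equal(d5$specificity, 100)
})

test_that("degenerate confusion inputs are reported, not crashed on", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("case\tL1_ngs\tL1_pcr\tstatus_ngs\tstatus_pcr",
               "1\t-\t-\tStable\tStable",
               "2\t-\t-\tStable\tStable"), f)
  m <- read_call_matrix(f)
  cf <- locus_vs_locus(m, "L1")
  expect_equal(cf$tp, 0L); expect_equal(cf$fn, 0L)
  expect_true(is.na(cf$sensitivity))
  expect_equal(cf$specificity, 100)
  one <- locus_vs_overall(m, "L1")
  expect_equal(one$tp + one$fp + one$tn + one$fn, 2L)
})

test_that("cohort statuses recomputed from locus calls match the records", {
  s1 <- series1_calls()
  cs1 <- cohort_summary(s1)
  expect_equal(unname(cs1$counts),
               c(17L, 1L, 26L))  # MSI-H, MSI-L, MSS
  expect_equal(cs1$n_agree, 44L)
  expect_equal(nrow(cs1$discrepancies), 0L)
  s2 <- series2_calls()
  cs2 <- cohort_summary(s2)
  expect_equal(unname(cs2$counts), c(3L, 0L, 3L))
  expect_equal(cs2$n_agree, 6L)
})

test_that("confusion tables round half-up to one decimal", {
  s1 <- series1_calls()
  tab <- confusion_table(list(D5S346 = locus_vs_locus(s1, "D5S346")))
  expect_equal(tab$sens, 66.7)
  expect_equal(tab$spec, 94.3)
  expect_equal(tab$tp, 6L)
})
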