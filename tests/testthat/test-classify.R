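test_that("modal length is the strict argmax of the read-count histogram", {
  expect_equal(modal_length(dist_of(c("116" = 5000, "115" = 900,
                                      "114" = 300))), 116L)
  expect_equal(modal_length(dist_of(c("113" = 4000, "116" = 3999))), 113L)
  expect_error(modal_length(dist_of(c("100" = 0)[0])), "empty")
  # brute-force argmax oracle on random distributions (distinct counts)
  set.seed(17)
  for (i in 1:50) {
    k <- sample(1:10, 1)
    lens <- sample(100:150, k)
    cts <- sample(1:5000, k)
    expect_equal(modal_length(dist_of(stats::setNames(cts, lens))),
                 lens[which.max(cts)])
  }
})

test_that("modal-length ties break toward the comparator, else shorter", {
  tie <- dist_of(c("114" = 100, "118" = 100))
  expect_equal(modal_length(tie), 114L)                    # shorter wins
  expect_equal(modal_length(tie, comparator = 118L), 118L) # closest wins
  expect_equal(modal_length(tie, comparator = 119L), 118L)
  expect_equal(modal_length(tie, comparator = 116L), 114L) # equidistant: shorter
})

test_that("locus calls follow the 2 bp / 4 bp modal deviation cut-offs", {
  p <- default_panel()
  cfg <- classify_config()
  bat26 <- p$loci$BAT26
  d18 <- p$loci$D18S55
  norm <- dist_of(c("116" = 5000, "115" = 900), "BAT26")
  tum_del3 <- dist_of(c("113" = 4000, "116" = 1000), "BAT26")
  tum_same <- dist_of(c("116" = 4500, "115" = 800), "BAT26")

  call <- call_locus(tum_del3, norm, bat26, cfg)
  expect_equal(call$delta_bp, 3L)
  expect_equal(call$status, "unstable")
  expect_equal(call$comparator_source, "matched_normal")

  expect_equal(call_locus(tum_same, norm, bat26, cfg)$status, "stable")
  # mononucleotide boundary: 1 bp stable, 2 bp unstable
  expect_equal(call_locus(dist_of(c("115" = 4000), "BAT26"), norm, bat26,
                          cfg)$status, "stable")
  expect_equal(call_locus(dist_of(c("114" = 4000), "BAT26"), norm, bat26,
                          cfg)$status, "unstable")
  # dinucleotide boundary: 2 bp stable, 4 bp unstable
  dnorm <- dist_of(c("147" = 3000), "D18S55")
  expect_equal(call_locus(dist_of(c("145" = 3000), "D18S55"), dnorm, d18,
                          cfg)$status, "stable")
  expect_equal(call_locus(dist_of(c("143" = 3000), "D18S55"), dnorm, d18,
                          cfg)$status, "unstable")
})

test_that("insertions and deletions of equal size give the same call", {
  p <- default_panel()
  cfg <- classify_config()
  norm <- dist_of(c("121" = 5000), "BAT26")
  del <- call_locus(dist_of(c("118" = 5000), "BAT26"), norm, p$loci$BAT26,
                    cfg)
  ins <- call_locus(dist_of(c("124" = 5000), "BAT26"), norm, p$loci$BAT26,
                    cfg)
  expect_equal(del$delta_bp, ins$delta_bp)
  expect_equal(del$status, ins$status)
})

test_that("shallow distributions yield no-call and are excluded", {
  p <- default_panel()
  cfg <- classify_config(min_reads_per_locus = 100)
  norm <- dist_of(c("121" = 5000), "BAT26")
  shallow <- dist_of(c("118" = 99), "BAT26")
  expect_equal(call_locus(shallow, norm, p$loci$BAT26, cfg)$status,
               "no_call")
  expect_equal(call_locus(norm, shallow, p$loci$BAT26, cfg)$status,
               "no_call")
  # exactly at the threshold is informative
  expect_equal(call_locus(dist_of(c("118" = 100), "BAT26"), norm,
                          p$loci$BAT26, cfg)$status, "unstable")
})

test_that("tumour-only mode uses the panel reference and refuses NA", {
  p <- default_panel()
  cfg <- classify_config()
  call <- call_locus(dist_of(c("118" = 5000), "BAT26"),
                     p$loci$BAT26$modal_length, p$loci$BAT26, cfg)
  expect_equal(call$comparator_source, "panel_reference")
  expect_equal(call$delta_bp, 3L)
  expect_equal(call$status, "unstable")
  noref <- locus_definition("X", "mononucleotide", "ACGTACGTCC",
                            "GGATCCTTGA", 60)
  expect_error(call_locus(dist_of(c("60" = 5000), "X"), noref$modal_length,
                          noref, cfg), "reference modal length")
})

test_that("overall status applies the 2-locus MSI-H rule", {
  cfg <- classify_config()
  mk <- function(statuses) data.frame(
    locus = paste0("L", seq_along(statuses)), status = statuses,
    stringsAsFactors = FALSE)
  expect_equal(overall_status(mk(c("unstable", "unstable", "unstable",
                                   "unstable", "stable")), cfg)$overall,
               "MSI-H")
  expect_equal(overall_status(mk(c("stable", "stable", "stable", "stable",
                                   "unstable")), cfg)$overall, "MSI-L")
  expect_equal(overall_status(mk(rep("stable", 5)), cfg)$overall, "MSS")
  expect_equal(overall_status(mk(rep("no_call", 5)), cfg)$overall,
               "indeterminate")
  # no_call loci are excluded from the denominator, not counted unstable
  r <- overall_status(mk(c("unstable", "unstable", "no_call", "no_call",
                           "no_call")), cfg)
  expect_equal(r$overall, "MSI-H")
  expect_equal(r$n_informative, 2L)
})

test_that("overall status is monotone over every 5-locus call vector", {
  cfg <- classify_config()
  rank <- c(MSS = 0L, "MSI-L" = 1L, "MSI-H" = 2L)
  # independent brute-force oracle: rank from the count of unstable loci
  oracle <- function(v) {
    n <- sum(v)
    if (n >= 2) 2L else if (n == 1) 1L else 0L
  }
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 5))
  status_of <- function(v) {
    calls <- data.frame(locus = paste0("L", 1:5),
                        status = ifelse(v, "unstable", "stable"),
                        stringsAsFactors = FALSE)
    overall_status(calls, cfg)$overall
  }
  for (i in seq_len(nrow(grid))) {
    v <- as.logical(grid[i, ])
    expect_equal(unname(rank[status_of(v)]), oracle(v))
    # flipping any stable locus to unstable never demotes the status
    for (j in which(!v)) {
      w <- v; w[j] <- TRUE
      expect_gte(rank[status_of(w)], rank[status_of(v)])
    }
  }
})

test_that("identical tumour and normal distributions are always stable", {
  set.seed(29)
  p <- default_panel()
  cfg <- classify_config()
  for (i in 1:20) {
    lens <- sample(100:150, sample(2:8, 1))
    d <- dist_of(stats::setNames(sample(100:6000, length(lens), TRUE),
                                 lens), "BAT26")
    call <- call_locus(d, d, p$loci$BAT26, cfg)
    expect_equal(call$delta_bp, 0L)
    expect_equal(call$status, "stable")
  }
})
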