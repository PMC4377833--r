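test_that("lookup table holds forward primer and reverse-complement keys", {
  p <- default_panel()
  lk <- build_lookup(p)
  expect_equal(nrow(lk), 5L)
  expect_equal(lk$fwd_key[lk$locus == "BAT26"], "TGACTACTTTTGACTTCAGCC")
  expect_equal(lk$rev_key[lk$locus == "BAT26"],
               reverse_complement("AACCATTCAACATTTTTAACCC"))
  expect_equal(nrow(build_lookup(msi_panel(list(), "empty"))), 0L)
})

test_that("reads are assigned by end-anchored flank matching", {
  p <- default_panel()
  lk <- build_lookup(p)
  set.seed(23)
  core <- rand_dna(60)
  read <- paste0(p$loci$BAT25$forward_primer, core,
                 reverse_complement(p$loci$BAT25$reverse_primer))
  expect_equal(assign_read(read, lk), "BAT25")
  # reverse orientation is detected and recorded
  asg <- assign_reads(reverse_complement(read), lk)
  expect_equal(asg$locus, "BAT25")
  expect_equal(asg$orientation, "reverse")
  # no shared flank -> unassigned
  expect_true(is.na(assign_read(rand_dna(100), lk)))
  # a flank in the middle of the read does not count (anchored matching)
  buried <- paste0("TT", read, "TT")
  expect_true(is.na(assign_read(buried, lk)))
})

test_that("flank mismatch tolerance recovers reads with primer errors", {
  p <- default_panel()
  lk <- build_lookup(p)
  fwd <- p$loci$BAT26$forward_primer
  substr(fwd, 5, 5) <- ifelse(substr(fwd, 5, 5) == "A", "C", "A")
  read <- paste0(fwd, strrep("A", 40),
                 reverse_complement(p$loci$BAT26$reverse_primer))
  expect_true(is.na(assign_read(read, lk, max_flank_mismatches = 0L)))
  expect_equal(assign_read(read, lk, max_flank_mismatches = 1L), "BAT26")
})

test_that("reads matching more than one locus are left unassigned", {
  # two loci whose primers differ by a single substitution
  p <- msi_panel(list(
    locus_definition("A", "mononucleotide", "ACGTACGTCC", "GGATCCTTGA", 60),
    locus_definition("B", "mononucleotide", "ACGTACGACC", "GGATCCTTCA", 60)
  ))
  lk <- build_lookup(p)
  read <- paste0("ACGTACGTCC", strrep("A", 30),
                 reverse_complement("GGATCCTTGA"))
  expect_equal(assign_read(read, lk, 0L), "A")
  expect_true(is.na(assign_read(read, lk, 1L)))  # ambiguous at 1 mismatch
})

test_that("grouping counts identical reads and conserves totals", {
  p <- default_panel()
  lk <- build_lookup(p)
  r <- paste0(p$loci$BAT25$forward_primer, strrep("A", 40),
              reverse_complement(p$loci$BAT25$reverse_primer))
  r2 <- paste0(p$loci$BAT25$forward_primer, strrep("A", 39),
               reverse_complement(p$loci$BAT25$reverse_primer))
  seqs <- c(r, r, r, r2)
  asg <- assign_reads(seqs, lk)
  g <- group_reads(seqs, asg)
  expect_equal(nrow(g), 2L)
  expect_equal(g$read_count, c(3L, 1L))  # descending count
  expect_equal(sum(g$read_count), sum(!is.na(asg$locus)))
  # empty input
  empty <- group_reads(character(0),
                       data.frame(locus = character(),
                                  orientation = character()))
  expect_equal(nrow(empty), 0L)
})

test_that("read conservation and order independence hold on random input", {
  set.seed(31)
  p <- default_panel()
  lk <- build_lookup(p)
  mk <- function(locus, corelen) paste0(
    locus$forward_primer, rand_dna(corelen),
    reverse_complement(locus$reverse_primer))
  seqs <- c(vapply(sample(60:70, 40, TRUE), mk, character(1),
                   locus = p$loci$BAT25),
            vapply(sample(60:70, 30, TRUE), mk, character(1),
                   locus = p$loci$D18S55),
            vapply(rep(120, 10), rand_dna, character(1)))
  bin <- bin_reads(seqs, p)
  expect_equal(sum(bin$counts), length(seqs))     # conservation
  expect_equal(unname(bin$counts["BAT25"]), 40L)
  expect_equal(unname(bin$counts["unassigned"]), 10L)
  expect_equal(bin$distributions$BAT25$total_reads, 40L)
  perm <- sample(seq_along(seqs))
  bin2 <- bin_reads(seqs[perm], p)
  expect_equal(bin2$distributions, bin$distributions)
  expect_equal(bin2$counts, bin$counts)
})

test_that("length distributions add counts per length", {
  g <- data.frame(locus = "BAT25",
                  seq = c(strrep("A", 123), strrep("C", 122),
                          strrep("G", 123)),
                  length_bp = c(123L, 122L, 123L),
                  read_count = c(500L, 40L, 7L))
  d <- length_distribution(g, "BAT25")
  expect_equal(d$counts, c("122" = 40L, "123" = 507L))
  expect_equal(d$total_reads, 547L)
  e <- length_distribution(g[0, ], "BAT25")
  expect_equal(e$total_reads, 0L)
  expect_length(e$counts, 0L)
})

test_that("noise-free simulated reads all bin to their true locus", {
  dir <- withr::local_tempdir()
  p <- tiny_panel()
  cfg <- simulation_config(p, depth_per_locus = 80, stutter_prob = 0,
                           substitution_error_rate = 0,
                           fraction_offtarget = 0, seed = 13)
  sim <- simulate_sample(cfg, "normal", dir = dir)
  pre <- preprocess_fastq(sim$r1, sim$r2)
  bin <- bin_reads(pre$seq, p)
  expect_equal(unname(bin$counts["unassigned"]), 0L)
  for (nm in names(p$loci)) {
    expect_equal(bin$distributions[[nm]]$total_reads, 80L)
    # point mass at the configured reference allele length
    d <- bin$distributions[[nm]]
    expect_length(d$counts, 1L)
    expect_equal(as.integer(names(d$counts)),
                 p$loci[[nm]]$amplicon_length)
  }
})
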