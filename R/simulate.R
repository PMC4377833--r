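# Deterministic non-primer flank filler: repeats of a fixed 12-mer chosen to
# share no long substring with any panel primer or repeat tract.
.FILLER <- "CTGACTGGATCC"

.filler_seq <- function(n) {
  if (n <= 0) return("")
  substr(strrep(.FILLER, ceiling(n / nchar(.FILLER))), 1L, n)
}

# synthetic adapter appended when a read runs past the fragment end
.ADAPTER <- strrep("GATCGGAAGAGCACACGTCTGAACTCCAGTCA", 8)

#' Synthetic allele for one panel locus
#'
#' Builds a reference amplicon: forward primer, deterministic 5' filler, the
#' microsatellite tract (`repeat_unit` repeated `repeat_count` times),
#' deterministic 3' filler, and the reverse complement of the reverse
#' primer, with fillers sized so the assembled amplicon has exactly the
#' locus's reference amplicon length. The tract length choices for the
#' default panel are realistic for these markers but synthetic: true
#' flanking sequence is not reproduced.
#'
#' @param locus An `msi_locus`.
#' @param repeat_unit Repeat unit, e.g. `"A"` or `"CA"`; defaults to `"A"`
#'   for mononucleotide and `"CA"` for dinucleotide loci.
#' @param repeat_count Number of repeat units in the reference allele;
#'   default 25 mononucleotide units or 13 dinucleotide units.
#' @return A list of class `allele_spec` with `locus_name`, `repeat_unit`,
#'   `repeat_count`, `flank5`, `flank3`.
#' @export
allele_spec <- function(locus, repeat_unit = NULL, repeat_count = NULL) {
  stopifnot(inherits(locus, "msi_locus"))
  if (is.null(repeat_unit))
    repeat_unit <- switch(locus$repeat_class,
                          mononucleotide = "A", dinucleotide = "CA")
  if (is.null(repeat_count))
    repeat_count <- switch(locus$repeat_class,
                           mononucleotide = 25L, dinucleotide = 13L)
  fwd <- locus$forward_primer
  rev_rc <- reverse_complement(locus$reverse_primer)
  tract <- nchar(repeat_unit) * repeat_count
  pad <- locus$amplicon_length - nchar(fwd) - nchar(rev_rc) - tract
  if (pad < 0)
    stop("locus '", locus$name, "': repeat tract of ", tract,
         " bp does not fit in the amplicon")
  pad5 <- pad %/% 2L
  structure(list(locus_name = locus$name,
                 repeat_unit = repeat_unit,
                 repeat_count = as.integer(repeat_count),
                 flank5 = paste0(fwd, .filler_seq(pad5)),
                 flank3 = paste0(.filler_seq(pad - pad5), rev_rc)),
            class = "allele_spec")
}

#' Assemble the amplicon sequence of an allele
#'
#' @param allele An [allele_spec()].
#' @param shift_units Signed change in repeat count relative to the
#'   reference allele (default 0). Mononucleotide units move the length by
#'   1 bp each, dinucleotide units by 2 bp.
#' @return The amplicon DNA string.
#' @export
allele_sequence <- function(allele, shift_units = 0L) {
  n <- allele$repeat_count + as.integer(shift_units)
  if (n < 1L) stop("shift removes the whole repeat tract")
  paste0(allele$flank5, strrep(allele$repeat_unit, n), allele$flank3)
}

#' Simulation configuration
#'
#' Conditions emulate MiSeq 2 x 150 bp amplicon resequencing of the panel:
#' per-locus depth of 5000 (the assay's typical coverage), PCR stutter as
#' geometric-decay slippage biased 4:1 toward contraction, independent
#' per-base substitution errors, per-base Phred qualities from a truncated
#' normal whose mean declines linearly after cycle 100, and a small
#' admixture of random off-target read pairs.
#'
#' @param panel An `msi_panel`.
#' @param shifts Named integer vector of tumour shifts in repeat units per
#'   locus (missing loci default to 0, i.e. stable).
#' @param alleles Optional named list of [allele_spec()] overrides; defaults
#'   are built per locus.
#' @param depth_per_locus Molecules simulated per locus (default 5000).
#' @param stutter_prob Probability a molecule stutters at all (default
#'   0.02).
#' @param stutter_geometric_p Geometric parameter for the slipped unit
#'   count (default 0.7; larger means mostly single-unit slips).
#' @param substitution_error_rate Per-base substitution probability
#'   (default 0.002).
#' @param read_length Cycles per mate (default 150).
#' @param quality_mean,quality_sd Phred quality model before truncation to
#'   \[2, 41\] (defaults 37 and 3).
#' @param quality_decline_start Cycle after which the mean declines
#'   (default 100).
#' @param quality_decline_rate Mean Phred lost per cycle past the decline
#'   start (default 0.05).
#' @param fraction_offtarget Fraction of additional random-sequence pairs
#'   (default 0.01).
#' @param seed RNG seed; identical seed and config give byte-identical
#'   FASTQ.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(panel = default_panel(), shifts = integer(0),
                              alleles = NULL,
                              depth_per_locus = 5000L,
                              stutter_prob = 0.02,
                              stutter_geometric_p = 0.7,
                              substitution_error_rate = 0.002,
                              read_length = 150L,
                              quality_mean = 37, quality_sd = 3,
                              quality_decline_start = 100L,
                              quality_decline_rate = 0.05,
                              fraction_offtarget = 0.01,
                              seed = 1L) {
  stopifnot(inherits(panel, "msi_panel"), depth_per_locus >= 0,
            stutter_prob >= 0, stutter_prob <= 1,
            stutter_geometric_p > 0, stutter_geometric_p <= 1,
            substitution_error_rate >= 0, substitution_error_rate <= 1,
            read_length >= 1, fraction_offtarget >= 0,
            fraction_offtarget <= 1)
  nms <- names(panel$loci)
  if (length(shifts) && (is.null(names(shifts)) ||
                         !all(names(shifts) %in% nms)))
    stop("shifts must be named after panel loci")
  sh <- stats::setNames(integer(length(nms)), nms)
  sh[names(shifts)] <- as.integer(shifts)
  if (is.null(alleles))
    alleles <- lapply(panel$loci, allele_spec)
  structure(list(panel = panel, shifts = sh, alleles = alleles,
                 depth_per_locus = as.integer(depth_per_locus),
                 stutter_prob = stutter_prob,
                 stutter_geometric_p = stutter_geometric_p,
                 substitution_error_rate = substitution_error_rate,
                 read_length = as.integer(read_length),
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 quality_decline_start = as.integer(quality_decline_start),
                 quality_decline_rate = quality_decline_rate,
                 fraction_offtarget = fraction_offtarget,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

.BASES <- c("A", "C", "G", "T")

.substitute_errors <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    # draw a uniformly different base
    ch[hit] <- vapply(ch[hit],
                      function(b) sample(setdiff(.BASES, b), 1L),
                      character(1), USE.NAMES = FALSE)
    seq <- paste(ch, collapse = "")
  }
  seq
}

#' Simulate one PCR/sequencing molecule from an allele
#'
#' With probability `stutter_prob` the repeat count slips by `k` units,
#' `k` drawn geometrically (parameter `stutter_geometric_p`), contracting
#' with probability 0.8 and expanding with probability 0.2; independent
#' substitution errors are then applied at `substitution_error_rate` per
#' base. Uses R's global RNG stream.
#'
#' @param allele An [allele_spec()].
#' @param cfg A [simulation_config()].
#' @param shift_units Signed template shift in repeat units (tumour
#'   alleles).
#' @return The molecule's DNA sequence.
#' @export
simulate_molecule <- function(allele, cfg, shift_units = 0L) {
  n <- allele$repeat_count + as.integer(shift_units)
  if (stats::runif(1) < cfg$stutter_prob) {
    k <- stats::rgeom(1, cfg$stutter_geometric_p) + 1L
    n <- n + if (stats::runif(1) < 0.8) -k else k
  }
  n <- max(n, 1L)
  seq <- paste0(allele$flank5, strrep(allele$repeat_unit, n), allele$flank3)
  .substitute_errors(seq, cfg$substitution_error_rate)
}

.random_seq <- function(n) paste(sample(.BASES, n, replace = TRUE),
                                 collapse = "")

# vectorised batch equivalent of simulate_molecule (same model, one RNG
# stream; draw order differs from the scalar version)
.simulate_molecules <- function(allele, cfg, shift_units, n) {
  n0 <- allele$repeat_count + as.integer(shift_units)
  stut <- stats::runif(n) < cfg$stutter_prob
  units <- rep(n0, n)
  ns <- sum(stut)
  if (ns > 0) {
    k <- stats::rgeom(ns, cfg$stutter_geometric_p) + 1L
    contract <- stats::runif(ns) < 0.8
    units[stut] <- n0 + ifelse(contract, -k, k)
  }
  units <- pmax(units, 1L)
  seqs <- paste0(allele$flank5, strrep(allele$repeat_unit, units),
                 allele$flank3)
  rate <- cfg$substitution_error_rate
  if (rate > 0) {
    nerr <- stats::rbinom(n, nchar(seqs), rate)
    for (i in which(nerr > 0)) {
      ch <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
      pos <- sample.int(length(ch), nerr[i])
      ch[pos] <- vapply(ch[pos],
                        function(b) sample(setdiff(.BASES, b), 1L),
                        character(1), USE.NAMES = FALSE)
      seqs[i] <- paste(ch, collapse = "")
    }
  }
  seqs
}

#' Simulate a paired-end FASTQ sample over the panel
#'
#' For every locus, `depth_per_locus` molecules are drawn from the locus
#' allele (the tumour role applies the configured repeat-unit shift to the
#' template before stuttering); each molecule is emitted as a mate pair:
#' mate 1 is the first `read_length` bases (padded with a synthetic adapter
#' when the amplicon is shorter), mate 2 the reverse complement of the last
#' `read_length` bases, padded likewise. Random off-target pairs are
#' appended at `fraction_offtarget`. Output order and content are fully
#' determined by `seed`, config and role; the tumour role uses the stream
#' `seed + 1` so tumour and normal samples are independent draws.
#'
#' @param cfg A [simulation_config()].
#' @param role `"normal"` or `"tumour"`.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix (default = role).
#' @param gzip Compress FASTQ output (default `FALSE`).
#' @return A list with `r1`, `r2`, `truth_file` (paths) and `truth`, a
#'   data.frame with one row per locus: `locus`, `role`,
#'   `true_modal_length` (expected modal amplicon length in bp) and
#'   `configured_shift` (repeat units; 0 for the normal role).
#' @export
simulate_sample <- function(cfg, role = c("normal", "tumour"), dir,
                            prefix = NULL, gzip = FALSE) {
  role <- match.arg(role)
  stopifnot(inherits(cfg, "simulation_config"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(prefix)) prefix <- role
  set.seed(cfg$seed + (role == "tumour"))

  loci <- cfg$panel$loci
  ids <- character(0); s1 <- character(0); s2 <- character(0)
  truth <- vector("list", length(loci))
  for (li in seq_along(loci)) {
    locus <- loci[[li]]
    al <- cfg$alleles[[locus$name]]
    shift <- if (role == "tumour") cfg$shifts[[locus$name]] else 0L
    dep <- cfg$depth_per_locus
    if (dep > 0) {
      ids <- c(ids, sprintf("%s_%s_%d", prefix, locus$name, seq_len(dep)))
      s1 <- c(s1, .simulate_molecules(al, cfg, shift, dep))
    }
    truth[[li]] <- data.frame(
      locus = locus$name, role = role,
      true_modal_length = locus$amplicon_length +
        nchar(al$repeat_unit) * shift,
      configured_shift = shift, stringsAsFactors = FALSE)
  }
  n_off <- round(cfg$fraction_offtarget * length(s1))
  if (n_off > 0) {
    # off-target fragments still overlap (1.5 read lengths) so they merge
    # and exercise the unassigned path downstream
    off <- vapply(seq_len(n_off),
                  function(i) .random_seq(round(1.5 * cfg$read_length)),
                  character(1))
    ids <- c(ids, sprintf("%s_offtarget_%d", prefix, seq_len(n_off)))
    s1 <- c(s1, off)
  }

  # fragment -> mate pair
  rl <- cfg$read_length
  mate1 <- substr(paste0(s1, .ADAPTER), 1L, rl)
  mate2 <- substr(paste0(reverse_complement(s1), .ADAPTER), 1L, rl)
  cyc <- seq_len(rl)
  mu <- cfg$quality_mean -
    cfg$quality_decline_rate * pmax(0L, cyc - cfg$quality_decline_start)
  draw_quals <- function(n) {
    q <- round(stats::rnorm(n * rl, mu, cfg$quality_sd))
    asplit(matrix(as.integer(pmin(41, pmax(2, q))), nrow = rl), 2)
  }
  q1 <- draw_quals(length(s1))
  q2 <- draw_quals(length(s1))

  ext <- if (gzip) ".fastq.gz" else ".fastq"
  r1 <- file.path(dir, paste0(prefix, "_R1", ext))
  r2 <- file.path(dir, paste0(prefix, "_R2", ext))
  write_fastq(ids, mate1, q1, r1)
  write_fastq(ids, mate2, q2, r2)
  truth <- do.call(rbind, truth)
  truth_file <- file.path(dir, paste0(prefix, "_truth.tsv"))
  utils::write.table(truth, truth_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(r1 = r1, r2 = r2, truth_file = truth_file, truth = truth)
}
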