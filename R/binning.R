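#' Build the primer lookup table for a panel
#'
#' One row per locus: the forward-flank key is the forward primer as printed
#' and the reverse-flank key is the reverse complement of the reverse primer,
#' i.e. the two sequences that bound every correctly merged amplicon at its
#' 5' and 3' ends.
#'
#' @param panel An `msi_panel`.
#' @return A data.frame with columns `locus`, `fwd_key`, `rev_key`.
#' @export
build_lookup <- function(panel) {
  stopifnot(inherits(panel, "msi_panel"))
  if (!length(panel$loci)) {
    return(data.frame(locus = character(), fwd_key = character(),
                      rev_key = character(), stringsAsFactors = FALSE))
  }
  data.frame(
    locus = vapply(panel$loci, `[[`, character(1), "name"),
    fwd_key = vapply(panel$loci, `[[`, character(1), "forward_primer"),
    rev_key = reverse_complement(
      vapply(panel$loci, `[[`, character(1), "reverse_primer")),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

# mismatches between the fixed-length prefix/suffix of each read and a key;
# reads shorter than the key never match (Inf)
.flank_mismatches <- function(seqs, key, end = c("prefix", "suffix")) {
  end <- match.arg(end)
  k <- nchar(key)
  n <- nchar(seqs)
  flank <- if (end == "prefix") substr(seqs, 1L, k) else
    substr(seqs, n - k + 1L, n)
  mm <- rep(Inf, length(seqs))
  long <- n >= k
  if (any(long)) {
    exact <- long & flank == key
    mm[exact] <- 0L
    rest <- long & !exact
    if (any(rest)) {
      kraw <- charToRaw(key)
      mm[rest] <- vapply(flank[rest],
                         function(s) sum(charToRaw(s) != kraw),
                         numeric(1), USE.NAMES = FALSE)
    }
  }
  mm
}

#' Assign merged reads to panel loci by flanking-primer lookup
#'
#' A read belongs to locus L when L's forward key matches its 5' end and L's
#' reverse key matches its 3' end, each anchored at the read end and allowing
#' at most `max_flank_mismatches` substitutions (no indels: a flank indel
#' would corrupt the length coordinate). The reverse complement of the read
#' is also tried and the matching orientation recorded. Reads matching no
#' locus, or more than one, are left unassigned — ambiguity is discarded
#' rather than arbitrated.
#'
#' @param seqs Character vector of merged read sequences.
#' @param lookup A lookup table from [build_lookup()].
#' @param max_flank_mismatches Allowed substitutions per flank (default 0,
#'   at most 2).
#' @return A data.frame with columns `locus` (locus name or `NA` for
#'   unassigned) and `orientation` (`"forward"`, `"reverse"` or `NA`).
#' @export
assign_reads <- function(seqs, lookup, max_flank_mismatches = 0L) {
  stopifnot(max_flank_mismatches >= 0L, max_flank_mismatches <= 2L)
  n <- length(seqs)
  if (n == 0L || nrow(lookup) == 0L) {
    return(data.frame(locus = rep(NA_character_, n),
                      orientation = rep(NA_character_, n),
                      stringsAsFactors = FALSE))
  }
  rc <- reverse_complement(seqs)
  hits <- matrix(FALSE, n, nrow(lookup))      # forward orientation
  hits_rc <- matrix(FALSE, n, nrow(lookup))   # reverse orientation
  for (j in seq_len(nrow(lookup))) {
    fk <- lookup$fwd_key[j]; rk <- lookup$rev_key[j]
    hits[, j] <-
      .flank_mismatches(seqs, fk, "prefix") <= max_flank_mismatches &
      .flank_mismatches(seqs, rk, "suffix") <= max_flank_mismatches
    hits_rc[, j] <-
      .flank_mismatches(rc, fk, "prefix") <= max_flank_mismatches &
      .flank_mismatches(rc, rk, "suffix") <= max_flank_mismatches
  }
  any_hit <- hits | hits_rc
  n_loci <- rowSums(any_hit)
  locus <- rep(NA_character_, n)
  orientation <- rep(NA_character_, n)
  ok <- n_loci == 1L
  if (any(ok)) {
    j <- max.col(any_hit[ok, , drop = FALSE], ties.method = "first")
    locus[ok] <- lookup$locus[j]
    fwd <- hits[cbind(which(ok), j)]
    orientation[ok] <- ifelse(fwd, "forward", "reverse")
  }
  data.frame(locus = locus, orientation = orientation,
             stringsAsFactors = FALSE)
}

#' Assign a single merged read
#'
#' @param seq A single merged read sequence.
#' @inheritParams assign_reads
#' @return The locus name, or `NA_character_` if unassigned.
#' @export
assign_read <- function(seq, lookup, max_flank_mismatches = 0L) {
  assign_reads(seq, lookup, max_flank_mismatches)$locus[1]
}

#' Group identical assigned reads into amplicon groups
#'
#' One group per distinct (locus, sequence) pair, oriented so that grouped
#' sequences all read forward-primer-first. Groups are sorted by descending
#' read count then ascending length, so the modal amplicon of each locus
#' comes first.
#'
#' @param seqs Character vector of merged reads.
#' @param assignment The data.frame returned by [assign_reads()] for `seqs`.
#' @return A data.frame with columns `locus`, `seq`, `length_bp`,
#'   `read_count`. The sum of `read_count` equals the number of assigned
#'   reads.
#' @export
group_reads <- function(seqs, assignment) {
  stopifnot(length(seqs) == nrow(assignment))
  keep <- !is.na(assignment$locus)
  if (!any(keep)) {
    return(data.frame(locus = character(), seq = character(),
                      length_bp = integer(), read_count = integer(),
                      stringsAsFactors = FALSE))
  }
  s <- seqs[keep]
  rev <- assignment$orientation[keep] == "reverse"
  if (any(rev)) s[rev] <- reverse_complement(s[rev])
  key <- paste(assignment$locus[keep], s, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  g <- data.frame(
    locus = vapply(parts, `[[`, character(1), 1L),
    seq = vapply(parts, `[[`, character(1), 2L),
    read_count = as.integer(tab),
    stringsAsFactors = FALSE
  )
  g$length_bp <- nchar(g$seq)
  g <- g[order(-g$read_count, g$length_bp, g$seq), ]
  rownames(g) <- NULL
  g[, c("locus", "seq", "length_bp", "read_count")]
}

#' Per-locus amplicon length distribution
#'
#' Collapses amplicon groups of one locus into a read-count histogram over
#' amplicon length (full merged amplicon, primers included) — the per-locus
#' profile whose mode defines the sample's microsatellite length.
#'
#' @param groups An amplicon-group data.frame from [group_reads()].
#' @param locus Locus name to extract.
#' @return An object of class `length_distribution`: list with `locus`,
#'   `counts` (named integer vector, names = length in bp, sorted by length)
#'   and `total_reads`.
#' @export
length_distribution <- function(groups, locus) {
  g <- groups[groups$locus == locus, , drop = FALSE]
  counts <- integer(0)
  if (nrow(g)) {
    agg <- tapply(g$read_count, g$length_bp, sum)
    counts <- as.integer(agg)
    names(counts) <- names(agg)
    counts <- counts[order(as.integer(names(counts)))]
  }
  structure(list(locus = locus, counts = counts,
                 total_reads = sum(counts)),
            class = "length_distribution")
}

#' Construct a length distribution directly from counts
#'
#' Convenience constructor used when the histogram is already known (e.g.
#' published profiles or simulator truth checks).
#'
#' @param counts Named numeric vector: names are lengths in bp, values read
#'   counts.
#' @param locus Locus name.
#' @return A `length_distribution`.
#' @export
as_length_distribution <- function(counts, locus = "locus") {
  stopifnot(!is.null(names(counts)), all(counts >= 0))
  counts <- counts[counts > 0]
  nm <- names(counts)
  counts <- stats::setNames(as.integer(counts), nm)
  structure(list(locus = locus,
                 counts = counts[order(as.integer(names(counts)))],
                 total_reads = sum(counts)),
            class = "length_distribution")
}

#' @export
print.length_distribution <- function(x, ...) {
  cat(sprintf("<length_distribution> %s: %d reads over %d length(s)\n",
              x$locus, x$total_reads, length(x$counts)))
  if (length(x$counts)) print(x$counts)
  invisible(x)
}

#' @export
#' @importFrom graphics barplot
plot.length_distribution <- function(x, ...) {
  barplot(x$counts, xlab = "amplicon length (bp)", ylab = "read count",
          main = x$locus, ...)
  invisible(x)
}

#' Full binning step: assign, group, and tabulate every locus
#'
#' @param seqs Merged read sequences.
#' @param panel An `msi_panel`.
#' @param max_flank_mismatches Allowed substitutions per flank.
#' @return A list with `groups` (data.frame), `distributions` (named list of
#'   `length_distribution`, one per panel locus), and `counts` (named integer
#'   vector: reads assigned per locus plus `unassigned`).
#' @export
bin_reads <- function(seqs, panel, max_flank_mismatches = 0L) {
  lookup <- build_lookup(panel)
  asg <- assign_reads(seqs, lookup, max_flank_mismatches)
  groups <- group_reads(seqs, asg)
  dists <- lapply(lookup$locus, function(l) length_distribution(groups, l))
  names(dists) <- lookup$locus
  per_locus <- vapply(dists, `[[`, integer(1), "total_reads")
  counts <- c(per_locus, unassigned = sum(is.na(asg$locus)))
  list(groups = groups, distributions = dists, counts = counts)
}
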