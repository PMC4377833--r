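#' Preprocessing configuration
#'
#' Parameters for paired-end read merging and whole-read quality filtering.
#' Merging searches for the overlap between mate 1 and the reverse complement
#' of mate 2; merged reads whose mean Phred quality falls below
#' `quality_threshold` are discarded (the Q30 filter: a mean of 30 corresponds
#' to an expected base-error rate below 1/1000).
#'
#' @param min_overlap Minimum acceptable overlap in bp (default 15).
#' @param max_mismatch_fraction Maximum fraction of mismatching bases allowed
#'   within the overlap (default 0.1).
#' @param quality_threshold Mean per-base Phred score below which a merged
#'   read is discarded (default 30). A read with mean exactly at the
#'   threshold is kept.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(min_overlap = 15L,
                              max_mismatch_fraction = 0.1,
                              quality_threshold = 30) {
  stopifnot(min_overlap >= 1, max_mismatch_fraction >= 0,
            max_mismatch_fraction <= 1, quality_threshold >= 0)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_fraction = max_mismatch_fraction,
                 quality_threshold = quality_threshold),
            class = "preprocess_config")
}

#' Merge one read pair into a single amplicon sequence
#'
#' Exhaustively scans all relative offsets of mate 1 against the reverse
#' complement of mate 2 and keeps the offset maximising the number of
#' matching bases, subject to an overlap of at least `min_overlap` bp and a
#' mismatch fraction at most `max_mismatch_fraction`; ties are broken toward
#' the longer overlap, then the smaller offset. Within the overlap the base
#' with the higher Phred score wins and the merged quality is the maximum of
#' the two; outside it, bases and qualities are taken as-is. Because mate 1
#' starts at the fragment's 5' end and mate 2 at its 3' end, sequence read
#' through into adapter beyond either fragment end is trimmed automatically:
#' the merged read spans exactly from the start of mate 1 to the end of
#' reverse-complemented mate 2.
#'
#' @param seq1,seq2 Mate sequences (character scalars, mate 2 as sequenced).
#' @param qual1,qual2 Integer Phred vectors, one score per base. Defaults to
#'   flat Q30 when omitted.
#' @param cfg A [preprocess_config()].
#' @return On success, a list with `seq`, `qual` (integer vector) and
#'   `mean_quality`; on failure to find an acceptable overlap, `NULL`
#'   (merge failure is a value, not an error).
#' @export
merge_pair <- function(seq1, seq2, qual1 = NULL, qual2 = NULL,
                       cfg = preprocess_config()) {
  n1 <- nchar(seq1); n2 <- nchar(seq2)
  if (is.null(qual1)) qual1 <- rep(30L, n1)
  if (is.null(qual2)) qual2 <- rep(30L, n2)
  stopifnot(length(qual1) == n1, length(qual2) == n2,
            all(qual1 >= 0 & qual1 <= 60), all(qual2 >= 0 & qual2 <= 60))
  r1 <- charToRaw(seq1)
  r2 <- charToRaw(reverse_complement(seq2))
  q2 <- rev(qual2)

  # offset d: position of r2's first base in r1 coordinates is d + 1
  ds <- seq.int(-(n2 - 1L), n1 - 1L)
  ol <- pmin(n1, ds + n2) - pmax(1L, ds + 1L) + 1L
  keep <- ol >= cfg$min_overlap
  ds <- ds[keep]; ol <- ol[keep]
  if (!length(ds)) return(NULL)
  ord <- order(-ol, ds)
  ds <- ds[ord]; ol <- ol[ord]

  best <- -1L; best_d <- NA_integer_
  for (i in seq_along(ds)) {
    if (ol[i] <= best) break  # matches cannot exceed overlap length
    d <- ds[i]
    a <- max(1L, d + 1L); b <- min(n1, d + n2)
    m <- sum(r1[a:b] == r2[(a - d):(b - d)])
    if (ol[i] - m <= cfg$max_mismatch_fraction * ol[i] && m > best) {
      best <- m; best_d <- d
    }
  }
  if (is.na(best_d)) return(NULL)

  d <- best_d
  len <- d + n2                       # fragment spans r1[1] .. r2 end
  pos <- seq_len(len)
  in1 <- pos <= n1
  in2 <- pos > d
  seq <- raw(len); qual <- integer(len)
  only1 <- in1 & !in2
  seq[only1] <- r1[pos[only1]]; qual[only1] <- qual1[pos[only1]]
  only2 <- in2 & !in1
  seq[only2] <- r2[pos[only2] - d]; qual[only2] <- q2[pos[only2] - d]
  both <- in1 & in2
  if (any(both)) {
    p <- pos[both]
    take1 <- qual1[p] >= q2[p - d]
    cons <- r2[p - d]
    cons[take1] <- r1[p][take1]
    seq[both] <- cons
    qual[both] <- pmax(qual1[p], q2[p - d])
  }
  list(seq = rawToChar(seq), qual = qual, mean_quality = mean(qual))
}

#' Whole-read quality filter
#'
#' @param mean_quality Mean per-base Phred score(s) of merged read(s).
#' @param cfg A [preprocess_config()].
#' @return Logical: `TRUE` for reads to keep (mean quality at or above the
#'   threshold).
#' @export
quality_filter <- function(mean_quality, cfg = preprocess_config()) {
  mean_quality >= cfg$quality_threshold
}

# --- FASTQ I/O (Biostrings) -------------------------------------------------

#' Read paired FASTQ files
#'
#' Reads 4-line FASTQ records (Phred+33), plain or gzip-compressed.
#'
#' @param r1,r2 Paths to the mate 1 and mate 2 FASTQ files.
#' @return A list with character vectors `id`, `seq1`, `seq2` and integer-list
#'   columns `qual1`, `qual2` (per-base Phred scores).
#' @export
read_fastq_pairs <- function(r1, r2) {
  for (f in c(r1, r2)) if (!file.exists(f)) stop("FASTQ file not found: ", f)
  rd <- function(f) {
    # several Biostrings coercions warn that quality metadata columns get
    # dropped; that is by design here, so the warning is muffled throughout
    out <- withCallingHandlers(
      tryCatch({
        x <- Biostrings::readQualityScaledDNAStringSet(
          f, quality.scoring = "phred")
        # a truncated record can slip through the reader with corrupt
        # qualities; the width comparison and conversions catch it here
        if (!identical(Biostrings::width(x),
                       Biostrings::width(Biostrings::quality(x))))
          stop("sequence and quality lengths disagree")
        seqs <- as.character(x)
        quals <- lapply(as.character(Biostrings::quality(x)),
                        function(q) utf8ToInt(q) - 33L)
        if (any(vapply(quals, function(q) any(q < 0 | q > 60), logical(1))))
          stop("Phred score outside [0, 60]")
        list(id = names(x), seq = unname(seqs), qual = unname(quals))
      }, error = function(e) e),
      warning = function(w) {
        if (grepl("metadata columns", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (inherits(out, "error"))
      stop("malformed FASTQ file '", f, "': ", conditionMessage(out),
           call. = FALSE)
    out
  }
  a <- rd(r1); b <- rd(r2)
  if (length(a$id) != length(b$id))
    stop("mate files have different read counts: ", r1, " vs ", r2)
  list(id = a$id, seq1 = a$seq, qual1 = a$qual,
       seq2 = b$seq, qual2 = b$qual)
}

#' Write reads to FASTQ
#'
#' @param ids,seqs Character vectors of read names and sequences.
#' @param quals List of integer Phred vectors (or `NULL` for flat Q30).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals = NULL, path) {
  if (is.null(quals)) quals <- lapply(nchar(seqs), function(n) rep(30L, n))
  qstr <- vapply(quals, function(q) intToUtf8(q + 33L), character(1))
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(seqs), Biostrings::PhredQuality(qstr))
  names(x) <- ids
  Biostrings::writeQualityScaledXStringSet(
    x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Merge and quality-filter a pair of FASTQ files
#'
#' File-level preprocessing: merges every pair with [merge_pair()], applies
#' the mean-quality filter, and returns the surviving merged reads together
#' with exact read accounting.
#'
#' @param r1,r2 FASTQ paths.
#' @param cfg A [preprocess_config()].
#' @return A list with `id`, `seq`, `qual` (merged reads passing the filter)
#'   and `counts`, a named integer vector with elements `pairs_in`, `merged`,
#'   `merge_failed`, `quality_discarded`, `kept`. Counts are conserved:
#'   `merged + merge_failed = pairs_in` and
#'   `kept + quality_discarded = merged`.
#' @export
preprocess_fastq <- function(r1, r2, cfg = preprocess_config()) {
  p <- read_fastq_pairs(r1, r2)
  n <- length(p$id)
  out_seq <- character(n); out_q <- vector("list", n)
  meanq <- numeric(n); ok <- logical(n)
  for (i in seq_len(n)) {
    m <- merge_pair(p$seq1[i], p$seq2[i], p$qual1[[i]], p$qual2[[i]], cfg)
    if (!is.null(m)) {
      ok[i] <- TRUE
      out_seq[i] <- m$seq; out_q[[i]] <- m$qual; meanq[i] <- m$mean_quality
    }
  }
  pass <- ok & quality_filter(meanq, cfg)
  counts <- c(pairs_in = n, merged = sum(ok),
              merge_failed = n - sum(ok),
              quality_discarded = sum(ok) - sum(pass),
              kept = sum(pass))
  list(id = p$id[pass], seq = out_seq[pass], qual = out_q[pass],
       counts = counts)
}
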