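#' Classification configuration
#'
#' The locus-instability rule compares the tumour's modal amplicon length
#' with a comparator (matched normal, or a fixed panel reference): a locus is
#' unstable when the absolute deviation reaches `mono_cutoff_bp` base pairs
#' for mononucleotide repeats or `di_cutoff_bp` for dinucleotide repeats
#' (both cut-offs inclusive). A sample is MSI-H when at least
#' `msi_high_min_unstable` informative loci are unstable, MSI-L when exactly
#' one is, and MSS when none is. Loci where either side has fewer than
#' `min_reads_per_locus` reads are reported NO_CALL and excluded from the
#' denominator.
#'
#' @param mono_cutoff_bp Instability cut-off for mononucleotide loci
#'   (default 2 bp, inclusive).
#' @param di_cutoff_bp Cut-off for dinucleotide loci (default 4 bp,
#'   inclusive).
#' @param min_reads_per_locus Minimum read depth for an informative call
#'   (default 100).
#' @param msi_high_min_unstable Unstable-locus count at or above which the
#'   sample is MSI-H (default 2, i.e. >= 40\% of a five-locus panel).
#' @return A list of class `classify_config`.
#' @export
classify_config <- function(mono_cutoff_bp = 2L, di_cutoff_bp = 4L,
                            min_reads_per_locus = 100L,
                            msi_high_min_unstable = 2L) {
  stopifnot(mono_cutoff_bp >= 1, di_cutoff_bp >= 1,
            min_reads_per_locus >= 0, msi_high_min_unstable >= 1)
  structure(list(mono_cutoff_bp = as.integer(mono_cutoff_bp),
                 di_cutoff_bp = as.integer(di_cutoff_bp),
                 min_reads_per_locus = as.integer(min_reads_per_locus),
                 msi_high_min_unstable = as.integer(msi_high_min_unstable)),
            class = "classify_config")
}

#' Modal amplicon length of a distribution
#'
#' The length carrying the maximum read count — the maximally expressed
#' amplicon in the tissue. At an exact tie in read counts the length closest
#' to `comparator` is preferred (conservative toward stability); without a
#' comparator, the shorter length wins. Both rules are deterministic.
#'
#' @param dist A `length_distribution` with at least one read.
#' @param comparator Optional comparator modal length in bp used only for
#'   tie-breaking.
#' @return Integer modal length in bp.
#' @export
modal_length <- function(dist, comparator = NULL) {
  stopifnot(inherits(dist, "length_distribution"))
  if (dist$total_reads < 1L || !length(dist$counts))
    stop("cannot take the modal length of an empty distribution (locus ",
         dist$locus, ")")
  lens <- as.integer(names(dist$counts))
  top <- lens[dist$counts == max(dist$counts)]
  if (length(top) == 1L) return(top)
  if (!is.null(comparator) && !is.na(comparator)) {
    top <- top[order(abs(top - comparator), top)]
    return(top[1])
  }
  min(top)
}

#' Call stability of one locus
#'
#' Computes the absolute deviation between the tumour's and the comparator's
#' modal lengths and applies the repeat-class cut-off. With a matched normal
#' the comparator is that sample's own distribution (`comparator_source`
#' `"matched_normal"`); in tumour-only mode it is the locus's fixed
#' `modal_length` reference (`"panel_reference"`). Either side falling below
#' `min_reads_per_locus` yields NO_CALL.
#'
#' @param tumour A `length_distribution` for the tumour.
#' @param comparator A `length_distribution` for the matched normal, or a
#'   single integer reference modal length (tumour-only mode).
#' @param locus The `msi_locus` being called (sets the cut-off via its
#'   repeat class).
#' @param cfg A [classify_config()].
#' @return A one-row data.frame: `locus`, `repeat_class`, `tumour_mode`,
#'   `comparator_mode`, `delta_bp`, `cutoff_bp`, `status` (one of "stable",
#'   "unstable", "no_call") and `comparator_source`.
#' @export
call_locus <- function(tumour, comparator, locus, cfg = classify_config()) {
  stopifnot(inherits(tumour, "length_distribution"),
            inherits(locus, "msi_locus"))
  cutoff <- switch(locus$repeat_class,
                   mononucleotide = cfg$mono_cutoff_bp,
                   dinucleotide = cfg$di_cutoff_bp,
                   stop("unknown repeat class: ", locus$repeat_class))
  if (inherits(comparator, "length_distribution")) {
    source <- "matched_normal"
    comp_ok <- comparator$total_reads >= cfg$min_reads_per_locus
    comp_mode <- if (comparator$total_reads >= 1L)
      modal_length(comparator) else NA_integer_
  } else {
    source <- "panel_reference"
    comp_mode <- as.integer(comparator)
    if (is.na(comp_mode))
      stop("locus '", locus$name,
           "' has no reference modal length; tumour-only calling needs an ",
           "explicit reference")
    comp_ok <- TRUE
  }
  tum_ok <- tumour$total_reads >= cfg$min_reads_per_locus
  if (!tum_ok || !comp_ok) {
    return(data.frame(
      locus = locus$name, repeat_class = locus$repeat_class,
      tumour_mode = NA_integer_, comparator_mode = comp_mode,
      delta_bp = NA_integer_, cutoff_bp = cutoff, status = "no_call",
      comparator_source = source, stringsAsFactors = FALSE))
  }
  tum_mode <- modal_length(tumour, comparator = comp_mode)
  delta <- abs(tum_mode - comp_mode)
  data.frame(
    locus = locus$name, repeat_class = locus$repeat_class,
    tumour_mode = tum_mode, comparator_mode = comp_mode,
    delta_bp = delta, cutoff_bp = cutoff,
    status = if (delta >= cutoff) "unstable" else "stable",
    comparator_source = source, stringsAsFactors = FALSE)
}

#' Combine locus calls into an overall MSI status
#'
#' MSI-H when the number of unstable informative loci reaches
#' `msi_high_min_unstable`; MSI-L when exactly one locus is unstable; MSS
#' when none is. A sample with no informative locus (all NO_CALL) is
#' indeterminate.
#'
#' @param calls A data.frame of locus calls (rows from [call_locus()],
#'   `rbind`-ed).
#' @param cfg A [classify_config()].
#' @param sample_id Sample identifier carried into the result.
#' @return An object of class `msi_result` with fields `sample_id`, `calls`,
#'   `n_unstable`, `n_informative` and `overall` (one of "MSS", "MSI-L",
#'   "MSI-H", "indeterminate").
#' @export
overall_status <- function(calls, cfg = classify_config(),
                           sample_id = "sample") {
  stopifnot(is.data.frame(calls), "status" %in% names(calls))
  informative <- calls$status %in% c("stable", "unstable")
  n_unstable <- sum(calls$status == "unstable")
  n_informative <- sum(informative)
  overall <- if (n_informative == 0L) "indeterminate"
  else if (n_unstable >= cfg$msi_high_min_unstable) "MSI-H"
  else if (n_unstable == 1L) "MSI-L"
  else "MSS"
  structure(list(sample_id = sample_id, calls = calls,
                 n_unstable = n_unstable, n_informative = n_informative,
                 overall = overall),
            class = "msi_result")
}

#' @export
print.msi_result <- function(x, ...) {
  cat(sprintf("<msi_result> sample '%s': %s (%d of %d informative loci unstable)\n",
              x$sample_id, x$overall, x$n_unstable, x$n_informative))
  print(x$calls[, setdiff(names(x$calls), "repeat_class")], row.names = FALSE)
  invisible(x)
}

#' @export
summary.msi_result <- function(object, ...) {
  cat("Sample:            ", object$sample_id, "\n")
  cat("Overall MSI status:", object$overall, "\n")
  cat("Unstable loci:     ",
      if (object$n_unstable) paste(
        object$calls$locus[object$calls$status == "unstable"],
        collapse = ", ") else "none", "\n")
  cat("Informative loci:  ", object$n_informative, "of",
      nrow(object$calls), "\n")
  invisible(object)
}

#' @export
as.data.frame.msi_result <- function(x, ...) {
  cbind(sample = x$sample_id, x$calls, overall = x$overall,
        stringsAsFactors = FALSE)
}
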