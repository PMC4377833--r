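#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta-distribution quantiles, returned in
#' percent. With \eqn{k} successes in \eqn{n} trials and \eqn{\alpha =
#' (1-\text{confidence})/2}, the lower bound is the \eqn{\alpha} quantile of
#' Beta(k, n-k+1) and the upper bound the \eqn{1-\alpha} quantile of
#' Beta(k+1, n-k); the boundaries collapse to 0 when \eqn{k=0} and to 100
#' when \eqn{k=n} (where the lower bound is \eqn{100\,\alpha^{1/n}}).
#'
#' @param successes,trials Integers, `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param confidence Coverage (default 0.95).
#' @return Named numeric vector `c(lower, upper)` in percent.
#' @export
clopper_pearson <- function(successes, trials, confidence = 0.95) {
  stopifnot(length(successes) == 1, length(trials) == 1)
  if (trials < 1) stop("trials must be >= 1")
  if (successes < 0 || successes > trials)
    stop("successes must lie in [0, trials]")
  alpha <- (1 - confidence) / 2
  lower <- if (successes == 0) 0 else
    stats::qbeta(alpha, successes, trials - successes + 1)
  upper <- if (successes == trials) 1 else
    stats::qbeta(1 - alpha, successes + 1, trials - successes)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Load a locus call matrix
#'
#' Reads a wide TSV with one row per case: a `case` column, `<locus>_ngs`
#' and (where the comparator assay tested the locus) `<locus>_pcr` columns
#' holding `+` (unstable) or `-` (stable), and `status_ngs` / `status_pcr`
#' columns in \{High, Low, Stable\}. The packaged fixtures
#' `series1_calls()` and `series2_calls()` use this schema.
#'
#' @param path TSV path.
#' @return An object of class `call_matrix`: list with `loci` (character),
#'   `ngs` and `pcr` (logical case x locus matrices, `TRUE` = unstable, `NA`
#'   where untested), `status_ngs`, `status_pcr` (character vectors) and
#'   `cases`.
#' @export
read_call_matrix <- function(path) {
  if (!file.exists(path)) stop("call matrix file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("case", "status_ngs", "status_pcr")
  if (!all(need %in% names(d)))
    stop("call matrix '", path, "' lacks required column(s): ",
         paste(setdiff(need, names(d)), collapse = ", "))
  loci <- sub("_ngs$", "", grep("^(?!status)[^ ]*_ngs$", names(d),
                                perl = TRUE, value = TRUE))
  if (!length(loci)) stop("call matrix '", path, "' has no locus columns")
  bad_status <- setdiff(unique(c(d$status_ngs, d$status_pcr)),
                        c("High", "Low", "Stable"))
  if (length(bad_status))
    stop("invalid MSI status value(s): ", paste(bad_status, collapse = ", "))
  to_logical <- function(x) {
    bad <- !(x %in% c("+", "-") | is.na(x))
    if (any(bad)) stop("invalid locus call '", x[bad][1], "' in ", path)
    x == "+"
  }
  grab <- function(suffix) {
    m <- sapply(loci, function(l) {
      col <- paste0(l, suffix)
      if (col %in% names(d)) to_logical(d[[col]]) else
        rep(NA, nrow(d))
    })
    m <- matrix(m, nrow = nrow(d), dimnames = list(d$case, loci))
    m
  }
  structure(list(cases = d$case, loci = loci,
                 ngs = grab("_ngs"), pcr = grab("_pcr"),
                 status_ngs = d$status_ngs, status_pcr = d$status_pcr),
            class = "call_matrix")
}

#' @export
print.call_matrix <- function(x, ...) {
  cat(sprintf("<call_matrix> %d cases x %d loci (%s)\n",
              length(x$cases), length(x$loci),
              paste(x$loci, collapse = ", ")))
  cat("NGS status counts:\n")
  print(table(factor(x$status_ngs, c("High", "Low", "Stable"))))
  invisible(x)
}

#' Packaged per-locus call matrices of the two validation cohorts
#'
#' `series1_calls()`: 44 colorectal tumours with matched normal tissue,
#' five NGS loci (BAT25, BAT26, BAT34c4, D18S55, D5S346); the comparator
#' multiplex-PCR assay shares BAT25, BAT26 and D5S346.
#' `series2_calls()`: 6 tumours without normal control, BAT25 and BAT26
#' only. These are test/evaluation data, not user input.
#'
#' @return A `call_matrix`.
#' @export
series1_calls <- function() {
  read_call_matrix(system.file("extdata", "series1_calls.tsv",
                               package = "msiamp", mustWork = TRUE))
}

#' @rdname series1_calls
#' @export
series2_calls <- function() {
  read_call_matrix(system.file("extdata", "series2_calls.tsv",
                               package = "msiamp", mustWork = TRUE))
}

.confusion <- function(truth, pred, confidence = 0.95) {
  stopifnot(length(truth) == length(pred), !anyNA(truth), !anyNA(pred))
  tp <- sum(truth & pred); fn <- sum(truth & !pred)
  tn <- sum(!truth & !pred); fp <- sum(!truth & pred)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  structure(list(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = sens, specificity = spec,
    sens_ci = if (tp + fn > 0) clopper_pearson(tp, tp + fn, confidence)
              else c(lower = NA_real_, upper = NA_real_),
    spec_ci = if (tn + fp > 0) clopper_pearson(tn, tn + fp, confidence)
              else c(lower = NA_real_, upper = NA_real_),
    confidence = confidence
  ), class = "msi_confusion")
}

#' @export
print.msi_confusion <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "n/a", sprintf("%.1f", round(v, 1)))
  cat(sprintf("<msi_confusion> tp=%d fp=%d tn=%d fn=%d\n",
              x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  sensitivity %s%% (%.0f%% CI %s-%s)\n", fmt(x$sensitivity),
              100 * x$confidence, fmt(x$sens_ci[1]), fmt(x$sens_ci[2])))
  cat(sprintf("  specificity %s%% (%.0f%% CI %s-%s)\n", fmt(x$specificity),
              100 * x$confidence, fmt(x$spec_ci[1]), fmt(x$spec_ci[2])))
  invisible(x)
}

#' NGS locus call against the comparator assay's call at the same locus
#'
#' Truth is the multiplex-PCR call for the locus, prediction the NGS call;
#' positives are unstable loci. Loci the comparator assay did not test
#' cannot be compared and raise an error.
#'
#' @param matrix A `call_matrix`.
#' @param locus Locus name.
#' @param confidence CI coverage (default 0.95).
#' @return An `msi_confusion`.
#' @export
locus_vs_locus <- function(matrix, locus, confidence = 0.95) {
  stopifnot(inherits(matrix, "call_matrix"))
  if (!locus %in% matrix$loci) stop("locus '", locus, "' not in matrix")
  pcr <- matrix$pcr[, locus]
  if (anyNA(pcr))
    stop("locus '", locus, "' was not tested by the comparator assay; ",
         "NGS-vs-PCR comparison is not possible")
  .confusion(truth = pcr, pred = matrix$ngs[, locus],
             confidence = confidence)
}

#' NGS locus call against overall MSI status
#'
#' Truth is whether the comparator assay classified the case MSI-High;
#' prediction is the NGS call at `locus`. Several cohorts can be pooled by
#' passing a list of matrices (the locus must have NGS calls in all of
#' them).
#'
#' @param matrices A `call_matrix` or list of them.
#' @param locus Locus name.
#' @param confidence CI coverage (default 0.95).
#' @return An `msi_confusion`.
#' @export
locus_vs_overall <- function(matrices, locus, confidence = 0.95) {
  if (inherits(matrices, "call_matrix")) matrices <- list(matrices)
  truth <- logical(0); pred <- logical(0)
  for (m in matrices) {
    stopifnot(inherits(m, "call_matrix"))
    if (!locus %in% m$loci)
      stop("locus '", locus, "' has no NGS calls in one of the matrices")
    truth <- c(truth, m$status_pcr == "High")
    pred <- c(pred, m$ngs[, locus])
  }
  .confusion(truth, pred, confidence)
}

#' Recompute cohort MSI statuses from per-locus NGS calls
#'
#' Applies the overall-status rule ([overall_status()]) to each case's NGS
#' locus calls, tallies MSI-H/MSI-L/MSS, and cross-checks the recomputed
#' statuses against the matrix's printed NGS status column.
#'
#' @param matrix A `call_matrix`.
#' @param cfg A [classify_config()].
#' @return A list with `counts` (named integer vector `MSI-H`, `MSI-L`,
#'   `MSS`), `status` (recomputed per case), `printed` (the matrix's NGS
#'   column translated to the same labels), `n_agree` and `discrepancies`
#'   (data.frame of disagreeing cases, zero rows when fully concordant).
#' @export
cohort_summary <- function(matrix, cfg = classify_config()) {
  stopifnot(inherits(matrix, "call_matrix"))
  n <- length(matrix$cases)
  status <- character(n)
  for (i in seq_len(n)) {
    calls <- data.frame(
      locus = matrix$loci,
      status = ifelse(matrix$ngs[i, ], "unstable", "stable"),
      stringsAsFactors = FALSE)
    status[i] <- overall_status(calls, cfg,
                                sample_id = as.character(matrix$cases[i]))$overall
  }
  printed <- c(High = "MSI-H", Low = "MSI-L", Stable = "MSS")[matrix$status_ngs]
  counts <- c("MSI-H" = sum(status == "MSI-H"),
              "MSI-L" = sum(status == "MSI-L"),
              "MSS" = sum(status == "MSS"))
  disc <- data.frame(case = matrix$cases, recomputed = status,
                     printed = unname(printed),
                     stringsAsFactors = FALSE)[status != printed, ,
                                               drop = FALSE]
  rownames(disc) <- NULL
  list(counts = counts, status = status, printed = unname(printed),
       n_agree = sum(status == printed), discrepancies = disc)
}

#' Tabulate marker performance for a report
#'
#' One row per requested (comparison, locus): confusion counts and
#' sensitivity/specificity with exact CIs, percentages rounded half-up to
#' one decimal for display.
#'
#' @param comparisons Named list of `msi_confusion` objects.
#' @return A data.frame with columns `comparison`, `tp`, `fp`, `tn`, `fn`,
#'   `sens`, `sens_ci_lo`, `sens_ci_hi`, `spec`, `spec_ci_lo`, `spec_ci_hi`.
#' @export
confusion_table <- function(comparisons) {
  r1 <- function(v) floor(v * 10 + 0.5) / 10  # round half-up, 1 decimal
  do.call(rbind, lapply(names(comparisons), function(nm) {
    x <- comparisons[[nm]]
    data.frame(comparison = nm, tp = x$tp, fp = x$fp, tn = x$tn, fn = x$fn,
               sens = r1(x$sensitivity),
               sens_ci_lo = r1(x$sens_ci[1]), sens_ci_hi = r1(x$sens_ci[2]),
               spec = r1(x$specificity),
               spec_ci_lo = r1(x$spec_ci[1]), spec_ci_hi = r1(x$spec_ci[2]),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}
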