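#' Run the full MSI pipeline on one sample
#'
#' End-to-end: merge overlapping mates, discard merged reads below the mean
#' quality threshold, bin reads to panel loci by flanking-primer lookup,
#' build per-locus amplicon length distributions, call each locus from the
#' modal-length deviation, and combine the calls into an overall MSI status.
#' With matched-normal FASTQs the comparator is the normal sample's own
#' distribution at each locus; without them the pipeline switches to
#' tumour-only mode and compares against each locus's fixed reference modal
#' length, refusing loci that do not declare one.
#'
#' @param tumour_r1,tumour_r2 Tumour FASTQ paths (required).
#' @param normal_r1,normal_r2 Matched-normal FASTQ paths, or `NULL` for
#'   tumour-only mode.
#' @param panel An `msi_panel` or a path to a panel YAML file.
#' @param sample_id Sample identifier used in reports.
#' @param out_dir Optional output directory; when given, writes the
#'   per-locus distribution TSV, the call report (TSV and JSON) and a run
#'   log with exact read accounting.
#' @param preprocess A [preprocess_config()].
#' @param classify A [classify_config()].
#' @param max_flank_mismatches Substitutions tolerated per primer flank
#'   during binning (default 0).
#' @return An `msi_result` with extra fields `distributions` (tumour; and
#'   `normal_distributions` in paired mode) and `accounting`, a data.frame
#'   of read counts per processing stage for each input sample.
#' @export
run_sample <- function(tumour_r1, tumour_r2,
                       normal_r1 = NULL, normal_r2 = NULL,
                       panel = default_panel(), sample_id = "sample",
                       out_dir = NULL,
                       preprocess = preprocess_config(),
                       classify = classify_config(),
                       max_flank_mismatches = 0L) {
  if (is.character(panel)) panel <- read_panel(panel)
  stopifnot(inherits(panel, "msi_panel"))
  if (!length(panel$loci)) stop("panel is empty")
  paired <- !is.null(normal_r1)
  if (paired && is.null(normal_r2))
    stop("normal_r2 is required when normal_r1 is given")

  process <- function(r1, r2, label) {
    pre <- preprocess_fastq(r1, r2, preprocess)
    bin <- bin_reads(pre$seq, panel, max_flank_mismatches)
    acct <- data.frame(sample = label,
                       stage = c(names(pre$counts), names(bin$counts)),
                       reads = c(unname(pre$counts), unname(bin$counts)),
                       stringsAsFactors = FALSE)
    list(dists = bin$distributions, accounting = acct)
  }

  tum <- process(tumour_r1, tumour_r2, "tumour")
  nor <- if (paired) process(normal_r1, normal_r2, "normal")

  use_loci <- panel$loci
  if (!paired) {
    has_ref <- !vapply(use_loci, function(l) is.na(l$modal_length),
                       logical(1))
    if (!any(has_ref))
      stop("tumour-only mode: no panel locus declares a reference modal ",
           "length")
    use_loci <- use_loci[has_ref]
  }
  calls <- do.call(rbind, lapply(use_loci, function(locus) {
    comparator <- if (paired) nor$dists[[locus$name]] else locus$modal_length
    call_locus(tum$dists[[locus$name]], comparator, locus, classify)
  }))
  rownames(calls) <- NULL
  res <- overall_status(calls, classify, sample_id = sample_id)
  res$distributions <- tum$dists
  if (paired) res$normal_distributions <- nor$dists
  res$accounting <- rbind(tum$accounting, if (paired) nor$accounting)

  if (!is.null(out_dir)) write_sample_reports(res, out_dir)
  res
}

#' Write the per-sample report files
#'
#' Produces `<id>_distributions.tsv` (sample, locus, length_bp,
#' read_count), `<id>_calls.tsv` (per-locus rows plus one overall row),
#' `<id>_calls.json` (same content) and `<id>_run.log` (read accounting).
#'
#' @param res An `msi_result` from [run_sample()].
#' @param out_dir Output directory, created if missing.
#' @return Named character vector of the written paths, invisibly.
#' @export
write_sample_reports <- function(res, out_dir) {
  stopifnot(inherits(res, "msi_result"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  id <- res$sample_id
  p <- function(suffix) file.path(out_dir, paste0(id, suffix))

  dist_rows <- do.call(rbind, lapply(res$distributions, function(d) {
    if (!length(d$counts)) return(NULL)
    data.frame(sample = id, locus = d$locus,
               length_bp = as.integer(names(d$counts)),
               read_count = unname(d$counts), stringsAsFactors = FALSE)
  }))
  if (is.null(dist_rows))
    dist_rows <- data.frame(sample = character(), locus = character(),
                            length_bp = integer(), read_count = integer())
  utils::write.table(dist_rows, p("_distributions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  calls <- as.data.frame(res)
  overall_row <- data.frame(sample = id, locus = "OVERALL",
                            repeat_class = NA, tumour_mode = NA,
                            comparator_mode = NA, delta_bp = NA,
                            cutoff_bp = NA, status = res$overall,
                            comparator_source = NA, overall = res$overall,
                            stringsAsFactors = FALSE)
  utils::write.table(rbind(calls, overall_row), p("_calls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(sample = id, overall = res$overall,
         n_unstable = res$n_unstable, n_informative = res$n_informative,
         calls = res$calls),
    p("_calls.json"), auto_unbox = TRUE, digits = NA, na = "null")

  if (!is.null(res$accounting))
    utils::write.table(res$accounting, p("_run.log"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(c(distributions = p("_distributions.tsv"),
              calls = p("_calls.tsv"), json = p("_calls.json"),
              log = p("_run.log")))
}

#' Run the pipeline over a sample sheet
#'
#' The sheet is a TSV with columns `sample_id`, `tumour_r1`, `tumour_r2`
#' and optionally `normal_r1`, `normal_r2` (empty or `NA` entries switch
#' that row to tumour-only mode). Failures are recorded per row and do not
#' stop the batch.
#'
#' @param sample_sheet Path to the sheet, or an equivalent data.frame.
#' @param panel,out_dir,preprocess,classify,max_flank_mismatches Passed to
#'   [run_sample()].
#' @return A list with `results` (named list of `msi_result` or `NULL` for
#'   failed rows), `cohort` (data.frame: one row per sample with per-locus
#'   statuses and the overall status) and `errors` (named character vector
#'   of failure messages, empty when all rows succeed).
#' @export
run_batch <- function(sample_sheet, panel = default_panel(), out_dir = NULL,
                      preprocess = preprocess_config(),
                      classify = classify_config(),
                      max_flank_mismatches = 0L) {
  sheet <- if (is.data.frame(sample_sheet)) sample_sheet else
    utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  if (is.character(panel)) panel <- read_panel(panel)
  need <- c("sample_id", "tumour_r1", "tumour_r2")
  if (nrow(sheet) && !all(need %in% names(sheet)))
    stop("sample sheet lacks required column(s): ",
         paste(setdiff(need, names(sheet)), collapse = ", "))
  results <- list(); errors <- character(0); rows <- list()
  for (i in seq_len(nrow(sheet))) {
    id <- sheet$sample_id[i]
    blank <- function(x) is.null(x) || is.na(x) || !nzchar(x)
    nr1 <- if ("normal_r1" %in% names(sheet) && !blank(sheet$normal_r1[i]))
      sheet$normal_r1[i]
    nr2 <- if ("normal_r2" %in% names(sheet) && !blank(sheet$normal_r2[i]))
      sheet$normal_r2[i]
    res <- tryCatch(
      run_sample(sheet$tumour_r1[i], sheet$tumour_r2[i], nr1, nr2,
                 panel = panel, sample_id = id, out_dir = out_dir,
                 preprocess = preprocess, classify = classify,
                 max_flank_mismatches = max_flank_mismatches),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors[id] <- conditionMessage(res)
      results[id] <- list(NULL)
    } else {
      results[[id]] <- res
      row <- stats::setNames(as.list(res$calls$status), res$calls$locus)
      rows[[id]] <- data.frame(sample = id, row, overall = res$overall,
                               stringsAsFactors = FALSE)
    }
  }
  cohort <- if (length(rows)) {
    all_cols <- Reduce(union, lapply(rows, names))
    do.call(rbind, lapply(rows, function(r) {
      r[setdiff(all_cols, names(r))] <- NA
      r[all_cols]
    }))
  } else {
    data.frame(sample = character(), overall = character())
  }
  rownames(cohort) <- NULL
  if (!is.null(out_dir) && nrow(cohort))
    utils::write.table(cohort, file.path(out_dir, "cohort.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  list(results = results, cohort = cohort, errors = errors)
}
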