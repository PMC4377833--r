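REPEAT_CLASSES <- c("mononucleotide", "dinucleotide")

#' Reverse complement of a DNA sequence
#'
#' Standard reverse complement over the alphabet A, C, G, T, N. Vectorised.
#' Needed throughout the pipeline to match the reverse-primer flank on merged
#' reads and to orient mate 2 of a pair.
#'
#' @param seq Character vector of DNA sequences over \{A,C,G,T,N\}.
#' @return Character vector of the same length with each element
#'   reverse-complemented. An involution: applying it twice returns the input.
#' @examples
#' reverse_complement("AACC")  # "GGTT"
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("seq must be a character vector")
  bad <- grepl("[^ACGTN]", seq)
  if (any(bad)) {
    stop("non-nucleotide character in sequence: ",
         substr(seq[bad][1], 1, 40))
  }
  comp <- chartr("ACGTN", "TGCAN", seq)
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))),
         character(1), USE.NAMES = FALSE)
}

#' Define one MSI marker locus
#'
#' A locus is characterised by its two inner-PCR flanking primers, its repeat
#' unit class (which sets the instability cut-off: 2 bp for mononucleotide,
#' 4 bp for dinucleotide repeats) and the reference amplicon length in base
#' pairs, measured on the full amplicon including both primers. Genomic
#' position fields are carried as opaque provenance labels and never used in
#' computation: the method is alignment-free.
#'
#' @param name Locus identifier, e.g. "BAT26".
#' @param repeat_class `"mononucleotide"` or `"dinucleotide"`.
#' @param forward_primer,reverse_primer DNA strings over \{A,C,G,T\}.
#' @param amplicon_length Reference amplicon length in bp (primers included);
#'   must exceed the combined primer length.
#' @param chromosome,coordinates Optional free-text position labels.
#' @param modal_length Optional reference modal length in bp, used as the
#'   comparator in tumour-only mode (quasimonomorphic markers only). `NA`
#'   means the locus cannot be called without a matched normal.
#' @return An object of class `msi_locus`.
#' @export
locus_definition <- function(name, repeat_class, forward_primer,
                             reverse_primer, amplicon_length,
                             chromosome = NA_character_,
                             coordinates = NA_character_,
                             modal_length = NA_integer_) {
  repeat_class <- match.arg(repeat_class, REPEAT_CLASSES)
  if (!nzchar(name)) stop("locus name must be non-empty")
  for (p in c(forward_primer, reverse_primer)) {
    if (!nzchar(p) || grepl("[^ACGT]", p)) {
      stop("locus '", name, "': primers must be non-empty strings over ACGT")
    }
  }
  amplicon_length <- as.integer(amplicon_length)
  if (amplicon_length <= nchar(forward_primer) + nchar(reverse_primer)) {
    stop("locus '", name, "': amplicon_length (", amplicon_length,
         ") must exceed the combined primer length")
  }
  modal_length <- as.integer(modal_length)
  structure(list(
    name = name,
    chromosome = as.character(chromosome),
    coordinates = as.character(coordinates),
    repeat_class = repeat_class,
    forward_primer = forward_primer,
    reverse_primer = reverse_primer,
    amplicon_length = amplicon_length,
    modal_length = modal_length
  ), class = "msi_locus")
}

#' @export
print.msi_locus <- function(x, ...) {
  cat(sprintf("<msi_locus> %s (%s), amplicon %d bp\n", x$name,
              x$repeat_class, x$amplicon_length))
  cat(sprintf("  F: 5'-%s-3'   R: 5'-%s-3'\n",
              x$forward_primer, x$reverse_primer))
  invisible(x)
}

#' Assemble a marker panel
#'
#' @param loci A list of [locus_definition()] objects.
#' @param name Panel identifier.
#' @return An object of class `msi_panel`: a named, ordered list of loci.
#'   Locus names must be unique and no primer may be a substring of another
#'   locus's primer (the binning lookup would otherwise be ambiguous).
#' @export
msi_panel <- function(loci, name = "panel") {
  if (!is.list(loci) || !all(vapply(loci, inherits, logical(1), "msi_locus")))
    stop("loci must be a list of msi_locus objects")
  nms <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nms))
    stop("duplicate locus name in panel: ", nms[duplicated(nms)][1])
  primers <- unlist(lapply(loci, function(l)
    stats::setNames(c(l$forward_primer, l$reverse_primer),
                    c(l$name, l$name))))
  for (i in seq_along(primers)) {
    for (j in seq_along(primers)) {
      if (names(primers)[i] != names(primers)[j] &&
          grepl(primers[i], primers[j], fixed = TRUE)) {
        stop("panel configuration error: primer of locus '",
             names(primers)[i], "' is a substring of a primer of locus '",
             names(primers)[j], "'")
      }
    }
  }
  names(loci) <- nms
  structure(list(name = name, loci = loci), class = "msi_panel")
}

#' @export
print.msi_panel <- function(x, ...) {
  cat(sprintf("<msi_panel> '%s': %d loci\n", x$name, length(x$loci)))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.msi_panel <- function(x, ...) {
  data.frame(
    locus = vapply(x$loci, `[[`, character(1), "name"),
    repeat_class = vapply(x$loci, `[[`, character(1), "repeat_class"),
    amplicon_length = vapply(x$loci, `[[`, integer(1), "amplicon_length"),
    modal_length = vapply(x$loci, `[[`, integer(1), "modal_length"),
    row.names = NULL
  )
}

#' @export
length.msi_panel <- function(x) length(x$loci)

#' The default five-marker colorectal MSI panel
#'
#' BAT25, BAT26 and BAT34c4 are mononucleotide markers; D18S55 and D5S346 are
#' dinucleotide markers. Primer sequences and reference amplicon lengths are
#' the inner-cycle PCR design of the assay this package implements; genomic
#' positions are provenance labels only. Reference modal lengths are set equal
#' to the reference amplicon lengths, which is the convention used by the
#' bundled read simulator for its unshifted (germline) alleles; replace them
#' with laboratory-calibrated values before tumour-only use on real data.
#'
#' @return An `msi_panel` of five loci.
#' @export
default_panel <- function() {
  msi_panel(name = "colorectal5", loci = list(
    locus_definition("BAT25", "mononucleotide",
                     "TCGCCTCCAAGAATGTAAGT", "TCTGCATTTTAACTATGGCTC", 123,
                     chromosome = "4q12", coordinates = "55598151-55598274",
                     modal_length = 123),
    locus_definition("BAT26", "mononucleotide",
                     "TGACTACTTTTGACTTCAGCC", "AACCATTCAACATTTTTAACCC", 121,
                     chromosome = "2p", coordinates = "47641487-47641608",
                     modal_length = 121),
    locus_definition("BAT34c4", "mononucleotide",
                     "ACCCTGGAGGATTTCATCTC", "AACAAAGCGAGACCCAGTCT", 130,
                     chromosome = "17p13.1", coordinates = "7572124-7572254",
                     modal_length = 130),
    locus_definition("D18S55", "dinucleotide",
                     "GGGAAGTCAAATGCAAATC", "AGCTTCTGAGTAATCTTATGCTGTG", 147,
                     chromosome = "18q22.1", coordinates = "61873501-61873648",
                     modal_length = 147),
    locus_definition("D5S346", "dinucleotide",
                     "ACTCACTCTAGTGATAAATCGGG", "AGCAGATAAGACAGTATTACTAGTT",
                     124,
                     chromosome = "5q22.2", coordinates = "112213624-112213748",
                     modal_length = 124)
  ))
}

#' Read a panel definition file
#'
#' Panels are stored as human-editable YAML: a top-level `name` plus a `loci`
#' map keyed by locus name, each with `repeat_class`, `forward_primer`,
#' `reverse_primer`, `amplicon_length` and optionally `chromosome`,
#' `coordinates` and `modal_length`. See the packaged
#' `extdata/colorectal5_panel.yaml` for the default panel.
#'
#' @param path Path to a panel YAML file.
#' @return An `msi_panel`.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) stop("panel file not found: ", path)
  doc <- tryCatch(yaml::read_yaml(path), error = function(e)
    stop("cannot parse panel file '", path, "': ", conditionMessage(e)))
  if (is.null(doc$loci) || !length(doc$loci))
    stop("panel file '", path, "' defines no loci")
  if (anyDuplicated(names(doc$loci)))
    stop("panel file '", path, "': duplicate locus name '",
         names(doc$loci)[duplicated(names(doc$loci))][1], "'")
  loci <- lapply(names(doc$loci), function(nm) {
    rec <- doc$loci[[nm]]
    for (f in c("repeat_class", "forward_primer", "reverse_primer",
                "amplicon_length")) {
      if (is.null(rec[[f]]))
        stop("panel file '", path, "': locus '", nm,
             "' is missing required field '", f, "'")
    }
    locus_definition(
      name = nm,
      repeat_class = rec$repeat_class,
      forward_primer = rec$forward_primer,
      reverse_primer = rec$reverse_primer,
      amplicon_length = rec$amplicon_length,
      chromosome = rec$chromosome %||% NA_character_,
      coordinates = rec$coordinates %||% NA_character_,
      modal_length = rec$modal_length %||% NA_integer_
    )
  })
  msi_panel(loci, name = doc$name %||% "panel")
}

#' Write a panel definition file
#'
#' @param panel An `msi_panel`.
#' @param path Output YAML path.
#' @return `path`, invisibly. `read_panel(write_panel(p, f))` reproduces `p`
#'   field for field.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "msi_panel"))
  loci <- lapply(panel$loci, function(l) {
    rec <- list(
      chromosome = l$chromosome,
      coordinates = l$coordinates,
      repeat_class = l$repeat_class,
      forward_primer = l$forward_primer,
      reverse_primer = l$reverse_primer,
      amplicon_length = l$amplicon_length
    )
    if (!is.na(l$modal_length)) rec$modal_length <- l$modal_length
    rec[!vapply(rec, function(v) is.na(v) || is.null(v), logical(1))]
  })
  yaml::write_yaml(list(name = panel$name, loci = loci), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
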