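# shared fixtures, all built in code

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")

# small two-locus panel (one mono, one di) with short primers for fast tests
tiny_panel <- function() {
  msi_panel(name = "tiny", loci = list(
    locus_definition("MONO1", "mononucleotide",
                     "ACGTACGTCC", "GGATCCTTGA", 60, modal_length = 60),
    locus_definition("DI1", "dinucleotide",
                     "TTGGCCAAGG", "CCTTAAGGCA", 70, modal_length = 70)
  ))
}

# the two mononucleotide quasimonomorphic markers of the default panel
mono_panel <- function() {
  p <- default_panel()
  msi_panel(p$loci[c("BAT25", "BAT26")], name = "mono2")
}

dist_of <- function(counts, locus = "L") as_length_distribution(counts, locus)

# fragment an amplicon into a 2 x read_length mate pair the way the
# simulator does (independent reimplementation for round-trip oracles)
fragment_pair <- function(amplicon, read_length = 150,
                          adapter = strrep("GTCAGTCAGG", 30)) {
  list(seq1 = substr(paste0(amplicon, adapter), 1, read_length),
       seq2 = substr(paste0(reverse_complement(amplicon), adapter),
                     1, read_length))
}
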