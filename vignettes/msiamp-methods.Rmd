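---
title: "msiamp: methods, parameter choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{msiamp: methods, parameter choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msiamp)
```

## The model

`msiamp` calls microsatellite instability (MSI) from amplicon deep
sequencing without any genome alignment. The unit of observation is the
*amplicon read*: a merged read pair spanning one marker locus from its
forward PCR primer to its reverse primer. Because a two-stage PCR design
guarantees that every genuine amplicon is primer-terminal, a read can be
attributed to its locus purely by matching the two flanking primer
sequences at its ends, and the microsatellite length change is visible
directly as a change in total amplicon length.

For each locus the package builds the read-count histogram over amplicon
length and summarises it by its **modal length** — the length carried by
the most reads. The modal length is a robust statistic here for two
reasons: PCR stutter products are (by construction of the slippage process)
less abundant than the template allele, and depth per locus in this assay
is high (thousands of reads), so the mode estimates the dominant allele
length with essentially no sampling noise.

A locus is **unstable** when the tumour's modal length deviates from the
comparator's by at least 2 bp (mononucleotide repeats) or 4 bp
(dinucleotide repeats). The asymmetry reflects the repeat unit: one slipped
dinucleotide unit moves the length 2 bp, so a 2 bp dinucleotide deviation
is only one unit — within the stutter/noise band — while 4 bp is two units.
Both cut-offs are inclusive and configurable (`classify_config`); lenient
cut-offs (1 bp / 2 bp) demonstrably misclassify stable tumours as unstable
because single-unit deviations arise from stutter alone.

Locus calls combine into the standard three-level status: MSI-H when at
least 2 informative loci are unstable (equivalently ≥ 40% of a five-locus
panel), MSI-L when exactly one is, MSS when none is. The absolute count
(not the fraction) is used because it is also the operative rule for the
two-locus tumour-only panel. A sample with no informative locus is
*indeterminate* — an explicit outcome rather than a silent MSS.

### Assumptions

* Reads are amplicon reads: primer-terminal, shorter than the combined
  mate length (so pairs overlap and merge).
* The dominant allele is the modal length. Heterozygous dinucleotide loci
  with two normal alleles are still summarised by the single global mode;
  this is deliberately the assay's own rule, and a two-allele
  deconvolution is out of scope.
* Tumour cellularity is high enough that the tumour allele dominates the
  tumour library. The modal statistic cannot see a subclonal shift that
  stays below the germline allele's read count.

## Comparator modes

With a **matched normal**, each locus's comparator is the normal sample's
own modal length — this cancels locus-specific artefacts and any ambiguity
about what "length" means, since both sides use the same coordinate.

**Tumour-only** mode is restricted to quasimonomorphic markers (BAT25,
BAT26), whose normal length is nearly invariant across individuals. Here
the comparator must be an explicit `modal_length` in the panel definition;
the pipeline refuses loci that do not declare one rather than guessing a
reference. The shipped default panel sets each reference modal length equal
to the reference amplicon length, which is the convention used by the
bundled simulator's unshifted alleles; for real data these entries should
be replaced with laboratory-calibrated values.

### The length coordinate

All lengths in `msiamp` are **full merged amplicon lengths, primers
included**. Published histograms for such assays sometimes use a trimmed
coordinate, so absolute modal lengths from different conventions are not
comparable; the instability statistic is a *difference* of modal lengths
and is invariant to the choice, which is why the convention is safe to fix
package-wide.

## Pipeline parameters

| Parameter | Default | Units | Why |
| --- | --- | --- | --- |
| `quality_threshold` | 30 | mean Phred | Q30 ≈ error < 1/1000 bp; reads at the threshold are kept |
| `min_overlap` | 15 | bp | short enough for 121–147 bp amplicons at 2×150, long enough that random 15-mer overlaps are vanishing |
| `max_mismatch_fraction` | 0.1 | fraction | tolerates sequencing error in the overlap without accepting spurious alignments |
| `max_flank_mismatches` | 0 | substitutions | exact primer match; raising to 1–2 recovers reads with primer-region errors |
| `mono_cutoff_bp` / `di_cutoff_bp` | 2 / 4 | bp | inclusive modal-deviation cut-offs (see above) |
| `min_reads_per_locus` | 100 | reads | below this the mode is not trusted; the locus becomes NO_CALL and leaves the denominator |
| `msi_high_min_unstable` | 2 | loci | the MSI-H rule as an absolute count |

`min_reads_per_locus` deserves a note: production runs of this assay reach
5,000–8,000× per locus, so the threshold is far below normal operating
depth. It exists to give degraded or down-sampled libraries an explicit
insufficient-data outcome instead of a confident call from a handful of
reads.

## Numerical and tie-break choices

* **Merging** scans every relative offset of mate 1 against the
  reverse-complemented mate 2 and keeps the offset with the most matching
  bases, subject to the overlap and mismatch bounds; ties go to the longer
  overlap, then the smaller offset. The scan orders candidates by overlap
  length and stops as soon as no remaining overlap can beat the best match
  count, which is exact (matches ≤ overlap length) and fast in the typical
  near-perfect case. Within the overlap the higher-Phred base wins and the
  merged quality is the per-base maximum. Because mate 1 starts at the
  fragment's 5' end and mate 2 at its 3' end, the merged read is clipped to
  that span, which silently removes adapter read-through — the common case
  for 121–147 bp amplicons sequenced at 2×150.
* **Modal-length ties** (two lengths with exactly equal read counts) break
  toward the length closest to the comparator mode, i.e. conservatively
  toward a *stable* call; with no comparator, toward the shorter length.
  Ties are essentially impossible at production depth but must be
  deterministic.
* **Ambiguous reads** matching more than one locus are discarded as
  unassigned rather than arbitrated (safety over yield); they are counted
  in the read accounting. Indels are not tolerated inside a flank because a
  flank indel would corrupt the very length coordinate being measured.
* **Degenerate inputs**: empty distributions raise an error from
  `modal_length` but surface as NO_CALL through `call_locus`; an empty
  panel, missing files and truncated FASTQ records are hard errors;
  merge failure is a value, not an exception.
* **Confidence intervals** are exact Clopper-Pearson from beta quantiles
  (`qbeta`), the only standard interval family consistent with every
  published bound this assay reports (e.g. a lower bound of
  100·0.025^(1/n) for *k* = *n*); Wilson and Wald intervals do not
  reproduce them. Displayed percentages are rounded half-up to one
  decimal; raw values are kept internally.

## The simulator

`simulate_sample` emulates one MiSeq-style amplicon library per role
(tumour/normal): for each locus, `depth_per_locus` molecules of a synthetic
allele — forward primer, deterministic filler, repeat tract, filler,
reverse-complemented reverse primer, sized to the reference amplicon length
— pass through a stutter step (with probability `stutter_prob` the repeat
count slips by a geometric number of units, contracting 4:1 more often than
expanding) and an i.i.d. substitution-error step, then are emitted as a
2×150 bp mate pair with truncated-normal per-base qualities whose mean
declines linearly after cycle 100, plus a 1% admixture of random
off-target pairs. Defaults (depth 5000, stutter 0.02, error 0.002 per
base) reflect the assay's reported depth and the generic behaviour of
polymerase slippage at short tandem repeats; no published stutter rates
exist for these exact amplicons, so the stutter parameters are an informed
choice made once, not a fitted quantity. Default repeat tracts are (T)₂₅,
(A)₂₆, (A)₂₄, (CA)₁₃, (CA)₁₃ for BAT25, BAT26, BAT34c4, D18S55 and D5S346.

What the simulator deliberately does **not** model: FFPE artefacts
(deamination), sample-index chemistry, realistic flanking sequence
(fillers are a fixed 12-mer repeat), platform-specific error spectra, and
allele mixtures from tumour heterogeneity. Tests passing on simulated data
therefore demonstrate the pipeline's correctness — binning fidelity, exact
length recovery, cut-off behaviour, determinism — not its robustness to
every artefact of archival clinical material.

Determinism: a fixed `seed` gives byte-identical FASTQ; the tumour role
draws from stream `seed + 1` so paired samples are independent.

## Problem sizes used in the checks

The automated checks run the full pipeline at reduced scale chosen to keep
the statistics decisive: end-to-end classification tests use depths of
120–400 reads per locus (still > `min_reads_per_locus`), and the
shift-recovery sweep (shifts of 0, ±1, ±2, ±3 repeat units at the two
mononucleotide markers, full noise model) uses depth 2,000. At these depths
the modal length is a deterministic function of the configured allele for
all practical purposes, so the boundary behaviour — |shift| ≥ 2 bp called
unstable, smaller shifts stable — is tested exactly, not statistically.
The cohort-level statistics are computed from the two packaged call
matrices (44 and 6 cases) and are exact arithmetic, independent of scale.

## Known limitations

* Single-mode comparison: allelic dropout or a second allele just below
  the modal count is invisible; markers like BAT26 can be stable despite
  mismatch-repair loss (e.g. large *MSH2* deletions), which is why panels
  include several loci.
* Tumour-only mode inherits the quality of the panel's reference modal
  lengths; it is only as quasimonomorphic as the marker.
* Exact flank matching (default) loses reads with primer-region
  sequencing errors (~8% at an error rate of 0.002/bp over two ~20 bp
  primers); this costs depth, not accuracy, and `max_flank_mismatches`
  recovers it when depth is scarce.
* The package processes demultiplexed per-sample FASTQ; sample-index
  demultiplexing is the sequencer's job.
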