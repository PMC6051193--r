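---
title: "Read-through marking: model, design choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-through marking: model, design choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtmark)
```

## The measurement and its model

In truncation-based CLIP methods the reference coordinate of a read's first
aligned nucleotide — the *cDNA start* — is the signal: reverse transcription
usually stops at the peptide left on the RNA after UV crosslinking and
proteolysis, so truncated cDNAs start at the crosslink site. cDNAs that read
through the crosslink instead start at the RNase I cleavage point, upstream
of the true binding site. Read-through marking makes the two populations
separable: an RNA oligo (5'-marker, DNA form `CAGTCCGACGATC`) ligated to the
fragment's 5' end is sequenced only in read-through cDNAs, because it is not
complementary to any PCR primer. The marker-ligation reaction is not 100%
efficient, so the `REMAINING` group is a mixture: all truncated cDNAs plus
the unmarked fraction of read-through cDNAs.

`rtmark` processes such libraries as

1. barcode/UMI extraction and demultiplexing (`extract_barcode()`,
   `demultiplex()`),
2. marker classification and stripping (`classify_marker()`): a read is
   `READ_THROUGH` iff its first `nchar(marker)` bases are within
   `max_mismatches` of the marker *and* the read extends beyond the marker,
3. 3'-adapter trimming (`trim_adapter()`),
4. alignment (external SAM/BAM, or the built-in exact-unique mapper for
   synthetic references) and strand-aware start assignment
   (`assign_cdna_starts()`),
5. UMI collapse (`collapse_umis()`) and the marker fraction
   (`marker_fraction()`),
6. per-group nucleotide composition around starts (`compute_composition()`,
   `compare_groups()`).

Both groups traverse the identical path; classification only labels reads.

## The generative simulator

`simulate_library()` draws, per molecule: a crosslink position with weight
`w_U` at T positions (the DNA proxy of uridine's UV-crosslinking preference)
and 1 elsewhere; a cleavage site uniformly positioned `frag_len_min` to
`frag_len_max` nt upstream, reweighted by `w_A` where the retained 5' base is
A (the RNase I preference); a 3' fragment extent of `downstream_min` to
`downstream_max` nt; truncation with probability `p_trunc` (else
read-through); marker ligation with probability `epsilon`, possible only for
read-through molecules — the model makes `marker_present ⇒ read-through` a
hard invariant; a read `barcode + [marker] + insert + adapter` truncated to
`read_length`; and `Geometric(pcr_geom_p)` identical PCR copies (support
≥ 1), each optionally mutated at `seq_error_rate`. A per-molecule truth table
(crosslink, cleavage, start, class, marker, UMI, copies) accompanies the
reads.

Default parameters are the conditions the package is exercised under, chosen
once:

| parameter | default | rationale |
|---|---|---|
| `p_trunc` | 0.9 | truncated cDNAs are the large majority (roughly 80–95%) of iCLIP libraries; 0.9 is the midpoint |
| `epsilon` | 0.5 | the ligation efficiency is not known quantitatively; 0.5 keeps both marked and unmarked read-through cDNAs abundant |
| `w_U`, `w_A` | 8 | only the *direction* of the crosslink/cleavage preferences is established; 8 makes the qualitative A-vs-T contrast robust at a few thousand sites without saturating the logo |
| `frag_len_min/max` | 20–40 nt | RNase I fragment 5' extents of a few tens of nt, typical of limited digestion |
| `downstream_min/max` | 19–35 nt | keeps every insert ≥ 20 nt, long enough to map uniquely on the default references |
| `n_refs × ref_length` | 2 × 50 kb | large enough that k-mers of insert length are effectively unique, small enough for desk-scale runs |
| `read_length` | 100 nt | a common single-end length; long enough to reach through barcode + marker into the insert |
| `pcr_geom_p` | 0.5 | mean two reads per molecule — enough duplication to make collapse meaningful |
| barcode | `NNNXXXXNN` | the classic 5-nt UMI split around a 4-nt experimental barcode |

The simulator deliberately does **not** model: immunoprecipitation enrichment
or binding-motif structure (crosslinks depend on base identity only, not on a
protein's sequence preference), RNA secondary structure, indels or
crosslink-induced mutations/deletions, quality-score variation, or lossy
3'-adapter ligation / RT priming (only the 5'-marker ligation is lossy).
Passing recovery tests on simulated data therefore demonstrates the
*bookkeeping* is exact — classification, coordinates, collapse keys,
composition counting — not that the pipeline is robust to real-data noise
such as sequencing errors at the marker boundary or mismapping; for real
libraries the mismatch tolerances and an external aligner exist precisely
because those effects occur.

## Conventions and numerical choices

- **Coordinates** are 0-based half-open internally and in BED output; SAM
  input is converted. The cDNA start of a minus-strand alignment is
  `end − 1`.
- **Offsets** around starts are labelled `−w … −1, +1 … +w` with no offset 0;
  `+1` is the cDNA's first nucleotide, following the "position 1" convention
  of start-site logos. The default window `w = 10` per side is wide enough to
  show that the signal concentrates at `+1` yet keeps matrices small; it is a
  display choice, not a statistical one, and is configurable.
- **Truncated cDNA starts** sit on the crosslinked nucleotide itself
  (`truncation_offset = 0`), which places the crosslink at logo position
  `+1`; `truncation_offset = 1` supports the crosslink-at-`−1` convention
  used elsewhere in the iCLIP literature.
- **Marker matching** defaults to exact (`max_mismatches = 0`), since no
  mismatch tolerance is established for the protocol; it is configurable. Ns
  count as mismatches everywhere (barcode, marker, adapter). A read equal to
  the marker alone is classified `REMAINING` and then dropped by the
  insert-length filter (default 15 nt) — it is never emitted as an empty
  read-through insert.
- **Barcode→sample assignment** requires a unique nearest barcode within
  `max_barcode_mismatches`; schemes whose barcodes are within that distance
  of each other are rejected at construction, and residual equidistant cases
  (possible when keys sit at distance `mm + 1`) return `UNASSIGNED` rather
  than guessing. `UNASSIGNED` reads are emitted but excluded from group
  statistics and the pipeline's downstream stages by default.
- **Marker/adapter order**: the marker is a 5' prefix and the adapter a 3'
  suffix, so classification and trimming commute on reads whose insert
  survives the length filter; the pipeline runs barcode → marker → adapter
  and the test suite checks the commutation.
- **Adapter trimming** takes the leftmost position whose overlap (≥
  `min_overlap`, default 3) matches the adapter prefix within
  `max_error_rate` (default 0). With a fixed read length the sequencer can
  stop 1–2 nt into the adapter, below `min_overlap`; those remnants stay on
  the insert and make *exact* matching fail for that small slice of reads.
  Where exact end-to-end recovery is the property under test, preparation
  runs with `min_overlap = 1`, which can only shorten inserts at the 3' end
  and never moves the cDNA start. Real-data workflows should keep the
  standard overlap; a mismatch-tolerant aligner absorbs remnants via
  soft-clipping.
- **The built-in mapper** accepts exact, unique occurrences only (both
  strands in `genome` mode, sense only in `transcriptome` mode, mirroring
  longest-mRNA transcriptome mapping); zero hits are unmapped,
  more than one multimapped and discarded but counted. It exists to make
  synthetic end-to-end runs hermetic; real data should be aligned externally
  (e.g. Bowtie2 with mismatches) and ingested via `read_sam_alignments()`,
  which keeps primary mapped records above a MAPQ threshold. Occurrences are
  `(reference, strand, position)` triples, so a palindromic insert matching
  one locus on both strands counts as two.
- **UMI collapse** groups on `(sample, ref_name, strand, pos, umi)` — strand
  and sample are included to avoid collapsing sense/antisense coincidences or
  merging experiments; UMIs are compared exactly (no directional/adjacency
  clustering). The collapsed record's flag is the majority, ties resolved to
  `REMAINING` (conservative: a flag conflict within a key can only be a
  coincidence, since the marker is stripped before mapping and the two
  classes start at different positions). The marker fraction is reported both
  over unique cDNAs and over raw mapped reads, since either denominator is
  defensible; with no cDNAs it is `NA`.
- **Composition** counts each unique cDNA once regardless of PCR support
  (read-weighted mode is a flag); window positions outside the reference
  contribute `N` and are excluded from that offset's column, so defined
  frequency columns sum to 1 and column totals may be below `n_sites`.
  Information content is `2 + Σ p log2 p` bits, clamped at 0 against
  floating-point underflow, with the Weblogo small-sample correction
  available but off by default. The group contrast reports frequency
  differences and a log2 ratio with pseudocount 1 on counts (4 on column
  totals); a per-offset chi-square helper exists but is not part of the
  default output, because the analysis is descriptive.

## Problem sizes

The test suite exercises unit properties at hundreds-to-thousands of
molecules and the end-to-end recovery checks at 20,000–60,000 molecules with
10–20 seeds each; `scripts/acceptance.R` uses 50,000 molecules for the
marker-fraction and exactness quantities and 20,000 for collision-free
deduplication, sizes at which the binomial standard error of the marker
fraction is about 0.1 percentage points and a single run completes in
seconds on one CPU.

## Known limitations

- The exact mapper does not tolerate mismatches or gaps, by design; it is not
  a substitute for genome-scale alignment and does not scale beyond
  desk-sized references.
- Variable-length or quality-aware trimming, paired-end reads, and UMI error
  correction are out of scope.
- The marker fraction of a real library depends on the (unknown) ligation
  efficiency, so it bounds, but does not equal, the read-through rate;
  interpretation should lean on the composition contrast, which is what the
  marked subset calibrates.
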