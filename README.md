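# rtmark

Read-through marking analysis for iCLIP libraries.

## The problem

iCLIP and its relatives (eCLIP, irCLIP, miCLIP, ...) map protein–RNA contacts
by UV-crosslinking proteins to RNA, fragmenting the RNA with RNase I,
immunoprecipitating the protein, and sequencing cDNAs. The peptide left at the
crosslink site usually stops reverse transcription, so the **start of a
truncated cDNA marks the crosslink site** at nucleotide resolution. But some
cDNAs read through the crosslink and extend to the RNase cleavage point;
unrecognised, they shift inferred binding sites upstream.

The read-through-marking protocol resolves the two populations
experimentally: an RNA oligonucleotide (the *5'-marker*, DNA form
`CAGTCCGACGATC`) is ligated to the 5' end of RNA fragments. It is not a PCR
primer site, so it is simply sequenced: a read beginning with the marker must
come from a read-through cDNA. `rtmark` implements the computational side of
this design for people analysing such libraries (and for anyone who wants to
study truncation vs read-through behaviour in silico):

- **readprep** — barcode/UMI extraction, sample demultiplexing, 5'-marker
  classification (`READ_THROUGH` vs `REMAINING`) and stripping, 3'-adapter
  trimming, length filtering, with exactly conserved counts;
- **alignment** — ingestion of externally aligned SAM/BAM (e.g. Bowtie2), or
  a strict built-in exact-unique mapper for synthetic references; strand-aware
  cDNA-start assignment (first aligned base); BED6 I/O;
- **dedup** — PCR-duplicate collapse on `(sample, reference, strand, start,
  UMI)`, reporting unique-cDNA counts and the marker fraction;
- **composition** — per-offset nucleotide count/frequency/information-content
  matrices around cDNA starts (Weblogo input), per marker group, with a
  group-contrast table; offset `+1` is the cDNA's first nucleotide and there
  is no offset 0;
- **simulator** — a generative model of the whole library: uridine-biased
  crosslinking (weight `w_U` at T), adenosine-biased RNase I cleavage
  (weight `w_A` at the retained 5' base), truncation with probability
  `p_trunc`, marker ligation with efficiency `epsilon`, barcode/UMI
  construction, geometric PCR duplication — with a per-molecule ground-truth
  table, so every pipeline stage is testable without downloads.

Key quantities, in the field's notation: the expected marker-read fraction is
`(1 − p_trunc) · ε`; per-offset information content is
`IC = 2 + Σ_b p_b log2 p_b` bits over `b ∈ {A, C, G, T}`.

## Worked example

Simulate a library under the default conditions (50 kb references,
`p_trunc = 0.9`, `epsilon = 0.5`, `w_U = w_A = 8`, geometric PCR copies) and
run the whole pipeline:

```r
library(rtmark)

report <- run_pipeline(list(seed = 20,
                            simulate = list(seed = 20, n_molecules = 20000)))
glance(report)
#> # A tibble: 1 × 8
#>   n_input n_prepared n_mapped n_unique_cdnas marker_fraction_unique
#>     <int>      <int>    <int>          <int>                  <dbl>
#> 1   40187      40187    40181          19996                 0.0494
#>   marker_fraction_raw argmax_rt_start argmax_rem_start
#>                 <dbl> <chr>           <chr>
#> 1              0.0500 A               T
```

40,187 reads (20,000 molecules times their PCR copies) collapse back to
19,996 unique cDNAs; 4.94% of unique cDNAs carry the 5'-marker, matching the
configured `(1 − 0.9) × 0.5 = 5%`. The position `+1` argmax bases reproduce
the signature contrast: read-through cDNA starts are A-enriched (the RNase I
preference at the retained 5' nucleotide), remaining starts are T-enriched
(the uridine preference of UV crosslinking).

```r
marker_fraction(report$dedup)
#> # A tibble: 1 × 7
#>   sample  n_unique n_rt_unique frac_unique n_raw n_rt_raw frac_raw
#>   <chr>      <int>       <int>       <dbl> <int>    <int>    <dbl>
#> 1 sample1    19996         988      0.0494 40181     2009   0.0500

report$contrast$by_offset[9:12, ]
#> # A tibble: 4 × 5
#>   offset argmax_rt argmax_rem info_bits_rt info_bits_rem
#>    <int> <chr>     <chr>             <dbl>         <dbl>
#> 1     -2 G         A               0.00349     0.000166
#> 2     -1 C         T               0.00250     0.0000849
#> 3      1 A         T               0.609       0.627
#> 4      2 T         T               0.00292     0.000334
```

Essentially all information content concentrates at position `+1`, as in
sequence logos of real iCLIP cDNA starts. `autoplot(report$composition$read_through)`
draws the logo-style bar chart; `tidy()` on any result returns the underlying
tibble.

Real libraries enter through `read_fastq()` + `prepare_reads()` +
`write_prepared_fastq()` (annotated read names), external alignment, then
`read_sam_alignments()` → `assign_cdna_starts()` → `collapse_umis()` →
`compute_composition()`. A thin command-line wrapper with the same stages
lives at `inst/cli/rtmark.R` (`simulate`, `prep`, `map`, `import-sam`,
`dedup`, `comp`, `run`).

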