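# ampevo

Molecular-evolution analysis of amphibian antimicrobial peptide (AMP)
precursor families.

Frog skin AMPs are translated as precursors: a hydrophobic signal peptide,
an acidic propiece, and the cationic mature peptide, separated by a dibasic
convertase site (KR/ER/RR). Two couplings between the propiece and the
mature peptide are of evolutionary interest: a negative correlation of
their *net charges* (the propiece neutralizing the mature peptide's
cationicity — the Net Charge Balance hypothesis) and a negative correlation
of their *lengths* (processing motifs being lost and re-appearing at other
positions — the Cut Point Sliding hypothesis). `ampevo` is a tested
pipeline for cloned precursor cDNA sets that computes everything such a
study needs:

* **Segmentation** — reading-frame selection for primer-truncated clones,
  then cut-point placement at the rightmost qualifying KR/RR/ER motif
  (annotation wins when present, provenance recorded).
* **Descriptors** — MW, theoretical pI (Bjellqvist pKa, bisection), integer
  net charge, GRAVY, Guruprasad instability index, per segment.
* **Diversity** — per-family nucleotide diversity
  π = 2/(n(n−1)) Σ_{i<j} d_ij/L with Nei's (1987) sampling SD.
* **Selection** — Nei–Gojobori dN/dS with pathway averaging and
  Jukes–Cantor correction, per region (propiece / mature), with
  neutral-line classification; pooled ts/tv ratios with the standard
  "-" (no transversions) and "/" (singleton family) table conventions.
* **Trees** — K2P distances, neighbor joining, Felsenstein and transfer
  bootstrap (TBE) supports, family monophyly tests.
* **Correlations** — Pearson r with two-sided p for length–length and
  charge–charge, per species and pooled.
* **Simulator** — a seeded generator of precursor families with known
  frames, cut points, ω, κ, and inter-segment couplings, so the whole
  pipeline is testable without downloading data.

## Worked example

The `analysis/` scripts run the whole workflow on the simulated gold
dataset (three pseudo-species blocks of 14 + 7 + 13 families):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_segment_describe.R
Rscript analysis/03_diversity_selection.R
Rscript analysis/04_phylogeny.R
Rscript analysis/05_correlations.R
```

which prints, among other things:

```
201 of 201 records segmented
cut-point recovery: 100.0%
mature peptides: MW 1957.4-5220.4 Da, pI 8.82-12.60, net charge +2..+7
propieces: net charge -6..+1 (acidic, as designed)

nucleotide diversity over 34 families: mean 0.023, range 0.007-0.036
mature-region classification against the neutral line:
above below    on
    2    30     2

monophyletic families: 12 of 12

length-length  pooled   n = 201  r = -0.753  p = 0.000
charge-charge  pooled   n = 201  r = -0.787  p = 0.000
```

Reading this: every simulated cDNA was segmented at its true cut point;
mature peptides are short, alkaline and cationic while propieces are
acidic; within-family diversity sits in the 0.007–0.036 band; most
families are classified below the neutral line (the simulator's ω = 0.3);
each family forms its own clade in the joint NJ tree; and the propiece
and mature peptide show the designed negative length and charge couplings
(generator targets ρ = −0.8).

The same machinery is available programmatically:

```r
library(ampevo)
records <- read_fasta("results/gold/gold.fasta")
res <- run_pipeline(records, "results/reports")
res$correlations
```

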