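---
title: "Methods: segmentation, descriptors and molecular-evolution statistics for AMP precursor families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: AMP precursor pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The biological object

Frog skin secretes antimicrobial peptides (AMPs) that are translated as
precursors with a conserved three-part architecture: a hydrophobic signal
peptide, an acidic propiece, and the cationic mature peptide. The propiece
ends at a dibasic convertase processing site — most often KR, sometimes ER
or RR — and the mature peptide begins immediately after it. Cloned cDNAs
obtained with degenerate primers anchored inside the signal peptide are
*primer-truncated*: they carry only part of the signal, and no start codon
is guaranteed.

`ampevo` takes sets of such cDNAs, grouped into families of near-identical
sequences, and computes the analyses this kind of study runs: segmentation,
per-segment physicochemical descriptors, within-family nucleotide
diversity, region-wise transition/transversion and dN/dS selection
summaries, distance-based trees with bootstrap supports, and the two
segment-coupling correlation tests (length–length, the "cut point sliding"
reading; charge–charge, the "net charge balance" reading).

## Segmentation

`pick_frame()` chooses the reading frame with the longest stop-free prefix
(ties go to the smallest frame index — a deterministic, documented
tie-break, not a biological claim) and errors when every frame stops within
10 codons. `segment_precursor()` then places the cut point:

* If `sig_peptide`/`mat_peptide` annotations are present they win, and the
  record carries `provenance = "annotation"`.
* Otherwise the scan finds the **rightmost** occurrence of a motif in
  {KR, RR, ER} whose implied mature length lies in
  `[min_mature, max_mature]` (defaults 8 and 63, bracketing the canonical
  10–60 residue AMP range with a small margin). Acidic propieces commonly
  contain internal dibasic pairs; the processing site is the one adjacent
  to the mature peptide, which is why the rightmost qualifying motif is
  used. Motif residues belong to the propiece, so the mature peptide starts
  at the residue after the motif — an unambiguous convention matching
  convertase semantics.
* For primer-truncated clones there is no reliable signal boundary, so
  `default_signal_end = 0`: the pre-cut region is treated as "propiece
  including residual signal", and every downstream statistic that says
  "propiece" uses that definition. When homologous annotation is
  available, it overrides this default. Where homologs disagree, we do not
  guess: provenance is recorded and an override (feature) table can be
  supplied.

Records with no qualifying motif are excluded *and logged* — never
silently dropped; strict mode turns exclusion into an error.

Coordinates are 1-based inclusive everywhere inside the package (R's
native indexing); GenBank feature locations already use that convention,
so there is exactly one convention and no boundary conversion to get
wrong.

## Descriptors

All descriptor conventions follow the ExPASy ProtParam family of tools, so
values are comparable with the numbers routinely reported for AMPs:

* **Molecular weight**: average residue masses plus one water (18.01524 Da).
* **Charge and pI**: Henderson–Hasselbalch sums over D, E, C, Y, H, K, R
  side chains and the termini with the Bjellqvist pKa set (terminal pKa
  values depend on the terminal residue where Bjellqvist specifies so).
  The modeled charge is strictly decreasing in pH, so the pI is its unique
  zero; it is found by bisection on [0, 14] down to an interval of 0.002,
  comfortably below the 2-decimal reporting precision, and is checked in
  the tests against a 0.001-step grid search on an independently coded
  charge function.
* **Integer net charge**: `count(K) + count(R) − count(D) − count(E)`,
  histidine and termini excluded. Published AMP tables rarely state their
  net-charge convention; the side-chain count is the most common one, and
  the modeled charge at pH 7 is available behind
  `charge_convention = "ph7"` so the correlation analysis can be run under
  either.
* **GRAVY**: mean Kyte–Doolittle hydropathy (bounded by the table extremes
  ±4.5; negative = hydrophilic).
* **Instability index**: the Guruprasad dipeptide-weight statistic,
  `II = (10/L) Σ DIWV(aa_i, aa_i+1)`, with the conventional stability call
  `II < 40`. We apply the threshold strictly, even though published family
  tables sometimes label values slightly above 40 "stable"; the `stable`
  column is always derivable from the reported II, so no information is
  lost.

Families contain several mature-peptide variants, and published per-family
descriptor tables do not say which variant they summarize. The descriptor
report therefore emits one row per peptide per segment; per-family means
and ranges can be computed from it without committing to a choice.

## Diversity, ts/tv and selection

**Nucleotide diversity.** π is the mean pairwise difference per site,
`π = 2/(n(n−1)) Σ_{i<j} d_ij/L`, computed after *complete deletion* of
columns containing gaps or N within the region mask (the common default of
the standard diversity tools; pairwise deletion is available behind a
flag, since the choice is a convention, not a result). The reported SD is
the square root of Nei's (1987) sampling variance,
`V = (n+1)π / (3(n−1)L) + 2(n²+n+3)π² / (9n(n−1))`, with no recombination
correction. π is computed on the whole retained cDNA after trimming by
default, with the region masks available to restrict it. Families with a
single sequence are an error at the function level and a "/" at the report
level.

**ts/tv.** Transition and transversion difference counts are pooled over
all sequence pairs within the region (pairwise deletion per pair);
the ratio is Σts/Σtv and is *undefined* — serialized "-" — when no
transversion was observed. This is a counting estimator, not a
maximum-likelihood κ: ML codon-model estimation is deliberately out of
scope, so these ratios are comparable in structure but not numerically
identical to codeml output. The same caveat applies to dN/dS below.

**NG86 dN/dS.** Synonymous site fractions per codon are computed from all
single-nucleotide neighbors; neighbors that would create a stop codon are
excluded and the position's single site is apportioned over the remaining
neighbors, so S + N = 3 per codon exactly. Codons differing at 2–3
positions are averaged over all orderings of the changes, excluding
pathways through stop codons (with renormalization over the remaining
pathways); a codon whose every pathway passes through a stop is skipped
with a warning. Sites are averaged between the two sequences, and
proportions are Jukes–Cantor corrected, `d = −(3/4) ln(1 − 4p/3)`, with
`p ≥ 3/4` an explicit error. Family-level dN and dS are unweighted means
over pairs; the neutral-line classification ("above"/"below"/"on") uses a
1e−12 tolerance so that exact ties are "on" without being fooled by float
noise. The entire counting machinery is validated in the tests against an
exhaustive pathway-enumeration oracle (exact on all ≤2-difference codon
pairs, plus 500 random ≤3-difference pairs).

## Trees and supports

K2P is the distance (`d = −½ ln((1−2P−Q)√(1−2Q))`): it separates
transitions from transversions consistently with the ts/tv analysis and is
the conventional companion of neighbor joining. NJ itself is the
Saitou–Nei algorithm (via `ape::nj`); negative branch lengths are clamped
to zero with the total deficit recorded. Bootstrap supports resample
alignment columns with replacement and re-run the same distance + NJ
pipeline. Felsenstein support is the fraction of replicates containing a
bipartition; transfer bootstrap expectation (TBE) is
`1 − mean(δ/(p−1))`, where δ is the minimum transfer distance of the
bipartition to any branch of the replicate and p the smaller side of the
split — the gradual support that remains informative on large, unstable
trees. Trivial splits (p = 1) have support fixed at 1, and TBE ≥
Felsenstein support by construction (checked in the tests). Newick output
scales supports to 0–100 and can hide values below a threshold (0.60 by
default in the pipeline), mirroring the usual "only values ≥ 60 shown"
figure convention. The naive O(branches²) transfer-distance matching is
accepted at this scale.

## Correlation tests

`pearson()` is the classical test: sample r with a two-sided p from
`t = r√((n−2)/(1−r²))` on n−2 df (a permutation oracle cross-checks it in
the tests). Reports print p to 3 decimals, so "0.000" means p < 0.0005.
The pooled correlation is computed over the union of records — not the
mean of per-species r — and per-species results are reported alongside it.
No multiple-testing correction is applied (two planned tests per scope).

## What the simulator emulates — and what it does not

`make_ancestor()`/`evolve_family()` generate families whose truth is fully
known, so every stage of the pipeline can be tested without external data.
The generator's defaults are the study conditions: primer-truncated
signals (10 of 22 residues kept), acidic propieces ending in KR, cationic
L/G-rich mature peptides, a length coupling of ρ = −0.8 between propiece
and mature peptide, negative charge coupling, transition bias κ = 4,
purifying ω = 0.3, and Poisson(5) substitutions per lineage — which puts
within-family π in the 0.01–0.05 band typical of such families.

Mechanics worth knowing:

* Lengths come from a rounded shared-deviation bivariate scheme; with
  ρ = −1 the propiece+mature sum is *exactly* constant because the
  propiece reuses the mature peptide's rounded deviation with opposite
  sign.
* ω is implemented as acceptance thinning of nonsynonymous proposals
  (valid for ω ≤ 1; ω > 1 thins synonymous proposals by 1/ω instead) —
  simple and directly oracle-checkable, avoiding codon-model matrix
  exponentiation.
* Members evolve on a star genealogy (independent lineages), not a
  coalescent: family trees are not an estimation target here; π, ω and κ
  recovery are.
* The generator rejects draws with spurious cut-point motifs or
  ambiguous reading frames, and (by default) rejects substitutions that
  would move the cut point — so segmentation truth is stable. Switching
  `protect_motif` off exercises the "no cut point" error path.

Not emulated: indels (families with deletions are constructed directly as
aligned fixtures — alignment is an *input* to this package, not something
it infers), recombination, demography, and among-site rate variation.
Passing the recovery tests therefore shows the estimators are correct
under substitution-only evolution with known truth; it does not certify
behavior on poorly aligned or recombining real data.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to what
the estimators need, not more: 50 families per (ω, κ) condition at 15
substitutions per lineage for selection recovery, 200 precursors for
correlation recovery, a 34-family gold dataset (14 + 7 + 13 families
across three pseudo-species blocks, mirroring the clade counts of the
motivating study design) for the end-to-end run, and 100 random 5–8 leaf
additive matrices for NJ exactness. Bootstrap replicates default to 100 in
the pipeline; supports are deterministic given the seed, and replicate
column draws are reproducible from it.

Known limitations: the GenBank flat-file reader parses only the subset of
the grammar the pipeline needs (LOCUS/ACCESSION/ORGANISM, simple
`start..end` peptide features, ORIGIN); ts/tv and dN/dS are counting
estimators, not ML; and families whose members differ in length are
skipped by the alignment-free family builder with a message — they must be
supplied pre-aligned.
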