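---
title: "Methods: conglutin discovery, marker selection and relative quantitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conglutin discovery, marker selection and relative quantitation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conglutinr)
```

## Scope and model

`conglutinr` reconstructs a targeted-proteomics workflow for the lupin
conglutin seed storage proteins: starting from sequence databases and
discovery-search peptide tables, it identifies candidate conglutin
isoforms, maps peptide conservation across a 46-accession panel, selects
subfamily-specific marker peptides for multiple reaction monitoring
(MRM), and converts MRM peak areas into batch-corrected relative
abundance profiles per conglutin subfamily and family. Everything runs at
desk scale with no external binaries; the wet-lab and instrument stages
(extraction, digestion, LC–MS acquisition, peak integration) and the
vendor database-search engine are out of scope — their *outputs*
(identification tables, peak-area matrices, domain annotations) are the
package's inputs.

## Sequence screening

**Database construction.** Open reading frames are called in all six
frames, ATG to stop, and kept when the coding length excluding the stop
codon is at least `min_nt` (default 150 nt). The cutoff is counted on the
coding sequence *excluding* the stop codon — the conservative reading of
a "150 nt cutoff" — and is configurable. By default only the longest ORF
per stop per frame is reported (first ATG after the previous stop), the
common convention; `all_orfs = TRUE` emits nested ORFs. Deduplication
removes exact sequence matches only: "100% identity" between sequences of
different lengths is ambiguous, and the exact-string rule is the testable
interpretation.

**Identity screen.** Candidates are screened against the 16 reference
conglutins by exhaustive pairwise alignment rather than BLASTp: at desk
scale (hundreds of candidates, 16 references) an exact ends-free global
alignment is affordable, removes an external dependency, and preserves
the ≥ 75% semantics. Scoring is match +1, mismatch 0, affine gaps (open
−10, extend −0.5 per residue, a length-L gap costing 10 + 0.5·L), with
end gaps free. Identity is 100 × matches / aligned columns, where the
aligned-column count includes internal gap columns but not the free end
gaps. The published method does not state whether its 75% screen used
local or global identity; ends-free global identity is our documented
choice. Traceback ties prefer diagonal, then up, then left, and the pair
is canonicalised (lexicographic order) before alignment so that identity
is exactly symmetric — without canonicalisation, co-optimal alignments
chosen by the tie-break could differ between argument orders.

**Structural confirmation.** Candidates above the identity threshold are
confirmed by family-diagnostic structure:

* α — at least one `CXnC` cysteine pair and two cupin_1 domains matching
  the 36–201 and 405–552 residue windows;
* β — exactly zero cysteines and two cupin_1 domains at 180–330 and
  390–551;
* δ — the nine-cysteine prolamin skeleton `CXnCXnCCXnCXCXnCXnCXnC`
  (inter-cysteine gap constraints ≥1, ≥1, =0, ≥1, =1, ≥1, ≥1, ≥1), with a
  tryp_alpha_amyl domain additionally required only for δ2 candidates;
* γ — TAXi_N (62–237) and TAXi_C (269–430) windows plus at least two
  cysteines before the TAXi_N start.

Cysteine patterns operate on the inter-cysteine gap vector, so wildcard
positions are implicitly non-cysteine; windowed matching accepts any
contiguous run of cysteines satisfying the constraints. Domain evidence
is consumed as an input table (from any external domain caller or the
synthetic truth); the package checks positions, it does not call domains.
A domain counts as matching a printed window when it overlaps it by at
least 50% of the window length — the window coordinates are published but
no tolerance is, so the 50% rule is our explicit, configurable choice.
How many `CXnC` repeats α and γ require is likewise unstated; the
defaults (α: ≥ 1 pair; γ: ≥ 2 cysteines before TAXi_N) are flagged as
interpretation. The semi-conserved β motifs (`HYXnR`,
`QQDEQEXnYXnLS`) are reported as annotations via `scan_motif()` but are
not classification gates, since they were only noted, not required.

**Trees.** Family trees are built by neighbor joining on
`d = 1 − identity/100` instead of a progressive multiple alignment: the
trees serve only to group variants with subfamilies, and NJ on the
already-computed identity matrix is fully specifiable and testable
(deterministic leaf order, four-point-condition recovery).

## Peptide conservation

Discovery observations are filtered to the allowed modifications
(carbamidomethyl C, oxidation M, N-terminal pyro-Glu) and a row-level
confidence threshold, default 0.99. The true identification FDR is set by
the upstream search engine; the confidence default approximates a 1% FDR
at the row level, and an optional `fdr` column filter is exposed for
tables that carry one. Peptides are keyed by bare sequence (modified
forms collapse), presence is per accession, and counts fall into six
frequency classes. The published class boundaries 26–35 and 35–40 overlap
at 35; the partition here is corrected to 36–40 so the classes are
disjoint (a requirement for testability), and the correction is
configurable. Peptides are mapped onto references by exact substring
match, every occurrence reported, including overlapping ones; a peptide
shared between a conglutin and a non-conglutin parent still counts toward
the conglutin's coverage, since the conservation map is a property of the
reference sequence.

## Marker selection

Tryptic digestion cleaves after K/R except before P, allows up to one
missed cleavage and keeps 8–30-residue products. Specificity asks which
background proteins contain the peptide as a *fully tryptic* substring:
one conglutin parent → unique; several conglutin parents → a protein
group (e.g. β4,6 — near-identical subfamilies that cannot be told apart
by peptides); any non-target parent → nonspecific. Selection applies five
gates in order (specificity; fully tryptic; confidence ≥ 0.95; restricted
modifications; S/N > 5), then drops survivors above `cv_max` (default
20%) and ranks per target by CV ascending, then median intensity
descending — "highest intensity and lowest variability" gives no
combination rule, so the lexicographic order (variability first) is the
package's choice. Transition lists are abstract labelled channels with
±30 s scheduling windows; fragment-ion m/z values come from a spectral
library in the original workflow and are out of scope.

## Quantitation statistics

**Batch correction.** Per peptide, log10 areas are fitted by least
squares to `intercept + β·injection_order + batch` with sum-to-zero batch
coding, and only the fitted batch terms are subtracted; the
injection-order covariate and the residuals are retained, so
within-batch contrasts are unchanged. This matches the fit of
`limma::removeBatchEffect` with an injection-order covariate (the test
suite asserts equality after aligning what is subtracted — limma also
removes the covariate term, we deliberately keep it, since a linear
drift retained in all runs cancels in percent-of-average profiles).
Corrected areas are stored back on the linear scale so every downstream
operation sees one convention.

**Profiles.** Replicate CV is 100 × sd/mean over an accession's
replicates on the linear scale. Accession values (means over replicates)
are normalised to percent of the panel average, which makes every
profile row average exactly 100. Family totals sum the accession means
of member peptides, group-assigned peptides contributing to their
group's family, before the same normalisation.

**Multivariate views.** PCA is an SVD of the column-scaled accession ×
peptide log10 matrix; unit-variance scaling is the default (mirroring
the defaults of the chemometrics tools this replaces) with centre-only
available, and since variance percentages are scaling-dependent no
published variance split is asserted anywhere. Component signs are fixed
by making each loading's largest-magnitude element positive. Before
PCA/HCA, peptides missing in more than half the runs are dropped and
remaining gaps imputed with half the peptide's minimum observed area (the
source method is silent on missingness; half-minimum is the common
left-censoring surrogate). HCA uses one-minus-Pearson distance with
average linkage; zero-variance samples are an error naming the sample.

**Dunnett comparisons.** One-way ANOVA is followed by Dunnett
many-to-one comparisons against an explicit control group (none is ever
implied; the caller must designate one). Adjusted p-values are
`P(max_j |T_j| ≥ |t_obs|)` under the joint null, evaluated by Monte-Carlo
integration of the multivariate t distribution: the environment provides
no Dunnett implementation, and the Monte-Carlo route (default 1e5 draws,
fixed seed; standard error of a p-value near 0.05 about 0.0007) is both
prescribed and reusable — `dunnett_reference()` precomputes the sorted
max-|T| sample for a design so that repeated calls are O(log n) lookups.
The significance threshold is fixed at p < 0.05 with no further
multiple-testing layer across peptides, matching the per-peptide
presentation of the source workflow.

## The synthetic world

The generators emit every input with known truth, under one seed, and
are bit-reproducible. Stated-world defaults: 46 accessions (D1–D16
domesticated, W1–W30 wild); 16 references (3 α, 7 β, 4 δ, 2 γ) with
planted cysteine skeletons and domain windows, β6 generated at 97.8%
identity to β4 and δ3 at ~98.7% to δ1 so that protein-group quantitation
is forced exactly where it is in the real family; 244 designed peptides
across the six frequency classes (42/30/30/28/28/86, echoing the
published panel's 17% rare / 35% ubiquitous split); marker candidates
designed so the five gates pass exactly 22 α, 37 β, 13 δ and 10 γ
peptides; β2–β6 suppressed to 1% of baseline in D1–D6; a 0.3 log10
two-batch offset with randomised injection order; 0.1 log10 total linear
drift; three replicates at a 10% target CV (under the published < 13%
technical variation). Replicate noise is multiplicative log-normal with
`σ = sqrt(ln(1 + cv²))`, which makes the linear-scale CV target analytic;
the true peak-area distribution is not published, so log-normality is an
assumption of the generator, not a claim about the data. Variants mutate
positions outside cysteines and domain windows first (never touching a
cysteine or creating one), so identity can be lowered without destroying
structure; decoys are residue-frequency-matched and rejection-sampled
below 70% identity to every reference, a clear margin under the 75%
screen.

What the generator does *not* emulate — and hence what a green test does
not establish — includes: real spectra, retention-time behaviour and
peak-integration error; correlated biological structure between
accessions (genotype effects are independent noise plus the planted
suppression); shared peptides between conglutins and the wider seed
proteome; and search-engine score distributions (confidence values are
planted on either side of the thresholds, not modelled).

## Numerical and degenerate-input choices

Alignment tie-breaks and endpoint preference are fixed as described;
empty sequences are errors. `dedupe` keeps the first-seen id. CV of a
zero-mean peptide is reported missing, and an all-zero profile vector is
an error rather than a NaN. PCA drops zero-variance variables with a
warning under unit-variance scaling (they carry no information and would
divide by zero). NJ branch lengths within 1e-12 of zero are snapped to
zero. The Dunnett reference validates that its design (group sizes,
degrees of freedom) matches the data it is applied to.

## Known limitations

* Identity-based screening against 16 references scales quadratically in
  sequence length and linearly in database size; it is meant for curated
  candidate sets, not proteome-wide BLAST replacement.
* Specificity is exact-substring based; isobaric near-matches (I/L) are
  not collapsed.
* The power of Dunnett comparisons at n = 3 replicates is modest: an
  independent Monte-Carlo oracle puts the detection rate of a
  3-pooled-SD shift (5 groups of 3) near 0.77 at α = 0.05, and the test
  suite asserts that oracle band rather than a higher aspiration.
* Family totals use all selected markers; whether a subset per family
  should be preferred is exposed to the caller via the marker map.
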