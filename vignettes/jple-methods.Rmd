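---
title: "Joint protein-ligand embedding: models, parameters and design choices"
author: "jple package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint protein-ligand embedding: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method it
implements: the model and its assumptions, the parameters that matter,
what the synthetic benchmark emulates (and what it does not), and the
numerical and design decisions that were genuinely open.

## The model

An RNA-binding protein (RBP) enters the model as a pair of vectors.
The *peptide profile* counts every gapped 5-mer template — four
specified residues and one wildcard position, so each 5-residue window
of the RNA-binding region (RBR) contributes five templates — over all
segments of the RBR. The RBR is the union of the protein's annotated
RNA-binding domains, each extended by a 15-residue flank (capturing
linkers and termini, where binding-relevant residues are known to sit),
with overlapping or adjacent extensions merged. The *RNA-binding
profile* is the vector of Z-scores over the 16,382 RNA 7-mers measured
by an RNAcompete-style assay (the 16,384 possible 7-mers minus the two
that spell the cloning restriction site).

Training stacks these vectors into matrices `P'` (proteins x templates)
and `R'` (proteins x 7-mers). Zero-variance columns are removed; the
remaining columns are centered and scaled to unit Euclidean norm — so
each retained feature contributes equally, and the stored means and
norms let query vectors be transformed identically and reconstructions
be returned on the raw measurement scale. The joint matrix `[P R]` is
factorized by SVD, and components are ranked **not** by singular value
but by their contribution to the variance of the RNA block,
`s_i = sigma_i^2 * ||v_Ri||^2`, which sums exactly to `trace(R R^T)`.
This is the method's central idea: the retained axes are those that
explain RNA specificity, which suppresses peptide variation unrelated
to binding. The retained dimension `d` is the smallest rank at which
the SVD of `R` alone reconstructs every training profile at a Pearson
correlation of at least 0.95 (`pccMin`).

Queries solve a least-squares problem against one block of the
retained axes (`embedProtein` against the peptide block, `embedRNA`
against the RNA block). Decoding is either *global* (the linear map
back through the retained axes, plus the stored column means) or
*local*: training proteins within e-sim `exp(-gamma * edist^2) >= 0.01`
of the query form a neighborhood whose raw profiles are averaged with
e-sim weights. The local decoder is the default for protein queries —
it is non-linear, respects the empirical geometry of the embedding,
and its output always lies in the convex hull of measured profiles;
the global decoder is the only decoder for RNA queries, whose output
(the reconstructed peptide profile `p*`) feeds the residue importance
score (RIS): each template's value, divided by its occurrence count in
the RBR, is added to all five residues of each occurrence.

### Parameters

| parameter | default | meaning |
|---|---|---|
| `flank` | 15 residues | RBD extension when building the RBR |
| `pccMin` | 0.95 | per-protein reconstruction floor that fixes `d` |
| `gamma` | 25 | RBF width converting e-dist to e-sim |
| `nbhThreshold` | 0.01 | e-sim floor for the decoding neighborhood; equivalently e-dist <= `sqrt(ln(100)/gamma)` ~ 0.429 |
| `confCutoff` | 0.127 | e-dist below which a query is called confident |
| `fwer` | 0.01 | family-wise error of the specific-7-mer Z-test (Bonferroni over the vocabulary) |
| `topN` | 10 | 7-mers aligned into a PFM |
| `thresholdFrac` | 0.1 | fraction of the maximal window score below which scan windows are ignored |
| `minSid` | 0.70 | identity floor of the homology-transfer baseline |

All defaults are the published operating points of the method; every
one is an explicit function argument (and a CLI flag).

## Numerical choices

* **Sign convention.** Each retained singular vector is flipped so its
  largest-magnitude entry is positive; `U` is flipped with it. This
  makes fits deterministic across LAPACK builds.
* **Ties** in component scores are broken by original singular-value
  order; ties among top 7-mers by vocabulary order; PFM placement ties
  prefer the smaller absolute offset, then the negative one.
* **Rank deficiency.** Encoders use a minimum-norm least-squares solve
  (SVD with a relative tolerance) — the closed-form normal-equations
  inverse presumes full column rank, which small fixtures can violate.
* **Degenerate inputs.** A zero embedding has undefined cosine; its
  e-dist is defined as 1 (neutral, never confident) with a warning. An
  empty local neighborhood returns the zero profile, flagged
  non-confident. Constant intensity columns abort quantification;
  7-mers contained in no probe inherit the minimum score with a
  warning. Windows containing an unknown residue (`X`) are skipped —
  they carry no usable evidence — and the wildcard in templates is
  positional, so `AXAAA` and `AAXAA` are distinct features.
* **Trimming.** The inner-95% mean drops `ceiling(0.025 n)` values from
  each tail after a stable sort, so the estimate is deterministic under
  ties. The Z-transform uses the population (n-denominator) standard
  deviation, matching "mean zero, standard deviation one" exactly.
* **Single-sample arrays.** The per-probe (row) normalization step is
  only applied when at least two samples are present; with one column
  it would annihilate the data. The real assay matrix always carries
  many protein columns, where the row step removes probe-level
  abundance artifacts.

## Open design decisions

* **Query-time preprocessing.** The encoder equations omit centering,
  but the decoder re-adds the column means; transforming queries with
  the stored training statistics (mask, subtract mean, divide by norm)
  is the only self-consistent reading, and is what makes the full-rank
  round-trip exact.
* **Homolog augmentation.** For RNA queries the peptide block can be
  replaced by homolog-augmented profiles: at every alignment start
  position the *distinct* 5-mer peptides across homologs each
  contribute their templates with weight 1/(number of distinct
  peptides). The alternative reading — accumulate raw counts over all
  homologs, then divide — double-counts identical homologs, which
  contradicts the requirement that a single identical homolog
  reproduce the unaugmented profile; the distinct-peptide reading is
  implemented. Windows never span alignment gap columns (a gapped
  window is not a real peptide).
* **Standardization cohort.** RIS values are conventionally computed
  from reconstructions standardized column-wise across a query cohort.
  The scores therefore depend on cohort composition; on small,
  group-structured cohorts (like the synthetic benchmark) the
  standardization rescales interface and background columns
  differently and can distort rankings, so the planted-recovery tests
  evaluate unstandardized reconstructions, while
  `standardizeReconstructions` is available (and used by the CLI `ris`
  subcommand) for heterogeneous cohorts.
* **PFM construction.** The published procedure states only that the
  top ten 7-mers are aligned without gaps. Here the top 7-mer seeds the
  alignment and each further 7-mer is placed greedily at the offset
  (any overlap of at least one column) maximizing identity to the
  running consensus; columns are normalized by their coverage rather
  than by `topN`, avoiding artificially flat flanks.
* **Identity denominator.** Pairwise identity divides exact matches by
  the full alignment length (conservative); dividing by the shorter
  sequence length is available as an option, mirroring the convention
  used in family-wise contexts.

## The synthetic benchmark

The generator produces protein families with planted
peptide-to-specificity structure so that every pipeline stage is
testable without external data. Its defaults define the study
conditions used by the tests and the acceptance script:

* **Families.** Founders are random 20-letter sequences with one KH or
  two RRM domains (60 residues each, 10-residue termini, 15-residue
  linker). Members are derived by point substitutions targeting an
  identity ladder of 0.95 / 0.90 / 0.80 / 0.50 — spanning the bands
  from near-duplicates to the edge of the homology-transfer regime.
* **Purifying selection with drift.** Six conserved 5-residue blocks in
  the first domain are the specificity-determining interface. They
  receive a deterministic substitution budget — a quarter of their
  proportional share, one substitution per drifted block — so
  interface divergence grows monotonically with sequence divergence.
  A mutated interface peptide is assigned an effect vector correlated
  at 0.75 with the ancestral block effect: specificity drifts
  gradually (neofunctionalization) rather than vanishing with the
  first substitution.
* **Convergent interfaces.** Beyond the first half (more generally,
  `groupSize`), families reuse the interface blocks of earlier
  families, forming specificity groups of unrelated proteins that bind
  the same motif. This mirrors the fact that RBP motifs recur across
  unrelated families — and it is precisely what lets the embedding
  separate interface templates from family background: interface
  templates recur across backgrounds, background templates do not.
* **Motif-like effects.** Effect vectors over 7-mers are built from
  random mono-, di-, tri- and tetra-nucleotide energies, which makes
  them *shift-coherent*: a 7-mer and its single-base shifts score
  similarly, as composition- and repeat-driven RBP preferences
  (poly-U, GU-repeats, AU-rich) do. This matters for quantification:
  with uncorrelated ("white") k-mer effects, the systematic
  contamination from overlapping probe windows bounds the achievable
  rank correlation near 0.77 no matter how many probes are measured,
  whereas shift-coherent profiles are recoverable. Planted positional
  motifs with rough k-mer landscapes are correspondingly
  under-represented — a known limitation of the benchmark, not of the
  quantification code.
* **Probe arrays.** Intensities are the summed softmax-scaled
  affinities (`exp(z/4)`, about two orders of magnitude of dynamic
  range) of all 7-mers in each ~40-nt probe, plus a shared lognormal
  per-probe effect and Gaussian noise at a probe-level signal-to-noise
  ratio of 3. The acceptance run uses 241,000 probes — the scale of
  the real assay — because per-7-mer estimates average over
  occurrences, and a 16,382-word vocabulary needs that many probes for
  stable ranks.

What passing these tests shows: the linear algebra is correct (exact
oracles), the pipeline recovers planted signal through featurization,
embedding, decoding, quantification and residue scoring, and the
confidence machinery orders queries sensibly. What it does not show:
performance on real proteins, where motifs are not exactly linear in
template counts, probes are designed rather than random, and homology
structure is far messier than a four-band ladder.

### Problem sizes

The test suite and acceptance script use a 60-protein benchmark (12
families x 5 members) for protein-query recovery with a stratified
hold-out (one non-founder per family — so no family loses both its
founder and its nearest member, which would confound distance with
training coverage); a 48-protein noise-free panel (24 families x 2
members, specificity groups of 4) for RNA-query and residue-importance
recovery; and a 241,000-probe array for quantification recovery. A fit
on the 60-protein benchmark takes a few seconds; the full acceptance
script runs in well under a minute on one CPU.

## Known limitations

* The planted model is linear and additive in template counts by
  construction, matching the embedding's own assumptions; it cannot
  reveal how the method degrades under strongly epistatic
  sequence-function maps.
* Domain annotations are an input; no domain scanning is performed.
* Interface evaluation consumes externally supplied contact labels;
  no structures are parsed.
* The exact retained dimension of the published full-scale model (122
  axes for 355 training proteins) is a property of that training set
  and is not asserted anywhere; the selection rule (0.95 floor) is.
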