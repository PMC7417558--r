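---
title: "Monitoring port biofouling with foulscan: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Monitoring port biofouling with foulscan: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foulscan)
```

## What the package models

Year-long biofouling surveys in ports follow a common template: settlement
panels (some coated with anti-corrosion paint, some bare steel) are immersed
for twelve months; every month a few grids are scraped from each panel for
DNA metabarcoding, the panels are photographed for image-based coverage
estimation, and wet weights are taken for biomass. The molecular arm
sequences several marker genes (16S, 18S, 23S rRNA and COI), clusters reads
into OTUs at 97% identity, assigns taxonomy from homology-hit tables, and
screens COI species assignments against non-indigenous-species (NIS)
checklists. foulscan implements this computational template end to end, with
a synthetic-data module that generates every input with planted ground truth
so the full pipeline can be exercised and validated offline.

## Survey bookkeeping

`samplingDesign()` encodes the design: 12 months, 2 painted + 4 bare panels
sampled monthly, 3 grids per panel per month, 2 extra whole-panel scrapes at
the end, 2 DNA pools per month. `buildSamplingManifest()` expands it:

```{r manifest}
str(buildSamplingManifest()[1:3])
```

216 scraped grids, 218 scraped samples, 26 DNA pools. The effective panel
area for biomass normalisation is the 20 cm x 20 cm face minus four 16 cm^2
carabiner patches, `effectiveArea()` = 336 cm^2; biomass per area is
(wet - clean) / area, clipped at zero.

## Read QC and OTU clustering

`qualityFilter()` discards reads shorter than 100 bp or with mean phred
quality below Q20. The quality rule is interpreted as *mean* read quality:
of the per-base and windowed alternatives this is the simplest reproducible
reading, and the synthetic read generator (two well-separated quality
regimes, means ~Q35 and ~Q15) makes the three interpretations agree on
generated data. A read failing both rules is counted once, as short, so the
QC report partitions its input.

`pairwiseIdentity()` defines the identity metric behind the 97% threshold:
matching columns over total columns of a global Needleman-Wunsch alignment
with match +1, mismatch -1, linear gap -2, score ties broken toward
matches. The scoring scheme is fixed and deliberately simple so an
independent dynamic-programming oracle can verify it exactly; symmetry is
guaranteed by canonicalising the operand order. `greedyCluster()` builds
OTUs greedily: sequences are processed in decreasing length (ties by id),
and each joins the *first* centroid at >= 97% identity or founds a new one —
the convention of greedy centroid-based clusterers, which makes the
partition independent of input order. Closed-reference mode instead assigns
each sequence to its *best* reference centroid, or to an unassigned pool.
Chimera removal is a pass-through stage accepting a precomputed exclusion
list, preserving the pipeline position without re-implementing a detector.

## Taxonomy adjudication

Homology hits arrive as tab-separated tables in two dialects: the 12-column
primary layout (`qseqid sseqid length pident gaps sstart send qcovs evalue
bitscore staxids stitle`) and a 10-column fallback layout whose taxon names
live in `sseqid`. The cascade in `assignTaxonomy()`:

1. primary hits are used if present, otherwise fallback hits
   (`source_db = "fallback"`); both empty gives `unassigned_no_hit`;
2. at most 5 hits are considered, matching a `max_target_seqs 5` search;
3. confidence filtering removes hits with alignment length < 200, identity
   < 90%, query coverage < 100%, gaps > 0, or a banned title keyword
   (*uncultured, unidentified, unclassified, environmental*;
   case-insensitive whole words). The coverage rule is enforced literally
   (`qcovs` must equal 100): strict, but unambiguous. Keyword removal is
   per hit; when every removal was for a keyword the OTU is
   `removed_banned`, otherwise `unassigned_all_filtered`;
4. if survivors span one genus, the OTU is `assigned_top_hit` with the
   lineage of the ranked winner. Ranking uses the four criteria in fixed
   order — identity desc, e-value asc, coverage desc, gaps asc — with
   subject id as a final deterministic tie-break;
5. if survivors span several genera, the winner must *strictly* beat every
   other-genus hit on the first differing criterion (`assigned_tiebreak`);
   otherwise the OTU is flagged `dubious` for manual curation rather than
   auto-resolved — cross-genus ties are exactly the cases a human would
   align by hand, so the artifact flags instead of guessing.

Genus/species parsing is dialect-specific: the primary dialect takes the
first two alphabetic tokens of the subject title; the fallback dialect
splits `sseqid` on `|` or `_`. Higher ranks come from an optional local
genus-to-lineage map; live taxonomy lookups are out of scope.

## NIS screening

COI is protein-coding, so genuine barcodes translate without internal stop
codons while pseudogenes (NUMTs) usually do not. `translateFrames()`
translates all six frames under a set of NCBI genetic codes — default
{1, 2, 4, 5, 9}, the standard code plus the mitochondrial tables common in
marine metazoans; ambiguity codes become `X` and never count as stops.
`orfValidate()` passes a sequence when some (frame, code) yields a
stop-free codon run covering >= 90% of the codons: amplicons may start
mid-codon and contain the odd miscalled base, so a strict full-length rule
would reject valid barcodes. `matchChecklist()` then reports an OTU iff it
is assigned to species level, the binomial matches a checklist entry after
case/whitespace normalisation (optionally through a user synonym map —
synonym resolution itself is delegated), and validation passes. Sequences
failing validation are retained in a side table of candidates for manual
review, mirroring how interrupted proteins are curated by hand in practice.

## Community statistics

All statistics are computed from first principles; vegan serves only as an
independent cross-check in the test suite.

* **Alpha diversity** (`alphaDiversity()`): observed richness; Chao1 in the
  bias-corrected form `S + F1(F1-1) / (2(F2+1))`, well-defined when
  doubletons are absent; Shannon with natural log; inverse Simpson.
* **Rarefaction** (`rarefactionCurve()`): mean richness over seeded
  subsamples without replacement, checked against the closed-form
  hypergeometric expectation `sum_i (1 - C(N - x_i, n) / C(N, n))`.
* **Bray–Curtis** (`brayCurtis()`): `d_ij = sum|x_i - x_j| / sum(x_i + x_j)`
  after appending one pseudo-OTU of constant 0.0001 to every sample, so
  pairs of empty samples are defined (distance 0). The dummy is a single
  appended column — a value was specified for this convention, not a
  mechanism, and one constant pseudo-taxon is the minimal implementation.
  Counts are used raw by default; because the square-root of relative
  abundances is an equally common convention for this analysis, it is
  available as `transform = "sqrt_relative"` and both paths are tested.
* **PERMANOVA** (`permanova()`): one-way, from the sums-of-squares
  identities `SS_T = (1/N) sum_{i<j} d_ij^2`,
  `SS_W = sum_g (1/n_g) sum_{i<j in g} d_ij^2`, pseudo-F =
  `(SS_B/(a-1)) / (SS_W/(N-a))`. The p-value uses the `(1 + b)/(1 + m)`
  convention over seeded random relabellings (default 9,999), which keeps
  p > 0; when a two-group design has at most `nPerm` distinct relabellings
  they are enumerated exhaustively and the p-value is exact. Sample order
  is canonicalised (sorted labels; group levels by order of appearance)
  before the permutation stream is drawn, so the p-value does not depend on
  row order or group naming. Only one-way designs are supported — the
  painted-vs-bare contrast is a single factor.
* **Dispersion homogeneity** (`dispersionTest()`): principal-coordinates
  embedding of the (semimetric) dissimilarity matrix via the double-centred
  Gower matrix, all non-null axes kept. Squared distance to the group
  centroid is the squared distance on positive-eigenvalue axes minus that
  on negative-eigenvalue axes, floored at zero — the standard correction
  for semimetric dissimilarities. Group *centroids* are used (the spatial
  median variant exists but the centroid form is the one whose F statistic
  matches the multivariate Levene construction tested here). The F
  statistic on the centroid distances gets its p-value by permuting those
  distances across samples.

## The synthetic-data module

The generators are first-class, tested code; every downstream stage is
validated against their planted truth.

* **Taxa** use a reserved pseudo-Latin namespace (genera prefixed "Ficto"),
  so generated binomials cannot collide with real checklists. COI
  references are assembled from codons that are never stops under codes
  {1, 2, 4, 5, 9}, making genuine barcodes pass translation validation by
  construction.
* **Reads** plant exact failure counts: `round(n * fracShort)` short reads
  and `round(n * fracLowQ)` low-quality reads (two quality regimes, per-base
  28–41 vs 3–19, so every read is unambiguous under the Q20 mean rule).
* **Hit tables** plant one of six cases per query — clean, no-hit,
  low-confidence, ambiguous-with-strict-winner, banned-keyword, NIS — each
  forcing one branch of the cascade; e-values are a decreasing function of
  bitscore so the rank correlations the tie-break assumes hold. Banned
  queries get banned titles on *all* hits so the case maps deterministically
  to `removed_banned`.
* **Abundance matrices** (`genAbundance()`) draw negative-binomial counts
  (size 10) around per-OTU log-normal means (meanlog log 50, sdlog 1) with
  a per-sample log-normal scale factor (sd 0.25). `locationShift` applies a
  +/- log-fold change on alternating OTUs in the painted group (composition
  moves, not just scale); `dispersionRatio` multiplies the painted group's
  per-sample scale sd, spreading samples without moving the centroid much.
  With shift 0 and ratio 1 all samples are generated identically, giving an
  exchangeable null. These constants were fixed once as a plausible
  amplicon-like regime and are deliberately not tunable.
* **Panel stacks** plant a single connected foreground block at gray 220 on
  background 50 with seeded Gaussian noise; the stored true coverage is the
  exact planted pixel fraction. Real panel photographs have texture,
  gradients and mixed organisms — the generator only emulates the
  bimodal-intensity situation in which histogram thresholding is the right
  tool, so passing tests certify the machinery, not segmentation of
  arbitrary photographs.

All randomness flows through one explicit integer seed per call and the
caller's RNG state is restored afterwards; identical seeds give identical
outputs byte for byte.

## Image quantification

`maxIntensityProjection()` takes the per-pixel maximum over slices (a
single photograph passes through unchanged). `toGray8()` averages channels
and rescales the input bit range to 0–255 with round-half-up.
`binarizeAndClean()` thresholds with exact Otsu (the smallest maximiser of
between-class variance over the 256-bin histogram — deterministic and
verifiable against exhaustive search; a constant image falls back to 128
with a warning), orients the foreground by an explicit `polarity` argument
(which phase is fouling is an imaging choice that must be stated per image
set; bright fouling is the default), and removes 8-connected components
below `minParticlePx` (default 5) — noise suppression is modelled as
minimum-particle-size removal because it immediately precedes particle
analysis in the workflow. `coveragePercent()` counts foreground within a
0-based, half-open ROI, which keeps area arithmetic exact.

## Problem sizes and numerical choices

The test suite and the acceptance script use these sizes, chosen as a
balance of statistical resolution and desk-scale runtime:

* type-I error: 500 replicates of n = 6 samples/group x 30 OTUs, 199
  permutations each; power: 200 replicates, location shift 1.0 (e-fold
  change, n = 5/group) and dispersion ratio 4 (n = 10/group);
* oracle equivalence: 500 random hit tables; 1,000 random count vectors for
  the diversity inequalities; 100 random images for Otsu; 50 noisy panels
  for coverage; 200 sequences (40 families) for clustering.

Tolerances: permutation p-values are exact counts, so equality checks are
exact; sums-of-squares identities are asserted to 1e-9; rarefaction is
compared to its closed form within ~3 Monte-Carlo standard errors.

## Known limitations

* The dispersion-homogeneity test is mildly anticonservative at small group
  sizes (empirical type-I ~0.06–0.07 at n = 6/group under the exchangeable
  null). The reference implementation (vegan's `betadisper` + `permutest`,
  and even the parametric F) shows the same rate on identical data: the
  distances to *estimated* centroids are not exchangeable quantities in
  small samples. At the nominal level this stays within the
  0.05 +/- 0.02 band, but users testing dispersion with few samples per
  group should prefer larger designs.
* Bray–Curtis is semimetric; the PCoA embedding therefore has negative
  eigenvalues and the corrected centroid distances can be floored at zero.
* The greedy join-first rule reproduces the convention of greedy
  clusterers, not an optimal partition; cluster counts depend on the
  length/id processing order exactly as documented.
* Taxonomy adjudication trusts the hit tables it is given; it does not run
  searches, resolve taxids against a live taxonomy, or compute
  lowest-common-ancestor summaries.
* NIS screening matches exact binomials (plus a user synonym map);
  genus-level or cryptogenic status inference is out of scope, and
  morphology-only detections can only enter as checklist metadata.
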