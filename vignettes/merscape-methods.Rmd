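---
title: "merscape: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{merscape: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

merscape is a comparative-genomics toolkit for mercury-resistant
bacteria.  Its core task is to find and classify *mer* operons — the
modular gene clusters whose reductase *merA* converts toxic Hg(II) to
volatile Hg(0) — in annotated genomes, and to place them in their
mobility and co-resistance context: flanking transposition modules and
phage/plasmid genes, co-resident metal-resistance loci such as the
cobalt–zinc–cadmium (*czc*) efflux pump, and the genome-wide census of
antibiotic-resistance (ARG), metal-resistance (MRG) and
mobile-genetic-element (MGE) genes whose co-occurrence underlies
co-selection.  This vignette records the models, the tunable
parameters, and the design decisions that were genuinely open.

## The detection model

Detection is anchored on *merA*.  Every CDS whose gene name or product
matches the merA lexicon (`"merA"` as a word, or the phrase
`"mercuric reductase"`) seeds a candidate operon, and the surrounding
neighborhood — `window_bp = 10000` bp measured from the anchor CDS
edges on each side — is screened for the accessory genes *merB*,
*merR*, *merT*, *merP*, *merC*, *merF*, *merD*, *merE* and *merG*.

Operon boundaries are a contiguity judgment that annotation pipelines
leave qualitative, so merscape operationalizes them with three
explicit, user-settable rules (`detector_params()`):

* **Gap rule** — the run stops when the intergenic gap between
  *directly adjacent* genes exceeds `max_intergenic_gap_bp = 500` bp.
  500 bp is a conventional operon-prediction cutoff: co-transcribed
  bacterial genes rarely sit farther apart.
* **Strand rule** — members must share the anchor strand
  (`require_same_strand = TRUE`), with one biological exception: a
  *merR* on the opposite strand immediately adjacent to the run is
  admitted (`allow_divergent_merR = TRUE`), because the regulator is
  frequently divergently transcribed from the structural genes.  The
  divergent *merR* terminates extension on its side.
* **Embedded-gene rule** — at most `max_embedded_nonmer = 1`
  consecutive unannotated CDS may be bridged; bridged genes are kept
  in the call as `"hyp"` members, since single hypothetical ORFs
  inside *mer* cassettes are common.

Two anchors inside one cassette produce overlapping calls that
`merge_calls()` unions; operons on different replicons stay separate,
which matters because multi-operon genomes (independent horizontal
acquisitions) are a real and reported configuration.

Classification is then deterministic from the member set:

* **architecture** — member symbols 5'→3' on the operon strand,
  hyphen-joined (e.g. `merR-merT-merP-merC-merA-merB`);
* **complete** — *merR* and *merA* present plus at least one transport
  gene of {*merT*, *merP*, *merC*, *merF*}.  This follows the
  canonical description of the regulator/transport/reductase core;
  *merF* counts as a transport substitute, and *merD*/*merE*/*merG*
  never affect completeness.  Whether "complete" should require
  *merR* specifically is not universally fixed in the literature; we
  adopt the regulator-inclusive reading and expose nothing that
  depends on the alternative.
* **spectrum** — `broad` iff *merB* is a member: the organomercurial
  lyase extends resistance from inorganic Hg(II) to organomercurials
  such as methylmercury; otherwise `narrow`.

Gene identification is lexicon-based (case-insensitive substring
matching on product/gene name, with word-boundary semantics for bare
`mer[A-Z]` symbols so that "poly**mera**se" never fires).  This makes
the detector independent of any specific annotation tool; the lexicons
ship as editable tables (`default_mer_lexicon()`, `default_lexicon()`)
and are a declared approximation of database-driven screens such as
CARD/DeepARG, which are deliberately out of scope.

Window scans do not wrap circular origins.  This is a documented
limitation: an operon spanning the origin of a circular replicon would
be truncated.  The synthetic generator never plants origin-spanning
operons, so tests do not certify that case.

## The census and its views

`assign_categories()` tags each CDS with hierarchical categories
(`ARG`, `MRG:mercury`, `MRG:czc`, …, `MGE:phage`, `MGE:insertion`,
`MGE:plasmid`).  Within one top-level group the highest-priority
matching category wins, so a product matching both "transposase" and
"integrase" counts once; the ARG/MRG/MGE groups are independent.
`census()` counts tags per genome; `zscore_standardize()` standardizes
each category column to mean 0 / sample SD 1 (denominator n − 1,
zero-SD columns mapped to 0) and clips to ±4 — the clip keeps extreme
single-genome outliers from saturating heatmap color scales while the
bound is wide enough that clipping is rare; `replicon_proportions()`
reports each category as a percentage of a replicon's CDSs, the view
in which plasmid enrichment of MGEs is visible.

## The statistics layer

All permutation machinery is implemented from first principles so
that seeds give bit-reproducibility and small designs can be
enumerated exactly; `vegan` and base R serve as independent
cross-checks in the test suite, never as the implementation.

* **Bray–Curtis**: d(x, y) = Σ|x−y| / Σ(x+y), with d = 0 for two
  all-zero profiles.  The triangle inequality does not hold in
  general and is not asserted.  Count profiles enter raw by default;
  presence/absence or total-normalized transforms are a caller-side
  choice (`bray_curtis()` takes any non-negative matrix), and raw
  counts are the default because the census is itself count-valued.
* **PERMANOVA** (one factor, free permutation of labels, no strata):
  SS_total = (1/n) Σ_{i<j} d²; SS_within sums the per-group analogues;
  pseudo-F = (SS_b/(g−1))/(SS_w/(n−g)).  When the number of distinct
  label arrangements is ≤ `exhaustive_limit` (default 10 000) the null
  is enumerated and p is exact; otherwise p = (b+1)/(m+1) over m
  sampled permutations.  The +1 convention keeps p > 0 and the test
  valid at finite m.
* **Dispersion homogeneity**: samples are embedded by PCoA; distances
  to *group centroids* are computed with the standard correction that
  axes with negative eigenvalues contribute negatively to the squared
  distance (floored at 0); a one-way ANOVA F on those distances is
  permuted.  Centroids (not spatial medians) are the declared mode.
  All-identical inputs are reported as p = 1 with a degeneracy flag
  rather than an error, so pipelines degrade gracefully.
* **Kruskal–Wallis / Dunn**: tie-corrected H with a χ² (g−1) p-value;
  Dunn z from mean ranks with the pooled tie correction, two-sided
  normal p, Bonferroni multiplied by all pairs.  The pipeline runs the
  pairwise tests only when the global test passes α — post hoc gating
  as commonly practiced — while `kruskal_dunn()` itself always
  returns them so the gating stays a pipeline policy, not a statistics
  limitation.
* **Dual correlation**: Pearson r and Spearman ρ (Pearson on
  mid-ranks), both with t-approximation p-values; an association is
  `reported` only when both p-values fall under α.  The joint rule is
  conservative by construction (its null report rate is below α,
  which the acceptance suite measures).  An exact permutation null is
  available behind a flag for n ≤ 10.
* **Ordinations**: PCA on the correlation structure (columns centered
  and unit-scaled; constant columns dropped with a warning), PCoA by
  double-centering −d²/2.  Bray–Curtis matrices are generally
  non-Euclidean, so PCoA reports the negative-eigenvalue mass instead
  of applying a Cailliez/Lingoes correction — coordinates live on the
  positive axes and the caller can judge distortion.  Axis signs are
  fixed so the largest-magnitude loading on each axis is positive,
  making ordinations reproducible.
* **Hierarchical clustering** defaults to average linkage (UPGMA-like
  on dissimilarities); the choice is recorded in the output since
  single/complete are also offered.

## The Mer-protein phylogeny

Trees are built from concatenated Mer-protein alignments (canonically
MerR, MerT, MerP, MerA — the proteins shared across operons) by
neighbor joining on Jukes–Cantor-corrected protein distances:

* p is the proportion of differing sites over columns where neither
  sequence has a gap or X — *pairwise* deletion, which preserves
  signal when a taxon misses one protein and is padded with gaps;
* d = −(19/20)·ln(1 − 20p/19), the 20-state Poisson correction;
  saturated pairs (p ≥ 19/20) receive a ceiling (default 5.0
  substitutions/site) and a flag rather than ±Inf;
* NJ joins the pair minimizing Q_ij = (n−2)d_ij − Σd_i − Σd_j, with
  the standard split branch lengths, negatives clipped to 0 (flagged),
  and ties broken by the lexicographically smallest label pair so the
  topology is deterministic;
* bootstrap supports resample alignment columns with replacement,
  rebuild the tree per replicate, and report the percentage of
  replicates containing each bipartition of the *full-data* tree.
  The alternative — a majority-rule consensus topology — answers a
  different question; attaching supports to the full-data tree keeps
  branch lengths meaningful and is the default (a consensus view can
  be built from the replicate trees by the caller).  Replicates with
  an incomparable pair are skipped and counted, with a warning above
  1 % skipped.

## The LAG classifier

Gene families are classified per lifestyle from a presence/absence
matrix: prevalence ≥ 60 % ⇒ restrictive, 40 % ≤ prevalence < 60 % ⇒
lax, and a family reaching a class in two or more lifestyles is
shared.  The published phrasing "40 %–59 %" is in integer percent; we
implement the half-open interval [0.40, 0.60) with exact rational
comparisons (counts against lifestyle sizes, thresholds snapped to
rationals over 10⁶), so 59.9 % is lax and no floating-point artifact
can flip a boundary family.  Whether shared families should also be
counted inside per-lifestyle totals is ambiguous; `lag_summary()`
reports both views (`n_total` and `n_exclusive`).  Lifestyle labels
come from metadata; the upstream machine-learning lifestyle predictor
is out of scope.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` builds multi-replicon genomes (a chromosome, an
optional second chromosome, and a plasmid) carrying planted operons
from seven template families that span the canonical architectures:
`merR/TPCAB`, the extended `merR/TPCAB-DE`, a *merF*-substituted
transport variant, an inorganic-only cassette lacking *merB*, an
isolated *merA*, a *tniABQ*-flanked (Tn5053-like) cassette and a
*czc*-adjacent cassette.  Defaults: intergenic gaps inside cassettes
are drawn from 10–150 bp (well under the 500 bp rule, so boundary
behavior is exercised by dedicated fixtures, not by chance); flanking
context genes sit 200–2000 bp from the cassette ends (inside the
10 kb window, outside the operon by the gap rule); scattered
ARG/MRG/MGE genes are Poisson-planted with per-category rates, and
operon-carrying genomes receive twice the phage/insertion rates —
emulating the elevated mobile-element load reported for mer-positive
genomes so that downstream contrasts have signal.  Background genes
draw products from a neutral vocabulary guaranteed to miss every
lexicon keyword, which makes census ground truth exact rather than
approximate.  One master seed drives per-genome streams derived by
stable hashing of (seed, genome index), so generation is reproducible
and order-independent.

Genomes are scaled down — 0.8 Mb chromosomes, 0.15 Mb plasmids,
~150 background genes — since every computation depends on feature
coordinates and labels, not on sequence length; no nucleotide or
amino-acid content of real *mer* genes is simulated.  Alignment
simulation uses the uniform 19-way replacement model, exactly the
process the Jukes–Cantor protein correction inverts, with Poisson
substitution counts per site along branches.

Passing tests on these cohorts therefore certify the *logic* of
detection, counting and statistics against exact ground truth.  They
do not certify robustness to real annotation noise: truncated or
mis-annotated products, pseudogenes, nested mobile elements,
origin-spanning operons, or vocabulary drift between annotation
pipelines.  On real data the lexicons are the component to adapt
first.

## Reproducibility and problem sizes

Every stochastic routine takes a seed; the pipeline derives per-stage
streams from one global seed and writes a manifest with MD5 checksums
of every output, so two runs with the same configuration are
byte-identical.  The validation suite uses cohort sizes of 30 genomes
with 20 planted operons, 1000-replicate null calibrations for the
PERMANOVA type-I error and the dual-correlation report rate, 200
random additive matrices (≤ 12 taxa) for NJ consistency, and
1000-replicate bootstraps on 4-taxon strong-signal simulations —
sizes chosen so the full suite exercises every claim in minutes on a
laptop while keeping binomial confidence intervals tight enough to be
meaningful.

## Known limitations

* Lexicon matching cannot recover genes whose annotations carry no
  recognizable keyword, and it inherits the annotation tool's
  vocabulary; it is a declared substitute for homology-based screens.
* Circular-origin wrap-around is not scanned.
* PERMANOVA is single-factor with free permutations; no strata or
  multi-factor designs.
* The NJ/JC stack is a distance method; model-based phylogenetics
  (ML/Bayesian, rate heterogeneity, empirical substitution matrices)
  is out of scope.
* Multiple-testing control beyond Bonferroni (e.g. FDR) is not
  provided.
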