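---
title: "Methods: calling inherited lncRNAs and circRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calling inherited lncRNAs and circRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inheritscan)
```

# The model

The central biological assumption is that the zygote is transcriptionally
silent until zygotic genome activation (about 4 hpf in zebrafish), so a
transcript detected in the zygote must be parentally deposited. Detection
in at least one gamete corroborates the call and identifies the parental
origin. `inheritscan` operationalises this as set logic over a
detection indicator: a transcript is *detected* in a sample when its FPKM
is at or above a threshold (default 0.1 FPKM, boundary inclusive).

Two inheritance rules cover two study designs:

* **Lenient** (many independent studies): detected in ≥ 1 sample of
  *every* zygote study and in ≥ 1 gamete sample of any study. Requiring
  every zygote study builds a between-study consensus and suppresses
  single-study artefacts; a study is identified by its `study_id`, and a
  one-sample study is a valid study.
* **Stringent** (few studies): detected in *all* zygote samples and in
  all samples of at least one gamete type. A gamete type with zero
  samples cannot satisfy the rule — we deliberately do not treat the
  universally-quantified clause as vacuously true, since an absent sample
  class is missing evidence, not evidence.

The stringent rule implies the lenient rule on the same data (detected in
all zygote samples implies detected in one sample of every study), and the
test suite asserts this containment on every fixture.

Gamete origin is the strictest defensible reading of a gamete-specific
transcript: `oocyte_specific` means *zero* sperm samples reach the
threshold (and at least one oocyte sample does); `sperm_specific` is the
mirror; anything else detected in both gamete types is `both_gametes`.
Because the boundary is inclusive, a sperm FPKM of exactly 0.1 removes
oocyte specificity. Transcripts satisfying a rule's zygote clause but
detected in no gamete are reported in a `zygote_only` diagnostic column
rather than silently discarded: they are candidates for early zygotic
transcription and deserve separate scrutiny, but the model cannot call
them inherited.

# Coordinates and genomic context

All internal coordinates are 0-based half-open; GTF and junction tables
(1-based inclusive) are converted only at the I/O boundary. Half-open
intervals make overlap arithmetic unambiguous: a lncRNA ending exactly
where a gene starts does not overlap it.

The analysis is unstranded throughout — the underlying libraries are a mix
of stranded and unstranded protocols, so strand is stored but never used
in an overlap test. *Genic* means the lncRNA's transcript span intersects
a protein-coding gene span by ≥ 1 bp; span (not exon) overlap is used
because intron-resident biotypes (`sense_intronic`, `retained_intron`)
count as genic. When the Ensembl biotype and the positional call disagree
(a `lincRNA`-labelled transcript overlapping a gene), position wins for
the genic/intergenic category and biotype only drives the subcategory
(`antisense` vs `sense_overlapping`); this precedence is a package
decision, as annotation labels lag assemblies.

Flanking genes are the ≤ 5 nearest genes wholly upstream and ≤ 5 wholly
downstream in reference orientation, ordered by edge-to-edge distance with
ties broken by lower gene start then lexicographic id (a deterministic
total order). Genes overlapping the lncRNA are excluded from flanks: they
belong to the overlap-conservation definition, and counting them twice
would let a single gene satisfy two supposedly independent definitions.

Chromosome-scaled density maps each transcript midpoint to
`1000 · midpoint / chromosome length`. The midpoint (rather than the TSS)
is used because it is orientation-independent, matching the unstranded
treatment; a position of exactly 1000 falls in the last histogram bin.
Adult-tissue breadth averages replicate samples per tissue (arithmetic
mean FPKM) before thresholding, and orders transcripts by hierarchical
clustering of `log2(mean FPKM + 1)` rows with average linkage and
Euclidean distance.

# Conservation

All three definitions require a counterpart in **both** target species;
per-species flags are exported for diagnostics.

* **Sequence**: ≥ 1 alignment hit at E ≤ 1e−5 (inclusive — the cutoff is
  stated without strictness, and inclusivity is the documented choice)
  against the target species' inherited lncRNA set, with no query-coverage
  requirement, since a short embedded regulatory element is a legitimate
  signal inside a long transcript. Hits whose subject is outside the
  inherited set are dropped with a warning.
* **Overlap**: some ortholog triplet (gZ, gM, gH) has gZ among the
  lncRNA's overlapping genes, gM overlapped by a mouse inherited lncRNA
  and gH by a human one.
* **Loci (synteny)**: some mouse counterpart shares ≥ 5 ortholog-linked
  genes with the reference flank set, and some human counterpart likewise.
  Sharing is counted as *distinct reference flank genes* whose ortholog
  appears in the candidate's flank set — set membership only, ignoring
  up/down orientation and order. That is the literal reading of the
  definition; an order-aware variant would be stricter and is not the
  default. A reference lncRNA with fewer than `min_shared` flank genes in
  total is flagged FALSE with the reason recorded, not errored.

The package ships a minimal word-seeded, ungapped similarity search
(`seeded_similarity_search()`, default word size 20) used by the synthetic
test harness: it scores the diagonal through every exact shared word
(+1 match / −2 mismatch) and reports the maximal segment. It deliberately
does **not** compute E-values — those depend on database-size statistics
(Karlin–Altschul parameters) that the pipeline has no business re-deriving;
production use consumes external tabular hits. Consequently
`sequence_conserved()` treats an unset (NA) e-value as passing: for seeded
hits, the existence of a seed-extended match *is* the evidence.

# circRNA calling

Backsplice junctions are filtered **per sample** — `junction_reads ≥ 2`
and `junction_ratio ≥ 0.05`, both inclusive — and a candidate exists
globally once it passes in one sample. Per-sample filtering is chosen
because the inheritance logic is itself phrased per sample (present in a
zygote sample and a gamete sample); pooling reads across samples before
filtering would let many weak samples manufacture a candidate that no
single sample supports. The junction ratio is taken from the input table;
where it must be recomputed, the convention `2c / (2c + l)` (circular
junction reads counted twice against linear reads) is used, matching the
detection tools' definition.

Category tests use the two backsplice coordinates as *points*: intergenic
iff both points fall outside all gene spans; exonic iff either point is
inside an annotated exon; intronic otherwise when either point is inside a
gene span. Exonic beats intronic by construction and the result is
independent of the annotation's row order. The spanned interval is used
only for reporting. Host genes are all genes containing either point — a
circle may legitimately span two genes. Candidate identity is the exact
(chromosome, start, end) triple; near-identical junctions are not merged,
which is a known limitation (±1 bp detection jitter would split a
candidate). The gene space passed to the category test is the caller's
choice; the pipeline passes protein-coding genes, consistent with
host-gene reporting. An optional maximum-span filter exists in spirit via
pre-filtering the junction table, but no span filter is applied by
default.

The circular-vs-linear comparison normalises a circle as junction reads
per million total backsplice reads per sample (averaged over zygote
samples, with absent records counted as zero reads) and takes the host's
linear level as the maximum mean-zygote FPKM over the host genes'
transcripts. A ratio above 1 — including a present circle over a
zero-expression host, reported as an infinite ratio — is flagged
`circ_exceeds_linear`. The two scales are different units; the flag is a
screening heuristic for circles that outrun their linear cognates, not a
calibrated fold change.

# Temporal grouping

Profiles over the five timepoints (0–4 hpf, replicates averaged) are
transformed as `log2(FPKM + 1)` and clustered by k-means (default k = 4,
10 restarts, fixed seed required — no silent nondeterminism). Initial
centers are drawn from *distinct* profiles so that degenerate inputs
(many identical rows) cluster without error; if there are fewer distinct
profiles than k, the effective k shrinks with a warning. Clusters are
relabelled by descending size with ties broken by the lowest original
label, making group numbering deterministic.

Per-profile mean-centering (the default) makes clustering shape-driven:
amplitude differences vanish and groups separate by trajectory shape.
This is the right view for "is the pool degraded or stable", but it is
*provably unable* to separate archetypes that differ only in amplitude —
a flat-high and a flat-low profile center to the same vector. The
synthetic archetypes include exactly such a pair, so planted-archetype
recovery runs with `center = FALSE`; the test suite checks both regimes
(amplitude recovery uncentered, shape recovery centered). Both behaviours
are correct for their question, which is why `center` is an argument
rather than a constant.

Stability labels are ratio criteria on each group's raw mean trajectory,
hence invariant to uniform positive scaling: *degraded* = final mean below
0.5× the initial mean with a monotone decline within a 10% per-step
tolerance; *induced* = 1 hpf mean above 2× the initial mean (a zero start
with later expression is induced); *stable* otherwise. The fold factors
and tolerance are configurable; the defaults encode "halved by ZGA" and
"doubled immediately after fertilization" as the qualitative patterns of
interest.

# Synthetic data: what it does and does not show

Every generator is deterministic given its seed and emits a manifest of
planted labels. Decision-relevant values keep a 2× margin around their
thresholds: planted-expressed cells are ≥ 0.2 FPKM and planted-absent
cells ≤ 0.05 around the 0.1 cutoff; planted candidate junctions have
reads ≥ 3 and ratio ≥ 0.1, non-candidates reads ≤ 1 or ratio ≤ 0.02.
Margins make downstream classification deterministic, which cleanly
separates *rule-correctness* tests (exact planted recovery, zero errors)
from *noise-robustness* questions, which the margins deliberately exclude.
Generators refuse parameter combinations that straddle a threshold or make
planted labels unrecoverable by construction (e.g. temporal noise at or
above half the minimum archetype separation).

What the generators emulate: the reference study layout (2 sperm samples
from 2 studies, 7 oocyte from 4, 10 zygote from 4, configurable), a ~20%
inherited fraction with mostly shared-gamete origins, biotype-annotated
annotations with antisense / sense-overlapping / intergenic lncRNA
placement, three-species synteny blocks with controlled shared-flank
counts (5–10 for conserved loci, 0–4 for decoys), planted exact shared
60-mers for sequence conservation, and junction tables realizing chosen
categories and origins.

What they do not emulate: FPKM distributions of real libraries, between-
study batch effects, mapping and quantification noise, annotation
incompleteness, near-threshold expression, or backsplice coordinate
jitter. Passing the planted-truth suite therefore demonstrates that the
decision rules are implemented exactly as specified — it does not measure
sensitivity or specificity on real data, where values near the threshold
dominate the error budget.

Problem sizes in the test suite (1000 transcripts for inheritance
recovery, ≤ a few hundred intervals for oracle comparisons over 20 random
draws, 23 lncRNAs per species for synteny, 50 junctions, 4 × 50 temporal
profiles) were chosen as the smallest sizes at which every rule, boundary
and tie-break is exercised, including all-pairs and all-candidates
brute-force oracles that would be quadratic or cubic at scale.

# Numerical and degenerate-input choices

* All detection and filter boundaries are inclusive (`>=`), matching the
  stated criteria; boundary fixtures pin each one.
* Missing FPKM cells become 0 with a message (quantifiers emit explicit
  zeros; absence means the transcript was filtered upstream).
* Empty inputs flow through: an annotation with no lncRNAs produces
  all-zero summaries and a successful run; an empty hit table produces a
  0-row hit frame with the standard 12 columns.
* Chromosome lengths come from a sizes file; transcripts beyond the
  stated length are an error, not a clamp.
* The ortholog map is restricted to one-to-one-to-one triplets;
  many-to-many rows should be expanded upstream to all triplets.
* Percentages in summary tables are always recomputable from the count
  and denominator columns in the same file — no independently rounded
  fields.

# Known limitations

* Gamete-origin calls inherit the detection threshold's arbitrariness;
  near 0.1 FPKM a single sample flips specificity. The threshold is a
  parameter precisely to allow sensitivity analyses.
* The internal seeded search is ungapped and exact-word seeded; it is an
  oracle for planted-segment tests, not a replacement for a full
  alignment tool on diverged sequences.
* circRNA candidate identity is exact-coordinate; fuzzy merging of
  near-identical junctions is not implemented.
* The circular-vs-linear flag compares different units (reads per million
  backsplice reads vs FPKM) and is a screen, not an effect size.
* Conservation calling assumes the inherited sets of the target species
  are given; the package classifies them with the same rules when
  expression data are provided, but does not validate external lists.
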