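---
title: "Methods: domain parsing and six-category classification of predicted structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: domain parsing and six-category classification of predicted structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Predicted whole proteomes arrive as single-chain models with two confidence
signals: a per-residue pLDDT score (0–100) and an n×n predicted aligned
error (PAE) matrix in Ångström. Residues of a rigid, co-folded unit have
low mutual PAE; linkers and disordered tails have high PAE against
everything. `afdomain` turns these signals, together with homology-hit
tables from sequence-profile and structure-alignment searches, into a
per-residue classification over six categories:

* **ASSIGNED** — a globular domain with a confident, high-coverage link to
  a reference domain;
* **UNASSIGNED** — globular, well-defined secondary structure, but no
  confident reference link;
* **PARTIAL** — a confident link without a high-coverage alignment (often
  pseudogenes or annotation errors);
* **SIMPLE** — 2 or fewer secondary-structure elements;
* **FLEXIBLE** — non-globular by PAE (linker/disordered) at adequate
  prediction confidence;
* **LOW_CONFIDENCE** — pLDDT below the confidence cutoff.

The package also tallies assigned domains by homologous group (H-group)
and stratum, tests population differences with a 2×2 chi-squared and
Bonferroni correction, builds redundancy-reduced representative sets by
greedy sequence clustering, and checks parsed domains against
sequence-annotation intervals.

# Parsing model

## Flexible-residue exclusion

Residue $i$ is flexible iff fewer than `flex_min_partners` (default 5)
residues $j$ with $|i-j| >$ `flex_seq_sep` (default 10) satisfy
$\mathrm{PAE}_{sym}(i,j) <$ `flex_partner_pae` (default 10 Å), where
$\mathrm{PAE}_{sym}$ is the mean of the $(i,j)$ and $(j,i)$ entries
(payloads are asymmetric; we preserve them at read time and symmetrise
only here). The partner-count form is robust to a few spuriously low PAE
entries, unlike a row-mean cutoff.

## Pair probabilities

Four pair features — Cα distance, symmetrised PAE, and the counts of
sequence-profile and structure-alignment hits covering both residues — are
transformed ($d \mapsto \min(d,40)/40$, $\mathrm{PAE} \mapsto
\min(\mathrm{PAE}, 31.75)/31.75$, counts $\mapsto \log(1+c)$) and combined
by logistic regression into the probability that the two residues share a
domain. The upstream method's exact weights are not published, so the
package fits the weights itself on the labelled synthetic benchmark
(`make_pair_training()`, 6 models, seed 1 by default) and persists them
with the run manifest; a small ridge penalty (`reg = 0.01`) keeps the
weights finite when the benchmark classes are linearly separable, which
well-separated PAE blocks make the common case. On real data the same
fitting entry point accepts any labelled pair table.

## Segment clustering

Maximal non-flexible runs are tiled into segments of `segment_len` = 5
residues. The segment length is fixed by the method; the remainder rule is
ours: a remainder of 1–2 is absorbed into the previous segment (length
6–7), a remainder of 3–4 keeps its own segment, and runs shorter than 3
residues revert to flexible. We cluster disjoint blocks rather than
overlapping 5-residue windows; windows would smooth boundaries at roughly
double the cost, and on block-structured PAE the difference vanishes.

Clustering is average-linkage agglomeration: segment affinity is the mean
pair probability over cross-segment residue pairs, cluster linkage the
mean affinity over segment pairs, and merging continues while the best
linkage is at least `pair_prob_cut` = 0.5 (a scale-free midpoint on a
probability). Ties are broken towards the pair containing the lowest
segment index, then the lowest partner index, so results are
deterministic. Clusters may combine non-adjacent segments, so
discontinuous domains are representable.

## Short-candidate merging

Candidates shorter than `min_domain_len` = 25 residues (the method says
"short" without a number; 25 sits just below the smallest folded domains)
are processed smallest-first: each merges into the sequence-adjacent
candidate with the higher inter-candidate mean pair probability when that
probability is ≥ 0.3, and is otherwise dropped, its residues reverting to
the flexible pool. Whether the upstream method keeps or drops unmergeable
short regions is unstated; dropping is conservative — a 10-residue island
that no neighbour claims is more plausibly a parsing artefact than a
domain.

# Classification model

## Secondary structure from Cα geometry

A P-SEA-style distance-window detector: residue $i$ is helical if
$d(i,i{+}2) \in [5.0, 6.0]$ Å and $d(i,i{+}3) \in [4.7, 6.1]$ Å, strand if
$d(i,i{+}2) \in [5.9, 7.3]$ Å and $d(i,i{+}3) \in [9.0, 11.5]$ Å (helix
wins on overlap), else coil. An SSE is a run of ≥ 6 H or ≥ 3 E. Cα-only
detection keeps the package independent of full-backbone input and lets
the fixture generator stay simple; the windows are documented constants.

## Category precedence

Per candidate: (1) mean pLDDT < `plddt_min` = 70 → LOW_CONFIDENCE;
(2) fewer than `sse_min_for_globular` = 3 SSEs → SIMPLE; (3) otherwise the
hit-based label. The precedence is our choice (the source material does
not order the rules): confidence filters must dominate homology calls,
because a low-confidence region cannot support a domain assignment no
matter how good its hits look. The pLDDT statistic used for demotion is
the candidate mean; mean versus median is immaterial on bimodal synthetic
confidence and the mean is the more common reporting convention.

## Assignment scoring

The candidate score is `confidence × ref_coverage` of the best hit
(highest product): ASSIGNED needs confidence ≥ `conf_min` = 0.8 and
coverage ≥ `cov_assign` = 0.7; PARTIAL needs the same confidence with
coverage < `cov_partial` = 0.5; everything else — the coverage grey zone
[0.5, 0.7) and the no-hit case — is UNASSIGNED. This transparent rule
replaces the upstream method's trained neural-network assignment, which is
out of scope here; the three cutoffs are package defaults, configurable
through `default_thresholds()`. Reference coverage means the aligned
fraction of the reference domain (not of the alignment), which is what
makes a partial domain "partial".

# Population statistics

Only ASSIGNED regions are tallied, per (H-group, stratum). The
row-and-column normalisation is the observed/expected ratio under
independence, $c_{sh} \cdot T / (r_s \cdot k_h)$, with 0/0 cells reported
as 0. The 2×2 chi-squared uses the closed form without Yates continuity
correction, matching the spreadsheet function conventionally used for
such analyses; degenerate margins return $\chi^2 = 0, p = 1$. Bonferroni's
$m$ counts groups present in the observed set by default ("per set"); the
union-universe alternative is selectable, and the significant-set size is
necessarily non-increasing in $m$.

# Representative sets

Greedy incremental clustering, longest-first with first-fit joining
(best-fit joining by flag), mirrors the documented behaviour of the
standard greedy clustering tools. Identity and coverage come from
Smith–Waterman local alignment (BLOSUM62, gap 11/1); the word size is a
pure k-mer prefilter and never changes identity values. The published
F-level triples are used verbatim: (identity, coverage, word) =
(0.99, 0.9, 5), (0.70, 0.7, 4), (0.40, 0.7, 2). For unassigned-domain
reduction the coverage mode is bidirectional at 0.7; the identity
threshold is not stated for that step, so the package documents 0.7 as
its default — consistent with the F70 level that the workflow pairs it
with. Representative selection is a strict priority order: previous >
manual > provisional manual > x-ray > better (lower) resolution > later
release > smallest id.

One caveat found while testing: on *short random sequences* the best
local alignment is a short, high-identity island, so raw local identity
between unrelated 50-mers averages well above 0.4. Clustering still
behaves because joining requires identity **and** coverage jointly; the
audit in `audit_clusters()` checks exactly the joint criterion.

# Annotation comparison

Obsolete-to-current record mapping requires exact sequence equality
(hence equal length); multiple matches map to the smallest current id and
set an ambiguity flag. A parsed domain counts as covered by sequence
annotations when ≥ 50% of its residues fall in the union of annotation
intervals; the 0.5 threshold is the package default (`theta`), chosen so
a domain split across two annotation entries still counts, and is
configurable because no canonical value exists.

# The synthetic generator

`generate_model()` builds chains block by block: ideal helices (rise
1.5 Å, radius 2.3 Å, 100°/residue) and pleated strands (3.3 Å step,
0.9 Å pleat) arranged into bundles, sandwiches, or mixed folds, with
self-avoiding random coils (3.8 Å steps, 3.0 Å clash cutoff) for linkers
and tails. PAE is sampled cell-wise — N(4, 1) within a domain block,
N(20, 3) across blocks, N(28, 2) when either residue is disordered —
clipped to [0.2, 31.75], the AFDB payload window, and left asymmetric as
real payloads are. pLDDT is N(90, 5) for ordered residues and N(50, 10)
for disordered tails. Linkers take the ordered distribution: a flexible
linker is a *confidently predicted* non-globular region, which is what
separates FLEXIBLE from LOW_CONFIDENCE. No quantitative PAE/pLDDT
distributions per category exist in the source material, so these
defaults are explicit parameters of `synthetic_spec()`.

`generate_proteome()` draws each model as three globular slots separated
by linkers plus a disordered tail; slot kinds are drawn with probability
proportional to mix weight over block length, and linker/tail lengths are
solved from the flexible and low-confidence weights, so realised residue
fractions track the requested mix. The default mix (0.66 assigned, 0.04
unassigned, 0.01 partial, 0.04 simple, 0.12 flexible, 0.13
low-confidence) reproduces the coverage profile typical of whole
predicted proteomes. Hits follow the ground truth by construction:
confidence ~ N(0.92, 0.04), reference coverage ~ N(0.85, 0.05) — or
N(0.30, 0.05) for partial-scenario blocks — with optional uniform-[0.1,
0.5]-confidence decoys to wrong groups.

**What the generator does not emulate**: inter-domain PAE anisotropy and
distance-dependent PAE decay, mid-range pLDDT plateaus, domains that pack
against each other (blocks are spatially separated), obligate-complex
context effects, and realistic hit-score distributions from actual search
tools. Recovery results on this benchmark therefore demonstrate that the
pipeline implements its rules correctly and recovers block-structured
signal; they do not measure accuracy on real predicted proteomes, where
confidence signals are far noisier.

# Numerical choices and degenerate inputs

* All stochastic steps are seeded; per-model seeds derive from a master
  seed, and identical seeds reproduce outputs byte-for-byte.
* Agglomeration ties are resolved within 1e-12 by segment index.
* Float output in tables is fixed at 4 decimals for stable diffs.
* Degenerate cases: empty segment lists cluster to empty candidate lists;
  a zero margin in the 2×2 test gives $p = 1$; an all-disordered model
  yields zero candidates with every residue flexible; empty region tables
  refuse to summarise.
* Problem sizes: the shipped benchmark uses 50 models of ~230 residues
  (about 11,500 residues, ~140 true domains), a 6-model training
  benchmark for the pair model, and 100 sequences in 10 families for
  clustering — sizes at which every documented recovery property is
  testable in seconds to a couple of minutes on one core.

# Known limitations

Single chains only (multi-model overlapping predictions for very long
proteins are excluded, as they were in the source analysis); Cα-only
geometry; no re-execution of profile or structure searches (hit tables
are inputs); no taxonomy-tree ordering of strata; no manual-curation or
new-H-group seeding workflow. The transparent assignment score is not a
drop-in reproduction of the upstream neural-network assignments — it is
designed to be auditable, not identical.
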