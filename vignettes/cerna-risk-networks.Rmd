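---
title: "From GWAS variants to endothelial circRNA circuits: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From GWAS variants to endothelial circRNA circuits: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cernarisk)
```

## The analysis in one paragraph

Circular RNAs (circRNAs) can act as miRNA sponges: by sequestering a miRNA
they relieve its repression of the miRNA's mRNA targets. Two transcripts that
compete for an overlapping miRNA pool are *competing endogenous RNAs*
(ceRNAs). `cernarisk` builds the global circRNA–mRNA ceRNA network from a
scored interaction table, overlays three channels of disease evidence —
proximity to GWAS risk variants, curated disease associations, and two-group
differential expression — extracts the disease-risk subnetwork, asks whether
its nodes are network hubs and bottlenecks, and finally narrows to
endothelial-cell (EC) biology by intersecting the risk triplets with genes
that recur across EC gene-expression programs, producing terminal
`variant -> circRNA -> miRNA -> gene -> program` circuit chains.

## The ceRNA model and its thresholds

An interaction table holds scored circRNA–miRNA and miRNA–mRNA binding
relations. Direction is ignored: the edges are treated as undirected binding
associations. Two retention rules define the network:

* **confidence `> 0.3`** (strict): edges at exactly the threshold are
  dropped. The cutoff is configurable (`min_confidence`), with duplicate
  edges collapsing to their maximum confidence — the conservative choice for
  a retention filter.
* **`>= 3` shared miRNAs** (`min_shared_mirnas`): a circRNA–mRNA pair is
  competitively regulated when the intersection of their miRNA partner sets
  has at least three members. Each pair expands into one
  (circRNA, miRNA, gene) *triplet* per shared miRNA.

Enumeration uses a miRNA-indexed join (an inverted index): the two bipartite
maps are joined on the miRNA axis and co-occurrences are counted per
(circRNA, gene) pair, materializing shared sets only for pairs that pass the
threshold. The naive all-pairs set-intersection algorithm is kept in the test
suite as the independent oracle; on study-shaped inputs (500 circRNAs x
300 miRNAs x 10,000 genes) the join completes in seconds where all-pairs
intersection would not.

circRNAs and genes live in distinct namespaces throughout (a circRNA named
after its host gene never collapses onto the gene node); graph vertices are
class-prefixed internally for the same reason.

## Variant-to-feature proximity

For each GWAS variant the mapping returns the union of (a) every
same-chromosome feature within `+/- window_bp` (default 500 kb, boundary
inclusive) and (b) the `n_closest_per_side` (default 2) nearest features
lying entirely on each side, regardless of distance — computed separately
for circRNAs and genes. The union semantics guarantee candidates even in
gene deserts while never discarding a window hit.

Several conventions are deliberate and documented because the rule itself
does not fix them:

* Coordinates are 0-based half-open (BED convention) everywhere internally.
* Distance is the gap to the nearest interval boundary base, 0 inside the
  interval; strand and transcription start sites are ignored.
* A feature containing the variant is reported as `inside` and excluded from
  the left/right ranking; ranking ties break by (distance, start, id) so the
  output is deterministic.
* "Inside" containment is strict under half-open intervals: a variant at
  `pos == end` is outside, at `pos == start` inside.

The terminal circuit stage attaches variants to circRNAs by strict
containment only — the biological reading is a variant that can alter the
sponge itself, not merely sit near it.

## Differential expression

Expression matrices are analyzed on the log2 scale (declared-linear input is
transformed as `log2(x + 1)`). Each feature is tested with the Welch
unequal-variance t statistic with Welch–Satterthwaite degrees of freedom —
chosen because it is assumption-light, self-contained, and well calibrated
at the small group sizes typical of these cohorts; a moderated (shrunken
variance) statistic is out of scope. "Adjusted p" means Benjamini–Hochberg,
the field default for FDR-style thresholds. A feature is called
differentially expressed when `adj_p < 0.05` **and** the linear fold change
exceeds 1.5 (`|log2fc| > log2(1.5)`, both strict). Degenerate rows (zero
variance in both groups, equal means) return t = 0, p = 1 rather than NaN.

## Risk network, topology, enrichment

A ceRNA pair enters the risk network when at least one endpoint carries any
disease flag (GWAS-nearby, curated-known, or DE) in its own class. miRNA
annotations are collected but do not drive edge retention; they gate the
circuit stage instead.

Topology is compared on the *background* network (all pairs before disease
filtering): the degree and unnormalized shortest-path betweenness of
disease-annotated nodes are tested against the remaining nodes with a
one-sided Mann–Whitney U test. Mann–Whitney is used because degree and
betweenness distributions are heavy-tailed, making t-tests inappropriate.
The implementation (via `stats::wilcox.test`) uses the exact U null for
small tie-free samples and the tie-corrected normal approximation otherwise;
the test suite checks it against full permutation enumeration for group
sizes up to 8, and betweenness against exhaustive all-pairs shortest-path
counting on graphs up to 30 nodes.

Enrichment of the risk-network genes is a flat one-sided hypergeometric
over-representation test per supplied gene set (`P[X >= k]`), BH-corrected
across terms, with the universe defaulting to all genes of the background
ceRNA network. No GO-DAG traversal or term-ancestry propagation is
performed — the collection is whatever GMT the user supplies.

## EC-specific circuits

The EC stage consumes a program collection (by default emulating 13 EC
programs of 300 genes each, supplied as GMT). Genes present in at least
`min_program_count` programs (default 6 of 13) are the *common program
genes* — recurrent actors across EC pathways. Risk-network triplets are kept
when their gene is a common program gene **and** their miRNA is on the
curated disease-miRNA list (a conjunctive filter); surviving chains are
annotated with the programs containing their gene and duplicated once per
inside-variant on their circRNA. The restriction to risk-network (rather
than global) triplets is the default because the chains are meant as
disease-risk hypotheses; it is a one-line change to run from the global
network instead.

## The synthetic-data generator

Every stage is testable without database downloads because the generator
emits a complete, internally consistent bundle with planted truth:

* **Interactome** — planted (circRNA, gene) pairs wired through dedicated
  shared miRNAs (never reused across planted pairs), plus independent
  Bernoulli background edges; all emitted confidences are drawn from
  U(0.31, 1) so wiring survives the default filter. With zero background the
  enumeration stage must recover exactly the planted pairs.
* **Genome and variants** — non-overlapping features on one or more
  chromosomes; a stated number of variants planted strictly inside distinct
  circRNAs, the rest placed uniformly outside every circRNA (rejection
  sampling), so the inside set is exact by construction.
* **Expression** — Gaussian noise on the log2 scale around per-feature
  baselines; planted features shift the case mean by `+/- effect_log2` with
  randomized sign so both fold-change tails are exercised. Defaults
  `effect_log2 = 2`, `noise_sd = 0.5` represent a strong (4 noise-SD,
  4-fold) microarray effect. Negative-binomial count simulation is a
  non-goal: the published analyses operate downstream of log2
  transformation.
* **Programs** — designated common genes placed in at least
  `min_program_count` programs, all other members capped below the
  threshold, so the frequency filter recovers exactly the designated set.

The `"paper"` preset mirrors the shape of the study inputs: 500 circRNAs x
300 miRNAs x 10,000 genes with background edge probability 0.05 and 50
planted pairs; 307 GWAS variants on a 22-chromosome genome with ±500 kb
windows and 2 variants planted inside circRNAs; circRNA expression with
24 case / 7 control samples and mRNA expression with 6 case / 9 control
samples; 13 programs x 300 genes with 20 designated common genes; and
curated lists of 29 circRNAs, 60 miRNAs and 54 genes (the miRNA list is
scaled to the 300-miRNA universe). The `"small"` preset is the same design
at unit-test scale. What the generator does **not** emulate: realistic
degree distributions of curated interactomes, platform/batch artifacts,
linkage disequilibrium among variants, and correlated expression — so green
tests demonstrate algorithmic correctness and calibration under the stated
model, not performance on real database snapshots.

```{r, eval = FALSE}
run <- run_pipeline(cerna_config(rng_seed = 7L),
                    out_dir = "run_out", synthetic = TRUE, preset = "paper")
print(run)
```

## Numerical and reproducibility choices

* All thresholds are strict inequalities exactly as stated above; ties at a
  threshold are excluded.
* Every stochastic stage derives its stream from one integer seed; a run
  with identical seed, parameters and inputs is byte-identical (outputs are
  plain text with fixed formatting, and the run manifest records md5
  checksums of every input and output). The manifest deliberately omits
  timestamps so that manifests, not just data files, reproduce exactly.
* All stage outputs are UTF-8, tab-delimited, LF-terminated text; networks
  additionally export as GraphML for Cytoscape-style viewers.
* Degenerate inputs are defined rather than accidental: empty interaction
  tables produce empty maps and empty pair sets; a window of 0 reduces the
  window rule to containment; `min_program_count` above the program count
  yields an empty common-gene set; report sections with zero results render
  explicit zeros.

Test problem sizes were chosen to keep the default suite in the minutes
range while still exercising study-shaped inputs once: oracle equivalence
runs on 200 random instances per rule, differential-expression calibration
on 200 null replicates of 1,000 features, and the end-to-end determinism
check runs the full `"paper"` preset twice.

## Known limitations

* The DE engine is an ordinary Welch t; published re-analyses of the
  underlying cohorts may have used moderated statistics, so DE counts on
  real data will differ.
* Proximity mapping is purely positional: no LD expansion, eQTL
  colocalization or fine-mapping.
* Enrichment treats gene sets as flat and independent.
* The variant-attachment rule requires containment; regulatory variants
  acting at a distance are visible in the proximity table but not attached
  to chains.
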