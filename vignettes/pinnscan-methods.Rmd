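---
title: "Methods: conservation and differentiation scans on multi-species alignments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conservation and differentiation scans on multi-species alignments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

pinnscan implements a comparative genome scan built on a reference-anchored
multi-species whole-genome alignment, modelled on the kind of analysis run
across the eleven pinniped genomes: a neutral phylogeny fitted from
non-coding windows, per-column GERP rejected-substitution (RS) conservation
scores, haploid FST between the two pinniped families (otariids vs
phocids, walrus excluded), sliding-window aggregation with coverage-based
eligibility filters and percentile outlier peaks, elim-Fisher GO enrichment
on top-percentile BUSCO sets, and synteny-based anchoring of assembly
scaffolds into mega-scaffolds. This vignette documents the models, the
parameters that matter, the numerical choices, and what the synthetic data
generator does and does not emulate.

## Alignment model and coordinates

All coordinates are 0-based and half-open internally; only the VCF and AGP
writers emit 1-based positions. MAF blocks are normalized at parse time:
sequence is case-folded, rows on the minus strand are reverse-complemented
into reference orientation, and duplicated species rows keep the first
occurrence (the analysis operates on single-copy orthologous columns).
Both `-` and `N` are treated as "species absent" at a column, since
neither carries character-state information; alignment depth therefore
counts the reference genome itself, so with 11 genomes the neutral-window
depth filter of `n_species - 1 = 10` means "at most one genome missing".
Columns that are insertions relative to the reference are skipped: every
downstream track is indexed by reference position.

## Neutral tree

Putatively neutral sequence is taken from fixed-length windows (defaults:
5,000 windows of 1 kb) that exclude annotated CDS entirely (a 1 bp overlap
disqualifies a placement) and meet the depth threshold at every position.
Windows are sampled without overlap to avoid pseudo-replication in the
branch-length fit. The sampler draws start positions uniformly over the
admissible placements, where a placement is admissible if taking it still
leaves enough packing capacity for the remaining windows; this makes the
sampler exact in the tight case (eligible length equal to `n * length`
forces the unique tiling) while remaining uniform in the ample case.

Branch lengths are fitted on the fixed topology by maximum likelihood
under JC69 (HKY85 optional), with Felsenstein pruning vectorized over site
patterns. Missing taxa at a site are marginalized (a vector of ones), not
dropped. The optimizer is deterministic: all lengths start at 0.05
substitutions/site and each branch in turn is optimized by 1-D bounded
search on [0, 10], sweeping until the relative log-likelihood improvement
falls below 1e-6 (at most 100 sweeps); a sweep never decreases the
likelihood because a candidate update is only accepted when it improves
it. JC69 is the default because the original pipeline's model is not
constrained by the analysis (scores are used relatively, not absolutely)
and it keeps every oracle closed-form. Note that on a rooted bifurcating
tree the two branches incident to the root are not separately identifiable
under a reversible model — only their sum is — so recovery checks use
unrooted (trifurcating-root) parameterizations.

## GERP RS scores

At each reference position with at least `min_coverage = 3` species
present, the neutral tree is projected onto the present species (degree-2
nodes collapsed, branch lengths summed). The projected total length
`T_projected` is the expected number of neutral substitutions; a per-column
rate multiplier `r` is estimated by ML under the same substitution model,
and

```
RS = T_projected * (1 - r_hat)
```

Positive RS indicates rejected substitutions (constraint), negative RS
acceleration; negative values are retained. The total neutral tree length
is the upper bound of attainable RS. A column whose present species all
carry the same base sits at the `r_hat = 0` boundary and scores exactly
`RS = T_projected`. Scoring is memoized on the (present-species set, base
pattern) pair, which makes genome-scale scans fast because a shallow
alignment repeats a small set of column patterns.

Two numerical caveats are deliberate and documented rather than hidden:

* **The `r_max` cap.** The rate multiplier is bounded (default 5,
  flagged in the output when hit). At the pinniped tree depth (total
  length ~0.086) a single observed substitution corresponds to
  `r ~ 1/0.086 ~ 12`, so the default cap binds on essentially every
  variant column and truncates the "observed" estimate. Users scanning
  shallow alignments who want uncapped acceleration estimates should
  raise `r_max` to well above `1/total_length`.
* **Per-column ML is not mean-calibrated.** Averaged over neutral sites,
  the per-column ML estimate of observed substitutions does not equal the
  neutral expectation: with the cap released the estimator overshoots on
  variant columns (Jensen-type bias of a per-site MLE), leaving the mean
  neutral RS near -0.1 x tree length across the depths we simulate, and
  with the default cap at shallow depth the truncation dominates and the
  mean is positive. Rank-based uses of RS (windows, percentile outliers,
  top-BUSCO sets) are unaffected, which is how the scores are used here;
  the per-site mean should not be interpreted as an unbiased substitution
  deficit. The test suite pins this behaviour: conserved-limit exactness
  and the tree-length bound hold exactly, monotonicity in the simulated
  rate holds strictly, and the mean-zero calibration check is asserted at
  the idealized tolerance and documented as failing for this estimator.

## SNPs and haploid FST

Each aligned genome contributes one haploid allele call per reference
position; any column where a called species differs from the reference
base yields a SNP record (multiallelic sites are flagged, kept in the VCF,
and excluded from FST). Between the two families we use a Hudson-type
estimator adapted to haploid samples, with clade sizes `n1, n2` and
alternate-allele frequencies `p1, p2`:

```
num = (p1 - p2)^2 - p1 (1 - p1)/(n1 - 1) - p2 (1 - p2)/(n2 - 1)
den = p1 (1 - p2) + p2 (1 - p1)
FST = num / den        (undefined when den = 0)
```

This is the one deliberate estimator substitution in the package: the
haploid-patched Weir-Cockerham variant used in the original analysis is
not printed anywhere in a reproducible form, while the Hudson ratio is
well-defined for small haploid samples and its sample-size correction
makes singletons contribute exactly zero. Window-level conclusions are
rank-based and robust to this choice. Sites need at least two non-missing
calls per clade; fixed inter-family differences give FST = 1 exactly, and
negative per-site values are retained in averages. Per-site ratio
averaging (the default, matching how the scores are averaged into
windows) carries the usual small negative bias at intermediate allele
frequencies; a permutation null over exchangeable species centres within
±0.02 of zero.

## Windows, filters and peaks

GERP and FST are averaged within broad (50 kb / 25 kb step) and fine
(10 kb / 5 kb) sliding windows and within complete-BUSCO intervals.
Windows start at multiples of the step; a final truncated window is kept
and flagged, and all means use the true window width. Coverage summaries
record the mean depth and the fraction of positions with >= 4 genomes
overall and >= 2 genomes within each family. The outlier analysis is
restricted to windows with the family coverage fraction >= 50% for *both*
families and SNP density strictly exceeding 1%; BUSCO universes for
enrichment use mean family depth >= 2 and SNP density >= 0.01 (inclusive,
"a minimum of 1 SNP per 100 bp"). Percentiles are type-7
(linear-interpolation) quantiles throughout; outlier windows are those
strictly above the 99.99th percentile, merged into peaks when their
intervals overlap or touch (the minimal reproducible delimitation rule;
the original study does not describe one). With few eligible windows a
percentile threshold is unstable, so a warning is emitted below 100.

## GO enrichment

The ontology is reduced to its `is_a` DAG (obsolete terms dropped, cycles
refused), annotations are propagated to all ancestors, and terms with
fewer than `min_node_size = 5` annotated universe BUSCOs are discarded.
Study sets are the BUSCOs at or above the 99th percentile of mean RS or
mean FST within the universe. Terms are tested deepest-first with a
one-sided Fisher exact test (hypergeometric upper tail); when a term's p
falls below `elim_alpha = 0.01` (the conventional elim cutoff; the
original analysis names the algorithm but not the cutoff) its annotated
genes are removed from all ancestors' counts before those are tested.
With `elim_alpha = 0` the procedure reduces exactly to the classic
per-term Fisher test, which is how the implementation is cross-checked.
Namespaces are tested separately, biological process by default. The top
10 terms are reported, ties broken by larger study count then term id.

## Scaffold anchoring

Only the 45 largest query scaffolds are considered for concatenation. Per
query and target, coverage is the union of query intervals aligned to that
target divided by query length — union rather than summed hit length so
that fractions cannot exceed 1 — and a query is anchored when its best
target strictly exceeds 33% coverage and strictly beats every other
target (ties unassign). Within a target group, queries are ordered by the
length-weighted mean target coordinate of their hits and oriented by the
strand carrying the majority of aligned length (ties +, then query name);
this deterministic heuristic replaces the interactive ordering/visual
checks of the original workflow and is flagged in the liftover header.
Groups are joined with 100-bp N gaps (AGP `U` rows: scaffold gap, linkage
yes, evidence align_genus); unassigned scaffolds are carried over
unchanged.

## Synthetic data generator

`simulation_config()` defaults define the emulated study: the 11-taxon
pinniped-like topology with branch lengths totalling 0.086
substitutions/site, the fur seal as reference, four otariids vs six
phocids with the walrus excluded, 5 conserved blocks covering ~5% of the
sequence at rate multiplier 0.1, clade-fixed differentiated sites at
frequency 0.001, and block-level dropout of ~8% of the sequence per
non-reference species (emulating unaligned regions). Sequences evolve
site-independently under JC69 via the closed-form transition
probabilities; there are no indels, so columns are trivially homologous.
Differentiated sites are *forced*, not evolved — a stress fixture
guaranteeing truth labels, not a coalescent model; the excluded walrus
keeps its evolved state there, so about half of the planted sites are
triallelic and excluded from FST exactly as a third lineage would cause
in real data. Everything is byte-deterministic under the config seed.

Because the generator omits indels, alignment error, paralogy,
rearrangement, repeat content and coalescent variance, passing tests
demonstrate the correctness of the computations on clean columns — not
robustness to aligner artifacts.

## Problem sizes used in checks

The packaged checks run at desk scale, chosen so each exercises the logic
it targets: likelihood oracles on <= 5-leaf trees (500 random columns
against exhaustive enumeration, tolerance 1e-9); branch-length recovery on
100 kb; neutral calibration and rate monotonicity on 10,000 sites;
permutation-null FST on ~25,000 segregating sites; sampler defaults
(5,000 x 1 kb) on a 5.6 Mb four-taxon alignment; enrichment power on 100
replicates of a 1,000-BUSCO universe; anchoring recovery on 30-fragment
shatters. The bundled acceptance script runs the full pipeline on a
500 kb eleven-taxon study with 300 x 500 bp neutral windows.
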