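---
title: "Classifying hybrid expression patterns and attributing biomass heterosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying hybrid expression patterns and attributing biomass heterosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybex)
```

## The question hybex answers

F1 hybrids of two cotton species — upland cotton (*Gossypium hirsutum*, here
GH) and island cotton (*G. barbadense*, GB) — show strong early-seedling
biomass vigor (heterosis): taller plants, larger leaves, more fresh and dry
mass than either parent. One route to explaining that vigor is to ask, gene
by gene, how the hybrid's expression level relates to the two parents'. If a
hybrid transcript sits *between* its parents, the gene behaves additively;
if it is statistically indistinguishable from one parent but not the other,
it shows expression-level dominance (ELD); if it is significantly above or
below *both* parents, it is transgressively up- or down-regulated (TUR /
TDR) — the expression signature of overdominance. The relative weight of
these classes, and how it differs between the reciprocal crosses
(HB = GH x GB, BH = GB x HB), is the quantity of interest.

hybex implements that analysis as a reusable, tested pipeline: homolog
pairing between the two parental genomes, count-based differential
expression, the twelve-bin pattern classifier, pattern proportions and
cross-stage intersections, phenotype heterosis indices, and term
enrichment — together with a synthetic-data generator that plants known
pattern truth so every step can be validated end to end.

## The classifier

Each homolog pair, at each developmental stage and for each hybrid, carries
three ternary differential-expression calls:

* `hb` — GB vs GH (up means GB higher),
* `fh` — hybrid vs GH (up means hybrid higher),
* `fb` — hybrid vs GB (up means hybrid higher).

`classify_bins()` maps the 27 possible call combinations onto twelve
Roman-numeral bins, a `conserved` outcome (all three `ns`), or `ambiguous`.
The bins collapse onto five categories:

| category | bins | meaning |
|---|---|---|
| Additive | I, XII | hybrid strictly between two differing parents |
| ELD-H | IV, IX | hybrid indistinguishable from GH, differing from GB |
| ELD-B | II, XI | hybrid indistinguishable from GB, differing from GH |
| TUR | V, VI, VIII | hybrid above both parents |
| TDR | III, VII, X | hybrid below both parents |

The category memberships are fixed; the within-category sub-bin conditions
are this package's canonical decision table, chosen to be symmetry
consistent: swapping the two parents (negate `hb`, exchange `fh`/`fb`) maps
I–XII, II–IV, XI–IX, VI–VIII, III–X onto each other and fixes V and VII,
and negating both hybrid comparisons maps the three TUR bins bijectively
onto the three TDR bins. Both bijections are asserted exhaustively in the
test suite, which is a stronger and more portable validation than
transcribing a schematic figure.

Fourteen of the 27 combinations are internally inconsistent (for example,
parents differing while the hybrid differs from neither) and are reported
as `ambiguous`, never silently dropped. `pattern_proportions()` defaults to
percentages over pairs assigned a Roman-numeral bin; the `"all"`
denominator is available when ambiguous and conserved pairs should count.

```{r}
classify_bins("up", "up", "up")       # above both parents: bin VI
bin_to_category(classify_bins("up", "up", "up"))
```

## The differential-expression engine

The three pairwise calls come from a deliberately closed-form
negative-binomial (NB) engine, every stage of which is checkable by hand:

* **Size factors** — median-of-ratios: for library *j*, the median over
  all-positive genes of count divided by the gene's geometric mean across
  libraries. The median is taken on the ratio scale, exactly as defined.
* **Dispersion** — per gene, the method-of-moments estimate
  `max(0, (var - mean)/mean^2)` pooled across replicated groups, shrunk
  50/50 toward a lowess trend of log10 dispersion over log10 mean, floored
  at 1e-8. With two replicates per group the raw estimate is very noisy;
  the trend carries most of the information, which is the standard remedy
  at this design size.
* **Wald test** — `log2fc = log2((mean_b + 0.5)/(mean_a + 0.5))` on
  normalized group means (the 0.5 pseudo-count stabilises zeros), with a
  delta-method standard error from the NB variance `mu + d*mu^2`, and a
  two-sided normal p-value. Groups that are all-zero on both sides return
  p = 1.
* **Correction and call** — Benjamini–Hochberg across genes;
  `up`/`down` requires both `|log2fc| > 1` and adjusted p below 0.05
  (both thresholds configurable).

A moment-based Wald test was chosen over a full GLM fit on purpose: it
keeps the engine dependency-light and every number reproducible with a
pocket calculator, at the cost of two known approximations. First, its
p-values track an exact Poisson rate test only asymptotically (the test
suite checks agreement in the moderate-significance regime at vanishing
dispersion). Second, rescaling one library and its depth by *k* is absorbed
by the size factors only up to a `k^(1/m)` drift of the geometric-mean
reference (*m* libraries), so genes sitting exactly on a decision boundary
can flip calls under rescaling; the suite asserts that only boundary genes
ever do. Null calibration is what matters for the classifier and is tested
directly: on 5,000 all-null NB genes at the study's 2-replicate design, the
fraction of adjusted-significant calls stays within Monte-Carlo error of
the nominal rate.

"Expressed" genes (the enrichment population) are those reaching
FPKM >= 1 (`count * 1e9 / (length * mapped_total)`) in at least one
library of a material-stage; the cutoff is configurable.

## Homolog pairing

`reciprocal_best_hits()` consumes two hit tables in the standard 12-column
tabular alignment format. Best hits are computed over the *full* tables
(highest bitscore; ties by lower E-value, then higher identity, then
lexicographic subject id; one row per query–subject combination), pairs
must be mutual best hits, and both winning rows must pass the filters:
E-value below 1e-5 and identity at least 90%. Applying the filters to the
winning rows rather than before the best-hit search makes the screen
monotone — tightening a threshold can only remove pairs — which the test
suite asserts alongside equivalence with an exhaustive brute-force
implementation. The 90% criterion is interpreted as alignment identity
(the `pident` column); an optional coverage filter exists but defaults to
off, since the source criterion does not specify a unit.

## The synthetic-data generator

The generator reproduces the study design: 4 materials (GH, GB, HB, BH) x
3 stages (cotyledon, one-leaf, trefoil) x 2 biological replicates = 24
libraries. Its defaults are the package's fixed study conditions:

* 6,000 homolog pairs; nominal depth 1e6 with log-normal(0, 0.1)
  per-library depth multipliers, so size factors are non-trivial;
* NB dispersion 0.05 — a typical value for well-replicated plant bulk
  RNA-seq;
* planted log2 effect 2 between adjacent expression levels, the
  "clearly differential" regime the classifier is designed for;
* category mix 10/15/15/35/25 (Additive/ELD-H/ELD-B/TUR/TDR) over
  non-conserved pairs and 30% conserved pairs — transgressive-dominated,
  as in the motivating system;
* base (low-level) expression drawn log-uniformly on 25–250 expected
  counts, spanning weakly to strongly expressed genes.

Planted means per bin form a geometric ladder low, low·2^e, low·2^(2e)
arranged to satisfy the bin's order relations; a machine check in the test
suite pushes every planted triple back through the decision table and
requires it to reproduce the planted bin. Pattern assignment is per stage
by default, so a pair can change bins across development — the cross-stage
intersection analysis depends on exactly that.

Hybrid expression is emitted per homeolog copy (an even split by default)
*and* as the pair-level sum, and the analysis defaults to the sum: each
parent contributes one copy, so the summed signal is the only
depth-comparable pair-level quantity. A consequence worth knowing: the sum
of two independent NB halves has variance `mu + d*mu^2/2`, mildly less
dispersed than a single NB draw at the same mean.

What the generator does *not* emulate: GC or length bias, batch effects,
correlated genes, multi-mapping ambiguity between subgenomes, or any
nucleotide-level process. Passing recovery tests therefore demonstrates
that the statistical machinery is correct under its own model, not that
real cotton data would classify with the same accuracy.

Phenotypes are generated by solving for parent means that realise the
planted mid-parent and over-parent heterosis exactly (GH anchored at 100
units, GB the high parent — matching the system, where island cotton is
the better early-biomass parent), then adding per-plant Gaussian noise;
six plants per material is the default, as in the motivating design.
Planted OPH above planted MPH is rejected: for positive trait means
OPH <= MPH algebraically.

## Heterosis indices and enrichment

`mph()` and `oph()` are the standard percent indices
`100*(F1 - meanP)/meanP` and `100*(F1 - bestP)/bestP`; the high-parent
comparison uses Student's pooled-variance t-test (`welch = TRUE` switches
to the unpooled form), with `**`/`*` at p < 0.01 / p < 0.05.
`heterosis_timecourse()` applies these per hybrid x trait x day and flags
the day of peak OPH. `ddct()` implements 2^-ddCt relative quantification
for qPCR validation data.

`hypergeom_enrich()` tests term over-representation with the upper-tail
hypergeometric probability and BH correction; the population defaults, in
the pipeline, to expressed homolog pairs rather than a whole genome —
the comparative framing only ever sees paired genes. "Rich factor" is
k/K (study genes in the term over population genes in the term), the
prevailing convention; k/n is available behind a flag. `top_terms()`
reproduces the top-50-pool, top-15-by-(FDR, rich factor) selection with a
deterministic term-id tie-break.

## Numerical choices and degenerate inputs

* Ternary-call gates use strict inequalities (`log2fc > 1`,
  `padj < 0.05`), matching the stated thresholds.
* All-zero comparisons return p = 1 and a `conserved`-compatible `ns`.
* Size factors fall back to total-count ratios (with a warning) when no
  gene is all-positive; unreplicated designs get a fixed prior dispersion
  of 0.1 with a warning rather than an error.
* Every generator takes one integer seed, restores the caller's RNG
  state, and is bit-reproducible; the pipeline derives stage seeds from
  its master seed by fixed offsets, so a run manifest (seed + thresholds)
  determines every output byte.
* Tie-breaks (best hits, top terms) always end in a lexicographic id
  comparison so results are stable across platforms.

## Problem sizes used in validation

The test suite validates category recovery on 6,000 pairs x 3 stages x 2
hybrids at the default conditions (accuracy on non-conserved pairs is
required to reach 90%; observed values are well above), null calibration
on 5,000 all-null genes, heterosis recovery over 200 simulated seasons of
6 plants, and the brute-force oracle equivalences on small instances
(hit tables up to 50 rows, universes up to 30 genes, id sets up to 100).
These sizes give stable proportions while keeping a full run in well under
a minute.

## Known limitations

* The Wald-on-moments engine is approximate at very low counts and
  exactly two replicates; a likelihood-based NB fit would be more
  efficient but is deliberately out of scope.
* ELD calls inherit the usual caveat of accept-the-null reasoning: with
  two replicates, "indistinguishable from one parent" partly reflects low
  power.
* The pattern taxonomy assumes the three comparisons are mutually
  consistent; the 14 inconsistent combinations are surfaced as
  `ambiguous` and excluded from default proportions.
* Enrichment treats terms as flat labels; no term-graph propagation.
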