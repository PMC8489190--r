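---
title: "Methods: lattice search for hierarchy-based anonymization"
author: "latticeanon"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lattice search for hierarchy-based anonymization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeanon)
```

## The anonymization problem

Releasing biomedical microdata — one row per person, attributes such as age,
sex, or postal code — risks re-identification even after names and IDs are
removed: combinations of seemingly harmless *quasi-identifiers* are often
unique. `latticeanon` mitigates this by **full-domain generalization** plus
**record suppression**. For each quasi-identifier the user supplies a
generalization hierarchy: level 0 holds the original values and each higher
level coarsens them (age `34` → `30-39` → `*`). A *generalization scheme*
`g = (g_1, …, g_m)` picks one level per attribute; applied globally it
recodes every record identically. Records that still violate the privacy
model afterwards have their quasi-identifier cells replaced by the
suppression token `*`.

The space of schemes is the lattice `{0..L_1} × … × {0..L_m}` ordered
componentwise, of size `∏(L_i + 1)` — tens of trillions of schemes for
realistic 20–30-attribute datasets, which is why heuristic search matters.

## Privacy models

**k-anonymity.** Records with identical generalized quasi-identifier tuples
form *equivalence classes*; a dataset is k-anonymous when every class has at
least `k` members. We follow the common recommendation `k = 5` as the default
of `anonymize()`. Enforcement is exact: precisely the records in classes of
size `< k` are suppressed.

**Population uniqueness.** A weaker, statistical model: the estimated
fraction of *population* records unique on the quasi-identifiers must not
exceed a threshold (typically 1%). The dataset is treated as a sample with
known sampling fraction π. We fit Pitman's two-parameter Poisson–Dirichlet
model PD(α, θ) to the sample's class-size histogram by the method of
moments: (θ, α) are chosen so that the expected number of classes and of
singleton classes at the sample size match the observed counts `u` and
`u1`. With the rising factorial `x^(r) = Γ(x+r)/Γ(x)`,

* `E K_n = (θ/α) ((θ+α)^(n) / θ^(n) − 1)` (for α > 0; the Ewens limit
  `θ(ψ(θ+n) − ψ(θ))` at α = 0), and
* `E K_{n,1} = n (θ+α)^(n−1) / (θ+1)^(n−1)`.

The estimate extrapolates the fit to the population size `N = round(n/π)`
as `E K_{N,1} / N`. Two cases are exact by construction: π = 1 returns the
sample-unique fraction `u1/n`, and a histogram with no singletons returns 0.

*Numerics.* All expectations use log-gamma arithmetic, rearranged so every
`lgamma` argument stays positive throughout the admissible box
`0 ≤ α < 1`, `θ > −α`. The two-equation system is solved by profiling: for
each α, `E K_n = u` is solved for θ by Brent root-finding (the expectation
is monotone in θ), and α is then found by a one-dimensional Brent root on
the singleton equation, bracketed by a sign-change scan over a fixed α grid
(step 0.05, endpoints 0 and 1 − 10⁻⁶ — staying off 1 keeps the log-gamma
terms well conditioned). Residual tolerance is 1e−9 with at most 200
iterations per root. Degenerate histograms (no singletons, all singletons,
no sign change in the box) never raise an error — the searches evaluate
thousands of candidate schemes and must not abort; instead the fit falls
back to α = 0 with θ matched to the class count alone and is flagged
`converged = FALSE`.

When suppression must reduce population uniqueness, whole classes are
removed in ascending order of class size (ties by first occurrence) until
the estimate meets the threshold. The model itself does not dictate which
records to drop; removing the smallest classes first targets the sample
uniques that drive the estimate while discarding the fewest records.

## Output quality: granularity

Fitness of a scheme is the **granularity** of its output after suppression:
each quasi-identifier cell loses `(leaves(v) − 1)/(D − 1)`, where
`leaves(v)` counts the level-0 values covered by the cell's generalized
value `v` and `D` is the attribute's leaf count (loss 0 when `D = 1`); a
suppressed cell loses 1. The score is `100 × (1 − mean cell loss)`: 100%
for untouched data, 0% when everything is removed. Suppressed records stay
in the denominator, so suppression is penalized by the score itself and no
separate suppression limit is imposed — up to 100% of records may be
suppressed, and an empty output trivially satisfies any privacy model at
quality 0.

## Search algorithms

All four searches optimize the same fitness — post-suppression granularity —
memoize evaluated schemes within a run, and break every tie toward the
lexicographically smallest level vector, which makes results reproducible
bit for bit.

* **Exhaustive** enumerates the whole lattice (refused above a configurable
  cap, default 100,000 schemes). It is the oracle the heuristics are tested
  against.
* **Greedy best-first, bottom-up and top-down** start at the bottom (no
  generalization) or top (all roots) and repeatedly expand the best
  evaluated-but-unexpanded scheme, evaluating its immediate up- (resp.
  down-) neighbours. Run to exhaustion they necessarily evaluate every
  scheme and hence return the exhaustive optimum; under a budget they
  return the incumbent. Budgets are checked between evaluations, never
  inside one.
* **Genetic** evolves two subpopulations of schemes; genes are
  per-attribute levels. Subpopulation 1 is seeded with a deterministic
  *triangle pattern* — row `j` sets the first `j` genes to their maximum
  and the rest to 0, ascending from the all-zero row — and filled with
  uniform-random schemes; subpopulation 2 is fully random. The pattern's
  row set is pinned here (cumulative-max rows including the all-zero row)
  and unit-tested, as published descriptions of it are pictorial only.

Per generation each subpopulation is sorted by fitness (descending, lex
tie-break) and refilled: the elite fraction is copied unchanged; the
crossover fraction consists of children of two distinct parents drawn from
the production fraction with probability proportional to the rank weight
`p − rank + 1`, each gene inherited from a uniformly chosen parent; the
remainder are mutants of uniformly chosen individuals with between 1 and
`max(1, round(0.05·m))` genes resampled uniformly over their full level
range (the current value included, so a mutation may be a silent no-op on a
gene — the simplest consistent reading of "altering" a gene). Every
`immigration_interval` generations the top `round(0.2·s)` of each
subpopulation replace the bottom of the other, both directions computed
from the pre-swap state. Fraction-derived counts use round-half-up with
floors of 1 elite and 2 producers, so tiny subpopulations remain
well-formed.

Defaults (`ga_config()`): elite 0.2, crossover 0.4, production 0.2,
mutation probability 0.05, immigration 0.2 every 10 iterations, 50
iterations, subpopulation size 50. These are the standard published
settings for this family of anonymization GAs; the production fraction of
0.2 (rather than the 0.8 sometimes suggested) is the value reported to work
better on both low- and high-dimensional data.

A single seeded generator drives each randomized run; the seed is a
required, logged configuration item, and the caller's R random stream is
saved and restored around every run.

## Local recoding

Global recoding wastes information when a few outlier records force either
heavy generalization or their own suppression. Local recoding applies
different schemes to different record subsets via an iterative partition
loop: run the inner search on the current records, emit the non-suppressed
ones with the scheme found, and feed the suppressed remainder (with
original values) into the next iteration. The loop stops when nothing
remains, an iteration rescues zero records, or after `iterations` rounds
(default 100); leftovers are suppressed. This "suppressed remainder becomes
the next input" rule is the simplest partition mechanism consistent with
applying different schemes to different partitions, and it makes iteration
1 with `iterations = 1` coincide exactly with global recoding.

Each emitted batch satisfies the privacy model on its own. For k-anonymity
the union is also k-anonymous: batches emitted under different schemes can
only merge classes, never split them (records from different batches that
happen to share a generalized tuple enlarge a class). For population
uniqueness no such union guarantee is claimed; the combined estimate can be
recomputed on the final output via `equivalence_classes()` +
`estimate_population_uniqueness()` and reported alongside the per-batch
guarantees.

## Synthetic data and the benchmark harness

`generate_dataset()` emulates categorical survey microdata: per attribute a
domain of `D` zero-padded codes, drawn uniformly or from a Zipf law
(default skew `s = 1` — the long-tailed mix of common and rare values that
makes suppression behaviour non-trivial), with a balanced hierarchy whose
level `ℓ` groups `b^ℓ` consecutive codes (top level `*`, height
`⌈log_b D⌉`). What it does *not* emulate: correlated attributes, semantic
hierarchies of uneven depth, missing-data patterns, or numeric attributes.
Passing tests on this generator therefore demonstrates algorithmic
correctness and the qualitative ranking of the searches, not quality
numbers transferable to any particular real dataset.

`run_benchmark()` repeats (algorithm × model × budget) combinations with
consecutive seeds and collects a long-format table; budgets are expressed
in evaluations as well as seconds so results are hardware-independent,
and timings are recorded but never asserted.

Problem sizes used by the test suite were chosen to exercise every code
path at desk scale: oracle-equivalence checks run 100 random instances with
2–5 quasi-identifiers, hierarchy heights ≤ 3 and ≤ 200 records; the
high-dimensional comparison uses 20 attributes with domains 8–32, Zipf
skew 1, 400 records, `k = 5`, 150-evaluation budgets and 10 seeded runs —
at this scale the bottom-up search is still stuck in the fully suppressed
lower region of the lattice while top-down and genetic have found feasible
schemes, reproducing the qualitative high-dimensional ranking. Pitman
validation simulates partitions of 5,000 records (25 replicates) and Zipf
populations of 10,000 individuals sampled at 10% (50 replicates).

## Numerical and representational choices

* **Exact lattice sizes.** Solution spaces exceed 2⁴⁶ schemes, so
  `lattice_size()` multiplies in an internal arbitrary-precision base-10⁴
  representation, returning a double when exact below 2⁵³ and an exact
  decimal string otherwise.
* **String-exact cells.** Cells are compared verbatim — no trimming, case
  folding, or type coercion; the empty string is an ordinary value that
  must appear among the hierarchy leaves. Determinism outweighs
  convenience here.
* **Hierarchy file dialect.** One delimited file per attribute, each row a
  leaf-to-root path, no header, default delimiter `;` — the de-facto
  hierarchy-CSV convention of existing anonymization tooling. Microdata use
  RFC-4180-style CSV with a header and configurable delimiter; both
  round-trip bit-exactly.
* **Tie-breaks.** Lexicographically smallest scheme everywhere (incumbent
  selection, greedy expansion order, GA sorting).
* **Suppressed rows are kept** in the output table with `*` in every
  quasi-identifier cell, and count in the quality denominator. Whether
  suppressed records should count there is genuinely open; counting them
  makes quality continuous in the suppression fraction and is documented
  behaviour.

## Limitations

* Sub-tree (per-node) generalization, cell-level suppression,
  microaggregation and quality models other than granularity are out of
  scope; the evaluation path is factored so an alternative quality function
  is a contained change.
* The exhaustive search is plain enumeration; it deliberately omits the
  pruning machinery of optimal anonymization algorithms and is intended as
  a small-lattice oracle, not a production optimizer.
* The Pitman moment system matches class and singleton counts; estimators
  based on other statistics (e.g. Zayatz, slide negative binomial) are not
  provided.
* Population-uniqueness evaluation refits the model after each class
  removal during suppression, which is exact but makes that model markedly
  slower than k-anonymity in large searches — matching the general
  experience that statistical privacy models dominate run time.
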