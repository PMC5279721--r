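---
title: "Methods: impact hierarchies, class asymmetry and phosphorylation dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: impact hierarchies, class asymmetry and phosphorylation dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phosym)
```

This vignette documents the models and procedures implemented by `phosym`,
the assumptions behind them, the parameters that matter, and the design
choices made where the design was genuinely open.

## Impact networks and hierarchy layers

The unit of evidence is an *impact relationship*: a directed edge from an
inactivated enzyme to a protein whose phospho-peptide abundance changed in
the inactivated strain. `build_network()` treats these edges as a simple
directed graph:

* **Self-loops are dropped** before any degree computation. The layer
  definitions (below) classify nodes by whether they impact *other* enzymes
  and are targeted *by* enzymes; an enzyme regulating its own
  phosphorylation state would make a node simultaneously "impacting" and
  "targeted" by construction, and the definitions are only consistent on
  self-loop-free graphs.
* **Duplicate edges collapse to one relationship.** A screen may report
  several differential phospho-peptides for the same enzyme-target pair;
  we do not treat peptide multiplicity as evidence of a stronger
  relationship.
* Isolated identifiers supplied through `node_universe` are retained so
  that enzymes screened but without any within-class relationship appear as
  OUTGROUP rather than silently vanishing.

Two layering schemes operate on the within-class (kinase-kinase)
subnetwork:

| scheme | TOP | MID | BOT | OUTGROUP |
|---|---|---|---|---|
| simple | out > 0, in = 0 | out > 0, in > 0 | out = 0, in > 0 | out = in = 0 |
| stringent | out ≥ 2, in ≤ 1 | out ≥ 2, in ≥ 2 | out ≤ 1, in ≥ 2 | out ≤ 1, in ≤ 1 |

Both schemes are total: every node receives exactly one label, and the
package tests this partition property on random graphs. The stringent
scheme's rationale is robustness — no assignment may rest on a single
(possibly noisy) relationship. Its OUTGROUP cell (out ≤ 1 and in ≤ 1) is
implicit in the three published rules; we label those nodes OUTGROUP
explicitly to keep the partition total. Two useful consequences, both
tested as properties: stringent-TOP nodes are always simple-TOP or
simple-MID (and stringent-BOT within simple-BOT/MID), and a single spurious
incoming edge flips a simple-TOP label to MID while leaving a stringent-TOP
label (out-degree ≥ 2) unchanged.

Enzymes annotated as both writer and eraser are rejected with an explicit
error in `phosphatase_placement()`: their handling is undefined in the
hierarchy construction, and silently assigning them to either class would
bias the placement tallies. OUTGROUP enzymes stay in the assignment object;
they are excluded from one-vs-rest profiling by default (overridable with
`include_outgroup = TRUE`) rather than being removed from the partition.

`restrict_to_measured()` implements the rule that only measured
genes/proteins enter an analysis: nodes outside the measured set are
removed (with logged counts) before layering or profiling.

Phosphatases are not layered. They participate in few within-class impact
relationships and are placed relative to the kinase hierarchy by raw edge
tallies (impacted kinases per layer, phosphatase-phosphatase edges,
incoming kinase edges). Whether a published placement figure used simple or
stringent thresholds for the phosphatases' own edges is not stated
anywhere we know of; the placement table therefore reports raw counts and
leaves interpretation to the caller.

## Statistical core

All comparisons reduce to three procedures:

* **Rank-sum (Mann-Whitney U).** For total sample size ≤ 20 (always
  forceable via `exact =`), the p-value comes from the exact permutation
  distribution of the rank sum, computed by a dynamic program over the
  observed rank multiset; ties are handled with average ranks (doubled so
  sums stay integral), so the exact path is valid with ties — a case where
  the usual exact algorithms decline. Larger samples use the normal
  approximation with tie correction and a 0.5 continuity correction. The
  suite verifies the exact path against full enumeration of all
  `choose(n, n_x)` group labelings and checks that the approximation stays
  within 0.02 of the exact p-value for group sizes 5–10.
* **Fisher's exact test** on 2×2 tables, by direct enumeration of the
  hypergeometric support. The two-tailed p-value follows the
  probability-mass rule (sum over tables no more probable than the observed
  one) — the dominant convention and the one `stats::fisher.test` uses,
  which serves as an independent cross-check in the tests.
* **Spearman correlation**, with an exact permutation p-value below n = 10
  and the t approximation from there on. Constant input is an explicit
  error rather than an `NA`.

One-tailed directions are an explicit caller argument. Where a figure-style
claim fixes the direction, pass it; the default `tail = "auto"` tests in
the direction of the observed median difference, which is the natural
reading of one-tailed tests reported alongside group medians. The tail used
is recorded in every `comparison_result`. No multiple-testing correction is
applied by default (reports carry raw p-values); the banding helper
`significance_stars()` marks p < 1e-6, p < 1e-3 and p < 0.05.

Group sizes in every result are counts of non-missing values, never raw
class sizes; this "only measured entities" contract is tested explicitly.

## The class-asymmetry battery

`run_battery()` executes a configured list of comparisons between two
opposing enzyme classes: numeric metrics (abundance in ppm, half-life in
minutes, PPI degree, differential-expression perturbation counts, NGI
counts) via rank-sum on medians, flag metrics (essentiality/criticality,
responsiveness, three phospho-capacity evidence sources) via Fisher.
Versus-background rows compare a class to all protein-coding records; the
background *includes* the focal class by default, matching genome-wide
denominators, with `exclude_class = TRUE` available. Phospho-capacity is
deliberately three separate flags (curated events, phospho-peptide
evidence, conserved sites with relative residue conservation score > 95),
compared independently, because the three evidence sources have different
coverage and biases. Errors in individual comparisons are recorded in the
report row and do not stop the battery, and output ordering follows the
configuration so identical inputs give byte-identical reports.

## The synthetic-data generator

The generator exists so that every downstream stage is exercised, under
known truth, without external downloads. It emulates the *statistical
structure* of the yeast kinome/phosphatome annotation tables, not any real
gene:

* **Abundance**: log-normal, parameterized by its median — protein ppm
  values are positive and right-skewed, and published summaries give only
  medians. Default medians 30.4 ppm (kinase) and 63 ppm (phosphatase) with
  log-sd 1, i.e. the documented ~2× eraser excess.
* **Essentiality**: Bernoulli, 23% (kinase) vs 10% (phosphatase).
* **PPI degree**: negative binomial (mean 12 vs 6, size 1) — interaction
  degrees are strongly overdispersed; only rank-test outcomes are published,
  so the means encode the direction with a realistic spread.
* **Responsiveness**: zero-inflated — 34% of either class is differentially
  expressed in at least one perturbation; given responsiveness the
  perturbation count is 1 + geometric, with medians 4 (kinase) vs 2
  (phosphatase). Non-responsive genes carry `NA` counts so that count
  comparisons run among responsive genes, as in the source analyses.
* **Half-life**: log-normal, medians 33 vs 42 minutes.
* **Phospho-capacity flags**: ~40–55% for kinases vs ~8–12% for
  phosphatases across the three evidence sources; conserved-site counts are
  1 + Poisson given the flag.
* **NGIs**: 67% of kinases and 74% of phosphatases have ≥ 1; counts given
  ≥ 1 are shifted geometric with medians 2 vs 4.
* **Missingness**: per-metric missing-at-random on the numeric metrics at a
  configurable rate (default 0), since real coverage is incomplete and the
  analyses must drop unmeasured values.

A single global seed drives everything, but each class/metric pair draws
from a substream derived from the seed and a textual label
(`substream_seed()`), so adding a metric or reordering the draws does not
shift the others. The planted-network generator samples Bernoulli edges in
four strata (top→mid, top→bot, mid→bot, mid→mid) and then repairs degrees
to the specified minima so that, before noise, the simple scheme is the
exact inverse of the planted labels; spurious edges are added afterwards
from a separate substream. The degree distribution of real impact networks
is not characterized in the literature we rely on — the stratified
Bernoulli model is a stand-in with the right qualitative shape, not a
fidelity claim. Passing tests on this generator demonstrate that the
pipeline's logic is correct under its assumed statistical structure; they
do not validate the biological conclusions on real screens, whose noise,
coverage and dependence structure differ.

## Phosphorylation dynamics

The model is deliberately the linear approximation: the unphosphorylated
protein is far more abundant than its phosphorylated form and hence not
rate-limiting, so `dY^P/dt = k − p·Y^P` with kinase activity rate `k`
(amount·time⁻¹) and phosphatase activity rate `p` (time⁻¹). Units are
abstract because no physical rates are attached to the argument. Starting
from `Y^P(0) = 0` (a signal switches the kinase on), the closed form is
`Y^P(t) = (k/p)(1 − e^(−pt))`, the steady state `k/p`, and the response
time `t_1/2 = ln(2)/p` — independent of `k`. No Michaelis-Menten
saturation, substrate depletion or stochastic kinetics is modelled; those
would change the quantitative picture but not the `k`-versus-`p`
asymmetry in the linear regime.

`numeric_trajectory()` cross-validates the closed form with a fixed-step
classical Runge-Kutta (RK4) integrator whose substep count doubles until a
step halving changes no grid value by more than 1e-9 (divergence raises an
error). Arbitrary initial values are supported only numerically. The
empirical half-rise time is located by linear interpolation between the
bracketing grid points; on the default grids (≈ 1600 points over eight
response times) the interpolation error is below 1e-4 in absolute time
across the rate sweep `k, p ∈ [0.1, 10]`, which is the tolerance the tests
assert.

## Numerical and interface choices

* Exact rank-sum enumeration is limited to total n ≤ 20 by default
  (the DP is exact for any size but the approximation is already within
  a fraction of a percent there).
* Fisher's two-tailed rule uses a `1 + 1e-7` relative slack when comparing
  table probabilities to the observed one, the standard guard against
  floating-point misclassification of equal-probability tables.
* `resolve_tail()` treats exactly equal summaries as two-tailed.
* TSV is the native table dialect with `"NA"` as the missing sentinel and
  mandatory headers; identifiers are opaque strings (no organism-specific
  ID normalization). Reports are written deterministically (no timestamps)
  so reruns are byte-identical; the JSON mirror stores full-precision
  p-values plus package version, seed and a configuration hash.
* `phosphatase_group_profile()` takes the phosphatase and kinase value
  vectors directly (rather than the placement table) so the same function
  serves numeric and flag metrics; the placement table remains the source
  of the per-layer tallies.
* The package's interface is its functions plus `scripts/acceptance.R`;
  no shell subcommand wrapper is shipped, as the intended use is from R.

## Problem sizes

The test suite and the acceptance script size their simulations as follows:
200 random graphs of up to 30 nodes for the classifier-oracle and partition
properties; 50 randomized planted specifications (plus 25 in the module
tests) for noiseless recovery; 100 random cases for each enumeration-oracle
comparison; 2000 replicates at group size 12 for type-I calibration; 200
replicates of the 187-gene yeast table for direction recovery; a 10×10
logarithmic (k, p) sweep with 1601-point grids for the dynamics. These
sizes keep every Monte-Carlo margin far from its threshold (e.g. direction
recovery runs at ≈ 98–100% against a 95% bound) while the whole suite runs
in well under a minute.

## Known limitations

* Published p-values obtained on real omics tables (abundance, PPI,
  essentiality and the per-layer validations) depend on database versions
  and identifier mappings; the package reproduces their *directions* on
  synthetic data with the documented parameters and exposes the readers
  needed to re-run them on real tables, but does not bundle those tables.
* The placement of dual-annotated (writer *and* eraser) enzymes is
  rejected rather than resolved.
* The impact-network generator does not model phospho-peptide-level
  measurement noise, only enzyme-level edges.
* Spearman's exact permutation path enumerates all n! permutations and is
  only used below n = 10 by design.
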