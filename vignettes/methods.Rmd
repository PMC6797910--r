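---
title: "Methods: detecting convergent adaptation to a continuous trait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting convergent adaptation to a continuous trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`traitpcoc` asks, for every column of a protein alignment: did this site
switch to a different amino-acid preference on the branches of the phylogeny
where a continuous environmental trait (temperature, log-depth) crossed some
threshold — and did it do so on several *independent* occasions? This
vignette records the model, the tunable parameters, and the numerical and
design decisions behind the implementation, in enough detail to reimplement
it.

## Trait reconstruction

Ancestral trait values are point estimates under Brownian motion on the
fixed, rooted species tree. `reconstruct_bm()` runs a two-pass Gaussian
message-passing scheme: the upward pass combines each node's children into a
precision-weighted subtree mean (weights `1/(branch + accumulated
variance)`), the downward pass folds in the rest of the tree. For a fixed
tree this reproduces the generalized-least-squares / maximum-likelihood
marginal estimates exactly; the suite verifies agreement with the explicit
covariance-matrix solution to 1e-8 on random 10–30 tip trees. Multifurcations
are handled natively (subtrees are independent given the parent state).

Assumptions worth stating: a single Brownian rate (no Ornstein–Uhlenbeck
pull, no rate shifts), no observation error on tip traits, and no
propagation of reconstruction uncertainty — scenarios are built from point
estimates, so spurious transitions near a cutoff are possible. Zero-length
branches are replaced by `1e-8 × tree height` to keep precisions finite;
this perturbs estimates far below any reported precision.

Whether the original workflow used ML, REML or independent contrasts is not
documented; on a fixed tree these agree for the marginal estimates, which is
all that is consumed downstream.

## From a continuous trait to convergent scenarios

Node values are binned with a fixed width anchored at the minimum observed
node value: `bin(v) = floor((v − min) / w)`. The width is the analysis's
resolution knob: **1.75 °C** for temperature, **0.2 log10(m)** for depth.
The anchor is a design choice — only the bin *boundaries* matter, and
anchoring at the minimum makes them a deterministic function of the data
while exhausting the same candidate set up to deduplication.

A candidate cutoff is placed at every interior boundary
`min + k·w, k = 1 … ⌈range/w⌉ − 1`. Each cutoff binarizes every node:
the `≥ cutoff` side is convergent by default, and the orientation is
inverted whenever the root would be convergent, so the root is always
ancestral (ties at the cutoff fall on the upper side, consistent with the
binning). A branch takes its child's state; *transition branches* are the
ancestral→convergent cut edges. A convergent-to-ancestral edge (a reversion)
leaves its subtree ancestral and is **not** a transition, but a later
re-entry into the convergent state below it is counted as a new independent
transition — the most literal reading of one-directional transition
placement.

Scenarios sharing a convergent branch set are deduplicated (lowest cutoff
kept) and any scenario with fewer than `min_transitions` (default **5**)
independent transitions is dropped; requiring several independent events is
the guard against phylogenetic pseudoreplication. Enumeration is verified
against a brute-force cutoff sweep.

## The site model

Each site evolves under a one-parameter profile-driven process — the
canonical CAT-style choice: substitution events occur at rate β and draw the
new residue from the site's stationary profile π, giving
`q_ij = β π_j (i ≠ j)` with `β = 1/(1 − Σ π²)` so that one unit of branch
length is one expected substitution at stationarity. The closed form
`P(t) = e^{−βt} I + (1 − e^{−βt}) 1πᵀ` is what makes exhaustive pair search
and large bootstrap loops affordable, and it is testable against the matrix
exponential to 1e-10. A richer exchangeability (LG/WAG-modulated) or
gamma-distributed rate variation would be drop-in changes at the transition
matrix, but are deliberately out of scope: the published description
specifies only the CAT category structure, and the calibration bootstrap
absorbs much of the misspecification this simplification introduces.

Four site models share one pruning engine, differing only in per-branch
matrices. With ancestral profile π_A and convergent profile π_C:

* **null** — π_A everywhere;
* **PC** — π_C on convergent branches, no change forced;
* **OC** — π_A everywhere, transition branches conditioned on ≥1 event;
* **PCOC** — π_C on convergent branches *and* transition branches
  conditioned on ≥1 event under π_C.

Under the closed form, conditioning on at least one event makes the child
state an independent draw from the profile (`P*_ij = π_j`): the "one
change" contract is exact, not approximate. The root prior is always π_A,
matching the construction that keeps the root ancestral. Felsenstein pruning
uses the O(20) per-edge form of the closed-form matrix with per-node
rescaling against underflow; the compiled engine (Rcpp) is mirrored by a
pure-R reference implementation and both are checked against exhaustive
enumeration over all ancestral state assignments on small trees (≤ 1e-9).

`site_pp()` maximizes the null model over the K single profiles and the
PCOC model over the `K(K−1)` ordered pairs with π_A ≠ π_C, then converts
the log-likelihood gap into a posterior probability under equal 0.5/0.5
model priors: `PP = plogis(logL₁ − logL₀)`. ML pair selection (not model
averaging) is the simplest defensible reading; the chosen pair is recorded
per site so the policy can be revisited. If both log-likelihoods are `−Inf`
(possible only with zero-length branches and conflicting states) the PP is
defined as 0.5.

`scan_alignment()` gap-prunes the tree per column (suppressed unary nodes,
summed branch lengths; columns sharing a gap pattern share the work),
re-derives each scenario's transitions on the pruned tree from surviving
node ids, skips scenarios that fall below `min_transitions` there — the
pseudoreplication guard is enforced per effective tree — and records the
maximum PP across viable scenarios. Columns with fewer than 4 ungapped taxa
or no viable scenario are `skipped_gaps`; columns with max PP below
`pp_threshold` (default **0.5**) are `below_threshold` and are not
bootstrapped. One numerical subtlety: PP saturates at 1.0 in double
precision, so the argmax over scenarios is taken on the unsaturated
log-likelihood gap (PP is strictly monotone in it); the reported maximum PP
is unchanged, only tie-breaking among numerically equal PPs is affected.
After a pruning that leaves the surviving root inside a scenario's
convergent set, the root prior remains the ancestral profile — the scenario
semantics are defined on the full tree.

## Bootstrap calibration

A PP is a relative model comparison, not a controlled error rate. For each
site at or above the threshold, `calibrate_site()` reuses the site's ML
profile pair and max-PP scenario (profiles of best fit to the column, not
random pairs) and simulates on the site's gap-pruned tree:

* `n_sims` **null** columns from the ancestral profile with Dirichlet noise
  (`Dirichlet(concentration · π_A)`, default concentration **100** — mean
  π_A, per-entry s.d. ≈ √(π(1−π)/101); the knob spans "no noise" (→∞) to
  heavy noise), no scenario;
* `n_sims` **convergent** columns under the π_A/π_C pair with forced
  changes on the scenario's transition branches.

Each simulated column is re-scored by the full `site_pp()` search. The
upper threshold is the `confidence` (default **0.95**) empirical quantile
of null PPs; the lower threshold is the `1 − confidence` quantile of
convergent PPs. Quantiles use the inverse-ECDF rule (type 1): the smallest
order statistic whose ECDF reaches the level — deterministic and
conservative at the default `n_sims = 1000` (tests and the bundled study
use 200 for speed; quantile noise at 200 is ~±0.03 in the band edges).
Calls: `adaptive` iff PP ≥ upper and > lower; `non_adaptive` iff PP ≤ lower
and < upper; otherwise `unresolved`, which covers both the white gap and
any band overlap.

The Dirichlet form of the published "noise added" is a design choice (it
stays on the simplex and has the profile as its mean); its concentration is
deliberately configurable. Noise applies to the null arm only, as
described. A consequence worth knowing: even with π_C = π_A the two arms
are *not* identical generators — the convergent arm keeps its forced
transition events, which the PCOC model rewards — so a degenerate
calibration yields overlapping bands (everything between them unresolved)
rather than literally indistinguishable PP distributions. Optional
lognormal branch-length multipliers (`blen_noise_sd`, off by default) add
branch-length uncertainty to the simulations; columns are still scored on
the stated tree.

Every random step derives its stream from `config$seed` and the site index
(streams kept below 2³¹), so thresholds and calls are bit-reproducible and
independent of which other sites are processed.

## Structural-context statistics

`ordered_quantile_normalize()` maps rank r (average ranks for ties) to the
standard normal quantile at `(r − 0.5)/n`. The published method name does
not pin the offset convention; `(r − 0.5)/n` is symmetric and keeps extremes
finite, and alternatives differ only in the third decimal at realistic n.
`bfactor_anova()` models the normalized flexibility as
`~ depth * temperature` with sum-to-zero contrasts and Type III sums of
squares (via `car::Anova`). `exact_contingency_test()` enumerates all
tables with the observed margins and sums multivariate hypergeometric
probabilities ≤ the observed one (relative tolerance 1e-12; a Monte Carlo
fallback handles totals above 500). `compare_site_context()` builds
(adaptive vs non-adaptive) × class tables — the non-adaptive sites supply
the expected composition — dropping unresolved/below-threshold/skipped
sites, whose inconclusiveness is a taxon-sampling artifact, and empty
classes.

## What the synthetic generator does and does not emulate

`sim_convergence_study()` is the package's standard study: a balanced
64-tip tree with uniform 0.15 substitutions/site branches, 7 four-tip
clades (28 tips) assigned the convergent habitat, tip traits at 0 vs 10
(°C scale) with 0.5 s.d. observation noise, and an alignment of 100 planted
convergent sites (hydrophobic→charged profile pair from the bundled
10-category set) plus 400 null sites. These defaults are fixed study
conditions, not tuning knobs. The bundled profile sets are synthetic,
biochemically motivated constructions (class-concentrated profiles mixed
with the uniform distribution), *not* the empirically fitted CAT
categories; any profile TSV can be supplied instead.

The generator draws sites from the same model family the scan fits, with a
single true scenario, no indels (gap handling is exercised by separate
fixtures), no among-site rate variation, no alignment error, and a clean
trait signal. Passing tests therefore demonstrate internal correctness and
calibration under the stated model — sensitivity ≈ 0.95 and a null
adaptive-call rate ≈ 0 at the standard conditions — not robustness to model
misspecification on real transcriptome data. Problem sizes throughout the
suite (trees of 3–64 tips, 40–500 sites, 50–200 bootstrap replicates) were
chosen as the smallest sizes at which the checked properties are
informative.

## Known limitations

* Brownian motion with point estimates can misplace transitions near a
  cutoff; an OU or rate-shift trait model is a natural extension.
* The substitution model has no indel process; convergently adaptive
  insertions/deletions are invisible (gapped taxa are simply pruned).
* Profiles are taken as given, not trained on the dataset.
* No multiplicity correction is applied across sites, matching the
  published workflow; downstream users should treat per-site calls
  accordingly.
* The exhaustive pair search is O(K²) pruning passes per site and scenario;
  K = 60 is desk-scale but not transcriptome-scale in pure R — the compiled
  engine and per-gap-pattern caching are what keep the default settings
  fast.
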