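---
title: "Filter-ensemble screening for substrate-selective inhibitors: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filter-ensemble screening for substrate-selective inhibitors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the science it implements:
the classifier and its assumptions, the tunable parameters and their
defaults, what the synthetic generators do and do not emulate, the
numerical choices, and the places where the design was genuinely open and
a decision had to be made.

## The screening problem

Substrate-selective inhibition asks for a ligand that blocks an enzyme's
processing of one substrate but not of another cleaved at the same
catalytic site. For a protease whose substrates differ in length, the
strategy implemented here is ligand-based: derive from known inhibitors the
sub-structures that occupy the *distal* subsites (positions P5–P2, away
from the scissile bond), and search a purchasable library for molecules
resembling those fragments rather than whole active-site blockers. The
funnel is: fragment derivation → Tanimoto similarity screen → Lipinski
applicability domain → classifier scoring → solubility gate → candidate
tiers.

## The ISE filter-ensemble classifier

A *filter* is a conjunction of 4–5 closed intervals on distinct numeric
molecular descriptors; a molecule passes iff inside all of them. Filters
are intrinsically interpretable (each is a box in descriptor space) and a
large ensemble of them, score-averaged, behaves like a soft nearest-class
model while remaining auditable.

**Range discretisation.** Each descriptor's observed min–max over the
training fold is covered by `n_divisions = 100` grid points; each pair of
distinct points bounds a candidate closed sub-range, so there are
n(n−1)/2 = 4950 per descriptor. For each descriptor, the single sub-range
that best separates the classes is kept; this *best-range pool* (one range
per usable descriptor) is the raw material for filters. Constant
descriptors cannot carry a range and are excluded.

**The selection objective.** Filters and ranges are ranked by the Matthews
correlation coefficient. With learning sets diluted to roughly 1 active per
200 inactives, the raw-count MCC has a known pathology: its optimum over
the 4950 ranges is frequently a *low-recall micro-range* — a sliver that
captures a handful of actives with zero false positives beats the full
signal window, because with n_actives ≪ n_inactives the count-based
geometric-mean denominator rewards precision far more than recall. A
conjunction built from such slivers has almost no recall and the resulting
scores cannot rank held-out actives. The package therefore computes the
selection MCC on class-normalised proportions by default
(`ise_config(mcc_components = "proportions")`): counts are divided by their
class sizes first, which reduces algebraically to

$$\mathrm{MCC_{prop}} = \frac{\mathrm{TPR} - \mathrm{FPR}}
{\sqrt{(\mathrm{TPR}+\mathrm{FPR})(2-\mathrm{TPR}-\mathrm{FPR})}},$$

the MCC of the class-balanced confusion matrix. Under this objective the
full planted window beats any sliver, and both classes weigh equally
regardless of dilution. The literal count-based formula remains available
as `mcc_components = "counts"` and is always what the exported `mcc()`
function computes; stored filters carry their raw confusion counts so
either statistic can be recomputed from them.

**Stochastic elimination.** While the number of possible filters exceeds
`exhaustive_threshold` (10⁶), the algorithm repeats: sample
`sample_size = 50 000` random filters (sizes drawn uniformly from {4, 5}),
score them, sort by MCC, and eliminate ranges that are *biased towards
failure* — appearing more than `alpha = 2` times their expectation in the
worst `decile_fraction = 0.10` of the sample while appearing less than
`beta = 0.5` times expectation in the best decile (a range's expectation is
its total sample appearances times the decile fraction). The thresholds
follow the qualitative rule "much more than expected among the worst, much
less among the best"; both are configurable, and a minimum-evidence guard
(`min_expected = 5` expected tail appearances) skips statistically
meaningless rounds. Elimination strictly shrinks the pool; a configured
iteration bound aborts with a diagnostic if the rule stalls. With a
one-best-range-per-descriptor pool, eliminating a range retires its
descriptor — that is precisely how a 180-descriptor pool (≈1.5 × 10⁹
five-range combinations) contracts until exhaustion is feasible. For this
reason the protective guard "a descriptor whose last range would be
eliminated keeps its best range" is off by default
(`protect_descriptors = FALSE`): always-on, it would forbid every
elimination and the contraction could never happen.

**Exhaustive finish and keep rule.** Below the threshold, every remaining
combination of sizes {4, 5} is evaluated (bit-packed conjunction counting
in C++; ~10⁵–10⁶ filters per fold in well under a second). A filter is
*kept* when either criterion grants it: MCC within 20% of the top
(`mcc_fraction = 0.8`), **or** rank within the top `max_filters = 1000`.
We read the "either … or" of the keep rule as this union deliberately: the
intersection reading (both conditions at once) leaves only the handful of
near-top filters on data with few informative descriptors, which collapses
the score below to a coarse step function; the union keeps the graded
ensemble that score-averaging needs.

**Cross-validation and merging.** `build_model()` makes a seeded,
stratified `n_folds = 5` split (shuffled round-robin, so class parity per
fold is within one molecule). Each fold trains on 4/5 and scores its
held-out 1/5, so every learning-set molecule receives exactly one held-out
score. Fold ensembles are then concatenated, *duplicate-similar* filters
removed — same descriptor set and every corresponding range pair with
interval-overlap Jaccard ≥ `similar_jaccard = 0.8`; the higher-MCC copy
survives — re-ordered by MCC and re-subjected to the keep rule.

**MBI scoring.** Every filter adds its efficiency when passed and subtracts
its inefficiency when failed; the average over all filters is the molecular
bioactivity index. In the default `mbi_mode = "proportion"`, efficiency is
TP/(TP+FP) and inefficiency TN/(TN+FN), so MBI ∈ [−1, 1]. The literal-ratio
reading (TP/FP, TN/FN, add-one smoothing of zero denominators) is retained
as `mbi_mode = "raw"` for comparison, but it is unbounded and its scale is
dominated by the zero-FP filters; the bounded mode is what makes score
thresholds (0.85, 0.2, −0.97) meaningful. Which mode the original method
used cannot be decided from its description; the package makes no claim to
reproduce external MBI values numerically.

## Chemistry layer

SMILES parsing, canonicalisation, MW, logP, donor/acceptor counts, TPSA and
molar refractivity come from OpenBabel (via ChemmineOB); path fingerprints
are OpenBabel FP2 (linear fragments up to 7 atoms, 1024 bits) — the same
fingerprint family the field uses for this kind of similarity screen — with
an ECFP circular option where the OpenBabel build provides it. Donor/
acceptor conventions differ between toolkits, so the package fixes one and
documents it: donors = N/O atoms bearing at least one hydrogen, acceptors =
count of N and O atoms. A set of connectivity descriptors (atom/bond/ring
counts, aromatic fraction, rotatable bonds) is derived from the canonical
SMILES and the connection table; the full default set has 20 descriptors
and is configurable through `descriptor_spec()`, which always requires the
Lipinski four. The original modelling used a proprietary ~200-descriptor
set that cannot be reproduced exactly and is not attempted.

**Fragment cleavage.** The proline-like P1 ring is defined structurally: a
saturated 5- or 6-membered ring of one nitrogen and otherwise carbons whose
nitrogen bears an exocyclic carbonyl carbon (equivalently the substructure
patterns O=C–N1CCCC1 / O=C–N1CCCCC1 with substituents allowed). Cleavage
cuts the acyl C–N bond and keeps the carbonyl-side component; everything on
the ring side, including ring substituents, is discarded, following the
reading that substitutions beyond the ring belong to the removed P1 part.
Sites are found by direct graph analysis (ring perception plus bond-order
checks) rather than a SMARTS engine, because the available SMARTS interface
reports match counts, not atom indices; the rule object still exposes ring
sizes and capping as configuration. Open valences are capped with hydroxyl
by default — yielding a carboxylic acid, which preserves the
hydrogen-bonding character of the cleaved amide — or with hydrogen
(aldehyde) on request; no capping can produce a radical, since exactly one
sigma bond is cut. Molecules with several sites are cleaved at each site,
and any residual motif inside a kept portion is cleaved again, so no
returned fragment contains the pattern. Multi-option cases return all
options; the package does not choose among them.

## Screening funnel

The applicability domain is fitted on the *original full inhibitors* (not
the fragments): per Lipinski descriptor, mean ± 2 sample standard
deviations (denominator n − 1), closed intervals, degenerate zero-variance
ranges flagged and treated as equality constraints. Boundary values pass —
the closed-interval convention is used everywhere in the package. The
solubility gate takes ≥ 2 cLogS estimates per molecule from pluggable
estimator functions (two documented heuristics ship: a Delaney-style linear
model in logP, MW, rotatable bonds and aromatic proportion, and the crude
0.5 − logP relation) and passes molecules with mean > −3.5 log units and
sample sd < 1.5; fewer than two estimates means "insufficient evidence",
never a pass. Candidate tiers follow the screening protocol: top (MBI >
0.85), mid (0.2 < MBI ≤ 0.85), low-MBI structural-similarity controls
(MBI < −0.97 and a similarity hit), and explicitly requested random
controls. The protocol text contains one self-contradictory sentence about
picking top candidates "only if MBI < 0.85"; the implementation uses the
definition consistent with everything else (> 0.85).

## Synthetic data: what it emulates and what it does not

`gen_descriptor_dataset()` plants, on 4 of 30 descriptors, sub-ranges of
width 0.2 inside [0, 1]; actives are drawn inside all four windows,
inactives and all noise descriptors are uniform. Class sizes default to
30 vs 6000 (≈1:200, the dilution a realistic screening learning set has).
A 5% *leak* probability makes the occasional active behave like background
on every signal descriptor — the analogue of a mislabelled or
mechanistically atypical active; leaks are per molecule, because the
generator's contract is that a non-leaked active lies inside *all* planted
windows. Descriptor values live on [0, 1] without loss of generality: the
grid is scale-free.

What passing recovery tests shows: the optimiser finds planted boxes, the
fold protocol scores held-out molecules sensibly, and ranking is strong
(held-out AUC typically 0.94–0.99 across seeds at the default
conditions — the acceptance suite measures exactly this over seeds 1–10).
What it does not show: behaviour on real descriptor distributions, which
are correlated, heavy-tailed and carry many weakly-informative axes rather
than four clean windows. Two structural losses cap synthetic AUC below 1:
leaked actives are by construction unrecoverable (each costs up to 1/n_act
of AUC), and fold-level ranges end at the extremes of the ~24 training
actives, so a held-out active just outside fails that descriptor's ranges.
Seeds drawing 2–3 leaked actives land just below an AUC of 0.95; this is a
property of the study conditions, not a tunable, and the package does not
adjust the generator to mask it.

`gen_smiles_fixture()` enumerates acylated pyrrolidine/piperidine scaffolds
(all cleavable by the default rule) and scaffold-diverse decoys (none
cleavable); `gen_library_fixture()` mixes methyl/ethyl esters of the same
acyl groups — Tanimoto-similar to the fragment acids, so the similarity
screen has true positives — with decoys. `gen_kinetics_data()` draws rates
from the closed-form laws (competitive Km′ = Km(1+I/Ki); noncompetitive
Vmax′ = Vmax/(1+I/Ki); uncompetitive both scaled) with multiplicative
Gaussian noise — the constant-CV assumption standard for initial-rate
assays — clipped at zero.

## Kinetics analytics

Michaelis–Menten fits use bounded Levenberg–Marquardt least squares
(`minpack.lm`), starting from Vmax₀ = max rate and Km₀ = concentration at
half-max, with parameter tolerances of 1e-14; noise-free synthetic data
round-trip to ≤ 1e-6 relative error. IC50 uses a four-parameter logistic
with auto-detected (and enforced) decreasing direction; the exact-fit case
is handled by the raw LM optimiser, which tolerates zero residuals.
Dixon regression fits 1/v against inhibitor concentration per substrate
level by ordinary least squares; zero rates are excluded (1/v undefined)
with a logged count. Line geometry calls the mechanism: intersection above
the I-axis at negative I → competitive; on the axis (within 5% of the
typical intercept) at negative I → noncompetitive; parallel (relative slope
difference < 5%) → uncompetitive; flat → none.

Inhibition-type calls from fold changes use a 15% "unchanged" band around
1, reflecting the conventional qualitative reading in which a fold of 1.04
is unchanged and 1.28 is an increase; the tolerance is configurable and
recorded inside every call object. Fold changes and selectivity ratios are
computed at full precision and rounded only for presentation (2 decimals).

## Numerical and reproducibility choices

- Ties in the best-range scan break towards the narrowest range, then the
  lowest lower bound; filter ordering ties break on a canonical
  serialisation of the ranges. Both make results independent of storage
  order.
- All randomness (sampling, fold splits, generators) flows through R's RNG
  from a single integer seed; identical (data, config, seed) give
  byte-identical model JSON and score CSVs, which the test suite asserts at
  the byte level.
- Model JSON is versioned and written at full precision
  (`digits = NA`), so serialise → read → serialise is byte-stable.
- Scoring-time values outside a filter's ranges — including values outside
  the training grid — simply fail that filter; missing descriptor values
  are fatal when building models and warn-and-exclude (NA score) when
  screening.
- Problem sizes in the test and acceptance suites: fold-level oracle checks
  use 6–8 descriptors and ≤ 100 molecules so that brute-force enumeration
  is the reference; recovery benchmarks use the full default generator
  (30 × 6030); the pipeline fixture screens ~45 molecules against ~9
  fragments. These sizes exercise every code path while keeping the whole
  suite in a few minutes on one core.

## Known limitations

- The descriptor set is an open 20-descriptor substitute; models built on
  it are not numerically comparable to models built on proprietary
  descriptor sets, and MBI values are only meaningful within one
  descriptor spec (which the model records).
- The elimination rule's default thresholds (α = 2, β = 0.5) encode "much
  more/much less than expected" conservatively; on pools with only mild
  worst-decile enrichment the rule may make no eliminations, in which case
  the run aborts at the iteration bound rather than silently looping.
- Proportion-based MBI compresses towards −1 when an ensemble contains many
  weak filters: absolute MBI values are then less interpretable than ranks,
  and the cutoff-table view (`score_table()`) should be read together with
  the AUC.
- Dixon mechanism calls assume the classical single-inhibitor models;
  mixed inhibition shows up as an off-axis intersection and is reported as
  "undetermined" rather than forced into a class.
- Tight-binding corrections, global multi-dataset Ki estimation and 3D
  pharmacophore screening are out of scope.
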