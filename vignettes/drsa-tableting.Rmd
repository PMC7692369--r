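---
title: "Dominance-based rough set analysis of pellet tableting data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dominance-based rough set analysis of pellet tableting data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Multiple-unit pellet systems (MUPS) are tablets compressed from coated
pellets. Compression can damage the polymer coating and change the release
profile of the active ingredient, so the central quality question for a
formulation is whether the dissolution profile *after* tableting is still
similar to the profile of the uncompressed pellets. Similarity is judged by
the f2 factor,

$$ f_2 = 50 \log_{10}\!\left(\frac{100}{\sqrt{1 + \tfrac{1}{n}\sum_{t}(R(t)-T(t))^2}}\right), $$

computed over paired sampling points of the reference (pellets) and test
(tablet) profiles; by regulatory convention $f_2 \ge 50$ means similar
release (class 1), $f_2 < 50$ means the profile changed (class 2). The
threshold is a sharp `>=` comparison on double-precision values — no
tolerance band — because the classification convention itself is sharp.
`similarityFactorF2()` uses every paired point by default; the regulatory
option of truncating one point past 85% dissolved exists (`truncate85`) but
is off, since the data this package targets use a fixed six-point grid
(1–6 h) for both profiles.

Each formulation is described by condition attributes — coating polymer,
tablet press type, compression force (kN), tablet mass (mg), hardness (N),
crushing strength (10^4 N/m², the crushing force divided by radius ×
thickness), friability (%), and excipient percentages — and the question
becomes: which regions of this attribute space preserve the release
profile? The dominance-based rough set approach (DRSA) answers with
monotonic decision rules such as "if Eudragit NE coating and compression
force > 6 kN and hardness ≥ 42.4 N, then class 1".

## The DRSA model

**Ordinal semantics.** DRSA assumes attribute scales are monotonically
related to class quality: a *gain* attribute favours the better class as it
grows, a *cost* attribute as it shrinks. For process data the direction is
not known a priori, so `cloneGainCost()` considers every
unknown-preference attribute in two copies — the first assumed gain, the
second cost. The transformation is non-invasive (values are untouched) and
lets rule induction discover the direction of each relationship by
conditioning on one copy or the other. Nominal attributes (the coating
polymer) are first expanded by `binarizeNominal()` into presence/absence
indicators, which are then ordered like any binary attribute. We replace
the nominal column rather than keeping it alongside the indicators: rules
only ever reference the indicators, and a retained unordered copy could
not carry conditions anyway.

**Dominance and approximations.** Object x weakly dominates y when x is at
least as good on every gain attribute and at most as good on every cost
attribute. A consequence worth stating explicitly: after the two-copy
transform each attribute constrains the comparison in both directions, so
weak dominance reduces to *equality of the condition description*, and the
dominance cones of `dominanceCone()` become the sets of indiscernible
formulations. The implementation evaluates each cloned pair once through a
grouping key, so the two copies are never double-counted. Inconsistency
then means what a technologist would expect: formulations with the same
description but different f2 class. `unionApproximations()` computes lower
and upper approximations of the upward union ("at least class 1" = class 1,
the preferred class) and the downward union ("at most class 2" = class 2);
the boundary flags the inconsistent objects and
`qualityOfClassification()` reports gamma, the fraction of objects outside
every boundary.

**Consistency measure.** `objectConsistency()` measures how consistent an
object is with a union as the fraction of its cone inside the union (1 =
fully consistent). This cone-membership fraction drives both
variable-consistency rule admissibility and VC-bagging sampling weights.
The admissibility threshold defaults to 1.0 — classical certain rules from
the lower approximation — because the source analysis does not state a
laxer level; it is a parameter (`consistencyThreshold`) wherever rules are
induced.

## Rule induction

`induceRules()` grows rules by sequential covering in the DomLEM style.
The coverage goal is the union's lower approximation (at the given
consistency threshold). A rule is grown greedily: among candidate
elementary conditions at observed attribute values (weak `>=` on gain
copies and `<=` on cost copies for upward unions, dually for downward
ones), pick the condition maximising rule confidence, breaking ties by
coverage of the not-yet-covered goal and then by attributes with fewer
distinct thresholds; stop when every matched object lies in the admissible
region. Premises are then pruned to minimality — `checkMinimality()`
verifies no single condition can be dropped — redundant rules are removed,
and the set is ranked by confirmation, then support. Thresholds are stored
as weak inequalities at observed values; `formatRule(strict = TRUE)`
renders the equivalent open-bound dialect (force `> 6` instead of
`>= 12` on the observed grid 6/12/18), since published rule tables mix
both spellings.

Rule quality is reported as support (objects matching premise and
conclusion), strength (support / table size; displayed truncated to four
decimals, the convention of the published tables, so 32/180 prints as
0.1777), confidence, and a Bayesian confirmation measure.
`confirmationMeasure()` implements four standard choices — `s`
$= P(H|E)-P(H|\neg E)$ (default), `c`, Kemeny–Oppenheim `f`, and the
log-likelihood ratio `l`. The source analysis does not name the measure
behind its printed values, so no attempt is made to reproduce them
numerically; all four implemented measures share the confirmation sign/zero
semantics (positive under positive association, zero under independence,
negative under anti-association), which is what the test suite asserts.

## Ensembles, cross-validation, relevance

`vcBaggingTrain()` builds a variable-consistency bagging ensemble:
bootstrap samples of size n drawn with probabilities proportional to each
object's cone-membership consistency for its own class (dominance-
inconsistent objects enter bags less often), rules induced per bag for both
unions. The bag count defaults to 30 — unstated in the source analysis, and
a conventional ensemble size at which bagged rule sets stabilise.
Classification (`classify()`) sums the strengths of all satisfied rules per
union; no-match objects get the training majority class and exact ties go
to class 2, the conservative choice (predicting a changed profile costs a
redundant experiment; the opposite error ships a bad formulation).

`crossValidate()` runs 5-fold stratified cross-validation repeated 100
times by default, the protocol of the source study. Folds preserve class
proportions within one object; all randomness flows from one root seed via
deterministic counters, so reports reproduce bit for bit. Precision is
macro-averaged over the two classes by default (micro is also recorded) —
the source's summary table does not say which; macro is the conservative
reading for mildly unbalanced classes.

`attributeRelevance()` scores an attribute by a confirmation measure over
(object, firing rule) events: E = "the premise involves the attribute",
H = "the rule's suggestion is correct". The score rises when rules using
the attribute vote correctly or rules omitting it vote wrongly. Attributes
appearing in few rules get high-variance scores; rankings are therefore
most meaningful for frequently used attributes, and an attribute absent
from every rule is reported `NA`.

## The synthetic generator

`generateTable()` emulates the structure of the tableting information
system: 180 formulations by default, the schema's domains (coating 1–3,
press 1–2, force {6, 12, 18} kN, mass 516–568 mg, hardness 11–297 N,
crushing strength 11–619 ×10^4 N/m², friability 0–10.1%), numeric values
uniform within range, and the one-hot filler pattern of real tablet masses
(one bulk filler per formulation, usually an Avicel binder, Kollidon CL
except in starch formulations). Classes are assigned by planted monotone
rules — by default an "elastic coating, adequate force and hardness" rule
and an "EC-free, modest mass, adequate crushing strength, Avicel 102"
rule, echoing the kind of relationships the method is meant to find — and
`round(inconsistency * n)` labels are then flipped, allocated to both
classes proportionally so stratification stays meaningful.

Two generator choices deserve comment:

* **Replicated design families.** Formulations are drawn as distinct
  design points replicated twice by default (`replicates = 2`). Tableting
  studies repeat compositions across process settings, and under the
  two-copy transform this is also exactly what allows label noise to
  surface as dominance inconsistency: a flipped label inside a replicated
  family creates an identical-description pair with conflicting classes,
  so gamma falls as the inconsistency rate rises. With unique continuous
  rows gamma would be trivially 1 at any noise level.
* **Default inconsistency 0.1.** The real table's inconsistency level is
  unknown; 10% label noise is a moderate, realistic level for a
  dissolution-classified endpoint and is the package's fixed default for
  study-sized simulations.

What the generator does *not* emulate: correlations between hardness,
crushing strength and compression force (attributes are drawn
independently), measurement error in f2 itself, and any mechanistic
compaction or dissolution physics. Passing tests on synthetic tables
therefore demonstrate correctness of the algorithms under a known monotone
ground truth, not predictive performance on real formulation data.

`generateProfiles()` inverts the f2 formula to build profile pairs with a
prescribed similarity: a first-order release curve and a constant offset
$d = \sqrt{10^{4 - f_2/25} - 1}$ (target 50 gives $d = \sqrt{99}$), plus a
common jitter that changes the shapes but not the differences.

## Numerical and degenerate-input choices

* Strength display truncates (not rounds) at four decimals with a 1e-7
  guard against binary representation error.
* Domain validation compares set members with a 1e-8 tolerance.
* Ties in dominance are resolved by weak inequality (reflexive cones).
* An empty lower approximation yields an empty rule set with a warning;
  a one-class table yields an unconditional rule covering everything.
* Bootstrap bags that degenerate to a single class are skipped with a
  warning; an ensemble needs at least one surviving bag.
* Confirmation of a premise matching all or no objects is undefined and
  returned as `NA` with a warning; the `l` measure may be ±Inf for
  one-sided premises.

## Problem sizes used by the checks

The bundled checks run 5-fold cross-validation at 10 repeats × 10 bags on
the 180-formulation synthetic stand-in, 2–3 repeats on the smaller control
tables, and property sweeps over 1000 random mini-tables; these sizes give
stable averages (repeat-to-repeat accuracy spread of a few percentage
points) while keeping a full run in minutes on one CPU. The full
100-repeat protocol is the package default for real analyses.

## Known limitations

* Voting classification is implemented for the two-class setting of the
  motivating analysis; approximations and rule induction handle k ordered
  classes.
* On noise-free data whose concept is a union of several planted rules,
  strength-weighted voting does not reach 100% held-out accuracy at
  moderate n — certain rules for the two classes can both fire near the
  boundary and the heavier side wins. Training-set classification is
  exact; held-out accuracy approaches 100% as n grows or when the concept
  is a single monotone rule.
* The confirmation values printed in the source analysis's rule tables are
  not reproducible without knowing its measure; only sign/zero semantics
  are guaranteed.
* Rule induction cost grows roughly with objects × attributes × distinct
  thresholds; the pure-R implementation is comfortable at the 180 × 50
  scale it targets.
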