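---
title: "Evidential diagnosis ranking from sparse phenotype data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidential diagnosis ranking from sparse phenotype data: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beliefmine)
```

## The problem

Rare genetic disorders — skeletal dysplasias are the motivating family —
resist ordinary supervised classification. A registry accumulates a few
hundred diagnosed cases spread over a hundred or more disorders, so most
classes have one to five examples; each patient exhibits a handful of
clinical features out of several hundred possible ones; and two patients
with the same disorder often share almost none of their recorded features.
Any method that needs well-estimated class-conditional distributions starves.
`beliefmine` instead treats every repeated phenotype–disorder co-occurrence
as a piece of *evidence* and combines evidence with the Dempster–Shafer
calculus, which can represent ignorance directly instead of spreading it
uniformly over alternatives. The output is deliberately not a hard
classification but a ranked list of candidate disorders with belief and
plausibility values — decision *support*, with the supporting rules
available for inspection.

## The model

**Encoding.** Phenotype terms and disorder terms are opaque strings matched
after trimming and case-folding, mapped to disjoint symbol namespaces
(`S1, S2, ...` and `D1, D2, ...`). Each case becomes a phenotype symbol set
plus an optional diagnosis symbol.

**Rule mining.** Every case contributes the transaction
`phenotypes ∪ {diagnosis}`. Frequent itemsets are found by a level-wise
(Apriori) search: size-k candidates are joined from frequent size-(k−1)
sets sharing a lexicographic prefix and pruned by downward closure; support
is counted by transaction-id intersection, which is exact and fast on
sparse sets. An itemset with exactly one disorder symbol `d` and phenotype
part `A` yields the rule `A → d` with

    confidence(A → d) = supp(A ∪ {d}) / supp(A).

Two parameters govern the search, and both defaults are part of the
method's identity rather than tuning knobs: an *absolute* minimum support
of 2 (relative support 2/N — low on purpose, because rare but repeated
associations are exactly what a rare-disorder corpus has to offer) and a
maximum itemset size of 10 (the lattice grows exponentially in itemset
size). No minimum-confidence filter is applied: every applicable rule
contributes mass during combination, and removing low-confidence rules
would bias the combined belief, not merely shrink the rule base.

**From rules to masses.** A rule of confidence `c` becomes a *simple
support function*: mass `c` on the focal set `antecedent ∪ {consequent}`
and mass `1 − c` on the frame of discernment Θ. The residual's destination
is a design decision: assigning it to Θ (ignorance) rather than to the
complement of the conclusion keeps the basic-belief axioms satisfied and
encodes "this rule may simply not apply", which is the correct reading of
a confidence below 1 in sparse data.

**Combination.** Applicable rules (antecedent ⊆ query) are fused with
Dempster's rule: for focal sets B and C the product mass `m1(B) m2(C)`
accrues to `B ∩ C`; empty intersections accrue to the conflict `K`; all
non-empty results are renormalized by `1 − K`. Θ behaves as the universal
set. Intersection is plain item-set intersection, so a product can retain
phenotypes while losing its disorder element; such conclusion-free focal
sets are kept as partial ignorance — they contribute to no candidate's
belief, because belief in a conclusion requires the conclusion. `K = 1` is
raised as a typed error (`beliefmine_total_conflict`), never a division by
zero; the ranking layer converts it into an explicit "no decision".
Normalization happens per pairwise combination (standard Dempster); the
fold order is fixed (antecedent size, then symbols) purely for
bit-reproducibility, since the rule is commutative and associative and the
test suite checks order invariance separately.

**Decision functions.** For a query set A and candidate disorder c, the
constrained belief and plausibility over the combined mass m are

    Bel_c(A, c) = Σ { m(F) : phenotypes(F) ⊆ A, disorder(F) = c }
    Pl_c(A, c)  = Σ { m(F) : phenotypes(F) ∩ A ≠ ∅ or phenotypes(F) = ∅,
                              disorder(F) = c } + m(Θ)

Candidates are ordered by belief alone — belief counts evidence that *must*
hold, plausibility also counts evidence that merely *may* hold, so
plausibility is reported but never decides. Ties fall back to plausibility,
then to symbol order, making rankings deterministic. How combined focal
sets that lost their conclusion should enter Pl_c is genuinely open (they
only exist after combination); here they count only through Θ, which
leaves belief — the decision criterion — untouched either way.

## Numerical choices

- Mass-function validity is enforced to 1e-9 (sum of masses = 1, no mass on
  the empty set, non-negativity).
- When many rules apply, the focal family can grow combinatorially. After
  each pairwise combination, focal sets with mass below 1e-12 are dropped
  and the survivors renormalized. The threshold is far below every
  tolerance used anywhere in the package; order-invariance tests still pass
  at 1e-9 with pruning active.
- With exactly one applicable rule the ranked belief equals the rule's
  confidence bit-for-bit (no arithmetic touches it) — a deliberately exact
  contract that the tests assert with `identical()`.

## Evaluation harness

Stratified k-fold cross-validation (default k = 5): cases are grouped by
diagnosis, shuffled per seed, and dealt round-robin, so per-fold class
counts deviate by at most one from perfect stratification. The ranker's
top-1 candidate is the prediction; a query that matches no rule (or hits
total conflict) counts as an *incorrect* prediction rather than being
dropped, keeping accuracy comparable with baselines that always predict.
Metrics: accuracy `100 L / N`; per-class precision
`correct_i / predictions_i` (0 by convention for never-predicted classes)
and recall `correct_i / N_i`; macro precision/recall are *unweighted* means
over the classes present in the test data — with heavy class imbalance a
weighted mean would collapse into accuracy and hide exactly the small
classes this method cares about.

The built-in baseline is a Bernoulli naive Bayes over the phenotype
vocabulary with add-one (Laplace) smoothing on the likelihoods and
unsmoothed class priors, ties broken by symbol order. It anchors the
design contrast: Bayesian reasoning needs an arbitrary estimator to paper
over zero counts, whereas the evidential model gives unassigned belief to
Θ explicitly.

## The synthetic generator

No public registry of coded rare-disorder cases exists at the scale needed
for testing, so the package generates collections with the published
statistical signature of such registries:

- **Rareness** — class sizes drawn from bins (1–2, 3–5, 6–10, 11–20,
  21–50, 51–110) with weights 0.42/0.28/0.14/0.07/0.05/0.04: ~70% of
  classes have at most five cases, ~4% exceed fifty. Default 114 disorders.
- **Dimensionality** — a vocabulary of 602 features; per-disorder signature
  sizes lognormal (median 15, mean ≈ 21.6) truncated to [4, 151].
- **Sparseness** — per-case feature counts `1 + Poisson(3)` capped at 20
  (mean ≈ 4); features drawn from the class signature with Gamma(2)
  weights; and a high off-signature noise rate (default 0.7).

The noise default deserves its justification: in real registries even
same-diagnosis cases share remarkably few features (published common-set
coverages of 10–27%, maximum per-feature coverage of 50% even in two-case
classes), and the count of distinct features observed for a disorder grows
with its case count. Idiosyncratic, case-specific features are the
mechanism that produces both effects, and the 0.7 rate together with the
Gamma(2) weight skew is what brings the observed mean per-feature coverage
of a default-configuration collection to ≈ 11–13%, against the 11.33%
target the generator aims for. These defaults were fixed once, as the
generator's definition of "realistic", and the test suite checks the
resulting coverage at scale (three fixed seeds, 160 disorders so each
collection exceeds 1000 cases, tolerance ±3 percentage points).

`generate_planted()` is the separable counterpart: every class gets a
unique signature carried by 100% of its cases, and the ground-truth rule
set (every signature subset → class, confidence 1) is returned for exact
recovery tests of the whole mining + ranking pipeline.

The scaled comparison experiment mirrors a six-class design of
well-represented disorders (class sizes 22, 75, 33, 28, 101, 24; 283
cases). For that all-large-class composition, sparseness equivalent to the
full registry needs much less noise: rate 0.12 with Gamma(0.5) weights
gives ≈ 11% mean coverage. On five seeds of this design the evidential
ranker's mean 5-fold accuracy is compared against the majority-class
baseline and against naive Bayes — a directional check of the method
ordering, not a reproduction of any published figure, since synthetic
classes are more separable than real ones.

## Problem sizes used by the tests

Chosen as a balance between statistical force and a comfortably quick
default test run: 200 random collections (≤ 12 symbols, ≤ 40 cases)
against the exhaustive power-set oracle; 40–60 random evidence sets for
the algebra properties; 100 random confidences for the exactness contract;
3 × 10 planted cases for recovery; five seeds of the 283-case six-class
design for the comparative experiment.

## Known limitations

- Exact term matching only: no ontology expansion (is-a/part-of), so two
  phenotypes related but not identical are independent symbols.
- One diagnosis per training case; co-occurring disorders are out of scope.
- Dempster's rule is the only combination rule offered; alternatives
  (Yager, Dubois–Prade) that redistribute conflict differently are not
  implemented.
- The synthetic generator reproduces marginal statistics (class sizes,
  coverage, features per case), not feature–feature correlation structure;
  passing tests demonstrate correctness of the machinery under realistic
  sparseness, not clinical accuracy.
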