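---
title: "Deep exploratory contrast mining: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep exploratory contrast mining: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contrastmine)
```

## The problem

Biomedical cohort discovery usually starts from a pre-defined target
population. `contrastmine` inverts that: given a categorical subject table
whose variables are split into *population* variables (used to define
subgroups — demographics, phenotype bands, comorbidities) and *measurement*
variables (used to characterize them — SNP genotypes, lab bands), it searches
the combinatorial space of **contrast subgroup pairs** and ranks them by how
sharply their measurement patterns differ. The output is a prioritized pool
of candidate cohort pairs, each with the explainable patterns that set its
two sides apart.

A contrast subgroup pair opposes two conjunctions of categories over the
same population variables, in positional correspondence:
\((C_{i,m} \wedge \dots \wedge C_{j,k}) \leftrightarrow
  (C_{i,n} \wedge \dots \wedge C_{j,l})\),
for example `(Female & Young) <-> (Male & Young)`. Two structural conditions
hold throughout: the sides are positionally matched (condition a), and a
population variable appears at most once per pair (condition b). The `"NA"`
category never takes part in a definition. Identity is symmetric — swapping
the two sides or reordering the pairs denotes the same object — which
`canonical_key()` encodes; the key registry built on it is what prevents the
search from evaluating any pair twice or oscillating.

## Contrast patterns and the J value

For a split into sides \(S_{G1}, S_{G2}\) (plus the outer remainder), a
pattern \(p\) is an itemset of measurement categories. Its support in a
group is the fraction of records containing it; the growth of a pattern is

\[ \mathrm{Growth} = \frac{\max(s_1, s_2)}{\min(s_1, s_2)}, \]

and is squashed by a scaled tanh,
\(\mathrm{Growth}_{norm} = \tanh(\mathrm{Growth}/G_{max}) \cdot G_{max}\),
so that a single explosive ratio cannot dominate the score. A pattern is
*effective* when it is frequent in at least one side (support \(\ge \alpha\)),
its growth reaches \(\beta\), no proper subset has strictly greater growth
(the subset-dominance rule — a longer pattern must add contrast, not dilute
it), and, optionally, its prevalence inside the pair is significantly higher
than in the outer group (two-sided Fisher exact test).

The pair's quality is the g-index-style **J value**: sort the effective
patterns' normalized growths decreasingly; J is the largest integer whose top
J values sum to at least \(J^2\). J therefore rewards both the number of
contrast patterns and their strength. Because the normalized growth is
bounded by \(G_{max}\), J is bounded by roughly
\(G_{max}\tanh(1) \approx 0.76\,G_{max}\); with the default cap of 10, J
saturates at 7 and ties at the ceiling are common — the search's tie-breaking
and path quotas are designed with this in mind (below).

For ranking, J is blended with a random baseline through a Bayesian average:

\[ J_{size} = \frac{N J_{ori} + \bar{M} \bar{J}}{N + \bar{M}}, \]

where \(\bar J\) and \(\bar M\) are the mean J and mean population size of
`baseline_k` uniformly random subgroup pairs drawn *before* path expansion,
and \(N\) is the pair's population size (preference `"larger"`) or its
reciprocal (`"smaller"`, for rare-disease work). The baseline uses the
original J of the random pairs — using their size-modified J would be
circular. The result always lies between \(J_{ori}\) and \(\bar J\), so
small accidental pairs shrink toward the baseline while well-populated
strong pairs keep their score.

## The search

Enumerating all \(n_c^{n_p}\) subgroups is hopeless, so the engine is a
floating selection wrapped in a multi-path expansion:

* **Inclusion** scores the extension of the current pair by every contrast
  pair of every remaining population variable. For a non-empty subgroup both
  alignments of a new category pair are distinct candidates (which category
  joins side 1 matters once there is a side 1); from the empty root the two
  alignments coincide.
* **Exclusion** scores the removal of each pair. In the single-path
  `floating_selection()` an exclusion is applied only when it strictly
  improves the best J recorded at the smaller size and does not merely undo
  the inclusion just made; continued exclusions are bounded by the visited
  registry and the two-pair minimum. This is the standard
  sequential-floating-selection reading; the stop rule is the relative gain
  \((J(k) - J(k-1))/J(k) \le \alpha_{stop}\) or \(k = l\) (`max_vars`). A
  zero J carries no gain information, so the search continues under the hard
  bound rather than dividing by zero.
* **Guided cascading shotgun** (`contrast_mine()`) expands many paths
  breadth-wise. At every node the number of surviving children is
  \(N_{track} = \max\{\lceil n p\rceil,\; |\{i : J_i \ge J_{best}(1-p)\}|\}\)
  — a quantity quota plus a quality quota. In the expansion driver the
  quality quota counts only children with \(J > 0\): when every move of a
  node scores zero the literal quota would equal \(n\) (everything ties with
  a zero best) and the search would degenerate to exhaustive enumeration of
  noise; zero-signal paths therefore consume only the \(\lceil n p\rceil\)
  quantity slots. The exported `n_track()` implements the formula literally.
  With the default `alpha_stop = 0` no relative-gain abandonment is applied
  during expansion — expansion is bounded by the quotas, `max_vars` and the
  registry — which is also what makes `expand_p = 1` provably equivalent to
  exhaustive search (a gain rule would cut paths whose J dips before rising).
  Every evaluated pair, surviving or not, enters the candidate pool; pruning
  only stops further *expansion*.

Tie-breaking everywhere is by canonical key, so a fixed seed gives a fixed
result regardless of evaluation order. Clinician-supplied trivial pairs can
be blacklisted by key and are neither evaluated nor expanded.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha_support` | 0.5 | minimum support on at least one side; lower it (down to 0.0005) for rare-disease work |
| `beta_growth` | 2 | minimum growth; at least twice as prevalent on one side |
| `growth_max` | estimated | tanh cap; estimated as the largest finite growth seen across random subgroup pairs (floored at \(2\beta\)), or user-supplied |
| `max_pattern_len` | 3 | items per pattern; published findings are 1–2-gene combinations |
| `min_side` | 20 | sides smaller than this score J = 0 instead of producing unstable supports |
| `outer_filter`, `outer_p_cutoff` | TRUE, 0.05 | per-pattern outer-group Fisher screen before J (no multiplicity correction by default; `bh_adjust` switches Benjamini–Hochberg on) |
| `max_vars` | 5 | maximal population variables per pair |
| `expand_p` | 0.1 | expansion factor p |
| `baseline_k` | 100 | random pairs behind the size modification |

The outer screen is applied before J computation; whether the original
pipeline filtered before or after scoring is not determinable from its
description, and a pre-J filter is the conservative choice (a pattern that is
not subgroup-specific should not contribute to the subgroup's score). It can
be disabled.

## The planted-cohort benchmark

`simulate_benchmark()` builds the synthetic testbed the package is validated
on: \(N\) planted subgroup pairs, \(N/k\) per inclusion length \(1..k\),
each with designed per-side sizes \(|T| \sim U[0.01, 0.1]\,|D|\) and planted
measurement patterns whose supports and growths are realized exactly
(carriers are sampled to the designed counts and the pattern's categories
are withheld from non-carrier members, so subsets of a planted pattern
automatically satisfy the Apriori property). Defaults are the desk-scale
study conditions (\(|D| = 10^4\), 5 population and 20 measurement variables,
cardinality 5, \(k = 3\), \(N = 6\)); the published full-scale setting
(\(10^6\) records, 100 measurements, cardinality 10, \(k = 5\)) is the same
generator with larger fields.

Two design choices deserve explanation:

* **Refinement chains with reserved categories.** Every planted pair of
  length \(\ell \ge 2\) extends a planted pair of length \(\ell - 1\) by one
  variable, with members nested per side, and planted category values are
  *reserved* — background records never take them. This guarantees that a
  planted definition selects exactly its designated members. Without
  reservation, chance-matching background records dilute planted supports
  below any realistic support threshold (a one-variable side at cardinality
  5 captures ~20% of the data by chance, an order of magnitude more than the
  planted members), and the benchmark becomes undiscoverable at any scale.
  With reservation but independently drawn definitions, the per-variable
  category budget (5 categories × 5 variables against 12 claimed pairs at
  the default N) cannot host the planted definitions at all. Chains resolve
  both constraints and are the benchmark's controlled form of pair overlap;
  `overlap_level` additionally shares subjects between chains.
* **Background and planted categories.** Remaining measurement cells are
  drawn from a unit normal discretized into `meas_cardinality` equal-width
  bins (a bell-shaped marginal); remaining population cells are uniform over
  the unreserved categories. Planted pattern categories are drawn excluding
  the modal background bin: a contrast planted on the modal category would
  be no more prevalent inside its pair than everywhere else, contradicting
  the premise that planted patterns are distinctive contrasts.

What the benchmark does *not* emulate: correlated measurement variables
(real SNP panels have LD structure), missing data, continuous measurements,
and definitions whose sides overlap on shared categories. Passing coverage
tests therefore shows the search recovers planted, well-separated signal —
not that it handles confounded real-world structure.

Coverage is the fraction of planted pairs whose canonical key appears in the
mined pool (exact-definition match); a secondary Jaccard-over-members mode
credits near-miss discoveries, which genuinely occur — the miner routinely
finds pairs contrasting a planted side against the unreserved background
with J as high as the planted pair itself.

## Numerical choices and degenerate inputs

* Zero-denominator growth (a "jumping" pattern absent from one side) is set
  to `growth_max` before normalization; finite ratios above the cap are
  likewise capped inside the pipeline. The bare `growth_rate()` defaults to
  an infinite cap so printed ratios reproduce exactly.
* Support comparisons use a `1e-12` slack so `alpha`-boundary counts are not
  lost to floating-point; the J inequality uses `1e-9` on the cumulative
  sums; subset dominance requires a strictly greater growth beyond `1e-12`.
* Equal supports give growth 1 and direction `side1` (a tie has no
  direction; the label is then arbitrary but deterministic).
* `discretize()` rejects constant input for equal-width bins and more bins
  than distinct values for equal-density; entropy splitting uses recursive
  binary information gain with the MDL acceptance rule. An adjacent-pairs
  rule is sometimes named alongside these in the literature without a
  definition; it is deliberately not implemented.
* Subjects with a missing-cell fraction above `max_missing` (default 0.5)
  are dropped at encoding; the ceiling is a free choice since no standard
  value exists.
* Fisher's exact test is computed by direct hypergeometric summation
  (`stats::dhyper`), matching `stats::fisher.test`'s two-sided convention
  (verified against it in the tests) at a fraction of the cost.

## Problem sizes used in the tests

Unit tests run on 6–200-record toys where brute-force oracles (exhaustive
itemset enumeration, full hypergeometric sums, exhaustive subgroup search)
are instant. The end-to-end coverage check uses the desk-scale benchmark —
five seeds, expansion factors 0.10 and 0.20 — chosen so the full suite
completes in minutes on one core while still exercising every planted
length. The same configuration is what `scripts/acceptance.R` reruns.

## Known limitations

* The search is exact only at `expand_p = 1`; at realistic factors coverage
  of *planted* structure is high but newly discovered background contrasts
  can outrank planted pairs — by design, since their contrast is real.
* J saturates at `0.76 * growth_max`; with small caps the ranking within
  the saturated tier falls to the size modification and the deterministic
  key order.
* Measurement variables are treated as independent items; no LD-aware or
  hierarchy-aware pattern pruning is attempted.
* Single-machine only: evaluations are independent given the shared
  read-only dataset and a mergeable registry, so the same pool would be
  produced by any execution order (the parallelism contract), but no
  distributed runtime is shipped.
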