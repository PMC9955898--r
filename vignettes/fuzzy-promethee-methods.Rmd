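---
title: "Fuzzy PROMETHEE II: model, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy PROMETHEE II: model, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpromethee)
```

## The decision problem

fpromethee ranks a finite set of alternatives — in the bundled data, nine
machine-learning classifiers for brain-tumor diagnosis — against several
conflicting criteria (prediction accuracy, precision, recall, processing
time, sensitivity, specificity), each with an optimisation aim (max or
min) and an importance weight. Expert judgements often arrive as words,
not numbers, so evaluations and weights may be given on a linguistic scale
whose terms are triangular fuzzy numbers (TFNs).

The pipeline is deliberately *defuzzify-first*: every linguistic term is
collapsed to a crisp scalar with the Yager centroid index before any
pairwise arithmetic. For a TFN $(l, m, u)$ the centroid is

$$ y(l, m, u) = \frac{l + m + u}{3}, $$

which is monotone in each component, equals $m$ for symmetric triangles,
and maps the default scale to strictly decreasing values
(VH $\approx 0.9167$, H $= 0.75$, M $= 0.5$, L $= 0.25$,
VL $\approx 0.0833$). Fuzzy pairwise arithmetic (adding or multiplying
TFNs) is intentionally out of scope: once crisp values exist, the
classical PROMETHEE machinery applies unchanged, and results stay easy to
audit.

## PROMETHEE II

For alternatives $a, b$ and criterion $j$ with crisp evaluations $f_j$,
the signed deviation is $d_j(a,b) = f_j(a) - f_j(b)$, with the sign
flipped on min-aim criteria so that positive always means "$a$ preferred".
Min criteria are handled purely by this sign flip — stored values are
never mutated, keeping raw data auditable. A preference function maps the
deviation to a degree $P_j(a,b) \in [0,1]$; the whole classical catalogue
(usual, U-shape, V-shape, level, linear, Gaussian) is available, with the
Gaussian

$$ P(d) = 1 - e^{-d^2 / 2s^2}, \qquad d > 0 $$

as the default. The aggregated index and the flows are

$$ \pi(a,b) = \frac{\sum_j w_j P_j(a,b)}{\sum_j w_j}, \qquad
   \phi^+(a) = \frac{1}{n-1}\sum_{x \ne a} \pi(a,x), \qquad
   \phi^-(a) = \frac{1}{n-1}\sum_{x \ne a} \pi(x,a), $$

and the complete ranking orders alternatives by the net flow
$\phi = \phi^+ - \phi^-$. Weights are normalised by their sum, so only
ratios matter and linguistic weights are scale-free; the $1/(n-1)$
normalisation keeps $\phi \in [-1, 1]$ and makes net flows sum to zero —
an invariant the engine actively verifies on every run.

## Tunable parameters

* **Gaussian threshold `s`** (same units as the criterion). When unset,
  each criterion uses the population standard deviation of its $n$ crisp
  evaluations — a spread-matched default in the spirit of the smart
  thresholds of common PROMETHEE software. A zero-spread criterion
  contributes zero preference rather than dividing by zero. `s` can be
  overridden per criterion (`promethee_flows(dm, s = c(accuracy = 0.2))`,
  the `#pf_s` CSV row, or `--s accuracy=0.2` on the command line). Because
  published applications rarely disclose their thresholds, rank-level
  conclusions here are always re-checked across a grid of `s` values.
* **Tie tolerance** (`tie_tol`, default `1e-9` on net flow). Tied
  alternatives share a competition-style rank (1, 2, 2, 4, ...), and keep
  input order within a group. The tolerance is deliberately tight: it
  groups exact duplicates (identical evaluation profiles produce
  bit-identical flows) without masking genuinely different profiles.
* **Weights**: linguistic terms are defuzzified with the same Yager
  centroid (VH $\to 0.92$, M $\to 0.50$ at two decimals); crisp weights
  are accepted anywhere a term is.
* **Banding** maps raw percentages onto terms, with half-open intervals
  `[lo, hi)` and a closed last interval, so a boundary value such as 95
  belongs to the upper band. Values below the lowest band raise an error
  instead of clamping: an out-of-calibration input should fail loudly.
  The bundled processing-time banding (`[0,350) -> L`, `[350,450] -> M`)
  is the unique two-band split consistent with all nine published time
  labels, and is user-overridable.

## The bundled study data

The fixture stores the published decision matrix *verbatim*: every cell
carries both the raw value and the printed term, even where the two
disagree with the study's own banding footnote (six cells do, e.g. a
precision of 95.78 printed as H although the rule says VH, and a
specificity of 94.69 printed as VH although the rule says H).
`validate_labels()` surfaces these discrepancies instead of silently
re-banding; analyses in linguistic mode use the printed terms, exactly as
published.

Two findings about the published tables deserve note. First, the printed
flow *values* (0.0251, 0.7433, ...) are not reproducible by any
implementation without the original Gaussian thresholds, which were never
disclosed; this package therefore asserts rank-level and structural
properties instead. Second, the published exact tie between two
alternatives whose recall terms differ cannot occur under any monotone
preference function with a positive recall weight; the engine is not
forced to reproduce it. What *is* robustly reproducible — and what the
test suite pins down — is the structure the data dictates: the CNN row
weakly dominates all eight competitors in linguistic mode, so it is rank 1
for every positive weight vector and every `s`; the two term-identical
rows (SVM and KNN) tie bit-for-bit; and CNN stays rank 1 in raw-numeric
mode across the whole threshold grid.

One published claim does not survive at this package's default
thresholds: after the specificity weight change VH $\to$ M, the top of the
ranking (including CNN's lead and the SVM/KNN tie) is unchanged, but two
mid-table entries swap relative to the baseline. The swap disappears for
most fixed `s` values and for all large `s` — consistent with the very
small published flow magnitudes, which point to a large undisclosed
threshold — so the package reports preservation honestly per
configuration rather than asserting it unconditionally.

## Sensitivity analysis

`perturb_weight()` is strictly one-at-a-time: one criterion's weight
changes, everything else stays fixed. Preservation compares ordered
tie-group sequences of names, not flow values, because flow values always
move a little. `stability_interval()` finds the maximal contiguous weight
interval around the baseline with an unchanged complete ranking by
scanning a grid over $(0, 1]$ at resolution 0.01 by default. An analytic
interval solver is possible but disproportionate at these problem sizes
($n \le$ tens); the grid scan is documented as approximate, and the
refinement property (halving the resolution moves endpoints by at most
one coarse step) is part of the test suite.

## The synthetic generator

`simulate_decision_matrix()` emulates the study's shape: by default 9
alternatives on 6 criteria, five max-aim percentage scores drawn uniformly
on $[70, 100]$ (two decimals, so the percentage banding always applies)
and one min-aim cost criterion drawn on $[300, 450]$ seconds (integers,
matching the published processing times). Terms are derived from banding,
so generated matrices are always label-consistent — useful as the clean
counterpart to the deliberately inconsistent fixture. Two structural
plants exist solely because they make downstream behaviour provable:

* a *dominant* alternative (column-wise best, strictly better somewhere)
  must be rank 1 under any positive weights and any valid preference
  function;
* a *duplicate* pair must tie exactly.

All draws flow from a single seed and the seed is recorded in the CSV
header, so any generated matrix is reproducible from its file alone. What
the generator does **not** emulate: correlated criteria (real performance
metrics co-vary strongly), measurement error, or the label/band
inconsistencies of transcribed real tables. Passing tests on synthetic
matrices therefore demonstrate the engine's algebraic correctness, not
robustness to messy real-world inputs — the fixture covers the latter.

## Numerical choices

* Flows are carried at full double precision; reports round to 4 decimals
  (flows) and 2 decimals (weights) only at the formatting stage.
* Exact-duplicate ties are bit-identical by construction (the same crisp
  values enter symmetric computations), so the `1e-9` tie tolerance is a
  guard, not a crutch.
* Engine correctness at small sizes ($n \le 4$, $k \le 3$) is checked
  against an independently coded brute-force triple loop to $10^{-12}$
  over hundreds of random matrices; limit behaviour ($s \to \infty$ kills
  all flows; $s \to 0^+$ recovers the usual criterion) is asserted
  explicitly.
* Problem sizes in the tests mirror the study (9 × 6) or stay smaller;
  the full suite and the reproduction script each run in seconds.

## Known limitations

* Only triangular membership functions and the centroid defuzzifier are
  provided; the pipeline's defuzzify-first design makes other
  defuzzifiers easy to add but none are exposed.
* PROMETHEE I partial preorders, GAIA-plane projections and group
  aggregation are out of scope.
* The stability interval is grid-based and one-dimensional; simultaneous
  multi-criterion weight regions are not explored.
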