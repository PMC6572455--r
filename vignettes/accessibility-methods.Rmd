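---
title: "Methods: distance-based accessibility indicators from joinpoint analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: distance-based accessibility indicators from joinpoint analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(careaccess)
```

## The model

`careaccess` quantifies the spatial accessibility of community care services
from two point tables: service users ("cases") and providers, each carrying
an administrative-area code and planar (or geographic) coordinates. The
analysis chain is:

1. **Filters.** Institutionalised cases are excluded (they do not travel to
   community services); providers sharing bitwise-identical coordinates are
   collapsed to the first-listed record (multiple services registered at one
   address are one supply point).
2. **Needs stratification.** Cases are split into *general demand* and
   *high level of need* by WHODAS 2.0 scores (below).
3. **Within-area spatial join.** Each case is matched to its nearest
   provider *in the same administrative area* — resource allocation is
   administered per area, so cross-boundary supply is not credited. Cases in
   provider-less areas are reported separately; they can have no indicator.
4. **Distance curve.** Nearest distances are binned into half-open 50 m bins
   `[50k, 50(k+1))` anchored at 0. The response analysed is the *per-bin
   frequency* `y_k` — the number of users whose nearest provider sits at that
   distance band — against the bin midpoint `x_k`.
5. **Joinpoint fit.** A continuous piecewise-linear model
   `y = β0 + β1 x + Σ γ_i (x − ψ_i)+` is fitted by least squares, the number
   of breakpoints is selected, and each slope change `γ_i` is tested.
6. **Indicators.** *PWD* = smallest significant breakpoint with slope
   `+ → −`; *TLD* = smallest significant breakpoint with slope `− → +`.
   Interpretation: within the PWD, provider supply still grows with distance
   (serving is worthwhile); between PWD and TLD it decays but users tolerate
   the trip; beyond the TLD, services are effectively out of reach.
7. **Classification, density, ranking.** Each area × stratum is classified
   (`both` / `only_pwd` / `only_tld` / `neither`), given its service density
   (cases per provider, 2 d.p.), and areas are ranked: only-TLD first
   (expressed demand with no profitable band), then both by descending TLD,
   then only-PWD, then neither; ties by higher density, then area code.

A distance `d` is zoned relative to an area's indicators with inclusive
bounds: `d ≤ PWD` profitable, `PWD < d ≤ TLD` tolerable, `d > TLD` beyond
tolerance. For an area with only a PWD the region past it is returned as
`unclassified` rather than guessed — with no upturn there is no evidence
about where tolerance ends.

### Why the frequency curve, not the cumulative count

A cumulative count of users by distance is non-decreasing, so its slope can
never change sign and neither indicator could exist. Only on the per-bin
frequency scale does "the distance band holding the maximum number of
matches" (the PWD peak) or a subsequent upturn (the TLD) have meaning; the
package therefore fits frequencies throughout.

## WHODAS 2.0 scoring and stratification

The 36-item WHO Disability Assessment Schedule 2.0, administered without the
four employment/study items (32 items), scores six domains — cognition (6
items), mobility (5), self-care (4), getting along (5), household life
activities (4), participation (8) — each rescaled to 0–100 by simple
sum-and-rescale scoring: `100 × Σ responses / (4 × n items)`; the summary
score rescales all 32 items. Higher scores mean more disability.

A case is *high level of need* when all four of these strict inequalities
hold (published institutionalisation-risk cutoffs for dementia cohorts):
D1 > 77.5, D2 > 78.5, D3 > 55, summary > 66.5. The conjunctive rule is the
only one that makes the two groups exhaustive and disjoint as described;
`needs_cutoffs(rule = "any")` provides the disjunctive alternative for
sensitivity analysis. Some printed summaries of the same cutoff set give
the mobility cutoff as 78 rather than 78.5; the package defaults to 78.5
with `needs_cutoffs(d2 = 78)` available. Pipelines may supply domain scores
directly and skip item scoring; IRT-based scoring is out of scope.

## Joinpoint fitting: numerical choices

* **Candidate grid.** Breakpoints are restricted to bin midpoints, with a
  minimum segment length of 3 bins (standard joinpoint practice). The fit is
  an exhaustive least-squares search over all admissible breakpoint
  combinations — each candidate design is reduced to an orthonormal basis so
  the search is a single pass of matrix products. For very long curves
  (beyond roughly 200 bins at `k = 2`) the candidate set is thinned evenly
  to cap the search at 20 000 combinations; curves of the length the method
  is designed for are always searched exhaustively, and the test suite
  checks grid-search optimality against an independent enumeration oracle.
* **Model selection.** Default is a forward sequential permutation test
  (the permutation analogue of the NCI joinpoint procedure): to test `k`
  vs `k − 1`, residuals of the `k − 1` fit are permuted, both models are
  re-searched on each permuted response, and the observed RSS ratio is
  compared with the permutation distribution; `k` grows while the test
  rejects at `alpha = 0.05` (999 permutations by default, `k_max = 4`).
  BIC (`n log(rss/n) + (2 + 2k) log n`) is the fast alternative. A curve
  with all counts equal short-circuits to `k = 0` with a note.
* **Slope-change significance.** Two-sided test of each `γ_i` with
  breakpoint locations held fixed: a permutation test (drop the hinge,
  permute reduced-model residuals, compare refitted `|γ_i|`) under the
  default path, a t-test under the BIC path. Exact-fit edge cases are
  resolved by the residual scale: zero residuals with a non-zero slope
  change is maximally significant; a zero slope change never is.
* **Reporting grid.** Estimated breakpoints live on bin midpoints (25, 75,
  …); reported PWD/TLD are rounded half-up to the nearest bin-width
  multiple, matching the 50 m granularity planners use. Recovery of a true
  breakpoint is therefore accurate to within one bin width by construction.
* **Determinism.** Fits are deterministic for fixed input; permutation
  results are reproducible for a fixed seed, and every pipeline stage
  derives its seed from the run seed recorded in the manifest.
* **Degenerate inputs.** Empty curves yield no fit and the area reports
  `neither`; curves shorter than two segments return the OLS line; an
  infeasible `(k, n_bins)` request signals an error rather than silently
  refitting.

The distance metric is planar Euclidean on projected metre coordinates by
default (the workflow of a GIS analysis in a projected national grid), with
haversine for longitude/latitude input. Straight-line distance understates
true travel burden, especially in cities; the match table's `distance`
column is deliberately plain so externally computed travel times can be
substituted upstream of the curve stage.

## What the synthetic generators emulate

`gen_area_points()` emulates a registry-like area: providers placed
uniformly or in clusters, and cases placed by inverse sampling of a target
binned density — each case picks a random provider, a distance drawn from
the target curve (bin by probability, uniform within bin) and a uniform
bearing. When a target curve is set, providers are forced at least two
curve-supports apart so a case sampled at any distance within the support
keeps its parent provider as the nearest; this is deliberately stricter
than separating by the largest breakpoint alone, since cases are sampled
beyond it and would otherwise be captured by neighbouring providers,
biasing the curve's right tail. Under that condition the empirical
nearest-distance curve is multinomial around the target, and the pipeline's
recovered PWD/TLD converge to the designed breakpoints as noise vanishes.

`gen_whodas_cohort()` draws domain and summary scores from a two-component
truncated-normal mixture moment-matched to a national community dementia
cohort (high-need domain means ≈ 90–99, general-demand ≈ 40–75, truncated to
[0, 100]), with the cutoff-relevant margins truncated to the correct side of
each cutoff: the generating label is then recovered exactly by
stratification, which makes label-recovery tests sharp. Domain scores are
drawn independently within a component — real WHODAS domains are
correlated — and demographics (age, sex, severity) are drawn from the
matching group profiles.

What passing tests on these generators show is that the *method* — matching,
binning, fitting, selection, extraction, classification, ranking — behaves
as specified under controlled curve shapes and mixtures. They do not show
that real registry data have detectable joinpoints, that straight-line
distance approximates travel burden, or that WHODAS domains are
independent; those are properties of the data, not the software.

## Study conditions used by the checks

The bundled reference tables (`taiwan_profile()`, `taiwan_indicators()`)
record the published national profile of 22 administrative areas: per-area
provider/case counts by needs group, and the published PWD/TLD values per
stratum. Desk-scale checks recompute from them the service densities
(Taipei 9.65, overall mean 5.45, seven areas above it), the indicator
extrema (650 m PWD, 6250 m TLD) and the four-way category counts
(15 / 2 / 2 / 3 across all cases). The registry filter arithmetic is
recomputed on cohorts constructed at the registry sizes (11 967 cases with
2263 institutional; 2116 providers with 330 coordinate repeats). The two
provider counts in circulation for the deduplicated registry (1786 from the
selection flow, 1782 in the density profile) are both surfaced: filters
reproduce 1786, the density table follows its own printed total.

Simulation sizes were chosen to keep the full suite at desk scale:
oracle-equivalence on 12–15-bin curves, breakpoint recovery at 200
replicates of 40-bin curves with noise at 10 % of peak, type-I control of
the permutation selector at 200 flat-curve simulations with 199
permutations, and end-to-end recovery on areas of 800–2000 cases. The
package defaults (999 permutations, `k_max = 4`) remain the analysis
settings; the reduced permutation count in the simulation studies only
widens the resolution of the estimated rejection rate, not the level of the
test.

## Known limitations

* Straight-line distance, not travel time; no road-network routing.
* Cross-area matching is disallowed by default (one `same_area = FALSE`
  switch exists for sensitivity analysis, without per-area reporting of
  foreign matches).
* Sparse areas — few cases, hence short or noisy curves — legitimately
  return `neither`; with very small strata the permutation test has little
  power and absence of an indicator should not be read as absence of need.
* The only-PWD zone past the PWD is reported `unclassified`; the method
  offers no principled outer bound there.
* Coordinate deduplication is exact; providers geocoded to slightly
  different coordinates at one address are not collapsed.
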