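---
title: "Segmental treatment planning and trial statistics: methods and design choices"
author: "stepup package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmental treatment planning and trial statistics: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stepup)
```

This vignette documents the models implemented by **stepup**, the
assumptions behind them, the numerical conventions, and the design
choices that were genuinely open — in enough detail that a maintainer
can tell deliberate behaviour from accident.

## 1. Densitometry

A CT voxel is modelled as a two-compartment linear mix of air
(−1000 HU) and tissue/water (0 HU), so the tissue fraction is
`f = (HU + 1000)/1000`, clipped to [0, 1] outside the calibration range.
This is the standard lung densitometry convention; nothing in the
planning design depends on a different calibration, and none is
specified by it, so the linear model is fixed rather than configurable.
Per segment, tissue volume is `Σ v·f` and air volume `Σ v·(1 − f)` over
its voxels of volume `v`, which makes tissue + air conserve the labelled
volume identically (the test suite checks this to 1e−9 relative).

The tissue-to-air ratio is expressed in **percent**,
`TAR = 100·tissue/air`. That choice matters: the screening threshold
"lower-lobe TAR below 11 %", the 2-point equal-disease tolerance and the
0.30-point combined-TAR tolerance are all absolute percentage points on
this scale. Whether those tolerances might instead be *relative*
percentages is undecidable from their one-line statements; absolute
points are adopted because the screening threshold is unambiguously an
absolute value on the same scale, and mixing conventions between
thresholds would be stranger than either pure reading.

TAR is computed from volumes, not masses. A mass-based ratio would scale
tissue by ≈1 g/ml and air by ≈1.2 mg/ml and produce values three orders
of magnitude larger than the stated 11 % threshold, so the volume
reading is the only one consistent with the printed numbers.

### The phantom generator

`generatePhantom()` encodes a target TAR as a mean Hounsfield value:
`f = TAR/(100 + TAR)`, `HU = −1000·(1 − f)` (e.g. TAR 10 % → −909.1 HU),
plus zero-mean Gaussian noise (default SD 20 HU) clipped to
[−1000, 0]. Because the summed volumes depend only on the mean
fraction, recovery is unbiased up to clipping, which is negligible at
emphysema-range means (−850 to −950 HU, several noise SDs from either
bound). Recovery precision is shot-noise limited: with SD 20 HU a
segment of *n* voxels recovers its TAR with a standard error of roughly
`2/sqrt(n)` percentage points, so the declared 0.5-point round-trip
tolerance presumes segments of at least a few thousand voxels. The
round-trip test therefore uses 20–60 ml segments at 0.01 ml/voxel
(2 000–6 000 voxels) — far smaller than real segments (hundreds of ml),
which only makes the check conservative in precision per ml. Voxels are
isotropic by default; anisotropic spacing enters via `spacing_mm`,
whose product defines the voxel volume. Phantoms emulate *densitometry*
only: block-shaped segments, no anatomy, no partial-volume boundary
effects, no scanner point-spread — passing tests say the volume
arithmetic is right, not that real HRCT segmentation would be.

## 2. The planning algorithm

### Heterogeneity index

The HI is implemented as `lower-lobe TAR / segmental TAR`. The defining
ratio is stated only pictorially in the source material, so the
direction is fixed by its meaning: upper-lobe-predominant disease means
the upper segment is *less* dense (lower TAR), and the eligibility rule
"HI of no less than 1.2" must select such segments, which requires the
lower-lobe TAR in the numerator. The inverse convention would make the
criterion select *healthier-than-lower-lobe* segments, contradicting
the stated intent of treating the most diseased tissue.

### Combined TAR

`combinedTAR()` aggregates treated segments by summing volumes before
taking the ratio, `100·Σtissue/Σair` — an air-weighted mean of the
segmental TARs — rather than an unweighted mean of per-segment TARs.
TAR is a ratio of volumes, and the aggregate of a set of segments
should equal the TAR the set would have if measured as one region; only
the volume-aggregated form has that property. The same convention
produces the merged LB1+2 entry from LB1 and LB2, which keeps "treat
LB1 and LB2 separately" and "treat LB1+2" numerically identical — the
reason the pair {LB1, LB2} is deduplicated to the merged segment when
options are enumerated.

### Enumeration

Session 1 takes one treatable segment of the primary lobe (left adds
LB1+2, giving 4 choices; right has 3), session 2 takes a single or an
unordered pair of distinct-tissue segments of the contralateral lobe
(right: 6 sets; left: 7, since {LB1, LB2} collapses into LB1+2). Hence
24 options with the left lobe primary, 21 with the right, 45 in total.
Nothing in the design fixes which lobe is treated first, so the default
enumerates both assignments and lets the constraint and selection rules
decide; `primary_side` pins it when a clinical decision already exists.

### Constraints and windows

An option is feasible iff session 1 treats 30–70 % of its lobe,
session 2 treats 40–80 % of its lobe, the combined fraction lies in
95–130 % (each lobe = 100 %, both = 200 %), neither session exceeds
1700 ml, and every treated segment has HI ≥ 1.2. All comparisons are
inclusive: the thresholds are stated as attained values ("no less
than", "not exceed"), so boundary cases pass. Fractions and the
combined target are kept on the stated 200 % two-lobe scale; no
attempt is made to reweight unequal lobe sizes beyond it.

**Lobe-fraction denominator.** On the left, the lobe contains the
lingula (LB4+LB5, roughly a third of its volume) which is never
treated. With the whole anatomical lobe as denominator, three
treatable segments can plausibly fail to reach the 40 % session-2
floor at realistic volumes, making the window unattainable by
construction. The default denominator is therefore the sum of the
*treatable* segment volumes; `denominator = "anatomical"` restores the
whole-lobe convention for sensitivity analyses. This is the one place
where the implementation had to choose between readings that change
results; the flag keeps both auditable.

### Selection

From the feasible set: (1) options treating a lobe's *unique*
least-diseased segment (largest TAR exceeding every other by more than
the 2-point tolerance; LB1+2 counts as treating LB1 and LB2) are
removed, unless that removal would empty the set — the dominance rule
can narrow but never annihilate. (2) A single survivor is chosen
outright. (3) Otherwise the minimum combined TAR wins; survivors within
0.30 points of it form a tie group, inside which the combined fraction
closest to the 110 % target is preferred. (4) Residual exact ties break
lexicographically on the canonical option id (C collation), making the
selection a deterministic function of its inputs. Every enumerated
option carries its computed volumes, fractions, minimum HI, combined
TAR, per-constraint verdicts, dominance-removal and tie-group flags in
the audit, and `revalidatePlan()` recomputes the chosen option from raw
volumes.

The test suite checks the whole pipeline against an independently
written brute-force oracle (its own enumeration, fraction, HI,
dominance and tie logic) on 500 generated lungs, including agreement on
every "no feasible plan" verdict.

## 3. Eligibility screening

Criteria that are computable from numbers are implemented with the
printed comparison directions and inclusive boundaries (FEV1 = 20 %
predicted passes the 20–45 % band; DLCO = 20 % and BMI = 32 pass their
exclusions; RV must *exceed* 150 %). History and imaging criteria that
no number can decide (bronchiectasis, exacerbation history, consent,
heterogeneous ULPE on imaging) are boolean attestations. Three
conventions deserve note:

* **mMRC threshold.** Both "≥ 2" and "> 2" circulate for the dyspnea
  criterion. The default is ≥ 2 — the broader, abstract-level
  statement — with `mmrc_rule = "gt2"` as a switch, and the applied rule
  echoed in the decision metadata so downstream consumers see which
  convention produced a verdict.
* **Pulmonary-artery pressure.** Right-heart-catheter values are
  definitive over echocardiography when both exist; with neither
  measured, the record is non-excluding only when the absence of
  pulmonary hypertension is attested.
* **Hospitalization count.** The "> 3 COPD-related hospitalizations in
  12 months" exclusion is an integer count with threshold > 3, combined
  with the 6-week recent-exacerbation attestation into one criterion.

The decision is a pure conjunction; a monotonicity test pushes each
numeric field through its threshold and checks that exactly the
expected criterion flips (FEV1 below 20 % deliberately flips two: the
inclusion band and the exclusion floor both name it).

## 4. Trial statistics

**Sample size.** Power is exact noncentral-*t* (not the normal
approximation): df `n_t + n_c − 2`, noncentrality
`δ/(σ·sqrt(1/n_t + 1/n_c))`. The routine returns the smallest
`n_c ≥ 2` with `n_t = ceiling(r·n_c)` reaching the target, so at an
exact 2:1 ratio the total is always a multiple of 3. Under the SGRQ
assumptions (δ = 11, σ = 14, 80 % power, α = 0.05 two-sided) this gives
20/40/60. Under the FEV1 assumptions (δ = 12, σ = 15) it also gives 60:
a total of 59 — the figure quoted for that endpoint in the design
literature, produced by a commercial program — is not a multiple of 3
and cannot arise under an exact 2:1 allocation; it evidently reflects
ratio rounding internal to that software (57 or 60 are the adjacent
exact-ratio candidates). The package documents rather than imitates
this: its convention is the exact ratio. Dropout inflation is
`ceiling(n·(1 + rate))` with a 1e−9 guard against float fuzz on exact
products; 60 at 15 % gives 69.

**Hochberg rule.** With two co-primary endpoints the trial is positive
iff both p-values are ≤ 0.05 or either is ≤ 0.025 — equivalently
`max(p) ≤ 0.05 || min(p) ≤ 0.025`, inclusive at both thresholds, and
monotone in each p-value.

**Responders.** FEV1's "≥ 12 % difference from baseline" is implemented
as *relative* change of the percent-predicted value (the convention of
earlier vapour-ablation reporting), with an absolute-points switch;
SGRQ responds at a drop of ≥ 8 points, 6MWT at a gain of ≥ 30 m, all
inclusive.

**Missing data.** The 12-month value is used when observed; missing
because of an SAE (including death) → the *worst* prior follow-up
value, where "worst" is direction-aware (lowest FEV1/6MWT, highest
SGRQ — the source does not define it, and any other reading would let
an SAE improve a subject's endpoint); missing otherwise → last
available prior follow-up; no follow-up data at all → baseline carried
into the ITT analysis and flagged for the sensitivity analysis that
excludes such subjects. Every series maps to exactly one provenance
class.

**Randomization.** Permuted blocks within site at 2:1 (block 3 = 2T+1C
by construction, block 6 available), so marginal imbalance is bounded
by one incomplete block per site. Each site's sequence derives
deterministically from the scheme seed and the site's rank, so late
enrolment at one site never perturbs another's sequence.

## 5. The synthetic-data engine

The generators' defaults *are* the study conditions, chosen once:

* **Outcomes** are normal with common SD per arm — exactly the
  assumption the t-test design makes — with the between-arm difference
  reaching the assumed effect at 12 months (11 points at SD 14 for
  SGRQ; 12 %-predicted at SD 15 for FEV1) and interpolating linearly at
  earlier visits. Baselines are plausible for the screened population
  (FEV1 ~ N(32, 6) %pred, SGRQ ~ N(60, 10), 6MWT ~ N(300, 60) m).
  Missingness is simple Bernoulli with a recorded cause ("sae" vs
  "other") and a uniformly chosen onset visit — no distributional model
  for dropout timing exists in the design, so none is invented — and by
  default is independent of outcome (switchable in principle for
  sensitivity work, deliberately not a tested pathway).
* **Virtual lungs** draw lower-lobe TARs from 12–20 % (clearing the
  11 % screen), treatable upper segments of 250–700 ml, lingula
  150–350 ml, lower lobes 1100–1900 ml, and set each upper segment's
  TAR to `lower-lobe TAR / HI` with `HI = 1 + strength·U(0.3, 1.3)`:
  strength 1 guarantees every segment passes HI ≥ 1.2, strength 0 gives
  a perfectly homogeneous (untreatable) lung. The oracle-equivalence
  tests deliberately widen the volume range to 150–900 ml and the
  lower-lobe TAR range to 10–22 % and sweep strength over [0, 1], so
  that every constraint — including the 1700 ml cap and the HI floor —
  actually rejects options and both feasible and infeasible verdicts
  occur in quantity.
* **Calendars.** Weeks are integers from study day 1 (first treatment
  session for the treatment arm, randomization for control). The
  second session is expressed in days for its ±7-day window: nominal
  day 91 (13 weeks), window 84–98, latest start 126 when the allowed
  4-week healing delay is added to the window's upper edge.

What the generators do **not** emulate: real HRCT noise structure and
segmentation error, correlated dropout, site effects, repeated-measures
correlation within subject beyond the shared baseline. Passing tests
validate the algorithmic machinery on data satisfying the design's own
assumptions; they are silent on robustness to violations of those
assumptions.

## 6. Numerical conventions and problem sizes

Tolerance comparisons are inclusive (`≤`) throughout. String ordering
uses C-locale radix sorting everywhere a tie-break or canonical id
depends on it. All randomness flows through explicit seeds via an
internal RNG-state-preserving helper; per-site and per-chunk seeds are
derived to stay below 2³¹. The Monte-Carlo power engine computes the
pooled two-sample t statistic in closed form, vectorised over
replicates and chunked at 20 000 to bound memory; a unit test pins it
replicate-for-replicate against `stats::t.test`. Problem sizes in the
routine test run — 500 lungs for oracle equivalence, 100 phantoms of
20–60 ml for the densitometry round trip, 10 000 replicates for the
power checks (100 000 in the acceptance script) — were chosen as the
smallest sizes at which the checked tolerances are comfortably inside
sampling noise.

## 7. Known limitations

* No vapour dose/energy model: the design states no formula linking
  treated volume to delivered energy, so the planner stops at volumes.
* No real-image ingestion: DICOM/HRCT segmentation is out of scope; the
  densitometry path starts at labelled voxels or per-segment tables.
* The eligibility screen evaluates the computable criteria; it is a
  decision aid, not a clinical adjudication.
* The planner's audit reports what the algorithm did; whether the
  2-point and 0.30-point tolerances are absolute (as implemented) or
  relative cannot be settled from the available statements, and a
  relative reading would change tie groups for lungs with TARs far
  from the 10 % scale the thresholds were evidently written for.
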