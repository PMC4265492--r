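# stepup

Quantitative-CT treatment planning and trial statistics for staged,
bilateral, **segmental** bronchoscopic lung volume reduction (LVR) in
upper-lobe predominant emphysema (ULPE).

In severe heterogeneous emphysema, ablating the most diseased upper-lobe
tissue lets the healthier remainder expand and improves lung function.
Because thermal vapour ablation works in the presence of collateral
ventilation, treatment can target individual bronchopulmonary segments
rather than whole lobes — but that turns target selection into a small
constrained optimisation problem. This package is for trialists,
image-analysis engineers and biostatisticians who need that selection
algorithm, the accompanying eligibility screen, and the supporting trial
design machinery in one reproducible, auditable implementation.

## The model

Per segment, quantitative CT yields a tissue volume and an air volume
(ml); their ratio in percent is the **tissue-to-air ratio**,

    TAR = 100 · V_tissue / V_air ,

a density measure: lower TAR means more emphysematous destruction. The
**heterogeneity index** of an upper-lobe segment compares it with the
ipsilateral lower lobe,

    HI = TAR_lower-lobe / TAR_segment ,

and a segment is treatable when HI ≥ 1.2. A **treatment option** treats
one segment of the primary upper lobe in session 1 and one or two
segments of the contralateral lobe in session 2 (left upper lobe: LB1,
LB2, LB3, with LB1 and LB2 mergeable into LB1+2; right: RB1, RB2, RB3;
the lingula LB4/LB5 is never treated). An option is feasible when

* session 1 treats 50 % ± 20 % of its lobe,
* session 2 treats 60 % ± 20 % of its lobe,
* together they treat 110 % +20/−15 % of the two lobes (each lobe
  counts as 100 %, both as 200 %),
* neither session exceeds 1700 ml, and
* every treated segment has HI ≥ 1.2.

Among feasible options, any option treating a lobe's *unique*
least-diseased segment (largest TAR by more than 2 TAR points) is
removed unless all remaining options treat one. The preferred plan then
minimises the **combined TAR**, `100 · ΣV_tissue / ΣV_air` over all
treated segments; options within 0.30 TAR points of the minimum are
treated as equivalent and the one whose combined fraction is closest to
the 110 % target wins.

The trial-statistics side implements the two-sample noncentral-*t*
sample size under an exact 2:1 allocation, 15 % dropout inflation, the
two-endpoint Hochberg decision rule (positive iff `max(p) ≤ 0.05` or
`min(p) ≤ 0.025`), responder definitions (FEV1 ≥ 12 % relative gain,
SGRQ ≥ 8-point drop, 6MWT ≥ 30 m gain), the missing-data hierarchy
(observed → worst-prior after an SAE → last observation carried forward
→ baseline intent-to-treat), site-stratified permuted-block
randomization, the per-arm visit calendars, and a synthetic-data engine
(voxel phantoms, virtual lungs, outcome cohorts, Monte-Carlo power).

## Worked example

```r
library(stepup)

tab <- readSegmentTable(system.file("extdata", "segments_f1.csv",
                                    package = "stepup"))
model <- buildLungModel(tab)
model
#> LungModel (11 segments, denominator = treatable)
#>   upper-lobe TAR range: 8.60-12.80%
#>   lower-lobe TAR: left 16.00%, right 15.00%

sel <- selectPlan(model)
sel
#> PlanSelection: feasible
#>   session 1 (left lobe): LB2  [480 ml, 33.1% of lobe]
#>   session 2 (right lobe): RB1,RB2  [1020 ml, 64.6% of lobe]
#>   combined fraction 97.7% (target 110%), combined TAR 8.896%
#>   options audited: 45
```

The audit explains the outcome: LB3 (TAR 12.8 %, more than 2 points
above its neighbours) is the left lobe's unique least-diseased segment,
so every option treating it is removed; the minimum combined TAR
(8.828 %, `left:LB1|RB1,RB2`) is within 0.30 points of several rivals,
and `left:LB2|RB1,RB2` wins the tie because its combined fraction sits
closest to the 110 % target. `planAudit(sel)` returns all 45 options
with every computed fraction, volume, HI and constraint verdict;
`revalidatePlan(sel, model)` re-derives the chosen plan from the raw
volumes.

On the statistics side:

```r
sampleSizeTwoSample(designAssumptions(11, 14))
#> $n_control   20
#> $n_treatment 40
#> $n_total     60
#> $achieved_power 0.8054519
inflateForDropout(60, 0.15)
#> [1] 69
```

A mean SGRQ difference of 11 points (SD 14) at 80 % power, two-sided
α = 0.05 and 2:1 allocation needs 60 patients (40/20); anticipating 15 %
loss to follow-up inflates enrolment to 69.

A command-line wrapper ships as `exec/stepup` inside the installed
package, with subcommands `plan`, `verify`, `screen`, `samplesize`,
`randomize`, `simulate`, `fixture-lung` and `phantom` (exit 0 = success,
2 = validation error, 3 = no feasible plan):

```sh
STEPUP=$(Rscript -e 'cat(system.file("exec/stepup", package = "stepup"))')
Rscript "$STEPUP" plan --segments segments.csv --out plan.json
```

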