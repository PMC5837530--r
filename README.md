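# longdbm

Longitudinal deformation-based morphometry in R, with a synthetic phantom
cohort for end-to-end validation.

After a moderate–severe traumatic brain injury (TBI), the brain keeps losing
tissue for months to years. Measuring that loss from a pair of structural MRI
scans is a registration problem: warp the baseline image onto the follow-up
image and read the local volume change off the warp. `longdbm` implements
that analysis chain for researchers who want a self-contained, testable
version of the longitudinal pipeline:

1. **Symmetric within-subject registration.** A single stationary velocity
   field `v` is estimated so that the baseline warped by `exp(-v/2)` matches
   the follow-up warped by `exp(+v/2)` (symmetric demons with fluid and
   diffusion regularization over a multi-resolution pyramid). The midpoint
   image is the subject's "temporal average"; the full warp is `exp(v)`.
2. **Jacobian determinant (JD) maps.** `JD(x) = det(∇(x + u(x)))` is the
   voxelwise volume ratio between the scans; `JD < 1` means local tissue
   loss. Maps are annualized geometrically, `exp(log JD / Δt)`, so differing
   inter-scan intervals are comparable.
3. **Summaries and statistics.** Tissue and per-ROI mean JD, annualized
   atrophy rates `100 · (V_followup − V_baseline)/V_baseline / Δt`,
   voxelwise group GLMs with TFCE + Freedman–Lane permutation correction,
   covariate-adjusted group models, hierarchical (Shapley) partitioning of
   R², a sulcus-versus-gyrus linear mixed model with a group × region-class
   interaction, Spearman correlations with neuropsychological scores under
   Benjamini–Hochberg FDR, and lesion-exclusion sensitivity re-runs.
4. **Trial power.** Cohen's d from pooled SDs and the per-arm sample size
   `N = ⌈2·((1.96 + 0.842)/(TE · ES))²⌉` for 80% power at two-sided
   α = 0.05, as a function of treatment effectiveness TE.

Real patient scans are not shipped. Instead, the `synthetic_cohort` tools
build longitudinal phantom pairs with *known* ground-truth deformation —
group-calibrated annual atrophy rates per tissue, excess sulcal atrophy in
cases, scanner offsets, lesions, variable inter-scan intervals — so every
stage can be verified by parameter recovery.

## Worked example

Simulate a subject with a uniform −2 %/yr atrophy, register the pair and
recover the rate:

```r
library(longdbm)

ph  <- buildTemplatePhantom(phantomSpec())      # 48^3 grid, 3 mm voxels
at  <- atrophySpec(rateMean = matrix(-2, 2, 2,
         dimnames = list(c("case","control"), c("GM","WM"))),
       rateSd = matrix(0, 2, 2,
         dimnames = list(c("case","control"), c("GM","WM"))),
       sulcalExcess = 1, lesionProb = 0, scannerOffset = 0)
rec  <- list(id = "P001", group = "case", scanner = "A", interval_years = 1)
def  <- drawSubjectDeformation(at, rec, ph$labels, seed = 7)
pair <- synthesizePair(ph$template, def$pullback, rec, phantomSpec(),
                       seed = 11, labels = ph$labels)

reg <- registerSymmetric(pair$baseline, pair$followup)
jd  <- annualizeJd(jacobianMap(reg$fullWarp), rec$interval_years)
tissueMeanJd(jd, tissueMask(ph$labels, "GM"))$mean
#> [1] 0.9815
tissueMeanJd(jd, tissueMask(ph$labels, "WM"))$mean
#> [1] 0.9786
```

Both compartment means sit within ±0.005 of the simulated annual volume
ratio 0.98 — i.e. the pipeline recovers a 2 %/yr loss to better than a
quarter of a percentage point. Effect sizes and trial sizes from the
study-condition rate distributions:

```r
cohensD(1.51, 1.60, 61, 0.22, 0.83, 32)
#> Cohen's d = 0.930 (95% CI 0.482 to 1.379), pooled SD = 1.387
sampleSizePerArm(te = 0.25, es = 1.15)
#> [1] 190
powerCurve(0.93, c(0.25, 0.5))
#>     te n_per_arm
#> 1 0.25       291
#> 2 0.50        73
```

So a placebo-controlled trial using the white-matter JD endpoint needs 190
subjects per arm to detect a 25% slowing of atrophy, versus 291 using
whole-brain volume change.

`runPipeline(defaultConfig())` executes the whole chain (simulate →
register → JD → summarize → voxelwise → cohort stats → power) on a 12 + 8
phantom cohort; `inst/scripts/longdbm-pipeline.R` wraps it for the shell.

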