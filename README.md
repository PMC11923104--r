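# StromaSurv

Automated quantification of the tumor microenvironment on H&E histology,
and its use for prognosis. In stroma-rich cancers such as pancreatic
ductal adenocarcinoma, the fractions of a pathologist-outlined region of
interest (ROI) occupied by desmoplastic stroma, tumor glands and
lymphocytes — **SIP**, **TIP** and **LIP** (stroma / tumor / lymphocytes
in percentage) — carry prognostic information: both unusually low *and*
unusually high SIP are unfavorable compared with an intermediate band,
and high LIP is protective. `StromaSurv` implements the full analysis
chain that turns a slide image into these markers and the markers into
risk groups:

1. **Tile geometry.** The ROI is tessellated into square tiles of
   396 px at 0.25 µm/px (a physical side of 396 × 0.25 = 99 µm). The
   segmentation network uses only unpadded ("valid") convolutions, so a
   396-px input window predicts its central 212-px output window; output
   windows partition the ROI while input windows overlap (the
   overlapping-tile strategy), with mirror reflection at slide borders.
2. **Stain normalization** by the Macenko method: optical-density
   conversion, low-OD filtering, SVD plane projection, percentile angle
   extremes, robust (99th-percentile) concentration scaling.
3. **Segmentation** with a valid-convolution U-Net (depth 4, two 3×3
   convolutions per block, 2×2 max-pooling, transpose-convolution
   upsampling, center-crop skip connections, 10 % dropout, softmax over
   {stroma, tumor, lymphocyte}), trained with Adam, batch-wise
   cross-entropy over non-ignored pixels, learning-rate reduction by 90 %
   after 3 flat epochs and early stopping after 5. The network,
   including backpropagation, is implemented in R/RcppArmadillo — no
   external deep-learning framework is required.
4. **Quantification.** Per slide,
   `A_Stroma = A_ROI − (A_Tumor + A_Lymphocytes)`, and
   SIP = A_Stroma/A_ROI, LIP = A_Lymph/A_ROI, TIP = A_Tumor/A_ROI
   (sip + lip + tip = 1 exactly).
5. **Cutpoints.** LIP is dichotomized by the maximally selected rank
   statistic (log-rank scores, Lausen–Schumacher adjusted p-value); SIP
   is split into three populations by an exhaustive X-tile-style search
   over all admissible cut pairs maximizing the 3-group log-rank
   chi-square. SIP-low and SIP-high are merged into **SIP-LH**, and
   patients fall into Group 1 (SIP-intermediate ∧ LIP-high), Group 3
   (SIP-LH ∧ LIP-low) or Group 2 (everything else).
6. **Survival analysis.** 30-day perioperative-mortality exclusion,
   Kaplan–Meier medians with log(−log) CIs, log-rank tests, and
   univariate → multivariate Cox modeling with p < 0.05 carry-forward.

Because clinical slides cannot ship with a package, `StromaSurv` also
contains first-class synthetic-data generators: procedural H&E-like
scenes (pink fibrous stroma, ring-shaped glands with pale lumina, dark
lymphocyte clusters) with *exact* ground-truth masks, and survival
cohorts with a known SIP/LIP-dependent hazard structure. Every stage of
the pipeline is tested end-to-end against these generators.

## Worked example

A synthetic cohort of 800 patients is generated with true SIP band
(0.54, 0.75], true LIP cut 0.02, and exponential hazards per group; the
cutpoint machinery then recovers this structure from the survival data
alone:

```r
library(StromaSurv)
params <- cohortParams(nPatients = 800, seed = 1)
cohort <- filterCohort(generateCohort(params))
#> filterCohort: removed 44 perioperative death(s) ...

(sipCut <- xtileTwoCut(cohort$sip, cohort$os_months, cohort$event,
                       markerName = "sip"))
#> CutpointResult [sip]: cuts 0.5471, 0.7545, max statistic 57.4080
#>   groups: SIP-low: 194, SIP-intermediate: 301, SIP-high: 261

(lipCut <- maxstatBinary(cohort$lip, cohort$os_months, cohort$event,
                         labels = c("LIP-low", "LIP-high"),
                         markerName = "lip"))
#> CutpointResult [lip]: cut 0.0202, max statistic 6.4574, p = 9.936e-09
#>   groups: LIP-low: 331, LIP-high: 425

cohort$group <- combinedGroups(mergeSipLH(groupLabels(sipCut)),
                               groupLabels(lipCut))
cmp <- compareGroups(cohort, "group")
cmp$groups[["1"]]
#> SurvivalSummary: n = 171, events = 108, median OS 32.1 months (95%CI: 25.8-37.3)
cmp$groups[["3"]]
#> SurvivalSummary: n = 201, events = 180, median OS 8.9 months (95%CI: 7.0-10.4)
cmp$contrasts
#>      contrast        hr     lower     upper            p
#> 1      1 vs 2 0.6213062 0.4975831 0.7757928 2.661205e-05
#> 2      1 vs 3 0.2538977 0.1952501 0.3301613 1.463523e-24
#> 3 1 vs others 0.5015248 0.4061091 0.6193585 1.461317e-10
```

The recovered cuts (0.547, 0.754) and 0.0202 sit on top of the
generating values; Group 1 (optimal stroma *and* high lymphocyte
infiltration) shows the survival advantage the grouping is designed to
capture, and the multivariate Cox model (`coxCarryForward(cohort,
c("sip", "lip", "age"))`) retains SIP and LIP as independent predictors.

For the imaging half, see the vignette (`vignettes/stroma-pipeline.Rmd`):
generating labeled scenes, training a small U-Net, segmenting a slide
through `segmentSlide()` and quantifying it with `quantifySlide()`.

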