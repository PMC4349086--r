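# flywalk

Automated morphometric phenotyping of single walking fruit flies
(*Drosophila melanogaster*) from two-channel image sequences, and
feature-based ranking for artificial-selection experiments.

Selection experiments on size-related traits need thousands of flies
phenotyped and sorted individually; manual measurement under a microscope is
the accuracy gold standard but far too slow. `flywalk` implements the
software side of an automated alternative: a fly walking up a narrow backlit
tunnel is imaged in two illumination channels — blue backlighting renders
the body silhouette and makes the wings translucent, red side-light
transilluminates the body so wing veins stay visible where wings overlap the
abdomen — and the package turns those frame sequences into a per-fly row of
morphometric traits, a sex call, and a selection decision.

## Pipeline

For each fly the package

1. **validates frames** — focus (variance of the Laplacian), border
   clearance, wing reflections, dorsal wing exposure, tunnel alignment and
   bilateral symmetry; a sequence is accepted iff it has ≥ 3 valid frames;
2. **aligns** the complemented blue frames by central image moments
   (centroid + second-moment major axis, abdomen-down convention);
3. **removes the moving legs** with a temporal 95th-percentile projection
   over the aligned stack;
4. **segments the body** into head, thorax and abdomen by marker-controlled
   watershed on the distance transform, and fits a second-moment ellipse to
   each segment; shoulder width SW comes from the thorax template scale;
5. **calls sex** by fusing the Pearson correlation of the abdominal
   luminance profile against average male/female curves with sex-comb
   detection (compact dark spots anterior to the head, eccentricity-filtered);
6. **measures the head**: ocelli located by normalized cross-correlation
   template matching, then the interocular distance IOD is the span between
   the outermost luminance-derivative peaks along the line through the
   posterior ocelli;
7. **measures the wings**: thin wing structures are extracted from both
   channels (blue off-body, red over the body), skeletonized (Zhang–Suen),
   and a B-spline template of the outline plus longitudinal veins L2–L5 is
   fitted by trimmed ICP followed by iterated least-squares spline refits.
   Wing length WL = |hinge − outline∩L3|, wing width
   WW = |outline∩L2 − outline∩L5|, wing area WA = area enclosed by the
   outline;
8. **ranks and selects** the top/bottom individuals per sex on relative wing
   size (default criterion WA/SW², dimensionless).

A parametric synthetic fly renderer (`sample_fly()`, `render_sequence()`,
`render_population()`) produces two-channel sequences with exact ground
truth for every trait, so the whole pipeline is testable without hardware,
and agreement statistics against manual measurements (bi-square robust
regression, percent residuals, boxplot summaries with the 1.5 box-width
outlier rule) are provided in `bisquare_regression()` /
`agreement_report()`.

## Worked example

```r
library(flywalk)

pop <- render_population(4, seed = 42, render_config(seed = 9))
names(pop$sequences) <- sprintf("fly_%03d", 1:4)
out <- analyze_batch(pop$sequences)
out$measurements[, c("fly_id","well_index","sex","iod","sw","wl","ww","wa")]
#>    fly_id well_index    sex   iod    sw     wl    ww   wa
#> 1 fly_001          1   male 21.57 35.58  75.83 31.24 2104
#> 2 fly_002          2   male 23.64 33.93  92.18 41.47 3219
#> 3 fly_003          3 female 26.34 40.59  98.65 45.29 3785
#> 4 fly_004          4 female 24.40 40.08 100.31 43.24 3679
```

All measurement columns are in pixels (`*_mm` columns use the configured
`mm_per_px`); `iod`/`sw` are the interocular distance and shoulder width,
`wl`/`ww`/`wa` the wing traits. Compare with the generator's truth table
`pop$truth`: here the wing traits agree to about a percent, the body traits
to a few percent. Selection then ranks each sex by relative wing size:

```r
sel <- select_extremes(score_records(out$measurements), n_top = 1, n_bottom = 1)
sel$table
#>   well_index  fly_id    sex score  group
#> 1          3 fly_003 female 2.297    top
#> 2          4 fly_004 female 2.290 bottom
#> 3          2 fly_002   male 2.796    top
#> 4          1 fly_001   male 1.662 bottom
```

A thin command-line driver with verbs `simulate`, `analyze`, `validate` and
`select` is installed at `inst/cli/flywalk.R`.

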