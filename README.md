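# gratio — binned g-ratio morphometry for axon–myelin analysis

The g-ratio of a myelinated nerve fiber is the ratio of the inner axon
diameter *a* to the outer fiber diameter *f* = *a* + 2*m* (axon plus the
two-sided myelin sheath):

&nbsp;&nbsp;&nbsp;&nbsp;*g* = *a* / (*a* + 2*m*)

In healthy mammalian tracts *g* stays near 0.6–0.8 across fiber calibers
(the axomyelin unit model); demyelination thins the sheath relative to the
axon and pushes *g* upward. Electron-microscopy segmentation tools produce
per-fiber axon and myelin measurements but leave the analysis — cleaning,
g-ratio computation, caliber stratification, statistics — to ad hoc
spreadsheet work. `gratio` is an R package for that post-segmentation step:

* **ingest** of spreadsheet workbooks holding paired per-sample columns
  `<Sample>_Ax` (axon diameter, µm) and `<Sample>_My` (myelin thickness,
  µm, two-sided);
* **biologically informed cleaning** with complete exclusion logging
  (axon < 0.15 µm, myelin < 0.03 µm, g outside [0.5, 0.9]; all bypassable
  as a unit, with strict-inequality semantics);
* **morphometry**: fiber diameter, full-precision and two-decimal g-ratio,
  and a plausibility flag for unexpected fiber-diameter/g correlations;
* **stratification** into six diameter bins derived from the control
  dataset and applied unchanged to all groups;
* **statistics** per bin (mean/median/SD, Shapiro–Wilk, Hartigan's dip test
  — implemented exactly in compiled code), a constant-g grand mean, and a
  Type II two-way group×bin ANOVA;
* a fully parameterized **synthetic-data generator** with mathematically
  exact ground-truth g-ratios, used to validate the entire pipeline.

## Worked example

Simulate a control and a demyelinated condition, then run the two-group
comparison exactly as one would on real exported measurements:

```r
library(gratio)

cfg <- sim_config(seed = 42)                     # 5 subgroups x 1000 fibers
write_simulated_workbook(simulate_condition(cfg, "CTL"), "ctl.xlsx")
write_simulated_workbook(simulate_condition(cfg, "EXP"), "exp.xlsx")

res <- run_comparison("ctl.xlsx", "exp.xlsx", "out", plots = FALSE)
res$control$grand_g$value
#> [1] 0.7091696
res$experimental$grand_g$value
#> [1] 0.8041793
print(as.data.frame(res$anova), digits = 4)
#>        term   df    sum_sq   mean_sq         F      p
#> 1     group    1 22.460331 2.246e+01 22840.334 0.0000
#> 2       bin    5  0.006823 1.365e-03     1.388 0.2254
#> 3 group:bin    5  0.005268 1.054e-03     1.071 0.3740
#> 4  residual 9986  9.819859 9.834e-04        NA     NA
```

The grand means recover the imposed condition parameters (0.70 and 0.80, up
to the generator's truncation effects), the group effect dominates, and the
per-bin summaries in `res$summaries` show the experimental g sitting above
control in every diameter bin. Outputs written to `out/` include the
cleaned-data, per-bin summary and exclusion workbooks plus a run manifest
with stage-by-stage row accounting.

A command-line wrapper over the same functions ships at
`inst/cli/gratio.R`:

```sh
Rscript inst/cli/gratio.R simulate --condition CTL --seed 42 --out ctl.xlsx
Rscript inst/cli/gratio.R analyze --input ctl.xlsx --group CTL --out-dir out
Rscript inst/cli/gratio.R compare --control ctl.xlsx --experimental exp.xlsx --out-dir out
```

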