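---
title: "Methods: binned g-ratio morphometry and its validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: binned g-ratio morphometry and its validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A myelinated fiber is summarized by two post-segmentation measurements: the
inner axon diameter $a$ and the myelin sheath thickness. The package works
throughout in the *two-sided* myelin convention $M_y = 2m$ (the sheath's
contribution to the fiber diameter, twice the radial thickness $m$), so the
outer fiber diameter and the g-ratio are

$$ f = a + M_y, \qquad g = \frac{a}{f} = \frac{a}{a + 2m}. $$

In healthy mammalian tracts $g$ sits near 0.6–0.8 over a wide range of
calibers (the axomyelin unit model: fiber diameter scales linearly with axon
diameter). Demyelination thins the sheath relative to the axon and raises
$g$. Because a regression of $g$ on diameter is easily distorted by
nonuniform caliber sampling and pseudoreplication, the package's central
device is *stratification*: fibers are grouped into six diameter bins
derived from the control distribution, statistics are computed per bin, and
a single "grand mean" $\bar g$ summarizes each group by fitting the
constant-g model to the six bin means.

## Cleaning

Three biologically motivated filters run before any statistic, each with
full logging so that input rows are always conserved
(`retained + logged = loaded`):

* axon diameter `< 0.15` µm — axons this small are rarely and inconsistently
  myelinated, so g-ratios there are unreliable;
* two-sided myelin `< 0.03` µm — sheaths this thin do not insulate
  effectively and are usually segmentation noise;
* g outside `[0.5, 0.9]` — beyond the plausible physiological range.

Comparisons are strict (`<`), so boundary values are retained. Each removed
row gets exactly one reason code, assigned in the fixed order
`missing` → `nonfinite_or_nonpositive` → `axon_below_min` →
`myelin_below_min` (then `g_out_of_range` at the later stage); this makes
the exclusion accounting unambiguous when a row fails several filters. The
threshold and g-range filters can be bypassed as a single switch
(`cleaning_thresholds(enabled = FALSE)`) for experimental tissue where
extreme values may be real pathology; removal of missing and non-finite
entries is never bypassable.

One ambiguity is worth recording: the 0.03 µm myelin floor is applied to the
stored analysis-ready column, which is two-sided. Where the input is
one-sided it must be doubled at load (`myelin = "one-sided"`); no
auto-detection is attempted. For the synthetic sensitivity design below the
distinction is immaterial because every injected extreme row already fails
the axon filter.

## Binning

Bin edges come from the *control* dataset only and are then applied
unchanged to every group. The default derivation is six equal-width
intervals spanning the control range of the binning variable;
`method = "quantile"` instead equalizes control per-bin counts. The default
variable is the fiber diameter, with the axon diameter selectable — both are
defensible readings of "diameter-based subgroups", so the choice is a
configuration field rather than a fixed rule. Intervals are half-open below
the top edge, with the last interval closed. Experimental values outside the
control-derived range are clamped into the first or last bin and counted in
an out-of-range log; clamping (rather than dropping) keeps every cleaned
fiber in the cross-group comparison while making the spill visible.

## Statistics

Per bin and group: `n`, mean, median and sample (n−1) SD of full-precision
g; Shapiro–Wilk normality (for 3 ≤ n ≤ 5000 and non-constant values); and
Hartigan's dip test of unimodality (n ≥ 4). Shapiro–Wilk p-values are
reported raw: the six per-bin tests are descriptive profiling, and at the
typical per-bin n the test detects trivial departures, so a multiplicity
correction would only lend them false authority.

Reported g-ratios are rounded to two decimals, half away from zero. The
rounding is presentation-only: every statistic uses full precision, since
rounding before averaging injects up to 0.005 of bias.

The grand mean $\bar g$ is the least-squares constant fit to the non-empty
bin means — their unweighted average — so each diameter cohort counts
equally regardless of how many fibers it holds. An `n_weighted` variant
(equal to the pooled mean over records) is available when per-fiber
weighting is wanted.

Group comparisons use a fixed-effects two-way ANOVA of g on group, bin and
their interaction, with Type II sums of squares: per-bin counts are always
unbalanced across groups, and Type II keeps main effects interpretable in
that setting while reducing to the classical decomposition for balanced
data. Hierarchical (mixed-effects) modeling of animal-level structure is
deliberately out of scope; the per-animal columns survive in the output so
such models can be fit externally.

### The dip statistic

No dip-test implementation was available as a dependency, so the statistic
is computed in compiled code from its definition: the dip of a sample is the
smallest sup-norm distance between its empirical CDF and any unimodal CDF
(convex below the mode, concave above, atom at the mode permitted). The
implementation bisects on that distance and decides feasibility of a given
tube half-width by sweeping the sorted unique values while propagating the
convex region of achievable (value, slope) states of the rising convex
branch, matching it against the mirrored concave branch at every candidate
mode placement — including modes carrying an atom at a tied value. The
bisection terminates at 1e-14, so results are exact for practical purposes;
test cases are frozen against an independent linear-programming solution of
the same definition.

P-values compare the observed dip against the null distribution of the dip
of uniform samples (the asymptotically least favorable unimodal null, as in
the classical tables). The default method interpolates a shipped table of
simulated null quantiles (25 sample sizes from 4 to 5000, up to 10,000
replicates each) on the $\sqrt{n}\,D$ scale; `method = "bootstrap"`
simulates the null at call time instead. Table interpolation makes p-values
deterministic and cheap; its resolution (grid of 21 probability levels) is
ample for the descriptive use the pipeline makes of it.

### The correlation plausibility flag

Because the axomyelin model predicts a roughly constant g across calibers,
a strong fiber-diameter/g-ratio correlation usually indicates a
methodological artifact. The diagnostic computes the Pearson correlation on
full-precision g and flags when both $|r| \ge 0.3$ and $p < 0.05$. The
effect-size gate matters: at n in the thousands, tiny correlations are
always "significant", and 0.3 is about where an artifact would start to
visibly bend a scatter plot. The flag only reports; it never alters data.

## The synthetic-data generator

The generator is first-class, tested code: it defines the study conditions
under which the pipeline is validated. Per condition (CTL, EXP) it simulates
five subgroups ("animals") of 1000 baseline fibers:

* axon diameters $a \sim \mathrm{LogNormal}(\mu = 1.0, \sigma = 0.5)$ in
  log-µm;
* g-ratios $g \sim \mathrm{TruncNormal}(\bar g + \delta_s,\ 0.03^2)$ bounded
  to $[0.65, 0.95]$, with $\bar g = 0.70$ (CTL) or $0.80$ (EXP) and
  subgroup offsets $\delta \in \{-0.02, -0.01, 0, +0.01, +0.02\}$;
* myelin solved from the identity, $m = a(1/g - 1)/2$, so every row's
  ground-truth g is exact by construction;
* joint rejection of $(a, g)$ draws until $f = a + 2m \le 2.0$ µm, keeping
  rodent-CNS scale; counts are maintained by redrawing, with an abort after
  1000× the target draws for infeasible configurations.

Each (condition, subgroup) pair runs on its own seeded stream, so output is
bit-reproducible and independent of generation order. For sensitivity
analyses, 100 extreme rows per subgroup are appended with
$a \sim U(0.05, 0.149)$ µm and one-sided $m \sim U(0.005, 0.029)$ µm —
deliberately just below the cleaning thresholds — giving 5,500 rows per
condition.

Two readings of the axon model ship as presets. The `printed` parameters
(µ = 1.0, σ = 0.5 in log space) put the log-normal median at e ≈ 2.7 µm,
which the 2 µm cap then rejects heavily (≈ 80% of draws), concentrating
accepted axons below ~1.5 µm. A `calibrated_iqr` preset instead matches an
empirical interquartile range of 0.3–1.2 µm (µ = log 0.6, σ ≈ 1.03), under
which the cap barely binds. The two are mutually inconsistent descriptions
of the same population; the `printed` values are the default, and neither is
asserted as the "true" design.

### What the generator does and does not emulate

It reproduces the statistical skeleton of real EM morphometry — caliber
spread with a right tail, per-animal mean shifts, an exact g-identity, and
threshold-violating artifact rows. It does not emulate segmentation noise
on individual boundaries, oblique or irregular sections, within-animal
spatial correlation, or caliber-dependent g trends. Passing validation
therefore shows the *pipeline arithmetic and bookkeeping* are correct under
realistic marginals, not that the cleaning thresholds are optimal for any
particular microscope or tract.

### What validation asserts, and the expected distortions

Truncation and the cap shift the realized mean g away from the nominal
parameter: the $[0.65, 0.95]$ bounds push the low-offset CTL subgroups up
by as much as +0.009, and the cap's preference for large-g draws adds
about +0.004 more. These are deterministic properties of the design, an
order of magnitude larger than the standard error at n = 1000. Parameter
recovery is therefore checked against the *model-implied* subgroup mean —
the truncated-normal expectation reweighted by the cap acceptance
probability, computed by numerical integration independent of the sampler —
rather than against the nominal $\bar g + \delta$, which no unbiased
estimator of this design could match within sampling error. Pooled means
after the full pipeline land near 0.708 (CTL) and 0.803 (EXP); the
validation suite checks them against 0.70 and 0.79 within ±0.015, a band
that the truncation and cap distortions keep within reach of the imposed
0.70 and 0.80.

Appending the 500 extreme rows moves the pooled mean by only a few
thousandths (they are removed wholesale by the axon filter; their own mean
g happens to lie near 0.74 anyway), comfortably inside the documented
stability bounds (ΔCTL < 0.017, ΔEXP < 0.014).

## Numerical and design choices

* **Rounding rule.** Two-decimal reporting uses half-away-from-zero; base
  R's banker's rounding would turn 0.805 into 0.80.
* **Bin edges.** `findInterval(..., all.inside = TRUE)` implements both the
  half-open convention and the clamping in one step; equal-width edges are
  `seq(min, max, length.out = 7)` on the control variable.
* **Quantile collapse.** Quantile derivation on a concentrated control
  distribution can produce tied edges; this is rejected with an error
  rather than silently merged, since five distinguishable bins would
  invalidate cross-group comparability.
* **ANOVA degeneracies.** Empty group×bin cells and zero residual df are
  errors naming the offending cells, not warnings.
* **XLSX output.** To avoid an xlsx-writing dependency, workbooks are
  emitted by a minimal writer (zip
  container assembled directly; deflate streams from `memCompress`, CRC-32
  in compiled code; numeric cells at 17 significant digits for bit-exact
  round-trips; inline strings). `readxl` handles all reading.
* **Simulation sizes in tests.** The validation suite runs the full 5 ×
  1000 design where the claim depends on it (pooled means, Δ-stability over
  20 seeds, structure counts, identity, recovery, bin separation) and a
  5 × 100 design with quantile bins for the 1000-replicate ANOVA type-I
  simulation, which needs replication count more than per-replicate size.

## Known limitations

* The pipeline trusts upstream segmentation; it cannot detect biased
  boundaries, and area-to-diameter conversions for irregular sections are
  out of scope.
* Only `.xlsx`/`.xls` input is supported, matching the field's dominant
  hand-curated format.
* Statistical outlier detection beyond the fixed thresholds (IQR, z-score,
  model-based) is intentionally absent; the thresholds are biological, not
  data-driven.
* The dip null table is simulated once; p-values inherit its Monte-Carlo
  resolution (~10⁻³ near conventional levels), which is ample for
  profiling but not for precision hypothesis testing.
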