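---
title: "Phenotypic screening and profiling of resistance-selective cytotoxic agents"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic screening and profiling of resistance-selective cytotoxic agents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mdrscreen)
library(dplyr)
```

## The problem

Multidrug resistance (MDR) — classically driven by overexpression of efflux
transporters such as P-glycoprotein — blunts the activity of many standard
cytotoxic drugs. One route around it is phenotype-first screening: expose a
resistant cell line and its drug-sensitive parent to a compound library and
look for compounds that kill the *resistant* phenotype preferentially,
rather than compounds that merely engage a nominated target. mdrscreen
implements the complete computational side of such a campaign: plate-level
survival quantification with assay QC, differential hit calling, censored
dose-response potency estimation, ex vivo activity indices across
diagnosis-annotated patient-cell panels, connectivity-map-style mechanism
inference, preranked gene-set enrichment, and hollow-fiber in vivo growth
analysis. Every stage is exercised against seeded synthetic data with
planted ground truth, so the pipeline's statistical behavior is testable
end to end.

## Survival index and assay quality control

The fluorometric cytotoxicity readout reports per-well fluorescence
proportional to the number of viable cells. The survival index of a test
well is

$$\mathrm{SI} = 100 \cdot \frac{F_\text{test} - \bar F_\text{blank}}
{\bar F_\text{control} - \bar F_\text{blank}},$$

with blank and control means taken per plate (two drug-free control
columns, one medium-only blank column per 384-well plate). The ratio makes
SI invariant to any positive affine transform of the raw fluorescence, and
replicate wells are averaged *after* SI computation so per-well volume
differences cancel. SI is deliberately not clipped: values above 100
(growth stimulation) and below 0 (fluorescence below blank) are preserved
as data.

A plate passes QC when the control-well coefficient of variation is below
30% and the control/blank signal ratio exceeds 10 for cell-line assays or
5 for primary cultures. Both inequalities are strict — a plate at exactly
30% CV or a 10.0 ratio fails — because the criteria are phrased as "less
than" and "more than". The CV criterion is read as the CV of the pooled
control wells per plate, the simplest reading consistent with per-plate
pass/fail. Failing plates are flagged and reported, never silently
dropped; whether to rerun them is an operational decision outside the
package.

## Differential hit calling

A compound is a hit when SI < 50% in the resistant line *and* SI > 50% in
its parent, both strict. The threshold is parameterized (default 50) for
reuse, and the screen is single-concentration: multi-concentration tables
must be reduced to the screen concentration first, which the package
enforces rather than guessing. Compounds scored in only one line are
excluded with a warning — imputing the missing line would manufacture
hits. The counter-screen summary (`panel_profile()`) pairs each resistant
line of a resistance panel with its parent and issues a per-mechanism
verdict; a pair is called "insensitive" to its resistance mechanism when
the resistant line's SI is at most 10 percentage points above the parent's.
The 10-point tolerance is our operational cut for a qualitative
"almost as sensitive" judgement; it is configurable.

```{r hits}
scr <- generate_screen(screen_scenario(n_compounds = 300, seed = 1))
hits <- compute_si(scr$wells) |>
  call_hits("8226/Dox40", "RPMI 8226")
filter(hits, is_hit)
```

## Dose-response model and censored IC50

Potency is estimated by least squares on the four-parameter logistic
survival curve

$$\mathrm{SI}(c) = \text{bottom} + \frac{\text{top} - \text{bottom}}
{1 + 10^{(\log_{10} c - \log_{10} m)\,h}},$$

where $m$ is the curve midpoint (inflection) and $h > 0$ the slope of the
*decline* — we parameterize the model so that a positive hill slope always
means survival decreasing with concentration, which keeps the slope bounds
$h \in [0.1, 10]$ meaningful for cytotoxicity data. The primary potency
readout is the **absolute IC50**, the concentration where the fitted curve
crosses SI = 50; it equals the midpoint only when the asymptotes are
symmetric about 50 ($(\text{top}+\text{bottom})/2 = 50$), so both are
reported.

Numerical choices, all visible in `fit_sigmoid()`:

* default bounds top $\in [50, 150]$, bottom $\in [-10, 50]$ — percent-of-
  control data motivates loose asymptotes; an optional constrained fit
  pins top = 100, bottom = 0;
* initialization from the observed extremes and the 50% crossing located
  by linear interpolation on log-concentration, hill = 1;
* five multi-starts jittering the log-midpoint by up to one decade, best
  sum of squares wins — a cheap guard against local minima at sparse
  5-point designs;
* all-identical SI values return a degenerate flat fit (hill = 0
  convention, converged, censored IC50) rather than an optimizer failure.

When the curve never crosses 50% within the tested range the IC50 is
censored and carried as a comparator plus bound (`">40"`, `"<0.004"`).
Censoring bounds are data, not constants: the cell-line dilution series
tops out at 40 uM while the ex vivo panel tops at 34 uM, and both are
accepted. Group medians respect censoring by ranking right-censored
values above all numeric values; when a middle rank lands on a censored
value the group median itself is censored. Mixed bounds within a group are
an error rather than a guess.

## Ex vivo activity indices

The patient-cell panel is profiled at the **reference concentration** —
the tested concentration with the largest SI standard deviation across
tumor samples (normal PBMC samples excluded), i.e. where the assay
discriminates best. Ties resolve to the lower concentration with a
warning. A sample *responds* when its SI is strictly below the overall
median SI of all tumor samples at that concentration, so samples exactly
at the median are non-responders and the overall tumor response rate is
pinned to $[0.5 - 1/n,\ 0.5]$ by construction — a useful structural check.

The **S/H ratio** divides the pooled solid-tumor response rate by the
pooled hematological rate (pooled at sample level, not averaged over
diagnoses — the n-weighted reading of a "total" rate); values below 1
indicate hematological preference. The **specificity ratio** divides the
censored median IC50 of normal PBMC by that of CLL samples; a censored
numerator propagates into the ratio, while a censored denominator is
refused as uninterpretable.

Hollow-fiber in vivo activity is summarized as net growth,
$(\mathrm{OD}_\text{retrieval} - \mathrm{OD}_\text{implantation}) /
\mathrm{OD}_\text{implantation} \times 100$, and groups are compared with
the two-sided pooled-variance Student's t-test — the pooled form because
that is the named test, not Welch's variant; groups of fewer than two
animals refuse the test.

## Connectivity scoring

Mechanism inference queries a database of drug-treatment *instances*, each
a full ranking of the probe universe (rank 1 = most up-regulated). The
query signature is built from a treated/control expression pair: probes
must exceed 300 arbitrary units *in both conditions*, carry present calls
in both, and belong to the allowed reference-probe list; survivors are
ranked by treated/control signal ratio (ties broken by probe id for
determinism — log versus raw ratios order identically for positive
signals) and the top 20 / bottom 10 become the up/down tag lists.

Each tag list is scored against an instance with the two-tail rank
Kolmogorov-Smirnov statistic: with ascending tag ranks $V_1 < \dots <
V_t$ in a universe of $n$,

$$a = \max_j\left(\frac{j}{t} - \frac{V_j}{n}\right), \qquad
  b = \max_j\left(\frac{V_j}{n} - \frac{j-1}{t}\right),$$

and the statistic is $a$ if $a > b$, else $-b$. The raw connectivity
score is $\mathrm{ks}_\text{up} - \mathrm{ks}_\text{down}$ when the two
tails disagree in sign and 0 otherwise — a profile cannot simultaneously
mimic and oppose the query. Normalization divides positive raw scores by
the maximum positive and negative ones by the absolute minimum, mapping
the extremes to exactly ±1; compounds are ranked by mean normalized score
over their instances. Instances store rank permutations rather than
intensities because the score is rank-only; this also keeps the synthetic
database compact. Tags missing from an instance's universe are dropped
with a warning and the tag count adjusted, mirroring cross-chip
compatibility filtering.

## Preranked GSEA

`gsea_preranked()` computes the classic running-sum enrichment score: hit
increments proportional to $|s|^w$ (normalized to sum 1, default
$w = 1$), miss decrements $1/(n - t)$, ES the signed extreme deviation.
The null is gene-tag permutation — random same-size gene sets — because a
preranked list admits no phenotype permutation. The nominal p-value
compares the observed ES against the *same-sign portion* of the null,
$(1 + k)/(1 + n_\text{same sign})$: conditioning on sign is what makes
the p-value uniform under the null (comparing against all permutations
would cap it near 0.5), and the add-one form keeps it at or above
$1/(n_\text{perm}+1)$. The ES computation only evaluates the running sum
at hits and immediately before hits, where its extremes must occur, so
permutations cost $O(t \log t)$ rather than $O(n)$.

## What the synthetic data emulates — and what it does not

The generators are pure functions of a scenario object (seed included),
so identical scenarios are byte-identical, and every generator emits its
ground truth in a sidecar table keyed by compound or sample id — never in
the files the analysis reads, so truth cannot leak into the pipeline.

* `generate_screen()`: a 3,000-compound, two-line, single-concentration
  screen on 384-well plates with the two-control-column / one-blank-column
  layout. Test-well fluorescence is
  $\text{blank} + (\text{control} - \text{blank}) \cdot S \cdot
  \varepsilon$ with true survival $S$ and multiplicative lognormal noise
  $\varepsilon$ (unit mean, CV 0.1 by default) — multiplicative because
  percent-of-control readouts are bounded below by zero. Non-hit
  compounds draw a shared true survival in $[0.7, 1.1]$ (most library
  compounds are inactive); one planted compound survives at 0.2 in the
  resistant line and 0.9 in the parent.
* `generate_panel()`: a diagnosis-annotated panel at realistic clinical
  scale (19 ovarian, 13 NHL, 4 PBMC, and so on — 99 tumor + 4 normal
  samples) with per-diagnosis log10-normal true IC50s. Solid diagnoses
  sit at 100 uM, far above the 34 uM top tested concentration, so their
  fitted IC50s come out censored; hematological locations are low
  micromolar; dispersion 0.4 log10 units and SI noise sd 5
  percentage points are our choice of a realistic ex vivo spread.
  Noise on SI is additive Gaussian, matching residuals of
  percent-of-control curves.
* `generate_connectivity_db()`: 500 probes, 60 instances in 6 mechanism
  classes (two compounds per class), each class sharing a fold-change
  template of 30 up / 15 down probes; instance rankings come from
  template-plus-Gaussian latent scores, and the query treated/control
  pair is generated from the query class's template with lognormal
  control intensities and 98% present calls.

What passing tests on these data do **not** show: real plates have
spatial/edge effects and the package deliberately applies no B-score or
positional correction (none is described for the assay it models); real
ex vivo samples differ in tumor-cell content and culture viability;
real expression profiles have correlated probes and batch structure that
the independent-noise templates lack. The synthetic results validate the
*computations*, not the wet-lab assay.

## Problem sizes and tolerances used in validation

The test suite and the acceptance script validate at these scales, chosen
to make the statistical checks sharp at interactive run times: exhaustive
KS-oracle enumeration over all 494 tag subsets of universes up to n = 8;
connectivity retrieval over 10 database seeds; 200 noisy 5-point curves
(SI noise sd 5) for IC50 recovery, requiring median relative error below
25%; five full 3,000-compound screens for hit recall and a sub-1%
false-positive bound among compounds at least 20 SI points from the
threshold; 100 exchangeable panels for the S/H null centering; 500
null GSEA trials at 200 permutations for p-value uniformity; and 1,000
simulated two-group fiber experiments for the t-test's type-I error
(expected within 5% ± 1.5%).

## Known limitations

* The dose-response fitter targets monotone curves; biphasic or
  bell-shaped responses are out of scope and will fit poorly (visible in
  `residual_sse`).
* Censored-median logic supports a single right-censoring bound per
  group, which is the panel's structure; interval or mixed censoring
  would need a survival-analysis treatment.
* Connectivity p-values across instance groups (specificity/enrichment
  of a compound's instances) are not computed — scoring stops at the
  normalized ranking, and GSEA reports nominal p only, no FDR q-values.
* The pipeline flags QC failures but takes no exclusion decision; a
  production campaign would add a rerun policy.
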