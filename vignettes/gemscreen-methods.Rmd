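---
title: "Models and methods behind gemscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gemscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gemscreen)
```

gemscreen packages the statistical machinery used to characterise how
bacteria evolve resistance to the chemotherapy drug gemcitabine and how
that resistance feeds back on drug availability: a pooled knockout
barcode screen, plate-reader dose–response fitting, a functional
drug-breakdown assay, spheroid/bacteria co-culture fitness landscapes,
Luria–Delbrück fluctuation analysis, and annotation of spontaneous
resistance mutations. This vignette describes each model, its
assumptions, and the numerical choices made where the design was
genuinely open. Every stage has a matching seeded generator so the whole
pipeline can be exercised end to end on synthetic data.

## Pooled barcode screen

Each knockout strain in the library carries a unique 20-bp barcode;
resistance or sensitivity manifests as enrichment or depletion of the
barcode in drug-treated cultures relative to untreated controls.
`count_barcodes()` assigns reads by exact substring match against the
barcode database, searching reverse complements as well (library
orientation is not guaranteed), with optional single-mismatch rescue
applied only when a read matches exactly one barcode. Reads are
conserved: assigned plus unassigned always equals the input.

Counts are modelled as negative binomial with variance
$\mu + \alpha\mu^2$. After median-of-ratios normalisation
(`estimate_size_factors()`), `wald_enrichment()` computes per-strain
log2 fold changes of the normalised condition means with a pseudocount
of 0.5 (avoiding infinite fold changes at zero counts) and tests them
with a Wald statistic. The dispersion $\alpha$ is estimated by the
method of moments pooled over conditions and shrunk on the log scale
toward a fitted mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$
(weight 0.3 on the per-strain estimate, and never below half the
trend). With three replicates per condition the raw moment estimator is
extremely noisy; the strong shrinkage is what keeps the test calibrated,
which we verify by simulation: across 20 null screens of 3000 strains
the fraction of strains reaching BH $q < 0.05$ is below 0.1%.

Hits use the screen's strict thresholds (fold change $\ge 16$ and
$q < 0.05$; `call_hits()`). The overlap of hits with slow-growing
knockouts (endpoint OD strictly below 0.11, the antimode of the
knockout collection's bimodal growth distribution) is tested with the
exact one-tailed hypergeometric tail (`fisher_overlap()`). Set-level
enrichment (`set_enrichment()`) is a deliberately simple analogue of
count-based gene-set methods: a Welch t of member versus non-member
fold changes, one-sided in each direction, BH-adjusted per direction —
not a reimplementation of GAGE, so hit lists on real data will differ
in detail from tools of that family.

## Dose–response curves and IC50

Growth is read at a fixed time (default 720 min; plates run longer, but
12 h is where strain characterisation is done), blank-subtracted,
replicate-averaged, and normalised to the zero-dose wells
(`relative_growth()`). `fit_4pl()` fits the four-parameter logistic
$r(d) = b + (t - b)/(1 + (d/x_{50})^{h})$ by Levenberg–Marquardt least
squares over a deterministic multi-start grid (Hill slope in
$\{0.5, 1, 2, 4\}$, midpoint at each interior dose; best RSS wins, ties
to the earlier start). Two IC50 notions are distinguished:

* the *relative* midpoint $x_{50}$ of the fitted curve, and
* the *absolute* IC50 reported as `ic50`: the dose at which the fitted
  curve equals half its fitted zero-dose value, solved in closed form.
  This matches the operational definition "concentration that reduced
  culture density by 50%".

Curves with less than 20% dynamic range are censored ("> max dose")
rather than extrapolated — fully resistant populations in an evolution
time course are exactly such curves, and `ic50_timecourse()` carries
the censoring sentinel into the heatmap rather than inventing a number.
Serial-transfer generation accounting is
`generations(days, dilution) = days * log2(dilution)`, floored for
completed doublings (7 days at 1:200 gives 53.5, i.e. ~53 generations).

The two bundled presets (`strain_preset()`) encode the package's
reference dose–responses: a highly sensitive fecal isolate (true IC50
0.7 µM) and a resistant K-12 lab strain (103 µM), each with a 12-point
dose series (11 doses in 1.6-fold serial dilution plus the zero-dose
reference) spanning its IC50. On noise-free generated curves the fitter
recovers these values to well under 1%.

## Drug-breakdown assay

A knockout's conditioned buffer (collected 15 or 45 min after drug
exposure) is fed to a drug-sensitive reporter strain; the reporter's
growth AUC (trapezoidal integral of blank-subtracted OD over hours,
`growth_auc()`) proxies residual drug. Fast degraders are detected on
the 15-min buffer (reporter grows *more* than with wild-type buffer,
one-tailed `greater`), slow degraders on the 45-min buffer (one-tailed
`less`), with BH adjustment per direction and a 0.1 FDR cutoff.

One design choice deserves emphasis. With 3 knockout versus 18
wild-type replicates, the Welch statistic has roughly 2.4 effective
degrees of freedom and very little power: in simulations with a 3-sd
planted effect it recalls only about half of the planted slow
degraders. The replicates come from a common protocol with comparable
variances, so `degrader_test()` defaults to the pooled-variance Student
t (19 df); the Welch form remains available via `var_equal = FALSE`.
A second point is intrinsic to the assay: all strains are compared
against the *same* 18 wild-type replicates, so errors are positively
correlated across strains and single-cohort class counts fluctuate by
several strains around the truth even when the FDR is controlled (BH at
0.1 with ~33 discoveries *expects* 2–3 false calls). Recovery of a
planted 10 fast / 23 slow / 55 null cohort is therefore assessed on
mean class counts across 50 simulated cohorts, which sit within ±2 of
the truth. Strains significant in both directions (a pathological case)
are set to `none` with a warning.

## Spheroid fitness landscapes

Spheroid areas over a 12-dose × 8-bacteria-level plate are normalised
in two steps: per-well division by the day-zero area, then a plate
rescaling that subtracts the minimum and divides by the second-largest
value minus the minimum. The minimum maps to 0 and the second-largest
value to 1; the single largest value may exceed 1 and is deliberately
not clipped (it follows directly from using the second-largest value as
the divisor, which makes the scale robust to a single outlier well).
Plates with fewer than three distinct values are rejected as
degenerate.

`fit_poly44()` fits the full bivariate quartic (15 monomials
$x^m y^n$, $m+n \le 4$) by ordinary least squares. Axes are
dilution-index coordinates rescaled to $[0,1]$: the doses form a
1.6-fold serial dilution, so index space is log-concentration space,
and the zero-dose column — which no log axis can represent — sits at
index 0 of the reversed axis. Whether to fit in index or concentration
coordinates was an open choice; index space is used and all front
shifts are reported in index (log-dose) units. In-model surfaces are
recovered exactly on the 12 × 8 grid (residual sums of squares at
machine precision), which is the natural correctness certificate for a
linear least-squares fitter.

`extract_front()` traces the EC50 front — the level set where the
fitted surface equals 0.5, the mid response — by marching-squares
contouring (via `grDevices::contourLines`) on a 500 × 500 evaluation
grid, and independently locates each bacteria row's crossing dose by
sign-change bracketing plus bisection; the two agree within grid
resolution, and front points satisfy $|f - 0.5| < 10^{-3}$. An empty
front is a valid result (a surface that never crosses the level).
`compare_fronts()` reports per-row signed crossing-dose shifts between
two strains with an exact sign test; a drug-degrading strain shifts the
front toward higher nominal dose at high bacteria levels, an
import-dead slow degrader shifts it the other way.

## Luria–Delbrück fluctuation analysis

Mutations arise during exponential growth; a mutation that happened
early leaves a large mutant clone, so parallel-culture colony counts
are heavy-tailed. In the Lea–Coulson formulation the number of
mutational events per culture is Poisson($m$) and a single event's
clone size follows $P(j) = 1/(j(j+1))$. Plating a fraction
$\varepsilon$ of the culture thins each clone binomially; the number of
colonies from one event then has probabilities

$$q_k = \sum_{j \ge \max(k,1)} \frac{1}{j(j+1)} \binom{j}{k}
\varepsilon^k (1-\varepsilon)^{j-k}.$$

`clone_pmf()` computes these *exactly* from the thinned probability
generating function: with $s = \varepsilon(1-z)$,
$g(z) = 1 + \varepsilon (1-z)(\ln\varepsilon + \ln(1-z)) /
(1 - \varepsilon(1-z))$, whose power-series coefficients obey a
two-term recurrence. The recurrence divides by $1-\varepsilon$ at each
step and is numerically stable precisely when $\varepsilon < 1/2$ (the
usual regime: plating efficiencies like 1:40); for
$\varepsilon \ge 1/2$ a directly summed windowed evaluation is used,
and $\varepsilon = 1$ reduces to $q_k = 1/(k(k+1))$. A useful special
value is $q_0 = 1 + \frac{\varepsilon}{1-\varepsilon}\ln\varepsilon$.

The observed count is the compound-Poisson sum over events, giving the
recursion $p_0 = e^{-m(1-q_0)}$,
$p_n = (m/n)\sum_{k=1}^n k\,q_k\,p_{n-k}$ (`count_pmf()`), which at
$\varepsilon = 1$ collapses to the classic mutant-count recursion.
`mle_m()` maximises the resulting likelihood by Newton–Raphson on the
score with analytic first and second derivatives (obtained by
differentiating the recursion), safeguarded by bisection within a
maintained bracket; the all-zero boundary case returns $\hat m = 0$.
Counts at or above a cap (default 1000) enter as right-censored
observations, $P(\text{count} \ge \text{cap})$ — a jackpot culture can
place a count in the tens of thousands and the $O(n_{\max}^2)$
recursion must not be dragged there; censoring keeps the likelihood
honest at bounded cost. `profile_ci()` inverts the likelihood-ratio
statistic against $\chi^2_1$ by bisection (lower endpoint 0 at the
boundary). Across 200 simulated designs matching the study conditions
(10 cultures, $\varepsilon = 1/40$, $N_0 = 730$, $N_t = 10^8$,
$m = 2$), the nominal 95% interval covers the truth 97% of the time.

Rates: $\mu = \hat m / (N_t - N_0)$ — mutations per cell division,
since a culture growing from $N_0$ to $N_t$ undergoes $N_t - N_0$
divisions. Dividing by $N_t$ instead (the convention in some published
analyses) is available as `divisor = "nt"`; with $N_0 \approx 730$ and
$N_t \sim 10^8$ the two differ by under $10^{-5}$ relative. Per-kilobase
normalisation rescales to a 1000-bp reference gene; gene lengths are
user inputs. `rate_ratio()` propagates profile bounds through the
ratio by interval arithmetic and returns an `Inf` sentinel for a zero
denominator rather than failing.

The generator (`simulate_fluctuation()`) draws clone sizes by the exact
inverse CDF $j = \lfloor 1/U \rfloor$ (valid because
$P(j \ge k) = 1/k$), truncated at $N_t$, and thins binomially — the
same model the estimator assumes, which is what makes the
chi-square/pmf and coverage checks genuine round trips. It does not
model differential mutant fitness, cell death, post-plating growth or
phenotypic lag, and neither does the likelihood; on real data these
would bias $\hat m$.

## Mutation annotation and conservation bias

`align_and_classify()` aligns a Sanger consensus to the reference CDS
with an ends-free alignment (match +1, mismatch −2, gap open 5, gap
extend 1 — values chosen for tolerance to consensus base-calling noise;
the ends-free form soft-clips up to ~30 bp of incidental vector or
primer sequence). Classification priority: a soft-clipped tail beyond
max(35 bp, 20% of the query), or an internal insertion of ≥ 50 bp,
signals a truncated alignment at a new junction (transposon class);
remaining gaps are indels with a frameshift flag; substitutions are
translated and called nonsense, missense, or silent; identity below 50%
or queries under 50 bp are unassigned (promoter-region mutations are
not detectable by design — the sequenced amplicon covers the CDS).
The `silent` class is an addition to the field's usual
missense/nonsense/indel vocabulary so that synonymous changes are not
conflated with "no difference". Across 500 random generated mutation
descriptors, classification round-trips to the descriptor's expected
class without error.

`conservation_bias_test()` asks whether missense positions concentrate
on evolutionarily conserved residues: a one-sided rank-sum comparison
of conservation scores at mutated positions against a background. The
default background is *all* positions (mutated included), mirroring how
such comparisons are usually phrased; a disjoint
(`background = "exclusive"`) option gives the cleanly calibrated
two-sample null, which is what the calibration simulations use. Small
problems (combined $n \le 16$) are solved by exhaustive enumeration of
rank assignments; larger ones use the normal approximation with
midrank tie correction (conservation scores live on a 1–9 scale, so
ties are the rule). On profiles generated with an 8-fold conservation
bias over 400 residues, the test rejects at $\alpha = 0.05$ in well
over 90% of simulations.

## Orchestration

`run_stage()` runs any stage from a list or YAML config (stage name,
named input paths, parameters, output directory), validating everything
before touching the filesystem, and writes a manifest with MD5 hashes
of inputs and outputs, echoed parameters, and the package version.
Floats in CSV outputs are serialised with 12 significant digits;
re-running an identical config is byte-identical, which the test suite
asserts on hashes. `write_report()` renders manifests into a fixed-order
human-readable summary. A thin command-line wrapper around these
functions ships in `inst/cli/`.

## Problem sizes and what the tests show

The simulation suites use 20 null screens of 3000 strains (FDR
calibration), 200 fluctuation designs (interval coverage), 50 breakdown
cohorts of 88 strains (class recovery), 100 noisy dose–response plates
(median IC50 error < 10% at noise sd 0.05), 500 mutation round trips,
and Monte-Carlo samples of $10^5$–$2\times10^5$ cultures for the
distributional oracles — sizes at which the Monte-Carlo error is far
below every asserted tolerance while the whole suite stays fast.

Passing these suites shows that each estimator recovers the truth of
the generative model it assumes, at the study's design sizes. It does
not show robustness to what the generators deliberately omit: day
effects and plate position effects in growth assays, amplification bias
and index hopping in sequencing, mutant fitness costs in fluctuation
assays, or segmentation error in spheroid imaging. Conclusions about
real data should lean on the calibration safeguards (dispersion
shrinkage, censoring, exact small-sample tests) rather than on the
round-trip results alone.
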