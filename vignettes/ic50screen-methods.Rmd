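---
title: "Methods: dose-response profiling and the IC50 correlation screen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dose-response profiling and the IC50 correlation screen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ic50screen)
```

# The analysis in one paragraph

Given plate-reader viability measurements of a cell-line panel under a dose
ladder of a compound, `ic50screen` estimates each line's IC50 by fitting a
Hill sigmoid to the untreated-normalized response, assembles the panel's
normalized and ranked IC50 profile (the *susceptibility signature*), screens
every transcript of an expression matrix for cross-line patterns that
correlate with that signature using exact small-sample rank statistics,
tests the resulting gene set for overlap with reference gene sets by an
upper-tail hypergeometric test, and quantifies drug effects on cell
motility with speed and a time-penalized persistence statistic. A set of
seeded simulators generates all four input types with known ground truth,
so every stage is testable end to end.

# Viability normalization and the Hill fit

## From raw fluorescence to percent viability

Raw well intensities $I_i$ are background-corrected by the mean blank-well
signal and expressed relative to the background-corrected untreated
reference $I_0$:

$$nI_i = 100\,\frac{I_i}{I_0},$$

and replicates are averaged into the mean normalized pattern

$$anI_i = \frac{1}{N}\sum_{j=1}^{N} nI_i(j).$$

Background-corrected values at or below zero are clipped to a small
positive floor (default $10^{-6}$, with a warning) so the ratio stays
defined; a panel series whose *untreated reference* falls at or below the
background is rejected outright ("reference signal below background"),
because nothing downstream is interpretable in that case.

## The dose-response model

The averaged pattern is modeled by the decreasing four-parameter Hill
sigmoid

$$anI(D) = \min + \frac{\max - \min}{1 + (D/IC_{50})^{H}},$$

with plateaus $\min,\max$ in percent of untreated, $IC_{50}$ in the dose
unit, and Hill coefficient $H > 0$. At $D = 0$ the model returns $\max$, at
$D = IC_{50}$ the midpoint $(\min+\max)/2$, and it is strictly decreasing
in $D$.

## Fitting numerics

The fit is nonlinear least squares (Levenberg–Marquardt with box
constraints, via `minpack.lm`), applied to the replicate-averaged pattern —
averaging first and fitting second matches the normalization chain above; a
`pooled = TRUE` mode fits all replicate points instead. Choices that
matter:

* **Starting values** are data-driven: $\min_0$ and $\max_0$ from the
  smallest/largest observed response, $IC_{50,0}$ from the dose whose
  response is nearest the midpoint, $H_0 = 1$.
* **Restarts.** The optimizer is restarted over a fixed geometric ladder of
  IC50 starting values spanning $0.1\times$–$10\times$ the data-driven
  start (10 restarts). The ladder is deterministic, so fits never consume
  random-number state and identical inputs give bit-identical results.
* **Bounds** keep the decreasing branch: plateaus in $[0, 200]$ percent,
  $H \in (0, 20]$, $IC_{50} > 0$. A fit whose $\max \le \min$ (an
  increasing or degenerate curve) is flagged non-converged.
* **Plausibility flag.** A fitted IC50 outside the non-zero dose range by
  more than a factor of 100 (configurable) is reported but flagged
  non-converged: with the sigmoid unresolved at both ends, the estimate is
  an extrapolation.
* **Degenerate inputs.** Fewer than 4 distinct non-zero doses is an error,
  as is a perfectly flat response ("no dose dependence").
* The untreated $D = 0$ point is included by default (the model is defined
  there); exclusion is available.

## Normalized profiles and ranks

Per-line IC50 values $V_i$ are normalized across the $m$-line panel,

$$nV_i = \frac{V_i - V_{\min}}{V_{\max} - V_{\min}} \in [0, 1],$$

and ranked ascending (rank 1 = most sensitive). Ties receive average ranks,
which keeps the downstream rank correlation well defined; if all values are
equal, $nV$ is set to 0 with a warning and all ranks tie. Profiles from
several timepoints are averaged on the normalized scale, then re-normalized
and re-ranked; for these averaged profiles the value column carries the
per-line mean normalized value (a unitless susceptibility score), since
absolute concentrations are not comparable across timepoints after
normalization. Non-converged fits are dropped from a profile with a
warning.

# The exact correlation screen

## Why exact p-values

With a typical panel of $n = 5$ cell lines, the null distribution of the
Spearman correlation is supported on only a handful of values; the familiar
large-sample approximations are badly calibrated. `spearman_exact()`
therefore enumerates all $n!$ permutations of the profile's ranks (ties:
the observed tied rank multiset is permuted) and reports inclusive tail
probabilities:

* $p^{+} = P(\rho_{\text{null}} \ge \rho_{\text{obs}})$,
* $p^{-} = P(\rho_{\text{null}} \le \rho_{\text{obs}})$,
* $p^{2} = P(|\rho_{\text{null}}| \ge |\rho_{\text{obs}}|)$.

At $n = 5$ the attainable one-sided levels are $1/120 \approx 0.0083$
($\rho = 1$), $5/120 \approx 0.0417$ ($\rho \ge 0.9$; the identity plus the
four adjacent-rank transpositions), $9/120$, and so on. Enumeration is
capped at $n = 8$ ($8! = 40320$ permutations); beyond the cap the
$t$-approximation is used with a notice.

## Sidedness and correction defaults

Screening is one-sided by default, in the direction of each transcript's
observed correlation. The reason is the discreteness above: at $n = 5$ the
*two*-sided floor is $2/120$ and only $|\rho| = 1$ clears a two-sided 0.05
threshold, which makes two-sided screening at that panel size nearly
vacuous; one-sided screening additionally admits $\rho \ge 0.9$ patterns
($p = 5/120$). Two-sided mode and Benjamini–Hochberg correction (within
each tail) are available by argument; the default reports nominal p-values,
which is the conventional choice for a hypothesis-generating screen whose
hits are validated downstream.

## Screen mechanics

Transcripts are first filtered by detection call: only rows called Present
or Marginal in **every** cell line are retained (the Absent call marks
signal indistinguishable from array background, and a single unreliable
line corrupts a five-point pattern). The matrix is aligned to the profile
by case-folded exact label match — an error lists any unmatched lines.
Rows with missing values are dropped with a logged count. Because the
profile is shared by all transcripts, the screen builds the permuted-rank
matrix once and evaluates all null correlations as a single matrix product,
which keeps the exact screen over tens of thousands of transcripts in the
sub-second range. Pearson mode substitutes raw values for ranks in both the
observed and permuted statistics, so its p-values are exact permutation
probabilities too.

`signature_correlation()` restricts the same machinery to a predefined gene
list (e.g. an epithelial–mesenchymal transition signature) across one or
more profiles and reports per-profile fractions of significant genes, so
two compounds' susceptibility profiles can be contrasted on the same
signature. `rank_lines_by_gene()` orders the panel by one gene's expression
(descending; stable on ties), the conventional way of placing lines on an
epithelial-to-mesenchymal axis via E-cadherin.

# Gene-set overlap

The overlap of the screen's hit set with a reference set is tested against
the hypergeometric null: drawing $n$ labels without replacement from a
universe of $N$ with $K$ marked,

$$P(X \ge k) = \sum_{j=k}^{\min(K,n)}
  \frac{\binom{K}{j}\binom{N-K}{n-j}}{\binom{N}{n}}.$$

The tail is **inclusive** of the observed $k$ — the standard enrichment
convention; a point-probability reading of the same four numbers gives
slightly smaller values and is not a tail test. The sum is accumulated in
log space (log-sum-exp over `dhyper(log = TRUE)` terms) so that tails of
order $10^{-13}$ and far below retain full relative precision. The
universe defaults to the detection-filtered transcript ids — the population
actually eligible for selection — and can be overridden. Set labels outside
the universe are dropped with a logged count before testing.

# Motility statistics

For a track observed at times $t_1 < \dots < t_k$:

* **speed** $= L / (t_k - t_1)$ with $L$ the summed Euclidean step lengths
  between consecutive observations (no interpolation across gaps);
* **persistence** $= (d / L)\,\sqrt{(t_k - t_1)/t_{\max}}$ with $d$ the
  first-to-last displacement and $t_{\max}$ the acquisition duration
  (default 2880 min = 48 h at 20-min frames).

The $\sqrt{t_{\text{tracked}}/t_{\max}}$ factor penalizes briefly tracked
cells, whose raw directionality ratio $d/L$ is upward-biased; a straight
full-duration track scores exactly 1 and persistence is bounded by
$\sqrt{t_{\text{tracked}}/t_{\max}} \le 1$. A stationary cell has $d/L =
0/0$; it is assigned persistence 0 and flagged degenerate — the value a
vanishing-displacement limit supports. Condition summaries report mean, sd
and n per group, with sd undefined for single-track groups.

# The synthetic-data generators

The generators define the study conditions under which the pipeline is
exercised and tested; their defaults are fixed once and mirror a realistic
small-panel study.

**Plates.** Five-line panels measured at 24/48/72 h in triplicate, with a
two-fold geometric dose ladder (a standard plate layout; the default ladder
is 0 plus 6.25–400 µM, configurable per compound) and additive Gaussian
noise on raw intensity — the simplest model consistent with
replicate-standard-deviation error reporting; a multiplicative option
exists. The default noise sd of 200 fluorescence units is 2% of the
untreated reference (10 000 units over a background of 100). Sample wells
read $\text{background} + \text{reference} \times anI(D)/100 + \epsilon$;
negative noisy readings are clipped at zero, as a real reader never
reports negative fluorescence. In the bundled end-to-end panel the test
compound's IC50s are flat across four lines with one resistant outlier,
while the reference compound grades monotonically across the panel —
the two qualitative susceptibility patterns the screen is meant to
distinguish. True `max` is 100% so that untreated-normalized plateaus
match the generating parameters; with any other `max` the normalization
rescales the recovered plateaus by construction (IC50 and $H$ are
unaffected).

**Expression.** A transcript × line matrix with planted structure: planted
transcripts are strictly increasing (or decreasing) affine transforms of a
planted susceptibility signature — Spearman $\pm 1$ before noise — plus
Gaussian pattern noise; the default universe of 22 277 transcripts mirrors
a common single-array transcript count and is a convention, not a
biological constant. Detection calls are drawn independently per cell
(Absent with the configured probability, the rest split Present/Marginal
85/15); the filtering *rule* is what the pipeline owns, so calls need no
mechanistic model. Non-planted rows are drawn i.i.d. and then
rejection-sampled until none reaches exact one-sided significance against
the planted signature at the guard level (default 0.05): with a 120-point
discrete null, roughly one i.i.d. null row in twelve would exceed the
screen's operating threshold by chance, and the returned truth table would
not be the unique correct answer. The guard makes "the screen recovers
exactly the planted sets" a well-posed property; disabling it
(`null_guard_alpha = NULL`) restores fully exchangeable nulls for
false-positive-rate studies.

**Tracks.** Persistent random walks at 20-min frames over 48 h: the turn
angle between consecutive steps is wrapped-Gaussian with
$E[\cos(\text{turn})] = p$ (sd $\sqrt{-2\log p}$; uniform headings at
$p = 0$), so $p \to 1$ gives straight paths and the persistence statistic
rises monotonically with $p$. Step length is speed × frame interval with
speed drawn once per cell. Early termination is geometric from the third
frame on, so every track retains the two points the statistics require.

**What the simulators do not emulate:** probe-level microarray physics
(hybridization, summarization, detection-call calculation), plate
spatial/edge effects, absolute cell-count calibration, cell division and
collision in tracks, and image-analysis artifacts. Tests passing on these
synthetics therefore validate the statistical machinery and its contracts,
not robustness to those real-data pathologies.

# Determinism

Every generator takes an explicit seed and restores the caller's RNG state;
the fit restarts are deterministic; output files are written atomically
with no timestamps. A full synthetic run (`run_all()`) under a fixed seed
is byte-identical across invocations — the property the test suite asserts
on the whole output tree.

# Problem sizes used by the tests

The suite exercises the screen at 300–1000 transcripts with 30–80 planted
rows, full-panel plate fits at 8–9 doses with up to 20 noisy repeats,
exhaustive hypergeometric enumeration up to $N = 12$, 10 000 random tracks
for the persistence bounds, and two complete end-to-end runs for the
determinism check; these sizes give stable properties while keeping the
default suite fast. The bundled `run_all()` fixture uses a 2000-transcript
universe with 60/40 planted transcripts and a reference set sharing 12
planted hits.

# Known limitations

* The exact screen is quadratic in nothing but factorial in panel size;
  beyond 8 lines it falls back to the $t$-approximation, where the
  discreteness argument for one-sided defaults no longer applies.
* IC50s are only identified within the dose range; the convergence flag
  marks extrapolated fits but cannot rescue a ladder that never brackets
  the midpoint.
* Probe-to-gene mapping is the caller's responsibility: transcripts are
  screened as rows, and only the signature lookup offers a max-mean
  collapse for duplicate labels.
* The hypergeometric test treats gene sets as unstructured label sets;
  correlated transcripts (co-expression, probe redundancy) make its null
  conservative or anticonservative in ways the test cannot see.
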