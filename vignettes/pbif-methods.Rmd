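---
title: "Population-based input functions for Logan VT: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Population-based input functions for Logan VT: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbifkin)
```

## The problem

Reversible-tracer PET quantification with the Logan plot needs the
metabolite-corrected arterial plasma curve $C_p(t)$. `pbifkin` evaluates
whether a population-based input function (PBIF) — the average of normalized
patient-specific input functions (PSAIFs) from a cohort, rescaled to the
individual — can replace arterial sampling without degrading the total
volume of distribution $V_T$ beyond its intrinsic test-retest variability.
Everything runs on synthetic cohorts with known ground truth, so the
pipeline's statistical behavior can be validated end to end.

## Models

### Input function

The total-blood curve is parameterized as a linear rise from zero to a peak
at $t_{peak}$ followed by a tri-exponential decay
$\sum_{i=1}^{3} A_i e^{-\lambda_i (t - t_{peak})}$. The parent (unmetabolized)
fraction follows a Hill-type model
$$f(t) = a + (1 - a)\,\frac{c^b}{c^b + t^b},$$
which satisfies $f(0) = 1$, decreases monotonically and plateaus at $a$.
The exact functional form used by commercial metabolite-correction tools is
not public; the Hill form reproduces the qualitative behavior (unit start,
monotone fall, late plateau) and is exposed through its own parameter type so
an alternative model can be substituted. The metabolite-corrected input is
the product of the fitted total-blood curve and the fitted parent fraction —
fitting happens first on the raw merged samples, correction afterwards; the
alternative order (correct the samples, then fit) is rejected because the
parent-fraction assay times are much sparser than the automated blood
sampling.

Fitted curves are resampled to a uniform 1-s grid over 0–90 min and rigidly
time-shifted so the maximum lands at $t = 30$ s. A rightward shift zero-pads
the left edge; a leftward shift clips the start of the rise and extends the
right end by evaluating the analytic fit beyond 90 min. For the peak-time
spread the generator draws (30 ± 3 s), the induced AUC perturbation is below
0.5 %; the tests quantify this and also exercise the larger loss that a
45-s peak would incur.

### Tissue kinetics

Regional TACs follow the two-tissue compartment model
$$\dot C_1 = K_1 C_p - (k_2 + k_3) C_1 + k_4 C_2,\qquad
  \dot C_2 = k_3 C_1 - k_4 C_2,$$
with measured activity $(1 - v_B)(C_1 + C_2) + v_B\,C_{wb}$, $v_B = 0.05$,
and $C_{wb}$ the total-blood curve. The simulator uses the analytic
bi-exponential impulse response convolved exactly with the piecewise-linear
$C_p$ (a linear recursion per eigenmode), which agrees with an adaptive ODE
solution to better than $10^{-7}$ relative; frames are trapezoid-averaged on
the 1-s grid. Ground-truth $V_T = (K_1/k_2)(1 + k_3/k_4)$ is exact by
construction.

### Logan analysis

$V_T$ is the late slope of
$\int_0^t C\,dT / C(t)$ against $\int_0^t C_p\,dT / C(t)$, evaluated at
frame mid-times. The plasma integral is trapezoidal on the 1-s grid; the
tissue integral is trapezoidal over mid-times with a straight segment
anchored at $(0, 0)$ — the pre-first-frame contribution is tiny but must be
deterministic. The linearity time $t^*$ is the earliest start index from
which the fitted line leaves every later point within a 10 % relative error;
the error is measured against the *fitted* value (a toggle selects the
observed-value denominator instead). When no index qualifies the last three
points are used and the result is flagged. Diagnostics are OLS $R^2$,
$\mathrm{AIC} = n\ln(\mathrm{RSS}/n) + 4$ (Gaussian likelihood, two
parameters), and the slope's standard error as a percentage of the slope
(unweighted OLS; no weighting scheme is assumed).

Two consequences are worth knowing. First, Logan with a finite $t^*$ is only
asymptotically unbiased: kinetics whose slow eigenrate
$\theta_2 = \tfrac12\big(s - \sqrt{s^2 - 4 k_2 k_4}\big)$, $s = k_2+k_3+k_4$,
is much below ~0.02 min$^{-1}$ do not equilibrate within 90 min and the
slope underestimates $V_T$ by several percent (the tests pin this behavior
down: the deficit is negative and shrinks as $k_4$ grows). Second, with
noisy TACs the transform's correlated noise produces the well-known negative
bias, asserted as a directional property over 200 replicates.

### PBIF construction and scaling

Aligned PSAIFs are normalized by one of
(a) $\mathrm{weight} \times \mathrm{dose}$, (b) AUC, (c)
$\mathrm{weight} \times \mathrm{AUC}$, and averaged pointwise with a sample
(n−1) SD over all cohort subjects except the target (leave-one-out). The AUC
in (b)/(c) is the 0–90 min trapezoidal area of the metabolite-corrected
curve — the span and the corrected (rather than total) curve are design
choices, made for consistency with the Logan integrals. Rescaling inverts
the normalization: scheme (a) multiplies back by the subject's weight and
dose; schemes (b)/(c) multiply back the weight where applicable and obtain
the AUC component by *tail scaling*: the ratio of the mean late blood
activity (60 and 90 min by default) to the mean PBIF value at the same
times. A least-squares tail fit is deliberately not used — single-sample
scaling is the clinically interesting operation, since a venous late sample
could replace arterial access entirely.

The candidate-time analysis scales the PBIF from a single (pseudo-)sample at
30, 37.5, 45, 52.5, 60, 75 or 90 min and reports the percent AUC error
against the true PSAIF. Pseudo-times (37.5, 52.5, 75) average the bracketing
real samples; the PBIF reference value at a pseudo-time is likewise the mean
of its two bracketing values, so a subject whose PSAIF is an exact scalar
multiple of the population shape yields zero error at every candidate.

### Agreement statistics

Test-retest uses the symmetric percent difference
$D = (\mathrm{retest} - \mathrm{test}) / \big((\mathrm{retest} +
\mathrm{test})/2\big) \times 100$; PBIF-vs-PSAIF uses the PSAIF-referenced
difference $D = (P_{PBIF} - P_{PSAIF}) / P_{PSAIF} \times 100$, which is
*not* antisymmetric (swapping arguments gives $-D/(1 + D/100)$; a test
asserts this). Bland-Altman limits are $\mathrm{bias} \pm k\,\mathrm{SD}$
with configurable coverage factor: the default is 1.96, while some published
tabulations are numerically consistent with $k = 2.0$ — both are exercised.
The coefficient of repeatability defaults to the standard-error-like form
$1.96\sqrt{\sigma^2/(N-1)}$ (with $\sigma^2$ the variance of $D$), matching
how it is sometimes printed in the applied literature even though the
conventional definition is $1.96\,\mathrm{SD}$; the conventional form sits
behind a flag. ICC defaults to the two-way mixed, single-measure,
consistency form ICC(3,1) — reported ICCs in this literature rarely name the
form — with absolute agreement ICC(2,1) selectable. Scheme comparison is a
one-way ANOVA followed by all three pairwise *paired* t-tests (the schemes
are applied to the same cohort) with Bonferroni correction
$p_{adj} = \min(1, 3p)$, plus Shapiro-Wilk per scheme. Sample (n−1)
variances are used throughout.

Gray-matter normalization divides each regional $V_T$ by the (optionally
volume-weighted) mean $V_T$ of designated gray-matter regions within the
same session, cancelling session-level multiplicative factors; it is offered
as an exploratory operation, not applied by default.

## The synthetic cohort: what it emulates, and what it does not

Defaults mirror the emulated study design: 18 subjects (12 PD, 6 HV, five HV
with same-day test-retest), injected dose 526.4 MBq with the reported 14 %
between-session CV, automated 15-s arterial sampling for 10 min plus manual
samples at 20/30/45/60/90 min, parent fractions assayed at
5/10/20/30/45/60/90 min, nine regions (white matter, cerebellum, thalamus,
caudate, putamen, pallidum, brainstem, hippocampus, amygdala) on the
32-frame (6×10 s, 4×30 s, 3×60 s, 2×120 s, 5×240 s, 12×300 s) schedule, and
a genotype effect multiplying $V_T$ by 0.60 for mixed-affinity binders with
a 1.15 factor for PD.

Values not fixed by that design are package assumptions, chosen once as
field-plausible and documented here rather than tuned:

- input-function peak time 0.5 ± 0.05 min (so peaks fall near the 30-s
  alignment target); amplitude level proportional to dose/weight with a 15 %
  lognormal subject factor; 10 % lognormal CV per decay rate; 10 % CV on the
  parent-fraction half-time (base $a = 0.05$, $b = 1.5$, $c = 12$ min);
- region templates with $K_1$ 0.08–0.16 mL·cm⁻³·min⁻¹ (lowest in white
  matter) and HV/HAB $V_T$ targets 3.2–4.9; $k_3 = k_4 = 0.05$ min$^{-1}$
  ($k_3/k_4 = 1$), in the literature range for second-generation TSPO
  tracers and fast enough that the Logan slope is within ~1.4 % of truth on
  the 90-min schedule — so recovery tests measure pipeline error, not model
  non-identifiability;
- a 50 % between-subject and 10 % between-session lognormal CV on the
  $V_T$ level (applied through $K_1$, shared across regions), which
  reproduces test-retest SDs near 17 % and ICCs near 0.95;
- measurement noise: additive Gaussian with
  $\mathrm{SD} = \eta \sqrt{C/\Delta}$ (count-statistics-like
  heteroscedasticity; $\Delta$ the sample or frame duration,
  $\eta = 0.05$ by default, exactly zero when requested).

Deliberate simplifications: whole blood and plasma are identified (no
plasma-to-whole-blood ratio or free fraction); activities are
decay-corrected by construction; no sampler dispersion or delay; no image
domain (no partial-volume effects, no reconstruction noise correlations);
parent-fraction assays are noise-free up to a small additive term. Because
the tri-exponential describes the *total* blood curve, the processing chain
is exactly well-specified on noise-free data — round-trip recovery to
machine precision is a test, and a real cohort would add model error on top.
One knowing divergence: in this generator the late-sample tail scaling is
*not* the best candidate time point (early candidates win), because tail
variability is dominated by the lognormal terminal-rate CV, whereas in real
cohorts inter-subject shape differences concentrate around the peak. The
candidate-time table is therefore a demonstration of the machinery, not a
reproduction of the published ordering.

## Numerical choices and degenerate inputs

All curves live on the shared 1-s grid (5401 points); integrals are
trapezoidal everywhere. Tri-exponential fitting is Levenberg-Marquardt with
a deterministic 12-point grid of log-spaced rate starts, amplitudes seeded
per start by a linear solve on the exponential basis, box constraints
keeping rates in $[10^{-4}, 50]$ min$^{-1}$, and lowest-RSS selection;
fitted rates are sorted and ties perturbed by $10^{-9}$ to honor the
strict-ordering invariant. A blood series whose maximum sits at the first
sample is accepted (the optimizer places $t_{peak}$ below it); a maximum at
the last sample is an error. A parent-fraction series identically 1 is
short-circuited to $a = 1$ (the Hill shape is then unidentifiable). Tissue
values clipped negative by the blood-volume correction warn in direct calls
and are tallied silently by the pipeline (`settings$n_frames_clipped`).
Frames with non-positive tissue activity are excluded from the Logan
transform.

Validation problem sizes: parameter recovery runs the full noise-free
18-subject cohort (162 region-fits); leave-one-out identity runs the
zero-variability cohort through all three schemes; the stochastic
acceptance run uses the default 18-subject / 5-retest conditions; the
$t^*$ search is checked against brute-force enumeration on 100 random
Logan plots; Monte-Carlo oracles use 200–2000 replicates under fixed seeds.

## Known limitations

- Logan is the only estimation route; compartmental NLS fitting of $V_T$ is
  out of scope, as are reference-tissue models.
- The PBIF leave-one-out pool uses one session per subject; retest sessions
  are rescaled against that pool rather than forming their own.
- The generator's AIF variability model is an assumption (see above); its
  CVs control the PBIF error budget directly, so absolute agreement numbers
  from synthetic runs characterize the method's machinery, not any
  particular tracer.
- `t*` candidates are frame mid-times; sub-frame placement is not attempted.
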