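---
title: "Methods: image quantification and censored statistics for preclinical ALS efficacy studies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image quantification and censored statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sodquant)
```

## What this package computes

Preclinical efficacy studies in the SOD1-G93A mouse model of ALS rest on
three kinds of quantification: automated measurement of
DAB-immunostained spinal-cord sections (motor-neuron counts and percent
area stained), rule-based derivation of longitudinal disease endpoints
(symptom onset, weight-loss onset, loss of the full wire hang, humane
euthanasia), and censored two-sample statistics for the resulting
time-to-event data. `sodquant` implements all three as a tested
pipeline, together with ground-truthed synthetic generators (section
images and a two-arm cohort) that make every stage verifiable without
access to animals or slides.

## The combined max(Wilcoxon, log-rank) permutation test

For a two-arm censored sample, both classic rank tests are built from
the same risk table: at each distinct event time $t_j$, with $n_j$ at
risk ($n_{1j}$ in arm 1), $d_j$ events ($d_{1j}$ in arm 1), the expected
arm-1 events are $e_{1j} = d_j n_{1j}/n_j$ and the hypergeometric
variance is
$v_j = n_{1j}(n_j - n_{1j}) d_j (n_j - d_j) / (n_j^2 (n_j - 1))$
(zero when $n_j = 1$). A weighted rank statistic is
$$Z_w = \frac{\sum_j w_j (d_{1j} - e_{1j})}{\sqrt{\sum_j w_j^2 v_j}},$$
with $w_j = 1$ giving the log-rank test (all event times weighted
equally) and $w_j = n_j$ the Gehan-Breslow generalization of the
Wilcoxon test, which up-weights early events while many animals remain
at risk. The two tests are sensitive to different alternatives; to avoid
committing in advance to a weighting, the combined statistic is
$$M = \max(|Z_{\text{log-rank}}|, |Z_{\text{Wilcoxon}}|),$$
and its null distribution is obtained by permuting arm labels with the
arm sizes fixed, which is exact under exchangeability. This buys
robustness to where in the time course the arms separate at a modest
price in power relative to the better of the two tests chosen with
hindsight.

Numerical conventions, each of which is tested:

* a subject censored at $t$ is still at risk at $t$ and leaves
  afterwards;
* when the number of label arrangements $\binom{n}{n_1}$ is at most
  20,000 the permutation distribution is enumerated exhaustively and
  $p$ is the proportion of arrangements (including the observed one)
  with $M_b \ge M_{\text{obs}}$; otherwise $B$ Monte-Carlo draws are
  used with the add-one estimator $p = (1 + \#\{M_b \ge
  M_{\text{obs}}\})/(B+1)$, which never returns zero;
* ties $M_b = M_{\text{obs}}$ count toward rejection (conservative);
* degenerate permutations with zero variance contribute $M_b = 0$ and a
  warning;
* the Wilcoxon weighting defaults to Gehan-Breslow; Peto-Prentice
  pooled-survival weights are available by flag. Which variant an
  individual historic analysis used is rarely recoverable, so the
  choice is exposed rather than asserted.

A worked example that is also frozen in the test suite: arms
$\{1,2,3\}$ and $\{4,5,6\}$, all events. The risk table gives
$U_{LR} = 1.85$, $V_{LR} = 0.6775$, $Z_{LR} = 2.248$; with Gehan
weights $U_W = 9$, $V_W = 18$, $Z_W = 2.121$ (9 is also the classic
Gehan count of concordant pairs). Of the 20 label arrangements only the
observed split and its mirror reach $M_{\text{obs}}$, so the exhaustive
$p = 2/20 = 0.10$.

```{r worked-example}
s <- surv_sample(1:6, rep(TRUE, 6), rep(c("A", "B"), each = 3))
combined_permutation_test(s, seed = 1)
```

## Survival models and summaries

`km_estimate()` computes the product-limit estimator per arm, the
median as the first event time with $S(t) \le 0.5$, and the restricted
mean (the integral of $S$ up to the largest observed time). Under heavy
censoring a nonparametric unrestricted mean does not exist; the
restricted mean is reported instead and is labelled as such.

`weibull_lrt()` compares arms parametrically: censored Weibull AFT
models with a common shape $k$ and arm-specific log-scale, against a
reduced model with a single scale, via the likelihood ratio on
$\chi^2_1$. The SOD1-G93A survival curve is steep and well
characterised, which is when a parametric family buys real power over
semiparametric alternatives. Fitting is delegated to
`survival::survreg()`; the comparison, the reporting scale
($k = 1/\texttt{scale}$, per-arm medians $\lambda (\ln 2)^{1/k}$) and
the validation (parameter recovery within 10% at $n = 200$, uniform
null LRT p-values) are this package's own.

The beam-test models follow the same pattern: latency with a linear
mixed model and foot slips with a Poisson GLMM, both with fixed
intercept, beam-size slope and treatment effect, random per-animal
intercept and beam-size slope (an animal-specific regression on
successive beams), fitted by maximum likelihood through `lme4` and
tested by LRT on the treatment term. Singular random-effect fits are
flagged, not hidden.

## Endpoint rules

Each rule is a small, exactly testable function:

* **Early symptom onset** — a session is positive when hindlimb tremor
  *or* loss of the hindlimb extension reflex is recorded; onset requires
  two *consecutive* positive sessions. The event is dated to the first
  session of the pair by default ("appearance", confirmed by the
  second); dating to the confirming session is available, since records
  of which convention a given historic analysis used rarely survive.
  The rule is verified against a brute-force scan over all 64 boolean
  sequences of length six.
* **Weight-loss onset** — the first observation at or below
  $(1 - f)$ of the running peak weight ($f = 0.05$ by default) after
  which the peak is never re-attained. The "sustained" qualifier makes
  the rule robust to measurement jitter: a transient dip followed by a
  new peak is ignored.
* **Last full wire hang** — sessions are best-of-three with a 60-s cap;
  the event is the greatest age with a 60-s score. Animals still at 60 s
  at their final session are right-censored there; animals that never
  reached 60 s are flagged (`never_full_hang`) rather than silently
  dropped.
* **Euthanasia criteria** — righting failure is *strictly more than*
  15 s (a righting time of exactly 15 s passes); the weight criterion is
  *at or below* 80% of the running peak (a 20% drop triggers). An
  absent righting measurement passes that criterion.
* **Censoring classification** — deaths at or near the humane criteria
  are events; deaths unrelated to disease progression (found dead
  without approaching criteria, i.e. probable injection accidents;
  euthanasia for injury; weight loss with no other critical signs) are
  censored. The seven-mode mapping is asserted verbatim in the tests.

Dosing arithmetic rounds the exact injection volume to the nearest
20 µl with ties rounding up (deterministic and documented), and the
powder-weight formula $W = 10/0.915 \times V$ applies the free-base
salt correction at the 10 mg/ml target concentration.

## The synthetic section generator

The generator emulates the material the image pipeline was built for:
brown (DAB) cell bodies and diffuse brown staining on a bluish
counterstained section against a white slide background. It makes no
claim to photorealism — no scanner artifacts, no intensity gradients,
no out-of-focus planes — so passing its tests shows that the
segmentation logic is correct, not that it is robust to every property
of real slides.

Fixed conventions and defaults: images are `[row, col, channel]`
arrays, origin top-left, 8-bit RGB; 0.65 µm/px; stain colour
(130, 80, 40), tissue (190, 190, 210), background white; cells are
mildly eccentric ellipses with equivalent diameters 15-40 µm (motor
neuron soma scale); tissue is a single ellipse or a bilateral
"butterfly" of two lobes. Non-touching cells are kept at least ~3 µm
apart so that regularizing morphology cannot merge them, while
requested *touching pairs* abut along a 1-3 px boundary — the watershed
stress case. Diffuse staining is painted as 8-12 px patches whose
centres are drawn from a dilated tissue region; small patches and
uniform coverage keep the stained fraction of any interior window close
to the whole-tissue fraction, which is what lets an eroded-mask
measurement recover the generated fraction to within a percentage
point. Painting stops when the realized fraction is within 0.01 of the
target; a shortfall is recorded, never hidden. Everything is
deterministic given the config seed (placement and rendering use
decoupled seed streams, `seed` and `seed + 1`).

## The image quantification pipeline

Tissue masking is per-channel RGB interval detection (reject near-white
background), closing then opening to fill pinholes and drop speckle,
and a minimum component area. Masks are eroded by a physical margin
(10 µm default) before stain-area analysis to avoid edge effects.

Motor-neuron detection is the three-stage procedure: (a) global colour
thresholds for stained somata inside the tissue mask, then opening;
(b) close-open with binary morphological reconstruction, which
regularizes blob outlines while preserving their geometry (the
reconstruction is implemented in-package by iterated conditional
dilation, as EBImage has no reconstruction primitive); (c) watershed on
the Gaussian-smoothed distance transform of the candidate mask — its
basins, the regional minima of the inverted landscape, split abutting
somata — followed by label-preserving dilation and an inclusive size
filter in µm². On uniformly stained synthetic somata the intensity
landscape inside a cell is flat, so the distance transform is the
informative landscape; the smoothing sigma (1 px) and watershed
tolerance (1 px) suppress spurious minima from pixelated ellipse
boundaries. All structural radii are configured in micrometres and
converted with the image scale; the numeric defaults were tuned once
against the synthetic palette and are instrument-specific, never
claims about any original acquisition.

Brown (DAB-positive) detection classifies a pixel positive when the
normalized blue ratio $B/(R+G+B)$ falls below a threshold (0.25 by
default; DAB brown scores ≈ 0.16, the bluish counterstain ≈ 0.36) and
the mean intensity is below a maximum that excludes white background; a
zero channel sum is never brown. Neighbouring positives are filtered
and merged by opening-closing. Percent area stained is
$100 \times |{\rm positive} \cap {\rm tissue}| / |{\rm tissue}|$.

The minimum cluster-size cutoff (180 µm²) applies to the *cluster /
enlarged-cell* endpoint, not to the plain percent-area endpoint —
`quantify_section()` exposes the three modes (`neurons`, `area`,
`clusters`) accordingly, and `filter_by_min_area()` keeps components at
or above the cutoff intact while removing smaller ones entirely.

Because automated counting systematically under-segments relative to a
human rater (partially stained or out-of-plane somata), the calibration
utility fits automated against manual counts by ordinary least squares
and reports the slope, $R^2$ and the mean fractional underestimate,
so automated counts are used as relative, not absolute, measures.

## The cohort simulator

`simulate_cohort()` generates the two-arm longitudinal study the
endpoint and statistics modules are tested against. Observations run
twice weekly from day 42 to day 63 and three times weekly thereafter
(the true weekday calendar of such studies is not modelled; sessions
are evenly spaced within weeks). Per animal: latent symptom onset is
normal (mean 70 d, SD 8, treated mean shifted by a configurable
amount); disease death is Weibull (shape 8, control scale 160 d, the
treated scale multiplied by a time ratio); weight follows logistic
growth to a latent peak near 105 d and then declines proportionally
(~0.4%/day), giving a unique maximum so peak tracking is unambiguous;
tremor and extension flags are Bernoulli with probability ramping
0.15/day after latent onset; wire-hang latency holds at 60 s until a
per-animal decline age (mean 95 d) and then falls 1.5 s/day with
per-trial noise clamped to [0, 60]. These latent forms are deliberately
the simplest that reproduce the qualitative shapes of such studies —
the generator emulates structure, it does not estimate a real cohort.

Non-disease (injection-related) deaths are a constant daily hazard
(0.0055/day) starting at 110 d, which produces late censoring at
roughly the 20-25% incidence such dosing studies report, with censored
animals living almost as long as the disease-death mean — so they
still contribute risk time. With the time ratio at 1 the two arms share
a survival distribution exactly, which is how the pipeline demonstrates
a treatment that relieves symptoms without extending life: the planted
+6 d onset shift is recovered by the derived endpoints to within 2 d
while the combined survival test stays non-significant in ≥ 90% of
replicates.

The beam generator produces 3 trials × {24, 19, 11} mm beams per
animal from the same mixed-model structure the fitters assume (fixed
intercept 80 s, −3 s/mm size slope, −10 s treatment; random intercept
SD 5, slope SD 0.4, residual SD 5; slips Poisson with log-mean
3.2 − 0.12·mm − 0.5·treated and matching random terms), so fixed-effect
recovery is a meaningful end-to-end check.

## Problem sizes and numerical tolerances

The validation suite uses sizes chosen to make the Monte-Carlo
tolerances meaningful: 500 fuzzed small samples for oracle equivalence
at 10⁻¹⁰; 1000 replicates at 25/arm with B = 500 for the combined
test's size (nominal 0.05, accepted in [0.03, 0.07] — the binomial
99% band is about ±0.018); 1000 replicates for Weibull null p
uniformity (KS); 10 synthetic sections of 512×512 px with 20-40 cells
for exact count recovery, plus noisy versions (noise SD 8, 0.65 µm
blur) at ±10%; and 200 cohort replicates at 200/arm for the end-to-end
dissociation property. The 512×512 canvas (333 µm square) rather than
the 1024×1024 default keeps the image suite quick without changing any
algorithmic behaviour.

## Known limitations

* The synthetic palette is a single fixed stain/counterstain pair; the
  colour-threshold defaults would need retuning for real acquisitions,
  and no colour-deconvolution step is provided.
* Region-restricted counting (e.g. ventral horn only) is supported only
  through an optional mask supplied by the caller; no anatomical prior
  is built in.
* The permutation test treats animals as exchangeable; litter or sex
  structure, if present, is not conditioned on.
* The cohort simulator draws symptom flags independently across
  sessions given the latent ramp; real exams are serially correlated.
* Fold-change analysis assumes duplicate wells are averaged upstream
  and a single reference gene.
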