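---
title: "Modelling and analysing ex vivo esophageal tissue mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and analysing ex vivo esophageal tissue mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(esomech)
library(dplyr)
```

## The measurement and the model

Organ-bath stiffness measurements of esophageal tissue strips work like this:
a strip of reference length $L_0$ is hung from a force transducer, stretched
until a small stable preload (~1 mN) registers, and then lengthened stepwise
(0.8 mm per step, one step every 2 minutes, output logged every 5 s). At each
step the force spikes instantaneously and relaxes to a plateau within the
2-minute hold. Lengthening is reversed once the hold-averaged force exceeds
40 mN (about 30 mN/mm&sup2; of tension for a typical strip), to avoid damaging
the tissue; stepwise shortening is then reversed as the force approaches zero.
Repeating this produces strain cycles whose tension-versus-strain curves carry
the mechanical signature of the tissue.

Tension is force per estimated cross-section, with the cross-sectional area
taken as $m / (\rho L_0)$ from the strip's wet mass, so

$$T = F \cdot \frac{\rho L_0}{m} \quad [\mathrm{mN/mm^2}].$$

The analysis model for a lengthening curve is the power law

$$T(\lambda) = A\,\lambda^{k}, \qquad \lambda = L/L_0,$$

fit by ordinary least squares on the double-log transformed points
($\ln T = b + k \ln\lambda$, $A = e^b$). Stiffness is its derivative
$A k \lambda^{k-1}$ (so $Ak$ at the reference length), and compliance is the
pointwise reciprocal. $k$ is the preferred parameter for group comparisons:
it is invariant to errors in $L_0$, which rescale $A$ but not the slope of the
log-log line.

`esomech` implements this analysis (`segment_steps()`,
`build_cycle_curves()`, `fit_power_law()`, `stiffness_at()`,
`compliance_curve()`, `subtract_cycles()`, `find_peak()`, `compare_k()`),
together with a forward constitutive model and protocol simulator
(`simulate_trace()`) that generates the transducer traces the analysis
consumes, and a paired expression-panel workflow (`generate_panel()`,
`call_rate_filter()`, `paired_de()`, and friends).

## The forward tissue model

The strip is modelled as two **additive** lumped elements.

**ECM element** (`ecm_params()`, default form `"engage"`): slack up to
$\lambda_s$ and

$$T_{ecm}(\lambda) = A_e\left[\left(\frac{\lambda}{\lambda_s}\right)^{k_e} - 1\right],
\qquad \lambda > \lambda_s,$$

continuous at the slack strain. This reproduces the hallmark of a strip whose
muscle tone has been abolished by stretch: zero stiffness from $L_0$ to
$2\times L_0$ (default $\lambda_s = 2$) followed by rapid stiffening, as a
cross-linked matrix polymer straightens and engages.

**Muscle element** (`muscle_params()`): a Gaussian length-tension curve

$$T_{act}(\lambda) = a \, T_{max}\, e^{-\left((\lambda - \lambda_{opt})/w\right)^2},$$

with activation $a \in [0, 1]$. The literature describes only a single-peaked
curve (maximal overlap of myosin and actin filaments, peak near
$2.5\times L_0$); the Gaussian is the simplest smooth unimodal choice and is a
deliberate design decision, not a claim about sarcomere mechanics. Activation
combines basal tone with per-agonist Hill occupancies complement-wise
(`activation_level()`): a second agonist augments the first, the combination
saturates at 1, and the beta-agonist isoproterenol multiplies activation by a
factor in $[0,1]$ — it attenuates force but can never invert it. These
interaction rules are likewise explicit design choices anchored only
qualitatively by the observed pharmacology (histamine acting independently of
carbachol; isoproterenol attenuating both).

**Tone plasticity.** Basal tone (default 0.3) is lost once the strip has been
stretched beyond a threshold strain (default 2.0) — implemented at the
lengthen-to-shorten reversal of the offending cycle — and is restored only by
an agonist dose. The timing matters: losing tone mid-lengthening would erase
the basal muscle contribution above $2\times L_0$ and move its apparent peak
to 2.0, whereas the observed basal difference curves peak near 2.5. Losing it
at the reversal reproduces both the cycle-1 curve (muscle present throughout
lengthening) and the cycle-1 shortening force that reaches zero near
$2\times L_0$, which is where cycle 2 then starts — the classic rightward
shift.

**Relaxation kinetics** (`relax_params()`): after each step the force follows
$F_{ss}(1 \pm \nu e^{-t/\tau})$ (overshoot $\nu = 0.5$, $\tau = 25$ s,
shortening floored at zero force). With these defaults the residual at 120 s
is $0.5 e^{-4.8} \approx 0.4\%$ of steady state, comfortably matching force
that "stabilizes within 2 minutes"; any $\tau < 120/\ln 10 \approx 52$ s
would keep the residual under 5%.

### Default constants

| Parameter | Default | Units | Why |
|---|---|---|---|
| $A_e$ | 10 | mN/mm&sup2; | ECM scale; puts matrix-only reversal near $2.5\,L_0$ |
| $k_e$ | 6 | — | steep engagement limb |
| $\lambda_s$ | 2.0 | — | zero-stiffness region ends at $2\times L_0$ |
| $T_{max}$ | 10 | mN/mm&sup2; | see below |
| $\lambda_{opt}$ | 2.5 | — | peak of the length-tension curve |
| $w$ | 0.6 | — | breadth of the peak |
| basal tone | 0.3 | — | resting activation |
| $\tau$, $\nu$ | 25 s, 0.5 | | settles within the 2-minute hold |
| carbachol EC50, $n$ | 0.1 uM, 1.5 | | 1 uM dose is ~97% saturating |
| $L_0$, $m$, $\rho$ | 15 mm, 20 mg, 1 mg/mm&sup3; | | makes 40 mN = 30 mN/mm&sup2; |

$T_{max} = 10$ mN/mm&sup2; is a calibration worth spelling out. The induced
(post-carbachol) cycle must still reach the neighbourhood of $2.5\times L_0$
before the 40 mN reversal trips — the measured induced curves do — which
bounds the muscle tension at the threshold relative to the ECM tension there
(~28 mN/mm&sup2; at $\lambda = 2.5$). A much larger $T_{max}$ (e.g. 20) makes
the simulated induced cycle reverse by $\approx 2.25\,L_0$ and the
length-tension peak unobservable inside the recorded strain range; 10 keeps
the induced reversal near $2.4\,L_0$ and the basal/induced peak structure
observable, while still giving induced tension clearly above basal.

### The pure power-law strip

`power_law_tissue()` builds a strip whose tension is exactly
$A\lambda^{k}$ at all strains at or above $L_0$ (ECM form `"power"`, slack 1,
no muscle). This is the model class of the regression itself, so traces
simulated from it have known ground-truth $A$ and $k$ — the right generating
model for parameter-recovery and group-comparison studies. The engagement
form can never play this role: its log-log slope is
$k_e x^{k_e}/(x^{k_e}-1)$ with $x = \lambda/\lambda_s$, which diverges at the
slack strain and exceeds $k_e$ everywhere, so a fitted exponent is not
comparable to $k_e$. The default amplitude $A = 0.12$ mN/mm&sup2; describes a
compliant strip (resting tension a fraction of a mN/mm&sup2;) whose trace
reverses near $2.45\,L_0$ with ~28 fit points per curve, mirroring the
measured curves' extent; a resting tension of 10 mN/mm&sup2; would reach the
40 mN ceiling after ~5 steps and leave too few points for a valid fit.

## The simulated protocol, end to end

```{r simulate}
tr <- simulate_trace(three_cycle_protocol(), default_tissue_params(),
                     noise_sd = 0.2, seed = 1)
curves <- tr |> segment_steps() |> build_cycle_curves()
fit_cycle_curves(curves)
```

The default three-cycle protocol applies 1 uM carbachol after cycle 2, and the
simulated record reproduces the canonical topology: cycle 1 (basal tone +
matrix) spans $1 \to 2.5\,L_0$; the shortening force reaches zero near
$2\,L_0$ because tone is gone, so cycle 2 (matrix only) starts there, the
rightward shift; carbachol then re-activates the muscle, the strip is
shortened back to preload tension near $1.5\,L_0$, and cycle 3 runs leftward
of cycle 2. Subtracting cycle 2 from cycles 1 and 3 isolates the muscle
element:

```{r decompose}
decompose_cycles(curves)$peaks
```

Peak refinement fits a parabola through the maximal point and its two
neighbours; the vertex is trusted only to within one grid step of the raw
maximum (it is clamped there, and abandoned for the raw maximum when the
three points are not concave), because with 0.8 mm steps and mN-scale noise
the three-point curvature of a shallow peak is noise-limited. Peaks that sit
on the curve boundary — common for the induced curve, whose reversal
truncates the rising limb just below the optimum — are flagged `boundary`.

## Noise model and numerical choices

* **Noise**: additive white Gaussian on every logged force sample, default
  sd 0.2 mN — small relative to the 1 mN preload and to hold-averaged forces;
  the instrumentation literature gives no noise figure. Hold averaging over
  24 samples reduces it to ~0.04 mN.
* **Preload**: simulated force is tissue tension times cross-section, with
  the ~1 mN preload treated as the near-zero stabilization level (it is the
  shortening stop threshold, not an additive offset). Curves therefore show
  exactly zero tension where the model is slack, and tension conversion does
  not subtract a baseline.
* **Tension floor**: points with tension at or below 0.05 mN/mm&sup2; are
  excluded from log-log fits (the log is undefined at zero, and the
  matrix-only cycle's slack region is genuinely tension-free). Valid fits
  require more than 5 retained points, else an invalid-fit object is
  returned rather than an error.
* **Hold-average bias**: averaging over the full hold keeps the decaying
  overshoot, inflating every hold mean by a factor
  $1 + \nu \frac{r(1-r^N)}{N(1-r)} \approx 1.10$ ($r = e^{-\Delta t/\tau}$).
  It cancels in the exponent $k$ (a pure scale factor in log space) and in
  cycle subtraction (common to both operands' shapes up to direction), but it
  is the dominant contribution to the ~10% bias in recovered $A$.
* **Subtraction and interpolation**: cycle curves are sparse (~10-30 points)
  and monotone in strain, so linear interpolation of the subtrahend onto the
  minuend's strains is used, restricted to the strain overlap.
* **Degenerate inputs**: zero-variance group comparisons short-circuit to
  exact equality; zero stiffness maps to an explicit undefined compliance
  marker (`NA` + `defined = FALSE`), not `Inf`; a protocol that can never
  reach the force reversal caps commanded strain at $3\,L_0$ with a warning
  flag.

## The expression-panel workflow

`generate_panel()` simulates a 96-gene panel over paired vehicle/cocktail
samples from 5 donors (matching the paired-design scale of interest):
log2 values are gene baseline + shared donor effect (sd 0.5) + gene-specific
treatment effect in the treated arm + noise (sd 0.5). Detection-call flags
model assay dropout: by default 36 of 96 genes get a 0.2 per-sample call
probability (the rest 0.98), so a 50% call-rate filter retains close to 60
informative genes on average.

The analysis chain is deliberately conventional: `call_rate_filter()`
(applied before any testing), two-way Ward/Euclidean clustering
(`cluster_panel()`; "Ward" read as the minimum-variance linkage, via
`hclust(method = "ward.D2")`), `pca_top3()` with a fixed sign convention
(largest-magnitude loading positive) for reproducible coordinates, and
`paired_de()`: a per-gene paired two-tailed t-test on log2 values with
Benjamini-Hochberg step-up adjustment across tested genes, significance at
adjusted p < 0.05. Undetected entries are treated as missing and drop their
donor pair for that gene only; genes with fewer than two complete pairs are
reported untested and excluded from the adjustment. Fold change is
$2^{\overline{\Delta \log_2}}$, the geometric-mean ratio — the estimator is
not pinned down by the upstream software's documentation, and fold-change
sets (`fold_change_sets()`, strict `> 5`-fold in magnitude, either direction)
and the volcano criterion (adjusted p < 0.05 and magnitude > 2) are exposed
with their thresholds as arguments.

```{r panel}
pm <- generate_panel(seed = 1)
flt <- call_rate_filter(pm, 0.5)
de <- paired_de(flt)
summary_row <- dplyr::filter(volcano_table(de), significant) |> nrow()
c(genes_retained = length(flt$genes), significant = summary_row)
```

## What the synthetic data does and does not emulate

The trace generator reproduces the protocol structure (step/hold/log timing,
force-threshold reversals, full-scale clipping), peak-then-plateau step
transients, additive element mechanics, tone plasticity, and dose events; the
panel generator reproduces pairing, donor correlation, treatment effects and
detection dropout. Neither emulates: slow drift or creep across cycles,
temperature/bath artefacts, hysteresis within a hold, plastic deformation
beyond the tone-loss rule, inter-donor heterogeneity of the mechanical
parameters (except where a study function draws them explicitly), real EDP
gene identities or their correlation structure, or qPCR preprocessing.
Passing tests therefore demonstrate that the analysis recovers what this
model family generates at realistic noise — not that the model captures every
property of living tissue.

## Problem sizes used in the shipped studies

The package's studies are sized to be informative yet quick: parameter
recovery uses 100 strips; fit-quality checks 5 traces x 3 cycles; the
decomposition peak summary 20 traces; the two-arm comparison 200 replicates
of 8 strips per arm (between-strip exponent sd 1.0, a substantial biological
spread against a 6-vs-9 arm difference); the null false-discovery study 500
panels of 60 genes x 5 pairs. These sizes give Monte Carlo standard errors
well inside the margins being checked.

## Known limitations

* The model is one-dimensional and lumped: no spatial continuum mechanics,
  no cross-bridge kinetics, no viscoelastic spectrum beyond a single
  relaxation time.
* Only hold-averaged forces are analysed (as in the instrument protocol);
  the transients are simulated but not exploited for viscoelastic parameter
  estimation.
* The engagement-form ECM is not itself a power law, so fitted exponents on
  engagement-form curves characterize the curve, not $k_e$; use
  `power_law_tissue()` when ground-truth exponents are needed.
* The agonist-response normalization assumes tension (per cross-section)
  units throughout; responses are not re-normalized per donor.
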