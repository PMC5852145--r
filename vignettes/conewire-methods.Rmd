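---
title: "Reverse engineering cGMP signalling from growth-cone membrane potentials: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{conewire methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(conewire)
```

## The scientific problem

A nerve growth cone converts an intracellular cGMP signal into a membrane
potential (MP) shift that decides its turning direction: low cGMP
hyperpolarizes (repulsion), high cGMP depolarizes (attraction).  Two cGMP
effectors are known — cyclic-nucleotide-gated channels (CNGC), which drive
hyperpolarizing chloride channels (ClC), and cGMP-dependent protein kinase
(PKG), which drives depolarizing sodium channels (NaC).  What is *not*
known is the wiring between the effectors' downstream factors (latent
variables we call Z for CNGC-DF and W for PKG-DF) and the two channels.
With four candidate cross-edges (Z→W, W→ClC, Z→NaC, W→Z), each of which
can be absent, activating, or inhibiting, there are $3^4 = 81$ candidate
topologies, M\_1 (no interaction) through M\_81.

`conewire` selects among these 81 deterministic models by Bayesian
evidence, using only MP time series (MPTS) recorded at 1 Hz under a small
set of pharmacological conditions: control, ClC blocked (DNDS), NaC
blocked (STX), PKG inhibited (KT5823), at stimulant (8-Br-cGMP) levels of
5 or 10 μM.

## The forward model

All 81 models share the same mesoscopic skeleton.  The stimulant rises as
$S(t) = S_\mathrm{eff}\,(1 - e^{-t/\tau_S})$, where $S_\mathrm{eff}$ is
the applied concentration for pipette injection or a Hill-saturating
permeation-corrected level
$P_{\max} S^{n_p} / (K_p^{n_p} + S^{n_p})$ for bath application.  The
effector activations are algebraic Hill functions,
$X = S^{n_X}/(K_X^{n_X} + S^{n_X})$ and
$Y = \eta_{PKG}\, S^{n_Y}/(K_Y^{n_Y} + S^{n_Y})$, and the two downstream
factors relax with first-order kinetics:

$$\dot Z = k_Z\,\big(A_Z X\, m(W; s_{W\to Z}, g_{W\to Z}) - Z\big), \qquad
  \dot W = k_W\,\big(A_W Y\, m(Z; s_{Z\to W}, g_{Z\to W}) - W\big),$$

with the pathway modifier $m(U; s, g)$ equal to $1$ (no interaction),
$1 + gU$ (activation) or $1/(1+gU)$ (inhibition).  Channel activities are
saturating and algebraic, $cl = \mathrm{sat}(Z\, m(W; s_{W\to Cl}))$,
$na = \mathrm{sat}(W\, m(Z; s_{Z\to Na}))$ with
$\mathrm{sat}(u) = u/(1+u)$, and the potential is additive:

$$\hat V(t) = V_K - \eta_{Cl} A_{Cl}\, cl(t) + \eta_{Na} A_{Na}\, na(t).$$

The binary flags $\eta_{Cl}, \eta_{Na}, \eta_{PKG}$ encode DNDS, STX and
KT5823.  Three structural consequences are load-bearing and are enforced
by tests: (i) $V_K$ is a pure additive bias, so steady-state shifts are
independent of it; (ii) blocking ClC leaves only the depolarizing term
($\hat V \ge V_K$), blocking NaC only the hyperpolarizing term, and
inhibiting PKG silences W entirely; (iii) every modifier equals 1 at
$g = 0$, so each complex model nests every simpler one — a complex model
can cut off unnecessary pathways by sending gains to zero.

The channel activities are taken algebraic in Z and W (not given their own
relaxation times): the recordings are slow potential shifts over minutes,
so any channel kinetics faster than the ~10–30 s downstream-factor
relaxation is unresolvable at a 1 s grid.  This was an open modelling
choice; the nesting and blocker-sign structure do not depend on it.

### Parameters and their split

The model parameters fall in three classes:

* **Core** ($\theta$, shared by all cells): $K_X, n_X, K_Y, n_Y$ (Hill
  constants, μM / dimensionless), $k_Z, k_W$ (1/s), the interaction gains
  $g$ of the topology's active pathways, and the population means
  $A_{Cl0}, A_{Na0}$ (mV), $A_{Z0}, A_{W0}$.
* **Peripheral** ($\varphi_i$, per recording): $V_K$ (mV), $\tau_S$ (s),
  $A_{Cl}, A_{Na}$ (mV), $A_Z, A_W$.  These absorb cell-to-cell
  variability (growth-cone size, channel density, electrode offset).
* **Condition** ($c$, known): $\eta_{Cl}, \eta_{Na}, \eta_{PKG}$,
  $S_{\max}$, route.

We include $A_Z$ and $A_W$ among the peripherals with core-level
population means ($A_{Z0}, A_{W0}$): the dose–response machinery replaces
them by those means, which is only coherent if the means are part of the
core.  (The alternative — treating them as pure core constants — would
make the per-cell amplitude variability land entirely on $A_{Cl},
A_{Na}$.)

Defaults: $K_X = 1.15$ μM and $K_Y = 16.61$ μM (the reported affinity
estimates: CNGC is the high-affinity arm, PKG the low-affinity one),
$n_X = 4$ and $n_Y = 2$ (cGMP binding-site counts), $k_Z = 0.1$/s,
$k_W = 0.01$/s, $A_{Cl0} = A_{Na0} = 10$ mV, $A_{Z0} = A_{W0} = 1$,
$\tau_S = 30$ s, permeation $P_{\max} = 20$ μM, $K_p = 10$ μM, $n_p = 2$.
The amplitude values are plumbing defaults chosen to produce realistic
traces (hyperpolarizing dips of a few mV converting to depolarization at
high dose).  The relaxation rates are anchored on the recordings' time
scales: the CNGC arm responds within tens of seconds ($k_Z$), while the
PKG-arm conversion is the slow process that puts steady state near 300 s
($k_W$); a faster $k_W$ would equilibrate every trace within ~150 s and
make late-phase forecasting trivially uninformative.  All of these are
config, not claims.

### Numerics

Integration uses an adaptive Cash–Karp RK45 (relative tolerance $10^{-6}$,
absolute $10^{-8}$) stepping exactly onto the 1 s output grid; states are
clamped nonnegative and capped at $10^9$ (mutually activating wirings can
be linearly unstable, but channel activities saturate long before the cap
matters).  Hill functions are evaluated in log space so extreme $K/S$
ratios neither overflow nor underflow.  Steady states are solved by damped
fixed-point iteration on $(Z^*, W^*)$ (damping 0.5, tolerance $10^{-10}$,
at most $10^4$ iterations) with a fallback to integration to $t = 5000$ s;
a tolerance-refinement test checks that halving the integrator tolerance
moves $\hat V$ by less than $10^{-3}$ mV.

## Priors

Most parameters get **left-truncated normal** priors.  The interaction
gains use the zero-peaked form (mode at 0): this is the sparsity device
that makes nested comparison meaningful — unlike a log-normal or Gamma
($k > 1$) prior, the density at zero is positive and maximal, so a complex
model can exactly imitate a simpler one at no likelihood cost, paying only
the Occam factor.  The default table (`default_priors()`):

| parameter | prior | rationale |
|---|---|---|
| $K_X$ | TN(0, 10, 0) μM | broad half-normal, high-affinity arm |
| $K_Y$ | TN(0, 30, 0) μM | broad half-normal, low-affinity arm |
| $n_X$ | TN(4, 1, 1) | CNGC binds 4 cGMP |
| $n_Y$ | TN(2, 1, 1) | PKG binds 2 cGMP |
| $k_Z, k_W$ | TN(0.1, 0.1, 0.001), TN(0.01, 0.03, 0.001) /s | minute-scale kinetics; lower bound excludes relaxation slower than ~1000 s, invisible in an 800 s recording |
| gains $g$ | TN(0, 1, 0) | zero-peaked sparsity |
| $A_{Cl0}, A_{Na0}$ | TN(10, 5, 0) mV | MP shifts of a few to ~20 mV |
| $A_{Z0}, A_{W0}$ | TN(1, 0.5, 0) | order-one gains |
| $V_K$ | N(−75, 10) mV | resting potential −80…−70 mV |
| $\tau_S$ | TN(30, 20, 1) s | diffusion-limited rise |
| $A_{Cl}, A_{Na}, A_Z, A_W$ | TN(mean = population mean, s.d. 5 mV / 0.5, 0) | hierarchical: centered on $A_{Cl0}$ etc. |

These are stand-ins with the documented zero-peak structure; the original
study derived prior scales from a cGMP-diffusion simulation that is out of
scope here, so all entries are overridable config.

## Likelihood

Each 1 Hz series contributes a Gaussian product
$\ln p(V_i \mid \varphi_i, \theta) = -T_i \ln(\sqrt{2\pi}\,\sigma_i) -
\sum_t \Delta V_i(t)^2 / (2\sigma_i^2)$ with
$\Delta V_i = V_i - \hat V$; series are standardized by their own noise
level $\sigma_i$, estimated in preprocessing as the unbiased s.d. of the
residual between the sampled trace and its 31 s centered moving average.
The smoother and window are not dictated by the source study; a moving
average is the simplest estimator whose bias on minute-scale trends is
negligible (tests allow 15% bias under a 10 mV/600 s sigmoid drift).
$\sigma_i$ is estimated *after* step-artifact correction — the artifact is
not observation noise and would otherwise inflate $\sigma_i$.

## Posterior sampling and point estimates

Sampling is blocked random-walk Metropolis over the joint
$(\theta, \varphi_1, \dots, \varphi_I)$ space: one core block plus one
block per series, proposals reflected at truncation bounds.  During
burn-in only, two adaptations run: a per-block scale multiplier steered
toward 20–40% acceptance, and per-coordinate scales taken from the
chain's own running spread (the classic adaptive-Metropolis recipe);
both freeze at the end of burn-in so the kept draws satisfy detailed
balance.  Point estimates are **posterior means** — the source framework's
"MAP" is defined as *mean* a posteriori, and we keep that convention.

## Evidence by stepping-stone sampling

The model-selection criterion is the log marginal likelihood
$\ln E(V, M)$.  We estimate it by stepping-stone sampling along the
inverse-temperature ladder $\beta_k = (k/K)^5$ (default $K = 8$, 2000
samples per rung): rung 0 samples the prior directly, later rungs run
warm-started Metropolis chains at their power posterior, and
$\ln E = \sum_k \ln \frac1n \sum_j e^{(\beta_{k+1}-\beta_k)\,
\ell_j^{(k)}}$ with $\ell$ the total log likelihood.  The Monte Carlo
standard error is assembled from blocked per-rung terms (blocking absorbs
chain autocorrelation, though it remains an underestimate for badly mixed
chains — which is why the recovery tests are replicated over seeds rather
than trusting a single s.e.).

Two desk-scale devices matter:

* **Rao–Blackwellization of $V_K$.**  The baseline enters $\hat V$ purely
  additively and carries an untruncated normal prior, so it is integrated
  out per series in closed form and dropped from the sampled space.  The
  evidence integral is unchanged; what changes is that the stiffest,
  highest-information coordinate of every peripheral block no longer has
  to be explored by the chain.  In our replicate studies this reduced the
  seed-to-seed spread of $\ln E$ by an order of magnitude.  (It is
  disabled automatically if $V_K$ is given a truncated prior.)
* **Data-informed initialization.**  Tempered chains start from a
  deterministic state whose peripheral baselines and amplitudes are read
  off the series (medians, population means); the core starts at prior
  centers.  This removes most of the burn-in travel that 16 series × 6
  peripheral coordinates would otherwise need.

The estimator is validated against closed forms: a conjugate Gaussian toy
(exact marginal known), an all-parameters-fixed edge case (evidence equals
the marginal likelihood exactly), and a nested linear-Gaussian pair where
the Occam ordering is provable and checked over seeds.

## Validation machinery

* **Evidence matrix** (9×9): rows enumerate $(s_{Z\to W}, s_{Z\to Na})$,
  columns $(s_{W\to Z}, s_{W\to Cl})$ with $s_{W\to Cl}$ major, so
  **group b** — the 27 models containing W ⊣ ClC inhibition, whose
  minimal member is M\_7 — is the right-hand three-column block.  Only
  that block structure is anchored by the source material; the
  within-block order is our convention.
* **LOO cross-validation**: per fold, core trained on all-but-one series,
  peripherals of the held-out series fit with the core frozen, held-out
  fitness = log likelihood per data point.  `fast_optimize` mode
  (alternating bounded L-BFGS-B, multi-start) is the desk default; `mcmc`
  mode reproduces the posterior-mean procedure.
* **Specificity**: with the core frozen to the identification estimate,
  per-topology fitness on label-shuffled same-core data should preserve
  the group-b/group-a contrast (each MPTS is a sum of ClC and NaC
  components, so mislabeling blockers hurts all models alike), while
  PKG-inhibited or different-core (netrin-like) data should abolish it.
  The scalar surrogate is `group_contrast` = mean(b) − mean(a) of
  per-point fitness.
* **Predictability**: peripherals trained on the initial 250 s only, core
  from the other series, forecast to 800 s; late-phase (250–800 s] fitness
  and normalized RMSE.  RMSE uses the $n-1$ denominator so that
  predicting the observed mean scores exactly 1.

## The synthetic world

The original recordings are not deposited, so the package ships a
generator that emulates the study design rather than any particular
dataset.  Defaults: 16 series at 10 μM (control 7 / DNDS 5 / STX 4),
generating topology M\_7 with $g_{W\to Cl} = 2$ (the smallest round gain
that makes the dose–response bidirectional on a 0.1–30 μM grid given the
reported affinities), 600 s recordings (the ~10-minute protocol; study
range 300–900 s), peripheral populations $V_K \sim$ N(−75, 3) mV,
$\tau_S \sim$ TN(30, 5, 1) s, amplitudes TN(mean, 2, 0) mV and gains
TN(1, 0.2, 0).  Noise is injected on a 10 Hz raw grid before decimation:
white observation noise (2 mV), single-sample 40 mV spikes at 0.02/s, and
a rectangular ±10 mV step of 30 s duration with probability 0.25 per
series.  A 5 μM design (2/5/4), a PKG-inhibited set, and a
"different-core" netrin-like set (NaC driven by the CNGC arm: the PKG arm
is given the CNGC arm's Hill parameters and kinetics, all cross-edges
removed) cover the specificity scenarios.

What the generator does *not* emulate: slow electrode drift, bursting or
spiking dynamics, correlated (non-white) observation noise, and any
biochemical detail of netrin-1 signalling.  A green test on synthetic data
therefore establishes that the *machinery* behaves as designed on data
satisfying the model's own assumptions — it cannot certify the biological
conclusion.

Two honest consequences of this stated world showed up in validation and
are worth knowing:

* At 1 Hz with a ~30 s stimulus rise, $K_X$ is only weakly identified
  (its likelihood profile is flat over roughly a factor of three): the dip
  onset it controls trades off against $\tau_S$ and $k_Z$.  Parameter
  *recovery* to ±25% at desk scale is therefore fragile even when model
  *selection* is solid — selection depends on the shape of the late-phase
  ClC decline, not on pinning $K_X$.
* Decimation removes spikes that fall between grid points, but a 10 Hz
  raw grid means ~1 in 10 spikes lands on a grid sample and survives into
  the 1 Hz series.  These rare 40 mV outliers penalize all models equally
  and inflate $\sigma_i$ slightly; the study's own description
  ("removes *most* of the spike noise") has the same property.

Recovery studies in the acceptance suite run on the default 600 s world
with reduced chain settings (documented in the tests themselves); each
replicate draws a fresh dataset and a fresh estimator seed.

Two further structural facts shape what validation can show here.  In the
specificity test, the different-core data's group contrast collapses to
the noise floor of the per-series refits (its sign is not even stable),
but the identification-world contrast is itself only ~20× that floor, so
ratio-based thresholds on the contrast are ill-conditioned at this noise
level.  In the predictability test, the five ClC-blocked (DNDS) series
are exact ties between any two models differing only in the W ⊣ ClC edge
— blocking ClC removes the only term they disagree on — so fold-fraction
criteria over the full design have a hard ceiling; the clearest forecast
advantage of the inhibition model is on the NaC-blocked (STX) folds.

## Known limitations

* Random-walk Metropolis is the only sampler; at publication scale one
  would want gradients or tempered transitions (the original work burned
  ~1000 CPU-days on this integral).
* The stepping-stone s.e. underestimates error when chains are stuck;
  replicate-over-seeds checks are the guard.
* Automatic step-artifact detection handles isolated rectangular or
  persistent steps; overlapping or drifting artifacts need manual
  annotations (the original workflow was manual too).
* The 81-model evidence matrix at default settings is hours of CPU; the
  shipped configurations are deliberately desk-scale.
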