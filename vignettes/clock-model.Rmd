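---
title: "A data-driven kinetic model of the Neurospora crassa circadian clock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A data-driven kinetic model of the Neurospora crassa circadian clock}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroclock)
```

## The model

The circadian clock of *Neurospora crassa* is a transcription–translation
feedback loop (TTFL). The White Collar Complex (WCC) is both the core
transcription activator and the blue-light photoreceptor; its inhibitor is
the FFC, the assembled complex of Frequency (FRQ), the FRQ-interacting RNA
helicase and casein kinase 1a. `neuroclock` implements an 18-state ODE
model of this loop with light input:

* **5 mRNAs** — `m_wcc`, `m_frq`, `m_vvd`, `m_csp1`, `m_fam3`;
* **7 WCC/VVD protein species** — dark-active `WCC`; phosphorylated,
  transcriptionally inactive `P_WCC`; the light-activated monomer `WCCs`
  (WCC\*); its homodimer `WCC2s` (WCC\*WCC\*, the potent light activator);
  the heterodimer `WCCVVDs` (WCC\*VVD\*); dark `VVD`; light-activated
  `VVDs` (VVD\*);
* **6 FRQ pools** — the maturation chain `F1`…`F5` and the active `FFC`.

Transcription of each gene is a basal rate plus Michaelis–Menten activation
terms — deliberately without Hill coefficients. The dark-equivalent
activator occupancy pools `WCC + WCCs + WCCVVDs` (the monomeric light form
and the heterodimer act like dark WCC), while `WCC2s` drives a separate
light term with its own `v_max` and `K_M` per promoter. *csp-1* and *fam-3*
are divisively repressed by CSP-1: because CSP-1 is a short-lived,
morning-specific repressor it is not carried as an explicit state but
treated at quasi-steady state proportional to its mRNA, giving repression
factors $1/(1 + m_{csp1}/K_{rep})$. This keeps the canonical state count of
18 while honouring the stated biology. *wcc* transcription is constitutive
in the dark (an unidentified TF) plus a light term; *fam-3* is constitutive
with CSP-1 repression only.

Without cooperative (Hill) activation, the oscillation depends on a delay in
the negative feedback: newly translated FRQ passes through a **linear chain
of six steps** (translation into `F1`, then five sequential conversions
ending in `FFC`), each pool also subject to first-order loss. The FFC acts
enzymatically on every WCC species, converting them into the common
phosphorylated pool `P_WCC`; dephosphorylation at rate `kd2` reactivates
WCC and closes the loop. Light converts `WCC` and `VVD` to their photoadduct
forms at a rate proportional to intensity; `WCCs` dimerizes reversibly with
itself (potent activation) and with `VVDs` (photoadaptation: the heterodimer
only has dark-type activity). Photoadducts revert spontaneously on the
hours time scale, and light-activated species are degraded fast — their
degradation rates are constrained to half-times of at most 3 h, a bound the
`ClockParameters` validity enforces and the fitting bounds encode.

The full reaction list — 46 reactions over 18 species — is available as a
table:

```{r}
head(reactionTable()[, c("reaction", "reactants", "products")], 8)
```

## Parameters

There are exactly 66 kinetic parameters (`clockParameterNames()`), in hours
and arbitrary concentration units (a.u.); light intensity is dimensionless
with the standard experimental light equal to 1 a.u. Observation scales
(counts-per-second per mRNA a.u. for each luciferase reporter) are carried
separately in `observationParams()`. Choices worth knowing:

* **Per-substrate catalytic constants.** The FFC-catalysed phosphorylation
  of the four WCC species carries a `(kcat, KMp)` pair per substrate. The
  shipped defaults make the phosphorylation of the dark WCC strong and
  nearly zero-order (`KMp_wcc` well below the operating WCC level), which
  provides the ultrasensitivity that replaces a Hill coefficient, while the
  light forms are phosphorylated only weakly — in the calibrated model,
  photoadaptation is driven by VVD, not by FFC destruction of the light
  activator.
* **Maturation chain.** Five shared-magnitude step rates `kmat_1..5`
  (default 1.0 per hour; expected transit ~5 h) and small intermediate
  losses `kdf_1..5`. The delay, not the loss, is what sustains the rhythm:
  see the maturation scan below.
* **`kd2 = 0.18` per hour** is the default WCC reactivation rate; the model
  is then a *damped* oscillator (damping ~0.01 per hour in darkness).
  Lowering `kd2` lengthens the residence of WCC in the phosphorylated
  reservoir, i.e. lengthens the feedback delay, which strengthens the
  oscillation: at 0.14 damping is much reduced and at 0.08 it is abolished
  (a limit cycle), with amplitude increasing along the way. This behaviour
  required the phosphorylated reservoir to be recycled nearly losslessly
  (`kdeg_pwcc = 0.01` per hour; phosphorylated WCC is the stable form).

## Simulation

The integrator is an adaptive embedded Dormand–Prince 5(4) pair written in
C++ (no stiff ODE package is assumed by the package), with a hard restart at
every light-intensity discontinuity so switching events are handled exactly.
Default tolerances are `rtol 1e-8`, `atol 1e-10`; analysis functions use
`1e-6`/`1e-8` for speed, which changes reported states by far less than any
tolerance used in the tests. States are clamped to zero in post-processing
if they fall within `-1e-8` of zero; anything lower raises an error. The
test suite cross-checks the compiled derivative against a stoichiometry-
matrix × flux oracle assembled independently from the reaction table, and
the adaptive solution against a fixed-step classical RK4 reference.

Initial conditions default to `burnInState()`: the model is run through a
96 h dark lead-in (to forget the arbitrary seed state) and then the
experimental synchronization regime — 12 h light, 12 h dark, 12 h light,
24 h dark — whose end state defines t = 0. Initial conditions are therefore
not free fit parameters in this implementation.

## Observation and rhythm analysis

Destabilized luciferase (lucPEST) tracks promoter activity closely, so each
reporter observable is a positive scale times its cognate mRNA plus an
optional background. Rhythms are quantified by least squares with
`fitDampedCosine()`: baseline + linear trend + $A e^{-\lambda t}
\cos(2\pi t/T + \phi)$, fitted by variable projection (the linear
coefficients are profiled out exactly; only period and damping are searched,
from spectral and multi-start initializations). A series is called rhythmic
if the relative amplitude exceeds 0.05 and the period lies inside 15–35 h
away from the band edges — an artifact convention, chosen because truly
arrhythmic model variants otherwise pin the fitted period at the band edge
with tiny amplitude. Fold inductions use a 22 h dark baseline before
lights-on, a 2 h peak-search window, and the mean over the last 3 h of the
light phase for the adapted level, matching the visual definitions of
"spike" and "adapted" levels in the reporter recordings.

## Estimation

`chiSquare()` is the weighted sum of squares
$\sum_i ((\hat y_i - y_i)/\sigma_i)^2$ with $\sigma_i$ the reported SD
floored at 1% of each series' maximum (zero-SD protection). Each objective
evaluation re-runs burn-in plus the mapped protocol per strain. `clockFit()`
draws Latin-hypercube starts in log-bounded space (each of n bins per free
dimension holds exactly one draw; deterministic given the seed) and refines
each start independently with a bounded derivative-free trust-region method
(BOBYQA) in log-parameter space; results are ranked by chi-square. A
derivative-based least-squares refiner was the original design, but with
finite-difference gradients it costs ~25 objective evaluations per
iteration here, and BOBYQA reaches the same optima several-fold cheaper.
Default bounds are wide per-class ranges (rates $10^{-4}$–$10^2$ per hour,
concentrations $10^{-3}$–$10^3$ a.u.); passing a reference set tightens the
free parameters to one decade either side of it, which is this package's
operational reading of restricting the space to a biologically meaningful
range. The half-time bound on light-activated species enters as a box
bound, not a penalty. Initial conditions default to the burn-in (they are
not free parameters); `clockFit(fit_initial_states = TRUE)` mirrors designs
in which the per-strain t = 0 state is itself part of the parameter vector,
adding 18 log-bounded initial concentrations per strain started from the
reference burn-in. `ensembleSummary()` summarizes the top-k parameter
sets in log10 space and flags a parameter as constrained when its top-k
range is under one decade; `leaveOutValidation()` refits on a reduced
dataset and scores held-out series by range-normalized RMSE.

## The synthetic-data generator

`generateDataset()` emulates the structure of replicate bioluminescence
tables: per (strain, reporter), replicate draws
$\mathcal N(\mu, (cv\,\mu + \text{floor})^2)$ truncated at zero, reported as
mean, SD and n on a 10-min grid (plate-reader cadence varies between setups;
the curves are near-continuous). Defaults are cv = 0.1 and n = 30,
mirroring "~30 measurements from three independent experiments". Truncated
Gaussian mean-proportional noise was chosen over a lognormal for
transparency; it is a parameter away from being swapped.

The shipped ground truth (`groundTruthParameters()`) is **not** an
experimentally fitted parameter set. It is a synthetic stand-in calibrated
against well-established reporter phenotypes and certified by
`certifyGroundTruth()`: damped ~24 h rhythms of all four reporters in
darkness with fam-3 in antiphase; a positive phase delay of the *vvd*
knockout for every reporter; WT lights-on inductions of ~18/~12-fold
(*frq*), ~50/~10-fold (*vvd*), ~6-fold with full adaptation (*csp-1*); a
~2× higher *vvd* spike and ~5× higher adapted *vvd* level in the knockout;
monotone damping reduction and amplitude growth as `kd2` is lowered over
0.18/0.14/0.08; and cycle-to-cycle repeatability of all observables under
repeated light-dark cycles. A green test on synthetic data therefore
establishes that the pipeline recovers what it put in — not that the model
or the ground truth is a validated description of any particular strain.

## Known limitations and honest edges

* **Slow reservoir drift under LD.** The stable phosphorylated-WCC
  reservoir turns over slowly by design (that slowness *is* the `kd2`
  damping mechanism). Under repeated light-dark cycles its cycle-mean
  still creeps by a few percent per cycle at cycles 6–10 before settling
  (~day 14). All reporter observables repeat to well under 1% of their
  maxima over the same window, which is the sense in which the entrained
  system is balanced; `entrainmentBalance()` reports the stricter
  species-level drift and flags it honestly (`balanced = FALSE` at the 1%
  species-level threshold for the shipped truth).
* **The refractory *frq* promoter is not modelled.** The real *frq*
  promoter is partially light-repressed, producing an overshoot after
  lights-on and a transient rise after lights-off in the knockout; simple
  Michaelis–Menten activation cannot reproduce this, and the model does not
  try.
* No temperature dependence or compensation; no desynchronization of
  hyphae (damping in the model is genuinely amplitude loss, not population
  dephasing); light-induced WCC phosphorylation is folded into the fast
  degradation of light-activated species rather than being an explicit
  state.
* The light-pulse dose-response experiments use a 15-min pulse placed at
  t = 7 min by default — pulse duration is a free experimental choice, so it
  is exposed as an argument.
* The maturation scan removes steps by making them effectively
  instantaneous (1-min residence, no loss), keeping the state count and the
  integrator's step size intact; with `keep_total_delay = TRUE` the
  remaining steps are rescaled so the expected transit time is preserved.

## A worked scan

```{r, eval = FALSE}
p <- groundTruthParameters()
maturationScan(p, steps = c(6, 4, 2, 1))
kd2Scan(p)       # 0.18 / 0.14 / 0.08 per hour
longDarkRun(p)   # 400 h free run, damping per reporter
```
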