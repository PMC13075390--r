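---
title: "Composing rate-defining processes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composing rate-defining processes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirchhoffpk)
```

## The model

Pharmacokinetic clearances (volume/time) and first-order rate constants
(1/time) are coefficients of proportionality between a rate of elimination
and the concentration or amount driving it. This package treats them the way
circuit analysis treats conductances. A *rate-defining process* is one that
could, alone, equal the measured total under limiting conditions — organ
blood flow for a high-extraction drug, the parent's elimination rate
constant for a downstream metabolite. Two rules compose them:

* **parallel** processes add: `CL_total = CL_1 + CL_2 + ...`
* **in-series** processes combine harmonically:
  `1/CL_total = 1/CL_1 + 1/CL_2 + ...`

and identically for rate constants. Everything else in the package is these
two rules applied to organs (renal, hepatic, saturable), to extravascular
input, and to metabolite chains — always alongside the traditional
differential-equation forms of the same quantities, computed separately and
tagged, never mixed.

Processes are constructed with `process_value()`, which enforces strict
positivity: a measured net difference (basolateral efflux exceeding influx,
reabsorption exceeding secretion beyond filtration) is not a rate-defining
process, and callers must form the signed difference *before* construction.
An intravenous bolus has an infinite entering clearance; `infinite_process()`
is an explicit sentinel rather than a large float so that the identity
`series(Inf, x) = x` holds exactly, bit for bit.

### Units

The quantities in this field circulate in mL/min and L/h interchangeably,
and silent mixing is the dominant practical error. Each process carries a
declared unit; the combinators refuse mixed units and mixed kinds, and
`convert_clearance()` / `convert_rate_constant()` do the conversions
explicitly. CLI summaries report clearances in both units.

## Organ models

**Renal.** `renal_clearance()` is
`series(Q_R, parallel(f_uB*GFR, CL_secretion - CL_reabsorption))`.
`net_tubular_transport()` inverts it for the net transport term given a
measured clearance; the result is a *signed* number (net reabsorption is
negative) and is deliberately returned as a plain numeric, because only the
parallel leaving *total* must be a positive rate-defining process — that
constraint is enforced where the bundle is constructed. The flow-free form
`renal_clearance_no_flow()` and the traditional four-unmeasurable-parameter
form `renal_clearance_traditional()` are provided for comparison.
`classify_renal_handling()` compares measured clearance to `f_uB*GFR`; the
equality band is a design choice with no canonical value, set at 5%
relative and configurable.

**Hepatic.** `hepatic_clearance()` is the series combination of up to three
terms: flow, unbound intrinsic clearance (metabolism plus biliary excretion
in parallel, `hepatic_intrinsic()`), and — only when declared
rate-defining — the positive unbound influx-minus-efflux transport
difference. Dropping the transport term yields the familiar two-term
`Q*fu*CLint/(Q + fu*CLint)` form; dropping flow yields the flow-unlimited
transport/metabolism form. The extended clearance model (`ecm_clearance()`)
is implemented exactly as published, including its willingness to evaluate
with efflux above influx, because exposing its behavior next to the series
form is the point of having both.

**Kp_uu curves.** `kpuu_curve()` returns the steady-state unbound
liver-to-blood partition coefficient each mechanistic liver model implies as
a function of hepatic availability F_H, when the conventional steady-state
clearance relation is taken at face value: `F_H` itself for the well-stirred
model, the log-mean `(1 - F_H)/(-log F_H)` for the parallel-tube model. The
closed form for the extended clearance model is not in general circulation,
so it is *derived here* from the flow-unlimited hepatocyte mass balance
(influx in, efflux plus elimination out), giving
`influx/(efflux + CL_int)`; the tests validate it against a numeric solve of
the two-compartment steady state rather than trusting the algebra, and the
qualitative claim that it sits below F_H is asserted over the uptake-limited
parameter regime (influx below efflux plus intrinsic clearance) in which the
ECM is actually used — it is algebraically false outside that regime, and
the package does not pretend otherwise. The systemic reference concentration
is taken as the unbound inlet concentration, the natural choice in the
steady-state infusion setting; the curves are sanity checks on the
mechanistic models (all bounded by 1), not tools for prediction.

The parallel-tube oracle used in the tests discretizes the tube into 1e4
well-stirred segments and averages boundary concentrations by trapezoid;
this carries O(1/N) bias in its own realized availability, so comparisons
are made at the availability the discrete tube actually attains.

**Saturable.** `saturable_clearance()` composes three rate-defining terms,
`V_max/K_M` (capacity), `V_max/S` (saturation) and `Q_H` (delivery), as
`1/CL = K_M/V_max + S/V_max + 1/Q_H`. With infinite flow this is exactly
the classical `V_max/(K_M + S)`.

## Extravascular input

With first-order absorption the entering clearance from the absorption site
is `CL_gut = k_a * V_gut` — `V_gut` being a formal volume with no more
physiological meaning than Vss, which is why no default is supplied and
`CL_gut` may be given directly. The measured oral clearance under the
composition view is `series(CL_gut, CL_iv_bolus)`; the traditional view
holds `CL_oral = CL_iv`. Both predictions are always computed from the same
inputs and tagged (`oral_comparison()`), because their divergence — apparent
bioavailability above unity, depressed oral renal clearance — is the
phenomenon of interest. The bioavailable fraction `F_true` scales the
absorbed amount only, never the gut clearance itself, matching the role F
plays in the dose/AUC relation. Two exact identities anchor the algebra:
`F_apparent * (CL_R ratio) = F_true`, and `MRT_oral = MRT_iv + MAT` as the
time-domain face of the harmonic rate-constant combination. Flip-flop
resolvability defaults to a 3-fold exponent separation (human-data working
range is 3- to 4-fold), configurable.

## Catenary chain and moments

`chain_solution()` gives the closed-form concentration of any species of
the D → M1 → M2 → M3 chain. Rather than hard-coding the three-exponential
Bateman coefficients, the solution is built by symbolic convolution of
`t^p * exp(-k t)` terms, which yields the distinct-rate coefficients
`k_D*k_M1*Dose/(prod(k_j - k_i) * V)` exactly and extends automatically to
the confluent (repeated-rate) polynomial-times-exponential forms. Repeated
rates sit behind an explicit `degenerate_ok` flag with a relative tolerance
of 1e-9, because the distinct-rate formula divides by rate differences and
its direct evaluation becomes numerically unreliable below roughly 1e-4
relative separation (coefficients grow as the inverse square of the
separation and cancel); the tests therefore check the confluent limit
against the stiff integrator, which is stable there. M3 is terminal and is
recovered by mass conservation; it carries a plateau term and has no finite
moments.

`moments()` integrates a sum of exponentials in closed form
(`AUC = sum c_i/k_i`, `AUMC = sum c_i/k_i^2`, generalized to the confluent
terms via factorials), and `mrt_kirchhoff()` is the one-line series
shortcut `sum(1/k_i)` — the package's central equivalence is that these two
routes agree identically, which the suite checks symbolically-in-spirit on
1000 random chains at 1e-10 relative tolerance.

## NCA

`nca()` pins one specific dialect so results are reproducible: linear
up/down trapezoid by default (log-down optional, and demonstrably better on
coarse monoexponential declines), terminal slope by least squares on log
concentrations, extrapolation `C_last/lambda_z` with the matching AUMC
tail. The terminal window defaults to all points past three times the peak
of the moment curve `t*C(t)`, falling back to the last three positive
points; both the window and the rule are configurable arguments rather than
hidden heuristics.

## Synthetic data

`generate_fixture()` draws replicate profiles from the closed-form
one-compartment or chain curves with proportional Gaussian noise
(`C_obs = C_true * (1 + CV*z)`, truncated at zero), CV capped at 0.5. It
emulates assay-style multiplicative error on an exactly known kinetic truth;
it does *not* emulate between-subject parameter variability, absorption-time
heterogeneity, LLOQ censoring, or sparse clinical sampling — so recovery
tests demonstrate estimator correctness on clean kinetics, not field
performance on clinical data. The recovery study conditions are 10%
proportional noise, 200 intravenous replicates sampled 0–72 h at 0.5 h
(dense enough that trapezoid bias is negligible against the 3% recovery
band), mean absolute relative error on CL below 3%. The generator uses one
local RNG stream seeded per call and restores the global seed state, so
fixture generation never perturbs other randomness.

## Problem sizes and numerical choices

Property suites run on generated cases under fixed seeds: 1000 random
chains for the moment/series-MRT equivalence, 100-draw suites for the
algebraic identities and bounds, 1e4 segments for the tube oracle (its
1e-4 agreement band follows from the trapezoid average's O(1/N^2) error),
integrator tolerances rtol 1e-10 / atol 1e-12 against a 1e-8 closed-form
agreement requirement. Random chain rates are drawn with at least 5%
relative separation so the distinct-rate closed form is evaluated only
where it is numerically trustworthy.

## Known limitations

Only flat parallel groups nested in one series chain are composed — there
is no general network solver, because no pharmacokinetic organ model needs
one. No multi-compartment disposition fitting, no deconvolution of k_a or
CL_gut from clinical data, no dispersion-model Kp_uu curve (its closed form
is not established alongside the others), and no in-vitro-to-in-vivo
scaling of intrinsic clearance. The one-compartment oral/iv pair is a
demonstration vehicle for the clearance algebra; dose/AUC and AUMC/AUC
moments, which the NCA utilities implement, are what carry over to
multi-exponential data.
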