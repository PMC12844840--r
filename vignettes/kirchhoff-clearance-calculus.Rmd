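---
title: "A clearance calculus from parallel and in-series rate-defining processes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A clearance calculus from parallel and in-series rate-defining processes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kirchpk)
```

## The model

For linear (first-order) kinetics, every total rate constant and every
total clearance that can be measured is assembled from *rate-defining
processes* by two combination rules. Processes acting in parallel —
simultaneous, mutually independent routes, such as metabolism and biliary
excretion of the same parent — add:

$$k_{total} = \sum_i k_i, \qquad CL_{total} = \sum_i CL_i.$$

Processes acting in series — sequential steps, each one's output feeding
the next, such as delivery to an organ followed by elimination inside it —
add in reciprocal:

$$\frac{1}{k_{total}} = \sum_i \frac{1}{k_i}, \qquad
  \frac{1}{CL_{total}} = \sum_i \frac{1}{CL_i}.$$

Because the mean residence time of a first-order step is the reciprocal of
its rate constant, the series rule is equivalent to the additivity of mean
times: the MRT of a chain is $\sum_i 1/k_i$. A *rate-defining* process is
one that could, by itself, set the measured total — which requires a
strictly positive value. Bidirectional membrane passage therefore enters
only as a net difference (influx − efflux, secretion − reabsorption), and
only when that difference is positive; a non-positive net is not
rate-defining and either errors or (on request) drops out of the series
entirely, since such processes simply do not appear in clearance
equations.

The package's assumptions are exactly the calculus's preconditions:
first-order kinetics throughout (no saturable steps), time-invariant
process values, and positivity of every stage.

## Why an independent oracle

The calculus makes quantitative claims that a differential-equation route
can check. `fo_network()` builds an arbitrary linear transfer network;
`species_moments()` computes each species' AUC and AUMC exactly by two
linear solves ($K\,\mathrm{AUC} = -A_0$, $K\,\mathrm{AUMC} =
-\mathrm{AUC}$), and `analytic_curves()`/`catenary_coefficients()` give the
closed-form polyexponential solutions. For every unidirectional catenary
chain, the oracle's AUMC/AUC of the terminal species equals the Kirchhoff
series sum of stage mean times — the package asserts this on randomized
chains to $10^{-9}$ h.

A genuine tension arises for *reversible, non-eliminating side exchange*
(a peripheral compartment on the dosed species). Every species' AUC is
provably invariant to such exchange (and the tests assert it), but the
moment-based MRT of a downstream species is not: each unit of mass that
detours into the side compartment waits there about $1/k_{return}$, so the
extra residence scales with the *ratio* of the exchange rates, not their
size. `kirchhoff_vs_oracle()` therefore reports both numbers — the
Kirchhoff series value, which ignores non-rate-defining exchange, and the
moment value, which includes the detour time — without encoding a
judgment. The vanishing-exchange limit that does converge is entry rate
$\to 0$ at fixed return rate; the joint limit (both $\to 0$ together) does
not, which is worth knowing before treating either number as "the" MRT.

## Organ models and their parameters

**Renal.** `renal_clearance()` composes kidney blood flow $Q_R$ (entering)
in series with the parallel leaving stage $f_{uB}\,GFR + (CL_{sec} -
CL_{reab})$. Inverting at an observed $CL_R$
(`renal_net_secretion_from_observed()`) gives the net secretory clearance
either with the blood-flow stage removed first or by the traditional
filtration-only subtraction; at moderate renal clearances the two differ
by more than twofold, which is the point of carrying $Q_R$.

**Hepatic.** `hepatic_clearance()` composes $Q_H$, the net basolateral
transport stage $f_{uB}(CL_{int,influx} - CL_{int,efflux})$, and intrinsic
elimination $f_{uB}\,CL_{int}$ in series. With the transport stage out of
scope this reduces *algebraically* to
$Q_H f_{uB} CL_{int}/(Q_H + f_{uB} CL_{int})$ — the familiar well-stirred
expression, obtained here with no organ-mixing assumption (the limit
checks, e.g. $CL_{int}\to\infty \Rightarrow CL_H \to Q_H$, pin this as the
only consistent two-stage form). The extended clearance concept
(`ecc_clearance()`) is implemented as published, full and simplified
forms, for side-by-side comparison; unlike the Kirchhoff path it carries
influx and efflux separately, so it remains finite at influx = efflux
where the net-transport stage is not rate-defining —
`compare_ecc_vs_kirchhoff()` reports exactly this structural difference
per parameter set rather than erroring.

**Perfusion back-calculation.** Steady-state single-pass data determine
the organ clearance as $Q_H(C_{in,u}-C_{out,u})/C_{in,u}$; the
"mechanistic" models differ only in the intra-organ reference
concentration used to back out $CL_{int}$ (outlet for the well-stirred
model, logarithmic mean for the parallel tube). Since the log-mean always
exceeds the outlet concentration, WSM-derived $CL_{int}$ is always the
larger — a pure algebraic fact the tests assert. The systemic reference
concentration $C_{blood}$ is deliberately a separate field of
`perfusion_ss()`: published steady-state identities leave its convention
implicit, so fixtures must carry their own.

Tunable parameters that matter:

- `dominance_fraction` (default **0.9**, dimensionless) in
  `classify_rate_limiting_step()`: the share of $1/CL_H$ one series stage
  must carry to be called rate-limiting. "Much greater" is never
  quantified in the literature this calculus comes from; 0.9 is a strict
  reading, and anything below it reports `"mixed"`.
- `threshold_ratio` (default **3**, dimensionless) in `flip_flop_rate()`:
  the absorption/elimination rate ratio beyond which the regime is
  labeled absorption- or elimination-limited. The composed rate itself is
  exact and label-free.
- Units: hours, liters, mg, mg/L are canonical (µg/mL is numerically
  identical to mg/L). All organ functions are unit-agnostic given
  consistency; `convert_flow()` makes the L/h ↔ mL/min conversion
  explicit rather than guessing.

## The NCA layer

`pk_curve()` canonicalizes a signed exponential-term list to strictly
decreasing exponents (merging duplicates within $10^{-9}$ relative);
moments to infinity are the closed forms $\mathrm{AUC}=\sum C_i/\lambda_i$,
$\mathrm{AUMC}=\sum C_i/\lambda_i^2$, signed terms included, so the
through-zero oral form needs no special casing. `nca_iv()` applies the
standard identities (CL = dose/AUC, $V_{ss} = CL\cdot MRT$, renal split by
fraction excreted unchanged). `oral_clearance_chain()` is where the
calculus earns its keep: the clearance operating after oral dosing is
computed from the *urinary* bioavailability
($CL_{oral} = F_{urine}\,Dose_{oral}/AUC_{oral}$, assumption-free), and the
absorption site follows from the series relation
$1/CL_{oral} = 1/CL_{iv} + 1/CL_{abs}$. Plasma-derived bioavailability is
reported unclamped: when $CL_{abs}$ is slow, AUC inflates and $F_{plasma}$
can legitimately exceed 1 — the tests construct such records on purpose.
A non-positive mean absorption time is a warning, not an error, because
noisy fitted inputs can produce it without being meaningless.

## Fitting and the synthetic generator

`generate_series()` samples a curve at stated times under either no noise,
proportional noise ($\times(1 + cv\cdot N(0,1))$, the multiplicative error
typical of PK assays), or additive noise; negative draws are clipped to
zero with a count. Each call takes one explicit seed and restores the
global RNG state, so fixtures are bitwise reproducible. The default
fixture grid is 0.25, 0.5, 1, 1.5, 2, 3, 4, 6, 8, 10, 12, 16, 20, 24 h,
chosen once so that both disposition phases of the worked biexponential
(half-lives 0.5 h and 4 h) are sampled.

`strip_exponentials()` is the classical method of residuals: fit the
terminal log-linear slope, subtract the back-extrapolation, repeat on the
positive residuals; oral curves strip the post-peak decline and recover
the absorption exponent from the residual rise, emitting a paired $\pm A$
start. The terminal window is found adaptively — extend backwards while
the next point stays on the current line within 0.002 log units, a
tolerance widened to $3\times$ the window's own residual RMS when the data
are noisy — so earlier phases do not leak into the slope on clean data and
the window does not collapse on noisy data. `refine_fit()` polishes by
Levenberg–Marquardt on the log scale for iv data and on the linear scale
with $1/\hat y$ weights for oral data (which pass through zero);
through-zero 2-term starts are refined in the constrained
parameterization $(A, \lambda_1, \lambda_1 + \delta)$ so the $C(0)=0$
shape and exponent ordering hold by construction. Term count is always
caller-specified; `compare_term_counts()` offers an AIC-style comparison
but is never applied silently.

What the generator emulates — and does not. It reproduces proportional or
additive assay error on a fixed design. It does not emulate
below-quantification-limit censoring, irregular or missed sampling,
inter-occasion or inter-subject variability, or urine-collection
time-courses (only cumulative recovery is modeled). Passing tests
therefore show the estimators behave correctly under clean multiplicative
error, not that they are robust to every field artifact.

One quantitative consequence is worth stating because the tests compute
it: at 5 % proportional noise on the 14-point default grid, the *fast*
exponent of the worked biexponential is weakly identified. The Fisher
information of that design puts the best achievable relative standard
error near 20 % (the fast phase contributes appreciably at only the first
four or five samples), so the median absolute error of any unbiased
estimator sits near 13 % — and refining from the true parameters performs
no better than refining from the stripped start. The slow (terminal)
exponent, by contrast, recovers to about 1 %. Fitted-curve *functionals*
dominated by the slow phase (AUC, MRT) remain accurate to a few percent.

## Numerical choices

- Eigendecomposition is used for closed-form curves only when eigenvalues
  are real and pairwise separated by more than $10^{-10}$ of the spectral
  radius; otherwise the solver falls back to dense matrix-exponential
  sampling on a geometric grid spanning $[10^{-3}/k_{max},\ 20/k_{min}]$
  and says so. Confluent (repeated-eigenvalue) closed forms are
  deliberately not emitted.
- Sinks (species with no outflow) are tracked as cumulative amounts via
  the integrated inflows, keeping the rate matrix invertible and making
  total mass auditable at every sample time (asserted to $10^{-9}$
  relative).
- Algebraic identities are tested at $10^{-9}$–$10^{-12}$ relative;
  golden numbers from the worked examples are compared at their printed
  precision (3–4 significant figures). Where a printed value was chained
  through rounded intermediates, full-precision recomputation agrees
  within 1 % and the tests use that tolerance rather than pretending to
  more digits than the source carries.
- Empty parallel/series groups are errors, not identities: a group with
  no rate-defining processes has no total (0 and $\infty$ are both
  non-rate-defining).
- Problem sizes in the test suite: randomized property sweeps use 10–100
  draws per law (100 for the chain-equality property), networks of 2–6
  species, and 50 seeded replicates for the noisy-recovery study; the
  whole suite runs in seconds.

## Known limitations

- Linear kinetics only: no Michaelis–Menten leaves, no time-varying
  rates, no multi-dose superposition.
- The dispersion model has no closed form here (its dispersion
  coefficient is a free parameter never fixed by the sources this
  calculus engages), and unbound tissue-to-plasma ratios ($Kp_{uu}$) are
  not estimated.
- The oral stripper assumes a single absorption exponent faster than the
  terminal slope; absorption profiles with lag times or parallel inputs
  need a different initializer (the refiner itself is general).
- The absorption-site volume is reported only when the caller supplies
  $k_{absorption}$; it is never inferred, because the paired-study record
  alone does not identify it.
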