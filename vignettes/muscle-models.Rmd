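---
title: "Active skeletal muscle constitutive models: methods and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Active skeletal muscle constitutive models: methods and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(activemuscle)
```

This vignette documents the four constitutive models implemented in
`activemuscle`, the kinematics of the homogeneous load cases, the activation
machinery, and the numerical decisions behind the solvers and the fitting
pipeline.

## Kinematics and notation

Deformations are described by the gradient $\mathbf F$ with $J = \det\mathbf
F$, right Cauchy–Green tensor $\mathbf C = \mathbf F^\top\mathbf F$, and
isochoric part $\bar{\mathbf C} = J^{-2/3}\mathbf C$. The fiber direction
$\mathbf m$ (unit, default $\mathbf e_3$) enters through the structural
tensor $\mathbf M = \mathbf m\otimes\mathbf m$; the fiber stretch is
$\lambda^2 = \mathbf C:\mathbf M$. Stresses are obtained from the strain
energy $\Psi(\mathbf C)$ as $\mathbf S = 2\,\partial\Psi/\partial\mathbf C$
(second Piola–Kirchhoff), $\mathbf P = \mathbf F\mathbf S$ (nominal), and
$\boldsymbol\sigma = J^{-1}\mathbf P\mathbf F^\top$ (Cauchy). Under full
incompressibility a reaction pressure term $-p\,\mathbf C^{-1}$ is added to
$\mathbf S$ and determined from the traction-free faces of each load case.

Six isochoric homogeneous load cases are provided, all with the fiber along
$\mathbf e_3$:

| Case  | $\mathbf F$ | Control variable |
|-------|-------------|------------------|
| UTCAF | $\mathrm{diag}(\lambda^{-1/2},\lambda^{-1/2},\lambda)$ | fiber stretch $\lambda$ |
| UTCTF | $\mathrm{diag}(\lambda,\lambda^{-1/2},\lambda^{-1/2})$ | transverse stretch $\lambda$ |
| SAF   | $\mathbf I + \nu\,\mathbf e_3\otimes\mathbf e_2$ | shear amount $\nu$ |
| PSAF  | $\mathrm{diag}(1/\lambda,1,\lambda)$ | $\lambda$ |
| PSTF  | $\mathrm{diag}(\lambda,1,1/\lambda)$ | $\lambda$ |
| PSTIF | $\mathrm{diag}(\lambda,1/\lambda,1)$ | $\lambda$ |

`nominal_response()` returns the work-conjugate nominal stress component of
each case; `response_sweep()` evaluates it over a grid.

## The active-stress model (ASE)

The isochoric energy is a Neo-Hookean matrix plus two fiber-shear terms and a
quadrature-defined fiber energy,

$$\Psi = \frac{\mu}{2}(\bar I_1 - 3) + G_1 B_1 + G_2 B_2^2
       + \Psi_{f}(\bar\lambda) + \frac{K}{2}(\ln J)^2,$$

with $B_1 = \bar I_5/\bar I_4^2 - 1$ and $B_2 = \operatorname{acosh}\theta$,
$\theta = (\bar I_1\bar I_4 - \bar I_5)/(2\sqrt{\bar I_4})$. The fiber Cauchy
stress combines a passive toe/linear law $f_{\xi p}$ (parameters $D_1$, $D_2$,
transition stretch $\lambda^*$, C1-continuous at $\lambda^*$) and an active
force–stretch bell $f_{\xi a}$ (optimal stretch $\lambda_{opt,a}$, clamped to
0.36 outside $[0.6, 1.4]\lambda_{opt,a}$), both scaled by the maximal fiber
stress $\sigma_{max}$; the activation time course multiplies only the active
part. $\Psi_f$ is the integral of $\sigma_f/\bar\lambda$, evaluated by
adaptive quadrature (`stats::integrate`, relative tolerance near machine
precision) and verified against finite differences in the test suite.

Two numerical points deserve note. First, $\operatorname{acosh}$ is evaluated
through a guarded `acosh_ratio()` helper: $B_2^2 \approx 2(\theta-1)$ near
$\theta = 1$, so $d(B_2^2)/d\mathbf C$ is finite and generally nonzero there,
and the series branch avoids catastrophic cancellation. Second, at UTCAF the
$B_1$ gradient vanishes identically and the $B_2$ gradient is exactly
cancelled by the reaction pressure, so the uniaxial-along-fiber response is
analytically independent of $G_1$ and $G_2$ — which is why those moduli are
flagged unidentifiable when fitting to UTCAF data alone.

## The generalized active-strain family (GASA, ASA, GASAM)

All three share the generalized-invariant energy

$$\Psi = \frac{\gamma}{4}\left[\frac{1}{\alpha}\!\left(e^{\alpha(\tilde I-1)}-1\right)
 + \frac{1}{\beta}\!\left(e^{\beta(\tilde J-1)}-1\right)
 + \frac{1}{\kappa}\!\left((\det\mathbf C)^{-\kappa}-1\right)\right],$$

where $\tilde I = \mathbf C:\tilde{\mathbf L} + \omega_a\,\mathbf C:\mathbf M$
with $\tilde{\mathbf L} = \omega_0(\mathbf I - \mathbf M)/2 + (1 -
\omega_0)\mathbf M$, and $\tilde J$ built analogously from the cofactor. The
activation level $\omega_a \in [0, 1)$ carries the active contribution; the
three models differ only in how $\omega_a$ is determined from the target
active nominal stress $P_a(\lambda) = P_{opt}\, a(t)\, f_\xi(\lambda)$:

* **GASA** calibrates $\omega_a$ so that the *frozen*-$\omega_a$ uniaxial
  stress increases by exactly $P_a$. This reduces to a scalar transcendental
  equation solved in closed form with the Lambert W function
  (`pracma::lambertWp`); the solution is verified in the tests against an
  independent bisection on the stress balance. Since $\omega_a$ is frozen
  when differentiating, $\mathbf S$ is exactly $2\,\partial\Psi/\partial
  \mathbf C$ at fixed $\omega_a$.
* **ASA** determines $\omega_a$ from an energy balance between the elastic
  and total uniaxial energies plus the active work integral
  $\int f_\xi\,d\lambda$ (closed-form piecewise-polynomial antiderivative).
  The balance is solved by Newton iteration with a bisection fallback, and
  the stress acquires an extra term from $d\omega_a/d\lambda$ (implicit
  differentiation of the balance).
* **GASAM** uses the closed form $\omega_a = \ln\varphi/(\alpha\lambda^2)$
  with an analytic derivative, and its stress includes the corresponding
  $S_{\omega_a}$ term.

Because $\omega_a = 0$ when passive, the three members have *identical
passive responses* in every load case, and GASA and ASA produce identical
tetanic uniaxial responses — both facts are acceptance-tested. For GASAM and
ASA the total-derivative property ($\mathbf S$ = exact derivative of
$\Psi(\mathbf C, \omega_a(\lambda(\mathbf C)))$) is verified against central
finite differences of the energy over 100 random unimodular deformation
gradients at $10^{-6}$ relative tolerance.

## Near incompressibility

Each load case's nearly incompressible counterpart relaxes only the stretch
of its traction-free face(s) by a one- or two-variable Newton solve on the
nominal traction: UTCAF and UTCTF keep the two lateral stretches *tied*
(matching the symmetry the incompressible kinematics prescribe) and solve a
single zero-traction condition; the pure shears free one stretch; SAF is
fully prescribed (its conjugate shear traction is pressure-independent). The
test suite verifies monotone convergence of the nearly incompressible
responses to the incompressible ones as $\kappa$ (or the ASE bulk modulus
$K$) grows, reaching below 1% at the reference penalties.

## Activation time courses

`muscle_activation()` supports passive, tetanic (optionally scaled), a
clamped tanh ramp `f_tanh`, and superposed motor-unit twitches (`f_twitch`,
`twitch_train`): three motor-unit pools with fractions $\rho_i$, amplitudes
$F_i$, and time constants $T_i$, stimulated at interval $I_i$, normalized so
the tetanic plateau is 1. Tabulated schedules can be read with
`read_activation_schedule()` (step interpolation).

## Parameter identification

`fit_passive()` / `fit_active()` implement a staged pipeline on
`experimental_curve` objects (generated synthetically by `generate_curves()`
with multiplicative Gaussian noise, or read from TSV files):

1. bounded Levenberg–Marquardt (`minpack.lm::nls.lm`) on relative-scale
   parameters, with box constraints from the parameter domains;
2. deterministic multi-start: up to four seeded log-uniform jitters of the
   start (alternating around the original start and the incumbent) whenever
   the residual norm exceeds $10^{-8}$ times the data norm;
3. for the ASE passive stage, a cascade that prefits $(D_1, D_2, \lambda^*)$
   on the UTCAF curve alone (which is independent of the shear moduli)
   before the joint fit — this removes a local minimum in which $\lambda^*$
   runs to its bound;
4. an identifiability report: parameters whose residual-Jacobian column norm
   is below $10^{-6}$ times the largest column norm are returned in
   `$unidentifiable` with a warning. A relative threshold is required
   because analytically null columns can carry finite-difference noise of
   order $10^{-7}$.

Structural non-identifiabilities are documented rather than hidden: for ASE,
$\sigma_{max}$ multiplies both fiber terms, so stress data determine only
$\sigma_{max} D_1$ and $\sigma_{max} a$.

## Problem sizes and limitations

All responses are homogeneous-deformation closed forms or scalar solves, so
sweeps, fits, and the acceptance script run in seconds. Limitations: a single
fiber family with perfect alignment; no viscoelasticity or history
dependence; the ASA Newton solve assumes the energy balance is monotone in
$\omega_a$ on $[0, 1)$ (guarded by the bisection fallback); the elasticity
tensor is computed by finite differences of $\mathbf S$ rather than
analytically.
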