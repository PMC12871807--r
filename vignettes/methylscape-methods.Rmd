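---
title: "Methods: methyl-axis order parameters, ensemble reweighting and side-chain entropy"
author: "methylscape authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methyl-axis order parameters, ensemble reweighting and side-chain entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylscape)
```

# The problem

Methyl groups are the workhorse probes of side-chain dynamics in large
proteins and membrane-protein assemblies. The amplitude of motion of the
methyl three-fold symmetry axis — for methionine, the S&delta;–C&epsilon;
bond — is captured by the squared generalized order parameter
$O^2_{axis}$, which runs from 0 (isotropic disorder) to 1 (complete
rigidity). Two routes lead to $O^2_{axis}$:

* **Experiment.** In a triple-quantum (3Q) relaxation experiment the
  build-up of "forbidden" 3Q proton coherence relative to the decay of
  "allowed" single-quantum (SQ) coherence is governed by the intra-methyl
  cross-correlated relaxation rate $\eta \propto O^2_{axis}\,\tau_c$, with
  a contribution $\delta$ from dipolar couplings to external protons.
* **Simulation.** A conformational ensemble yields $O^2_{axis}$ directly
  from the distribution of the methyl-axis unit vector.

This package implements both routes, a maximum-entropy scheme that
reweights the ensemble so its back-calculated $O^2_{axis}$ values match
the NMR estimates, and the side-chain conformational entropy maps that the
reweighted ensemble supports. A seeded synthetic-data layer provides every
stage with analytically known ground truth.

# Relaxation models

With $s = \sqrt{\eta^2 + \delta^2}$ and delay $T$, the intensity ratio is

$$\frac{I_{3Q}}{I_{SQ}} =
  \frac{3}{4}\frac{\eta\tanh(sT)}{s - \delta\tanh(sT)} .$$

The classical estimator (`fit_ratio_nls()`) fits this ratio by non-linear
least squares. The ratio is scale-free and its envelope terms cancel, but
on noisy sparse data the quotient's error explodes as $I_{SQ}$ decays, and
the fit can fail outright — this failure mode is flagged, not hidden.

The simultaneous model (`fit_simultaneous_bayes()`) instead fits the two
curves jointly,

$$I_{3Q}(T) = 3\,\eta\tanh(sT)\cdot A_0\textstyle\sum_i f_i e^{-R_iT},
\qquad
I_{SQ}(T) = 4\,(s - \delta\tanh(sT))\cdot A_0\textstyle\sum_i f_i e^{-R_iT},$$

sharing $\eta$, $\delta$, the amplitude $A_0$ and an $N$-exponential
relaxation envelope (default $N = 2$; configurable 1 or 2), with
independent homoscedastic Gaussian noise per coherence type, each noise
scale estimated. Dividing the two model curves recovers the ratio model
exactly for every parameter draw — an identity the test suite asserts to
$10^{-12}$.

**Normalization.** Both curves are divided by one shared scale, the SQ
maximum. Normalizing each curve by its own maximum would destroy the
relative 3Q/SQ amplitude, which is precisely where $\eta$ lives once the
envelope is free; the shared-$A_0$ structure of the model only makes sense
if one scale is used. Per-curve normalization remains available as an
option for comparison.

**Priors.** All scale parameters carry weakly informative half-normal
priors whose scales derive from the data: the gross SQ decay rate (from a
log-linear fit, floored at $1/T_{max}$) sets the rate and
$\eta$/$\delta$ scales, and the residual spread of a crude fit sets the
noise scale. Envelope fractions are uniform on the simplex. Rates are
parameterized as ordered increments ($R_2 = R_1 + \Delta$, $\Delta > 0$),
which removes label switching by construction.

**Sampling.** The joint posterior is explored with an adaptive
random-walk Metropolis sampler (Haario-type covariance adaptation and
Robbins–Monro scale tuning confined to the warmup phase, so the retained
chain has a fixed kernel), two chains by default, with split-$\hat R$
convergence diagnostics and a flag when $\max \hat R \ge 1.1$. The
$\delta$–envelope ridge of this model is genuinely flat at seven delays,
so those coordinates mix slowly and the flag fires honestly; $\eta$, the
scientifically loaded parameter, mixes well ($\hat R \approx 1.01$) and
is what the round-trip tests certify: posterior means within 2% of truth
on noiseless data, and within 3 posterior standard deviations of truth in
$\ge 90\%$ of noisy replicates at 2% noise.

**Posterior predictive.** `posterior_predictive()` draws replicate data
sets from the fitted model. In intensity space the spread is
delay-independent; in ratio space it grows with delay because the SQ
denominator decays — the model-based account of why ratio fitting is
fragile.

# From $\eta$ to $O^2_{axis}$

The conversion
$$\eta = \frac{9}{10}\,[P_2(\cos\theta_{axis,HH})]^2\,O^2_{axis}\,
  \frac{(\mu_0/4\pi)^2\gamma_H^4\hbar^2\,\tau_c}{r_{HH}^6}$$
and its algebraic inverse are implemented in `eta_from_o2()` /
`o2_from_eta_value()`; their composition is the identity to machine
precision, which is tested on a grid. The squared dipolar prefactor
$(\mu_0/4\pi)^2$ is part of the standard proton–proton dipolar coupling
constant and is required for dimensional consistency; with it, typical
methionine rates ($\eta \approx 30$–$80\ \mathrm{s^{-1}}$ at
$\tau_c \approx 60\ \mathrm{ns}$) land in the expected
$O^2_{axis} \approx 0.1$–$0.35$ range of the J'/J motional classes.
Defaults: $r_{HH} = 1.813$ Å, $\theta_{axis,HH} = 90^\circ$ (geometric
factor $1/4$), $\gamma_H = 2.675 \times 10^8\ \mathrm{rad\,s^{-1}T^{-1}}$,
all overridable via `physical_constants()`.

The rotational correlation time comes from SAXS: `guinier_fit()` regresses
$\ln I$ on $q^2$ inside the self-consistent window $qR_g \le 1.3$, and
`tau_c_from_rg()` applies the isotropic Stokes–Einstein form
$\tau_c = 4\pi\eta_{visc}R^3/(3k_BT)$ with Monte-Carlo propagation of the
$R_g$ uncertainty (Gaussian, truncated positive; a warning fires when
truncation becomes material at $\sigma \ge \mu/3$). Two deliberate
choices:

* **Units of $R_g$.** The input is interpreted in Ångström. A
  receptor–detergent particle with $R_g$ of tens of *nanometres* is not
  physically plausible; the configuration validator warns when a config
  declares `rg_unit: nm` with a large value.
* **Form of the relation.** The standard denominator factor 3 is kept by
  default and exposed as a switch (`denominator_3 = FALSE` gives the
  variant without it). With the defaults, $R_g = 37.85$ Å, 1.099 cP and
  298.15 K give $\tau_c \approx 60.6$ ns. The radius entering the
  relation is $R_g$ itself; an option rescales to the solid-sphere
  hydrodynamic radius $R_h = R_g/0.7746$.

`o2_from_eta()` pairs random draws of $\eta$ and $\tau_c$, so both error
sources propagate into the $O^2_{axis}$ distribution. Samples outside
$[0,1]$ are counted and reported; they are clipped only for
motional-class assignment (`classify_motional_class()`, boundaries
$0.30/0.50/0.80$ for J'/J/$\alpha$/$\omega$, configurable), never in the
stored samples — downstream reweighting needs the real spread.

# Ensemble order parameters

The tensor expansion
$$O^2 = \tfrac{3}{2}\left[\langle x^2\rangle^2 + \langle y^2\rangle^2 +
  \langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
  2\langle yz\rangle^2\right] - \tfrac{1}{2}$$
is computed over (optionally weighted) frame averages of the methyl-axis
unit vector, in two parameterizations: the Cartesian
S&delta;&rarr;C&epsilon; bond vector in the superposed molecular frame
(`superpose_frames()` does the C&alpha; least-squares fit; Kabsch/SVD
with the proper-rotation branch enforced), and the local
spherical-coordinate form rebuilt from the polar bond angle and the
&chi;3 dihedral, which is internal to the residue and therefore blind to
residual global motion. On wobbling synthetic trajectories the angle
route gives systematically higher $O^2$ than the vector route, as
expected, and this ordering is asserted in the tests.

The internal time correlation function
$C_{int}(\tau) = \langle P_2(\hat\mu(t)\cdot\hat\mu(t+\tau))\rangle_t$
uses $P_2(x) = (3x^2-1)/2$ — the factor $1/2$ is required for
$C_{int}(0)=1$. Its long-time plateau (default read-out: last point;
`tail_mean` optional) must agree with the tensor value on converged
trajectories; the suite checks both against the closed form
$P_2(\cos\beta)^2 = 1/9$ for an equal-population three-site jump at the
tetrahedral angle. TCF origin spacing and maximum lag are not dictated by
the method; dense origins with `max_lag` well under half the trajectory
are the defaults and both are exposed.

# Maximum-entropy reweighting

Because $O^2$ is quadratic in the averaged tensor components, it is
non-linear in the frame weights, and the Lagrange-dual construction used
for linear observables does not apply. The package therefore minimizes

$$L(w) = \chi^2(w) + \theta\,S_{REL}(w), \qquad
\chi^2 = \sum_i \frac{(O^2_i(w) - O^2_{NMR,i})^2}{\sigma_i^2}, \qquad
S_{REL} = \sum_j w_j \ln\frac{w_j}{w^0_j},$$

directly over non-negative *unnormalized* weights (normalization is part
of the objective, so the analytic gradient carries the simplex-projection
term) with L-BFGS-B. The gradient is verified against central finite
differences to $10^{-5}$ on random instances. Zero weights use the
$0\ln 0 = 0$ limit; the boundary derivative is floored rather than left
infinite so the optimizer can hold frames at zero. Convergence defaults:
projected-gradient tolerance $10^{-8}$, 5000 iterations.

$\theta$ is chosen from an L-curve: `l_curve_scan()` solves a descending
log-spaced grid with warm starts, `select_theta_elbow()` picks the
maximum-curvature point of $\log\chi^2$ vs $\log\theta$ (a
$\chi^2$-plateau rule is the alternative; flat curves return the largest
$\theta$ with a "no elbow" flag). The effective fraction of retained
frames is reported as $N_{eff} = e^{-S_{REL}}$ by default — the
relative-entropy definition standard in maximum-entropy ensemble work —
with the Kish ratio $(\sum w)^2/(N\sum w^2)$ selectable; the choice is
recorded in the output.

## What reweighting can and cannot identify

One fact discovered while validating the recovery fixture deserves its
own section. Consider the canonical synthetic test: &chi;3 rotamer wells
at $(60^\circ, 180^\circ, -60^\circ)$, uniform prior populations, target
populations $(0.6, 0.2, 0.2)$, and per-residue targets equal to the
analytic $O^2$ of the target mixture.

* For equidistant wells at a common polar angle, $O^2$ is **exactly
  invariant under relabeling the wells**: cyclically permuting the
  populations corresponds to a rigid rotation about the symmetry axis,
  which leaves the Frobenius norm of the second-moment tensor unchanged.
  Which well receives the 0.6 is therefore a gauge freedom the data
  cannot fix, and in practice the optimizer resolves it toward whichever
  well the finite prior sample happened to over-represent.
* Worse, the Kullback–Leibler divergence is **nearly constant along the
  whole $O^2$ level curve** (for this geometry, 0.148 at the
  permuted-target points against roughly 0.150 at the two-well mixtures
  on the same curve), so even modulo relabeling, a single $O^2$
  constraint per residue pins the population vector only weakly.
* Breaking the geometric symmetry does not rescue label-level recovery:
  for wells at $(180^\circ, 65^\circ, -65^\circ)$ the minimum-divergence
  point on the level set provably sits away from the generating
  populations.

The functionals that *are* identifiable are exactly the ones the analysis
reports: the back-calculated $O^2$ values (recovered within $1\sigma$ on
the fixture) and the binned dihedral entropy — for a uniform prior the
entropy is $\ln M$ minus the divergence, hence nearly invariant along the
level curve, and the end-to-end test recovers the analytic target-mixture
entropy within 0.05. Per-well population tables from reweighted ensembles
should be read with this in mind; the package's tests assert the labeled
population comparison as well, and its failure on the symmetric fixture
documents the identifiability limit rather than an optimizer defect.

# Side-chain entropy

`weighted_dihedral_histogram()` accumulates frame weights in fixed
$10^\circ$ bins over $(-180^\circ, 180^\circ]$ (36 bins; edges anchored
at $-180^\circ$, with a configurable offset for rotamer-boundary
sensitivity checks), and the per-residue entropy is the Gibbs–Shannon
form averaged over the residue's &chi; angles,

$$S_{SC} = -\frac{1}{N_\chi}\sum_\chi\sum_k P_\chi(k)\ln P_\chi(k),$$

dimensionless ($k_B \equiv 1$) and bounded by $\ln 36 \approx 3.58$ per
dihedral. The marginal-per-dihedral reading (rather than the joint
&chi;-space histogram) is the default: it matches the single sum over $M$
bins with the $1/N_\chi$ prefactor, and keeps per-residue magnitudes
below $\ln 36$; a joint mode is provided and labeled experimental —
for independent dihedrals the two coincide, which is tested. Eligibility
follows the field's rules: residues with one to three &chi; angles enter;
glycine (no &chi;), alanine (symmetric methyl rotation, no conformational
entropy) and lysine/arginine (four or more &chi; angles, histograms do not
converge) are excluded with reasons reported.

`entropy_buildup()` recomputes the estimate on growing trajectory
prefixes — the convergence diagnostic of choice when only one continuous
segment is available; a residue whose effective frame count
($N_{eff}\times N$) falls below 100 is flagged low-confidence rather than
dropped. `delta_entropy()` differences two state profiles over their
common residues with the convention that positive $\Delta S$ means the
second state is more disordered.

# The synthetic-data layer

The generators are first-class, tested code, because every downstream
stage is validated against them:

* `simulate_decay_curves()` evaluates the 3Q/SQ models exactly and adds
  independent homoscedastic Gaussian noise per coherence — the same noise
  family the Bayesian likelihood assumes.
* `simulate_rotamer_trajectory()` runs a Metropolis Markov chain over the
  rotamer wells (propose a uniformly random other well, accept by
  population ratio) with wrapped Gaussian intra-well libration. Only the
  stationary law matters for $O^2$ and entropy, so the contract is on the
  stationary distribution, not on kinetics; a warning fires when wells
  sit closer than three libration widths and the histogram oracle would
  blur.
* `analytic_o2_jump()` evaluates the tensor expansion exactly over the
  stationary mixture using wrapped-normal circular moments
  $E[e^{in\phi}] = e^{in\phi_0 - n^2\sigma^2/2}$ — closed form, no
  quadrature, independent of any trajectory.
* `analytic_chi_bin_probs()` / `analytic_chi_entropy()` give the exact
  binned distribution and entropy of the stationary mixture.
* `simulate_weighted_ensemble()` bundles independent per-residue
  trajectories under prior populations with analytic targets under
  *different* populations — the recovery fixture for the reweighting
  stage.

What the generators deliberately do **not** emulate: force-field
energetics, correlated inter-residue motion, anisotropic tumbling,
spectrometer artifacts, or heteroscedastic noise. Green tests certify the
estimators under their stated statistical assumptions; they do not
certify those assumptions for any particular real data set.

# Problem sizes and numerical choices

The validation suite uses sizes chosen to make sampling error comfortably
smaller than the assertion tolerances while keeping the whole suite quick
to run: $10^5$ frames for trajectory-convergence checks (sampling error
on $O^2 \approx 0.003$, asserted at 0.02), $2\times 10^4$ frames
$\times$ 10 residues for the reweighting recovery study, 50 replicates
for the $\eta$ round-trip coverage check, and a 13-point log-spaced
$\theta$ grid spanning $10^{-2}$–$10^4$. The bundled demo configuration
(`demo_config()`, also shipped as `inst/extdata/demo_config.yaml`) runs
the full pipeline in seconds at 2000 frames and is byte-reproducible for
a fixed seed.

Other numerical choices: intensities are fitted on the shared-max
normalized scale with a small floor ($10^{-6}$) under the estimated noise
scales so that noiseless data remain finite-likelihood; the Guinier
window iterates to self-consistency from the full profile; L-curve solves
warm-start from the previous $\theta$; tiny negative weight components
returned by the bounded optimizer (round-off at the active bound) are
clamped to zero; and all tabular outputs are written with enough digits
to round-trip exactly.

# Known limitations

* The $\delta$/envelope posterior ridge means $\delta$ and the $R_i$ are
  weakly determined from seven delays; only $\eta$ (and functions of it)
  should be over-interpreted.
* Isotropic tumbling is assumed throughout; anisotropic diffusion tensors
  and SAXS structure-factor corrections are out of scope.
* Reweighting identifies ensemble functionals, not labeled rotamer
  populations (see above).
* Entropies are marginal per dihedral; correlations between &chi; angles
  within a residue (and between residues) are not captured by the default
  estimator.
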