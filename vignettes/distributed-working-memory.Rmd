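---
title: "Modelling distributed working memory on a mesoscale connectome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling distributed working memory on a mesoscale connectome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distwm)
```

## The model

`distwm` implements a multiregional mean-field model of working memory in
the mouse brain. Each cortical area is a reduced local circuit with two
stimulus-selective excitatory populations (A, B) and one shared inhibitory
population (C). The state of each population is a synaptic gating variable:
NMDA gating for the excitatory pools,

$$\frac{dS_{A}}{dt} = -\frac{S_A}{\tau_N} + \gamma\,(1 - S_A)\,r_A,$$

which saturates at 1, and GABA gating for the inhibitory pool,
$dS_C/dt = -S_C/\tau_G + \gamma_I r_C$. Firing rates relax with a fast time
constant $\tau_r$ toward population transfer functions of the total input
current: a smooth, strictly increasing curve
$\phi_E(I) = (aI - b) / (1 - e^{-d(aI-b)})$ for excitatory cells (the
removable singularity at $aI = b$ evaluates to $1/d$) and a rectified
linear curve $\phi_I(I) = [\,(c_1 I - c_0)/g_I + r_{0I}\,]_+$ for
interneurons. Each population additionally receives an
Ornstein-Uhlenbeck noise current with stationary standard deviation
$\sigma\sqrt{\tau_{\mathrm{noise}}/2}$.

Two anatomical gradients make areas differ:

* **PV interneuron gradient.** Local inhibitory weights grow linearly with
  the area's normalized PV cell fraction,
  $g_{EI,i} = g_{EI,0}(1 + g_{EI,\mathrm{scaling}}\,\mathrm{PV}_i)$ and
  likewise $g_{II,i}$. Sensory areas (high PV) are strongly inhibited;
  frontal areas (low PV) are not.
* **Counterstream inhibitory bias (CIB).** Long-range connections are split
  by a sigmoid coefficient of the hierarchy difference between target $i$
  and source $j$, $m_{ij} = 1/(1 + e^{-\beta(h_i - h_j)})$: feedforward
  projections ($m > 0.5$) excite mostly excitatory cells
  ($W_E = m \circ W$), feedback projections mostly inhibitory cells
  ($W_I = (1 - m) \circ W$). The split conserves the total weight exactly.

Connectivity itself is staged: raw anterograde projection densities are
multiplied by source volume and divided by target neuron density, compressed
by a power law $W^{k_\mathrm{scale}}$ (five orders of magnitude of anatomy
would otherwise dwarf the rate model), and max-normalized so the strongest
connection is 1. All matrices are target-by-source and carry a zero
diagonal: self-projections are not modelled.

Integration is forward Euler-Maruyama at `dt = 0.5` ms with every state
variable starting at zero; the 2 s pre-stimulus interval doubles as burn-in
to the baseline fixed point. A trial applies `I_stim = 0.5` nA to the
stimulated population during `[2, 2.5)` s and runs to 10 s; the delay rate
of an area is its mean rate over the window from 2 s to 0.5 s before trial
end, and an area counts as *persistent* when that mean strictly exceeds
5 Hz — the same threshold the attractor census uses.

## Parameters and regimes

`model_params()` carries every scalar in internal units (seconds, nA, Hz;
the transfer-function constant `d = 308` ms enters as 0.308 s so that
$a I$ in Hz is dimensionally consistent). Three presets matter:

* `reference` — `g_E_self = 0.4` nA, `g_EI_0 = 0.192` nA: no area is
  bistable in isolation, so persistence is a property of long-range loops.
* `alternative` — `g_E_self = 0.6` nA balanced by `g_EI_0 = 0.5` nA:
  low-PV areas are independently bistable.
* `thalamocortical` — cortical coupling weakened tenfold
  (`mu_EE = 0.01` nA) and AMPA-mediated thalamocortical conductances
  enabled; the thalamus has no recurrent or inhibitory connections, and
  reticular-nucleus inhibition is folded into the constant background
  `I_th_0`.

A note on signs: the model equations are sometimes restated with a `+` in
front of the inhibitory gating terms of the cortical currents. Inhibition
must be subtractive for the circuit to function — the subtractive
convention is also what reproduces the reference baseline eigenvalues
below — so the minus sign is used everywhere; the package treats the
plus-sign variant as an erratum.

`I_th_0` has no tabulated value; it defaults to 0.3 nA, which holds the isolated
thalamic baseline near 0.3 Hz (below the 5 Hz persistence threshold) while
keeping the thalamic transfer function responsive to cortical drive. The
value is recorded in every run manifest.

## Stability analysis

With $\tau_r \ll \tau_N$ the rates can be slaved to their transfer
functions, leaving a three-dimensional gating system per isolated area.
`fixed_point()` solves it by damped Newton iteration with the analytic
Jacobian (`local_jacobian()`), from a low-activity guess for the baseline
state or a high-activity guess for the memory state; roots are accepted at
residual $10^{-10}$ and cross-checked against plain forward integration
(`relax_local()`). `jacobian_eigs()` reports the eigenvalues sorted by
descending real part. For the reference parameters at PV = 0 the baseline
eigenvalues are $(-10.4, -12.5, -229.8)\,\mathrm{s}^{-1}$ with inhibition
intact and $(-7.4, -7.9, -232.3)\,\mathrm{s}^{-1}$ with $g_{EI} = 0$; in the
latter case the inhibitory eigenvalue obeys the closed form
$-1/\tau_G - \gamma_I (c_1/g_I) g_{II,0}$ because the excitatory block
decouples. The PV value entering these numbers is the minimum of the
normalized gradient (PV = 0); that choice is verified by the closed-form
identity rather than assumed. Fixed points landing within $10^{-6}$ nA of
the $\phi_I$ rectification kink are rejected as non-differentiable rather
than silently one-sided.

`scenario_battery()` runs the five standard settings (isolated; isolated
without local inhibition; intact; without long-range E-to-I; without local
I-to-E). Isolated scenarios are solved analytically; coupled scenarios by
noise-free simulation, with "left baseline" meaning a delay rate above
5 Hz. On dense synthetic connectomes the coupled network loses its baseline
when either inhibition route is removed — the global
inhibition-stabilized-network signature — while isolated reference areas
remain stable even without local inhibition. Note that this global
instability needs enough convergent excitation: on very small synthetic
networks (a few tens of areas are enough at the default density) the effect
appears only weakly, which is why the battery fixtures here use 43 areas.

`bifurcation_scan()` locates the saddle-node at which the low-activity
state vanishes by a descending scan plus bisection to $10^{-4}$ nA,
declaring the state "present" only when the Newton solve converges to a
low-rate root *and* relaxation from the origin stays below threshold.

## Synthetic data: what it emulates and what it does not

No anatomical dataset ships with the package. `synthetic_atlas()` draws
hierarchy uniformly on $[0,1]$, builds the PV fraction as an affine
function of hierarchy plus noise orthogonalized so the *sample* correlation
equals the target exactly (default $r = -0.35$), and draws volumes and
neuron densities log-normally. `synthetic_weights()` draws log-uniform
magnitudes spanning five decades at 97% connection density. These match the
summary statistics the model relies on — the PV-hierarchy anticorrelation,
the dynamic range, the near-complete connectivity — but *not* the module
structure, degree sequence or specific strong reciprocal loops of a real
connectome. Consequently data-dependent headline quantities (exact
attractor counts, which named areas form the core, the precise
rate-hierarchy correlation) are not reproduced by synthetic runs, and the
package's tests assert motifs and trends rather than such values:
transient-sensory/persistent-frontal separation with an abrupt rate
transition, the direction of census trends in coupling parameters, loss of
thalamus-dependent persistence under thalamic inhibition.

Two hand-built fixtures complement the random generators.
`census_fixture()` couples four independently bistable low-PV areas so the
attractor landscape interpolates between a product structure (weak
coupling) and a merged one (strong coupling); `tc_loop_fixture()` wires
five cortical and three thalamic areas so that delay activity survives only
through the thalamocortical loop. Both are synthetic constructions designed
to put the model mechanisms on display at desk scale, not downsampled
real data.

## Graph measures

Structural predictors operate on any staged matrix: `input_strength()`
(row sums), `eigenvector_centrality()` (Perron vector for nonnegative
matrices, normalized to unit sum; for the signed cell type-specific
variants, where Perron theory does not apply, the package takes the
eigenvalue of largest real part, uses the real part of its vector, fixes
the sign so the largest-magnitude entry is positive and normalizes to unit
Euclidean norm — a documented convention rather than a theorem), and
`loop_strength()`. A loop is a directed simple cycle; rotations are one
cycle, and for length $\ge 3$ the two orientations are distinct. The
implementation uses closed-form corrections of matrix-power diagonals
(lengths 2-4, the lengths the analyses use) and is tested against recursive
enumeration.

The cell type-specific variant reweights every projection by
$m_{ij} - \mathrm{PV}_i (1 - m_{ij})$ — the net excitatory effect after
accounting for how much of the feedback lands on interneurons and how
inhibitory the target is — then max-normalizes. Two controls isolate the
ingredients: `sign_only` keeps only $\mathrm{sgn}(2m - 1)$, `noPV` keeps
$2m - 1$ (equivalently the cell type coefficient at PV $\equiv 1$; with
PV $\equiv 0$ the coefficient reduces to $m$ instead). Classification of
persistent/core areas from a measure uses unregularized univariate logistic
regression with in-sample accuracy; perfect separation is caught and
flagged rather than left to glm warnings.

## Perturbation protocol and area roles

Simulated optogenetics injects `I_inh = 5` nA into an area's inhibitory
population, either during the stimulus window or from 2 s after stimulus
offset to trial end. The effect of inhibiting a set of areas is the ratio
of the mean delay rate of *eligible* areas (persistent in control, not
themselves inhibited) to the control mean. Areas are classified with a 10%
decrement cutoff: strong stimulus-phase effect makes an area **input**
(assigned first); among the rest, strong delay-phase effect with persistent
activity makes **core**, weak effect with persistent activity **readout**,
and the remainder **nonessential**. An area with a strong delay effect but
no persistent activity of its own has no label in the classification scheme; it
falls into nonessential here. Classification runs noise-free by default so
labels cannot be flipped by noise. Per-attractor core analysis uses the
stricter ratio cutoff 0.95 on the attractor's own active areas.

## Attractor census

`enumerate_attractors()` stimulates every subset of a candidate list
(noise-free), thresholds the delay rates of all areas at 5 Hz into a binary
pattern over population A (all stimuli target A, so A-selective patterns
are the natural code), deduplicates exactly, and keeps the all-low pattern
aside as the baseline. Candidates default to the top areas by the rank sum
of hierarchy and (negative) PV. Census runs use the full 10 s trial: on
shorter trials, marginal slow decays — trajectories drifting back to
baseline past a saddle — can still be above threshold inside the averaging
window and masquerade as attractors. Sweeps co-scale `mu_IE` with `mu_EE`
at the standard ratio 1.67.

## Numerical choices, at a glance

* Forward Euler-Maruyama, `dt = 0.5` ms $< \min\tau/4$; NMDA gating
  provably stays in $[0,1]$ at this step for rates below ~1.5 kHz, and the
  simulator tracks the observed gating range so tests can assert it.
* Noise discretization `x += -x/τ dt + σ√dt N(0,1)`; the Euler stationary
  s.d. carries an $O(dt/\tau)$ bias, so calibration checks run at
  `dt = 0.1` ms.
* Newton iteration is damped (step halving on residual growth) with NMDA
  gating clamped to $[0,1]$ during iteration; non-convergence is an error
  carrying the last iterate, never a silent result.
* Degenerate inputs fail loudly and by name: zero volumes/densities,
  constant vectors under min-max normalization, all-zero matrices,
  hierarchy gaps with no informative neighbours, ambiguous leading
  eigenvalues.
* Hierarchy imputation happens on the normalized scale (the scale on which
  the default affine coefficients were fit) and imputed values are not
  clamped; range
  invariants are asserted over measured areas.
* Test problem sizes (6-43 areas, 6-10 s trials, loop lengths 2-4) were
  chosen as the smallest instances on which each mechanism is unambiguous.

## Known limitations

* The synthetic connectome has no community structure; analyses whose
  outcome depends on specific strong loops (e.g. which area is core) are
  only meaningful on the constructed fixtures or on user-supplied data.
* `loop_strength()` is limited to lengths 2-4.
* Interhemispheric projections, AMPA components of cortico-cortical
  connections, layer-resolved PV densities and explicit reticular-nucleus
  dynamics are out of scope, matching the model's own simplifications.
* Multi-trial decoding statistics are not implemented; the model's analyses
  are single-trial, deterministic-plus-small-noise.
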