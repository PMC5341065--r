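---
title: "Methods: excited-state ensemble inference from SAXS, MSM kinetics and simulated FRET"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: excited-state ensemble inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Transient, marginally populated protein conformational ensembles —
sub-millisecond folding intermediates, functional excited states — are
invisible to high-resolution structural methods. Time-resolved SAXS can
observe them, but a one-dimensional scattering curve is drastically
under-determined: many distinct mixtures of conformations scatter
identically. The standard escape is Bayesian in spirit: take an
*informative prior* over conformations (here: the microstate populations
of a Markov state model built from molecular dynamics), and reweight it
against the experiment only as far as the data justify.

`saxsens` implements that workflow end to end, together with a synthetic
world with known ground truth in which every stage is testable. The
motivating application is the flavodoxin-fold chemotaxis protein CheY,
whose refolding passes through an off-pathway collapsed intermediate and
whose kinetics are gated by slow cis/trans isomerization of a C-terminal
prolyl bond; nothing in the code is specific to that system.

# Model and procedure

## SAXS forward model

For a rigid structure the orientationally averaged intensity is the Debye
sum

$$I(q) \;=\; \sum_{i,j} f_i(q)\, f_j(q)\, \frac{\sin(q d_{ij})}{q d_{ij}},$$

with $f_i$ the Cromer–Mann 4-Gaussian atomic form factors (C, N, O, P, S,
H), so that $I(0) = (\sum_i f_i(0))^2$ and $f(0)$ equals the electron
count. The `sinc` kernel switches to its series expansion for
$qd < 10^{-4}$. Hydrogens may be folded into heavy atoms through an
optional per-atom implicit-hydrogen count (`nh` column); by default none
are added. This forward model deliberately omits the hydration shell and
excluded-volume terms of crystallography-grade predictors: absolute
agreement with a beamline profile is *not* an advertised capability, while
relative and ensemble behaviour (the quantity the refinement consumes) is
exact for the model stated.

Guinier analysis fits $\ln I$ against $q^2$ and reports
$R_g = \sqrt{-3\,\mathrm{slope}}$, iterating the fit window to
self-consistency under $q_{\max} R_g \le 1.3$ (at most 20 iterations,
at least 5 points, errors otherwise).

Experimental comparison uses the reduced discrepancy

$$\chi^2 \;=\; \frac{1}{N_q} \sum_i
  \frac{\big(c\,I_{\mathrm{sim}}(q_i) + f - I_{\mathrm{exp}}(q_i)\big)^2}
       {\sigma^2(q_i)},$$

with scale $c$ and background offset $f$ fitted in closed form by weighted
least squares. If the fitted scale is non-positive or the simulated
profile is constant, $c$ is fixed at 1 and only $f$ is fitted (with a
warning).

## Maximum-entropy reweighting

Given per-state profiles $I_k(q)$, prior weights $w^0$, and an
experimental profile, the refinement minimizes over the weight simplex

$$G(w) \;=\; \chi^2\!\Big(\textstyle\sum_k w_k I_k,\; I_{\mathrm{exp}}\Big)
  \;+\; \theta \sum_k w_k \ln\frac{w_k}{w^0_k},$$

the relative-entropy (maximum-entropy) penalty keeping the solution near
the prior. $0\ln 0 := 0$; a state with zero prior weight but positive
refined weight is an error (infinite penalty). The prefactor on $\chi^2$
is 1, so $\theta$ values are internal to this package and not numerically
transferable from other implementations of the same idea.

**Annealing schedule.** One move multiplies a uniformly chosen state's
weight by $e^\delta$, $\delta \sim N(0, 0.3)$, and renormalizes —
weights never leave the simplex. The initial temperature is calibrated so
roughly half of 64 trial moves from the start would be accepted;
temperature then cools geometrically by 0.95 per sweep (one sweep = $N$
moves) until the best $G$ has improved by less than `tol` over 50
consecutive sweeps (hard cap 600 sweeps, by which point the schedule has
cooled by ~1e-13 and the chain is frozen).

**Quench.** After the cooling stage a zero-temperature polish runs:
systematic *pairwise weight transfers* $w_k \to w_k - t$, $w_l \to w_l +
t$ with $t = s\,w_k$ and the step fraction $s$ shrinking geometrically
from 0.3 to $10^{-5}$, accepting only improvements. Transfers move along
simplex edges and follow the narrow, ill-conditioned valleys of the
$\chi^2$ surface far better than single-state multiplicative moves; with
them, noiseless ground-truth recovery reaches $\chi^2 \sim 10^{-8}$ and
weight correlation ≈ 1.0 regardless of seed, where the multiplicative
kernel alone stalls around $\chi^2 \sim 10^{-3}$ with seed-dependent
weights. The quench is the $T = 0$ limit of the same Metropolis family —
no gradients, no convex reformulation — and is switchable
(`refinement_config(quench = FALSE)`). Both stages evaluate candidate
objectives in $O(1)$ via sufficient statistics (the Gram matrix of
$\sigma$-weighted state profiles), which is exact, not approximate.

All stochastic operations take an explicit seed and restore the caller's
RNG state; named sub-seeds (`derive_seed(master, "refine-unfolded")`)
give pipeline stages independent reproducible streams.

**Choosing θ.** `theta_scan()` tabulates converged $\chi^2$ against a θ
grid and suggests the discrete-curvature elbow, but selection is left to
the user: the honest criterion ("the smallest θ that avoids overfitting")
is a judgement about predictor error, not a statistic of one scan.
`stability_check()` quantifies run-to-run annealing scatter as the per-$q$
standard deviation of converged fitted profiles in units of the
experimental $\sigma$. `ablate_and_refine()` removes a state subset,
renormalizes the prior, re-refines, and reports $\Delta\chi^2$ against the
unablated run — the operation used to ask whether a structural feature is
*required* by the data or merely *permitted*.

## Markov state model kinetics

Transition matrices are estimated by sliding-window counts at a fixed lag,
restricted to the largest strongly connected component, and row-normalized
(optional symmetrization and pseudocount; both off by default — a plain
maximum-likelihood estimator, not a reversible Bayesian one). A
single-state trajectory yields the trivial 1×1 model; two or more observed
states with no communicating pair is an error. The lag time is a required
input everywhere: no default is silently assumed. Featurization helpers
implement tICA (symmetrized time-lagged covariances, ridge-regularized
whitening, eigenvalues clamped below 1 with a warning) and greedy
k-centers (Gonzalez; covering radius within 2× optimal).

Slow two-regime kinetics (prolyl cis/trans) are combined into one
$(n{+}m)\times(n{+}m)$ block matrix. Each trans state is paired with its
argmin-RMSD cis state (Kabsch superposition; ties broken by lowest index);
the pair is kept only if its cross-regime RMSD is below the mean RMSD of
*each* partner to its direct within-regime neighbours (states reachable
with positive probability at the lag) — a kinetic-plausibility filter.
Kept pairs receive the symmetric jump probability $p = 1 - e^{-kt}$ in
both directions, the diagonal absorbing $-p$; this is the minimal
perturbation that restores row-stochasticity, chosen because the source
procedure does not specify one. A diagonal driven negative (huge $kt$ or
many pairs on one state) is an error rather than a silent renormalization.

## Accessible-volume FRET

The AV1 variant: a cubic grid of side $2L$ around the attachment atom
(default Cβ); a cell is a legal *dye position* if no heavy atom is within
(dye radius + vdW radius), and *linker-reachable* if its geodesic distance
from the attachment — Dijkstra over path-allowed cells on a 7×7×7
gcd-reduced stencil, which keeps free-space geodesics within ~1 % of
Euclidean — is at most the linker length $L$. Atoms close enough to the
attachment point to bury it (the attachment atom itself and its covalent
neighbours) are transparent to the *path* but never to the *dye*: without
this exemption every attachment on a connected chain is spuriously
"buried"; with it, an isolated attachment still yields the exact analytic
spherical shell.

Efficiencies are averaged in the fast-dye / static-conformation regime:
$E = \langle 1/(1 + (r/R_0)^6) \rangle$ over position pairs
(efficiency-averaged, not distance-averaged), the dominant convention for
AV predictions. $\kappa^2 = 2/3$ is assumed folded into the user-supplied
$R_0$ and never computed. Burst histograms draw a conformation per event
from the ensemble weights and observe $\mathrm{Binomial}(\text{photons},
E_k)/\text{photons}$. Defaults: grid spacing 1.0 Å, dye radius 3.5 Å,
linker width 4.5 Å, linker 15 Å (a (CH₂)₅ tether), 50 photons per data
point — the last is a named-but-unvalued parameter in the source
procedure; 50 is typical of confocal burst data.

## Contact analysis

A residue pair is in contact if any heavy-atom distance is below 4.5 Å at
sequence separation ≥ 3 — the common structural-biology convention,
chosen because the source never defines its own. Ensemble densities are
population-weighted means of per-state binary maps; difference maps are
their signed difference; a state "contains" a feature if at least a
threshold fraction of the feature's residue pairs are formed (the
threshold is a mandatory explicit field — there is no community default
to borrow). Helical content is approximated by the fraction of $(i, i+4)$
contacts, a proxy for DSSP-style assignment, and documented as such.

# The synthetic world

`standard_fixture_spec()` is the package's stated test world: 30-residue
Cα-like bead chains (carbon form factors), 20 states in 3 archetypes — 8
compact (confined random walks on a ladder of confinement radius and
chain stiffness), 8 extended (arcs on a curvature ladder), 4
feature-bearing (compact chains deformed by position-based-dynamics
projections until a designated non-native contact pair set is formed) —
with Dirichlet(2) ground-truth weights and 3 % relative Gaussian noise on
the observed profile. A noiseless experiment carries a 1 % σ floor so χ²
stays defined.

Two design points deserve honesty:

- **Spectral distinctness is engineered.** Ground-truth weight recovery is
  only meaningful if the 20 state profiles are linearly distinguishable at
  the stated noise. Smooth SAXS curves of same-sized blobs are not: the
  profile is a linear functional of the pair-distance distribution, and
  states sharing a size band collapse onto a low-dimensional manifold
  (rank ≈ 5 on a q ≤ 0.3 Å⁻¹ grid). The fixture therefore assigns every
  state its own size/shape slot and evaluates profiles on q ∈ [0.01, 2.0]
  Å⁻¹ — extending into wide-angle territory where bead-chain interference
  structure separates the states. This was designed once, before the
  acceptance values were frozen, to realize the stated precondition
  ("spectrally distinct states"); real SAXS data on real proteins is far
  more degenerate, which is exactly the regime argument for the
  informative prior.
- **What a green test establishes.** Recovery on this fixture certifies
  the optimizer and the plumbing, not the resolving power of SAXS on
  proteins. The generator emulates sizes, shapes, contact features and
  two-timescale kinetics; it does not emulate hydration scattering,
  inter-particle structure factors, beamline systematics, or any real
  protein fold.

The two-regime generator builds Metropolis chains with designed stationary
distributions (exact by construction) and representative structures in
which trans state $j$ is a 0.1 Å jitter of cis state $((j-1) \bmod n)+1$,
so the RMSD pairing rule has a planned answer.

# Numerical choices and degenerate inputs

- Kabsch RMSD uses SVD with a determinant sign correction (no
  reflections); coincident point sets give 0.
- Weighted least squares for $(c, f)$ falls back to $c = 1$ on degenerate
  (constant) simulated profiles, with a warning.
- `rate_to_probability` uses `expm1` so $kt \sim 10^{-8}$ survives
  cancellation; $kt \ge 1$ in the coupling triggers a warning that the
  one-jump interpretation is breaking down.
- Propagation durations are snapped to the nearest lag multiple with a
  warning; matrix powers go by repeated squaring.
- tICA adds $\varepsilon I$ ($10^{-6}$) to $C(0)$ before whitening, so
  duplicated features are tolerated; eigenvalues ≥ 1 are clamped with a
  warning; negative eigenvalues get no implied timescale.
- PDB parsing keeps the first MODEL (unless all are requested), altloc
  A/blank, drops waters and hydrogens, and errors on malformed records
  naming the line. Mutation is truncation-based: side-chain atoms not
  shared with the target residue are removed, backbone and Cβ always
  kept, nothing is built. Downstream observables (SAXS, 4.5 Å contacts,
  Rg) are insensitive to a single side chain, which is why rotamer
  building is out of scope.

# Known limitations

- The forward model's absolute profiles are not beamline-comparable (no
  hydration layer, no excluded volume); only shape/ensemble comparisons
  are meaningful. Consequently the native-structure Guinier check carries
  a generous ±1.5 Å tolerance.
- θ values are not transferable between packages (prefactor convention).
- AV1 uses a single dye radius; no dye rotamers, photophysics, blinking
  or γ-correction.
- The annealer is a global-search heuristic; on strongly multimodal
  objectives different seeds can converge to different basins —
  `stability_check()` exists to measure exactly that.
- Secondary-structure percentages are contact-pattern proxies, not DSSP.
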