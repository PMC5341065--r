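# saxsens

Inference of transiently populated ("excited state") protein conformational
ensembles by combining a molecular-simulation prior with small-angle X-ray
scattering (SAXS) data, plus simulated single-molecule FRET for
cross-validation.

Low-resolution experiments such as SAXS cannot pin down an atomistic
ensemble on their own: many different mixtures of conformations produce the
same scattering curve. `saxsens` implements the standard remedy — start
from an informative prior (e.g. the state populations of a Markov state
model built from molecular dynamics), and reweight it against the
experiment no more than the data justify. The package covers the whole
workflow at desk scale:

- **SAXS forward model** — Debye equation over tabulated Cromer–Mann
  atomic form factors, `I(q) = Σᵢⱼ fᵢ(q) fⱼ(q) sin(q dᵢⱼ)/(q dᵢⱼ)`, with
  Guinier analysis (`ln I ≈ ln I₀ − q²Rg²/3`), scale/offset fitting and
  reduced χ² against experiment.
- **Maximum-entropy ensemble reweighting** — minimize
  `G(w) = χ²(w) + θ Σₖ wₖ ln(wₖ/w⁰ₖ)` over the weight simplex by simulated
  annealing, with a θ scan for regularization selection, run-to-run
  stability checks, and state-ablation re-refinement.
- **Markov state model kinetics** — tICA, k-centers clustering, transition
  counting, population propagation `p(t) = p₀ Tᵗ/τ`, and coupling of two
  slowly interconverting prolyl cis/trans regimes into one block-structured
  model via `p = 1 − e^{−kt}` with an RMSD-based pairing rule.
- **Ensemble contact analysis** — population-weighted contact densities,
  difference maps, and feature classification ("does this state contain a
  given non-native contact set?").
- **Accessible-volume FRET** — grid/geodesic dye clouds around an
  attachment atom, Förster efficiencies `E = 1/(1+(r/R₀)⁶)`, and
  shot-noise-limited efficiency histograms.
- **Synthetic data with known ground truth** — toy bead-chain ensembles
  (compact / extended / feature-bearing archetypes), noisy synthetic
  experiments and two-regime kinetic models, so every stage is testable
  without any external download.

## Worked example

Generate the standard 20-state synthetic fixture, a noisy "experiment"
from known ground-truth weights, and refine a uniform prior against it:

```r
library(saxsens)

ens  <- generate_toy_ensemble(standard_fixture_spec(seed = 1))
expt <- generate_synthetic_experiment(ens$profiles, ens$weights,
                                      noise = 0.03, seed = 11)
fit <- anneal_refine(ensemble_weights(rep(1/20, 20)), ens$profiles,
                     expt$observed, refinement_config(theta = 0.1, seed = 42))
print(fit)
#> refinement_result: 20 states, G = 0.8688 (chi2 = 0.838, penalty = 0.3073), 600 sweeps

cor(fit$weights$w, ens$weights)
#> [1] 0.879

feat <- feature_definition("non-native pair set",
                           cbind(c(8, 9, 10), c(25, 24, 23)), threshold = 0.5)
classify_states(ens$contact_maps, feat, fit$weights)$fraction
#> [1] 0.167   # ground truth places 0.133 on feature-bearing states

guinier_rg(ensemble_profile(ens$profiles, fit$weights))$rg
#> [1] 8.6     # Angstrom
```

Reading the output: χ² ≈ 0.84 means the refined ensemble curve sits within
about one experimental error bar of the data (χ² ≈ 1 is a perfect
statistically consistent fit at 3 % noise); the entropy penalty 0.31 says
the refined weights moved only moderately away from the uniform prior at
θ = 0.1. The refined ensemble puts 16.7 % of its population on states
carrying the designated non-native contact feature, close to the 13.3 %
the generator planted — SAXS constrains this only loosely, which is
precisely why the regularized-prior machinery exists.

The three-step pipeline (refine against unfolded-state data → propagate
with the kinetic model → refine against refolded-state data) is available
as `run_inference(pipeline_config(...))`, and on the command line:

```sh
inst/cli/saxsens make-fixtures --seed 1 --out fixtures/
inst/cli/saxsens refine --profiles fixtures/ --exp fixtures/experiment.dat \
                        --theta 0.5 --seed 7 --out refined.json
inst/cli/saxsens fret --pdb structure.pdb --donor 7 --acceptor 63 \
                      --r0 42 --linker 15 --out hist.tsv
```

## Vignette

`vignettes/methods.Rmd` documents the model, the numerical choices
(annealing schedule, quench, contact definition, form factors, AV
variant), what the synthetic generator does and does not emulate, and the
package's known limitations.
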