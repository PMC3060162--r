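# patchcomm

Simulation and analysis of a grow-and-disperse patch ecosystem: many
species compete for a single resource through repeated cycles of local
exponential growth on discrete patches followed by global dispersal, with
environmental noise entering through the dispersal dilution factor. The
package is for theoretical ecologists studying how shared environmental
fluctuations interact with competition in species-rich communities — the
tension between the Moran effect (noise synchronizes species) and
compensatory dynamics (competition drives them out of step), which in
many-species systems produces alternating correlation patterns and
dynamic clusters of abundant species along the phenotype axis.

## Model

Each species is a point `(mu_k, Y_k)` on a rate/yield trade-off: `mu_k`
is its exponential growth rate while patch resource lasts, `Y_k` its
offspring per unit resource. A cycle seeds each patch with Poisson counts
`m_k ~ Pois(alpha * n_k)`, grows every patch to resource exhaustion at
time `T(m)` solving

    sum_k m_k (exp(mu_k T) - 1) / Y_k = R,

and pools the final abundances `f_k(m) = m_k exp(mu_k T)` into the exact
expectation update

    n_k(t+1) = sum_m P(m | alpha n(t)) f_k(m),

truncated at a certified total seed count (neglected Poisson mass below a
set tolerance). On top of this the package provides:

* **Community construction** — solve the efficiencies `Y` that make a
  prescribed equal-abundance state a fixpoint (`solve_efficiencies()`),
  and the complete-dominance (large-resource) hierarchy
  (`dominance_fixpoint()`).
* **Linear theory** — exact Jacobian `J` and noise vector `r` at the
  fixpoint, eigenmodes with relaxation times `tau = -1/log(lambda)`,
  noise couplings `gamma`, stationary amplitudes
  `p^2 sigma_alpha^2 / (1 - lambda^2)`, interaction-weighted eigenvectors
  and their roughness ordering, and the fixpoint sensitivity
  `(I - J)^{-1} r` (`linearize()` and friends).
* **Stochastic simulation** — log-normal white noise in `alpha` with the
  log-mean anchored at `log(alpha0)`, clamped-species counterfactuals
  sharing bitwise-identical noise, and pulse/press perturbation
  experiments (`simulate_trace()`, `perturbation_experiment()`).
* **Statistics** — pairwise correlation versus phenotypic distance in the
  full / single-free / pairwise-free regimes, abundance profiles over
  `z = log(mu)`, and empirical eigenmode amplitudes
  (`correlation_vs_distance()`, `profile_snapshots()`,
  `empirical_mode_amplitudes()`).

## Worked example

```r
library(patchcomm)

# the 6-species reference community: mu geometric on [0.1, 0.3],
# equal abundances 100/6 per patch, alpha = 0.001
fp <- solve_efficiencies(100 / 6, mu_grid(6), 1e-3)
fp
#> fixpoint: 6 species, alpha0 = 0.001, residual 2.49e-14 (converged, 2 iterations)

nm <- noise_model(cv = 0.15, alpha0 = 1e-3)
lm <- linearize(fp, sigma_alpha = nm$sigma_alpha)
mode_table(lm)[, c("lambda", "tau", "gamma", "amp2", "roughness_rank")]
#>      lambda       tau       gamma     amp2  roughness_rank
#> 1 0.9996622  2960.07    2.592884  7674.69               6
#> 2 0.9991821  1221.74   38.585138 47141.40               5
#> 3 0.9981897   551.41  119.527096 65909.66               4
#> 4 0.9949175   195.75  335.467018 65668.22               3
#> 5 0.9891989    91.58  431.659408 39531.79               2
#> 6 0.9693468    32.12  147.645134  4742.02               1
```

The slowest deformation (`tau` = 2,960 cycles) is the most jagged profile
(roughness rank 6), yet couples weakest to the noise (`gamma`); the
stationary amplitudes `amp2 = gamma * tau` peak at intermediate roughness
— the linear-theory signature of phenotypic clustering: noise pumps smooth
deformations, but rugged ones persist, so the typical abundance profile
carries clusters a few species wide.

```r
# noisy trajectory and correlation structure
tr <- simulate_trace(fp, nm, cycles = 20000, seed = 1)
cc <- correlation_vs_distance(tr, "full", burn_in = 1000)
head(cc$binned)
```

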