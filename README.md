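# mitoreticulum

Mitochondria in most animal cells form a partially connected, constantly
remodeled network — the chondriome — whose architecture is set by two
coupled processes: enzymatic fission and fusion, and motor-driven
positioning of the organelles on the microtubule (MT) cytoskeleton.
`mitoreticulum` is an R package for cell biophysicists and systems
biologists that models this coupling in an idealized, spherically
symmetric cell whose MTs are grafted at a central centrosome, and asks how
the radial organization of the cytoskeleton imprints itself on the
structure of the reticulum.

## The model

**Cytoskeleton.** Each of the `n_f` MTs is a freely rotating chain (FRC):
bonds of length *a* = 20 nm at a fixed bond angle *θ* with uniform
torsion, equivalent to a worm-like chain of persistence length
*L*<sub>p</sub> = 2*a*/*θ*². Grafted ends point uniformly over the sphere.
An explicit Monte Carlo array provides the empirical radial densities; a
semi-analytic layer provides the same quantities in closed form from the
two-branch (series / Hermite-resummed) end-to-end distance distribution
*P*(*r*, *ρ*) of a semiflexible chain:

- *Q*<sub>j</sub>(*r*) = *n*<sub>f</sub> ∫ *P*(*r*, *ρ*) ε<sup>j</sup>(*ρ*) d*ρ* —
  shell density of MT contour occupied by *j* superimposed mitochondria,
  with the motor-biased occupancy ε(*ρ*) ∝ e<sup>ψρ</sup> normalized to
  the total mitochondrial length *M*;
- *S*<sub>jj</sub>(*r*) = *Q*<sub>j</sub>(*r*) ∫ *Q*<sub>j</sub>(ξ)
  *A*(ξ, *r*)/(4πξ²) dξ — density of occupied two-fiber crossings within
  the proximity threshold σ (the organelle diameter), with the
  spherical-cap factor *A*; in the bulk,
  *S*<sub>00</sub> ≈ σ³*Q*<sub>0</sub>²/(3*r*²).

**Graph dynamics.** The reticulum is a graph of fixed 0.2-µm edges with
nodes of degree 1 (free end), 2 (bulk) and 3 (branch). Tip-to-tip fusion
(ratio α₁) and tip-to-side fusion (ratio α₂) with their reverse fissions
obey the mass-action steady state
u₂ = (α₁/2)u₁², u₃ = α₂u₁u₂, u₁ + 2u₂ + 3u₃ = 2*Q*₁ per radial shell,
where α₁ ∝ γ(Q₂ + S₁₁) and α₂ ∝ γS₁₁ carry the position dependence and γ
is the global fusion-to-fission balance. The same reactions drive an exact
event-driven (Gillespie) agent-based simulation that also yields
cluster-size distributions and the largest-cluster (supercluster)
fraction. Because the occupied-crossing density falls off sharply with
radius, the cell partitions into a branched perinuclear zone and a more
fragmented periphery, with the border moving outward as γ grows and the
whole pattern reversing when the motor bias ψ pushes mitochondria
peripherally.

See the methods vignette (`vignettes/mitoreticulum-methods.Rmd`) for
assumptions, parameter units, numerical choices and limitations.

## Worked example

```r
library(mitoreticulum)
cfg <- mito_config()                      # the reference cell
profiles <- density_profiles(cfg)
profiles
#> radial density profiles: 100 shells of 0.16 um (Lp = 32 um, psi = 0 /um)
#>   integral of Q1 = 1001.30 um (M = 1000 um)

ss <- solve_radial_steady_state(cfg, gamma = 0.1, profiles = profiles)
ss[ss$r %in% c(3.92, 7.92, 11.92), c("r","u1","u2","u3","frac3","s_um")]
#>        r   u1   u2    u3  frac3  s_um
#> 25  3.92 12.1 46.9 12.76 0.2655 0.573
#> 50  7.92 13.6 61.5  5.16 0.1018 1.045
#> 75 11.92 14.1 66.6  2.65 0.0513 1.409

partition_border(ss)
#> [1] 1.68

ens <- radial_ensemble(cfg, gamma = 0.1, runs = 100,
                       radii = c(4, 8, 12), profiles = profiles)
ens$summary[, c("r", "n_edges", "u1", "u2", "u3", "largest_frac")]
#>       r n_edges    u1   u2   u3 largest_frac
#> 1  3.92      58  9.82 38.2 9.92        0.812
#> 2  7.92      61 10.96 49.7 3.87        0.541
#> 3 11.92      62 11.35 53.3 2.05        0.454
```

Reading the numbers: at the physiological fusion–fission balance
(γ = 0.1) the node densities are dominated by bulk nodes (`u2`), the
branching fraction `frac3` falls from 27% at 4 µm to 5% at 12 µm, and the
mean segment length `s_um` grows from ~0.6 µm perinuclearly to ~1.4 µm at
the periphery. The stochastic ensembles (58–62 edges per 0.16-µm shell,
100 runs) show the same node composition at finite size, and the mean
largest-cluster fraction decays from 0.81 near the centrosome to 0.45 at
12 µm — the perinuclear supercluster with scattered peripheral
mitochondria. The deterministic partition border (first radius where bulk
nodes overtake branching nodes) sits at 1.68 µm and moves outward with γ.

A thin command-line front end over the same functions ships in
`inst/cli/mitoreticulum.R` (subcommands `generate-cs`, `steady-state`,
`simulate`).

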