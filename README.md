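# eeipm — evolutionarily explicit Integral Projection Models

`eeipm` simulates, generation by generation, the joint distribution of the
two components of a quantitative trait: the breeding value *A* (the
additive-genetic contribution) and the environmental component *E*, with
the phenotype *z = A + E*. It is built for quantitative geneticists and
structured-population modellers who want to ask how environmental change —
in particular a deteriorating environment that depresses the mean of *E*
each generation — reshapes multi-generational evolutionary predictions that
single-generation tools like the breeder's equation cannot make.

## The model

The discretized bivariate density *N(A, E, t)* is iterated by

  N(A′, E′, t+1) = ∫ D((A′,E′) | (A,E), θ, t) · R(A+E, θ, t) · N(A, E, t) dA dE

where *R* is a fitness function (linear β₀ + β_z·z or exponential
exp(b·z), optionally with an environment term) and *D* is the
parent–offspring map: breeding values inherited with the mid-parent mean
(four selectable treatments of the additive genetic variance, from
mid-parent convolution with segregation variance to constant-variance
Gaussian inheritance and variance erosion), and environmental components
regenerated by developmental noise around a possibly trending mean, with
optional nongenetic inheritance. Selection acts first; the operators do not
commute. The life history is annual, so mean fitness is the per-generation
population growth rate, w̄(t) = n(t+1)/n(t), and the selection differential is
S = cov(z, w)/w̄, decomposed into its A and E parts.

Two interchangeable engines perform the projection: a dense kernel-matrix
product (for verification at coarse resolution) and a fast vector
algorithm that never forms the n²-sized operator and makes 500-bin-per-
component runs take milliseconds per generation. They agree to normalized
L1 < 1e−8.

## Worked example

Model 1 (constant environment — a dynamic breeder's equation) for 10
generations on the bundled 500×500 mesh:

```r
library(eeipm)
traj <- run_eeipm(preset_config("model1", generations = 10))
traj
#> eeipm_trajectory: 10 generations (engine: fast)
#>  generation       n  mean_A mean_E  mean_z mean_fitness      S_z
#>           1 1.00000 18.0000     18 36.0000      1.10000 0.363636
#>           2 1.10000 18.1818     18 36.1818      1.11818 0.357724
#>           3 1.23000 18.3607     18 36.3607      1.13607 0.352092
#>           4 1.39736 18.5367     18 36.5367      1.15367 0.346719
#>           5 1.61210 18.7101     18 36.7101      1.17101 0.341586
#>          ...
#>          10 4.08642 19.5405     18 37.5405      1.25405 0.318967
```

Read: the population starts with mean breeding value and mean environment
18 (phenotype 36), mean fitness 1.1, and a selection differential of
0.1·4/1.1 = 0.364. Each generation the mean breeding value advances by
h²·S (0.5 · 0.364 = 0.182 at first), the environment mean stays at 18, and
because fitness is a fixed linear function of the phenotype, mean fitness —
the population growth rate — rises, which *weakens* selection over time
(S_z falls from 0.364 to 0.319).

Contrast with model 2, identical except the environment deteriorates by
0.5 trait units per generation:

```r
m2 <- run_eeipm(preset_config("model2", generations = 10))
cmp <- compare_trajectories(m2, traj)
cmp[c(5, 10), ]
#>    generation d_mean_A d_mean_E d_mean_z d_mean_fitness
#> 5           5   0.0506     -2.0  -1.9494        -0.1949
#> 10         10   0.3112     -4.5  -4.1888        -0.4189
attr(cmp, "summary")
#> "the first trajectory's mean breeding value advanced further (by 0.311212 at generation 10)"
```

The deteriorating environment holds mean fitness down, so selection stays
strong and evolution of the mean breeding value is *faster* (+0.31 by
generation 10) even as the mean phenotype falls behind (−4.19): evolution
is fastest when it is cryptic.

A command-line runner wraps the same functions:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "eeipm.R", package = "eeipm"))')" \
  run --preset model2 --generations 20 --out model2.csv
```

which writes the full-precision trajectory CSV and a JSON manifest of the
resolved configuration. `simulate_ibm()` runs an individual-based
Monte-Carlo version of the same model (10⁵ individuals in a few hundred
milliseconds) whose mean trajectories match the deterministic projection
within Monte-Carlo error.

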