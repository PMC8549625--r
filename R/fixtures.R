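#' Deterministic small fixtures for tests and examples
#'
#' Ready-made small inputs:
#'
#' * `"coarse-model1"`, `"coarse-model2"` — the bundled presets at 50-bin
#'   resolution and 5 generations (small enough for the dense full engine;
#'   used for engine-equivalence checks).
#' * `"point-mass"` — a state with a single occupied cell on a 10 x 10 grid.
#' * `"two-cell"` — masses 1 and 3 at breeding values 1 and 2 (same E),
#'   so the mean breeding value is 1.75.
#' * `"figure1-gaussian"` — a centred bivariate Gaussian state with
#'   `mean_A = mean_E = 0` and `var_A = var_E = 0.5` on a 100-bin
#'   `[-5, 5]^2` grid.
#'
#' @param kind fixture name (see above).
#' @param seed accepted for interface uniformity; every fixture is
#'   deterministic.
#' @return a `population_state` or an `eeipm_config`, depending on `kind`.
#' @export
make_fixture <- function(kind = c("coarse-model1", "coarse-model2",
                                  "point-mass", "two-cell",
                                  "figure1-gaussian"),
                         seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    "coarse-model1" = preset_config("model1", generations = 5L,
                                    grid_bins = 50L, seed = seed),
    "coarse-model2" = preset_config("model2", generations = 5L,
                                    grid_bins = 50L, seed = seed),
    "point-mass" = {
      g <- build_grid(0, 10, 10, 0, 10, 10)
      dens <- numeric(g$n_cells)
      dens[45] <- 1
      population_state(g, dens, t = 1L)
    },
    "two-cell" = {
      g <- build_grid(0.5, 3.5, 3, 0.5, 3.5, 3)  # mid-points 1, 2, 3
      m <- matrix(0, nrow = g$n_e, ncol = g$n_a)
      m[2, 1] <- 1  # (A = 1, E = 2)
      m[2, 2] <- 3  # (A = 2, E = 2)
      population_state(g, flatten_state_matrix(m), t = 1L)
    },
    "figure1-gaussian" = {
      g <- build_grid(-5, 5, 100, -5, 5, 100)
      gaussian_state(g, 0, 0, 0.5, 0.5, 0, total_size = 1, t = 1L)
    })
}
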