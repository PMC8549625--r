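#' Construct a population state on a trait grid
#'
#' A population state is the discretized bivariate density `N(A, E, t)`:
#' a non-negative number of individuals per grid cell, together with the
#' generation index `t` and the total population size `n` (the sum of the
#' densities).
#'
#' @param grid a [build_grid()] mesh.
#' @param density numeric vector of per-cell individual counts, flattened
#'   A-major with E fastest.
#' @param t generation index (integer >= 1).
#' @return An object of class `population_state`.
#' @export
population_state <- function(grid, density, t = 1L) {
  stopifnot_grid(grid)
  if (length(density) != grid$n_cells)
    stop("density length does not match grid", call. = FALSE)
  if (any(!is.finite(density)))
    stop("density must be finite", call. = FALSE)
  # FFT-based convolutions can leave values a few ulp below zero
  neg <- density < 0
  if (any(neg)) {
    if (min(density) < -1e-9 * max(sum(abs(density)), 1))
      stop("density must be non-negative", call. = FALSE)
    density[neg] <- 0
  }
  t <- as.integer(t)
  if (is.na(t) || t < 1L) stop("generation index t must be >= 1", call. = FALSE)
  structure(list(grid = grid, density = density, t = t, n = sum(density)),
            class = "population_state")
}

#' @export
print.population_state <- function(x, ...) {
  s <- summarize_state(x)
  cat(sprintf(
    "population_state: t = %d, n = %.6g, mean_A = %.4f, mean_E = %.4f, mean_z = %.4f\n",
    x$t, x$n, s$mean_A, s$mean_E, s$mean_z))
  invisible(x)
}

is_population_state <- function(x) inherits(x, "population_state")

stopifnot_state <- function(state) {
  if (!is_population_state(state))
    stop("expected a 'population_state' object", call. = FALSE)
  invisible(state)
}

#' Discretize a bivariate Gaussian onto a trait grid
#'
#' Evaluates the bivariate-normal density of `(A, E)` at each cell mid-point,
#' multiplies by the cell area (mid-point rule), and rescales so that the
#' densities sum to `total_size`. If more than 1% of the Gaussian mass falls
#' outside the grid the truncation is reported with a warning.
#'
#' @param grid a [build_grid()] mesh.
#' @param mean_A,mean_E means of the breeding value and environmental
#'   component.
#' @param var_A,var_E,cov_AE elements of the (positive-definite)
#'   variance-covariance matrix.
#' @param total_size total population size `n` (> 0); densities are absolute
#'   individual counts, not probabilities, because `n(t)` is dynamically
#'   meaningful (mean fitness is the per-generation growth rate).
#' @param t generation index of the state.
#' @return A [population_state()].
#' @export
gaussian_state <- function(grid, mean_A, mean_E, var_A, var_E, cov_AE = 0,
                           total_size = 1, t = 1L) {
  stopifnot_grid(grid)
  if (total_size <= 0) stop("total_size must be > 0", call. = FALSE)
  det_sigma <- var_A * var_E - cov_AE^2
  if (var_A <= 0 || var_E <= 0 || det_sigma <= 0)
    stop("covariance matrix must be positive definite", call. = FALSE)
  a <- grid_cell_A(grid) - mean_A
  e <- grid_cell_E(grid) - mean_E
  quad <- (var_E * a^2 - 2 * cov_AE * a * e + var_A * e^2) / det_sigma
  dens <- exp(-0.5 * quad) / (2 * pi * sqrt(det_sigma)) * grid$da * grid$de
  covered <- sum(dens)
  if (covered < 0.99)
    warning(sprintf(
      "grid covers only %.3f of the Gaussian mass; consider wider limits",
      covered), call. = FALSE)
  population_state(grid, dens * (total_size / covered), t = t)
}

#' Moment summary of a population state
#'
#' Density-weighted means, variances and covariance of `A`, `E` and
#' `z = A + E` over the cell mid-points, plus the narrow-sense heritability
#' `h^2 = var_A / var_z`. Variances are population (not sample) moments.
#'
#' @param state a [population_state()] with `n > 0`.
#' @return A list of class `generation_record` with elements `t`, `n`,
#'   `mean_A`, `mean_E`, `mean_z`, `var_A`, `var_E`, `cov_AE`, `var_z`,
#'   `heritability`.
#' @export
summarize_state <- function(state) {
  stopifnot_state(state)
  if (state$n <= 0) stop("degenerate state: total population size is zero",
                         call. = FALSE)
  g <- state$grid
  p <- state$density / state$n
  a <- grid_cell_A(g)
  e <- grid_cell_E(g)
  mean_A <- sum(p * a)
  mean_E <- sum(p * e)
  da <- a - mean_A
  de <- e - mean_E
  var_A <- sum(p * da^2)
  var_E <- sum(p * de^2)
  cov_AE <- sum(p * da * de)
  var_z <- sum(p * (da + de)^2)
  structure(list(
    t = state$t, n = state$n,
    mean_A = mean_A, mean_E = mean_E, mean_z = mean_A + mean_E,
    var_A = var_A, var_E = var_E, cov_AE = cov_AE, var_z = var_z,
    heritability = if (var_z > 0) var_A / var_z else NA_real_
  ), class = "generation_record")
}

#' Marginal distributions of a state
#'
#' Sum the per-cell densities over E within each A category (or over A within
#' each E category). Returned as absolute mass per category.
#'
#' @param state a [population_state()].
#' @return numeric vector over `a_mid` (resp. `e_mid`).
#' @export
a_marginal <- function(state) {
  stopifnot_state(state)
  colSums(unflatten_state(state$density, state$grid))
}

#' @rdname a_marginal
#' @export
e_marginal <- function(state) {
  stopifnot_state(state)
  rowSums(unflatten_state(state$density, state$grid))
}

#' Export a state snapshot as delimited text
#'
#' Writes one row per grid cell with columns `A_mid`, `E_mid`, `density`,
#' in flattened order, tab-separated.
#'
#' @param state a [population_state()].
#' @param path output file path.
#' @export
write_state <- function(state, path) {
  stopifnot_state(state)
  df <- data.frame(A_mid = grid_cell_A(state$grid),
                   E_mid = grid_cell_E(state$grid),
                   density = state$density)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
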