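#' Specify the genetic-inheritance treatment of the additive variance
#'
#' Four treatments of the additive genetic variance are supported, following
#' the structured-population-modelling literature:
#'
#' 1. Convolve the selected-parent breeding-value distribution with itself
#'    to get mid-parent values, then add Gaussian segregation variance
#'    `sigma_seg`. Offspring variance: `var_s / 2 + sigma_seg`.
#' 2. A linear, Gaussian inheritance kernel (typical of a standard IPM)
#'    passing through `(A_bar_s, A_bar_s)` with slope 0.5 and conditional
#'    variance `residual_var`. Offspring variance:
#'    `0.25 * var_s + residual_var`.
#' 3. A Gaussian offspring distribution with constant variance
#'    `sigma_AA_target` and mean equal to the postselection mean breeding
#'    value.
#' 4. Selection erodes the additive variance: implemented here as the
#'    mid-parent convolution of approach 1 with no segregation variance
#'    (`sigma_seg = 0`), so under flat fitness the variance halves every
#'    generation. This reading is a documented choice; the literature leaves
#'    the mechanics open.
#'
#' All four preserve the mean: the offspring mean breeding value equals the
#' postselection parental mean (the mid-parent rule of quantitative
#' genetics).
#'
#' Defaults (resolved against the initial additive variance `sigma_AA0` when
#' used inside a model configuration): `sigma_seg = sigma_AA0 / 2`, the
#' infinitesimal-model value that keeps the no-selection variance
#' stationary (`v -> v/2 + v/2`); `residual_var = 0.75 * sigma_AA0`, which
#' keeps the approach-2 offspring variance stationary
#' (`0.25 v + 0.75 v = v`).
#'
#' @param approach integer 1-4.
#' @param sigma_AA_target constant offspring additive variance (approach 3).
#' @param sigma_seg segregation variance (approach 1).
#' @param residual_var conditional variance of the approach-2 kernel.
#' @return An object of class `genetic_spec`. The approach-2 kernel slope is
#'   fixed at 0.5.
#' @export
genetic_spec <- function(approach, sigma_AA_target = NULL, sigma_seg = NULL,
                         residual_var = NULL) {
  approach <- as.integer(approach)
  if (is.na(approach) || !approach %in% 1:4)
    stop("approach must be 1, 2, 3 or 4", call. = FALSE)
  chk <- function(v, nm) {
    if (!is.null(v) && (!is.finite(v) || v < 0))
      stop(sprintf("%s must be a non-negative number", nm), call. = FALSE)
    v
  }
  if (approach == 3L && is.null(sigma_AA_target))
    stop("approach 3 requires sigma_AA_target", call. = FALSE)
  if (approach == 1L && is.null(sigma_seg))
    stop("approach 1 requires sigma_seg", call. = FALSE)
  if (approach == 2L && is.null(residual_var))
    stop("approach 2 requires residual_var", call. = FALSE)
  structure(list(approach = approach,
                 sigma_AA_target = chk(sigma_AA_target, "sigma_AA_target"),
                 sigma_seg = chk(sigma_seg, "sigma_seg"),
                 residual_var = chk(residual_var, "residual_var"),
                 slope = 0.5),
            class = "genetic_spec")
}

is_genetic_spec <- function(x) inherits(x, "genetic_spec")

# Discretize a Gaussian on a mid-point mesh: pdf at mid-points times step,
# renormalized. Errors if more than max_outside of the mass lies off the
# mesh. var = 0 degenerates to a point mass in the nearest cell.
discretize_gaussian <- function(mids, mean, var, step, max_outside = 1e-3,
                                what = "distribution") {
  if (var < 0) stop("variance must be >= 0", call. = FALSE)
  p <- numeric(length(mids))
  if (var == 0) {
    p[which.min(abs(mids - mean))] <- 1
    return(p)
  }
  p <- stats::dnorm(mids, mean, sqrt(var)) * step
  covered <- sum(p)
  if (1 - covered > max_outside)
    stop(sprintf(
      "%s places %.3g of its mass outside the grid (limit %.3g): grid too narrow",
      what, 1 - covered, max_outside), call. = FALSE)
  p / covered
}

#' Distribution of mid-parent breeding values
#'
#' Convolves a parental breeding-value distribution with itself under random
#' mating (both parents drawn independently from the same distribution, with
#' identical demography for the sexes) and halves the axis, giving the
#' distribution of `(A_mother + A_father) / 2` re-expressed on the original
#' A mid-point mesh.
#'
#' The self-convolution lives naturally on a mesh of spacing `da / 2`;
#' half-step points are reassigned to the two neighbouring original cells in
#' equal parts. The mean is preserved exactly; the variance is halved up to
#' an interpolation term bounded by `da^2 / 4` times the reassigned mass.
#'
#' @param A_marginal probability vector over the grid's A mid-points.
#' @param grid a [build_grid()] mesh.
#' @return probability vector over `grid$a_mid`.
#' @examples
#' g <- build_grid(0.5, 3.5, 3, 0.5, 3.5, 3)  # A mid-points 1, 2, 3
#' midpoint_convolution(c(0.5, 0, 0.5), g)    # 0.25, 0.50, 0.25
#' @export
midpoint_convolution <- function(A_marginal, grid) {
  stopifnot_grid(grid)
  n <- grid$n_a
  if (length(A_marginal) != n)
    stop("A_marginal length does not match grid$n_a", call. = FALSE)
  tot <- sum(A_marginal)
  if (tot <= 0) stop("A_marginal has no mass", call. = FALSE)
  p <- A_marginal / tot
  if (n == 1L) return(1)
  # c[k] = P(i + j = k + 1) over parental category indices i, j
  conv <- stats::convolve(p, rev(p), type = "open")
  conv[conv < 0] <- 0  # FFT round-off
  # mid-parent value of conv[k] is a_mid[1] + (k - 1) * da / 2:
  # odd k sits on an original mid-point, even k half-way between two
  q <- numeric(n)
  k <- seq_along(conv)
  on_mesh <- (k %% 2L) == 1L
  q[(k[on_mesh] + 1L) / 2L] <- conv[on_mesh]
  half <- conv[!on_mesh] / 2
  lo <- k[!on_mesh] / 2L
  q[lo] <- q[lo] + half
  q[lo + 1L] <- q[lo + 1L] + half
  q / sum(q)
}

#' Approach-2 inheritance kernel
#'
#' For each parental breeding value `A`, a Gaussian over offspring `A'` with
#' conditional mean `A_bar_s + 0.5 * (A - A_bar_s)` (a line of slope 0.5
#' through `(A_bar_s, A_bar_s)`) and conditional variance
#' `spec$residual_var`. Columns are renormalized over the truncated A range
#' so that all transitions out of a parental category sum to one.
#'
#' @param spec a [genetic_spec()] with `residual_var` set.
#' @param grid a [build_grid()] mesh.
#' @param mean_As postselection mean breeding value.
#' @return an `n_a x n_a` column-stochastic matrix; columns index parental
#'   A, rows offspring A'.
#' @export
approach2_kernel <- function(spec, grid, mean_As) {
  if (!is_genetic_spec(spec)) stop("expected a 'genetic_spec'", call. = FALSE)
  stopifnot_grid(grid)
  if (is.null(spec$residual_var))
    stop("approach2_kernel requires residual_var", call. = FALSE)
  cond_mean <- mean_As + spec$slope * (grid$a_mid - mean_As)
  K <- vapply(cond_mean, function(m)
    discretize_gaussian(grid$a_mid, m, spec$residual_var, grid$da,
                        max_outside = 1, what = "inheritance kernel column"),
    numeric(grid$n_a))
  K
}

# Offspring A distribution from a parental (postselection) marginal.
# Shared by the public wrapper and the fast engine.
offspring_A_from_marginal <- function(A_marginal, grid, spec) {
  tot <- sum(A_marginal)
  if (tot <= 0) stop("postselection state has no mass", call. = FALSE)
  p <- A_marginal / tot
  mean_As <- sum(grid$a_mid * p)
  switch(spec$approach,
    { # 1: mid-parent convolution + segregation variance
      q <- midpoint_convolution(p, grid)
      convolve_segregation(q, grid, spec$sigma_seg)
    },
    { # 2: marginalized slope-0.5 Gaussian kernel
      as.numeric(approach2_kernel(spec, grid, mean_As) %*% p)
    },
    { # 3: constant-variance Gaussian at the postselection mean
      discretize_gaussian(grid$a_mid, mean_As, spec$sigma_AA_target, grid$da,
                          what = "offspring breeding-value distribution")
    },
    { # 4: erosion — mid-parent convolution, no segregation variance
      midpoint_convolution(p, grid)
    })
}

# Convolve a probability vector on the A mesh with a zero-mean Gaussian of
# variance sigma_seg discretized at mesh offsets. Errors when more than
# 0.1% of the resulting mass would fall off the mesh; otherwise truncates
# and renormalizes.
convolve_segregation <- function(p, grid, sigma_seg) {
  if (sigma_seg == 0) return(p)
  da <- grid$da
  K <- max(1L, ceiling(6 * sqrt(sigma_seg) / da))
  g <- stats::dnorm(seq(-K, K) * da, 0, sqrt(sigma_seg))
  g <- g / sum(g)
  full <- stats::convolve(c(numeric(K), p, numeric(K)), rev(g), type = "open")
  full[full < 0] <- 0
  idx <- (2 * K + 1):(2 * K + grid$n_a)
  inside <- full[idx]
  outside <- sum(full) - sum(inside)
  if (outside > 1e-3)
    stop(sprintf(
      "segregation-variance convolution places %.3g of the mass outside the A range: grid too narrow",
      outside), call. = FALSE)
  inside / sum(inside)
}

#' Offspring breeding-value distribution
#'
#' Produces the probability distribution of offspring breeding values over
#' the grid's A mid-points from a postselection population state, under the
#' configured inheritance treatment. For every approach the mean equals the
#' postselection mean breeding value up to grid tolerance.
#'
#' @param post_state postselection [population_state()] with `n > 0`.
#' @param spec a [genetic_spec()].
#' @return probability vector over `post_state$grid$a_mid` summing to 1.
#' @export
offspring_A_distribution <- function(post_state, spec) {
  stopifnot_state(post_state)
  if (!is_genetic_spec(spec)) stop("expected a 'genetic_spec'", call. = FALSE)
  offspring_A_from_marginal(a_marginal(post_state), post_state$grid, spec)
}
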