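#' Specify a fitness function R(z, theta, t)
#'
#' Fitness (expected lifetime reproductive success) is a function of the
#' phenotype `z = A + E` and, optionally, of a scalar environmental value
#' `theta`:
#'
#' * linear: `w = beta0 + beta_z * z + beta_theta * theta`
#' * exponential: `w = exp(rate * z + beta_theta * theta)`
#'
#' A linear fitness function can go negative; the `negative_policy` controls
#' what happens when a negative value is met on an occupied cell. Under
#' `"error"` (the default) selection aborts, naming the offending phenotype
#' range; under `"clamp"` negative values are set to zero and the clamped
#' mass is reported as a message. Silent clamping is never done on occupied
#' cells, since it would bias selection differentials unannounced.
#'
#' @param form `"linear"` or `"exponential"`.
#' @param beta0 intercept (linear form).
#' @param beta_z slope of fitness on the phenotype, per trait unit (linear
#'   form).
#' @param beta_theta coefficient of the scalar environment value; 0 means
#'   fitness is unaffected by environmental variation.
#' @param rate exponential rate `b` in `w = exp(b * z)` (exponential form).
#' @param negative_policy `"error"` or `"clamp"`.
#' @return An object of class `fitness_spec`.
#' @examples
#' f <- fitness_spec("linear", beta0 = -2.5, beta_z = 0.1)
#' # zero crossing at z = 25
#' -f$beta0 / f$beta_z
#' @export
fitness_spec <- function(form = c("linear", "exponential"),
                         beta0 = 0, beta_z = 0, beta_theta = 0, rate = NULL,
                         negative_policy = c("error", "clamp")) {
  form <- match.arg(form)
  negative_policy <- match.arg(negative_policy)
  if (form == "exponential") {
    if (is.null(rate) || !is.finite(rate))
      stop("exponential fitness needs a finite 'rate'", call. = FALSE)
  }
  structure(list(form = form, beta0 = beta0, beta_z = beta_z,
                 beta_theta = beta_theta, rate = rate,
                 negative_policy = negative_policy),
            class = "fitness_spec")
}

is_fitness_spec <- function(x) inherits(x, "fitness_spec")

#' Evaluate a fitness function on a grid
#'
#' One fitness value per flattened cell, depending on the cell only through
#' its phenotype `z = A + E` (cells with equal z get equal fitness) and on
#' the scalar environment `theta`. Values may be negative for a linear
#' spec; the policy is enforced against occupied cells by
#' [apply_selection()], where the population state is known.
#'
#' @param spec a [fitness_spec()].
#' @param grid a [build_grid()] mesh.
#' @param theta scalar environment value for the generation (default 0).
#' @return numeric vector of per-cell fitness, carrying the spec's
#'   `negative_policy` as an attribute.
#' @export
evaluate_fitness <- function(spec, grid, theta = 0) {
  if (!is_fitness_spec(spec)) stop("expected a 'fitness_spec'", call. = FALSE)
  stopifnot_grid(grid)
  z <- phenotype_values(grid)
  w <- switch(spec$form,
    linear = spec$beta0 + spec$beta_z * z + spec$beta_theta * theta,
    exponential = exp(spec$rate * z + spec$beta_theta * theta))
  attr(w, "negative_policy") <- spec$negative_policy
  w
}

#' Apply selection to a population state
#'
#' Multiplies each cell's density by its fitness: `N_s(A, E, t) =
#' R(A + E, theta, t) * N(A, E, t)`. The returned total `n` is the
#' population size at birth of the next generation, `sum(R * N)`.
#'
#' Cells holding less than `occupied_tol` of the total population mass are
#' treated as unoccupied: negative fitness there is replaced by zero without
#' triggering the policy (the far Gaussian tail of a discretized state is
#' never exactly empty).
#'
#' @param state a [population_state()].
#' @param fitness per-cell fitness vector from [evaluate_fitness()] (or any
#'   numeric vector matching the grid).
#' @param negative_policy `"error"` or `"clamp"`; defaults to the policy
#'   attached to `fitness`, else `"error"`.
#' @param occupied_tol relative per-cell mass below which a cell counts as
#'   unoccupied for the negative-fitness check.
#' @return The postselection [population_state()] (same generation index).
#'   Attribute `clamped_mass` records any population mass whose negative
#'   fitness was clamped on occupied cells.
#' @export
apply_selection <- function(state, fitness,
                            negative_policy = NULL,
                            occupied_tol = 1e-8) {
  stopifnot_state(state)
  if (length(fitness) != state$grid$n_cells)
    stop("fitness vector does not match grid", call. = FALSE)
  if (is.null(negative_policy))
    negative_policy <- attr(fitness, "negative_policy")
  if (is.null(negative_policy)) negative_policy <- "error"
  negative_policy <- match.arg(negative_policy, c("error", "clamp"))
  w <- as.numeric(fitness)
  clamped_mass <- 0
  neg <- w < 0
  if (any(neg)) {
    occupied <- state$density > occupied_tol * state$n
    bad <- neg & occupied
    if (any(bad)) {
      if (negative_policy == "error") {
        z <- phenotype_values(state$grid)
        stop(sprintf(
          "negative fitness on occupied cells (z in [%.4g, %.4g]); use a bounded fitness function or negative_policy = 'clamp'",
          min(z[bad]), max(z[bad])), call. = FALSE)
      }
      clamped_mass <- sum(state$density[bad])
      message(sprintf(
        "apply_selection: clamped negative fitness on %d occupied cells (mass %.3g of %.3g)",
        sum(bad), clamped_mass, state$n))
    }
    w[neg] <- 0
  }
  post <- population_state(state$grid, w * state$density, t = state$t)
  attr(post, "clamped_mass") <- clamped_mass
  post
}

#' Selection summary: mean fitness and selection differentials
#'
#' Computes the mean fitness `w_bar`, the covariance of the phenotype with
#' absolute fitness `cov(z, w)`, and the selection differentials
#' `S_z = cov(z, w) / w_bar`, decomposed into the breeding-value and
#' environmental components `S_A = cov(A, w) / w_bar` and
#' `S_E = cov(E, w) / w_bar` (so `S_z = S_A + S_E`). The angle of the
#' selection displacement vector `(S_A, S_E)` from the A-axis is reported
#' in degrees: when the two component variances are equal and their
#' covariance is zero the vector points at 45 degrees.
#'
#' `S_z` equals the postselection minus the preselection mean phenotype; the
#' identity is algebraic on the discrete state.
#'
#' @param pre_state state before selection.
#' @param post_state state after [apply_selection()] (same grid).
#' @param fitness the per-cell fitness that was applied (as used, i.e. after
#'   any clamping it is still passed unclamped here; covariances use the
#'   realized weights `post_state$density / pre_state$density` implicitly by
#'   recomputation from `fitness` with negatives clamped to zero).
#' @return A list of class `selection_summary` with `mean_fitness`,
#'   `cov_zw`, `S_z`, `S_A`, `S_E`, `angle_deg`.
#' @export
selection_summary <- function(pre_state, post_state, fitness) {
  stopifnot_state(pre_state); stopifnot_state(post_state)
  if (!identical(pre_state$grid$n_cells, post_state$grid$n_cells))
    stop("states must share a grid", call. = FALSE)
  if (pre_state$n <= 0) stop("degenerate preselection state", call. = FALSE)
  w <- pmax(as.numeric(fitness), 0)
  g <- pre_state$grid
  p <- pre_state$density / pre_state$n
  a <- grid_cell_A(g); e <- grid_cell_E(g); z <- a + e
  w_bar <- sum(p * w)
  if (w_bar <= 0) stop("degenerate selection: mean fitness is zero",
                       call. = FALSE)
  cov_zw <- sum(p * z * w) - sum(p * z) * w_bar
  cov_aw <- sum(p * a * w) - sum(p * a) * w_bar
  cov_ew <- sum(p * e * w) - sum(p * e) * w_bar
  S_A <- cov_aw / w_bar
  S_E <- cov_ew / w_bar
  structure(list(
    mean_fitness = w_bar, cov_zw = cov_zw,
    S_z = cov_zw / w_bar, S_A = S_A, S_E = S_E,
    angle_deg = atan2(S_E, S_A) * 180 / pi
  ), class = "selection_summary")
}
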