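#' Build the full transition operator D(t)
#'
#' Assembles the dense parent-to-offspring transition matrix `D` whose
#' columns are probability distributions over offspring `(A', E')` cells,
#' one column per parental `(A, E)` cell, in the flattened A-major order.
#' `D` factorizes as a Kronecker product `K_A %x% K_E` of an A-inheritance
#' operator and an E operator. For inheritance approaches 1, 3 and 4 the
#' offspring A distribution depends on the parental generation only through
#' summary statistics of the postselection state, so all columns of `K_A`
#' are identical; approach 2 (and nongenetic inheritance `f > 0` for E)
#' yield genuinely parent-dependent columns.
#'
#' Dense operators scale as the square of the cell count; grids above
#' `max_cells` cells are refused with a pointer to the fast engine.
#'
#' @param grid a [build_grid()] mesh.
#' @param genetic_spec a [genetic_spec()].
#' @param env_model an [environment_model()].
#' @param t_next offspring generation index.
#' @param post_state the postselection state (supplies the marginals and
#'   moments the operator is conditioned on).
#' @param fitness optional per-cell fitness vector stored alongside as
#'   `R_diag` (the diagonal of the selection matrix R(t)).
#' @param max_cells dense-operator guard (default 10000 cells).
#' @return A list of class `kernel_operators` with elements `D`
#'   (column-stochastic `n_cells x n_cells` matrix), `R_diag`, `t_next`.
#' @export
build_kernel <- function(grid, genetic_spec, env_model, t_next, post_state,
                         fitness = NULL, max_cells = 10000) {
  stopifnot_grid(grid)
  if (!is_genetic_spec(genetic_spec))
    stop("expected a 'genetic_spec'", call. = FALSE)
  if (!is_environment_model(env_model))
    stop("expected an 'environment_model'", call. = FALSE)
  stopifnot_state(post_state)
  if (grid$n_cells > max_cells)
    stop(sprintf(
      "grid has %d cells (> %d): a dense operator would need %.2g entries; use the fast engine (engine = 'fast')",
      grid$n_cells, max_cells, as.numeric(grid$n_cells)^2), call. = FALSE)
  marg <- a_marginal(post_state)
  mean_As <- sum(grid$a_mid * marg) / sum(marg)
  if (genetic_spec$approach == 2L) {
    K_A <- approach2_kernel(genetic_spec, grid, mean_As)
  } else {
    pA <- offspring_A_from_marginal(marg, grid, genetic_spec)
    K_A <- matrix(pA, nrow = grid$n_a, ncol = grid$n_a)
  }
  pE <- offspring_E_distribution(env_model, t_next, post_state)
  K_E <- if (is.matrix(pE)) pE else matrix(pE, nrow = grid$n_e, ncol = grid$n_e)
  structure(list(D = kronecker(K_A, K_E), R_diag = fitness, t_next = t_next),
            class = "kernel_operators")
}

#' One generation step with the full kernel-matrix engine
#'
#' Applies selection first (`N_s = R N`), then the parent-to-offspring
#' transition operator (`N(t+1) = D N_s`) — the two do not commute, and
#' selection must act before inheritance since only reproducing parents
#' transmit trait components. The next total population size is
#' `n(t+1) = sum(R N)`, preserved exactly by the column-stochastic `D`.
#'
#' @param state start-of-generation [population_state()].
#' @param fitness a [fitness_spec()] or a per-cell fitness vector.
#' @param genetic_spec a [genetic_spec()].
#' @param env_model an [environment_model()].
#' @param max_cells dense-operator guard passed to [build_kernel()].
#' @return the next [population_state()] (generation `state$t + 1`).
#' @export
step_full <- function(state, fitness, genetic_spec, env_model,
                      max_cells = 10000) {
  stopifnot_state(state)
  t_next <- state$t + 1L
  if (is_fitness_spec(fitness))
    fitness <- evaluate_fitness(fitness, state$grid,
                                theta = environment_mean(env_model, state$t))
  post <- apply_selection(state, fitness)
  if (post$n <= 0)
    stop("extinction: postselection population size is zero", call. = FALSE)
  full_step_from_post(post, genetic_spec, env_model, t_next, fitness,
                      max_cells)
}

full_step_from_post <- function(post, genetic_spec, env_model, t_next,
                                fitness = NULL, max_cells = 10000) {
  op <- build_kernel(post$grid, genetic_spec, env_model, t_next, post,
                     fitness = fitness, max_cells = max_cells)
  population_state(post$grid, as.numeric(op$D %*% post$density), t = t_next)
}

#' One generation step with the fast vector engine
#'
#' Constructs `N(t+1)` directly from the postselection vector without ever
#' populating the `n_cells x n_cells` operator:
#' the next population size is the postselection total; the postselection
#' mean breeding value and A marginal feed the offspring A probability
#' vector; the environment model supplies the offspring E probability
#' vector; and the next state is their outer product (replicated blockwise
#' over the flattened ordering) rescaled to the next population size.
#'
#' Requires offspring `(A', E')` to be conditionally independent of the
#' parental cell given postselection summaries — true for all four genetic
#' approaches (approach 2 through its marginalized offspring distribution)
#' with `nongenetic_fraction = 0`. With `f > 0` the offspring E depends on
#' the parental cell and the fast engine refuses; use [step_full()].
#'
#' @inheritParams step_full
#' @return the next [population_state()]; identical (to floating-point
#'   round-off) to [step_full()] on the same configuration.
#' @export
step_fast <- function(state, fitness, genetic_spec, env_model) {
  stopifnot_state(state)
  if (!is_genetic_spec(genetic_spec))
    stop("expected a 'genetic_spec'", call. = FALSE)
  if (env_model$nongenetic_fraction > 0)
    stop(paste("the fast engine requires offspring E independent of the",
               "parental cell (nongenetic_fraction = 0); use step_full"),
         call. = FALSE)
  t_next <- state$t + 1L
  if (is_fitness_spec(fitness))
    fitness <- evaluate_fitness(fitness, state$grid,
                                theta = environment_mean(env_model, state$t))
  post <- apply_selection(state, fitness)
  if (post$n <= 0)
    stop("extinction: postselection population size is zero", call. = FALSE)
  fast_step_from_post(post, genetic_spec, env_model, t_next)
}

fast_step_from_post <- function(post, genetic_spec, env_model, t_next) {
  g <- post$grid
  pA <- offspring_A_from_marginal(a_marginal(post), g, genetic_spec)
  pE <- offspring_E_distribution(env_model, t_next, post)
  dens <- rep(pA, each = g$n_e) * rep(pE, times = g$n_a)
  population_state(g, dens * (post$n / sum(dens)), t = t_next)
}

#' Iterate an EE-IPM over generations
#'
#' Runs the per-generation map defined by a model configuration (see
#' [eeipm_config()] and [preset_config()]) and returns a trajectory of
#' per-generation records: population size, component means and
#' (co)variances, mean fitness, the phenotype-fitness covariance, selection
#' differentials on z, A and E, the realized change in the mean breeding
#' value, heritability, and the angle of the selection vector.
#'
#' Records describe start-of-generation states; selection summaries are
#' computed within each generation. `delta_mean_A` of generation `t` is
#' `mean_A(t + 1) - mean_A(t)` (one extra internal step supplies it for the
#' final generation). If the population goes extinct the run halts with the
#' event logged in the trajectory.
#'
#' @param config a validated model configuration list.
#' @param store_states keep every start-of-generation state in the result
#'   (memory grows with `generations * n_cells`).
#' @return An object of class `eeipm_trajectory`: list with `records` (a
#'   data frame, one row per generation), `config`, `events`, and optionally
#'   `states`.
#' @examples
#' traj <- run_eeipm(preset_config("model1", generations = 3,
#'                                 grid_bins = 100))
#' traj$records[, c("generation", "mean_A", "mean_E", "mean_fitness")]
#' @export
run_eeipm <- function(config, store_states = NULL) {
  cfg <- resolve_config(config)
  if (is.null(store_states)) store_states <- isTRUE(cfg$run$store_states)
  grid <- build_grid(cfg$grid$a_min, cfg$grid$a_max, cfg$grid$n_a,
                     cfg$grid$e_min, cfg$grid$e_max, cfg$grid$n_e)
  fit <- fitness_spec(cfg$fitness$form, beta0 = cfg$fitness$beta0,
                      beta_z = cfg$fitness$beta_z,
                      beta_theta = cfg$fitness$beta_theta,
                      rate = cfg$fitness$rate,
                      negative_policy = cfg$fitness$negative_policy)
  gen <- genetic_spec(cfg$genetic$approach,
                      sigma_AA_target = cfg$genetic$sigma_AA_target,
                      sigma_seg = cfg$genetic$sigma_seg,
                      residual_var = cfg$genetic$residual_var)
  env <- environment_model(cfg$environment$mean0, cfg$environment$trend,
                           cfg$environment$sigma_EE,
                           cfg$environment$nongenetic_fraction,
                           cfg$environment$theta_series)
  engine <- cfg$run$engine
  G <- cfg$run$generations
  if (!is.null(cfg$run$seed)) set.seed(cfg$run$seed)  # the IPM is deterministic

  state <- gaussian_state(grid, cfg$init$mean_A, cfg$init$mean_E,
                          cfg$init$var_A, cfg$init$var_E, cfg$init$cov_AE,
                          total_size = cfg$init$n0, t = 1L)
  events <- character()
  records <- vector("list", G)
  states <- if (store_states) vector("list", G) else NULL
  clamp_total <- 0
  for (t in seq_len(G)) {
    s <- summarize_state(state)
    theta <- environment_mean(env, t)
    w <- evaluate_fitness(fit, grid, theta = theta)
    post <- suppressMessages(apply_selection(state, w))  # clamp events summarized below
    clamp_total <- clamp_total + attr(post, "clamped_mass")
    extinct <- post$n <= 0
    ss <- if (extinct) {
      list(mean_fitness = 0, cov_zw = NA_real_, S_z = NA_real_,
           S_A = NA_real_, S_E = NA_real_, angle_deg = NA_real_)
    } else {
      selection_summary(state, post, w)
    }
    records[[t]] <- data.frame(
      generation = t, n = s$n,
      mean_A = s$mean_A, mean_E = s$mean_E, mean_z = s$mean_z,
      var_A = s$var_A, var_E = s$var_E, cov_AE = s$cov_AE, var_z = s$var_z,
      mean_fitness = ss$mean_fitness, cov_zw = ss$cov_zw,
      S_z = ss$S_z, S_A = ss$S_A, S_E = ss$S_E,
      delta_mean_A = NA_real_, heritability = s$heritability,
      angle_deg = ss$angle_deg)
    if (store_states) states[[t]] <- state
    if (extinct) {
      events <- c(events, sprintf("extinction at generation %d", t))
      warning(sprintf("population extinct at generation %d; run halted", t),
              call. = FALSE)
      records <- records[seq_len(t)]
      if (store_states) states <- states[seq_len(t)]
      break
    }
    # generation G's step only supplies delta_mean_A; skip it when an
    # explicit theta series ends at G
    if (t == G && !is.null(env$theta_series) &&
        t + 1L > length(env$theta_series)) break
    nxt <- if (engine == "fast") {
      fast_step_from_post(post, gen, env, t + 1L)
    } else {
      full_step_from_post(post, gen, env, t + 1L, fitness = w,
                          max_cells = cfg$run$max_cells %||% 10000)
    }
    records[[t]]$delta_mean_A <- summarize_state(nxt)$mean_A - s$mean_A
    if (t < G) state <- nxt  # generation G's step only supplies delta_mean_A
  }
  if (clamp_total > 0)
    events <- c(events, sprintf(
      "negative fitness clamped on occupied cells (total mass %.4g)",
      clamp_total))
  structure(list(records = do.call(rbind, records), config = cfg,
                 events = events, states = states),
            class = "eeipm_trajectory")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.eeipm_trajectory <- function(x, ...) {
  r <- x$records
  cat(sprintf("eeipm_trajectory: %d generations (engine: %s)\n",
              nrow(r), x$config$run$engine))
  show <- r[, c("generation", "n", "mean_A", "mean_E", "mean_z",
                "mean_fitness", "S_z")]
  print(utils::head(as.data.frame(lapply(show, signif, digits = 6)), 10),
        row.names = FALSE)
  if (nrow(r) > 10) cat(sprintf("... %d more generations\n", nrow(r) - 10))
  for (ev in x$events) cat("event:", ev, "\n")
  invisible(x)
}
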