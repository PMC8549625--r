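coarse_cfg <- make_fixture("coarse-model1")

test_that("the dense operator is column-stochastic over varied configs", {
  set.seed(3)
  g <- build_grid(0, 40, 20, 0, 40, 20)
  env <- environment_model(18, -0.5, 2)
  for (spec in list(genetic_spec(1, sigma_seg = 1),
                    genetic_spec(2, residual_var = 1.5),
                    genetic_spec(3, sigma_AA_target = 2),
                    genetic_spec(4))) {
    st <- gaussian_state(g, runif(1, 14, 22), 18, 2, 2, 0)
    post <- apply_selection(st, evaluate_fitness(
      fitness_spec("linear", beta0 = 5, beta_z = 0.05), g))
    op <- build_kernel(g, spec, env, 2, post)
    expect_equal(colSums(op$D), rep(1, g$n_cells), tolerance = 1e-12)
    expect_true(all(op$D >= 0))
  }
})

test_that("with a point-mass parent the kernel column is an outer product", {
  pm <- make_fixture("point-mass")
  g <- pm$grid
  spec <- genetic_spec(3, sigma_AA_target = 1)
  env <- environment_model(5, 0, 1)
  post <- apply_selection(pm, evaluate_fitness(fitness_spec("linear",
                                                            beta0 = 1), g))
  op <- build_kernel(g, spec, env, 2, post)
  nxt <- population_state(g, as.numeric(op$D %*% post$density), t = 2)
  pA <- offspring_A_distribution(post, spec)
  pE <- offspring_E_distribution(env, 2, post)
  outer_dens <- rep(pA, each = g$n_e) * rep(pE, times = g$n_a) * post$n
  expect_equal(nxt$density, outer_dens, tolerance = 1e-12)
})

test_that("grids beyond the dense guard are refused with a pointer to fast", {
  g <- build_grid(0, 40, 150, 0, 40, 150)
  st <- gaussian_state(g, 18, 18, 2, 2, 0)
  post <- apply_selection(st, evaluate_fitness(fitness_spec("linear",
                                                            beta0 = 1), g))
  expect_error(build_kernel(g, genetic_spec(3, sigma_AA_target = 2),
                            environment_model(18, 0, 2), 2, post),
               "fast")
})

test_that("full and fast engines agree to high precision", {
  # derived oracle: one step of each engine on the same inputs
  g <- build_grid(0, 40, 50, 0, 40, 50)
  st <- gaussian_state(g, 18, 18, 2, 2, 0)
  fit <- fitness_spec("linear", beta0 = -2.5, beta_z = 0.1,
                      negative_policy = "clamp")
  env <- environment_model(18, -0.5, 2)
  for (spec in list(genetic_spec(1, sigma_seg = 1),
                    genetic_spec(2, residual_var = 1.5),
                    genetic_spec(3, sigma_AA_target = 2),
                    genetic_spec(4))) {
    a <- step_full(st, fit, spec, env)
    b <- step_fast(st, fit, spec, env)
    expect_lt(state_l1(a, b), 1e-8)
    expect_equal(a$n, b$n, tolerance = 1e-12)
  }
})

test_that("engines stay equivalent across whole multi-generation runs", {
  for (name in c("coarse-model1", "coarse-model2")) {
    cfg <- make_fixture(name)
    cfg_full <- cfg
    cfg_full$run$engine <- "full"
    fast <- run_eeipm(cfg, store_states = TRUE)
    full <- run_eeipm(cfg_full, store_states = TRUE)
    l1 <- vapply(seq_along(fast$states), function(i)
      state_l1(fast$states[[i]], full$states[[i]]), numeric(1))
    expect_lt(max(l1), 1e-8)
  }
})

test_that("selection and inheritance do not commute", {
  g <- build_grid(0, 40, 50, 0, 40, 50)
  st <- gaussian_state(g, 18, 18, 2, 2, 0)
  fit <- fitness_spec("linear", beta0 = -2.5, beta_z = 0.1,
                      negative_policy = "clamp")
  spec <- genetic_spec(3, sigma_AA_target = 2)
  env <- environment_model(18, 0, 2)
  correct <- step_fast(st, fit, spec, env)
  # reversed order: inherit from the unselected parents, then select
  pA <- offspring_A_distribution(st, spec)
  pE <- offspring_E_distribution(env, 2, st)
  inherited <- population_state(
    g, rep(pA, each = g$n_e) * rep(pE, times = g$n_a) * st$n, t = 2)
  reversed <- suppressMessages(apply_selection(
    inherited, evaluate_fitness(fit, g)))
  expect_gt(state_l1(correct, reversed), 1e-3)
})

test_that("flat fitness scales the population and preserves the mean", {
  g <- build_grid(0, 40, 100, 0, 40, 100)
  st <- gaussian_state(g, 18, 18, 2, 2, 0, total_size = 3)
  fit <- fitness_spec("linear", beta0 = 1.7)
  env <- environment_model(18, 0, 2)
  nxt <- step_fast(st, fit, genetic_spec(3, sigma_AA_target = 2), env)
  expect_equal(nxt$n, 1.7 * st$n, tolerance = 1e-12)
  expect_equal(summarize_state(nxt)$mean_A, 18, tolerance = 1e-9)
  expect_equal(summarize_state(nxt)$mean_E, 18, tolerance = 1e-9)
  expect_equal(summarize_state(nxt)$var_A, 2, tolerance = 1e-3)
})

test_that("the fast engine refuses nongenetic inheritance", {
  g <- build_grid(0, 40, 50, 0, 40, 50)
  st <- gaussian_state(g, 18, 18, 2, 2, 0)
  env <- environment_model(18, 0, 2, nongenetic_fraction = 0.3)
  expect_error(step_fast(st, fitness_spec("linear", beta0 = 1),
                         genetic_spec(3, sigma_AA_target = 2), env),
               "step_full")
  # the full engine handles it
  nxt <- step_full(st, fitness_spec("linear", beta0 = 1),
                   genetic_spec(3, sigma_AA_target = 2), env,
                   max_cells = 2500)
  expect_equal(nxt$n, st$n, tolerance = 1e-12)
})

test_that("trajectories reproduce the two environments' mean-E dynamics", {
  m1 <- run_eeipm(make_fixture("coarse-model1"))
  m2 <- run_eeipm(make_fixture("coarse-model2"))
  expect_equal(m1$records$mean_E, rep(18, 5), tolerance = 1e-6)
  expect_equal(diff(m2$records$mean_E), rep(-0.5, 4), tolerance = 1e-6)
  # identical first generations make generation 2 coincide exactly;
  # divergence starts at generation 3 through mean fitness
  dA <- m2$records$mean_A - m1$records$mean_A
  expect_equal(dA[2], 0, tolerance = 1e-12)
  expect_true(all(dA[3:5] > 0))
  expect_true(all(m1$records$mean_z[2:5] > m2$records$mean_z[2:5]))
  # growth-rate law: mean fitness is the realized growth rate
  expect_equal(m1$records$mean_fitness[1:4],
               m1$records$n[2:5] / m1$records$n[1:4], tolerance = 1e-12)
})

test_that("per-generation records satisfy the quantitative-genetic identities", {
  tr <- run_eeipm(coarse_cfg)
  r <- tr$records
  expect_equal(r$var_z, r$var_A + r$var_E + 2 * r$cov_AE, tolerance = 1e-9)
  expect_equal(r$S_z, r$S_A + r$S_E, tolerance = 1e-12)
  expect_equal(r$delta_mean_A, r$heritability * r$S_z, tolerance = 1e-3)
  expect_true(all(r$heritability >= 0 & r$heritability <= 1))
})

test_that("extinction halts a run with a logged event", {
  cfg <- make_fixture("coarse-model1")
  cfg$fitness$beta0 <- 0
  cfg$fitness$beta_z <- 0  # flat zero fitness: everyone dies
  cfg$run$generations <- 5L
  expect_warning(tr <- run_eeipm(cfg), "extinct")
  expect_equal(nrow(tr$records), 1L)
  expect_match(tr$events, "extinction", all = FALSE)
})
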