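grid500 <- build_grid(0, 40, 500, 0, 40, 500)

# a generic postselection state: Gaussian state times a linear fitness
post_gaussian <- function(grid = grid500, mean_A = 18, var_A = 2) {
  st <- gaussian_state(grid, mean_A, 18, var_A, 2, 0)
  w <- evaluate_fitness(fitness_spec("linear", beta0 = -2.5, beta_z = 0.1,
                                     negative_policy = "clamp"), grid)
  suppressMessages(apply_selection(st, w))
}

marginal_mean <- function(p, mids) sum(p * mids)
marginal_var <- function(p, mids) sum(p * mids^2) - sum(p * mids)^2

test_that("mid-parent convolution matches brute-force enumeration", {
  g <- build_grid(0.5, 3.5, 3, 0.5, 3.5, 3)  # A mid-points 1, 2, 3
  # equal mass at A = 1 and A = 3: pairings (1,1), (1,3), (3,1), (3,3)
  q <- midpoint_convolution(c(0.5, 0, 0.5), g)
  oracle <- midparent_oracle(c(1, 3), c(0.5, 0.5))
  expect_equal(q, c(0.25, 0.5, 0.25))
  expect_equal(oracle$probs[match(g$a_mid, oracle$values)], q)

  # point mass maps to itself
  expect_equal(midpoint_convolution(c(0, 1, 0), g), c(0, 1, 0))
})

test_that("mid-parent convolution preserves the mean and halves variance", {
  post <- post_gaussian()
  p <- a_marginal(post) / post$n
  q <- midpoint_convolution(p, grid500)
  expect_equal(sum(q), 1)
  expect_equal(marginal_mean(q, grid500$a_mid),
               marginal_mean(p, grid500$a_mid), tolerance = 1e-10)
  ratio <- marginal_var(q, grid500$a_mid) / marginal_var(p, grid500$a_mid)
  expect_equal(ratio, 0.5, tolerance = 0.01)
})

test_that("the slope-0.5 kernel has the documented conditional structure", {
  spec <- genetic_spec(2, residual_var = 1.5)
  mean_As <- 20.3
  K <- approach2_kernel(spec, grid500, mean_As)
  expect_equal(colSums(K), rep(1, 500))
  cond_means <- as.numeric(crossprod(K, grid500$a_mid) / colSums(K))
  # passes through (A_bar_s, A_bar_s)
  j <- which.min(abs(grid500$a_mid - mean_As))
  expect_equal(cond_means[j], mean_As + 0.5 * (grid500$a_mid[j] - mean_As),
               tolerance = 1e-6)
  # least-squares slope of conditional means on parental A is 0.5
  slope <- coef(lm(cond_means ~ grid500$a_mid))[2]
  expect_equal(unname(slope), 0.5, tolerance = 1e-6)

  # zero residual variance degenerates to the nearest-cell map
  K0 <- approach2_kernel(genetic_spec(2, residual_var = 0), grid500, 20)
  expect_true(all(colSums(K0 > 0) == 1))
  hit <- apply(K0, 2, which.max)
  expect_equal(grid500$a_mid[hit],
               grid500$a_mid[
                 vapply(20 + 0.5 * (grid500$a_mid - 20),
                        function(m) which.min(abs(grid500$a_mid - m)), 1L)])
})

test_that("offspring variance follows each inheritance treatment", {
  post <- post_gaussian()
  p <- a_marginal(post) / post$n
  m_s <- marginal_mean(p, grid500$a_mid)
  v_s <- marginal_var(p, grid500$a_mid)

  q1 <- offspring_A_distribution(post, genetic_spec(1, sigma_seg = 1))
  expect_equal(marginal_mean(q1, grid500$a_mid), m_s, tolerance = 1e-6)
  expect_equal(marginal_var(q1, grid500$a_mid), v_s / 2 + 1, tolerance = 5e-3)

  q2 <- offspring_A_distribution(post, genetic_spec(2, residual_var = 1.5))
  expect_equal(marginal_mean(q2, grid500$a_mid), m_s, tolerance = 1e-6)
  expect_equal(marginal_var(q2, grid500$a_mid), 0.25 * v_s + 1.5,
               tolerance = 5e-3)

  q3 <- offspring_A_distribution(post, genetic_spec(3, sigma_AA_target = 2))
  expect_equal(marginal_mean(q3, grid500$a_mid), m_s, tolerance = 1e-9)
  expect_equal(marginal_var(q3, grid500$a_mid), 2, tolerance = 1e-6)

  q4 <- offspring_A_distribution(post, genetic_spec(4))
  expect_equal(marginal_mean(q4, grid500$a_mid), m_s, tolerance = 1e-6)
  expect_equal(marginal_var(q4, grid500$a_mid), v_s / 2, tolerance = 5e-3)

  # approach 4 is approach 1 without segregation variance
  q1z <- offspring_A_distribution(post, genetic_spec(1, sigma_seg = 0))
  expect_equal(q4, q1z)
})

test_that("every approach preserves the postselection mean on varied states", {
  set.seed(7)
  g <- build_grid(0, 40, 200, 0, 40, 200)
  specs <- list(genetic_spec(1, sigma_seg = 0.7),
                genetic_spec(2, residual_var = 1.2),
                genetic_spec(3, sigma_AA_target = 1.5),
                genetic_spec(4))
  for (rep in 1:4) {
    st <- gaussian_state(g, runif(1, 14, 22), runif(1, 14, 22),
                         runif(1, 0.8, 3), runif(1, 0.8, 3), 0)
    w <- evaluate_fitness(fitness_spec("linear", beta0 = 6,
                                       beta_z = runif(1, -0.1, 0.1)), g)
    post <- apply_selection(st, w)
    m_s <- marginal_mean(a_marginal(post) / post$n, g$a_mid)
    for (spec in specs) {
      q <- offspring_A_distribution(post, spec)
      expect_lt(abs(marginal_mean(q, g$a_mid) - m_s), 2 * g$da)
    }
  }
})

test_that("approaches 1 and 2 agree to two moments when matched", {
  post <- post_gaussian()
  p <- a_marginal(post) / post$n
  v_s <- marginal_var(p, grid500$a_mid)
  sigma_seg <- 0.9
  # matched conditional variance: 0.25 var_s + sigma_seg
  q1 <- offspring_A_distribution(post, genetic_spec(1, sigma_seg = sigma_seg))
  q2 <- offspring_A_distribution(
    post, genetic_spec(2, residual_var = 0.25 * v_s + sigma_seg))
  expect_equal(marginal_mean(q1, grid500$a_mid),
               marginal_mean(q2, grid500$a_mid), tolerance = 1e-6)
  expect_equal(marginal_var(q1, grid500$a_mid),
               marginal_var(q2, grid500$a_mid), tolerance = 5e-3)
})

test_that("a too-narrow grid triggers the boundary-mass error", {
  g <- build_grid(0, 4, 40, 0, 4, 40)
  st <- gaussian_state(g, 2, 2, 0.2, 0.2, 0)
  post <- apply_selection(st, evaluate_fitness(fitness_spec("linear",
                                                            beta0 = 1), g))
  expect_error(offspring_A_distribution(post, genetic_spec(1, sigma_seg = 9)),
               "outside")
  expect_error(offspring_A_distribution(post,
                                        genetic_spec(3, sigma_AA_target = 50)),
               "outside")
})
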