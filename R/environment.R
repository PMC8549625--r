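#' Specify the dynamics of the environmental component
#'
#' The offspring environmental component is shaped by three processes:
#' random developmental noise (mean-zero, constant variance `sigma_EE`), a
#' possibly trending environment that moves the mean of E each generation
#' (a reaction norm: every breeding value's expressed phenotype shifts
#' identically), and, optionally, nongenetic inheritance transmitting a
#' fraction `f` of the parental postselection E deviation to offspring.
#'
#' The start-of-generation mean is `E_bar(t) = mean0 + trend * (t - 1)`, so
#' the first generation has mean `mean0`. An explicit `theta_series` (one
#' value per generation) overrides the linear trend.
#'
#' @param mean0 mean environmental component at the first generation.
#' @param trend per-generation change in the mean (trait units/generation);
#'   0 for a constant environment, negative for a deteriorating one.
#' @param sigma_EE developmental-noise variance (constant over time).
#' @param nongenetic_fraction transmission fraction `f` in `[0, 1]`; 0 means
#'   pure developmental noise (offspring E independent of parents).
#' @param theta_series optional numeric vector of per-generation means.
#' @return An object of class `environment_model`.
#' @export
environment_model <- function(mean0, trend = 0, sigma_EE,
                              nongenetic_fraction = 0, theta_series = NULL) {
  if (!is.finite(sigma_EE) || sigma_EE < 0)
    stop("sigma_EE must be a non-negative number", call. = FALSE)
  f <- nongenetic_fraction
  if (!is.finite(f) || f < 0 || f > 1)
    stop("nongenetic_fraction must lie in [0, 1]", call. = FALSE)
  if (!is.null(theta_series) && !is.numeric(theta_series))
    stop("theta_series must be numeric", call. = FALSE)
  structure(list(mean0 = mean0, trend = trend, sigma_EE = sigma_EE,
                 nongenetic_fraction = f, theta_series = theta_series),
            class = "environment_model")
}

is_environment_model <- function(x) inherits(x, "environment_model")

#' Mean environmental component at a generation
#'
#' `E_bar(t) = mean0 + trend * (t - 1)`, or `theta_series[t]` when a series
#' is supplied.
#'
#' @param model an [environment_model()].
#' @param t generation index (>= 1).
#' @return scalar mean of E for generation `t`.
#' @export
environment_mean <- function(model, t) {
  if (!is_environment_model(model))
    stop("expected an 'environment_model'", call. = FALSE)
  t <- as.integer(t)
  if (any(is.na(t)) || any(t < 1L))
    stop("generation index t must be >= 1", call. = FALSE)
  if (!is.null(model$theta_series)) {
    if (any(t > length(model$theta_series)))
      stop("theta_series shorter than requested generation", call. = FALSE)
    return(model$theta_series[t])
  }
  model$mean0 + model$trend * (t - 1)
}

#' Offspring environmental-component distribution
#'
#' With `nongenetic_fraction = 0` (pure developmental noise) the offspring E
#' is independent of the parental cell: a discretized Gaussian over the E
#' mid-points with mean [environment_mean()] at the offspring generation and
#' variance `sigma_EE`, returned as a probability vector. This conditional
#' independence is what licenses the fast vector engine.
#'
#' With `f > 0` a conditional kernel is returned instead: one column per
#' parental E category, Gaussian with conditional mean
#' `environment_mean + f * (E_parent - E_bar_s)` (where `E_bar_s` is the
#' postselection mean of E) and variance `sigma_EE`, columns renormalized.
#'
#' @param model an [environment_model()].
#' @param t_next generation index of the offspring.
#' @param post_state postselection [population_state()] (required; supplies
#'   `E_bar_s` when `f > 0`).
#' @return probability vector over `e_mid` (`f = 0`) or an `n_e x n_e`
#'   column-stochastic matrix (`f > 0`).
#' @export
offspring_E_distribution <- function(model, t_next, post_state) {
  if (!is_environment_model(model))
    stop("expected an 'environment_model'", call. = FALSE)
  stopifnot_state(post_state)
  if (post_state$n <= 0) stop("postselection state has no mass", call. = FALSE)
  g <- post_state$grid
  m <- environment_mean(model, t_next)
  if (model$nongenetic_fraction == 0) {
    return(discretize_gaussian(g$e_mid, m, model$sigma_EE, g$de,
                               what = "offspring E distribution"))
  }
  pE <- e_marginal(post_state)
  mean_Es <- sum(g$e_mid * pE) / sum(pE)
  cond_mean <- m + model$nongenetic_fraction * (g$e_mid - mean_Es)
  vapply(cond_mean, function(mu)
    discretize_gaussian(g$e_mid, mu, model$sigma_EE, g$de, max_outside = 1,
                        what = "offspring E kernel column"),
    numeric(g$n_e))
}
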