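#' Build a mid-point mesh over (A, E) space
#'
#' Discretizes the plane of breeding values `A` and environmental components
#' `E` into `n_a * n_e` rectangular cells. Cell centres sit at
#' `a_min + (i - 0.5) * delta_a` (and likewise for E), the standard mid-point
#' rule used to approximate an integral projection kernel by a matrix.
#'
#' Flattened cell ordering is A-major with E varying fastest: the first `n_e`
#' elements of a flattened vector share the smallest A mid-point, the next
#' `n_e` the second A mid-point, and so on.
#'
#' @param a_min,a_max lower and upper integration limits for A (trait units).
#' @param n_a number of A categories (>= 1).
#' @param e_min,e_max lower and upper integration limits for E.
#' @param n_e number of E categories (>= 1).
#' @return An object of class `trait_grid`: a list with the limits, counts,
#'   cell widths `da`, `de`, mid-point sequences `a_mid`, `e_mid`, and the
#'   flattened length `n_cells = n_a * n_e`.
#' @examples
#' g <- build_grid(1, 10, 100, 1, 10, 100)
#' g$n_cells  # 10000
#' @export
build_grid <- function(a_min, a_max, n_a, e_min, e_max, n_e) {
  if (!is.numeric(a_min) || !is.numeric(a_max) || a_max <= a_min)
    stop("invalid A range: need a_max > a_min", call. = FALSE)
  if (!is.numeric(e_min) || !is.numeric(e_max) || e_max <= e_min)
    stop("invalid E range: need e_max > e_min", call. = FALSE)
  n_a <- as.integer(n_a); n_e <- as.integer(n_e)
  if (is.na(n_a) || n_a < 1L || is.na(n_e) || n_e < 1L)
    stop("category counts n_a and n_e must be integers >= 1", call. = FALSE)
  da <- (a_max - a_min) / n_a
  de <- (e_max - e_min) / n_e
  structure(list(
    a_min = a_min, a_max = a_max, n_a = n_a,
    e_min = e_min, e_max = e_max, n_e = n_e,
    da = da, de = de,
    a_mid = a_min + (seq_len(n_a) - 0.5) * da,
    e_mid = e_min + (seq_len(n_e) - 0.5) * de,
    n_cells = n_a * n_e
  ), class = "trait_grid")
}

#' @export
print.trait_grid <- function(x, ...) {
  cat(sprintf("trait_grid: A in [%g, %g] x %d, E in [%g, %g] x %d (%d cells)\n",
              x$a_min, x$a_max, x$n_a, x$e_min, x$e_max, x$n_e, x$n_cells))
  invisible(x)
}

is_trait_grid <- function(x) inherits(x, "trait_grid")

stopifnot_grid <- function(grid) {
  if (!is_trait_grid(grid)) stop("expected a 'trait_grid' object", call. = FALSE)
  invisible(grid)
}

#' Per-cell breeding values and environmental components
#'
#' Return the A (or E) mid-point of every flattened cell, in flattened
#' (A-major, E-fastest) order.
#'
#' @param grid a [build_grid()] mesh.
#' @return numeric vector of length `grid$n_cells`.
#' @export
grid_cell_A <- function(grid) {
  stopifnot_grid(grid)
  rep(grid$a_mid, each = grid$n_e)
}

#' @rdname grid_cell_A
#' @export
grid_cell_E <- function(grid) {
  stopifnot_grid(grid)
  rep(grid$e_mid, times = grid$n_a)
}

#' Phenotype value of every grid cell
#'
#' The phenotype is the sum of the breeding value and the environmental
#' component, `z = A + E`; two cells with equal `A + E` carry the same
#' phenotype (and later the same fitness).
#'
#' @param grid a [build_grid()] mesh.
#' @return numeric vector of per-cell `z` in flattened order.
#' @export
phenotype_values <- function(grid) {
  grid_cell_A(grid) + grid_cell_E(grid)
}

#' Reshape a flattened state vector to an E-by-A matrix (and back)
#'
#' The matrix form has one row per E mid-point and one column per A
#' mid-point; `flatten_state_matrix(unflatten_state(x, grid))` is the
#' identity.
#'
#' @param x flattened density vector of length `grid$n_cells`.
#' @param grid the mesh the vector lives on.
#' @return `unflatten_state`: an `n_e x n_a` matrix. `flatten_state_matrix`:
#'   a vector in flattened order.
#' @export
unflatten_state <- function(x, grid) {
  stopifnot_grid(grid)
  if (length(x) != grid$n_cells)
    stop("state vector length does not match grid", call. = FALSE)
  matrix(x, nrow = grid$n_e, ncol = grid$n_a,
         dimnames = list(E = NULL, A = NULL))
}

#' @rdname unflatten_state
#' @param m an `n_e x n_a` matrix.
#' @export
flatten_state_matrix <- function(m) as.vector(m)
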