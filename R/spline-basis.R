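#' Build a penalized-spline basis over an age range
#'
#' Places `n_knots` knot positions evenly over `[min(ages), max(ages)]`,
#' repeats the boundary knots `degree + 1` times, and evaluates the B-spline
#' basis and its analytic first derivative at the supplied ages via
#' [splines::splineDesign()]. With this construction the basis has
#' `K = n_knots + degree - 1` columns, every design row sums to 1
#' (partition of unity) and every derivative row sums to 0.
#'
#' @param ages Evaluation ages (years); must span a positive range.
#' @param n_knots Number of knot positions (default 19).
#' @param degree Spline degree (default 3, cubic).
#' @return An object of class `spline_basis`: list with `knots` (the full
#'   knot vector), `inner_knots`, `degree`, `design_matrix`
#'   (`length(ages) x K`), `derivative_matrix` (same shape) and `ages`.
#' @export
build_basis <- function(ages, n_knots = 19L, degree = 3L) {
  stopifnot(length(ages) >= 1, all(is.finite(ages)))
  if (n_knots < degree + 1) stop("need n_knots >= degree + 1")
  rng <- range(ages)
  if (diff(rng) <= 0) stop("ages span a degenerate (zero-width) range")
  inner <- seq(rng[1], rng[2], length.out = n_knots)
  knots <- c(rep(rng[1], degree), inner, rep(rng[2], degree))
  ord <- degree + 1L
  basis <- list(
    knots = knots, inner_knots = inner, degree = as.integer(degree),
    ages = as.numeric(ages),
    design_matrix = splines::splineDesign(knots, ages, ord = ord,
                                          outer.ok = FALSE),
    derivative_matrix = if (degree == 0) {
      matrix(0, length(ages), n_knots - 1)   # piecewise constant: slope 0
    } else {
      splines::splineDesign(knots, ages, ord = ord, derivs = 1,
                            outer.ok = FALSE)
    })
  class(basis) <- "spline_basis"
  basis
}

#' Evaluate an existing basis at new ages
#'
#' @param basis A `spline_basis`.
#' @param ages New evaluation ages; must lie within the knot range
#'   (no extrapolation).
#' @param derivs Derivative order (0 = the basis itself, 1 = d/d age).
#' @return Matrix of basis evaluations, `length(ages) x K`.
#' @export
eval_basis <- function(basis, ages, derivs = 0L) {
  stopifnot(inherits(basis, "spline_basis"))
  rng <- range(basis$inner_knots)
  if (any(ages < rng[1] - 1e-9 | ages > rng[2] + 1e-9)) {
    stop("ages outside the knot range [", signif(rng[1], 4), ", ",
         signif(rng[2], 4), "]; spline extrapolation is not supported")
  }
  ages <- pmin(pmax(ages, rng[1]), rng[2])
  splines::splineDesign(basis$knots, ages, ord = basis$degree + 1L,
                        derivs = derivs, outer.ok = FALSE)
}

# Difference-penalty matrix: rows are order-`order` differences of the
# coefficient vector (the P-spline random-walk penalty).
difference_matrix <- function(K, order = 2L) {
  D <- diag(K)
  for (i in seq_len(order)) D <- diff(D)
  D
}
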