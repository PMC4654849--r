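#' The Ishigami benchmark function
#'
#' \deqn{f(\xi) = \sin(\xi_1) + a \sin^2(\xi_2) + b\, \xi_3^4 \sin(\xi_1),}
#' with each \eqn{\xi_i} uniform on \eqn{[-\pi, \pi]}. A standard
#' benchmark for variance-based sensitivity analysis: strongly
#' non-linear, non-monotonic, with one pure interaction (between
#' \eqn{\xi_1} and \eqn{\xi_3}) and all its variance components known in
#' closed form. Defaults `a = 7`, `b = 0.1`.
#'
#' @param x Numeric vector of length 3 (or a 3-column matrix of points).
#' @param a,b Amplitudes of the \eqn{\sin^2} and quartic coupling terms.
#' @return Scalar (or vector, for matrix input).
#' @examples
#' ishigami(c(pi / 2, pi / 2, 0))  # 1 + 7
#' @export
ishigami <- function(x, a = 7, b = 0.1) {
  if (is.null(dim(x))) {
    if (length(x) != 3) stop("the Ishigami function takes 3 coordinates")
    x <- matrix(x, 1, 3)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3) stop("the Ishigami function takes 3 coordinates")
  as.numeric(sin(x[, 1]) + a * sin(x[, 2])^2 + b * x[, 3]^4 * sin(x[, 1]))
}

#' Parameter space of the Ishigami function
#'
#' Three independent uniform inputs on \eqn{[-\pi, \pi]}.
#' @return A [parameter_space()].
#' @export
ishigami_space <- function() {
  parameter_space(c("x1", "x2", "x3"), rep(-pi, 3), rep(pi, 3))
}

#' Closed-form statistics of the Ishigami function
#'
#' Exact mean, variance and all Sobol' indices under independent uniform
#' inputs on \eqn{[-\pi,\pi]^3}:
#' \deqn{Var = \frac{1}{2} + \frac{a^2}{8} + \frac{b\pi^4}{5}
#'   + \frac{b^2\pi^8}{18},}
#' with first-order variance components
#' \eqn{V_1 = \frac{1}{2}(1 + b\pi^4/5)^2}, \eqn{V_2 = a^2/8},
#' \eqn{V_3 = 0}, and the single interaction component
#' \eqn{V_{13} = 8 b^2 \pi^8 / 225}. All other components vanish.
#'
#' @param a,b Function parameters.
#' @return List with `mean`, `variance`, and named Sobol' indices `S1`,
#'   `S2`, `S3`, `S12`, `S13`, `S23`, `S123`.
#' @examples
#' round(unlist(ishigami_exact_stats()), 2)
#' @export
ishigami_exact_stats <- function(a = 7, b = 0.1) {
  V1 <- (1 + b * pi^4 / 5)^2 / 2
  V2 <- a^2 / 8
  V13 <- 8 * b^2 * pi^8 / 225
  V <- V1 + V2 + V13
  list(mean = a / 2, variance = V,
       S1 = V1 / V, S2 = V2 / V, S3 = 0,
       S12 = 0, S13 = V13 / V, S23 = 0, S123 = 0)
}

#' Additive two-parameter polynomial test function
#'
#' \eqn{f(\xi) = \xi_1 + 2 \xi_2} on the reference cube, with exact
#' variance components \eqn{V_1 = 1/3}, \eqn{V_2 = 4/3}; hence
#' \eqn{S_1 = 0.2}, \eqn{S_2 = 0.8} and no interaction. A permanent
#' exact, fast fixture for the Sobol' machinery.
#'
#' @param x Length-2 vector (or 2-column matrix) on \eqn{[-1,1]^2}.
#' @return Scalar (or vector).
#' @export
additive_poly <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  x <- as.matrix(x)
  if (ncol(x) != 2) stop("additive_poly takes 2 coordinates")
  as.numeric(x[, 1] + 2 * x[, 2])
}

#' Run the full Ishigami validation of the GSA engine
#'
#' Reproduces the engine's reliability study on the Ishigami function:
#' for each requested number of quadrature points it builds the tensor
#' design, evaluates the function, and runs a [convergence_sweep()] up to
#' `p_hat_max`, tracking the six subsets S1, S2, S13, S3, S12, S23.
#'
#' @param Nq_values Integer vector of quadrature points per dimension.
#' @param p_hat_max Largest truncation order per sweep.
#' @param a,b Ishigami parameters.
#' @param ... Tolerances passed to [convergence_sweep()].
#' @return List with `sweeps` (one [convergence_sweep()] per `Nq`, named
#'   `"Nq<value>"`), `table` (row-bound convergence rows across all
#'   `Nq`), and `exact` ([ishigami_exact_stats()]).
#' @export
ishigami_validation <- function(Nq_values = c(2, 5, 8, 10), p_hat_max = 15,
                                a = 7, b = 0.1, ...) {
  space <- ishigami_space()
  track <- list(1L, 2L, c(1L, 3L), 3L, c(1L, 2L), c(2L, 3L))
  sweeps <- lapply(Nq_values, function(nq) {
    d <- build_design(space, nq)
    y <- ishigami(d$points, a = a, b = b)
    convergence_sweep(d, y, p_hat_max = p_hat_max, subsets = track, ...)
  })
  names(sweeps) <- paste0("Nq", Nq_values)
  list(sweeps = sweeps,
       table = do.call(rbind, lapply(sweeps, `[[`, "table")),
       exact = ishigami_exact_stats(a, b))
}
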