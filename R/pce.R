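#' Evaluate an unnormalized Legendre polynomial
#'
#' Standard Legendre polynomials \eqn{P_k} on \eqn{[-1,1]} (so
#' \eqn{P_0 \equiv 1}, \eqn{P_1(x) = x}), evaluated by the stable
#' three-term recurrence
#' \eqn{k P_k(x) = (2k-1) x P_{k-1}(x) - (k-1) P_{k-2}(x)}.
#' Under the uniform density on \eqn{[-1,1]} their squared norm is
#' \eqn{1/(2k+1)}; the basis is deliberately kept unnormalized with the
#' norm constants tracked explicitly.
#'
#' @param order Polynomial order, a non-negative integer.
#' @param x Numeric vector of evaluation points in \eqn{[-1,1]}.
#' @return Numeric vector `P_order(x)`.
#' @examples
#' legendre_eval(2, 1)  # (3x^2 - 1)/2 at x = 1
#' @export
legendre_eval <- function(order, x) {
  if (length(order) != 1L || order < 0 || order != round(order))
    stop("'order' must be a non-negative integer")
  x <- as.numeric(x)
  if (order == 0) return(rep(1, length(x)))
  if (order == 1) return(x)
  pm1 <- rep(1, length(x))
  p <- x
  for (k in 2:order) {
    pn <- ((2 * k - 1) * x * p - (k - 1) * pm1) / k
    pm1 <- p
    p <- pn
  }
  p
}

#' Total-degree multi-index basis for a polynomial chaos expansion
#'
#' Enumerates all n-tuples of univariate Legendre orders with total degree
#' at most `p_hat`. The number of terms is
#' \eqn{(n+\hat p)! / (n!\, \hat p!)}. Terms are listed in graded
#' lexicographic order: ascending total degree, ties broken by ascending
#' lexicographic comparison of the tuple (dimension 1 most significant),
#' so the constant term comes first and the terms of degree at most
#' \eqn{p < \hat p} always form a prefix.
#'
#' @param n Dimension (number of parameters), at least 1.
#' @param p_hat Maximum total degree (approximation order), at least 0.
#' @return An object of class `pce_basis`: list with `n`, `p_hat`,
#'   `indices` (integer matrix, one row per term) and `norms_sq`
#'   (squared norms \eqn{\prod_k 1/(2\,\mathrm{index}(i,k)+1)} under the
#'   uniform density).
#' @examples
#' total_degree_basis(3, 2)$indices  # 10 terms
#' @export
total_degree_basis <- function(n, p_hat) {
  if (length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer")
  if (length(p_hat) != 1L || p_hat < 0 || p_hat != round(p_hat))
    stop("'p_hat' must be a non-negative integer")
  n <- as.integer(n); p_hat <- as.integer(p_hat)
  idx <- as.matrix(expand.grid(rep(list(0:p_hat), n)))
  dimnames(idx) <- NULL
  idx <- idx[rowSums(idx) <= p_hat, , drop = FALSE]
  ord <- do.call(order, c(list(rowSums(idx)),
                          lapply(seq_len(n), function(k) idx[, k])))
  idx <- idx[ord, , drop = FALSE]
  storage.mode(idx) <- "integer"
  norms_sq <- apply(idx, 1, function(m) prod(1 / (2 * m + 1)))
  structure(list(n = n, p_hat = p_hat, indices = idx, norms_sq = norms_sq),
            class = "pce_basis")
}

#' @export
print.pce_basis <- function(x, ...) {
  cat("Total-degree Legendre basis: n =", x$n, ", p_hat =", x$p_hat,
      ",", nrow(x$indices), "terms\n")
  invisible(x)
}

# Basis evaluation matrix at the design's unit points: one column per term.
# Uses the per-dimension node table so each univariate polynomial is
# evaluated only Nq times.
.basis_matrix <- function(design, basis) {
  if (basis$n != design$space$n)
    stop("basis dimension (", basis$n, ") does not match the design (",
         design$space$n, ")")
  p_hat <- basis$p_hat
  # P[k+1, l] = P_k(node_l)
  P <- vapply(seq_along(design$unit_nodes),
              function(l) vapply(0:p_hat, function(k)
                legendre_eval(k, design$unit_nodes[l]), numeric(1)),
              numeric(p_hat + 1))
  P <- matrix(P, nrow = p_hat + 1)
  m <- nrow(design$node_index)
  N <- nrow(basis$indices)
  Phi <- matrix(1, m, N)
  for (i in seq_len(N)) {
    for (k in seq_len(basis$n)) {
      o <- basis$indices[i, k]
      if (o > 0) Phi[, i] <- Phi[, i] * P[o + 1, design$node_index[, k]]
    }
  }
  Phi
}

.check_alignment <- function(design, samples) {
  samples <- as.numeric(samples)
  if (length(samples) != nrow(design$points))
    stop("got ", length(samples), " samples for ", nrow(design$points),
         " design points; samples must follow the design enumeration order")
  if (any(!is.finite(samples))) stop("samples contain non-finite values")
  samples
}

#' Fit a polynomial chaos expansion by spectral projection
#'
#' Computes one expansion coefficient per basis term as the
#' quadrature-weighted inner product of the samples with the basis
#' polynomial, divided by the term's squared norm:
#' \eqn{u_i = \langle u, \Phi_i\rangle / \|\Phi_i\|^2}, with the inner
#' product approximated by the design's tensor Gauss-Legendre rule. The
#' samples must be aligned with the design's enumeration order (see
#' [build_design()]).
#'
#' @param design A [build_design()] object.
#' @param samples Numeric vector, one scalar output per design point.
#' @param basis A [total_degree_basis()] with the design's dimension.
#' @return An object of class `pce_model`: list with `basis`,
#'   `coefficients`, `space`, `design_Nq` and the data moments of the
#'   samples (`mean_data`, `var_data`).
#' @export
spectral_projection <- function(design, samples, basis) {
  stopifnot(inherits(design, "quadrature_design"), inherits(basis, "pce_basis"))
  samples <- .check_alignment(design, samples)
  Phi <- .basis_matrix(design, basis)
  u <- as.numeric(crossprod(Phi, design$weights * samples)) / basis$norms_sq
  dm <- data_moments(design, samples)
  structure(list(basis = basis, coefficients = u, space = design$space,
                 design_Nq = design$Nq,
                 mean_data = dm$mean, var_data = dm$var),
            class = "pce_model")
}

#' @export
print.pce_model <- function(x, ...) {
  m <- pce_moments(x)
  cat("Polynomial chaos expansion: n =", x$basis$n, ", p_hat =",
      x$basis$p_hat, "(", length(x$coefficients), "terms )\n")
  cat(sprintf("  mean = %.6g   Var_PCE = %.6g   Var_data = %.6g\n",
              m$mean, m$variance, x$var_data))
  invisible(x)
}

#' Mean and variance of a fitted polynomial chaos expansion
#'
#' The mean is the constant coefficient \eqn{u_0}; the variance is
#' \eqn{\mathrm{Var}_{PCE} = \sum_{i\ge 1} u_i^2 \|\Phi_i\|^2}, which is
#' non-negative and non-decreasing in the truncation order for fixed
#' samples.
#'
#' @param model A [spectral_projection()] fit.
#' @return List with `mean` and `variance`.
#' @export
pce_moments <- function(model) {
  stopifnot(inherits(model, "pce_model"))
  u <- model$coefficients
  nrm <- model$basis$norms_sq
  list(mean = u[1], variance = sum(u[-1]^2 * nrm[-1]))
}

#' Quadrature-weighted moments of the raw samples
#'
#' First and second moments of the sampled output under the design's
#' product weights: \eqn{\mu_{data} = \sum_l w_l u_l} and
#' \eqn{\mathrm{Var}_{data} = \sum_l w_l u_l^2 - \mu_{data}^2}. These are
#' the reference values against which the PCE variance is checked by the
#' convergence diagnostic.
#'
#' @param design A [build_design()] object.
#' @param samples Numeric vector aligned with the design.
#' @return List with `mean` and `var`.
#' @export
data_moments <- function(design, samples) {
  stopifnot(inherits(design, "quadrature_design"))
  samples <- .check_alignment(design, samples)
  mu <- sum(design$weights * samples)
  list(mean = mu, var = max(0, sum(design$weights * samples^2) - mu^2))
}

#' Variance mismatch between data and PCE
#'
#' The signed difference
#' \eqn{err_{Var} = \mathrm{Var}_{data} - \mathrm{Var}_{PCE}}, reported
#' together with its relative magnitude
#' \eqn{|err_{Var}| / \mathrm{Var}_{data}} when the data variance is
#' positive. A small mismatch, together with Sobol' indices that are
#' stable across truncation orders, signals a trustworthy analysis.
#'
#' @param var_data Quadrature-weighted sample variance.
#' @param var_pce PCE variance from the same design and samples.
#' @return List with `err_var` and `rel_err_var` (`NA` when
#'   `var_data` is 0).
#' @export
err_var <- function(var_data, var_pce) {
  e <- var_data - var_pce
  list(err_var = e,
       rel_err_var = if (var_data > 0) abs(e) / var_data else NA_real_)
}
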