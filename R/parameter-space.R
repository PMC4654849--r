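#' Define a space of independently, uniformly distributed parameters
#'
#' A `parameter_space` holds the names and physical ranges of the varying
#' model parameters and provides the affine map between physical units and
#' the reference cube \eqn{[-1, 1]^n} on which the Legendre polynomial
#' chaos basis is orthogonal. Each parameter is treated as an independent
#' uniform random variable over its range.
#'
#' @param names Character vector of parameter identifiers.
#' @param lower,upper Numeric vectors of physical range bounds, one entry
#'   per parameter, with `lower < upper` elementwise.
#'
#' @return An object of class `parameter_space` with fields `names`,
#'   `lower`, `upper` and `n` (the dimension).
#'
#' @examples
#' sp <- parameter_space(c("lambda_c", "D"), c(10, 1e-14), c(3000, 5e-13))
#' from_unit(sp, matrix(0, 1, 2))   # physical midpoints
#' @export
parameter_space <- function(names, lower, upper) {
  names <- as.character(names)
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  n <- length(names)
  if (n < 1L) stop("a parameter space needs at least one parameter")
  if (length(lower) != n || length(upper) != n)
    stop("'lower' and 'upper' must have one entry per parameter")
  if (anyDuplicated(names)) stop("parameter names must be unique")
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("range bounds must be finite")
  if (any(lower >= upper)) stop("every range must satisfy lower < upper")
  structure(list(names = names, lower = lower, upper = upper, n = n),
            class = "parameter_space")
}

#' @export
print.parameter_space <- function(x, ...) {
  cat("Parameter space (", x$n, " independent uniform parameter",
      if (x$n > 1) "s", "):\n", sep = "")
  for (k in seq_len(x$n))
    cat(sprintf("  %-12s [%g, %g]\n", x$names[k], x$lower[k], x$upper[k]))
  invisible(x)
}

#' Map points between physical units and the reference cube
#'
#' `from_unit()` maps coordinates on the reference cube \eqn{[-1,1]^n} to
#' physical units; `to_unit()` is its inverse. The two are exact affine
#' inverses of one another up to floating-point round-off.
#'
#' @param space A [parameter_space()].
#' @param x A numeric matrix with one column per parameter (a vector is
#'   taken as a single point).
#' @return A matrix of the same shape in the other coordinate system.
#' @export
from_unit <- function(space, x) {
  x <- .as_point_matrix(space, x)
  lo <- matrix(space$lower, nrow(x), space$n, byrow = TRUE)
  hi <- matrix(space$upper, nrow(x), space$n, byrow = TRUE)
  out <- lo + (x + 1) / 2 * (hi - lo)
  colnames(out) <- space$names
  out
}

#' @rdname from_unit
#' @export
to_unit <- function(space, x) {
  x <- .as_point_matrix(space, x)
  lo <- matrix(space$lower, nrow(x), space$n, byrow = TRUE)
  hi <- matrix(space$upper, nrow(x), space$n, byrow = TRUE)
  out <- 2 * (x - lo) / (hi - lo) - 1
  colnames(out) <- space$names
  out
}

.as_point_matrix <- function(space, x) {
  if (is.null(dim(x))) x <- matrix(as.numeric(x), nrow = 1)
  x <- as.matrix(x)
  if (ncol(x) != space$n)
    stop("expected ", space$n, " coordinates per point, got ", ncol(x))
  storage.mode(x) <- "double"
  x
}
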