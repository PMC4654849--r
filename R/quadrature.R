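#' One-dimensional Gauss-Legendre rule, normalized to the uniform density
#'
#' Returns the `Nq` Gauss-Legendre nodes on \eqn{[-1, 1]} together with
#' weights rescaled to the uniform probability density \eqn{1/2}, so that
#' the weights sum to one and weighted sums approximate expectations
#' \eqn{E[f(\xi)]} of a uniform variable on \eqn{[-1,1]}. The rule
#' integrates polynomials up to degree \eqn{2 N_q - 1} exactly.
#'
#' @param Nq Number of quadrature points, a positive integer.
#' @return A list with numeric vectors `nodes` (ascending, symmetric about
#'   zero) and `weights` (positive, summing to one).
#' @examples
#' gauss_legendre_rule(2)  # nodes +-1/sqrt(3), weights 1/2 each
#' @export
gauss_legendre_rule <- function(Nq) {
  if (length(Nq) != 1L || !is.finite(Nq) || Nq < 1 || Nq != round(Nq))
    stop("'Nq' must be a positive integer")
  Nq <- as.integer(Nq)
  if (Nq == 1L) return(list(nodes = 0, weights = 1))
  g <- pracma::gaussLegendre(Nq, -1, 1)
  ord <- order(g$x)
  nodes <- g$x[ord]
  # enforce exact symmetry of the abscissae about zero
  nodes <- (nodes - rev(nodes)) / 2
  w <- g$w[ord] / 2
  w <- (w + rev(w)) / 2
  list(nodes = nodes, weights = w / sum(w))
}

#' Build a tensor Gauss-Legendre design over a parameter space
#'
#' Constructs the full tensor product of a one-dimensional Gauss-Legendre
#' rule over the reference cube and maps each node to physical parameter
#' units. The design carries product weights normalized to the joint
#' uniform density, so weighted sums over the design approximate
#' expectations over the parameter space.
#'
#' Enumeration order contract: points are enumerated with the *first*
#' parameter varying fastest (odometer order over per-dimension node
#' indices, dimension 1 least significant), nodes ascending within each
#' dimension. Sample vectors passed to [spectral_projection()] and
#' [data_moments()] must follow this order; [write_design()] exports it.
#'
#' @param space A [parameter_space()].
#' @param Nq Quadrature points per dimension.
#' @param point_cap Refuse designs with more than this many points
#'   (guards against accidental combinatorial explosion).
#' @return An object of class `quadrature_design`: list with `space`,
#'   `Nq`, `unit_nodes`, `unit_weights`, `unit_points` (matrix, reference
#'   cube), `points` (matrix, physical units), `weights` (product
#'   weights, summing to one) and `node_index` (matrix of per-dimension
#'   node indices).
#' @examples
#' sp <- parameter_space("lambda_c", 10, 3000)
#' build_design(sp, 3)$points
#' @export
build_design <- function(space, Nq, point_cap = 1e6) {
  stopifnot(inherits(space, "parameter_space"))
  rule <- gauss_legendre_rule(Nq)
  Nq <- as.integer(Nq)
  n_points <- Nq^space$n
  if (n_points > point_cap)
    stop("design would contain ", n_points, " points, above the cap of ",
         point_cap, "; raise 'point_cap' explicitly if this is intended")
  # odometer enumeration, dimension 1 fastest
  idx <- as.matrix(expand.grid(rep(list(seq_len(Nq)), space$n)))
  dimnames(idx) <- list(NULL, space$names)
  unit_points <- matrix(rule$nodes[idx], nrow(idx), space$n)
  colnames(unit_points) <- space$names
  weights <- apply(matrix(rule$weights[idx], nrow(idx), space$n), 1, prod)
  structure(list(space = space, Nq = Nq,
                 unit_nodes = rule$nodes, unit_weights = rule$weights,
                 unit_points = unit_points,
                 points = from_unit(space, unit_points),
                 weights = weights, node_index = idx),
            class = "quadrature_design")
}

#' @export
print.quadrature_design <- function(x, ...) {
  cat("Tensor Gauss-Legendre design: ", x$Nq, " points/dimension, ",
      nrow(x$points), " points over ", x$space$n, " parameter",
      if (x$space$n > 1) "s", "\n", sep = "")
  print(x$space)
  invisible(x)
}

#' Evaluate a black-box function over a quadrature design
#'
#' Convenience helper applying `f` row-wise to the physical design points,
#' in the design's enumeration order.
#'
#' @param design A [build_design()] object.
#' @param f Function taking one numeric parameter vector, returning a scalar.
#' @param unit If `TRUE`, pass reference-cube coordinates instead of
#'   physical ones.
#' @return Numeric vector of samples aligned with the design.
#' @export
evaluate_design <- function(design, f, unit = FALSE) {
  stopifnot(inherits(design, "quadrature_design"))
  pts <- if (unit) design$unit_points else design$points
  vapply(seq_len(nrow(pts)), function(i) as.numeric(f(pts[i, ])), numeric(1))
}

#' Export / import a quadrature design as CSV
#'
#' One row per design point: point index, unit coordinates (`u_<name>`),
#' physical coordinates (`<name>`), and the product weight.
#'
#' @param design A [build_design()] object.
#' @param path File path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns a data frame in enumeration order.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "quadrature_design"))
  u <- design$unit_points
  colnames(u) <- paste0("u_", design$space$names)
  df <- data.frame(point = seq_len(nrow(u)), u, design$points,
                   weight = design$weights, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  df[order(df$point), , drop = FALSE]
}

#' Read per-point output samples keyed by point index
#'
#' Reads a CSV with a `point` column plus one column per output measure
#' and returns the measure columns reordered to the design enumeration
#' order (ascending point index).
#'
#' @param path File path.
#' @return A data frame of measure columns, one row per design point.
#' @export
read_samples <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"point" %in% names(df)) stop("samples file needs a 'point' column")
  df <- df[order(df$point), , drop = FALSE]
  df[, setdiff(names(df), "point"), drop = FALSE]
}
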