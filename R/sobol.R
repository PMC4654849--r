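# Subset bookkeeping: each basis term is assigned the set of its active
# dimensions (univariate order > 0); a Sobol' index for subset J sums the
# variance contributions u_i^2 ||Phi_i||^2 of exactly the terms whose
# active set equals J.

.term_active <- function(indices) {
  apply(indices > 0, 1, function(a) which(a), simplify = FALSE)
}

.dims_key <- function(dims) paste(dims, collapse = ",")

.all_subsets <- function(n) {
  if (n > 16) stop("refusing to enumerate all subsets for n > 16")
  out <- list()
  for (sz in seq_len(n)) out <- c(out, utils::combn(n, sz, simplify = FALSE))
  out
}

.normalize_subsets <- function(subsets, space_names, n) {
  if (identical(subsets, "all")) return(.all_subsets(n))
  if (!is.list(subsets)) subsets <- list(subsets)
  lapply(subsets, function(s) {
    if (is.character(s)) {
      pos <- match(s, space_names)
      if (anyNA(pos)) stop("unknown parameter name(s): ",
                           paste(s[is.na(pos)], collapse = ", "))
      s <- pos
    }
    s <- sort(unique(as.integer(s)))
    if (length(s) < 1 || any(s < 1) || any(s > n))
      stop("subsets must be non-empty sets of dimensions in 1..", n)
    s
  })
}

#' Sobol' sensitivity indices from a polynomial chaos expansion
#'
#' Decomposes the PCE variance into contributions of parameter subsets.
#' For a subset J the index is the sum of \eqn{u_i^2 \|\Phi_i\|^2} over
#' exactly those basis terms whose set of active dimensions equals J,
#' divided by the total PCE variance. First-order indices correspond to
#' singleton subsets; over all non-empty subsets the indices sum to one.
#'
#' @param model A [spectral_projection()] fit with positive variance.
#' @param subsets `"all"` (every non-empty subset of the dimensions) or a
#'   list of subsets, each given as parameter names or dimension indices.
#' @return An object of class `sobol_result`: list with `indices` (data
#'   frame with columns `subset` — parameter names joined by `:` —,
#'   `dims`, `order`, `index`), `variance_pce`, `var_data`, `err_var`,
#'   `rel_err_var`, and `total` (named vector of total indices per
#'   parameter, i.e. the sum over all reported subsets containing it).
#' @examples
#' sp <- parameter_space(c("x1", "x2"), c(-1, -1), c(1, 1))
#' d <- build_design(sp, 3)
#' y <- evaluate_design(d, function(p) p[1] + 2 * p[2])
#' fit <- spectral_projection(d, y, total_degree_basis(2, 2))
#' sobol_indices(fit)$indices  # S1 = 0.2, S2 = 0.8
#' @export
sobol_indices <- function(model, subsets = "all") {
  stopifnot(inherits(model, "pce_model"))
  n <- model$basis$n
  nms <- model$space$names
  subs <- .normalize_subsets(subsets, nms, n)
  contrib <- model$coefficients^2 * model$basis$norms_sq
  active <- .term_active(model$basis$indices)
  var_pce <- sum(contrib[-1])
  if (var_pce <= 0)
    stop("PCE variance is zero (constant output); Sobol' indices undefined")
  key <- vapply(active, .dims_key, character(1))
  sums <- tapply(contrib, key, sum)
  vals <- vapply(subs, function(s) {
    v <- sums[match(.dims_key(s), names(sums))]
    if (is.na(v)) 0 else as.numeric(v)
  }, numeric(1)) / var_pce
  df <- data.frame(
    subset = vapply(subs, function(s) paste(nms[s], collapse = ":"),
                    character(1)),
    dims = vapply(subs, .dims_key, character(1)),
    order = lengths(subs),
    index = vals,
    stringsAsFactors = FALSE)
  total <- vapply(seq_len(n), function(k)
    sum(df$index[vapply(subs, function(s) k %in% s, logical(1))]),
    numeric(1))
  names(total) <- nms
  ev <- err_var(model$var_data, var_pce)
  structure(list(indices = df, variance_pce = var_pce,
                 var_data = model$var_data,
                 err_var = ev$err_var, rel_err_var = ev$rel_err_var,
                 total = total),
            class = "sobol_result")
}

#' @export
print.sobol_result <- function(x, digits = 4, ...) {
  cat(sprintf("Sobol' indices (Var_PCE = %.6g, Var_data = %.6g, err_Var = %.3g)\n",
              x$variance_pce, x$var_data, x$err_var))
  df <- x$indices[order(x$indices$order, -x$indices$index), ]
  for (i in seq_len(nrow(df)))
    cat(sprintf("  S(%s) = %.*f\n", df$subset[i], digits, df$index[i]))
  invisible(x)
}

#' Convergence sweep over truncation orders with a reliability flag
#'
#' Re-uses one set of samples on a fixed design to fit polynomial chaos
#' expansions of every order \eqn{\hat p = 1 \ldots \hat p_{max}} and
#' tabulates, per order, the data variance, the PCE variance, the
#' variance mismatch and the tracked Sobol' indices. An order is *stable*
#' when the relative variance mismatch `|err_Var|/Var_data` is below
#' `tol_var_rel` *and* no tracked index moved by more than `tol_sobol`
#' from the previous order. The `converged` flag marks orders belonging
#' to a run of at least `run_length` consecutive stable orders; the
#' recommended order is the smallest flagged one. An all-`FALSE` flag
#' column is a valid outcome meaning the analysis cannot be trusted at
#' this number of quadrature points.
#'
#' @param design A [build_design()] object.
#' @param samples Numeric vector aligned with the design.
#' @param p_hat_max Largest truncation order to examine (at least 1).
#' @param subsets Subsets to track, as in [sobol_indices()].
#' @param tol_var_rel Relative variance-mismatch tolerance.
#' @param tol_sobol Maximum allowed change of any tracked index between
#'   consecutive orders.
#' @param run_length Minimum length of a run of stable orders for the
#'   flag.
#' @return An object of class `convergence_table`: list with `table`
#'   (one row per order: `Nq`, `p_hat`, `var_data`, `var_pce`,
#'   `err_var`, `rel_err_var`, one `S...` column per tracked subset,
#'   `stable`, `converged`), `recommended` (`NA` if none), `models`
#'   metadata and the tolerances used.
#' @export
convergence_sweep <- function(design, samples, p_hat_max, subsets = "all",
                              tol_var_rel = 1e-3, tol_sobol = 5e-3,
                              run_length = 2) {
  stopifnot(inherits(design, "quadrature_design"))
  if (p_hat_max < 1) stop("'p_hat_max' must be at least 1")
  n <- design$space$n
  subs <- .normalize_subsets(subsets, design$space$names, n)
  sub_keys <- vapply(subs, .dims_key, character(1))
  sub_cols <- paste0("S", vapply(subs, function(s)
    paste(s, collapse = if (n > 9) "." else ""), character(1)))

  basis <- total_degree_basis(n, p_hat_max)
  model <- spectral_projection(design, samples, basis)
  contrib <- model$coefficients^2 * basis$norms_sq
  degree <- rowSums(basis$indices)
  key <- vapply(.term_active(basis$indices), .dims_key, character(1))
  var_data <- model$var_data

  rows <- vector("list", p_hat_max)
  S_prev <- NULL
  for (p in seq_len(p_hat_max)) {
    sel <- degree >= 1 & degree <= p
    var_pce <- sum(contrib[sel])
    S <- vapply(sub_keys, function(k) sum(contrib[sel & key == k]),
                numeric(1))
    S <- if (var_pce > 0) S / var_pce else S * 0
    ev <- err_var(var_data, var_pce)
    stable <- !is.na(ev$rel_err_var) && ev$rel_err_var < tol_var_rel &&
      !is.null(S_prev) && max(abs(S - S_prev)) < tol_sobol
    r <- data.frame(Nq = design$Nq, p_hat = p, var_data = var_data,
                    var_pce = var_pce, err_var = ev$err_var,
                    rel_err_var = ev$rel_err_var)
    r[sub_cols] <- as.list(S)
    r$stable <- stable
    rows[[p]] <- r
    S_prev <- S
  }
  tab <- do.call(rbind, rows)

  # converged = member of a maximal run of >= run_length stable orders
  conv <- rep(FALSE, p_hat_max)
  rl <- rle(tab$stable)
  ends <- cumsum(rl$lengths)
  starts <- ends - rl$lengths + 1
  for (j in seq_along(rl$values))
    if (rl$values[j] && rl$lengths[j] >= run_length)
      conv[starts[j]:ends[j]] <- TRUE
  tab$converged <- conv
  recommended <- if (any(conv)) min(tab$p_hat[conv]) else NA_integer_

  structure(list(table = tab, recommended = recommended,
                 model = model, subsets = subs,
                 tol_var_rel = tol_var_rel, tol_sobol = tol_sobol,
                 run_length = run_length),
            class = "convergence_table")
}

#' @export
print.convergence_table <- function(x, ...) {
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) round(v, 4))
  print(tab, row.names = FALSE)
  if (is.na(x$recommended)) {
    cat("No converged truncation order: the indices cannot be trusted",
        "at this number of quadrature points.\n")
  } else {
    cat("Recommended truncation order: p_hat =", x$recommended, "\n")
  }
  invisible(x)
}

#' Sobol' indices at the recommended order of a convergence sweep
#'
#' @param sweep A [convergence_sweep()] result.
#' @param p_hat Truncation order to use; defaults to the sweep's
#'   recommended order (error if the sweep did not converge).
#' @param subsets Subsets to report, as in [sobol_indices()].
#' @return A [sobol_indices()] result at the chosen order.
#' @export
sobol_at <- function(sweep, p_hat = NULL, subsets = "all") {
  stopifnot(inherits(sweep, "convergence_table"))
  if (is.null(p_hat)) {
    if (is.na(sweep$recommended))
      stop("sweep did not converge; pass an explicit 'p_hat'")
    p_hat <- sweep$recommended
  }
  full <- sweep$model
  basis <- total_degree_basis(full$basis$n, p_hat)
  keep <- seq_len(nrow(basis$indices))  # graded prefix of the full basis
  sub <- structure(list(basis = basis,
                        coefficients = full$coefficients[keep],
                        space = full$space, design_Nq = full$design_Nq,
                        mean_data = full$mean_data,
                        var_data = full$var_data),
                   class = "pce_model")
  sobol_indices(sub, subsets)
}
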