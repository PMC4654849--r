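#' Configure a sensitivity study
#'
#' Bundles everything a replicated design-and-simulate study needs: the
#' varying parameters with their physical ranges, the fixed model
#' parameters, the quadrature resolution, the replicate count and the
#' seed schedule. The varying parameter names must be fields of
#' [cpm_params()].
#'
#' @param space A [parameter_space()] over (a subset of) the CPM
#'   parameters.
#' @param fixed A [cpm_params()] object supplying every non-varying
#'   parameter.
#' @param Nq Gauss-Legendre points per dimension.
#' @param p_hat_max Largest truncation order for the GSA stage.
#' @param replicates Simulations per design point (different seeds),
#'   at least 1.
#' @param base_seed Base of the deterministic seed schedule.
#' @param n_mcs Simulation length; defaults to `fixed$n_mcs`.
#' @param lacuna_min_size Minimum lacuna size in sites; defaults to the
#'   cell target area.
#' @param out_dir Optional directory for resumable per-run results.
#' @return A list of class `study_config`.
#' @export
study_config <- function(space, fixed = cpm_params(), Nq = 4,
                         p_hat_max = 3, replicates = 3, base_seed = 1,
                         n_mcs = fixed$n_mcs,
                         lacuna_min_size = fixed$A_target,
                         out_dir = NULL) {
  stopifnot(inherits(space, "parameter_space"),
            inherits(fixed, "cpm_params"))
  bad <- setdiff(space$names, names(fixed))
  if (length(bad))
    stop("varying parameters are not CPM parameters: ",
         paste(bad, collapse = ", "))
  if (replicates < 1) stop("'replicates' must be at least 1")
  structure(list(space = space, fixed = fixed, Nq = as.integer(Nq),
                 p_hat_max = as.integer(p_hat_max),
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 n_mcs = as.integer(n_mcs),
                 lacuna_min_size = lacuna_min_size,
                 out_dir = out_dir),
            class = "study_config")
}

#' Shipped study profiles
#'
#' `"desk"` is the scaled-down profile used for development and testing:
#' a 96 x 96 lattice with 25 cells of the reference size (50 sites,
#' keeping the one-cell lacuna threshold and the diffusion-length
#' geometry of the full model), 1500 MCS, 4 quadrature points per
#' dimension (256 design points), truncation orders up to 3 and 3
#' replicates. This is the smallest configuration in which the
#' network-formation phenomenon survives: with substantially fewer or
#' smaller cells the cell mass cannot enclose even a single cell-sized
#' lacuna, and the lacuna count is identically zero over the whole
#' parameter space. `"cluster"` is the full-scale study profile: a
#' 400 x 400 lattice with 256 cells of 50 sites, 5000 MCS, 10 quadrature
#' points per dimension (10000 design points) and 20 replicates; it is
#' intended for batch execution on substantial hardware, not for
#' interactive use. Both vary the four mechanism parameters over their
#' studied physical ranges: chemotactic sensitivity `lambda_c` in
#' \[10, 3000\], diffusion coefficient `D` in \[1e-14, 5e-13\] m^2/s,
#' cell rigidity `lambda_A` in \[5, 300\] and cell-cell adhesion
#' `J_cell_cell` in \[0, 120\].
#'
#' @param profile `"desk"` or `"cluster"`.
#' @param base_seed Seed schedule base.
#' @param out_dir Optional resumable output directory.
#' @return A [study_config()].
#' @export
study_profile <- function(profile = c("desk", "cluster"), base_seed = 1,
                          out_dir = NULL) {
  profile <- match.arg(profile)
  space <- parameter_space(
    c("lambda_c", "D", "lambda_A", "J_cell_cell"),
    lower = c(10, 1e-14, 5, 0),
    upper = c(3000, 5e-13, 300, 120))
  if (profile == "desk") {
    fixed <- cpm_params(n_cells = 25, A_target = 50, lattice_size = 96,
                        n_mcs = 1500)
    study_config(space, fixed, Nq = 4, p_hat_max = 3, replicates = 3,
                 base_seed = base_seed, out_dir = out_dir)
  } else {
    fixed <- cpm_params()  # reference scale: 400^2, 256 cells, 5000 MCS
    study_config(space, fixed, Nq = 10, p_hat_max = 12, replicates = 20,
                 base_seed = base_seed, out_dir = out_dir)
  }
}

#' Deterministic seed schedule for replicated batches
#'
#' A pure function of `(base_seed, point, replicate)` built on an
#' integer mixing function, so any single run of a batch can be
#' reproduced in isolation and batches can be executed in any order or
#' in parallel without coordination.
#'
#' @param base_seed,point,replicate Integers.
#' @return A non-negative integer seed below 2^31.
#' @export
derive_seed <- function(base_seed, point, replicate) {
  .hash_seed(as.integer(base_seed), as.integer(point),
             as.integer(replicate))
}

.point_params <- function(config, i) {
  p <- unclass(config$fixed)
  for (k in seq_len(config$space$n))
    p[[config$space$names[k]]] <- config$design$points[i, k]
  do.call(cpm_params, p)
}

#' Run the replicated simulation batch of a study
#'
#' Builds the tensor design over the study's parameter space and, for
#' every design point, runs `replicates` simulations with seeds from
#' [derive_seed()], measures each final configuration, and averages the
#' measures per point. With `out_dir` set, per-run rows are appended to
#' `runs.csv` as they complete and already-present runs are skipped on
#' restart, so an interrupted batch resumes where it stopped; failed
#' runs are recorded and the batch continues. The averaged table is
#' independent of completion order.
#'
#' @param config A [study_config()].
#' @param verbose Print a progress line per design point.
#' @return An object of class `cpm_batch`: list with `design`, `runs`
#'   (per-run rows) and `table` (per-point means and standard
#'   deviations of `compactness` and `lacuna_count`, aligned with the
#'   design enumeration order).
#' @export
run_batch <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "study_config"))
  design <- build_design(config$space, config$Nq)
  config$design <- design
  n_pts <- nrow(design$points)

  runs_path <- NULL
  done <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    runs_path <- file.path(config$out_dir, "runs.csv")
    if (file.exists(runs_path)) {
      done <- utils::read.csv(runs_path)
    }
  }

  rows <- if (!is.null(done)) split(done, seq_len(nrow(done))) else list()
  for (i in seq_len(n_pts)) {
    params_i <- .point_params(config, i)
    for (j in seq_len(config$replicates)) {
      if (!is.null(done) &&
          any(done$point == i & done$replicate == j)) next
      seed_ij <- derive_seed(config$base_seed, i, j)
      t0 <- proc.time()[["elapsed"]]
      res <- tryCatch(
        run_simulation(params_i, seed_ij, n_mcs = config$n_mcs,
                       lacuna_min_size = config$lacuna_min_size),
        error = function(e) e)
      if (inherits(res, "error")) {
        row <- data.frame(point = i, replicate = j, seed = seed_ij,
                          compactness = NA_real_,
                          lacuna_count = NA_real_,
                          wall_s = NA_real_,
                          status = conditionMessage(res))
      } else {
        row <- data.frame(point = i, replicate = j, seed = seed_ij,
                          compactness = res$measures$compactness,
                          lacuna_count = res$measures$lacuna_count,
                          wall_s = proc.time()[["elapsed"]] - t0,
                          status = "ok")
      }
      rows[[length(rows) + 1L]] <- row
      if (!is.null(runs_path)) {
        first <- !file.exists(runs_path)
        utils::write.table(row, runs_path, sep = ",", col.names = first,
                           row.names = FALSE, append = !first)
      }
    }
    if (verbose)
      message(sprintf("design point %d/%d done", i, n_pts))
  }
  runs <- do.call(rbind, rows)
  runs <- runs[order(runs$point, runs$replicate), ]

  agg <- function(v, f) {
    out <- rep(NA_real_, n_pts)
    ok <- stats::aggregate(v, by = list(point = runs$point), FUN = f,
                           na.rm = TRUE)
    out[ok$point] <- ok$x
    out
  }
  tab <- data.frame(point = seq_len(n_pts), design$points,
                    compactness_mean = agg(runs$compactness, mean),
                    compactness_sd = agg(runs$compactness, stats::sd),
                    lacuna_count_mean = agg(runs$lacuna_count, mean),
                    lacuna_count_sd = agg(runs$lacuna_count, stats::sd),
                    n_ok = agg(!is.na(runs$compactness), sum),
                    check.names = FALSE)
  structure(list(design = design, runs = runs, table = tab,
                 config = config),
            class = "cpm_batch")
}

#' @export
print.cpm_batch <- function(x, ...) {
  cat("CPM study batch: ", nrow(x$design$points), " design points x ",
      x$config$replicates, " replicates\n", sep = "")
  utils::str(x$table, max.level = 1)
  invisible(x)
}

#' One- or two-dimensional measure scans
#'
#' Sweeps the named axis parameters over their Gauss-Legendre nodes
#' while pinning every other varying parameter at a supplied value, and
#' returns the replicate-averaged measure grid. This is the
#' visual-inspection companion of the variance-based analysis: a 1-axis
#' scan gives a parameter sweep with mean and standard deviation, a
#' 2-axis scan an intensity grid.
#'
#' @param config A [study_config()].
#' @param axes One or two parameter names from the study's space.
#' @param fixed_values Named values for the remaining varying
#'   parameters (required if any).
#' @param cap Optional display cap: grid values are reported as
#'   `pmin(value, cap)` in the `*_capped` columns (used to reveal
#'   structure masked by a dominant parameter, e.g. capping the lacuna
#'   count at 5).
#' @param replicates Override the study replicate count.
#' @return Data frame with the axis coordinates, per-cell measure means
#'   and standard deviations, and capped variants if `cap` is set.
#' @export
slice_scan <- function(config, axes, fixed_values = NULL, cap = NULL,
                       replicates = config$replicates) {
  stopifnot(inherits(config, "study_config"))
  if (!all(axes %in% config$space$names))
    stop("unknown axis parameter(s): ",
         paste(setdiff(axes, config$space$names), collapse = ", "))
  if (length(axes) < 1 || length(axes) > 2)
    stop("'axes' must name one or two parameters")
  others <- setdiff(config$space$names, axes)
  if (length(others) && !all(others %in% names(fixed_values)))
    stop("pinned values required for: ",
         paste(setdiff(others, names(fixed_values)), collapse = ", "))

  rule <- gauss_legendre_rule(config$Nq)
  axis_vals <- lapply(axes, function(a) {
    k <- match(a, config$space$names)
    from_unit_1d <- config$space$lower[k] +
      (rule$nodes + 1) / 2 * (config$space$upper[k] - config$space$lower[k])
    from_unit_1d
  })
  names(axis_vals) <- axes
  grid <- expand.grid(axis_vals)

  rows <- lapply(seq_len(nrow(grid)), function(i) {
    p <- unclass(config$fixed)
    for (a in axes) p[[a]] <- grid[i, a]
    for (o in others) p[[o]] <- fixed_values[[o]]
    params_i <- do.call(cpm_params, p)
    m <- vapply(seq_len(replicates), function(j) {
      seed_ij <- derive_seed(config$base_seed, 1000000L + i, j)
      r <- run_simulation(params_i, seed_ij, n_mcs = config$n_mcs,
                          lacuna_min_size = config$lacuna_min_size)
      c(r$measures$compactness, r$measures$lacuna_count)
    }, numeric(2))
    data.frame(grid[i, , drop = FALSE],
               compactness_mean = mean(m[1, ]),
               compactness_sd = stats::sd(m[1, ]),
               lacuna_count_mean = mean(m[2, ]),
               lacuna_count_sd = stats::sd(m[2, ]),
               row.names = NULL, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(cap)) {
    out$compactness_capped <- pmin(out$compactness_mean, cap)
    out$lacuna_count_capped <- pmin(out$lacuna_count_mean, cap)
  }
  out
}

#' Variance-based GSA of a batch's measure table
#'
#' Runs the convergence sweep and the Sobol' decomposition for each
#' measure of a completed batch (or any measure table aligned with a
#' design): per measure it reports the convergence table, the indices
#' at the recommended truncation order (or at `p_hat_max`, flagged
#' untrusted, if the sweep did not converge), the per-parameter total
#' indices and the interaction share
#' \eqn{1 - \sum_j S_j}.
#'
#' @param batch A [run_batch()] result, or a list with elements
#'   `design` and `table` (point-aligned measure columns ending in
#'   `_mean`).
#' @param measures Character vector of measure names (default the
#'   batch's measures).
#' @param p_hat_max Largest truncation order (default from the study).
#' @param ... Tolerances passed to [convergence_sweep()].
#' @return An object of class `gsa_report`: per-measure list with
#'   `sweep`, `p_hat_used`, `trusted`, `sobol`, `total`,
#'   `interaction_share` and `first_order`.
#' @export
gsa_pipeline <- function(batch, measures = c("compactness", "lacuna_count"),
                         p_hat_max = NULL, ...) {
  design <- batch$design
  tab <- batch$table
  if (is.null(p_hat_max))
    p_hat_max <- if (!is.null(batch$config)) batch$config$p_hat_max else 3L
  out <- lapply(measures, function(m) {
    col <- paste0(m, "_mean")
    if (!col %in% names(tab)) col <- m
    if (!col %in% names(tab)) stop("no column '", m, "' in the table")
    y <- tab[[col]]
    if (data_moments(design, y)$var <= 0) {
      # constant measure over the design: the decomposition is undefined
      nn <- design$space$names
      return(list(measure = m, sweep = NULL, p_hat_used = NA_integer_,
                  trusted = FALSE, constant = TRUE, sobol = NULL,
                  total = stats::setNames(rep(NA_real_, length(nn)), nn),
                  first_order = stats::setNames(rep(NA_real_, length(nn)),
                                                nn),
                  interaction_share = NA_real_))
    }
    sweep <- convergence_sweep(design, y, p_hat_max = p_hat_max, ...)
    trusted <- !is.na(sweep$recommended)
    p_use <- if (trusted) sweep$recommended else p_hat_max
    sob <- sobol_at(sweep, p_hat = p_use)
    first <- sob$indices$index[sob$indices$order == 1]
    names(first) <- sob$indices$subset[sob$indices$order == 1]
    list(measure = m, sweep = sweep, p_hat_used = p_use,
         trusted = trusted, constant = FALSE, sobol = sob,
         total = sob$total, first_order = first,
         interaction_share = 1 - sum(first))
  })
  names(out) <- measures
  structure(out, class = "gsa_report")
}

#' @export
print.gsa_report <- function(x, ...) {
  for (m in names(x)) {
    r <- x[[m]]
    if (isTRUE(r$constant)) {
      cat("==", m, ": constant over the design; indices undefined\n")
      next
    }
    cat("==", m, if (!r$trusted) "(NOT CONVERGED - untrusted)" else "",
        "\n")
    cat("  p_hat used:", r$p_hat_used, "\n")
    df <- r$sobol$indices[order(r$sobol$indices$order,
                                -r$sobol$indices$index), ]
    df <- df[df$index > 1e-12 | df$order == 1, ]
    for (i in seq_len(nrow(df)))
      cat(sprintf("  S(%s) = %.4f\n", df$subset[i], df$index[i]))
    cat(sprintf("  interaction share = %.4f\n", r$interaction_share))
    cat("  total indices:",
        paste(sprintf("%s %.4f", names(r$total), r$total),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a GSA report to JSON (plus a CSV convergence table)
#'
#' @param report A [gsa_pipeline()] result.
#' @param json_path JSON output path.
#' @param csv_path Optional CSV mirror of the convergence rows.
#' @return `json_path`, invisibly.
#' @export
write_gsa_report <- function(report, json_path, csv_path = NULL) {
  payload <- lapply(report, function(r) {
    if (isTRUE(r$constant))
      return(list(constant = TRUE, trusted = FALSE))
    idx <- as.list(r$sobol$indices$index)
    names(idx) <- r$sobol$indices$subset
    list(p_hat_used = r$p_hat_used, trusted = r$trusted,
         recommended_p_hat = r$sweep$recommended,
         var_data = r$sobol$var_data,
         var_pce = r$sobol$variance_pce,
         err_var = r$sobol$err_var,
         sobol = idx, total = as.list(r$total),
         interaction_share = r$interaction_share,
         convergence = r$sweep$table)
  })
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) {
    rows <- do.call(rbind, lapply(names(report), function(m) {
      t <- report[[m]]$sweep$table
      if (is.null(t)) return(NULL)
      cbind(measure = m, t)
    }))
    utils::write.csv(rows, csv_path, row.names = FALSE)
  }
  invisible(json_path)
}

#' Chemoattractant diffusion length
#'
#' The characteristic distance \eqn{\sqrt{D/\epsilon}} over which the
#' secreted chemoattractant decays in the matrix; it sets the distance
#' over which branches attract each other and thereby branch spacing
#' and thickness.
#'
#' @param D Diffusion coefficient, m^2/s; positive.
#' @param epsilon Decay rate, 1/s; positive.
#' @param dx Lattice spacing in metres (for the lattice-unit value).
#' @return List with `meters`, `micrometers` and `sites`.
#' @examples
#' diffusion_length(4e-12, 1e-3)$micrometers  # ~63.2
#' @export
diffusion_length <- function(D, epsilon, dx = 2e-6) {
  if (any(D <= 0) || any(epsilon <= 0) || any(dx <= 0))
    stop("'D', 'epsilon' and 'dx' must be positive")
  l <- sqrt(D / epsilon)
  list(meters = l, micrometers = 1e6 * l, sites = l / dx)
}
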