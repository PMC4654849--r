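#' Parameters of the contact-inhibition Cellular Potts Model
#'
#' Bundles every model parameter with the reference defaults used
#' throughout the package. Adhesion energies and the constraint weights
#' are dimensionless; the fluctuation amplitude `mu` scales them.
#' One Monte Carlo Step (MCS) represents `mcs_duration` seconds; the
#' chemoattracant PDE is integrated with `diffusion_substeps`
#' forward-Euler substeps per MCS on the lattice grid (`dx` metres per
#' site).
#'
#' The reaction rates `alpha`, `epsilon` and the cell-matrix adhesion
#' `J_cell_ECM` are held fixed in the sensitivity studies; their
#' defaults are a reference profile derived from the published
#' contact-inhibition model family, chosen so that the chemoattractant
#' diffusion length \eqn{\sqrt{D/\epsilon}} spans roughly 1.5 to 11
#' lattice sites over the studied diffusion range, the regime in which
#' spheroids sprout into networks. They are ordinary configuration
#' entries and can be overridden freely.
#'
#' @param J_cell_cell Cell-cell adhesion energy.
#' @param J_cell_ECM Cell-matrix adhesion energy.
#' @param J_cell_border Repulsive adhesion between cells and the lattice
#'   frame (default 100).
#' @param lambda_A Volume-constraint rigidity.
#' @param A_target Preferred cell area in lattice sites (default 50).
#' @param lambda_c Chemotactic sensitivity at cell-ECM interfaces.
#' @param mu Amplitude of random membrane fluctuations (default 50).
#' @param alpha Chemoattractant secretion rate at cell sites, 1/s.
#' @param epsilon Chemoattractant decay rate in the ECM, 1/s.
#' @param D Chemoattractant diffusion coefficient, m^2/s.
#' @param n_cells Number of cells in the initial spheroid (default 256).
#' @param lattice_size Interior lattice side length in sites (default
#'   400); an immutable border frame is added around it.
#' @param dx Lattice spacing in metres (default 2e-6).
#' @param mcs_duration Seconds represented by one MCS (default 30).
#' @param diffusion_substeps PDE substeps per MCS (default 15); doubled
#'   automatically whenever the forward-Euler stability ratio
#'   \eqn{D\,\Delta t / \Delta x^2} would exceed 0.2.
#' @param n_mcs Default simulation length in MCS (default 5000).
#' @return A list of class `cpm_params`.
#' @export
cpm_params <- function(J_cell_cell = 40, J_cell_ECM = 20,
                       J_cell_border = 100,
                       lambda_A = 50, A_target = 50, lambda_c = 500,
                       mu = 50, alpha = 1e-3, epsilon = 1e-3, D = 1e-13,
                       n_cells = 256, lattice_size = 400, dx = 2e-6,
                       mcs_duration = 30, diffusion_substeps = 15,
                       n_mcs = 5000) {
  p <- list(J_cell_cell = J_cell_cell, J_cell_ECM = J_cell_ECM,
            J_cell_border = J_cell_border, lambda_A = lambda_A,
            A_target = A_target, lambda_c = lambda_c, mu = mu,
            alpha = alpha, epsilon = epsilon, D = D, n_cells = n_cells,
            lattice_size = lattice_size, dx = dx,
            mcs_duration = mcs_duration,
            diffusion_substeps = diffusion_substeps, n_mcs = n_mcs)
  num <- unlist(p)
  if (any(!is.finite(num)) || any(num < 0))
    stop("all CPM parameters must be finite and non-negative")
  if (p$mu <= 0) stop("'mu' must be positive")
  if (p$n_cells < 1) stop("'n_cells' must be at least 1")
  if (p$n_cells * p$A_target > p$lattice_size^2)
    stop("lattice too small to hold n_cells * A_target sites")
  structure(p, class = "cpm_params")
}

#' @export
print.cpm_params <- function(x, ...) {
  cat("CPM parameters:\n")
  for (nm in names(x)) cat(sprintf("  %-18s %g\n", nm, x[[nm]]))
  invisible(x)
}

# PDE substepping: the nominal substep count is doubled until the
# forward-Euler stability ratio D*dt/dx^2 drops to 0.2 or below (the
# hard 2-D limit is 0.25; the nominal 15-substep setting sits exactly on
# it at the top of the studied diffusion range).
.pde_setup <- function(params) {
  n_sub <- params$diffusion_substeps
  adjusted <- FALSE
  repeat {
    dt <- params$mcs_duration / n_sub
    ratio <- params$D * dt / params$dx^2
    if (ratio <= 0.2 || n_sub >= 2^20) break
    n_sub <- 2L * n_sub
    adjusted <- TRUE
  }
  list(dt = dt, n_sub = n_sub, ratio = ratio, adjusted = adjusted)
}

#' Initialize a simulation state with a central spheroid
#'
#' Builds the lattice with its immutable border frame, places a
#' rasterized disc of exactly `n_cells * A_target` sites (the sites
#' nearest the lattice centre, deterministic tie-break) at the centre,
#' and partitions the disc into `n_cells` contiguous cells by
#' nearest-seed assignment from seeds on a jittered grid inside the
#' disc. The chemoattractant field starts at zero everywhere.
#'
#' @param params A [cpm_params()] object.
#' @param seed Integer seed; the same seed yields a bit-identical state.
#' @return An object of class `cpm_state`: list with `sigma` (integer
#'   matrix, `(L+2) x (L+2)`, frame = -1, ECM = 0, cells = 1..n),
#'   `chem` (numeric matrix, same shape), `areas` (per-cell site
#'   counts), `mcs_count`, and the PDE substepping actually in effect.
#' @export
cpm_init <- function(params, seed) {
  stopifnot(inherits(params, "cpm_params"))
  set.seed(seed)
  L <- as.integer(params$lattice_size)
  n_cells <- as.integer(params$n_cells)
  total <- n_cells * params$A_target
  ctr <- (L + 1) / 2
  d2 <- outer((seq_len(L) - ctr)^2, (seq_len(L) - ctr)^2, "+")
  ord <- order(d2, row(d2), col(d2))
  sel <- ord[seq_len(total)]
  rs <- ((sel - 1L) %% L) + 1L
  cs <- ((sel - 1L) %/% L) + 1L
  r_disc <- sqrt(total / pi)

  # jittered-grid seeds inside the disc, retried until every cell is
  # non-empty (a near-certainty on the first pass)
  for (attempt in 1:50) {
    sp <- sqrt(params$A_target)
    g <- seq(ctr - r_disc, ctr + r_disc, by = sp)
    seeds <- expand.grid(r = g, c = g)
    seeds$r <- seeds$r + stats::runif(nrow(seeds), -0.35, 0.35) * sp
    seeds$c <- seeds$c + stats::runif(nrow(seeds), -0.35, 0.35) * sp
    inside <- (seeds$r - ctr)^2 + (seeds$c - ctr)^2 <= r_disc^2
    seeds <- seeds[inside, , drop = FALSE]
    if (nrow(seeds) < n_cells) {
      k <- n_cells - nrow(seeds)
      th <- stats::runif(k, 0, 2 * pi)
      rr <- r_disc * sqrt(stats::runif(k))
      seeds <- rbind(seeds, data.frame(r = ctr + rr * sin(th),
                                       c = ctr + rr * cos(th)))
    } else if (nrow(seeds) > n_cells) {
      dctr <- (seeds$r - ctr)^2 + (seeds$c - ctr)^2
      seeds <- seeds[order(dctr)[seq_len(n_cells)], , drop = FALSE]
    }
    dd <- outer(rs, seeds$r, "-")^2 + outer(cs, seeds$c, "-")^2
    assign_id <- max.col(-dd, ties.method = "first")
    if (length(unique(assign_id)) == n_cells) break
  }
  if (length(unique(assign_id)) != n_cells)
    stop("could not construct ", n_cells, " non-empty cells; ",
         "increase A_target or the lattice size")

  sigma <- matrix(-1L, L + 2L, L + 2L)
  sigma[2:(L + 1), 2:(L + 1)] <- 0L
  sigma[cbind(rs + 1L, cs + 1L)] <- as.integer(assign_id)
  areas <- as.integer(tabulate(assign_id, nbins = n_cells))
  pde <- .pde_setup(params)
  structure(list(sigma = sigma,
                 chem = matrix(0, L + 2L, L + 2L),
                 areas = areas, mcs_count = 0L,
                 pde_dt = pde$dt, pde_substeps = pde$n_sub,
                 pde_adjusted = pde$adjusted, seed = seed),
            class = "cpm_state")
}

#' @export
print.cpm_state <- function(x, ...) {
  L <- nrow(x$sigma) - 2L
  cat("CPM state: ", L, "x", L, " lattice, ", length(x$areas),
      " cells, ", x$mcs_count, " MCS elapsed\n", sep = "")
  cat(sprintf("  cell sites %d, chem total %.4g, PDE dt %.3gs x %d substeps%s\n",
              sum(x$areas), sum(x$chem), x$pde_dt, x$pde_substeps,
              if (isTRUE(x$pde_adjusted)) " (auto-increased)" else ""))
  invisible(x)
}

#' Advance a state by whole Monte Carlo Steps
#'
#' One MCS performs as many copy attempts as there are interior lattice
#' sites (random source site, random 8-neighbour target; attempts are
#' skipped when the two sites share an identifier or either is part of
#' the border frame), followed by the PDE substeps. Uses R's global RNG
#' stream; seed with `set.seed()` (or use [run_simulation()]) for
#' reproducibility.
#'
#' @param state A [cpm_init()] state.
#' @param params The [cpm_params()] used to build it.
#' @param n Number of MCS to advance.
#' @return The advanced `cpm_state`.
#' @export
cpm_mcs <- function(state, params, n = 1) {
  stopifnot(inherits(state, "cpm_state"), inherits(params, "cpm_params"))
  pde <- .pde_setup(params)
  res <- .cpm_advance(state$sigma, state$chem, state$areas, as.integer(n),
                      params$J_cell_cell, params$J_cell_ECM,
                      params$J_cell_border, params$lambda_A,
                      params$A_target, params$lambda_c, params$mu,
                      params$alpha, params$epsilon,
                      params$D * pde$dt / params$dx^2, pde$dt, pde$n_sub)
  state$sigma <- res$sigma
  state$chem <- res$chem
  state$areas <- res$areas
  state$mcs_count <- state$mcs_count + as.integer(n)
  state$pde_dt <- pde$dt
  state$pde_substeps <- pde$n_sub
  state$pde_adjusted <- pde$adjusted
  state
}

#' Run a complete simulation
#'
#' Seeds the RNG, initializes the spheroid and advances `n_mcs` Monte
#' Carlo Steps. Optionally samples the output measures along the way.
#' Deterministic: the same `params` and `seed` reproduce the final
#' configuration bit for bit.
#'
#' @param params A [cpm_params()] object.
#' @param seed Integer seed.
#' @param n_mcs Simulation length; defaults to `params$n_mcs`.
#' @param record_every If set, compute compactness and lacuna count
#'   every this many MCS and return the trajectory.
#' @param lacuna_min_size Minimum lacuna size used when recording
#'   (defaults to `A_target`).
#' @return List of class `cpm_run`: `state` (final [cpm_init()] state),
#'   `image` (interior label matrix), `measures` (final
#'   [measure_image()] row) and optionally `trajectory`.
#' @export
run_simulation <- function(params, seed, n_mcs = params$n_mcs,
                           record_every = NULL,
                           lacuna_min_size = params$A_target) {
  state <- cpm_init(params, seed)
  traj <- NULL
  if (is.null(record_every)) {
    state <- cpm_mcs(state, params, n_mcs)
  } else {
    done <- 0L
    rows <- list()
    while (done < n_mcs) {
      k <- min(record_every, n_mcs - done)
      state <- cpm_mcs(state, params, k)
      done <- done + k
      m <- measure_image(label_image(state), min_size = lacuna_min_size)
      rows[[length(rows) + 1L]] <- cbind(data.frame(mcs = done), m)
    }
    traj <- do.call(rbind, rows)
  }
  img <- label_image(state)
  out <- list(state = state, image = img,
              measures = measure_image(img, min_size = lacuna_min_size),
              trajectory = traj, seed = seed)
  class(out) <- "cpm_run"
  out
}

#' @export
print.cpm_run <- function(x, ...) {
  cat("CPM run (seed ", x$seed, ", ", x$state$mcs_count, " MCS)\n",
      sep = "")
  print(x$measures, row.names = FALSE)
  invisible(x)
}

#' Extract the interior label image of a state
#'
#' @param state A [cpm_init()] state.
#' @return Integer matrix of cell identifiers (0 = ECM) without the
#'   border frame.
#' @export
label_image <- function(state) {
  stopifnot(inherits(state, "cpm_state"))
  L <- nrow(state$sigma) - 2L
  state$sigma[2:(L + 1), 2:(L + 1)]
}

#' Energy change of a single copy attempt
#'
#' Computes the change of the Hamiltonian if the identifier at `source`
#' were copied into the adjacent site `target`: the adhesion change over
#' the target's 8 neighbour pairs, the volume-constraint change for the
#' growing and the shrinking cell, and the contact-inhibited chemotaxis
#' bias ([chemotaxis_delta()]).
#'
#' @param state A [cpm_init()] state.
#' @param source,target Length-2 `(row, col)` coordinates in the full
#'   lattice (frame included); `target` must be one of `source`'s 8
#'   neighbours and hold a different identifier.
#' @param params A [cpm_params()] object.
#' @return Scalar energy change.
#' @export
delta_hamiltonian <- function(state, source, target, params) {
  stopifnot(inherits(state, "cpm_state"), inherits(params, "cpm_params"))
  .cpm_delta_h(state$sigma, state$chem, state$areas,
               as.integer(source[1]), as.integer(source[2]),
               as.integer(target[1]), as.integer(target[2]),
               params$J_cell_cell, params$J_cell_ECM,
               params$J_cell_border, params$lambda_A, params$A_target,
               params$lambda_c)
}

#' Contact-inhibited chemotaxis term of a copy attempt
#'
#' \eqn{\Delta H_{chem} = \lambda_c (c(source) - c(target))} when exactly
#' one of the two sites holds a cell and the other is ECM; zero at
#' cell-cell interfaces (contact inhibition) and whenever the border
#' frame is involved.
#'
#' @param state A [cpm_init()] state.
#' @param source,target Full-lattice `(row, col)` coordinates.
#' @param lambda_c Chemotactic sensitivity.
#' @return Scalar.
#' @export
chemotaxis_delta <- function(state, source, target, lambda_c) {
  stopifnot(inherits(state, "cpm_state"))
  s <- state$sigma[source[1], source[2]]
  t <- state$sigma[target[1], target[2]]
  if ((s > 0 && t == 0) || (s == 0 && t > 0))
    lambda_c * (state$chem[source[1], source[2]] -
                  state$chem[target[1], target[2]])
  else 0
}

#' Boltzmann acceptance of copy attempts
#'
#' Accepts with probability 1 when the energy change is non-positive,
#' otherwise with probability \eqn{e^{-\Delta H/\mu}}. Vectorized; draws
#' one uniform variate per energetically unfavourable attempt from R's
#' global RNG stream.
#'
#' @param delta_H Numeric vector of energy changes.
#' @param mu Positive fluctuation amplitude.
#' @return Logical vector.
#' @export
metropolis_accept <- function(delta_H, mu) {
  if (mu <= 0) stop("'mu' must be positive")
  acc <- delta_H <= 0
  up <- which(!acc)
  if (length(up))
    acc[up] <- stats::runif(length(up)) < exp(-delta_H[up] / mu)
  acc
}

#' One or more explicit reaction-diffusion steps
#'
#' Forward-Euler update of the chemoattractant field on the lattice:
#' cell sites gain `alpha * dt` (no decay), ECM sites decay by
#' `epsilon * dt * c`, all interior sites diffuse by the 5-point
#' Laplacian, and the border ring is held fixed at its value. Errors
#' out when the stability ratio `D * dt / dx^2` exceeds the 2-D
#' forward-Euler limit of 1/4.
#'
#' @param chem Numeric matrix (full lattice, frame included).
#' @param sigma Integer matrix of identifiers, same shape.
#' @param params A [cpm_params()] object (supplies `alpha`, `epsilon`,
#'   `D`, `dx`).
#' @param dt Time step in seconds.
#' @param n Number of steps.
#' @return The updated field.
#' @export
pde_step <- function(chem, sigma, params, dt, n = 1) {
  stopifnot(inherits(params, "cpm_params"))
  ratio <- params$D * dt / params$dx^2
  if (ratio > 0.25)
    stop(sprintf(
      "unstable PDE step: D*dt/dx^2 = %.3g > 0.25; reduce dt or substep",
      ratio))
  .cpm_pde_steps(chem, sigma, params$alpha, params$epsilon, ratio, dt,
                 as.integer(n))
}
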