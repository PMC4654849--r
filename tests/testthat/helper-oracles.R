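# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: the Hamiltonian is summed over the whole
# lattice, polynomial statistics are integrated analytically in the
# monomial basis, and hull membership is re-derived by an external
# point-in-polygon routine.

# ---- full-lattice CPM energy ------------------------------------------

# Total Hamiltonian: adhesion over every unordered 8-neighbour pair plus
# the quadratic volume penalty over all cells. sigma is the full lattice
# (frame = -1).
brute_hamiltonian <- function(sigma, params, n_cells) {
  J <- function(s1, s2) {
    if (s1 == s2) return(0)
    c1 <- s1 > 0; c2 <- s2 > 0
    if (c1 && c2) return(params$J_cell_cell)
    if ((c1 && s2 == 0) || (c2 && s1 == 0)) return(params$J_cell_ECM)
    if ((c1 && s2 == -1) || (c2 && s1 == -1)) return(params$J_cell_border)
    0
  }
  nr <- nrow(sigma); nc <- ncol(sigma)
  tot <- 0
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # each pair once
  for (r in seq_len(nr)) for (cl in seq_len(nc)) {
    for (o in offs) {
      r2 <- r + o[1]; c2 <- cl + o[2]
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      tot <- tot + J(sigma[r, cl], sigma[r2, c2])
    }
  }
  areas <- tabulate(sigma[sigma > 0], nbins = n_cells)
  tot + params$lambda_A * sum((params$A_target - areas)^2)
}

# Random small lattice with frame, k cells occupying random patches.
random_lattice <- function(L, k, fill = 0.4) {
  sigma <- matrix(-1L, L + 2L, L + 2L)
  inner <- matrix(0L, L, L)
  n_occ <- round(fill * L * L)
  sites <- sample(L * L, n_occ)
  inner[sites] <- sample.int(k, n_occ, replace = TRUE)
  sigma[2:(L + 1), 2:(L + 1)] <- inner
  sigma
}

# ---- exact Sobol' statistics of monomial-basis polynomials ------------

# A polynomial is a list(coef, expo): coef numeric length m, expo an
# m x n integer matrix of exponents. All statistics are over independent
# uniforms on [-1, 1]^n, using E[xi^k] = 0 (k odd) or 1/(k+1) (k even).

mono_moment <- function(k) ifelse(k %% 2 == 1, 0, 1 / (k + 1))

poly_eval <- function(poly, X) {
  X <- as.matrix(X)
  vals <- rep(0, nrow(X))
  for (i in seq_along(poly$coef)) {
    term <- rep(poly$coef[i], nrow(X))
    for (j in seq_len(ncol(X))) {
      e <- poly$expo[i, j]
      if (e > 0) term <- term * X[, j]^e
    }
    vals <- vals + term
  }
  vals
}

# integrate out every dimension NOT in keep
poly_marginalize <- function(poly, keep, n) {
  drop <- setdiff(seq_len(n), keep)
  coef <- poly$coef
  expo <- poly$expo
  for (j in drop) {
    coef <- coef * mono_moment(expo[, j])
    expo[, j] <- 0L
  }
  ok <- coef != 0
  list(coef = coef[ok], expo = expo[ok, , drop = FALSE])
}

poly_mean <- function(poly, n) {
  sum(poly_marginalize(poly, integer(0), n)$coef)
}

# E[poly^2] by expanding the product of every term pair
poly_second_moment <- function(poly, n) {
  m <- length(poly$coef)
  tot <- 0
  for (i in seq_len(m)) for (j in seq_len(m)) {
    e <- poly$expo[i, ] + poly$expo[j, ]
    tot <- tot + poly$coef[i] * poly$coef[j] * prod(mono_moment(e))
  }
  tot
}

# Exact variance component V_J for every non-empty subset J, by
# Moebius inversion of g_T = E[(E[f | xi_T])^2] - mean^2.
poly_sobol_exact <- function(poly, n) {
  subsets <- list()
  for (sz in seq_len(n))
    subsets <- c(subsets, utils::combn(n, sz, simplify = FALSE))
  mu <- poly_mean(poly, n)
  gs <- c(list(0), lapply(subsets, function(T) {
    poly_second_moment(poly_marginalize(poly, T, n), n) - mu^2
  }))
  names(gs) <- c("", vapply(subsets, paste, character(1), collapse = ","))
  V <- vapply(subsets, function(J) {
    tot <- 0
    for (sz in 0:length(J)) {
      Ts <- if (sz == 0) list(integer(0)) else
        lapply(utils::combn(seq_along(J), sz, simplify = FALSE),
               function(ii) J[ii])
      for (T in Ts) {
        key <- paste(T, collapse = ",")
        tot <- tot + (-1)^(length(J) - sz) * gs[[match(key, names(gs))]]
      }
    }
    tot
  }, numeric(1))
  names(V) <- vapply(subsets, paste, character(1), collapse = ",")
  list(mean = mu, variance = sum(V), components = V, subsets = subsets)
}

random_poly <- function(n, max_degree = 4, n_terms = 6) {
  expo <- matrix(0L, n_terms, n)
  for (i in seq_len(n_terms)) {
    d <- sample(0:max_degree, 1)
    if (d > 0) {
      dims <- sample(n, min(n, sample(1:min(3, n), 1)))
      parts <- diff(c(0, sort(sample(0:d, length(dims) - 1)), d))
      expo[i, dims] <- parts
    }
  }
  list(coef = round(stats::runif(n_terms, -2, 2), 3), expo = expo)
}

# ---- independent hull membership --------------------------------------

# Count lattice sites inside-or-on the convex hull of integer points,
# via pracma's point-in-polygon test (with boundary = TRUE).
hull_count_oracle <- function(pts) {
  pts <- unique(pts[, 1:2, drop = FALSE])
  h <- grDevices::chull(pts[, 2], pts[, 1])
  poly <- pts[h, , drop = FALSE]
  rr <- range(pts[, 1]); cc <- range(pts[, 2])
  grid <- expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2])
  inp <- pracma::inpolygon(grid$r, grid$c, poly[, 1], poly[, 2],
                           boundary = TRUE)
  sum(inp)
}

# ---- simple flood-fill component labelling ----------------------------

# 4-connected components of value == 0 via an R queue; independent of the
# package's compiled labelling.
label_zero_oracle <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (start in which(img == 0 & lab == 0)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      r <- ((p - 1L) %% nr) + 1L; cl <- ((p - 1L) %/% nr) + 1L
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        r2 <- r + d[1]; c2 <- cl + d[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        q <- (c2 - 1L) * nr + r2
        if (img[q] == 0 && lab[q] == 0L) {
          lab[q] <- nxt
          queue <- c(queue, q)
        }
      }
    }
  }
  lab
}

lacuna_count_oracle <- function(img, min_size) {
  lab <- label_zero_oracle(img)
  if (max(lab) == 0) return(0L)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  enclosed <- setdiff(which(sizes > 0), border[border > 0])
  sum(sizes[enclosed] >= min_size)
}
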