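desk_params <- function(...) {
  cpm_params(n_cells = 9, A_target = 16, lattice_size = 40, n_mcs = 50, ...)
}

test_that("initialization builds the centred spheroid deterministically", {
  p <- cpm_params(n_cells = 25, A_target = 20, lattice_size = 64)
  st <- cpm_init(p, seed = 3)
  expect_equal(sum(st$areas), 25 * 20)
  expect_equal(length(st$areas), 25)
  expect_true(all(st$areas > 0))
  img <- label_image(st)
  expect_equal(sum(img > 0), 500)
  # the occupied sites are the ones nearest the centre (a disc)
  occ <- which(img > 0, arr.ind = TRUE)
  ctr <- (64 + 1) / 2
  expect_lt(max(sqrt((occ[, 1] - ctr)^2 + (occ[, 2] - ctr)^2)),
            sqrt(500 / pi) + 1.5)
  # chemoattractant starts at zero; frame in place
  expect_equal(sum(st$chem), 0)
  expect_true(all(st$sigma[1, ] == -1L) && all(st$sigma[, 1] == -1L))
  # bit-identical under the same seed
  st2 <- cpm_init(p, seed = 3)
  expect_identical(st$sigma, st2$sigma)
  expect_error(cpm_params(n_cells = 100, A_target = 50, lattice_size = 20),
               "too small")
})

test_that("incremental energy changes match the brute-force Hamiltonian", {
  set.seed(42)
  p <- cpm_params(n_cells = 4, A_target = 10, lattice_size = 12,
                  J_cell_cell = 31, J_cell_ECM = 17, lambda_A = 9,
                  lambda_c = 120)
  checked <- 0
  while (checked < 60) {
    sigma <- random_lattice(sample(4:12, 1), 4)
    st <- structure(list(sigma = sigma,
                         chem = matrix(runif(length(sigma)), nrow(sigma)),
                         areas = tabulate(sigma[sigma > 0], nbins = 4),
                         mcs_count = 0L),
                    class = "cpm_state")
    L <- nrow(sigma) - 2
    src <- c(sample(2:(L + 1), 1), sample(2:(L + 1), 1))
    nb <- c(sample(-1:1, 1), sample(-1:1, 1))
    if (all(nb == 0)) next
    tgt <- src + nb
    if (any(tgt < 2) || any(tgt > L + 1)) next
    if (sigma[src[1], src[2]] == sigma[tgt[1], tgt[2]]) next
    dH <- delta_hamiltonian(st, src, tgt, p)
    after <- sigma
    after[tgt[1], tgt[2]] <- sigma[src[1], src[2]]
    oracle <- brute_hamiltonian(after, p, 4) -
      brute_hamiltonian(sigma, p, 4) +
      chemotaxis_delta(st, src, tgt, p$lambda_c)
    expect_equal(dH, oracle, tolerance = 1e-9)
    checked <- checked + 1
  }
})

test_that("a cell at target area pays lambda_A for one extra site", {
  p <- cpm_params(n_cells = 1, A_target = 4, lattice_size = 8,
                  lambda_c = 0, J_cell_cell = 0, J_cell_ECM = 0,
                  lambda_A = 13)
  sigma <- matrix(-1L, 10, 10)
  sigma[2:9, 2:9] <- 0L
  sigma[4:5, 4:5] <- 1L  # 2x2 cell, exactly at its target area
  st <- structure(list(sigma = sigma, chem = matrix(0, 10, 10),
                       areas = 4L, mcs_count = 0L), class = "cpm_state")
  dH <- delta_hamiltonian(st, c(4, 4), c(4, 3), p)
  expect_equal(dH, 13)  # (A-(a+1))^2 - (A-a)^2 = 1 when a = A
})

test_that("chemotaxis is contact-inhibited and linear in the gradient", {
  sigma <- matrix(-1L, 6, 6)
  sigma[2:5, 2:5] <- 0L
  sigma[3, 3] <- 1L
  sigma[3, 4] <- 2L
  chem <- matrix(0, 6, 6)
  chem[3, 3] <- 0.05
  chem[4, 3] <- 0.04
  st <- structure(list(sigma = sigma, chem = chem, areas = c(1L, 1L),
                       mcs_count = 0L), class = "cpm_state")
  # cell extending into ECM: lambda_c * (c(source) - c(target))
  expect_equal(chemotaxis_delta(st, c(3, 3), c(4, 3), 100), 1.0)
  # uniform field: no bias
  st$chem[] <- 0.2
  expect_equal(chemotaxis_delta(st, c(3, 3), c(4, 3), 100), 0)
  # both sites cells: contact inhibition switches the term off
  st$chem <- chem
  expect_equal(chemotaxis_delta(st, c(3, 3), c(3, 4), 100), 0)
})

test_that("Boltzmann acceptance has the right limit frequencies", {
  expect_true(all(metropolis_accept(c(-5, 0, -1e-9), mu = 50)))
  set.seed(9)
  n <- 1e5
  acc <- metropolis_accept(rep(50, n), mu = 50)
  p_hat <- mean(acc)
  p_true <- exp(-1)
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_hat - p_true), 3 * se)
  expect_equal(mean(metropolis_accept(rep(1e4, 1000), mu = 50)), 0)
  expect_error(metropolis_accept(1, mu = 0), "positive")
})

test_that("area bookkeeping stays consistent with the lattice over MCS", {
  p <- desk_params()
  set.seed(17)
  st <- cpm_init(p, seed = 17)
  for (i in 1:5) {
    st <- cpm_mcs(st, p, n = 10)
    img <- label_image(st)
    expect_identical(st$areas,
                     as.integer(tabulate(img[img > 0],
                                         nbins = length(st$areas))))
  }
  expect_equal(st$mcs_count, 50L)
})

test_that("a rigid volume constraint holds areas near target without chemotaxis", {
  p <- cpm_params(n_cells = 9, A_target = 50, lattice_size = 100,
                  lambda_A = 1000, lambda_c = 0, alpha = 0, n_mcs = 100)
  r <- run_simulation(p, seed = 4, n_mcs = 100)
  expect_true(all(abs(r$state$areas - 50) <= 2))
})

test_that("simulations are reproducible and the RNG schedule is single-stream", {
  p <- desk_params()
  r1 <- run_simulation(p, seed = 23, n_mcs = 30)
  r2 <- run_simulation(p, seed = 23, n_mcs = 30)
  expect_identical(r1$image, r2$image)
  expect_identical(r1$state$chem, r2$state$chem)
  r3 <- run_simulation(p, seed = 24, n_mcs = 30)
  expect_false(identical(r1$image, r3$image))
  # trajectory recording does not perturb the dynamics
  r4 <- run_simulation(p, seed = 23, n_mcs = 30, record_every = 10)
  expect_identical(r1$image, r4$image)
  expect_equal(nrow(r4$trajectory), 3)
})

test_that("chemoattractant stays non-negative and decays without secretion", {
  p <- desk_params(alpha = 0)
  set.seed(2)
  st <- cpm_init(p, seed = 2)
  st$chem[2:41, 2:41] <- matrix(runif(1600), 40)
  mass0 <- sum(st$chem)
  st <- cpm_mcs(st, p, n = 5)
  expect_true(all(st$chem >= 0))
  expect_lt(sum(st$chem), mass0)
})

test_that("label images round-trip through the text dialect", {
  p <- desk_params()
  r <- run_simulation(p, seed = 6, n_mcs = 10)
  path <- withr::local_tempfile(fileext = ".txt")
  write_label_matrix(r$image, path)
  expect_identical(read_label_matrix(path), r$image)
  cpath <- withr::local_tempfile(fileext = ".txt")
  write_chem_matrix(r$state$chem, cpath)
  expect_equal(read_chem_matrix(cpath), r$state$chem, tolerance = 0)
})
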