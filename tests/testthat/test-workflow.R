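tiny_study <- function(base_seed = 1, out_dir = NULL, replicates = 2) {
  space <- parameter_space(c("lambda_c", "D"),
                           lower = c(10, 1e-14), upper = c(3000, 5e-13))
  fixed <- cpm_params(n_cells = 4, A_target = 10, lattice_size = 24,
                      n_mcs = 20)
  study_config(space, fixed, Nq = 2, p_hat_max = 2,
               replicates = replicates, base_seed = base_seed,
               out_dir = out_dir)
}

test_that("the seed schedule is a pure function with well-separated streams", {
  s <- derive_seed(1, 7, 3)
  expect_identical(derive_seed(1, 7, 3), s)
  expect_true(s >= 0 && s < 2^31)
  grid <- expand.grid(b = 1:3, p = 1:20, r = 1:5)
  seeds <- mapply(derive_seed, grid$b, grid$p, grid$r)
  expect_equal(anyDuplicated(seeds), 0)
})

test_that("study configs validate their varying parameters", {
  space <- parameter_space("not_a_param", 0, 1)
  expect_error(study_config(space, cpm_params()), "not CPM parameters")
  expect_error(tiny_study(replicates = 0), "at least 1")
  desk <- study_profile("desk")
  expect_equal(desk$space$names, c("lambda_c", "D", "lambda_A",
                                   "J_cell_cell"))
  expect_equal(desk$fixed$lattice_size, 96)
  expect_equal(desk$lacuna_min_size, 50)
  cluster <- study_profile("cluster")
  expect_equal(cluster$Nq, 10)
  expect_equal(cluster$replicates, 20)
  expect_equal(nrow(build_design(cluster$space, cluster$Nq)$points), 10000)
})

test_that("batches are reproducible, aligned with the design, and resumable", {
  b1 <- run_batch(tiny_study())
  expect_equal(nrow(b1$table), 4)  # Nq^n = 2^2
  expect_equal(nrow(b1$runs), 8)
  expect_true(all(b1$runs$status == "ok"))
  expect_equal(b1$table$point, 1:4)
  b2 <- run_batch(tiny_study())
  expect_equal(b1$table, b2$table)

  # resumability: a partially filled runs.csv is completed, not redone
  dir <- withr::local_tempdir()
  b3 <- run_batch(tiny_study(out_dir = dir))
  runs <- utils::read.csv(file.path(dir, "runs.csv"))
  expect_equal(nrow(runs), 8)
  partial <- runs[runs$point <= 2, ]
  utils::write.csv(partial, file.path(dir, "runs.csv"), row.names = FALSE)
  b4 <- run_batch(tiny_study(out_dir = dir))
  expect_equal(b4$table$compactness_mean, b3$table$compactness_mean)
  expect_equal(b4$table$lacuna_count_mean, b3$table$lacuna_count_mean)
})

test_that("single runs of a batch can be reproduced in isolation", {
  cfg <- tiny_study()
  b <- run_batch(cfg)
  i <- 3; j <- 2
  design <- build_design(cfg$space, cfg$Nq)
  p <- cpm_params(n_cells = 4, A_target = 10, lattice_size = 24,
                  n_mcs = 20, lambda_c = design$points[i, "lambda_c"],
                  D = design$points[i, "D"])
  r <- run_simulation(p, derive_seed(cfg$base_seed, i, j), n_mcs = 20,
                      lacuna_min_size = cfg$lacuna_min_size)
  row <- b$runs[b$runs$point == i & b$runs$replicate == j, ]
  expect_equal(row$compactness, r$measures$compactness)
  expect_equal(row$lacuna_count, r$measures$lacuna_count)
})

test_that("slice scans pin the off-axis parameters and honour the cap", {
  cfg <- tiny_study()
  s1 <- slice_scan(cfg, "lambda_c", fixed_values = list(D = 1e-13),
                   replicates = 2)
  expect_equal(nrow(s1), 2)  # Nq nodes on one axis
  expect_true(all(c("compactness_mean", "compactness_sd",
                    "lacuna_count_mean", "lacuna_count_sd") %in% names(s1)))
  s2 <- slice_scan(cfg, c("lambda_c", "D"), cap = 0.5, replicates = 1)
  expect_equal(nrow(s2), 4)
  expect_true(all(s2$compactness_capped <= 0.5))
  expect_equal(s2$compactness_capped, pmin(s2$compactness_mean, 0.5))
  expect_error(slice_scan(cfg, "nope", fixed_values = list()), "unknown")
  expect_error(slice_scan(cfg, "lambda_c"), "pinned values")
})

test_that("the GSA pipeline reproduces the engine on an analytic measure table", {
  # route Ishigami samples through the pipeline as if they were a batch
  d <- build_design(ishigami_space(), 10)
  y <- ishigami(d$points)
  fake <- list(design = d, table = data.frame(response_mean = y),
               config = NULL)
  rep <- gsa_pipeline(fake, measures = "response", p_hat_max = 9)
  r <- rep$response
  expect_true(r$trusted)
  expect_equal(r$p_hat_used, 8)
  ex <- ishigami_exact_stats()
  expect_equal(round(unname(r$first_order), 2),
               round(c(ex$S1, ex$S2, ex$S3), 2))
  expect_equal(r$interaction_share, 1 - sum(r$first_order),
               tolerance = 1e-12)
  # total index = sum of indices of all subsets containing the parameter
  idx <- r$sobol$indices
  tot1 <- sum(idx$index[grepl("(^|,)1(,|$)", idx$dims)])
  expect_equal(unname(r$total["x1"]), tot1, tolerance = 1e-12)
  # report serialization
  json <- withr::local_tempfile(fileext = ".json")
  csvp <- withr::local_tempfile(fileext = ".csv")
  write_gsa_report(rep, json, csvp)
  back <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_equal(back$response$p_hat_used, 8)
  expect_equal(back$response$sobol[["x1:x3"]], ex$S13, tolerance = 1e-3)
  expect_equal(nrow(utils::read.csv(csvp)), 9)
})

test_that("a constant measure is reported as degenerate, not an error", {
  d <- build_design(parameter_space(c("a", "b"), c(0, 0), c(1, 1)), 2)
  fake <- list(design = d, table = data.frame(flat_mean = rep(2, 4)),
               config = NULL)
  rep <- gsa_pipeline(fake, measures = "flat", p_hat_max = 2)
  expect_true(rep$flat$constant)
  expect_false(rep$flat$trusted)
  expect_true(all(is.na(rep$flat$first_order)))
  json <- withr::local_tempfile(fileext = ".json")
  write_gsa_report(rep, json)
  expect_true(jsonlite::read_json(json)$flat$constant)
})

test_that("diffusion length follows sqrt(D / epsilon)", {
  dl <- diffusion_length(4e-12, 1e-3)
  expect_equal(dl$meters, sqrt(4e-9), tolerance = 1e-12)
  expect_equal(dl$micrometers, 63.24555, tolerance = 1e-6)
  expect_equal(diffusion_length(4 * 2e-13, 1e-3)$meters,
               2 * diffusion_length(2e-13, 1e-3)$meters, tolerance = 1e-12)
  dx <- 2e-6
  expect_equal(diffusion_length(1e-3 * dx^2, 1e-3, dx)$sites, 1,
               tolerance = 1e-12)
  expect_error(diffusion_length(-1, 1), "positive")
})

test_that("study configurations round-trip through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c(
    "parameters:",
    "  lambda_c: {lower: 10, upper: 3000}",
    "  D: {lower: 1.0e-14, upper: 5.0e-13}",
    "fixed:",
    "  n_cells: 4",
    "  A_target: 10",
    "  lattice_size: 24",
    "Nq: 2",
    "replicates: 2",
    "base_seed: 7"), path)
  cfg <- read_study_config(path)
  expect_equal(cfg$space$names, c("lambda_c", "D"))
  expect_equal(cfg$space$upper, c(3000, 5e-13))
  expect_equal(cfg$fixed$n_cells, 4)
  expect_equal(cfg$replicates, 2)
  expect_equal(cfg$base_seed, 7)

  shipped <- system.file("extdata", "desk_study.yaml", package = "cpmgsa")
  cfg2 <- read_study_config(shipped)
  expect_equal(cfg2$space$n, 4)
  expect_equal(cfg2$fixed$lattice_size, 96)
})
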