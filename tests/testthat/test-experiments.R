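test_that("the scan run-length rule rounds up to powers of ten with a floor", {
  expect_equal(cv_run_length(200, 5e-5, 12), 1e7)   # 1e6/0.12 = 8.3e6
  expect_equal(cv_run_length(1000, 2e-5, 12), 1e7)  # 1e6/0.24 = 4.2e6
  expect_equal(cv_run_length(1e4, 1e-2, 10), 1e4)   # floor kicks in
  expect_equal(cv_run_length(100, 1e-3, 10), 1e6)   # exact power stays
  expect_equal(cv_run_length(1000, 2e-5, 12, t_budget = 1e4), 1e5)
})

test_that("fixture maps are reproducible and match their requested spectrum", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  fx1 <- make_fixture_map(L = 6, K = 2, n_phenotypes = 4,
                          phi_profile = c(0.4, 0.3, 0.2, 0.1), seed = 7,
                          out_dir = d1)
  fx2 <- make_fixture_map(L = 6, K = 2, n_phenotypes = 4,
                          phi_profile = c(0.4, 0.3, 0.2, 0.1), seed = 7,
                          out_dir = d2)
  for (f in basename(fx1$files)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # a different seed gives a different map
  fx3 <- make_fixture_map(L = 6, K = 2, n_phenotypes = 4,
                          phi_profile = c(0.4, 0.3, 0.2, 0.1), seed = 8)
  g <- phenoburst:::all_genotypes(fx1$map)
  expect_false(identical(map_phenotype(fx1$map, g),
                         map_phenotype(fx3$map, g)))
})

test_that("unclustered fixtures have binomially distributed portals", {
  fx <- make_fixture_map(L = 10, K = 2, n_phenotypes = 6,
                         phi_profile = c(0.5, 0.1, 0.1, 0.1, 0.1, 0.1),
                         portal_clustering = 0, seed = 19)
  nc <- fx$nc
  n <- length(nc$genotypes)
  expect_gt(n, 100)
  for (p in paste0("P", 1:5)) {
    # a member's 10 neighbours each carry p with probability ~ 0.1
    # (the member itself is conditioned to be P0, neighbours are iid)
    want <- 1 - (1 - 0.1)^10
    got <- portal_probability(nc, p)
    se <- sqrt(want * (1 - want) / n)
    expect_lt(abs(got - want), 4 * se)
  }
})

test_that("clustered fixtures concentrate portals without changing frequencies", {
  base <- make_fixture_map(L = 8, K = 2, n_phenotypes = 4,
                           phi_profile = c(0.45, 0.25, 0.2, 0.1), seed = 3)
  clus <- make_fixture_map(L = 8, K = 2, n_phenotypes = 4,
                           phi_profile = c(0.45, 0.25, 0.2, 0.1), seed = 3,
                           portal_clustering = 0.6)
  g <- phenoburst:::all_genotypes(base$map)
  expect_identical(sort(map_phenotype(base$map, g)),
                   sort(map_phenotype(clus$map, g)))
})

test_that("burst histograms flag the over-weighted zero bin on a random map", {
  phi <- c(p0 = 0.36, pb = 0.004, NONE = 0.636)
  m <- make_random_gp_map(phi, L = 12, K = 4, seed = 23)
  r <- run_burst_histogram(m, "pb", N = 1000, u = 2e-5,
                           generations = 5e5, dt = 3000, seed = 2)
  expect_identical(length(r$counts), as.integer(5e5 / 3000))
  expect_gt(mean(r$counts == 0), stats::dpois(0, r$poisson_mean))
  expect_gt(r$V_t, 1)
  expect_equal(unname(sum(r$summary)), 1)
  expect_error(run_burst_histogram(m, "absent", N = 100, u = 2e-5,
                                   generations = 1e4, seed = 1),
               "zero mutation probability")
})

test_that("the average-rate control stays inside the Poisson band", {
  phi <- c(p0 = 0.36, pb = 0.004, NONE = 0.636)
  r <- run_burst_histogram("average_rate", "pb", phi = phi, N = 1000,
                           u = 2e-5, generations = 2e6, dt = 3000, seed = 4)
  # the within-band fraction matches the analytic Poisson mass
  se <- sqrt(r$poisson_band_mass * (1 - r$poisson_band_mass) /
               length(r$counts))
  expect_lt(abs(r$summary[["within"]] - r$poisson_band_mass), 3 * se + 0.01)
})

test_that("cv scans report one row per grid point with the rule's run lengths", {
  phi <- c(p0 = 0.36, pb = 0.01, NONE = 0.63)
  grid <- data.frame(N = c(100, 100), u = c(2e-4, 2e-3))
  out <- run_cv_scan("average_rate", "pb", grid, phi = phi, seed = 5,
                     t_budget = 1e4)
  expect_identical(nrow(out), 2L)
  expect_equal(out$T, vapply(1:2, function(i)
    cv_run_length(grid$N[i], grid$u[i], 12, t_budget = 1e4), numeric(1)))
  expect_true(all(is.finite(out$V_t)))
})

test_that("average-rate two-peak winner frequencies follow the ratio law", {
  phi <- c(p0 = 0.36, pf = 2e-3, pr = 1e-3, NONE = 0.637)
  out <- run_two_peak("average_rate", "pf", "pr", s_f = 0.02,
                      s_r_grid = c(0.05), reps = 120, phi = phi,
                      N = 500, u = 2e-5, seed = 6)
  expect_identical(out$n_decided, 120L)
  # for the average-rate model the two theory columns coincide
  expect_equal(out$theory_times, out$theory_ratio)
  expect_gt(out$ci_hi, out$theory_ratio)
  expect_lt(out$ci_lo, out$theory_ratio)
})

test_that("experiment configurations load from JSON", {
  cfg <- list(map = "average_rate", N = 500, u = 2e-5, generations = 1e5,
              tracked = "pb", rng_seed = 3,
              phi = list(p0 = 0.36, pb = 0.01, NONE = 0.63))
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  back <- read_experiment_config(f)
  expect_equal(back$N, 500)
  expect_equal(unlist(back$phi), c(p0 = 0.36, pb = 0.01, NONE = 0.63))
})
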