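test_that("without mutation the population only drifts among existing genotypes", {
  fx <- shared_fixture()
  sch <- fitness_scheme("P0", restrict_to_nc = FALSE)
  r <- wright_fisher_run(fx$map, sch, N = 50, u = 0, generations = 500,
                         seed = 2, tracked = c("P1", "P2", "P3"),
                         nc = fx$nc, burn_in = 0)
  expect_identical(nrow(r$events), 0L)
  expect_true(all(r$final$genotype %in% fx$nc$genotypes[1]))
  expect_equal(sum(r$final$count), 50)
})

test_that("population size is conserved and runs are reproducible from the seed", {
  fx <- shared_fixture()
  sch <- fitness_scheme("P0", restrict_to_nc = TRUE)
  r1 <- wright_fisher_run(fx$map, sch, N = 100, u = 1e-3,
                          generations = 5000, seed = 33, tracked = "P1",
                          nc = fx$nc)
  r2 <- wright_fisher_run(fx$map, sch, N = 100, u = 1e-3,
                          generations = 5000, seed = 33, tracked = "P1",
                          nc = fx$nc)
  expect_identical(r1$events, r2$events)
  expect_identical(r1$final, r2$final)
  expect_equal(sum(r1$final$count), 100)
  # a different seed gives a different log
  r3 <- wright_fisher_run(fx$map, sch, N = 100, u = 1e-3,
                          generations = 5000, seed = 34, tracked = "P1",
                          nc = fx$nc)
  expect_false(identical(r1$events, r3$events))
})

test_that("appearance rates match the introduction-rate law r = N L u phi", {
  fx <- shared_fixture()
  sch <- fitness_scheme("P0", restrict_to_nc = FALSE)
  N <- 100; u <- 1e-4; L <- 6; gens <- 1e6
  r <- wright_fisher_run(fx$map, sch, N = N, u = u, generations = gens,
                         seed = 5, tracked = "P1", nc = fx$nc)
  expected <- N * u * L * fx$nc$phi[["P1"]] * gens
  # block the run to get an empirical standard error that respects the
  # bursty autocorrelation of the appearance process
  blocks <- interval_counts(r, "P1", dt = gens / 20)
  se <- stats::sd(blocks) / sqrt(length(blocks)) * length(blocks)
  expect_lt(abs(nrow(r$events) - expected), 3 * se)
})

test_that("neutral substitutions follow the molecular clock t_ne = 1/(u L rho)", {
  fx <- shared_fixture()
  sch <- fitness_scheme("P0", restrict_to_nc = FALSE)
  r <- wright_fisher_run(fx$map, sch, N = 100, u = 5e-5, generations = 2e6,
                         seed = 11, nc = fx$nc, track_substitutions = TRUE)
  gaps <- diff(r$substitutions$generation)
  expect_gt(length(gaps), 50)
  t_ne <- 1 / (5e-5 * 6 * fx$nc$rho)
  expect_lt(abs(mean(gaps) - t_ne) / t_ne, 0.15)
})

test_that("losing every viable individual raises an error naming the generation", {
  fx <- shared_fixture()
  # nothing is viable: selection has no one to pick from
  sch <- fitness_scheme("not-a-phenotype")
  expect_error(
    wright_fisher_run(fx$map, sch, N = 20, u = 0, generations = 10,
                      seed = 1, nc = fx$nc, burn_in = 0),
    "generation")
})

test_that("the average-rate model is Poissonian and logs no genotypes", {
  phi <- c(p0 = 0.35, pb = 0.01, NONE = 0.64)
  sch <- fitness_scheme("p0", restrict_to_nc = FALSE)
  r <- average_rate_run(phi, sch, N = 1000, u = 2e-5, L = 12,
                        generations = 3e5, seed = 6, tracked = "pb")
  expect_true(all(is.na(r$events$parent_genotype)))
  expect_gt(nrow(r$events), 200)
  times <- unique(r$events$generation)
  v <- coefficient_of_variation(times)
  # Poisson gaps: V near 1 (generous band for a short run)
  expect_lt(abs(v - 1), 0.15)
  # same-seed reproducibility
  r2 <- average_rate_run(phi, sch, N = 1000, u = 2e-5, L = 12,
                         generations = 3e5, seed = 6, tracked = "pb")
  expect_identical(r$events, r2$events)
})

test_that("average-rate mutation supply matches L*u per individual", {
  phi <- c(p0 = 0.5, pb = 0.5)
  sch <- fitness_scheme("p0", restrict_to_nc = FALSE)  # pb unviable
  N <- 200; u <- 1e-4; L <- 10; gens <- 5e4
  r <- average_rate_run(phi, sch, N = N, u = u, L = L, generations = gens,
                        seed = 8, tracked = "pb")
  # the resident population stays on p0, so the pb appearance count is a
  # thinned version of the total mutation supply N * u * L per generation
  full <- N * u * L * phi[["pb"]] * gens
  expect_lt(abs(nrow(r$events) - full), 3 * sqrt(full))
})

test_that("fixation detection applies the strict 25% rule with ordered tie-breaks", {
  expect_identical(
    detect_fixation(c(grey = 24, red = 76), "grey"),
    list(fixed = TRUE, winner = "red"))
  expect_false(detect_fixation(c(grey = 25, red = 75), "grey")$fixed)
  expect_identical(
    detect_fixation(c(grey = 0, b = 50, a = 50), "grey")$winner, "a")
  df <- data.frame(phenotype = c("x", "y"), count = c(10, 90))
  expect_identical(detect_fixation(df, "x")$winner, "y")
})

test_that("event logs round-trip through the TSV format", {
  phi <- c(p0 = 0.4, pb = 0.02, NONE = 0.58)
  sch <- fitness_scheme("p0", s = c(pb = 0.05), restrict_to_nc = FALSE)
  r <- average_rate_run(phi, sch, N = 300, u = 1e-4, L = 12,
                        generations = 1e5, seed = 10, tracked = "pb",
                        stop_at_fixation = TRUE)
  expect_identical(nrow(r$fixations), 1L)
  expect_identical(r$fixations$phenotype, "pb")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_event_log(r, f)
  back <- read_event_log(f)
  expect_identical(sum(back$event_type == "fixation"), 1L)
  app <- back[back$event_type == "appearance", ]
  expect_equal(app$generation, r$events$generation)
  expect_identical(app$phenotype_id, r$events$phenotype)
})
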