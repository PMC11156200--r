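test_that("scaling times obey their defining algebra", {
  p <- scaling_times(N = 1000, u = 2e-5, L = 12, K = 4, rho = 0.35,
                     portal_prob = 0.1)
  expect_equal(p$t_ne, 1 / (12 * 2e-5 * 0.35))
  expect_equal(p$t_gene, 3 / (1000 * 2e-5))
  expect_equal(p$M, p$t_ne / p$t_gene)
  expect_equal(p$t_port, p$t_ne / 0.1)
  # K = 2 with N = 1/u: every specific neighbour arises once per generation
  expect_equal(scaling_times(N = 1e4, u = 1e-4, L = 10, K = 2,
                             rho = 0.5)$t_gene, 1)
  # if every genotype is a portal, t_port collapses onto t_ne
  q <- scaling_times(N = 100, u = 1e-4, L = 10, K = 4, rho = 0.4,
                     portal_prob = 1)
  expect_equal(q$t_port, q$t_ne)
  expect_error(scaling_times(N = 100, u = 1e-4, L = 10, K = 4, rho = 0),
               "rho")
})

test_that("the Kimura fixation probability has the right limits", {
  expect_equal(p_fix_kimura(0, 500), 1 / 500)
  expect_equal(p_fix_kimura(1e-13, 500), 1 / 500)
  # N -> infinity at s = 0.1: 1 - exp(-0.2)
  expect_equal(p_fix_kimura(0.1, 1e9), 1 - exp(-0.2), tolerance = 1e-6)
  # monotone in s
  s <- c(0.001, 0.01, 0.05, 0.1)
  expect_true(all(diff(p_fix_kimura(s, 1000)) > 0))
})

test_that("burst saturation follows p_portal_fix and its 1/M threshold", {
  expect_equal(p_portal_fix(0.5, 2), 0.5)    # p_fix * M = 1
  expect_equal(p_portal_fix(1, 1e9), 1, tolerance = 1e-8)
  expect_true(all(diff(p_portal_fix(c(0.01, 0.05, 0.2), 10)) > 0))
  expect_true(all(diff(p_portal_fix(0.05, c(1, 10, 100))) > 0))
  # beyond p_fix * M = 20, doubling p_fix changes the outcome by < 5%
  pf <- 0.21; M <- 100
  rel <- abs(p_portal_fix(2 * pf, M) - p_portal_fix(pf, M)) /
    p_portal_fix(pf, M)
  expect_lt(rel, 0.05)
  expect_equal(selection_threshold(100), 0.01)
})

test_that("origin-fixation times scale with phi and s as expected", {
  # doubling phi halves the time
  expect_equal(t_fix_average_rate(2e-3, 0.05, 1000, 2e-5, 12),
               t_fix_average_rate(1e-3, 0.05, 1000, 2e-5, 12) / 2)
  # in the linear regime 1/N << s << 1, t_fix is proportional to 1/s
  t1 <- t_fix_average_rate(1e-3, 0.01, 1e5, 2e-5, 12)
  t2 <- t_fix_average_rate(1e-3, 0.02, 1e5, 2e-5, 12)
  expect_equal(t1 / t2, 2, tolerance = 0.02)
  expect_identical(t_fix_average_rate(0, 0.05, 1000, 2e-5, 12), Inf)
})

test_that("the multi-peak first-fixation law is normalised and symmetric", {
  expect_equal(first_fixation_probability(c(5, 5)), c(0.5, 0.5))
  expect_equal(first_fixation_probability(rep(3.3, 7)), rep(1 / 7, 7))
  set.seed(2)
  for (i in 1:20) {
    t <- stats::rlnorm(sample(2:6, 1), meanlog = 8, sdlog = 2)
    p <- first_fixation_probability(t)
    expect_equal(sum(p), 1)
    # shorter fixation times win more often
    expect_identical(order(p), order(t, decreasing = TRUE))
  }
  expect_error(first_fixation_probability(c(1, -1)), "> 0")
})

test_that("the two-peak ratio law is recovered from origin-fixation times", {
  grid <- expand.grid(phi_f = c(7.4e-3, 1e-3), phi_r = c(2.3e-4, 1e-4),
                      s_f = c(0.01, 0.05), s_r = c(0.02, 0.1),
                      N = c(200, 1000))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    t_r <- t_fix_average_rate(g$phi_r, g$s_r, g$N, 2e-5, 12)
    t_f <- t_fix_average_rate(g$phi_f, g$s_f, g$N, 2e-5, 12)
    expect_equal(first_fixation_probability(c(t_r, t_f))[1],
                 p_r_fixes_origin_fixation(g$phi_f, g$phi_r, g$s_f, g$s_r,
                                           g$N))
  }
  # equal spectra and advantages: a fair coin
  expect_equal(p_r_fixes_origin_fixation(1e-3, 1e-3, 0.05, 0.05, 500), 0.5)
})

test_that("theory reports assemble all quantities consistently", {
  rep <- theory_report(N = 1000, u = 2e-5, L = 12, K = 4, rho = 0.35,
                       phi = c(pb = 1.7e-2, pr = 1.3e-3),
                       s = c(pr = 0.05),
                       portal_prob = c(pr = 0.12), target = "pr")
  expect_equal(rep$params$NuL, 0.24)
  expect_equal(rep$M, rep$t_ne / rep$t_gene)
  expect_equal(rep$selection_threshold, 1 / rep$M)
  expect_equal(rep$target$introduction_rate, 1.3e-3 * 0.24)
  expect_equal(rep$target$t_fix_average_rate,
               1 / (rep$target$introduction_rate * rep$target$p_fix))
  js <- jsonlite::toJSON(rep, auto_unbox = TRUE)
  expect_true(jsonlite::validate(js))
})
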