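test_that("random GP maps are deterministic pure functions of (genotype, seed)", {
  phi <- c(A = 0.5, B = 0.3, NONE = 0.2)
  m1 <- make_random_gp_map(phi, L = 12, K = 4, seed = 11)
  m2 <- make_random_gp_map(phi, L = 12, K = 4, seed = 11)
  m3 <- make_random_gp_map(phi, L = 12, K = 4, seed = 12)
  g <- c("AUACGAAACGUA", "GGGGAAAACCCC", "AAAAAAAAAAAA")
  expect_identical(map_phenotype(m1, g), map_phenotype(m2, g))
  expect_false(identical(map_phenotype(m1, replicate(50, paste(
    sample(c("A", "C", "G", "U"), 12, TRUE), collapse = ""))),
    map_phenotype(m3, replicate(50, paste(
      sample(c("A", "C", "G", "U"), 12, TRUE), collapse = "")))))
  expect_error(make_random_gp_map(c(A = 0.5, B = 0.4), L = 12, K = 4,
                                  seed = 1), "sum to 1")
})

test_that("random GP map frequencies converge to phi over sampled genotypes", {
  phi <- c(A = 0.5, B = 0.3, NONE = 0.2)
  m <- make_random_gp_map(phi, L = 12, K = 4, seed = 5)
  set.seed(1)
  n <- 1e5
  g <- replicate(n, paste(sample(c("A", "C", "G", "U"), 12, TRUE),
                          collapse = ""))
  g <- unique(g)  # distinct genotypes are independent draws
  freq <- table(map_phenotype(m, g)) / length(g)
  for (p in names(phi)) {
    se <- sqrt(phi[[p]] * (1 - phi[[p]]) / length(g))
    expect_lt(abs(freq[[p]] - phi[[p]]), 3 * se)
  }
})

test_that("a one-phenotype random map is wholly neutral", {
  m <- make_random_gp_map(c(P0 = 1), L = 4, K = 2, seed = 3)
  proto_genos <- phenoburst:::all_genotypes(m)
  expect_true(all(map_phenotype(m, proto_genos) == "P0"))
  nc <- nc_statistics(build_neutral_component("HHHH", m), m)
  expect_identical(length(nc$genotypes), 16L)
  expect_equal(nc$rho, 1)
})

test_that("topology maps preserve the neutral graph exactly and exclude external p0", {
  fx <- shared_fixture()
  tm <- make_topology_gp_map(fx$nc, seed = 21, K = 2)
  # NC members keep p0 and the rebuilt component is identical
  expect_true(all(map_phenotype(tm, fx$nc$genotypes) == fx$nc$phenotype))
  nc_t <- build_neutral_component(fx$nc$genotypes[1], tm)
  expect_identical(nc_t$genotypes, fx$nc$genotypes)
  expect_identical(nc_t$edges, fx$nc$edges)
  # no genotype outside the NC ever draws p0
  all_g <- phenoburst:::all_genotypes(fx$map)
  outside <- setdiff(all_g, fx$nc$genotypes)
  expect_false(any(map_phenotype(tm, outside) == fx$nc$phenotype))
  # outward mutation spectrum matches the renormalised phi within 3 SE
  nc_t <- nc_statistics(nc_t, tm)
  phi_rest <- fx$nc$phi[names(fx$nc$phi) != fx$nc$phenotype]
  phi_rest <- phi_rest / sum(phi_rest)
  out_t <- nc_t$phi[names(nc_t$phi) != nc_t$phenotype]
  out_t <- out_t / sum(out_t)
  # number of distinct boundary genotypes drawing labels independently
  n_draws <- sum(fx$nc$adjacent_counts)
  for (p in names(phi_rest)) {
    se <- sqrt(phi_rest[[p]] * (1 - phi_rest[[p]]) / n_draws)
    got <- if (p %in% names(out_t)) out_t[[p]] else 0
    expect_lt(abs(got - phi_rest[[p]]), 3 * se + 1e-12)
  }
  expect_error(make_topology_gp_map(
    structure(list(phenotype = "P0", genotypes = "AA",
                   phi = c(P0 = 1)), class = "neutral_component"),
    seed = 1, K = 2), "no mass")
})

test_that("community detection resolves planted cliques and is reproducible", {
  # two 10-cliques joined by one edge
  glue <- function(members) t(combn(members, 2))
  a <- sprintf("A%02d", 1:10)
  b <- sprintf("B%02d", 1:10)
  nc <- structure(list(phenotype = "P0", genotypes = sort(c(a, b)),
                       edges = rbind(glue(a), glue(b), c("A01", "B01"))),
                  class = "neutral_component")
  cm <- detect_communities(nc, seed = 4)
  expect_identical(length(unique(cm)), 2L)
  expect_identical(length(unique(cm[a])), 1L)
  expect_identical(length(unique(cm[b])), 1L)
  expect_false(cm[["A01"]] == cm[["B01"]])
  expect_identical(detect_communities(nc, seed = 4), cm)

  # a complete graph is a single community
  k <- sprintf("K%02d", 1:8)
  nck <- structure(list(phenotype = "P0", genotypes = k,
                        edges = glue(k)), class = "neutral_component")
  expect_identical(length(unique(detect_communities(nck, seed = 1))), 1L)

  # partition files round-trip
  f <- withr::local_tempfile(fileext = ".tsv")
  write_communities(cm, f)
  expect_identical(read_communities(f), cm)
})

test_that("community maps permute labels within strata and preserve phi exactly", {
  fx <- shared_fixture()
  nc <- fx$nc
  comms <- detect_communities(nc, seed = 9)
  cmap <- make_community_gp_map(fx$map, nc, comms, seed = 31)

  # recompute the component on the overlay: same NC, exactly the same phi
  nc_c <- nc_statistics(build_neutral_component(nc$genotypes[1], cmap), cmap)
  expect_identical(nc_c$genotypes, nc$genotypes)
  expect_equal(nc_c$phi, nc$phi)

  # stratum label multisets are exactly preserved; multi-community
  # neighbours are untouched
  member_set <- nc$genotypes
  boundary_info <- new.env(parent = emptyenv())
  for (g in member_set) {
    cm <- comms[[g]]
    nb <- point_mutation_neighbors(g, fx$map)
    for (x in setdiff(nb, member_set)) {
      rec <- if (exists(x, boundary_info, inherits = FALSE))
        get(x, boundary_info) else list(comms = integer(0), n = 0L)
      rec$comms <- unique(c(rec$comms, cm))
      rec$n <- rec$n + 1L
      assign(x, rec, boundary_info)
    }
  }
  boundary <- ls(boundary_info)
  info <- lapply(boundary, get, envir = boundary_info)
  ncomm <- vapply(info, function(r) length(r$comms), integer(1))
  multi <- boundary[ncomm > 1]
  expect_identical(map_phenotype(cmap, multi), map_phenotype(fx$map, multi))
  single <- boundary[ncomm == 1]
  strat_key <- paste(vapply(info[ncomm == 1], function(r) r$comms, integer(1)),
                     vapply(info[ncomm == 1], function(r) r$n, integer(1)))
  for (key in unique(strat_key)) {
    members <- single[strat_key == key]
    expect_identical(sort(map_phenotype(cmap, members)),
                     sort(map_phenotype(fx$map, members)))
  }
  expect_error(make_community_gp_map(fx$map, nc,
                                     comms[-1], seed = 1), "cover")
})

test_that("a single-community partition reproduces the reference spectrum", {
  fx <- shared_fixture()
  one <- setNames(rep(1L, length(fx$nc$genotypes)), fx$nc$genotypes)
  cmap <- make_community_gp_map(fx$map, fx$nc, one, seed = 8)
  nc_c <- nc_statistics(build_neutral_component(fx$nc$genotypes[1], cmap),
                        cmap)
  expect_equal(nc_c$phi, fx$nc$phi)
})
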