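test_that("BFS extraction equals exhaustive connected-component labelling", {
  fx <- shared_fixture()
  seed <- fx$nc$genotypes[1]
  oracle <- oracle_component_of(seed, fx$map)
  expect_identical(fx$nc$genotypes, oracle)
  # and from a different member of the same component
  nc2 <- build_neutral_component(fx$nc$genotypes[length(fx$nc$genotypes)],
                                 fx$map)
  expect_identical(nc2$genotypes, oracle)
  expect_identical(nc2$edges, fx$nc$edges)
})

test_that("a seed with no neutral neighbours forms a singleton component", {
  map <- isolated_seed_map()
  nc <- build_neutral_component("HHH", map)
  expect_identical(nc$genotypes, "HHH")
  expect_identical(nrow(nc$edges), 0L)
  nc <- nc_statistics(nc, map)
  expect_identical(nc$rho, 0)
  expect_identical(unname(nc$phi[["Y"]]), 1)
})

test_that("building from an undefined-phenotype seed errors", {
  proto <- phenoburst:::new_gp_map("proto", L = 2L, K = 2L,
                                   alphabet = c("H", "P"))
  genos <- phenoburst:::all_genotypes(proto)
  map <- table_gp_map(setNames(rep("NONE", 4), genos),
                      alphabet = c("H", "P"))
  expect_error(build_neutral_component("HH", map), "NONE")
})

test_that("component statistics are exact enumeration fractions", {
  fx <- shared_fixture()
  nc <- fx$nc
  D <- 6 * (2 - 1)
  total <- length(nc$genotypes) * D
  expect_equal(sum(nc$phi), 1)
  expect_equal(unname(nc$phi[[nc$phenotype]]), nc$rho)
  expect_true(nc$rho >= 0 && nc$rho <= 1)
  expect_true(nc$rho_component <= nc$rho)
  # n_counts aggregates back to phi exactly
  agg <- tapply(nc$n_counts$count, nc$n_counts$phenotype, sum)
  expect_equal(as.numeric(agg[names(nc$phi)]) / total,
               unname(nc$phi))
  expect_equal(sum(nc$n_counts$count), total)
  # portals are non-empty exactly where phi > 0
  expect_setequal(names(nc$portals), names(nc$phi))
  expect_true(all(vapply(nc$portals, length, integer(1)) > 0))
  expect_true(all(unlist(nc$portals[names(nc$portals) != nc$phenotype]) %in%
                    nc$genotypes))
})

test_that("portal probabilities match direct enumeration", {
  fx <- shared_fixture()
  nc <- fx$nc
  for (p in names(nc$phi)) {
    # brute force: member genotypes with >= 1 mutation to p
    hits <- vapply(nc$genotypes, function(g) {
      any(map_phenotype(fx$map,
                        point_mutation_neighbors(g, fx$map)) == p)
    }, logical(1))
    expect_equal(portal_probability(nc, p), mean(hits))
  }
  expect_identical(portal_probability(nc, "no-such-phenotype"), 0)
})

test_that("per-member mutation-count distributions are normalised and consistent", {
  fx <- shared_fixture()
  nc <- fx$nc
  for (p in names(nc$phi)) {
    w <- portal_count_distribution(nc, p)
    expect_equal(sum(w), 1)
    n_vals <- as.numeric(names(w))
    # the mean neighbour count recovers phi exactly
    expect_equal(sum(n_vals * w) / 6, unname(nc$phi[[p]]))
    # weight at zero complements the portal probability
    p_zero <- if ("0" %in% names(w)) w[["0"]] else 0
    expect_equal(1 - p_zero, portal_probability(nc, p))
  }
})

test_that("neutral components round-trip through node/edge TSV files", {
  fx <- shared_fixture()
  stem <- file.path(withr::local_tempdir(), "nc")
  write_neutral_component(fx$nc, stem)
  back <- read_neutral_component(stem)
  expect_identical(back$phenotype, fx$nc$phenotype)
  expect_identical(back$genotypes, fx$nc$genotypes)
  expect_identical(back$edges, fx$nc$edges)
  expect_equal(back$phi, fx$nc$phi)
  expect_equal(back$rho, fx$nc$rho)
  expect_equal(back$rho_component, fx$nc$rho_component)
  expect_identical(back$portals, fx$nc$portals)
})

test_that("adjacent-genotype counts identify phenotypes operationally", {
  fx <- shared_fixture()
  nc <- fx$nc
  counts <- nc$adjacent_counts
  # counts are distinct non-member genotypes; cross-check one phenotype by
  # direct enumeration
  p <- names(counts)[1]
  adj <- unique(unlist(lapply(nc$genotypes, function(g) {
    nb <- point_mutation_neighbors(g, fx$map)
    nb[map_phenotype(fx$map, nb) == p]
  })))
  adj <- setdiff(adj, nc$genotypes)
  expect_identical(unname(counts[[p]]), length(adj))
  if (sum(counts == counts[[p]]) == 1) {
    expect_identical(identify_adjacent_phenotype(nc, counts[[p]]), p)
  }
  expect_error(identify_adjacent_phenotype(nc, 10^9), "exactly one")
})
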