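test_that("point-mutation neighbourhoods have size L(K-1) in deterministic order", {
  proto <- phenoburst:::new_gp_map("proto", L = 12L, K = 4L,
                                   alphabet = c("A", "C", "G", "U"))
  g <- "AUACGAAACGUA"
  nb <- point_mutation_neighbors(g, proto)
  expect_length(nb, 12 * 3)
  expect_false(g %in% nb)
  expect_false(anyDuplicated(nb) > 0)
  # every neighbour differs at exactly one position
  ham <- vapply(strsplit(nb, ""), function(x)
    sum(x != strsplit(g, "")[[1]]), integer(1))
  expect_true(all(ham == 1))
  # position-major order: first neighbours mutate position 1
  expect_equal(substr(nb[1:3], 2, 12), rep(substr(g, 2, 12), 3))

  hp <- phenoburst:::new_gp_map("proto", L = 2L, K = 2L,
                                alphabet = c("H", "P"))
  expect_setequal(point_mutation_neighbors("HH", hp), c("PH", "HP"))

  expect_error(point_mutation_neighbors("AXACGAAACGUA", proto),
               "invalid genotype")
})

test_that("HP folding matches a naive exhaustive-enumeration oracle on the full 3x3 space", {
  map <- hp_gp_map(3)
  proto <- phenoburst:::new_gp_map("proto", L = 9L, K = 2L,
                                   alphabet = c("H", "P"))
  genotypes <- phenoburst:::all_genotypes(proto)
  expect_length(genotypes, 512)
  got <- map_phenotype(map, genotypes)
  # the all-P sequence has no H-H contacts: every walk ties at 0
  expect_identical(got[genotypes == "PPPPPPPPP"], "NONE")
  # the oracle encodes conformations differently, so compare the induced
  # partitions: identical degeneracy decisions, and a bijection between
  # the two labellings of folded genotypes
  oracle <- vapply(genotypes, oracle_fold_hp, character(1), n = 3)
  expect_identical(unname(oracle == "NONE"), got == "NONE")
  folded <- got != "NONE"
  pairs <- unique(data.frame(pkg = got[folded], ora = unname(oracle[folded])))
  expect_identical(anyDuplicated(pairs$pkg), 0L)
  expect_identical(anyDuplicated(pairs$ora), 0L)
  # folding is pure: a second evaluation is identical
  expect_identical(map_phenotype(map, genotypes[1:20]), got[1:20])
})

test_that("fold_hp validates the lattice size", {
  expect_error(fold_hp("HPHP", lattice_side = 3), "lattice_side")
})

test_that("biomorph development is deterministic, bounded and mirror-symmetric", {
  map <- biomorph_gp_map()
  expect_equal(genotype_space_size(map), 7^8 * 8)

  g <- "1,-2,0,3,1,1,-3,2,5"
  expect_identical(develop_biomorph(g), develop_biomorph(g))

  expect_error(develop_biomorph("4,0,0,0,0,0,0,0,1"), "out of range")
  expect_error(develop_biomorph("0,0,0,0,0,0,0,0,9"), "out of range")
  expect_error(develop_biomorph("0,0,0,0,0,0,0,0"), "invalid")

  # each of the first 8 genes has 6 alternatives, gene 9 has 7
  expect_length(point_mutation_neighbors(g, map), 8 * 6 + 7)

  set.seed(42)
  for (i in 1:100) {
    v <- c(sample(-3:3, 8, replace = TRUE), sample(1:8, 1))
    grid <- develop_biomorph(v, as_matrix = TRUE)
    # bilateral symmetry about the centre column (column 30 is unused by
    # the symmetric rasterisation)
    expect_equal(grid[, 1:29], grid[, 29:1])
  }
})

test_that("GP map tables round-trip through the TSV format", {
  fx <- shared_fixture()
  genotypes <- phenoburst:::all_genotypes(fx$map)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gp_map_table(fx$map, genotypes, f)
  back <- read_gp_map_table(f)
  expect_identical(back$alphabet, fx$map$alphabet)
  expect_identical(map_phenotype(back, genotypes),
                   map_phenotype(fx$map, genotypes))
  expect_error(map_phenotype(back, "ZZZZZZ"), "not in table")
})

test_that("genotype sequences round-trip through FASTA", {
  seqs <- c(a = "AUACGAAACGUA", b = "GGGGAAAACCCC")
  f <- withr::local_tempfile(fileext = ".fasta")
  write_genotypes_fasta(seqs, f, names = names(seqs))
  back <- read_genotypes_fasta(f)
  expect_identical(unname(back), unname(seqs))
  expect_identical(names(back), names(seqs))
})

test_that("genotype codes invert cleanly", {
  fx <- shared_fixture()
  genotypes <- phenoburst:::all_genotypes(fx$map)
  codes <- phenoburst:::genotype_to_code(genotypes, fx$map)
  expect_identical(sort(codes), as.numeric(seq_along(genotypes) - 1))
  expect_identical(phenoburst:::code_to_genotype(codes, fx$map), genotypes)
})
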