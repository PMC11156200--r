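# Independent brute-force oracles used across the suite.  These deliberately
# re-derive results with naive algorithms and share no code with the package
# internals they check.

# --- exhaustive neutral-component labelling --------------------------------
# Connected components of the phenotype-preserving mutation graph over an
# entire (small) genotype space, by union-find over all pairs at Hamming
# distance 1.
oracle_component_of <- function(seed, map) {
  genotypes <- phenoburst:::all_genotypes(map)
  ph <- map_phenotype(map, genotypes)
  idx <- seq_along(genotypes)
  names(idx) <- genotypes
  parent <- idx
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  chars <- strsplit(genotypes, "", fixed = TRUE)
  for (i in idx) {
    for (pos in seq_len(map$L)) {
      for (b in map$alphabet) {
        if (b != chars[[i]][pos]) {
          t <- chars[[i]]
          t[pos] <- b
          j <- idx[[paste(t, collapse = "")]]
          if (j > i && ph[i] == ph[j]) unite(i, j)
        }
      }
    }
  }
  root <- find(idx[[seed]])
  sort(genotypes[vapply(idx, find, integer(1)) == root & ph == ph[idx[[seed]]]])
}

# --- naive HP folding -------------------------------------------------------
# Enumerates every directed compact walk by its own recursion, evaluates
# energies directly, and decides the phenotype with its own symmetry
# handling (coordinate lists instead of the package's cell indices).
oracle_fold_hp <- function(seq_hp, n) {
  h <- strsplit(seq_hp, "", fixed = TRUE)[[1]] == "H"
  ncell <- n * n
  walks <- list()
  dfs <- function(path) {
    if (nrow(path) == ncell) {
      walks[[length(walks) + 1L]] <<- path
      return()
    }
    last <- path[nrow(path), ]
    for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
      nxt <- last + d
      if (nxt[1] >= 1 && nxt[1] <= n && nxt[2] >= 1 && nxt[2] <= n &&
          !any(path[, 1] == nxt[1] & path[, 2] == nxt[2])) {
        dfs(rbind(path, nxt))
      }
    }
  }
  for (r in 1:n) for (c in 1:n) dfs(matrix(c(r, c), 1))
  energy <- function(w) {
    e <- 0
    for (i in seq_len(ncell - 2)) {
      for (j in seq(i + 2, ncell)) {
        if (sum(abs(w[i, ] - w[j, ])) == 1 && h[i] && h[j]) e <- e - 1
      }
    }
    e
  }
  sym_images <- function(w) {
    tr <- list(function(p) p,
               function(p) cbind(p[, 2], n + 1 - p[, 1]),
               function(p) cbind(n + 1 - p[, 1], n + 1 - p[, 2]),
               function(p) cbind(n + 1 - p[, 2], p[, 1]),
               function(p) cbind(p[, 1], n + 1 - p[, 2]),
               function(p) cbind(n + 1 - p[, 1], p[, 2]),
               function(p) cbind(p[, 2], p[, 1]),
               function(p) cbind(n + 1 - p[, 2], n + 1 - p[, 1]))
    keys <- character(0)
    for (f in tr) {
      img <- f(w)
      keys <- c(keys,
                paste(apply(img, 1, paste, collapse = "."), collapse = ";"),
                paste(rev(apply(img, 1, paste, collapse = ".")), collapse = ";"))
    }
    keys
  }
  e_all <- vapply(walks, energy, numeric(1))
  mn <- min(e_all)
  winners <- walks[e_all == mn]
  ids <- unique(vapply(winners, function(w) min(sym_images(w)), character(1)))
  if (length(ids) == 1L) ids else "NONE"
}

# --- small fixture builders -------------------------------------------------
# memoised fixture maps shared across tests (construction is deterministic)
.fixture_cache <- new.env(parent = emptyenv())
shared_fixture <- function(L = 6, K = 2, n_phenotypes = 4,
                           phi_profile = c(0.4, 0.3, 0.2, 0.1), seed = 7) {
  key <- paste(L, K, n_phenotypes, paste(phi_profile, collapse = "_"), seed,
               sep = "|")
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- make_fixture_map(
      L = L, K = K, n_phenotypes = n_phenotypes,
      phi_profile = phi_profile, seed = seed)
  }
  .fixture_cache[[key]]
}

# a hand-built table map: one isolated genotype of phenotype X in a sea of Y
isolated_seed_map <- function() {
  proto <- phenoburst:::new_gp_map("proto", L = 3L, K = 2L,
                                   alphabet = c("H", "P"))
  genotypes <- phenoburst:::all_genotypes(proto)
  ph <- setNames(rep("Y", length(genotypes)), genotypes)
  ph[["HHH"]] <- "X"
  table_gp_map(ph, alphabet = c("H", "P"))
}
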