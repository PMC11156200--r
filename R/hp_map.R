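#' Hydrophobic-polar (HP) lattice protein GP map
#'
#' Genotypes are strings over `{H, P}` of length `lattice_side^2`.  The
#' phenotype is the minimum-energy *compact* conformation: a self-avoiding
#' walk that covers every site of the square lattice.  The energy model
#' favours hydrophobic contacts, assigning one free-energy unit (-1) to every
#' pair of `H` residues that are adjacent on the lattice but not consecutive
#' along the chain.  If the minimum is degenerate - two or more conformations
#' that are not related by a lattice symmetry or chain reversal tie at the
#' minimum energy - the genotype is assigned the undefined phenotype
#' `"NONE"`, mirroring the degenerate-MFE rule of the RNA map.
#'
#' Compact walks are enumerated once per lattice side (a depth-first search
#' over Hamiltonian paths of the grid) and canonicalised under the 8 lattice
#' symmetries; chain reversal is additionally folded into the phenotype
#' identifier, so that symmetric refolds of the same conformation never
#' create spurious degeneracy.
#'
#' @param lattice_side side of the square lattice (2-5; the paper-scale 5x5
#'   lattice is supported but full-space enumeration at that size is
#'   long-running).
#' @return a `gp_map` of type `"hp"`.
#' @export
hp_gp_map <- function(lattice_side = 3) {
  stopifnot(lattice_side >= 2, lattice_side <= 5)
  conf <- hp_conformations(lattice_side)
  new_gp_map("hp", L = lattice_side^2, K = 2L, alphabet = c("H", "P"),
             lattice_side = lattice_side, conformations = conf)
}

# cache of enumerated conformations, keyed by lattice side
.hp_cache <- new.env(parent = emptyenv())

# the 8 symmetries of the n x n grid acting on (row, col) pairs
hp_symmetries <- function(n) {
  list(
    function(r, c) cbind(r, c),
    function(r, c) cbind(c, n + 1 - r),          # rot 90
    function(r, c) cbind(n + 1 - r, n + 1 - c),  # rot 180
    function(r, c) cbind(n + 1 - c, r),          # rot 270
    function(r, c) cbind(r, n + 1 - c),          # mirror cols
    function(r, c) cbind(n + 1 - r, c),          # mirror rows
    function(r, c) cbind(c, r),                  # transpose
    function(r, c) cbind(n + 1 - c, n + 1 - r)   # anti-transpose
  )
}

# enumerate all compact self-avoiding walks (Hamiltonian paths) of the n x n
# grid, grouped into symmetry classes; per class: a representative walk, the
# list of non-bonded lattice contacts (chain index pairs), and a phenotype
# identifier canonical under symmetry + chain reversal
hp_conformations <- function(n) {
  key <- as.character(n)
  if (!is.null(.hp_cache[[key]])) return(.hp_cache[[key]])
  ncell <- n * n
  nbr <- vector("list", ncell)
  for (cell in seq_len(ncell)) {
    r <- (cell - 1L) %/% n + 1L
    c <- (cell - 1L) %% n + 1L
    cand <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    ok <- cand[, 1] >= 1 & cand[, 1] <= n & cand[, 2] >= 1 & cand[, 2] <= n
    nbr[[cell]] <- (cand[ok, 1, drop = TRUE] - 1L) * n + cand[ok, 2, drop = TRUE]
  }
  walks <- list()
  path <- integer(ncell)
  used <- logical(ncell)
  dfs <- function(cell, depth) {
    path[depth] <<- cell
    used[cell] <<- TRUE
    if (depth == ncell) {
      walks[[length(walks) + 1L]] <<- path
    } else {
      for (nx in nbr[[cell]]) if (!used[nx]) dfs(nx, depth + 1L)
    }
    used[cell] <<- FALSE
  }
  for (start in seq_len(ncell)) dfs(start, 1L)

  syms <- hp_symmetries(n)
  apply_sym <- function(walk, f) {
    r <- (walk - 1L) %/% n + 1L
    c <- (walk - 1L) %% n + 1L
    rc <- f(r, c)
    (rc[, 1] - 1L) * n + rc[, 2]
  }
  walk_key <- function(w) paste(w, collapse = ",")
  canon_sym <- function(walk) {
    min(vapply(syms, function(f) walk_key(apply_sym(walk, f)), character(1)))
  }
  canon_full <- function(walk) {
    keys <- c(vapply(syms, function(f) walk_key(apply_sym(walk, f)), character(1)),
              vapply(syms, function(f) walk_key(rev(apply_sym(walk, f))), character(1)))
    min(keys)
  }

  seen <- new.env(parent = emptyenv())
  classes <- list()
  for (w in walks) {
    ck <- canon_sym(w)
    if (!exists(ck, seen, inherits = FALSE)) {
      assign(ck, TRUE, seen)
      pos_of <- integer(ncell)
      pos_of[w] <- seq_len(ncell)
      contacts <- NULL
      for (cell in seq_len(ncell)) {
        for (nx in nbr[[cell]]) {
          i <- pos_of[cell]; j <- pos_of[nx]
          if (j > i + 1L) contacts <- rbind(contacts, c(i, j))
        }
      }
      classes[[length(classes) + 1L]] <- list(
        walk = w,
        contacts = contacts,  # chain-index pairs, NULL if none
        phenotype = paste0("HP", n, "x", n, ":", canon_full(w))
      )
    }
  }
  .hp_cache[[key]] <- classes
  classes
}

#' Fold HP sequences on the compact lattice
#'
#' @param seqs character vector over `{H,P}` of length `lattice_side^2`.
#' @param lattice_side side of the lattice; inferred from the sequence length
#'   when omitted.
#' @param map optionally a prebuilt [hp_gp_map()].
#' @return character vector of phenotype identifiers; `"NONE"` when the
#'   minimum energy is degenerate across inequivalent conformations.
#' @export
fold_hp <- function(seqs, lattice_side = NULL, map = NULL) {
  if (is.null(map)) {
    if (is.null(lattice_side)) {
      lattice_side <- as.integer(round(sqrt(nchar(seqs[1]))))
    }
    if (lattice_side^2 != nchar(seqs[1])) {
      stop("sequence length must equal lattice_side^2")
    }
    map <- hp_gp_map(lattice_side)
  }
  map_phenotype(map, seqs)
}

#' @export
map_phenotype.hp_gp_map <- function(map, genotypes) {
  check_genotype(map, genotypes)
  conf <- map$conformations
  vapply(genotypes, function(g) {
    h <- strsplit(g, "", fixed = TRUE)[[1]] == "H"
    e <- vapply(conf, function(cl) {
      if (is.null(cl$contacts)) return(0)
      -sum(h[cl$contacts[, 1]] & h[cl$contacts[, 2]])
    }, numeric(1))
    mn <- min(e)
    at_min <- which(e == mn)
    ids <- unique(vapply(conf[at_min], `[[`, character(1), "phenotype"))
    if (length(ids) == 1L) ids else PHENOTYPE_NONE
  }, character(1), USE.NAMES = FALSE)
}
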