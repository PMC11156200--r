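#' Seeded random GP map
#'
#' The simplest null model: every genotype is assigned an independent
#' phenotype draw with fixed probabilities `phi`.  The draw is a pure
#' deterministic hash of (genotype, seed), so the map is lazily evaluable
#' over the whole `K^L` space without materialising it, and the same
#' genotype always returns the same phenotype.  Setting the frequency of
#' each phenotype to its mutation probability from a reference NC makes the
#' map's mean mutation spectrum match that NC.
#'
#' @param phi named numeric vector of phenotype probabilities, summing to 1.
#' @param L sequence length.
#' @param K alphabet size.
#' @param seed integer seed that fixes the map.
#' @param alphabet symbols; defaults to RNA for `K = 4`, `{H,P}` for
#'   `K = 2`, otherwise `A, B, C, ...`.
#' @return a `gp_map` of type `"random"`.
#' @export
make_random_gp_map <- function(phi, L, K, seed,
                               alphabet = default_alphabet(K)) {
  if (abs(sum(phi) - 1) > 1e-9) stop("phi must sum to 1")
  if (is.null(names(phi)) || anyDuplicated(names(phi))) {
    stop("phi must have unique phenotype names")
  }
  new_gp_map("random", L = L, K = as.integer(K), alphabet = alphabet,
             phi = phi, cum_phi = cumsum(phi / sum(phi)),
             map_seed = as.double(seed))
}

default_alphabet <- function(K) {
  if (K == 4) c("A", "C", "G", "U")
  else if (K == 2) c("H", "P")
  else LETTERS[seq_len(K)]
}

#' @export
map_phenotype.random_gp_map <- function(map, genotypes) {
  idx <- .rmap_phenotype_idx(symbol_indices(genotypes, map),
                             map$map_seed, map$cum_phi)
  names(map$phi)[idx]
}

#' Topology GP map
#'
#' Null model that keeps the reference NC and all of its neutral point
#' mutation links exactly, but erases non-neutral correlations: every
#' genotype outside the NC draws an independent random phenotype from the
#' reference spectrum restricted to non-initial phenotypes (renormalised so
#' the non-neutral probabilities sum to one).  No genotype outside the NC is
#' ever assigned the initial phenotype.
#'
#' @param nc reference [neutral_component][build_neutral_component] (with
#'   [nc_statistics()] if `phi` is not given).
#' @param phi spectrum to draw from; defaults to the component's `phi`.
#'   The initial-phenotype entry is removed and the rest renormalised.
#' @param seed integer seed fixing the random assignment.
#' @param L,K,alphabet genotype-space parameters; default to RNA-like
#'   values inferred from the component's genotypes.
#' @return a `gp_map` of type `"topology"`.
#' @export
make_topology_gp_map <- function(nc, phi = nc$phi, seed,
                                 L = nchar(nc$genotypes[1]), K = 4,
                                 alphabet = default_alphabet(K)) {
  if (is.null(phi)) stop("phi missing: run nc_statistics() or pass phi")
  p0 <- nc$phenotype
  phi_rest <- phi[names(phi) != p0]
  if (length(phi_rest) == 0 || sum(phi_rest) <= 0) {
    stop("phi has no mass on non-initial phenotypes")
  }
  phi_rest <- phi_rest / sum(phi_rest)
  member_env <- list2env(
    setNames(as.list(rep(TRUE, length(nc$genotypes))), nc$genotypes),
    parent = emptyenv())
  new_gp_map("topology", L = L, K = as.integer(K), alphabet = alphabet,
             p0 = p0, members = member_env,
             phi_rest = phi_rest, cum_phi = cumsum(phi_rest),
             map_seed = as.double(seed))
}

#' @export
map_phenotype.topology_gp_map <- function(map, genotypes) {
  out <- character(length(genotypes))
  in_nc <- vapply(genotypes, exists, logical(1), envir = map$members,
                  inherits = FALSE)
  out[in_nc] <- map$p0
  if (any(!in_nc)) {
    idx <- .rmap_phenotype_idx(symbol_indices(genotypes[!in_nc], map),
                               map$map_seed, map$cum_phi)
    out[!in_nc] <- names(map$phi_rest)[idx]
  }
  out
}

#' Detect network communities of a neutral component
#'
#' Partitions the component's neutral graph into communities by greedy
#' agglomerative modularity maximisation.  Vertices are shuffled with the
#' seed before clustering so ties are broken reproducibly; every genotype
#' ends up in exactly one community.
#'
#' @param nc a [build_neutral_component()] result.
#' @param seed integer seed for the tie-breaking shuffle.
#' @return named integer vector: community id per genotype.
#' @export
detect_communities <- function(nc, seed = 1) {
  stopifnot(length(nc$genotypes) >= 1)
  if (nrow(nc$edges) == 0) {
    return(setNames(seq_along(nc$genotypes), nc$genotypes))
  }
  perm <- withr_seed(seed, sample(nc$genotypes))
  g <- igraph::graph_from_edgelist(nc$edges, directed = FALSE)
  g <- igraph::add_vertices(
    g, sum(!nc$genotypes %in% igraph::V(g)$name),
    name = setdiff(nc$genotypes, igraph::V(g)$name))
  g <- igraph::permute(g, match(igraph::V(g)$name, perm))
  cl <- igraph::cluster_fast_greedy(g)
  mem <- igraph::membership(cl)
  # the single-community partition has modularity 0; if the greedy result
  # is no better (degenerate graphs, e.g. cliques), prefer the trivial one
  if (igraph::modularity(cl) <= 1e-12) mem[] <- 1L
  out <- setNames(as.integer(mem[nc$genotypes]), nc$genotypes)
  # renumber communities in order of first appearance for stability
  setNames(as.integer(factor(out, levels = unique(out[nc$genotypes]))),
           nc$genotypes)
}

# evaluate expr under a temporary RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv(), inherits = FALSE) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  expr
}

#' Community GP map
#'
#' Null model that randomises non-neutral mutational neighbourhoods one NC
#' community at a time, partially erasing non-neutral correlations.  For
#' each community, the non-NC genotypes adjacent to that community and to no
#' other community are collected and stratified by their exact number `n` of
#' mutational connections to the NC; phenotype labels are then permuted
#' within each `(community, n)` stratum.  Genotypes adjacent to several
#' communities are left unchanged, so the component's mutation spectrum
#' `phi` is preserved exactly.
#'
#' @param reference the GP map the component lives on.
#' @param nc the reference component (statistics not required).
#' @param communities named community membership from
#'   [detect_communities()], covering every component genotype.
#' @param seed integer seed for the stratum permutations.
#' @return a `gp_map` of type `"community"`: an overlay storing only the
#'   reassigned genotypes, with lookups falling through to `reference`.
#' @export
make_community_gp_map <- function(reference, nc, communities, seed) {
  if (!all(nc$genotypes %in% names(communities))) {
    stop("communities must cover every component genotype")
  }
  # which communities is each boundary genotype adjacent to, and how many
  # links does it have to the NC as a whole?
  member_set <- list2env(
    setNames(as.list(rep(TRUE, length(nc$genotypes))), nc$genotypes),
    parent = emptyenv())
  adj_comms <- new.env(parent = emptyenv())  # boundary genotype -> community ids
  n_links <- new.env(parent = emptyenv())    # boundary genotype -> #links to NC
  for (g in nc$genotypes) {
    cm <- communities[[g]]
    nb <- point_mutation_neighbors(g, reference)
    outside <- nb[!vapply(nb, exists, logical(1), envir = member_set,
                          inherits = FALSE)]
    for (x in outside) {
      assign(x, unique(c(if (exists(x, adj_comms, inherits = FALSE))
        get(x, adj_comms, inherits = FALSE), cm)), adj_comms)
      assign(x, (if (exists(x, n_links, inherits = FALSE))
        get(x, n_links, inherits = FALSE) else 0L) + 1L, n_links)
    }
  }
  boundary <- sort(ls(adj_comms, all.names = TRUE))
  bc <- lapply(boundary, get, envir = adj_comms)
  single <- boundary[vapply(bc, length, integer(1)) == 1L]
  comm_of <- vapply(single, function(x) get(x, adj_comms)[1], integer(1))
  links_of <- vapply(single, get, integer(1), envir = n_links)
  overlay <- new.env(parent = emptyenv())
  strata <- split(single, list(comm_of, links_of), drop = TRUE)
  withr_seed(seed, {
    for (stratum in strata) {
      if (length(stratum) < 2) next
      labels <- map_phenotype(reference, stratum)
      perm <- sample(length(stratum))
      for (i in seq_along(stratum)) {
        assign(stratum[i], labels[perm[i]], overlay)
      }
    }
  })
  new_gp_map("community", L = reference$L, K = reference$K,
             alphabet = reference$alphabet,
             reference = reference, overlay = overlay,
             p0 = nc$phenotype)
}

#' @export
map_phenotype.community_gp_map <- function(map, genotypes) {
  out <- character(length(genotypes))
  in_overlay <- vapply(genotypes, exists, logical(1), envir = map$overlay,
                       inherits = FALSE)
  out[in_overlay] <- vapply(genotypes[in_overlay], get, character(1),
                            envir = map$overlay, inherits = FALSE)
  if (any(!in_overlay)) {
    out[!in_overlay] <- map_phenotype(map$reference, genotypes[!in_overlay])
  }
  out
}

#' Write / read a community partition file
#'
#' TSV `genotype<TAB>community_id`.
#'
#' @param communities named integer vector from [detect_communities()].
#' @param file path.
#' @export
write_communities <- function(communities, file) {
  utils::write.table(
    data.frame(genotype = names(communities),
               community_id = as.integer(communities)),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_communities
#' @export
read_communities <- function(file) {
  tab <- utils::read.table(file, sep = "\t", header = TRUE,
                           colClasses = c(genotype = "character",
                                          community_id = "integer"))
  setNames(tab$community_id, tab$genotype)
}
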