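#' Extract the neutral component of a seed genotype
#'
#' A neutral component (NC) is a maximal set of genotypes that share one
#' phenotype and are mutually connected through single phenotype-preserving
#' point mutations.  The component is found by breadth-first search from the
#' seed over point-mutation neighbours, keeping neighbours with an identical
#' phenotype; the result (member set and neutral edge set) is independent of
#' traversal order.
#'
#' @param seed a genotype whose phenotype is not `"NONE"`.
#' @param map a [gp_map][new_gp_map].
#' @param max_size abort with an error if the component exceeds this many
#'   genotypes (guards against percolating components on random maps).
#' @return an object of class `neutral_component` with elements `phenotype`,
#'   `genotypes` (sorted lexicographically), `edges` (2-column character
#'   matrix of unordered neutral links, each row sorted), and statistics
#'   slots filled by [nc_statistics()].
#' @export
build_neutral_component <- function(seed, map, max_size = Inf) {
  p0 <- map_phenotype(map, seed)
  if (p0 == PHENOTYPE_NONE) {
    stop("seed genotype maps to the undefined phenotype NONE")
  }
  members <- new.env(parent = emptyenv())
  assign(seed, TRUE, members)
  frontier <- seed
  edges_a <- character(0)
  edges_b <- character(0)
  n_members <- 1L
  while (length(frontier)) {
    nxt <- character(0)
    for (g in frontier) {
      nb <- point_mutation_neighbors(g, map)
      ph <- map_phenotype(map, nb)
      neutral <- nb[ph == p0]
      if (length(neutral)) {
        # record each unordered edge once (from its smaller endpoint)
        lo <- pmin(g, neutral)
        hi <- pmax(g, neutral)
        keep <- g == lo
        edges_a <- c(edges_a, lo[keep])
        edges_b <- c(edges_b, hi[keep])
        new <- neutral[!vapply(neutral, exists, logical(1),
                               envir = members, inherits = FALSE)]
        for (x in new) assign(x, TRUE, members)
        n_members <- n_members + length(new)
        if (n_members > max_size) {
          stop("neutral component exceeds max_size = ", max_size)
        }
        nxt <- c(nxt, new)
      }
    }
    frontier <- unique(nxt)
  }
  genotypes <- sort(ls(members, all.names = TRUE))
  edges <- unique(cbind(edges_a, edges_b))
  # the loop above only records edges seen from the lexicographically smaller
  # endpoint's neighbourhood, so every edge is found (both endpoints are
  # expanded) and recorded once
  dimnames(edges) <- NULL
  if (length(edges) == 0) edges <- matrix(character(0), ncol = 2)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  structure(
    list(phenotype = p0, genotypes = genotypes, edges = edges,
         rho = NULL, rho_component = NULL, phi = NULL, portals = NULL,
         n_counts = NULL, adjacent_counts = NULL),
    class = "neutral_component")
}

#' @export
print.neutral_component <- function(x, ...) {
  cat(sprintf("<neutral component>  phenotype %s: %d genotypes, %d neutral edges\n",
              x$phenotype, length(x$genotypes), nrow(x$edges)))
  if (!is.null(x$rho)) {
    cat(sprintf("  robustness rho = %.4f (within-component %.4f), %d adjacent phenotypes\n",
                x$rho, x$rho_component, length(x$phi) - 1L))
  }
  invisible(x)
}

#' Mutation-spectrum statistics of a neutral component
#'
#' Enumerates all `|NC| * L * (K - 1)` point mutations from component
#' members and fills in:
#' \describe{
#'   \item{`rho`}{mutational robustness: the fraction of phenotype-preserving
#'     mutations.  This counts every mutation to the component's phenotype,
#'     including mutations to same-phenotype genotypes outside the component
#'     (other NCs of the same neutral set).}
#'   \item{`rho_component`}{the stricter fraction counting only mutations to
#'     component members; the two conventions are dynamically distinct when
#'     fitness is restricted to the initial NC.}
#'   \item{`phi`}{named vector: probability that a random point mutation on
#'     the component yields each phenotype, exact counts over the total.
#'     `phi[phenotype]` equals `rho` and the entries sum to one.}
#'   \item{`portals`}{named list: for each phenotype, the member genotypes
#'     with at least one mutation to it (the portal genotypes).}
#'   \item{`n_counts`}{data frame `(genotype, phenotype, count)`: number of
#'     point mutations from each member to each phenotype.}
#'   \item{`adjacent_counts`}{named vector: number of *distinct* non-member
#'     genotypes of each phenotype adjacent to the component (the node
#'     counts printed when an NC and its mutational halo are drawn).}
#' }
#'
#' @param nc a [build_neutral_component()] result.
#' @param map the GP map the component was built on.
#' @return the component with statistics filled in.
#' @export
nc_statistics <- function(nc, map) {
  p0 <- nc$phenotype
  members <- nc$genotypes
  member_set <- list2env(setNames(as.list(rep(TRUE, length(members))), members),
                         parent = emptyenv())
  total <- 0
  count_by_phen <- new.env(parent = emptyenv())
  neutral_in_component <- 0
  portal_env <- new.env(parent = emptyenv())
  adj_env <- new.env(parent = emptyenv())
  rows_g <- character(0); rows_p <- character(0); rows_n <- integer(0)
  for (g in members) {
    nb <- point_mutation_neighbors(g, map)
    ph <- map_phenotype(map, nb)
    total <- total + length(nb)
    tab <- table(ph)
    for (p in names(tab)) {
      prev <- if (exists(p, count_by_phen, inherits = FALSE))
        get(p, count_by_phen, inherits = FALSE) else 0
      assign(p, prev + as.integer(tab[[p]]), count_by_phen)
      pg <- if (exists(p, portal_env, inherits = FALSE))
        get(p, portal_env, inherits = FALSE) else character(0)
      assign(p, c(pg, g), portal_env)
    }
    rows_g <- c(rows_g, rep(g, length(tab)))
    rows_p <- c(rows_p, names(tab))
    rows_n <- c(rows_n, as.integer(tab))
    in_comp <- vapply(nb, exists, logical(1), envir = member_set,
                      inherits = FALSE)
    neutral_in_component <- neutral_in_component + sum(ph == p0 & in_comp)
    outside <- nb[!in_comp]
    ph_out <- ph[!in_comp]
    for (p in unique(ph_out)) {
      prev <- if (exists(p, adj_env, inherits = FALSE))
        get(p, adj_env, inherits = FALSE) else character(0)
      assign(p, unique(c(prev, outside[ph_out == p])), adj_env)
    }
  }
  phens <- sort(ls(count_by_phen, all.names = TRUE))
  counts <- vapply(phens, get, numeric(1), envir = count_by_phen)
  phi <- counts / total
  nc$phi <- phi
  # a singleton component with no neutral neighbours has rho = 0 (and no
  # p0 entry in the enumeration counts)
  nc$rho <- if (p0 %in% phens) unname(phi[p0]) else 0
  nc$rho_component <- neutral_in_component / total
  nc$portals <- setNames(lapply(phens, function(p)
    sort(unique(get(p, portal_env, inherits = FALSE)))), phens)
  nc$n_counts <- data.frame(genotype = rows_g, phenotype = rows_p,
                            count = rows_n, stringsAsFactors = FALSE)
  adj_ph <- sort(ls(adj_env, all.names = TRUE))
  nc$adjacent_counts <- setNames(
    vapply(adj_ph, function(p) length(get(p, adj_env, inherits = FALSE)),
           integer(1)), adj_ph)
  nc
}

#' Portal probability of a phenotype
#'
#' The probability that an arbitrary genotype of the component is a portal
#' to phenotype `p`, i.e. has at least one point mutation to `p`.
#'
#' @param nc a component with statistics ([nc_statistics()]).
#' @param p phenotype identifier.
#' @return `|portals[p]| / |genotypes|`; 0 for phenotypes absent from all
#'   neighbourhoods.
#' @export
portal_probability <- function(nc, p) {
  if (is.null(nc$portals)) stop("run nc_statistics() first")
  if (!p %in% names(nc$portals)) return(0)
  length(nc$portals[[p]]) / length(nc$genotypes)
}

#' Per-member distribution of mutation counts to a phenotype
#'
#' The distribution of `n_p`, the number of point mutations a component
#' member has to phenotype `p` (including members with zero), weighted
#' uniformly over members.  This is the mixture-weight input of
#' [poisson_mixture_prediction()].
#'
#' @inheritParams portal_probability
#' @return named numeric vector: names are counts (`"0"`, `"1"`, ...),
#'   values their frequencies over members (summing to one).
#' @export
portal_count_distribution <- function(nc, p) {
  if (is.null(nc$n_counts)) stop("run nc_statistics() first")
  sub <- nc$n_counts[nc$n_counts$phenotype == p, ]
  n <- setNames(rep(0L, length(nc$genotypes)), nc$genotypes)
  n[sub$genotype] <- sub$count
  tab <- table(n) / length(n)
  setNames(as.numeric(tab), names(tab))
}

#' Identify an adjacent phenotype by its adjacent-genotype count
#'
#' Selects the phenotype adjacent to the component that is carried by
#' exactly `n_adjacent` distinct neighbouring genotypes.  This is the
#' operational way to pin down a tracked phenotype from a published node
#' count when its structure string is not printed.
#'
#' @inheritParams portal_probability
#' @param n_adjacent required number of distinct adjacent genotypes.
#' @return the phenotype identifier; an error if no or several phenotypes
#'   match.
#' @export
identify_adjacent_phenotype <- function(nc, n_adjacent) {
  if (is.null(nc$adjacent_counts)) stop("run nc_statistics() first")
  hits <- names(nc$adjacent_counts)[nc$adjacent_counts == n_adjacent]
  if (length(hits) != 1) {
    stop("expected exactly one phenotype with ", n_adjacent,
         " adjacent genotypes, found ", length(hits))
  }
  hits
}

#' Serialize / deserialize a neutral component
#'
#' Two TSV files: `<stem>_nodes.tsv` with long-format per-genotype mutation
#' counts (`genotype, phenotype, count`; header lines carry the component
#' phenotype) and `<stem>_edges.tsv` with the neutral edge list.
#'
#' @param nc a component with statistics.
#' @param stem path stem for the two files.
#' @return `write_neutral_component` returns the file paths invisibly;
#'   `read_neutral_component` reconstructs the component (statistics are
#'   recomputed from the node counts).
#' @export
write_neutral_component <- function(nc, stem) {
  if (is.null(nc$n_counts)) stop("run nc_statistics() first")
  nodes_file <- paste0(stem, "_nodes.tsv")
  edges_file <- paste0(stem, "_edges.tsv")
  con <- file(nodes_file, "w")
  writeLines(paste0("#phenotype=", nc$phenotype), con)
  utils::write.table(nc$n_counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  utils::write.table(data.frame(genotype_a = nc$edges[, 1],
                                genotype_b = nc$edges[, 2]),
                     edges_file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nodes_file, edges_file))
}

#' @rdname write_neutral_component
#' @export
read_neutral_component <- function(stem) {
  nodes_file <- paste0(stem, "_nodes.tsv")
  edges_file <- paste0(stem, "_edges.tsv")
  lines <- readLines(nodes_file, n = 1)
  p0 <- sub("^#phenotype=", "", lines)
  nodes <- utils::read.table(nodes_file, sep = "\t", header = TRUE,
                             comment.char = "#", colClasses = c(
                               genotype = "character",
                               phenotype = "character", count = "integer"))
  edges <- utils::read.table(edges_file, sep = "\t", header = TRUE,
                             colClasses = "character")
  genotypes <- sort(unique(nodes$genotype))
  total <- sum(nodes$count)
  counts <- tapply(nodes$count, nodes$phenotype, sum)
  phi <- counts[sort(names(counts))] / total
  edges_m <- as.matrix(edges)
  dimnames(edges_m) <- NULL
  portals <- lapply(split(nodes$genotype, nodes$phenotype),
                    function(g) sort(unique(g)))
  member_set <- genotypes
  within <- nodes$phenotype == p0
  structure(
    list(phenotype = p0, genotypes = genotypes, edges = edges_m,
         rho = if (p0 %in% names(phi)) unname(phi[p0]) else 0,
         rho_component = 2 * nrow(edges_m) / total,
         phi = setNames(as.numeric(phi), names(phi)),
         portals = portals[sort(names(portals))],
         n_counts = nodes, adjacent_counts = NULL),
    class = "neutral_component")
}
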