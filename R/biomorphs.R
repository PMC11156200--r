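#' Biomorphs developmental GP map
#'
#' Richard Dawkins's biomorphs map a genotype of nine integers onto a 2D
#' line drawing through a recursive branching ("tree growing") process; the
#' drawing, rasterised onto a 30x30 binary grid, is the phenotype.  Genes
#' 1-8 define the branch displacement vectors of the eight drawing
#' directions and gene 9 sets the recursion depth.  The genotype space is
#' bounded: `-3 <= g1..g8 <= 3` and `1 <= g9 <= 8`, giving `7^8 * 8 =
#' 46,118,408` genotypes.
#'
#' The displacement convention is fixed by one documented constant table
#' (see [biomorph_direction_table()]): directions `d = 0..7` have horizontal
#' displacement `dx = (0, g1, g2, g3, 0, -g3, -g2, -g1)[d+1]` and vertical
#' displacement `dy = (g4, g5, g6, g7, g8, g7, g6, g5)[d+1]`.  Because `dx`
#' is antisymmetric and `dy` symmetric under the direction mirror
#' `d -> (8 - d) mod 8`, and growth starts in direction 4 (on the mirror
#' axis), every rendered biomorph is bilaterally mirror-symmetric.
#'
#' Genotypes are encoded as comma-separated integer strings, e.g.
#' `"1,-2,0,3,1,1,-3,2,5"`.
#'
#' @return a `gp_map` of type `"biomorph"`.
#' @export
biomorph_gp_map <- function() {
  map <- new_gp_map("biomorph", L = 9L, K = NA_integer_, alphabet = NULL,
                    ranges = biomorph_gene_ranges(),
                    cache = new.env(parent = emptyenv()))
  map
}

#' Per-gene value ranges of the biomorphs genotype
#' @return list of integer vectors, one per gene position.
#' @export
biomorph_gene_ranges <- function() {
  c(rep(list(-3:3), 8), list(1:8))
}

#' The displacement-vector convention of the biomorph drawing
#'
#' @param g integer vector of length 9.
#' @return a list with `dx` and `dy`, the per-direction displacements for
#'   directions 0-7.
#' @export
biomorph_direction_table <- function(g) {
  list(dx = c(0, g[1], g[2], g[3], 0, -g[3], -g[2], -g[1]),
       dy = c(g[4], g[5], g[6], g[7], g[8], g[7], g[6], g[5]))
}

biomorph_parse <- function(g) {
  v <- suppressWarnings(as.integer(strsplit(g, ",", fixed = TRUE)[[1]]))
  if (length(v) != 9 || anyNA(v)) stop("invalid biomorph genotype: ", g)
  rng <- biomorph_gene_ranges()
  for (i in 1:9) {
    if (!(v[i] %in% rng[[i]])) {
      stop("biomorph gene ", i, " out of range: ", v[i])
    }
  }
  v
}

biomorph_format <- function(v) paste(v, collapse = ",")

# collect all line segments of the recursive drawing
biomorph_segments <- function(v) {
  dt <- biomorph_direction_table(v)
  segs <- matrix(0, nrow = 2^v[9] - 1, ncol = 4)
  k <- 0L
  grow <- function(x, y, len, dir) {
    dir <- dir %% 8L
    x2 <- x + len * dt$dx[dir + 1L]
    y2 <- y + len * dt$dy[dir + 1L]
    k <<- k + 1L
    segs[k, ] <<- c(x, y, x2, y2)
    if (len > 1L) {
      grow(x2, y2, len - 1L, dir - 1L)
      grow(x2, y2, len - 1L, dir + 1L)
    }
  }
  grow(0, 0, v[9], 4L)
  segs
}

#' Develop a biomorph genotype into its 30x30 binary-grid phenotype
#'
#' @param g a biomorph genotype, either an integer vector of length 9 or its
#'   comma-separated string encoding.
#' @param as_matrix return the 30x30 0/1 matrix instead of the digest
#'   string.
#' @return the phenotype identifier (a string of 900 bits, row-major), or
#'   the binary matrix if `as_matrix = TRUE`.
#' @export
develop_biomorph <- function(g, as_matrix = FALSE) {
  v <- if (is.character(g)) biomorph_parse(g) else {
    biomorph_parse(biomorph_format(as.integer(g)))
  }
  segs <- biomorph_segments(v)
  grid <- matrix(0L, 30, 30)
  ext <- max(abs(segs), 1e-9)
  s <- 14 / ext
  for (i in seq_len(nrow(segs))) {
    x1 <- segs[i, 1] * s; y1 <- segs[i, 2] * s
    x2 <- segs[i, 3] * s; y2 <- segs[i, 4] * s
    npts <- max(2L, ceiling(2 * max(abs(x2 - x1), abs(y2 - y1))) + 1L)
    tt <- seq(0, 1, length.out = npts)
    ix <- 15L + round(x1 + tt * (x2 - x1))
    iy <- 15L + round(y1 + tt * (y2 - y1))
    ix <- pmin(pmax(ix, 1L), 30L)
    iy <- pmin(pmax(iy, 1L), 30L)
    grid[cbind(iy, ix)] <- 1L
  }
  if (as_matrix) return(grid)
  paste(as.integer(t(grid)), collapse = "")
}

#' @export
map_phenotype.biomorph_gp_map <- function(map, genotypes) {
  vapply(genotypes, function(g) {
    if (exists(g, map$cache, inherits = FALSE)) {
      return(get(g, map$cache, inherits = FALSE))
    }
    ph <- develop_biomorph(g)
    assign(g, ph, map$cache)
    ph
  }, character(1), USE.NAMES = FALSE)
}

#' @export
point_mutation_neighbors.biomorph_gp_map <- function(g, map) {
  v <- biomorph_parse(g)
  rng <- biomorph_gene_ranges()
  out <- character(0)
  for (pos in 1:9) {
    for (val in rng[[pos]]) {
      if (val != v[pos]) {
        t <- v
        t[pos] <- val
        out <- c(out, biomorph_format(t))
      }
    }
  }
  out
}

#' @export
genotype_space_size.biomorph_gp_map <- function(map) {
  prod(vapply(biomorph_gene_ranges(), length, integer(1)))
}
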