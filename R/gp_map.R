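#' Genotype-phenotype map objects
#'
#' A GP map is a deterministic, pure function from genotypes to phenotype
#' identifiers.  Genotypes are fixed-length strings over a finite alphabet
#' (for the biomorphs map, nine bounded integers encoded as a comma-separated
#' string).  Phenotypes are opaque character identifiers; the distinguished
#' identifier `"NONE"` marks the undefined/non-folding phenotype, which is
#' treated as an ordinary (unviable unless assigned fitness) phenotype value
#' throughout.
#'
#' @param type character scalar naming the map flavour.
#' @param L sequence length.
#' @param K alphabet size.
#' @param alphabet character vector of symbols, in canonical order.
#' @param ... map-specific fields stored on the object.
#' @return an object of class `c("<type>_gp_map", "gp_map")`.
#' @keywords internal
new_gp_map <- function(type, L, K, alphabet, ...) {
  structure(
    list(type = type, L = L, K = K, alphabet = alphabet, ...),
    class = c(paste0(type, "_gp_map"), "gp_map")
  )
}

#' The identifier of the undefined ("non-folding") phenotype
#' @export
PHENOTYPE_NONE <- "NONE"

#' @export
print.gp_map <- function(x, ...) {
  cat(sprintf("<%s GP map>  L = %d, K = %d, alphabet = {%s}\n",
              x$type, x$L, x$K, paste(x$alphabet, collapse = "")))
  invisible(x)
}

#' Map genotypes to phenotypes
#'
#' Evaluates the map's phenotype function on a vector of genotypes.  The
#' function is pure: repeated calls with the same genotype always return the
#' same phenotype identifier.  Implementations may memoise results.
#'
#' @param map a [gp_map][new_gp_map] object.
#' @param genotypes character vector of genotypes.
#' @return character vector of phenotype identifiers (`"NONE"` for the
#'   undefined phenotype).
#' @export
map_phenotype <- function(map, genotypes) UseMethod("map_phenotype", map)

#' @export
map_phenotype.default <- function(map, genotypes) {
  stop("no phenotype function for map type ", map$type)
}

check_genotype <- function(map, g) {
  s <- strsplit(g, "", fixed = TRUE)
  ok <- vapply(s, function(x) length(x) == map$L && all(x %in% map$alphabet),
               logical(1))
  if (!all(ok)) {
    stop("invalid genotype(s): ", paste(utils::head(g[!ok], 3), collapse = ", "),
         " (length must be ", map$L, ", symbols in {",
         paste(map$alphabet, collapse = ""), "})")
  }
  invisible(TRUE)
}

#' Enumerate all single point-mutation neighbours of a genotype
#'
#' Every sequence genotype has exactly `L * (K - 1)` point-mutation
#' neighbours.  The order is deterministic: position-major, and within a
#' position the alphabet order of the map (the current symbol is skipped).
#' For the biomorphs map each position `i` instead has `range_i - 1`
#' neighbours, in ascending numeric order.
#'
#' @param g a single genotype.
#' @inheritParams map_phenotype
#' @return character vector of neighbouring genotypes; `g` itself is never
#'   included.
#' @export
point_mutation_neighbors <- function(g, map) UseMethod("point_mutation_neighbors", map)

#' @export
point_mutation_neighbors.gp_map <- function(g, map) {
  stopifnot(length(g) == 1L)
  check_genotype(map, g)
  s <- strsplit(g, "", fixed = TRUE)[[1]]
  out <- character(map$L * (map$K - 1L))
  k <- 0L
  for (pos in seq_len(map$L)) {
    for (b in map$alphabet) {
      if (b != s[pos]) {
        t <- s
        t[pos] <- b
        k <- k + 1L
        out[k] <- paste(t, collapse = "")
      }
    }
  }
  out
}

# neighbours for many genotypes at once, deduplicated, order preserved
neighbors_many <- function(gs, map) {
  unique(unlist(lapply(gs, point_mutation_neighbors, map = map),
                use.names = FALSE))
}

#' Size of a map's genotype space
#'
#' @inheritParams map_phenotype
#' @return number of genotypes (`K^L` for sequence maps; the product of the
#'   per-gene ranges for biomorphs).
#' @export
genotype_space_size <- function(map) UseMethod("genotype_space_size", map)

#' @export
genotype_space_size.gp_map <- function(map) map$K^map$L

# ---------------------------------------------------------------------------
# genotype <-> integer code helpers (base-K, position 1 = least significant);
# codes match the convention of the compiled engine.
# ---------------------------------------------------------------------------

genotype_to_code <- function(genotypes, map) {
  stopifnot(map$K^map$L <= 2^53)
  idx <- symbol_indices(genotypes, map)  # n x L, 0-based
  as.numeric(idx %*% map$K^(seq_len(map$L) - 1))
}

code_to_genotype <- function(codes, map) {
  L <- map$L; K <- map$K
  out <- character(length(codes))
  for (i in seq_along(codes)) {
    c0 <- codes[i]
    sym <- integer(L)
    for (j in seq_len(L)) {
      sym[j] <- c0 %% K
      c0 <- c0 %/% K
    }
    out[i] <- paste(map$alphabet[sym + 1L], collapse = "")
  }
  out
}

symbol_indices <- function(genotypes, map) {
  check_genotype(map, genotypes)
  m <- matrix(0L, nrow = length(genotypes), ncol = map$L)
  for (i in seq_along(genotypes)) {
    s <- strsplit(genotypes[i], "", fixed = TRUE)[[1]]
    m[i, ] <- match(s, map$alphabet) - 1L
  }
  m
}

# ---------------------------------------------------------------------------
# table-backed GP map and the on-disk GP-map table format
# ---------------------------------------------------------------------------

#' GP map backed by an explicit genotype-to-phenotype table
#'
#' Used for maps loaded from file and for small exhaustively enumerated
#' fixture maps.  Lookups for genotypes absent from the table raise an error
#' unless a `fallback` function is supplied.
#'
#' @param phenotypes named character vector: names are genotypes, values
#'   phenotype identifiers.
#' @param alphabet character vector of symbols.
#' @param fallback optional function(genotypes) -> phenotype ids used for
#'   genotypes missing from the table.
#' @return a `gp_map` of type `"table"`.
#' @export
table_gp_map <- function(phenotypes, alphabet, fallback = NULL) {
  stopifnot(length(phenotypes) > 0, !is.null(names(phenotypes)))
  L <- nchar(names(phenotypes)[1])
  env <- list2env(as.list(phenotypes), parent = emptyenv())
  new_gp_map("table", L = L, K = length(alphabet), alphabet = alphabet,
             lookup = env, fallback = fallback)
}

#' @export
map_phenotype.table_gp_map <- function(map, genotypes) {
  known <- vapply(genotypes, exists, logical(1), envir = map$lookup,
                  inherits = FALSE)
  out <- character(length(genotypes))
  out[known] <- vapply(genotypes[known], get, character(1),
                       envir = map$lookup, inherits = FALSE)
  if (any(!known)) {
    if (is.null(map$fallback)) {
      stop("genotype(s) not in table: ",
           paste(utils::head(genotypes[!known], 3), collapse = ", "))
    }
    out[!known] <- map$fallback(genotypes[!known])
  }
  out
}

#' Write / read a GP map table file
#'
#' The format is TSV with two header lines `#alphabet=...` and `#L=...`,
#' followed by `genotype<TAB>phenotype_id` rows.  The undefined phenotype is
#' written as the literal token `NONE`.
#'
#' @param map a `gp_map`.
#' @param genotypes genotypes to tabulate (the table stores only these).
#' @param file path.
#' @return `write_gp_map_table` returns `file` invisibly;
#'   `read_gp_map_table` returns a [table_gp_map()].
#' @export
write_gp_map_table <- function(map, genotypes, file) {
  ph <- map_phenotype(map, genotypes)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c(paste0("#alphabet=", paste(map$alphabet, collapse = "")),
               paste0("#L=", map$L)), con)
  utils::write.table(data.frame(genotype = genotypes, phenotype = ph),
                     con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname write_gp_map_table
#' @export
read_gp_map_table <- function(file) {
  lines <- readLines(file)
  hdr <- grep("^#", lines, value = TRUE)
  alphabet <- strsplit(sub("^#alphabet=", "", grep("^#alphabet=", hdr, value = TRUE)),
                       "", fixed = TRUE)[[1]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ph <- vapply(parts, `[`, character(1), 2)
  names(ph) <- vapply(parts, `[`, character(1), 1)
  table_gp_map(ph, alphabet = alphabet)
}

#' Read / write genotype sequences as FASTA
#'
#' Thin wrappers around Biostrings for the RNA alphabet.
#'
#' @param file path to a FASTA file.
#' @param genotypes character vector of sequences.
#' @param names optional sequence names.
#' @return `read_genotypes_fasta` returns a character vector of sequences.
#' @export
read_genotypes_fasta <- function(file) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("reading FASTA requires the Biostrings package")
  }
  x <- Biostrings::readBStringSet(file)
  out <- toupper(as.character(x))
  names(out) <- names(x)
  out
}

#' @rdname read_genotypes_fasta
#' @export
write_genotypes_fasta <- function(genotypes, file, names = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("writing FASTA requires the Biostrings package")
  }
  if (is.null(names)) names <- paste0("g", seq_along(genotypes))
  x <- Biostrings::BStringSet(genotypes)
  names(x) <- names
  Biostrings::writeXStringSet(x, file)
  invisible(file)
}
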