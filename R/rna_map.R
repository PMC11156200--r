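#' RNA secondary-structure GP map
#'
#' Maps RNA sequences to their minimum-free-energy (MFE) dot-bracket
#' secondary structure, computed with the ViennaRNA package's `RNAsubopt`
#' tool at default parameters.  A sequence is assigned the undefined
#' phenotype `"NONE"` when two or more structures tie at the minimum free
#' energy (degenerate MFE), following the convention that such sequences are
#' non-folding.  Folding results are memoised in an in-memory cache, which
#' can optionally be spilled to / restored from a TSV file so that long runs
#' do not refold sequences.
#'
#' `RNAsubopt` is invoked in batches (one process for many sequences), so
#' breadth-first searches over tens of thousands of sequences take seconds.
#'
#' @param L sequence length (default 12).
#' @param cache_file optional path of a TSV fold cache to preload and to
#'   which [save_rna_cache()] writes.
#' @return a `gp_map` of type `"rna"`.
#' @seealso [rna_available()], [fold_rna()]
#' @export
rna_gp_map <- function(L = 12, cache_file = NULL) {
  if (!rna_available()) {
    stop("the RNA GP map requires ViennaRNA's RNAsubopt on the PATH; ",
         "RNA-dependent features are unavailable")
  }
  map <- new_gp_map("rna", L = L, K = 4L, alphabet = c("A", "C", "G", "U"),
                    cache = new.env(parent = emptyenv()),
                    cache_file = cache_file)
  if (!is.null(cache_file) && file.exists(cache_file)) {
    tab <- utils::read.table(cache_file, sep = "\t", header = FALSE,
                             colClasses = "character", quote = "")
    for (i in seq_len(nrow(tab))) assign(tab[i, 1], tab[i, 2], map$cache)
  }
  map
}

#' Is the RNA folding engine available?
#'
#' @return `TRUE` if ViennaRNA's `RNAsubopt` executable is on the PATH.
#' @export
rna_available <- function() nzchar(Sys.which("RNAsubopt"))

#' ViennaRNA version string, for provenance records
#' @export
rna_engine_version <- function() {
  if (!rna_available()) return(NA_character_)
  out <- suppressWarnings(system2("RNAsubopt", "--version", stdout = TRUE))
  sub("^\\S+\\s+", "", out[1])
}

# one RNAsubopt call for a batch of sequences; returns the unique MFE
# structure per sequence, or "NONE" when the minimum is degenerate
rna_fold_batch <- function(seqs) {
  if (length(seqs) == 0) return(character(0))
  inp <- tempfile(fileext = ".seq")
  on.exit(unlink(inp))
  writeLines(seqs, inp)
  out <- system2("RNAsubopt", c("-e", "0"), stdin = inp, stdout = TRUE)
  res <- character(length(seqs))
  i <- 0L
  n_struct <- 0L
  mfe_struct <- ""
  flush_one <- function() {
    if (i > 0L) res[i] <<- if (n_struct == 1L) mfe_struct else PHENOTYPE_NONE
  }
  for (line in out) {
    if (grepl("^[ACGUacgu]", line)) {
      flush_one()
      i <- i + 1L
      n_struct <- 0L
    } else {
      n_struct <- n_struct + 1L
      if (n_struct == 1L) mfe_struct <- sub("\\s.*$", "", line)
    }
  }
  flush_one()
  if (i != length(seqs)) stop("RNAsubopt output could not be parsed")
  res
}

#' Fold RNA sequences to their MFE dot-bracket structure
#'
#' @param seqs character vector of sequences over `{A,C,G,U}`.
#' @param map an [rna_gp_map()]; created on the fly when omitted.
#' @return character vector of dot-bracket structures, `"NONE"` where the
#'   MFE is degenerate.
#' @export
fold_rna <- function(seqs, map = NULL) {
  if (is.null(map)) map <- rna_gp_map(L = nchar(seqs[1]))
  map_phenotype(map, seqs)
}

#' @export
map_phenotype.rna_gp_map <- function(map, genotypes) {
  check_genotype(map, genotypes)
  known <- vapply(genotypes, exists, logical(1), envir = map$cache,
                  inherits = FALSE)
  unknown <- unique(genotypes[!known])
  if (length(unknown)) {
    ph <- rna_fold_batch(unknown)
    for (k in seq_along(unknown)) assign(unknown[k], ph[k], map$cache)
  }
  vapply(genotypes, get, character(1), envir = map$cache, inherits = FALSE,
         USE.NAMES = FALSE)
}

#' Persist the RNA fold cache
#'
#' Writes all memoised `sequence -> structure` pairs as TSV so later sessions
#' (or repeated experiment configurations) can skip refolding.
#'
#' @param map an [rna_gp_map()].
#' @param file destination; defaults to the map's `cache_file`.
#' @export
save_rna_cache <- function(map, file = map$cache_file) {
  stopifnot(!is.null(file))
  seqs <- ls(map$cache, all.names = TRUE)
  utils::write.table(
    data.frame(seq = seqs,
               ph = vapply(seqs, get, character(1), envir = map$cache)),
    file, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}
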