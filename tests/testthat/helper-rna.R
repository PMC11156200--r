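# The reference RNA neutral component (seed AUACGAAACGUA) is expensive
# enough (~40k folds) that the suite builds it once and shares it.
.rna_cache <- new.env(parent = emptyenv())
rna_reference_nc <- function() {
  if (is.null(.rna_cache$nc)) {
    map <- rna_gp_map(L = 12)
    nc <- build_neutral_component("AUACGAAACGUA", map)
    .rna_cache$map <- map
    .rna_cache$nc <- nc_statistics(nc, map)
  }
  .rna_cache$nc
}
rna_reference_map <- function() {
  invisible(rna_reference_nc())
  .rna_cache$map
}
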