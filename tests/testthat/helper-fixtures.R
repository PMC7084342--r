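load_gerres <- local({
  cache <- new.env(parent = emptyenv())
  function(species) {
    if (is.null(cache[[species]])) {
      cache[[species]] <- read_feature_tsv(gerres_fixture(species))
    }
    cache[[species]]
  }
})

# a small hand-laid circular annotation used across structural tests
toy_genome <- function(sequence = NULL, length = 60L) {
  mitogenome(
    tibble::tibble(
      name = c("geneA", "geneB", "geneC"),
      category = c("PCG", "rRNA", "control"),
      strand = c("H", "H", "H"),
      start = c(1L, 21L, 41L), end = c(20L, 40L, 60L)
    ),
    label = "toy", length = length, circular = TRUE, sequence = sequence
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
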