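#' Genetic code table
#'
#' Wraps an NCBI genetic-code table (default: translation table 2, the
#' vertebrate mitochondrial code, under which AGA/AGG are stops, ATA
#' encodes Met and TGA encodes Trp) into the structure the codon-usage
#' and divergence functions consume: the 64-codon map, the stop set, and
#' the synonymous families partitioning the non-stop codons.
#'
#' @param id NCBI translation table id as a string (default `"2"`).
#' @return An object of class `genetic_code`: list with `id`, `codons`
#'   (named character vector codon -> one-letter amino acid, `*` for
#'   stop), `stops`, and `families` (amino acid -> codon vector).
#' @examples
#' code <- genetic_code()
#' code$codons["TGA"]  # Trp under the vertebrate mitochondrial code
#' @export
genetic_code <- function(id = "2") {
  map <- Biostrings::getGeneticCode(id)
  # Biostrings returns RNA-alphabet codons for some ids; normalize to DNA
  names(map) <- chartr("U", "T", names(map))
  stopifnot(length(map) == 64)
  stops <- names(map)[map == "*"]
  nonstop <- map[map != "*"]
  families <- split(names(nonstop), unname(nonstop))
  structure(list(id = id, codons = map, stops = stops,
                 families = families),
            class = "genetic_code")
}

#' @export
print.genetic_code <- function(x, ...) {
  cat(sprintf("<genetic_code> NCBI table %s: %d stop codons (%s), %d families\n",
              x$id, length(x$stops), paste(x$stops, collapse = ","),
              length(x$families)))
  invisible(x)
}

# one-letter -> three-letter amino acid names, for reporting
.aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys",
          Q = "Gln", E = "Glu", G = "Gly", H = "His", I = "Ile",
          L = "Leu", K = "Lys", M = "Met", F = "Phe", P = "Pro",
          S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val",
          "*" = "Stop")

.all_codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
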