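#' Genome length
#'
#' @param x A [mitogenome].
#' @return Declared length in bp; if the annotation declares none, the
#'   maximum feature end.
#' @export
genome_length <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  if (nrow(x$features) == 0) abort("empty annotation")
  if (!is.null(x$length) && x$length > 0) x$length else max(x$features$end)
}

# rows of `feats` fully nested inside another feature (the paper's
# spacing convention is consecutive-pair only, so these are excluded)
.nested_rows <- function(feats) {
  n <- nrow(feats)
  nested <- logical(n)
  for (i in seq_len(n)) {
    nested[i] <- any(feats$start <= feats$start[i] &
                       feats$end >= feats$end[i] &
                       seq_len(n) != i &
                       !(feats$start == feats$start[i] &
                           feats$end == feats$end[i] & seq_len(n) > i))
  }
  nested
}

#' Adjacency profile: spacings between consecutive features
#'
#' For each consecutive pair of features (ordered by start), the signed
#' spacing `downstream$start - upstream$end - 1`: positive values are
#' intergenic spacers, negative values overlaps, zero abutting genes. On
#' a circular genome the origin-spanning pair (last feature, first
#' feature) is included with spacing
#' `(length - last$end) + (first$start - 1)`. Features fully nested
#' inside another feature are excluded with a warning.
#'
#' @param x A [mitogenome].
#' @return A tibble with columns `upstream`, `downstream`, `spacing`.
#' @examples
#' gf <- read_feature_tsv(gerres_fixture("filamentosus"))
#' adjacency_profile(gf) |> dplyr::filter(spacing < 0)
#' @export
adjacency_profile <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  feats <- x$features
  if (nrow(feats) < 2) {
    return(tibble(upstream = character(), downstream = character(),
                  spacing = integer()))
  }
  nested <- .nested_rows(feats)
  if (any(nested)) {
    warn(paste0("feature(s) nested inside another excluded from the ",
                "adjacency profile: ",
                paste(feats$name[nested], collapse = ", ")))
    feats <- feats[!nested, ]
  }
  n <- nrow(feats)
  up <- feats[-n, ]
  down <- feats[-1, ]
  out <- tibble(
    upstream = up$name,
    downstream = down$name,
    spacing = down$start - up$end - 1L
  )
  if (x$circular) {
    out <- bind_rows(out, tibble(
      upstream = feats$name[n],
      downstream = feats$name[1],
      spacing = (genome_length(x) - feats$end[n]) + (feats$start[1] - 1L)
    ))
  }
  out
}

#' Intergenic spacer summary
#'
#' Counts strictly positive spacings in the [adjacency_profile()] and
#' their total length.
#'
#' @param x A [mitogenome].
#' @return One-row tibble: `n_spacers`, `total_bp`.
#' @examples
#' igs_summary(read_feature_tsv(gerres_fixture("filamentosus")))
#' @export
igs_summary <- function(x) {
  adj <- adjacency_profile(x)
  pos <- adj$spacing[adj$spacing > 0]
  tibble(n_spacers = length(pos), total_bp = sum(pos))
}

#' Gene-overlap summary
#'
#' Counts strictly negative spacings in the [adjacency_profile()]; the
#' total is reported as a positive number of overlapped bp.
#'
#' @param x A [mitogenome].
#' @return One-row tibble: `n_overlaps`, `total_bp`.
#' @export
overlap_summary <- function(x) {
  adj <- adjacency_profile(x)
  neg <- adj$spacing[adj$spacing < 0]
  tibble(n_overlaps = length(neg), total_bp = sum(abs(neg)))
}

#' Locate the light-strand replication origin spacer
#'
#' The origin of L-strand replication (O_L) of vertebrate mitogenomes
#' sits in the spacer between tRNA-Asn and tRNA-Cys. Returns the spacing
#' of that adjacency; a non-positive spacing is reported with
#' `has_ol = FALSE`.
#'
#' @param x A [mitogenome] containing both tRNA-Asn and tRNA-Cys.
#' @return One-row tibble: `spacing` (bp), `has_ol`.
#' @examples
#' locate_ol(read_feature_tsv(gerres_fixture("filamentosus")))
#' @export
locate_ol <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  if (!all(c("tRNA-Asn", "tRNA-Cys") %in% x$features$name)) {
    abort("tRNA-Asn and/or tRNA-Cys absent; cannot locate O_L")
  }
  adj <- adjacency_profile(x) |>
    filter(.data$upstream == "tRNA-Asn", .data$downstream == "tRNA-Cys")
  if (nrow(adj) == 0) {
    abort("tRNA-Asn and tRNA-Cys are not adjacent in this annotation")
  }
  tibble(spacing = adj$spacing[1], has_ol = adj$spacing[1] > 0)
}

#' Strand-by-category feature census
#'
#' @param x A [mitogenome].
#' @return Tibble with one row per (strand, category) combination
#'   observed, column `n`, plus the complete category totals accessible
#'   via `dplyr::count()` on [features()].
#' @examples
#' strand_census(read_feature_tsv(gerres_fixture("filamentosus")))
#' @export
strand_census <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  if (nrow(x$features) == 0) {
    return(tibble(strand = character(), category = character(),
                  n = integer()))
  }
  x$features |> count(.data$strand, .data$category, name = "n")
}

#' Total protein-coding length and genome share
#'
#' @param x A [mitogenome] with at least one protein-coding gene.
#' @return One-row tibble: `total_bp` (sum of PCG sizes), `percent`
#'   (share of the genome, in percent, rounded half-even to 2 decimals).
#' @examples
#' pcg_length_stats(read_feature_tsv(gerres_fixture("filamentosus")))
#' @export
pcg_length_stats <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  pcg <- x$features |> filter(.data$category == "PCG")
  if (nrow(pcg) == 0) abort("no protein-coding genes in annotation")
  total <- sum(pcg$size)
  tibble(total_bp = total,
         percent = round(100 * total / genome_length(x), 2))
}

#' Extract the coding-strand sequence of a gene
#'
#' Returns the subsequence `start..end` (1-based, inclusive) of the
#' genome, reverse-complemented when the feature lies on the L strand.
#' On circular genomes a feature with `end < start` wraps across the
#' origin.
#'
#' @param x A [mitogenome] with sequence attached.
#' @param gene Feature name. For the duplicated Leu/Ser tRNAs, `which`
#'   selects among copies in genome order.
#' @param which Index among identically named features (default 1).
#' @return A single nucleotide string (coding strand).
#' @export
gene_sequence <- function(x, gene, which = 1L) {
  stopifnot(inherits(x, "mitogenome"))
  if (is.null(x$sequence)) abort("annotation has no sequence attached")
  hits <- x$features |> filter(.data$name == gene)
  if (nrow(hits) == 0) abort(paste0("gene '", gene, "' not found"))
  f <- hits[which, ]
  s <- if (f$end >= f$start) {
    str_sub(x$sequence, f$start, f$end)
  } else {
    if (!x$circular) abort("end < start on a linear genome")
    paste0(str_sub(x$sequence, f$start, x$length),
           str_sub(x$sequence, 1L, f$end))
  }
  if (f$strand == "L") reverse_complement(s) else s
}

#' Reverse complement of a nucleotide string
#'
#' @param s Nucleotide string (IUPAC codes handled by Biostrings).
#' @return The reverse complement, as a character string.
#' @export
reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Table-1-style per-feature summary
#'
#' One row per feature with size, downstream spacing and (when sequence
#' is attached) GC percentage of the coding-strand sequence.
#'
#' @param x A [mitogenome].
#' @return A tibble.
#' @export
feature_summary <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  adj <- adjacency_profile(x)
  out <- x$features |>
    mutate(.row = dplyr::row_number()) |>
    left_join(adj |> mutate(.row = dplyr::row_number()) |>
                select(".row", "spacing"),
              by = ".row") |>
    select(-".row")
  if (!is.null(x$sequence)) {
    out$gc_percent <- vapply(seq_len(nrow(out)), function(i) {
      comp <- nucleotide_composition(
        gene_sequence(x, out$name[i],
                      which = sum(out$name[seq_len(i)] == out$name[i])))
      round(100 * (comp$G + comp$C) / comp$n, 2)
    }, numeric(1))
  }
  out
}
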