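#' Nucleotide composition of a sequence
#'
#' Case-insensitive A/T/G/C counts; `U` is treated as `T`. Ambiguity
#' codes (N, R, Y, ...) and gaps are excluded from the counts and
#' tallied in `ambiguous`.
#'
#' @param sequence A nucleotide string.
#' @return One-row tibble: counts `A`, `T`, `G`, `C`, total `n`,
#'   `ambiguous`, fractions `a`, `t`, `g`, `c`, and `at_content`.
#' @examples
#' nucleotide_composition("ACGT")
#' @export
nucleotide_composition <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  chars <- str_split_1(toupper(sequence), "")
  chars[chars == "U"] <- "T"
  n_a <- sum(chars == "A"); n_t <- sum(chars == "T")
  n_g <- sum(chars == "G"); n_c <- sum(chars == "C")
  n <- n_a + n_t + n_g + n_c
  amb <- sum(!chars %in% c("A", "T", "G", "C", "-"))
  frac <- function(k) if (n > 0) k / n else NA_real_
  tibble(
    A = n_a, T = n_t, G = n_g, C = n_c, n = n, ambiguous = amb,
    a = frac(n_a), t = frac(n_t), g = frac(n_g), c = frac(n_c),
    at_content = frac(n_a + n_t)
  )
}

# accept either a sequence string or a composition row
.as_composition <- function(x) {
  if (is.character(x)) nucleotide_composition(x) else as_tibble(x)
}

#' AT skew
#'
#' `(A - T) / (A + T)`: compositional asymmetry between the two strands.
#' Undefined (returned as `NA`) when `A + T = 0`.
#'
#' @param x A nucleotide string or a [nucleotide_composition()] row.
#' @return A single numeric value in `[-1, 1]` or `NA`.
#' @examples
#' at_skew("AAAT")
#' @export
at_skew <- function(x) {
  comp <- .as_composition(x)
  if (comp$A + comp$T == 0) return(NA_real_)
  (comp$A - comp$T) / (comp$A + comp$T)
}

#' GC skew
#'
#' `(G - C) / (G + C)`. Undefined (`NA`) when `G + C = 0`.
#'
#' @inheritParams at_skew
#' @return A single numeric value in `[-1, 1]` or `NA`.
#' @examples
#' gc_skew("GGGCC")
#' @export
gc_skew <- function(x) {
  comp <- .as_composition(x)
  if (comp$G + comp$C == 0) return(NA_real_)
  (comp$G - comp$C) / (comp$G + comp$C)
}

#' Per-gene skew profile over the protein-coding genes
#'
#' Computes AT and GC skew on the coding-strand sequence of each
#' protein-coding gene (L-strand genes are reverse-complemented first),
#' ordered by genome position.
#'
#' @param x A [mitogenome] with sequence attached.
#' @return A tibble of class `skew_profile`: `gene`, `strand`, `start`,
#'   `at_skew`, `gc_skew`.
#' @export
pcg_skew_profile <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  if (is.null(x$sequence)) abort("annotation has no sequence attached")
  pcg <- x$features |> filter(.data$category == "PCG")
  if (nrow(pcg) == 0) abort("no protein-coding genes in annotation")
  out <- pcg |>
    mutate(
      seq = map_chr(seq_len(nrow(pcg)), function(i) {
        gene_sequence(x, pcg$name[i],
                      which = sum(pcg$name[seq_len(i)] == pcg$name[i]))
      }),
      at_skew = map_dbl(.data$seq, at_skew),
      gc_skew = map_dbl(.data$seq, gc_skew)
    ) |>
    select("name", "strand", "start", "at_skew", "gc_skew") |>
    rename(gene = "name") |>
    arrange(.data$start)
  class(out) <- c("skew_profile", class(out))
  attr(out, "label") <- x$label
  out
}

#' Base composition partitioned by codon position
#'
#' Assigns each base of each in-frame coding sequence to codon position
#' `((i - 1) mod 3) + 1`, independently per gene, and tallies the
#' composition of the three partitions. Trailing incomplete codons
#' contribute only the positions they contain (so position totals can
#' differ, as they do when genes end in incomplete stop codons).
#'
#' @param cds_list List (or character vector) of coding-strand sequences,
#'   each in reading frame from its first base.
#' @return A three-row tibble (one per codon position) with the columns
#'   of [nucleotide_composition()] plus `position`.
#' @examples
#' codon_position_composition(c("ATGAAA", "ATG"))
#' @export
codon_position_composition <- function(cds_list) {
  cds_list <- unlist(cds_list)
  stopifnot(length(cds_list) > 0)
  pooled <- vapply(1:3, function(p) {
    paste(vapply(cds_list, function(s) {
      chars <- str_split_1(s, "")
      idx <- which(((seq_along(chars) - 1L) %% 3L) + 1L == p)
      paste(chars[idx], collapse = "")
    }, character(1)), collapse = "")
  }, character(1))
  bind_rows(lapply(1:3, function(p) {
    nucleotide_composition(pooled[p]) |> mutate(position = p, .before = 1)
  }))
}

#' Table-2-style composition report for a genome
#'
#' Rows: complete genome (H strand), the three codon positions of the
#' pooled protein-coding genes and their total, pooled tRNA, pooled
#' rRNA, and the control region. Percentages rounded half-even to two
#' decimals.
#'
#' @param x A [mitogenome] with sequence attached.
#' @return A tibble: `region`, `A`, `T`, `G`, `C` (percent), `at_percent`,
#'   `n`.
#' @export
composition_report <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  if (is.null(x$sequence)) abort("annotation has no sequence attached")
  pct_row <- function(region, comp) {
    tibble(region = region,
           A = round(100 * comp$a, 2), T = round(100 * comp$t, 2),
           G = round(100 * comp$g, 2), C = round(100 * comp$c, 2),
           at_percent = round(100 * comp$at_content, 2), n = comp$n)
  }
  seq_of <- function(i) {
    gene_sequence(x, x$features$name[i],
                  which = sum(x$features$name[seq_len(i)] ==
                                x$features$name[i]))
  }
  cat_seq <- function(cat) {
    idx <- which(x$features$category == cat)
    paste(vapply(idx, seq_of, character(1)), collapse = "")
  }
  pcg_idx <- which(x$features$category == "PCG")
  cds <- vapply(pcg_idx, seq_of, character(1))
  pos <- codon_position_composition(cds)
  bind_rows(
    pct_row("complete_genome", nucleotide_composition(x$sequence)),
    pct_row("pcg_pos1", pos[1, -1]),
    pct_row("pcg_pos2", pos[2, -1]),
    pct_row("pcg_pos3", pos[3, -1]),
    pct_row("pcg_total", nucleotide_composition(paste(cds, collapse = ""))),
    pct_row("tRNA", nucleotide_composition(cat_seq("tRNA"))),
    pct_row("rRNA", nucleotide_composition(cat_seq("rRNA"))),
    pct_row("control", nucleotide_composition(cat_seq("control")))
  )
}
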