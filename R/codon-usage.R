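#' Classify a coding sequence's terminal codons
#'
#' Mitochondrial protein-coding genes frequently end in incomplete stop
#' codons (`TA` or a bare `T`) that are completed to `TAA` by
#' polyadenylation of the transcript. The stop classification is read
#' from the sequence length modulo 3: a length divisible by 3 whose last
#' three bases are a stop codon yields that stop; a remainder of 2
#' ending in `TA` yields `"TA"`; a remainder of 1 ending in `T` yields
#' `"T"`; anything else `"none"`.
#'
#' @param cds Coding-strand sequence (>= 4 bases), in frame from base 1.
#' @param code A [genetic_code()].
#' @return One-row tibble: `start_codon`, `stop_class`.
#' @examples
#' classify_terminal_codons("ATGAAATAA")
#' @export
classify_terminal_codons <- function(cds, code = genetic_code()) {
  cds <- toupper(cds)
  len <- nchar(cds)
  stopifnot(len >= 4)
  start_codon <- str_sub(cds, 1, 3)
  r <- len %% 3L
  stop_class <- if (r == 0L) {
    last3 <- str_sub(cds, len - 2, len)
    if (last3 %in% code$stops) last3 else "none"
  } else if (r == 2L && str_sub(cds, len - 1, len) == "TA") {
    "TA"
  } else if (r == 1L && str_sub(cds, len, len) == "T") {
    "T"
  } else {
    "none"
  }
  tibble(start_codon = start_codon, stop_class = stop_class)
}

# split an in-frame sequence into complete codons (incomplete tail dropped)
.codon_split <- function(s) {
  s <- toupper(s)
  n_full <- nchar(s) %/% 3L
  if (n_full == 0) return(character(0))
  substring(s, 3L * (seq_len(n_full) - 1L) + 1L, 3L * seq_len(n_full))
}

#' Count codons over one or more coding sequences
#'
#' Complete codons are counted per gene and pooled; trailing incomplete
#' codons (sequence length not divisible by 3) are discarded and tallied.
#' With `drop_terminal_stop = TRUE` (the default) a terminal complete
#' stop codon is excluded from the counts. Internal stop codons raise a
#' warning (annotation and reading frame may legitimately disagree) but
#' are still counted.
#'
#' @param cds_list Character vector or list of in-frame coding-strand
#'   sequences; names, if present, are used in warnings.
#' @param code A [genetic_code()].
#' @param drop_terminal_stop Exclude a terminal complete stop codon?
#' @return A tibble of class `codon_counts`, 64 rows: `codon`,
#'   `amino_acid` (one-letter; `*` = stop), `aa3`, `count`. Attributes:
#'   `n_incomplete` (discarded trailing codons), `discarded_bases`,
#'   `n_terminal_stops`.
#' @examples
#' count_codons(c("ATGATG", "ATGAA"))
#' @export
count_codons <- function(cds_list, code = genetic_code(),
                         drop_terminal_stop = TRUE) {
  cds_list <- unlist(cds_list)
  stopifnot(length(cds_list) > 0)
  if (is.null(names(cds_list))) {
    names(cds_list) <- paste0("cds", seq_along(cds_list))
  }
  tally <- stats::setNames(integer(64), .all_codons())
  n_incomplete <- 0L
  discarded_bases <- 0L
  n_terminal_stops <- 0L
  for (nm in names(cds_list)) {
    codons <- .codon_split(cds_list[[nm]])
    rem <- nchar(cds_list[[nm]]) %% 3L
    if (rem > 0L) {
      n_incomplete <- n_incomplete + 1L
      discarded_bases <- discarded_bases + rem
    }
    if (length(codons) == 0) next
    if (drop_terminal_stop && rem == 0L &&
          codons[length(codons)] %in% code$stops) {
      codons <- codons[-length(codons)]
      n_terminal_stops <- n_terminal_stops + 1L
    }
    internal_stops <- which(codons %in% code$stops)
    if (length(internal_stops) > 0) {
      warn(sprintf("internal stop codon(s) in %s at codon position(s) %s",
                   nm, paste(internal_stops, collapse = ", ")))
    }
    ok <- codons %in% names(tally)
    t0 <- table(codons[ok])
    tally[names(t0)] <- tally[names(t0)] + as.integer(t0)
  }
  out <- tibble(
    codon = names(tally),
    amino_acid = unname(code$codons[names(tally)]),
    aa3 = unname(.aa3[unname(code$codons[names(tally)])]),
    count = unname(tally)
  )
  class(out) <- c("codon_counts", class(out))
  attr(out, "n_incomplete") <- n_incomplete
  attr(out, "discarded_bases") <- discarded_bases
  attr(out, "n_terminal_stops") <- n_terminal_stops
  out
}

#' Amino-acid usage frequencies
#'
#' Share of each amino acid among all counted non-stop codons.
#'
#' @param counts A [count_codons()] table.
#' @param code A [genetic_code()].
#' @return Tibble: `amino_acid`, `aa3`, `count`, `frequency` (sums to 1).
#' @export
amino_acid_usage <- function(counts, code = genetic_code()) {
  nonstop <- counts |> filter(.data$amino_acid != "*")
  total <- sum(nonstop$count)
  if (total == 0) abort("no counted codons")
  nonstop |>
    group_by(.data$amino_acid, .data$aa3) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(frequency = .data$count / total) |>
    arrange(desc(.data$frequency))
}

#' Relative synonymous codon usage (RSCU)
#'
#' For codon `c` in a synonymous family `F` of size `k` with family
#' total `X_F > 0`, `RSCU(c) = k * x_c / X_F`: the observed count
#' relative to its expectation under uniform use within the family. A
#' value of 1 means no bias, above 1 the codon is used more often than
#' its synonyms. Families with zero total get `NA` for every member.
#'
#' @param counts A [count_codons()] table.
#' @param code A [genetic_code()].
#' @return Tibble of class `rscu_table`: `codon`, `amino_acid`, `aa3`,
#'   `count`, `family_size`, `rscu`.
#' @examples
#' counts <- count_codons("ATGTTATTATTGCTA")
#' rscu(counts) |> dplyr::filter(amino_acid == "L")
#' @export
rscu <- function(counts, code = genetic_code()) {
  out <- counts |>
    filter(.data$amino_acid != "*") |>
    group_by(.data$amino_acid) |>
    mutate(
      family_size = dplyr::n(),
      family_total = sum(.data$count),
      rscu = ifelse(.data$family_total > 0,
                    .data$family_size * .data$count / .data$family_total,
                    NA_real_)
    ) |>
    ungroup() |>
    select("codon", "amino_acid", "aa3", "count", "family_size", "rscu")
  class(out) <- c("rscu_table", class(out))
  out
}
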