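#' Construct an annotated mitogenome
#'
#' A `mitogenome` couples an ordered, stranded, 1-based feature map of a
#' (usually circular) mitochondrial genome with an optional H-strand
#' nucleotide sequence. The feature map is an ordinary tibble, so all the
#' usual dplyr verbs apply to `features(x)`.
#'
#' @param features A data frame with columns `name`, `category` (one of
#'   `"PCG"`, `"tRNA"`, `"rRNA"`, `"control"`), `strand` (`"H"` or `"L"`),
#'   `start`, `end` (1-based, inclusive), and optionally `anticodon`,
#'   `start_codon`, `stop_codon`. Rows are sorted by `start` (ties by
#'   `end`); a `size` column is derived as `end - start + 1`.
#' @param label Identifier for the genome (species and/or accession).
#' @param length Total length of the molecule in bp. Defaults to the
#'   maximum feature end.
#' @param circular Is the molecule circular? Default `TRUE`.
#' @param sequence Optional H-strand sequence string of exactly `length`
#'   characters.
#' @return An object of class `mitogenome`.
#' @examples
#' toy <- mitogenome(
#'   tibble::tibble(
#'     name = c("geneA", "geneB"), category = c("PCG", "tRNA"),
#'     strand = c("H", "L"), start = c(1, 101), end = c(99, 170)
#'   ),
#'   label = "toy", length = 200
#' )
#' toy
#' @export
mitogenome <- function(features, label = "unnamed", length = NULL,
                       circular = TRUE, sequence = NULL) {
  stopifnot(is.data.frame(features))
  needed <- c("name", "category", "strand", "start", "end")
  missing_cols <- setdiff(needed, names(features))
  if (length(missing_cols) > 0) {
    abort(paste0("features is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  feats <- as_tibble(features)
  for (col in c("anticodon", "start_codon", "stop_codon")) {
    if (!col %in% names(feats)) feats[[col]] <- NA_character_
  }
  feats <- feats |>
    mutate(start = as.integer(.data$start), end = as.integer(.data$end)) |>
    arrange(.data$start, .data$end)

  wraps <- feats$end < feats$start  # legal only on circular molecules
  if (nrow(feats) > 0) {
    if (any(wraps) && !isTRUE(circular)) {
      abort(paste0("feature '", feats$name[wraps][1],
                   "' has end < start on a linear molecule"))
    }
    bad_cat <- setdiff(unique(feats$category),
                       c("PCG", "tRNA", "rRNA", "control"))
    if (length(bad_cat) > 0) {
      abort(paste0("unknown feature category: ",
                   paste(bad_cat, collapse = ", ")))
    }
    if (!all(feats$strand %in% c("H", "L"))) {
      abort("strand must be 'H' or 'L'")
    }
    dup <- feats |> count(.data$name) |> filter(.data$n > 1)
    allowed_dup <- c("tRNA-Leu", "tRNA-Ser")
    if (any(!dup$name %in% allowed_dup)) {
      abort(paste0("duplicate feature name: ",
                   paste(setdiff(dup$name, allowed_dup), collapse = ", ")))
    }
    if (any(!is.na(feats$anticodon) & feats$category != "tRNA")) {
      abort("anticodon given for a non-tRNA feature")
    }
  }

  if (is.null(length)) {
    length <- if (nrow(feats) > 0) max(feats$end) else 0L
  }
  length <- as.integer(length)
  if (nrow(feats) > 0 && max(feats$end) > length) {
    abort("feature end exceeds declared genome length")
  }
  feats <- feats |>
    mutate(size = ifelse(wraps, length - .data$start + 1L + .data$end,
                         .data$end - .data$start + 1L)) |>
    select("name", "category", "strand", "start", "end", "size",
           "anticodon", "start_codon", "stop_codon")
  odd_trna <- feats |>
    filter(.data$category == "tRNA", .data$size < 60 | .data$size > 95)
  if (nrow(odd_trna) > 0) {
    warn(paste0("tRNA size outside 60-95 bp sanity range: ",
                paste(odd_trna$name, collapse = ", ")))
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length) {
      abort(sprintf("sequence length (%d) != declared length (%d)",
                    nchar(sequence), length))
    }
  }
  structure(
    list(label = label, length = length, circular = isTRUE(circular),
         sequence = sequence, features = feats),
    class = "mitogenome"
  )
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s: %s bp, %s, %d features%s\n",
              x$label, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features),
              if (is.null(x$sequence)) " (no sequence)" else ""))
  print(x$features, ...)
  invisible(x)
}

#' Feature table of a mitogenome
#'
#' @param x A [mitogenome].
#' @return The feature tibble (one row per gene/element).
#' @export
features <- function(x) {
  stopifnot(inherits(x, "mitogenome"))
  x$features
}

#' @method tidy mitogenome
#' @export
tidy.mitogenome <- function(x, ...) x$features

#' @method glance mitogenome
#' @export
glance.mitogenome <- function(x, ...) {
  cats <- x$features |> count(.data$category)
  n_of <- function(cat) {
    m <- cats$n[cats$category == cat]
    if (length(m) == 0) 0L else as.integer(m)
  }
  tibble(
    label = x$label, length = x$length, circular = x$circular,
    n_features = nrow(x$features),
    n_pcg = n_of("PCG"), n_trna = n_of("tRNA"),
    n_rrna = n_of("rRNA"), n_control = n_of("control"),
    has_sequence = !is.null(x$sequence)
  )
}

#' Packaged Gerres feature-table fixtures
#'
#' Paths to the feature tables transcribed from the published annotations
#' of the three *Gerres* mitogenomes (GenBank MG587039, MN075144,
#' MT023107). These carry coordinates only, no sequence.
#'
#' @param species One of `"filamentosus"`, `"erythrourus"`,
#'   `"decacanthus"`.
#' @return Path to the packaged TSV.
#' @examples
#' gf <- read_feature_tsv(gerres_fixture("filamentosus"))
#' glance(gf)
#' @export
gerres_fixture <- function(species = c("filamentosus", "erythrourus",
                                       "decacanthus")) {
  species <- match.arg(species)
  system.file("extdata", paste0("gerres_", species, "_features.tsv"),
              package = "mitocomp", mustWork = TRUE)
}
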