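#' Read a feature-table TSV
#'
#' The format is a plain TSV of feature rows preceded by a single
#' metadata header line `#label=<id> length=<bp> circular=<0|1>` and a
#' column-name row. Columns: `name`, `category`, `strand`, `start`,
#' `end`, and optionally `anticodon`, `start_codon`, `stop_codon`.
#'
#' @param path Path to the TSV file.
#' @return A [mitogenome] (without sequence).
#' @examples
#' gf <- read_feature_tsv(gerres_fixture("filamentosus"))
#' genome_length(gf)
#' @export
read_feature_tsv <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) {
    abort("missing '#label=... length=... circular=...' header line")
  }
  meta_kv <- str_match(
    header, "#\\s*label=(\\S+)\\s+length=(\\d+)\\s+circular=([01])")
  if (is.na(meta_kv[1, 1])) {
    abort("malformed metadata header; expected '#label=<id> length=<bp> circular=<0|1>'")
  }
  feats <- readr::read_tsv(
    path, skip = 1L, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      name = readr::col_character(), category = readr::col_character(),
      strand = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), .default = readr::col_character()
    )
  )
  if (nrow(feats) == 0) abort("no features")
  if (any(feats$end < feats$start)) {
    abort(paste0("start > end in feature '",
                 feats$name[which(feats$end < feats$start)[1]], "'"))
  }
  mitogenome(
    feats,
    label = meta_kv[1, 2],
    length = as.integer(meta_kv[1, 3]),
    circular = meta_kv[1, 4] == "1"
  )
}

#' Write a feature-table TSV
#'
#' Inverse of [read_feature_tsv()]; `read_feature_tsv(write_feature_tsv(x))`
#' round-trips the annotation (sequence, if any, is not written).
#'
#' @param x A [mitogenome].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(x, path) {
  stopifnot(inherits(x, "mitogenome"))
  header <- sprintf("#label=%s length=%d circular=%d",
                    x$label, x$length, as.integer(x$circular))
  out <- x$features |> select(-"size")
  writeLines(header, path)
  suppressMessages(readr::write_tsv(out, path, append = TRUE,
                                    col_names = TRUE, na = ""))
  invisible(path)
}

# feature category -> GenBank feature key
.gb_key <- c(PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA", control = "D-loop")

#' Read a GenBank flat file
#'
#' Minimal reader for annotated mitogenome records: parses LOCUS,
#' gene/CDS/tRNA/rRNA/D-loop features (including `complement(...)`
#' locations, mapped to the L strand) and the ORIGIN sequence block.
#' Feature names are normalized via [normalize_gene_name()].
#'
#' @param path Path to a GenBank flat file.
#' @return A [mitogenome] with sequence attached when an ORIGIN block is
#'   present (a warning is raised when it is not).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) abort("not a GenBank flat file: no LOCUS line")
  lm <- str_match(locus[1], "^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp")
  if (is.na(lm[1, 1])) abort("malformed LOCUS line")
  label <- lm[1, 2]
  len <- as.integer(lm[1, 3])
  circular <- grepl("circular", locus[1], ignore.case = TRUE)

  feat_start <- grep("^FEATURES", lines)
  origin_start <- grep("^ORIGIN", lines)
  end_rec <- grep("^//", lines)
  feat_end <- min(c(origin_start, end_rec, length(lines) + 1L)) - 1L
  feat_lines <- if (length(feat_start) > 0 && feat_start[1] < feat_end) {
    lines[(feat_start[1] + 1L):feat_end]
  } else character(0)

  # split the feature block into (key, location, qualifiers) chunks: a new
  # feature starts at column 6 with a non-blank key
  is_new <- grepl("^     \\S", feat_lines)
  idx <- cumsum(is_new)
  feats <- list()
  for (i in seq_len(max(idx, 0))) {
    chunk <- feat_lines[idx == i]
    head_m <- str_match(chunk[1], "^\\s*(\\S+)\\s+(\\S.*)$")
    key <- head_m[1, 2]
    if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "D-loop", "D_loop")) next
    loc <- head_m[1, 3]
    quals <- chunk[-1]
    comp <- str_detect(loc, "complement")
    pos <- str_match(loc, "(\\d+)\\.\\.[<>]?(\\d+)")
    if (is.na(pos[1, 1])) {
      abort(paste0("cannot parse location '", loc, "' of feature #", i))
    }
    gene_q <- str_match(quals, "/(?:gene|product)=\"([^\"]+)\"")[, 2]
    gname <- gene_q[!is.na(gene_q)][1]
    category <- switch(key,
      CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
      "D-loop" = "control", "D_loop" = "control", gene = NA_character_)
    # standalone gene features duplicate CDS/tRNA/rRNA ones; keep only typed
    if (is.na(category)) next
    if (is.na(gname)) {
      abort(paste0("feature #", i, " (", key, " ", loc,
                   ") has no /gene or /product qualifier"))
    }
    feats[[length(feats) + 1L]] <- tibble(
      name = normalize_gene_name(gname), category = category,
      strand = if (comp) "L" else "H",
      start = as.integer(pos[1, 2]), end = as.integer(pos[1, 3])
    )
  }
  if (length(feats) == 0) abort("no features found in GenBank record")
  feat_tbl <- list_rbind(feats) |> distinct()

  sequence <- NULL
  if (length(origin_start) > 0) {
    seq_end <- if (length(end_rec) > 0) {
      min(end_rec[end_rec > origin_start[1]]) - 1L
    } else length(lines)
    raw <- lines[(origin_start[1] + 1L):seq_end]
    sequence <- toupper(gsub("[^A-Za-z]", "", paste(raw, collapse = "")))
  } else {
    warn("no ORIGIN block: annotation loaded without sequence")
  }
  mitogenome(feat_tbl, label = label, length = len,
             circular = circular, sequence = sequence)
}

#' Write a GenBank flat file
#'
#' Writes a [mitogenome] (which must carry a sequence) in GenBank flat
#' format re-readable by [read_genbank()]. L-strand features are written
#' as `complement(start..end)` locations.
#'
#' @param x A [mitogenome] with sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path) {
  stopifnot(inherits(x, "mitogenome"))
  if (is.null(x$sequence) || nchar(x$sequence) == 0) {
    abort("cannot write GenBank record without sequence")
  }
  if (nchar(x$sequence) != x$length) {
    abort("sequence length inconsistent with declared genome length")
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s",
                     x$label, x$length,
                     if (x$circular) "circular" else "linear"), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  for (i in seq_len(nrow(x$features))) {
    f <- x$features[i, ]
    loc <- sprintf("%d..%d", f$start, f$end)
    if (f$strand == "L") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-16s%s", .gb_key[[f$category]], loc), con)
    writeLines(sprintf("                     /gene=\"%s\"", f$name), con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(x$sequence)
  starts <- seq(1L, nchar(s), by = 60L)
  for (p in starts) {
    chunk <- str_sub(s, p, min(p + 59L, nchar(s)))
    blocks <- substring(chunk, seq(1, nchar(chunk), 10),
                        pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Write sequences to FASTA
#'
#' @param sequences Named character vector or list of nucleotide strings.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  sequences <- unlist(sequences)
  if (length(sequences) == 0 || any(nchar(sequences) == 0)) {
    abort("refusing to write empty sequence(s)")
  }
  x <- Biostrings::DNAStringSet(sequences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write a square distance matrix in PHYLIP format
#'
#' @param m Square numeric matrix with row names (taxon labels).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip_matrix <- function(m, path) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m), !is.null(rownames(m)))
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste0(sprintf("%-10s", substr(rownames(m)[i], 1, 10)),
                      paste(sprintf("%.6f", m[i, ]), collapse = "  "))
             }, character(1)))
  writeLines(lines, path)
  invisible(path)
}
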