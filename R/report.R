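#' Run the full comparative summary over one or more genomes
#'
#' Orchestrates every analysis stage and writes the summary artifacts to
#' `out_dir`: per genome a feature summary (sizes, spacings, strand
#' census, spacer/overlap/O_L statistics) as TSV + JSON and, when the
#' genome carries sequence, a composition table, a per-gene skew table
#' and a codon-usage/RSCU table. With two or more sequence-bearing
#' genomes it also writes per-gene pairwise divergence (p-distance
#' partitions, NG86 Ka/Ks) in long TSV form and square PHYLIP distance
#' matrices. A manifest of artifacts with input checksums is written
#' last. Outputs contain no timestamps, so reruns on identical inputs
#' are byte-identical.
#'
#' @param inputs Character vector of annotation paths (feature TSV or
#'   GenBank; GenBank detected by a LOCUS line) and/or [mitogenome]
#'   objects in a list.
#' @param out_dir Output directory (created if needed).
#' @param code A [genetic_code()].
#' @param genes Genes for pairwise divergence; default all 13 PCGs
#'   common to the inputs.
#' @return Tibble manifest (invisible): `artifact`, `path`, `md5`.
#' @export
run_summary <- function(inputs, out_dir, code = genetic_code(),
                        genes = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genomes <- lapply(inputs, function(inp) {
    if (inherits(inp, "mitogenome")) return(inp)
    first <- readLines(inp, n = 1L)
    if (startsWith(first, "LOCUS")) read_genbank(inp) else
      read_feature_tsv(inp)
  })
  artifacts <- list()
  add <- function(name, path) {
    artifacts[[length(artifacts) + 1L]] <<- tibble(
      artifact = name, path = path,
      md5 = unname(tools::md5sum(path)))
  }

  for (g in genomes) {
    base <- file.path(out_dir, g$label)
    feat_path <- paste0(base, "_features.tsv")
    suppressMessages(readr::write_tsv(feature_summary(g), feat_path,
                                      na = ""))
    add(paste0(g$label, "/features"), feat_path)

    structural <- c(
      as.list(glance(g)),
      list(igs = as.list(igs_summary(g)),
           overlaps = as.list(overlap_summary(g)),
           o_l = as.list(locate_ol(g)),
           pcg = as.list(pcg_length_stats(g)),
           strand_census = strand_census(g))
    )
    json_path <- paste0(base, "_summary.json")
    jsonlite::write_json(structural, json_path, auto_unbox = TRUE,
                         digits = NA, dataframe = "rows")
    add(paste0(g$label, "/summary"), json_path)

    if (!is.null(g$sequence)) {
      comp_path <- paste0(base, "_composition.tsv")
      suppressMessages(readr::write_tsv(composition_report(g), comp_path))
      add(paste0(g$label, "/composition"), comp_path)

      skew_path <- paste0(base, "_skew.tsv")
      suppressMessages(readr::write_tsv(
        as_tibble(pcg_skew_profile(g)), skew_path))
      add(paste0(g$label, "/skew"), skew_path)

      pcg <- g$features |> filter(.data$category == "PCG")
      cds <- stats::setNames(
        map_chr(pcg$name, function(nm) gene_sequence(g, nm)), pcg$name)
      counts <- suppressWarnings(count_codons(cds, code))
      usage_path <- paste0(base, "_rscu.tsv")
      suppressMessages(readr::write_tsv(rscu(counts, code), usage_path))
      add(paste0(g$label, "/rscu"), usage_path)
    } else {
      message("note: ", g$label,
              " has no sequence; composition/codon tables skipped")
    }
  }

  with_seq <- Filter(function(g) !is.null(g$sequence), genomes)
  if (length(with_seq) >= 2) {
    if (is.null(genes)) {
      genes <- Reduce(intersect, lapply(with_seq, function(g) {
        g$features$name[g$features$category == "PCG"]
      }))
    }
    div <- list_rbind(map(genes, function(gn) {
      tryCatch(pairwise_gene_matrix(with_seq, gn, code = code),
               error = function(e) {
                 message("divergence skipped for ", gn, ": ",
                         conditionMessage(e))
                 NULL
               })
    }))
    if (!is.null(div) && nrow(div) > 0) {
      div_path <- file.path(out_dir, "divergence.tsv")
      suppressMessages(readr::write_tsv(div, div_path, na = ""))
      add("divergence", div_path)

      labels <- map_chr(with_seq, function(g) g$label)
      for (metric in c("p_all", "ka", "ks")) {
        m <- matrix(0, length(labels), length(labels),
                    dimnames = list(labels, labels))
        agg <- div |>
          group_by(.data$a, .data$b) |>
          summarise(v = mean(.data[[metric]], na.rm = TRUE),
                    .groups = "drop")
        for (r in seq_len(nrow(agg))) {
          m[agg$a[r], agg$b[r]] <- agg$v[r]
          m[agg$b[r], agg$a[r]] <- agg$v[r]
        }
        mp <- file.path(out_dir, paste0("matrix_", metric, ".phy"))
        write_phylip_matrix(m, mp)
        add(paste0("matrix/", metric), mp)
      }
    }
  }

  manifest <- list_rbind(artifacts)
  suppressMessages(readr::write_tsv(manifest,
                                    file.path(out_dir, "manifest.tsv")))
  invisible(manifest)
}
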