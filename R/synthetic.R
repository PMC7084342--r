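#' Default gene-order template for synthetic mitogenomes
#'
#' The 38-feature vertebrate mitochondrial gene order (13 PCGs, 22
#' tRNAs, 2 rRNAs, control region, including the duplicated Leu/Ser
#' tRNAs), with sizes, strands, downstream spacings, anticodons and
#' terminal codons taken from the packaged *G. filamentosus* feature
#' table. `spacing_after[i]` is the signed gap between feature `i` and
#' feature `i + 1` (the last entry is the origin-spanning gap).
#'
#' @return A tibble with columns `name`, `category`, `strand`, `size`,
#'   `spacing_after`, `anticodon`, `start_codon`, `stop_codon`.
#' @export
mito_template <- function() {
  g <- read_feature_tsv(gerres_fixture("filamentosus"))
  adj <- adjacency_profile(g)
  g$features |>
    mutate(spacing_after = adj$spacing) |>
    select("name", "category", "strand", "size", "spacing_after",
           "anticodon", "start_codon", "stop_codon")
}

#' Configuration for the synthetic-mitogenome generator
#'
#' @param label Genome label.
#' @param template Gene-order template tibble (see [mito_template()]);
#'   sizes and signed spacings define the tiling.
#' @param composition Length-4 probability vector (A, T, G, C) for
#'   non-coding sequence and background. Default mirrors the H-strand
#'   composition typical of fish mitogenomes (A 0.27, T 0.27, G 0.17,
#'   C 0.29).
#' @param codon_bias Optional named probability vector over non-stop
#'   codons used for protein-coding genes; default uniform.
#' @return A list of class `mito_config`.
#' @export
mito_config <- function(label = "synthetic",
                        template = mito_template(),
                        composition = c(A = 0.27, T = 0.27,
                                        G = 0.17, C = 0.29),
                        codon_bias = NULL) {
  stopifnot(is.data.frame(template),
            all(c("name", "category", "strand", "size",
                  "spacing_after") %in% names(template)))
  composition <- composition / sum(composition)
  len <- sum(template$size) + sum(template$spacing_after)
  if (len < max(template$size)) {
    abort(sprintf(
      "unrealizable tiling: sum(sizes) + sum(gaps) - sum(overlaps) = %d",
      len))
  }
  structure(list(label = label, template = as_tibble(template),
                 composition = composition, codon_bias = codon_bias,
                 length = as.integer(len)),
            class = "mito_config")
}

.sample_bases <- function(n, probs) {
  if (n <= 0) return(character(0))
  sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = probs)
}

#' Generate a synthetic protein-coding sequence
#'
#' Draws `n_codons` internal codons i.i.d. from a codon-bias
#' distribution over the non-stop codons of the genetic code, prefixed
#' with a start codon and suffixed with a (possibly incomplete) stop.
#' Total length is `3 + 3 * n_codons + nchar(stop)`.
#'
#' @param n_codons Number of internal codons.
#' @param bias Named probability vector over non-stop codons (default
#'   uniform).
#' @param code A [genetic_code()].
#' @param start_codon Start codon (default `"ATG"`).
#' @param stop Stop suffix: one of `"TAA"`, `"TAG"`, `"AGA"`, `"AGG"`,
#'   `"TA"`, `"T"`, or `""` (none).
#' @param seed Optional integer seed (scoped to this call).
#' @return A coding-strand nucleotide string.
#' @examples
#' generate_cds(5, seed = 1)
#' @export
generate_cds <- function(n_codons, bias = NULL, code = genetic_code(),
                         start_codon = "ATG", stop = "TAA", seed = NULL) {
  stopifnot(n_codons >= 0,
            stop %in% c(code$stops, "TA", "T", ""))
  nonstop <- setdiff(names(code$codons), code$stops)
  if (is.null(bias)) {
    bias <- stats::setNames(rep(1 / length(nonstop), length(nonstop)),
                            nonstop)
  }
  if (!all(names(bias) %in% nonstop)) {
    abort("codon bias must be a distribution over non-stop codons")
  }
  bias <- bias / sum(bias)
  draw <- function() {
    body <- if (n_codons > 0) {
      sample(names(bias), n_codons, replace = TRUE, prob = bias)
    } else character(0)
    paste0(start_codon, paste(body, collapse = ""), stop)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate an annotated synthetic mitogenome with known truth
#'
#' Tiles a circular genome with the configured feature layout, plants a
#' generated sequence for every feature (protein-coding genes via
#' [generate_cds()] with the template's terminal codons; other features
#' and intergenic background drawn from the background composition),
#' and returns both the [mitogenome] and a truth record. Spacer and
#' overlap summaries computed on the output recover the configured
#' totals exactly; where adjacent features overlap, the downstream
#' feature's bases overwrite the shared positions.
#'
#' @param config A [mito_config()].
#' @param seed Integer seed (single stream for the whole genome).
#' @param with_sequence Generate sequence (default `TRUE`)? With
#'   `FALSE`, only the coordinate layout is built.
#' @return A list: `genome` (a [mitogenome]) and `truth` (list with
#'   `features` incl. planted sense sequences, `config`, `seed`).
#' @examples
#' syn <- generate_annotation(mito_config(), seed = 42)
#' igs_summary(syn$genome)
#' @export
generate_annotation <- function(config, seed = 1L, with_sequence = TRUE) {
  stopifnot(inherits(config, "mito_config"))
  tpl <- config$template
  n <- nrow(tpl)
  starts <- integer(n); ends <- integer(n)
  starts[1] <- 1L
  for (i in seq_len(n)) {
    ends[i] <- starts[i] + tpl$size[i] - 1L
    if (i < n) starts[i + 1] <- ends[i] + tpl$spacing_after[i] + 1L
  }
  len <- config$length
  if (ends[n] + tpl$spacing_after[n] != len) {
    abort(sprintf(
      "tiling identity violated: last end %d + origin gap %d != length %d",
      ends[n], tpl$spacing_after[n], len))
  }
  if (any(starts < 1L) || any(ends > len)) {
    abort("unrealizable tiling: a feature falls outside 1..length")
  }
  feats <- tpl |>
    mutate(start = starts, end = ends) |>
    select("name", "category", "strand", "start", "end",
           "anticodon", "start_codon", "stop_codon")

  planted <- rep(NA_character_, n)
  sequence <- NULL
  if (with_sequence) {
    sequence <- withr::with_seed(seed, {
      genome <- .sample_bases(len, config$composition)
      for (i in seq_len(n)) {
        size <- ends[i] - starts[i] + 1L
        s <- if (tpl$category[i] == "PCG") {
          stop_suffix <- tpl$stop_codon[i] %||% "TAA"
          if (is.na(stop_suffix)) stop_suffix <- "TAA"
          start_cd <- tpl$start_codon[i]
          if (is.na(start_cd)) start_cd <- "ATG"
          inner <- size - 3L - nchar(stop_suffix)
          if (inner < 0 || inner %% 3L != 0) {
            abort(sprintf(
              "feature '%s': size %d incompatible with start/stop codons",
              tpl$name[i], size))
          }
          generate_cds(inner %/% 3L, bias = config$codon_bias,
                       start_codon = start_cd, stop = stop_suffix)
        } else {
          paste(.sample_bases(size, config$composition), collapse = "")
        }
        planted[i] <- s
        h_seq <- if (tpl$strand[i] == "H") s else reverse_complement(s)
        pos <- ((seq.int(starts[i], ends[i]) - 1L) %% len) + 1L
        genome[pos] <- str_split_1(h_seq, "")
      }
      paste(genome, collapse = "")
    })
  }
  genome <- mitogenome(feats, label = config$label, length = len,
                       circular = TRUE, sequence = sequence)
  truth <- list(
    features = feats |> mutate(planted_sequence = planted),
    config = config, seed = seed
  )
  list(genome = genome, truth = truth)
}

# enumerate the single-base mutations of a codon, classified
.codon_mutations <- function(codon, code) {
  aa <- code$codons[[codon]]
  out <- list()
  for (pos in 1:3) {
    for (to in .mutants_at(codon, pos)) {
      if (to %in% code$stops) next
      out[[length(out) + 1L]] <- list(
        pos = pos, to_codon = to,
        class = if (code$codons[[to]] == aa) "synonymous"
                else "nonsynonymous")
    }
  }
  out
}

#' Evolve a coding sequence by planted substitution counts
#'
#' Applies exactly `n_syn` synonymous and `n_nonsyn` nonsynonymous
#' single-base substitutions at uniformly chosen eligible codons (at
#' most one substitution per codon, so NG86 counting recovers the
#' planted classes exactly), never creating a stop codon. The start
#' codon, a terminal stop codon and any incomplete trailing codon are
#' left untouched.
#'
#' @param cds In-frame coding sequence (as from [generate_cds()]).
#' @param n_syn,n_nonsyn Numbers of substitutions to plant.
#' @param code A [genetic_code()].
#' @param seed Optional integer seed (scoped to this call).
#' @return A list: `sequence` (the descendant) and `ledger`, a tibble
#'   with one row per substitution (`codon_index`, `position` in
#'   sequence coordinates, `from_codon`, `to_codon`, `from`, `to`,
#'   `class`). Replaying the ledger on the ancestor reproduces the
#'   descendant exactly.
#' @examples
#' anc <- generate_cds(50, seed = 2)
#' ev <- evolve_cds(anc, n_syn = 5, n_nonsyn = 2, seed = 3)
#' nrow(ev$ledger)
#' @export
evolve_cds <- function(cds, n_syn, n_nonsyn, code = genetic_code(),
                       seed = NULL) {
  run <- function() {
    codons <- .codon_split(cds)
    tail_len <- nchar(cds) %% 3L
    n_cod <- length(codons)
    eligible <- setdiff(seq_len(n_cod), 1L)  # keep the start codon
    if (n_cod > 0 && codons[n_cod] %in% code$stops) {
      eligible <- setdiff(eligible, n_cod)
    }
    muts <- lapply(seq_len(n_cod), function(i) {
      if (!i %in% eligible || codons[i] %in% code$stops) return(list())
      .codon_mutations(codons[i], code)
    })
    pick <- function(k, cls, excluded) {
      has <- which(vapply(muts, function(m) {
        any(vapply(m, function(x) x$class == cls, logical(1)))
      }, logical(1)))
      has <- setdiff(has, excluded)
      if (length(has) < k) {
        abort(sprintf("infeasible plan: %d %s changes requested, %d codons eligible",
                      k, cls, length(has)))
      }
      sort(has[sample.int(length(has), k)])
    }
    syn_at <- pick(n_syn, "synonymous", integer(0))
    nonsyn_at <- pick(n_nonsyn, "nonsynonymous", syn_at)
    apply_one <- function(i, cls) {
      opts <- Filter(function(x) x$class == cls, muts[[i]])
      ch <- opts[[sample.int(length(opts), 1)]]
      tibble(codon_index = i,
             position = 3L * (i - 1L) + ch$pos,
             from_codon = codons[i], to_codon = ch$to_codon,
             from = str_sub(codons[i], ch$pos, ch$pos),
             to = str_sub(ch$to_codon, ch$pos, ch$pos),
             class = cls)
    }
    ledger <- bind_rows(
      map(syn_at, apply_one, cls = "synonymous"),
      map(nonsyn_at, apply_one, cls = "nonsynonymous")
    )
    out <- codons
    if (nrow(ledger) > 0) out[ledger$codon_index] <- ledger$to_codon
    descendant <- paste0(paste(out, collapse = ""),
                         if (tail_len > 0) {
                           str_sub(cds, nchar(cds) - tail_len + 1L,
                                   nchar(cds))
                         } else "")
    if (nrow(ledger) == 0) {
      ledger <- tibble(codon_index = integer(), position = integer(),
                       from_codon = character(), to_codon = character(),
                       from = character(), to = character(),
                       class = character())
    }
    list(sequence = descendant, ledger = ledger |> arrange(.data$position))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate an aligned coding pair at a planted Ka/Ks ratio
#'
#' Generates an ancestor of `n_codons` internal codons, computes its
#' NG86 site counts `S` and `N`, and evolves a descendant carrying
#' `n_syn` synonymous and `round(omega * n_syn * N / S)` nonsynonymous
#' substitutions, so that the planted rate ratio
#' `(Nd/N) / (Sd/S)` equals `omega`.
#'
#' @param n_codons Internal codons in the ancestor.
#' @param omega Planted Ka/Ks.
#' @param n_syn Number of synonymous substitutions (default scales as
#'   5% of codons).
#' @param code A [genetic_code()].
#' @param seed Integer seed.
#' @return List: `ancestor`, `descendant`, `ledger`, `planted`
#'   (one-row tibble with `omega`, `n_syn`, `n_nonsyn`, `S`, `N`).
#' @export
simulate_kaks_pair <- function(n_codons, omega, n_syn = NULL,
                               code = genetic_code(), seed = 1L) {
  withr::with_seed(seed, {
    anc <- generate_cds(n_codons, code = code)
    tabs <- .ng86_tables(code)
    codons <- .codon_split(anc)
    codons <- codons[!codons %in% code$stops]
    S <- sum(tabs$sites[codons, "s"])
    N <- sum(tabs$sites[codons, "n"])
    if (is.null(n_syn)) n_syn <- max(1L, round(0.05 * n_codons))
    n_nonsyn <- as.integer(round(omega * n_syn * N / S))
    ev <- evolve_cds(anc, n_syn = n_syn, n_nonsyn = n_nonsyn, code = code)
    list(ancestor = anc, descendant = ev$sequence, ledger = ev$ledger,
         planted = tibble(omega = omega, n_syn = n_syn,
                          n_nonsyn = n_nonsyn, S = S, N = N))
  })
}
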