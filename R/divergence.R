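#' Codon-position-partitioned p-distance
#'
#' Proportion of differing sites between two equal-length, in-frame
#' aligned coding sequences, computed over all sites (`p_all`), the
#' pooled first and second codon positions (`p_12`), and the third
#' position (`p_3`). Codon columns containing any gap or ambiguity in
#' either sequence are excluded from every partition and tallied.
#'
#' @param a,b Aligned nucleotide strings of equal length (gaps `-`
#'   allowed).
#' @return One-row tibble: `p_all`, `p_12`, `p_3`, site counts
#'   `sites_all`, `sites_12`, `sites_3`, and `excluded_codons`. A
#'   partition with zero comparable sites yields `NA`.
#' @examples
#' p_distance("ATGAAA", "ATGAAG")
#' @export
p_distance <- function(a, b) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) abort("sequences must be aligned (equal length)")
  ca <- str_split_1(a, ""); cb <- str_split_1(b, "")
  n_full <- length(ca) %/% 3L
  keep_len <- 3L * n_full
  ca <- ca[seq_len(keep_len)]; cb <- cb[seq_len(keep_len)]
  codon_idx <- rep(seq_len(n_full), each = 3L)
  valid_base <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  bad_codons <- unique(codon_idx[!valid_base])
  keep <- !(codon_idx %in% bad_codons)
  pos <- rep(1:3, times = n_full)
  diffs <- ca != cb
  part <- function(sel) {
    n <- sum(keep & sel)
    tibble(p = if (n > 0) sum(diffs[keep & sel]) / n else NA_real_,
           sites = n)
  }
  all_p <- part(rep(TRUE, keep_len))
  p12 <- part(pos %in% c(1L, 2L))
  p3 <- part(pos == 3L)
  tibble(p_all = all_p$p, p_12 = p12$p, p_3 = p3$p,
         sites_all = all_p$sites, sites_12 = p12$sites,
         sites_3 = p3$sites, excluded_codons = length(bad_codons))
}

# ---- NG86 machinery ------------------------------------------------------

# lazily built per-code-id cache of site counts and pathway-averaged
# difference counts over the 64x64 codon grid
.ng86_cache <- new.env(parent = emptyenv())

.mutants_at <- function(codon, pos) {
  bases <- c("A", "C", "G", "T")
  cur <- str_sub(codon, pos, pos)
  vapply(setdiff(bases, cur), function(bb) {
    out <- codon
    str_sub(out, pos, pos) <- bb
    out
  }, character(1))
}

#' Synonymous and nonsynonymous site counts of a codon (NG86)
#'
#' For each of the nine single-base mutations of the codon, classifies
#' the change as synonymous (same amino acid) or nonsynonymous.
#' Mutations creating a stop codon are excluded and the remaining
#' fractions at that position renormalized, so `s + n = 3` always holds.
#'
#' @param codon A non-stop codon (A/C/G/T only).
#' @param code A [genetic_code()].
#' @return Named numeric vector `c(s = ..., n = ...)`.
#' @examples
#' ng86_sites("TTT")  # only TTT->TTC is synonymous: s = 1/3
#' @export
ng86_sites <- function(codon, code = genetic_code()) {
  codon <- toupper(codon)
  if (!codon %in% names(code$codons)) abort("invalid codon")
  if (codon %in% code$stops) abort("stop codon has no NG86 site counts")
  aa <- code$codons[[codon]]
  s <- 0
  for (pos in 1:3) {
    muts <- .mutants_at(codon, pos)
    legal <- muts[!muts %in% code$stops]
    if (length(legal) == 0) next  # position contributes 0 syn, 1 nonsyn
    s <- s + sum(code$codons[legal] == aa) / length(legal)
  }
  c(s = s, n = 3 - s)
}

# all permutations of 1..k (k <= 3 needed)
.perms <- function(k) {
  if (k == 1) return(list(1L))
  if (k == 2) return(list(c(1L, 2L), c(2L, 1L)))
  out <- list()
  for (i in 1:3) for (p in .perms(2)) {
    out[[length(out) + 1L]] <- c(i, setdiff(1:3, i)[p])
  }
  out
}

#' Synonymous and nonsynonymous differences between two codons (NG86)
#'
#' Codons differing at `d` positions are connected by `d!` orderings of
#' the single-base substitutions; each step is classified as synonymous
#' or nonsynonymous and the counts are averaged over all orderings
#' (equal weights). Pathways passing through a stop codon are excluded
#' and the weights renormalized. If every pathway is illegal, the
#' per-position changes are classified directly against `codon_a` and
#' the result flagged (`fallback = TRUE`).
#'
#' @param codon_a,codon_b Non-stop codons.
#' @param code A [genetic_code()].
#' @return One-row tibble: `sd`, `nd`, `n_diff`, `n_pathways` (legal),
#'   `fallback`.
#' @examples
#' ng86_differences("TTT", "TTC")  # one synonymous change
#' @export
ng86_differences <- function(codon_a, codon_b, code = genetic_code()) {
  codon_a <- toupper(codon_a); codon_b <- toupper(codon_b)
  for (cd in c(codon_a, codon_b)) {
    if (!cd %in% names(code$codons) || cd %in% code$stops) {
      abort(paste0("'", cd, "' is not a valid non-stop codon"))
    }
  }
  diff_pos <- which(str_split_1(codon_a, "") != str_split_1(codon_b, ""))
  d <- length(diff_pos)
  if (d == 0) {
    return(tibble(sd = 0, nd = 0, n_diff = 0L, n_pathways = 1L,
                  fallback = FALSE))
  }
  sd_tot <- 0; nd_tot <- 0; n_legal <- 0L
  for (perm in .perms(d)) {
    cur <- codon_a
    sd <- 0; nd <- 0; legal <- TRUE
    for (step in perm) {
      p <- diff_pos[step]
      nxt <- cur
      str_sub(nxt, p, p) <- str_sub(codon_b, p, p)
      if (nxt %in% code$stops) { legal <- FALSE; break }
      if (code$codons[[cur]] == code$codons[[nxt]]) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (legal) {
      sd_tot <- sd_tot + sd; nd_tot <- nd_tot + nd
      n_legal <- n_legal + 1L
    }
  }
  if (n_legal > 0) {
    return(tibble(sd = sd_tot / n_legal, nd = nd_tot / n_legal,
                  n_diff = d, n_pathways = n_legal, fallback = FALSE))
  }
  # no stop-free pathway: classify each position change directly
  sd <- 0; nd <- 0
  for (p in diff_pos) {
    nxt <- codon_a
    str_sub(nxt, p, p) <- str_sub(codon_b, p, p)
    if (!nxt %in% code$stops &&
          code$codons[[codon_a]] == code$codons[[nxt]]) sd <- sd + 1
    else nd <- nd + 1
  }
  tibble(sd = sd, nd = nd, n_diff = d, n_pathways = 0L, fallback = TRUE)
}

# build (or fetch) lookup tables over the full codon grid for a code
.ng86_tables <- function(code) {
  key <- paste0("code_", code$id)
  if (!is.null(.ng86_cache[[key]])) return(.ng86_cache[[key]])
  codons <- names(code$codons)
  nonstop <- setdiff(codons, code$stops)
  sites <- matrix(NA_real_, nrow = 64, ncol = 2,
                  dimnames = list(codons, c("s", "n")))
  for (cd in nonstop) sites[cd, ] <- ng86_sites(cd, code)
  sd_m <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_m <- sd_m
  fb_m <- matrix(FALSE, 64, 64, dimnames = list(codons, codons))
  for (a in nonstop) for (b in nonstop) {
    r <- ng86_differences(a, b, code)
    sd_m[a, b] <- r$sd; nd_m[a, b] <- r$nd; fb_m[a, b] <- r$fallback
  }
  res <- list(sites = sites, sd = sd_m, nd = nd_m, fallback = fb_m)
  .ng86_cache[[key]] <- res
  res
}

#' Jukes-Cantor correction of a proportion of differences
#'
#' `d = -(3/4) * log(1 - 4p/3)`; saturates (returns `NA`) at
#' `p >= 3/4`.
#'
#' @param p Proportion of differing sites, in `[0, 1]`.
#' @return Corrected distance, or `NA` when saturated.
#' @examples
#' jukes_cantor(0.1)
#' @export
jukes_cantor <- function(p) {
  ifelse(p >= 0.75 | p < 0, NA_real_, -0.75 * log(1 - 4 * p / 3))
}

#' NG86 Ka/Ks for an aligned coding-sequence pair
#'
#' Nei-Gojobori (1986) counting with equal-weight pathway averaging and
#' Jukes-Cantor correction. Synonymous (`S`) and nonsynonymous (`N`)
#' site counts are averaged over the two sequences; synonymous (`Sd`)
#' and nonsynonymous (`Nd`) differences are summed over codon pairs;
#' `pS = Sd/S`, `pN = Nd/N`; `Ks = JC(pS)`, `Ka = JC(pN)`,
#' `omega = Ka/Ks`. Codon columns containing gaps, ambiguity codes, or a
#' stop codon in either sequence are excluded (complete-codon deletion)
#' and tallied.
#'
#' @param a,b Aligned in-frame nucleotide strings of equal length.
#' @param code A [genetic_code()].
#' @return Object of class `kaks_result`; see [tidy.kaks_result()] /
#'   [glance.kaks_result()]. Fields include `S`, `N`, `Sd`, `Nd`, `pS`,
#'   `pN`, `ks`, `ka`, `omega`, `n_codons` (compared),
#'   `excluded_codons`, and flags `saturated_s`, `saturated_n`,
#'   `zero_ks` (omega undefined when Ks is 0 or either class saturates).
#' @examples
#' r <- kaks("ATGTTTAAAGGG", "ATGTTCAAAGGG")
#' glance(r)
#' @export
kaks <- function(a, b, code = genetic_code()) {
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) abort("sequences must be aligned (equal length)")
  ca <- .codon_split(a); cb <- .codon_split(b)
  valid <- function(cd) grepl("^[ACGT]{3}$", cd)
  ok <- valid(ca) & valid(cb) & !(ca %in% code$stops) & !(cb %in% code$stops)
  excluded <- sum(!ok)
  ca <- ca[ok]; cb <- cb[ok]
  if (length(ca) == 0) abort("no comparable codons")
  tabs <- .ng86_tables(code)
  S <- (sum(tabs$sites[ca, "s"]) + sum(tabs$sites[cb, "s"])) / 2
  N <- (sum(tabs$sites[ca, "n"]) + sum(tabs$sites[cb, "n"])) / 2
  Sd <- sum(tabs$sd[cbind(ca, cb)])
  Nd <- sum(tabs$nd[cbind(ca, cb)])
  any_fallback <- any(tabs$fallback[cbind(ca, cb)])
  pS <- Sd / S; pN <- Nd / N
  ks <- jukes_cantor(pS); ka <- jukes_cantor(pN)
  saturated_s <- is.na(ks); saturated_n <- is.na(ka)
  zero_ks <- !saturated_s && ks == 0
  omega <- if (saturated_s || saturated_n || zero_ks) NA_real_ else ka / ks
  structure(
    list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
         ks = ks, ka = ka, omega = omega,
         n_codons = length(ca), excluded_codons = excluded,
         saturated_s = saturated_s, saturated_n = saturated_n,
         zero_ks = zero_ks, pathway_fallback = any_fallback,
         code_id = code$id, method = "NG86+JC"),
    class = "kaks_result"
  )
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf(
    "<kaks_result> NG86+JC over %d codons: Ka=%.4f Ks=%.4f omega=%s\n",
    x$n_codons, x$ka, x$ks,
    if (is.na(x$omega)) "NA" else sprintf("%.4f", x$omega)))
  invisible(x)
}

#' Tidy an NG86 Ka/Ks result
#'
#' @param x A [kaks()] result.
#' @param ... Unused.
#' @return A long tibble of the counted quantities (`term`, `estimate`).
#' @method tidy kaks_result
#' @export
tidy.kaks_result <- function(x, ...) {
  tibble(
    term = c("S", "N", "Sd", "Nd", "pS", "pN", "ks", "ka", "omega"),
    estimate = c(x$S, x$N, x$Sd, x$Nd, x$pS, x$pN, x$ks, x$ka, x$omega)
  )
}

#' One-row summary of an NG86 Ka/Ks result
#'
#' @param x A [kaks()] result.
#' @param ... Unused.
#' @return One-row tibble with estimates, sizes and validity flags.
#' @method glance kaks_result
#' @export
glance.kaks_result <- function(x, ...) {
  tibble(
    S = x$S, N = x$N, Sd = x$Sd, Nd = x$Nd, pS = x$pS, pN = x$pN,
    ks = x$ks, ka = x$ka, omega = x$omega, n_codons = x$n_codons,
    excluded_codons = x$excluded_codons, saturated_s = x$saturated_s,
    saturated_n = x$saturated_n, zero_ks = x$zero_ks,
    pathway_fallback = x$pathway_fallback, method = x$method
  )
}

#' Pairwise per-gene divergence across genomes
#'
#' For one gene present in every genome, computes the p-distance
#' partitions and the NG86 Ka/Ks for every unordered pair of genomes.
#' Gene sequences must already be alignable without gaps (equal
#' lengths); otherwise supply pre-aligned sequences via `aligned`.
#'
#' @param genomes List of [mitogenome]s with sequences.
#' @param gene Gene name.
#' @param aligned Optional named character vector of pre-aligned
#'   sequences (names matching genome labels) overriding extraction.
#' @param code A [genetic_code()].
#' @param trim_terminal Drop the start codon and the (possibly
#'   incomplete) stop from each coding sequence before comparison
#'   (default `TRUE`).
#' @return A tibble, one row per pair: `gene`, `a`, `b`, the
#'   [p_distance()] columns, and the [glance.kaks_result()] columns.
#' @export
pairwise_gene_matrix <- function(genomes, gene, aligned = NULL,
                                 code = genetic_code(),
                                 trim_terminal = TRUE) {
  stopifnot(length(genomes) >= 2)
  labels <- map_chr(genomes, function(g) g$label)
  seqs <- if (!is.null(aligned)) {
    aligned[labels]
  } else {
    stats::setNames(map_chr(genomes, gene_sequence, gene = gene), labels)
  }
  if (trim_terminal) {
    seqs <- vapply(seqs, function(s) {
      body_len <- 3L * ((nchar(s) - 3L) %/% 3L)  # drop incomplete tail
      str_sub(s, 4L, 3L + body_len)
    }, character(1))
    # drop the terminal codon only when it is a stop in every genome,
    # keeping the sequences aligned
    last <- str_sub(seqs, nchar(seqs) - 2L, nchar(seqs))
    if (all(last %in% code$stops)) {
      seqs <- str_sub(seqs, 1L, nchar(seqs) - 3L)
    }
  }
  if (length(unique(nchar(seqs))) != 1) {
    abort(paste0("unequal '", gene, "' lengths across genomes: supply a ",
                 "pre-aligned input via `aligned`"))
  }
  pairs <- utils::combn(seq_along(seqs), 2)
  out <- map(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    bind_cols(
      tibble(gene = gene, a = labels[i], b = labels[j]),
      p_distance(seqs[[i]], seqs[[j]]),
      glance(kaks(seqs[[i]], seqs[[j]], code))
    )
  })
  list_rbind(out)
}
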