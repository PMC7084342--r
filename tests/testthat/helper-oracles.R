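# Independent brute-force oracles for the NG86 counting machinery.
# These are written against Biostrings' code table directly and share no
# code with the package implementation.

oracle_code_table <- function() {
  tab <- Biostrings::getGeneticCode("2")
  names(tab) <- chartr("U", "T", names(tab))
  tab
}

# depth-first enumeration of every ordering of the differing positions;
# returns the average (sd, nd) over stop-free paths, or NULL if none
oracle_pathway_counts <- function(a, b, tab = oracle_code_table()) {
  stops <- names(tab)[tab == "*"]
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (length(pos) == 0) return(c(sd = 0, nd = 0))
  acc <- list(sd = 0, nd = 0, n = 0L)
  walk <- function(cur, remaining, sd, nd) {
    if (length(remaining) == 0) {
      acc$sd <<- acc$sd + sd
      acc$nd <<- acc$nd + nd
      acc$n <<- acc$n + 1L
      return(invisible())
    }
    for (p in remaining) {
      nxt <- cur
      nxt[p] <- bv[p]
      nxt_codon <- paste(nxt, collapse = "")
      if (nxt_codon %in% stops) next
      same_aa <- tab[[paste(cur, collapse = "")]] == tab[[nxt_codon]]
      walk(nxt, setdiff(remaining, p),
           sd + as.numeric(same_aa), nd + as.numeric(!same_aa))
    }
  }
  walk(av, pos, 0, 0)
  if (acc$n == 0L) return(NULL)
  c(sd = acc$sd / acc$n, nd = acc$nd / acc$n)
}

# direct enumeration of the nine mutants, with per-position stop
# renormalization
oracle_site_counts <- function(codon, tab = oracle_code_table()) {
  stops <- names(tab)[tab == "*"]
  cv <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    syn <- 0L; legal <- 0L
    for (bb in setdiff(c("A", "C", "G", "T"), cv[p])) {
      mut <- cv
      mut[p] <- bb
      mutc <- paste(mut, collapse = "")
      if (mutc %in% stops) next
      legal <- legal + 1L
      if (tab[[mutc]] == tab[[codon]]) syn <- syn + 1L
    }
    if (legal > 0) s <- s + syn / legal
  }
  c(s = s, n = 3 - s)
}

all_codons_oracle <- function() {
  b <- c("A", "C", "G", "T")
  apply(expand.grid(b, b, b, stringsAsFactors = FALSE), 1, paste,
        collapse = "")
}
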