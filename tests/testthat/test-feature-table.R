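test_that("packaged fixtures load with the published structure", {
  gf <- load_gerres("filamentosus")
  ge <- load_gerres("erythrourus")
  gd <- load_gerres("decacanthus")
  expect_equal(nrow(features(gf)), 38)
  expect_equal(genome_length(gf), 16673)
  expect_equal(genome_length(ge), 16728)
  expect_equal(genome_length(gd), 16871)
  # GD tRNA-Ile row: 3923..3993 -> 71 bp
  ile <- features(gd) |> dplyr::filter(name == "tRNA-Ile")
  expect_equal(ile$size, 71)
  g <- glance(gf)
  expect_equal(c(g$n_pcg, g$n_trna, g$n_rrna, g$n_control),
               c(13, 22, 2, 1))
})

test_that("genome length falls back to max feature end when undeclared", {
  x <- mitogenome(tibble::tibble(name = "g", category = "PCG",
                                 strand = "H", start = 1, end = 100))
  expect_equal(genome_length(x), 100)
})

test_that("feature table reader rejects malformed input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#label=x length=100 circular=1",
               "name\tcategory\tstrand\tstart\tend"), tf)
  expect_error(read_feature_tsv(tf), "no features")
  writeLines(c("#label=x length=100 circular=1",
               "name\tcategory\tstrand\tstart\tend",
               "g1\tPCG\tH\t50\t10"), tf)
  expect_error(read_feature_tsv(tf), "start > end")
  writeLines(c("#label=x length=100 circular=1",
               "name\tcategory\tstrand\tstart\tend",
               "g1\tPCG\tH\t1\t30", "g1\tPCG\tH\t40\t60"), tf)
  expect_error(read_feature_tsv(tf), "duplicate")
})

test_that("adjacency spacings match the published intergenic column", {
  gf <- load_gerres("filamentosus")
  adj_gf <- adjacency_profile(gf)
  expect_equal(adj_gf$spacing[adj_gf$upstream == "ATP8"], -10)
  adj_gd <- adjacency_profile(load_gerres("decacanthus"))
  expect_equal(
    adj_gd$spacing[adj_gd$upstream == "tRNA-Ile" &
                     adj_gd$downstream == "tRNA-Gln"], 40)
  expect_equal(max(adj_gd$spacing), 40)
  # origin-spanning pair closes the circle with zero gap in all fixtures
  expect_equal(adj_gf$spacing[adj_gf$upstream == "D-loop"], 0)
  # two abutting toy features
  adj_toy <- adjacency_profile(toy_genome())
  expect_equal(adj_toy$spacing, c(0, 0, 0))
})

test_that("spacer and overlap censuses reproduce the published tallies", {
  expect_equal(igs_summary(load_gerres("filamentosus")),
               tibble::tibble(n_spacers = 13L, total_bp = 87L))
  expect_equal(igs_summary(load_gerres("decacanthus")),
               tibble::tibble(n_spacers = 12L, total_bp = 167L))
  expect_equal(overlap_summary(load_gerres("filamentosus")),
               tibble::tibble(n_overlaps = 5L, total_bp = 23L))
  expect_equal(overlap_summary(load_gerres("decacanthus")),
               tibble::tibble(n_overlaps = 4L, total_bp = 22L))
  # perfectly tiled toy genome has neither spacers nor overlaps
  expect_equal(igs_summary(toy_genome())$n_spacers, 0L)
  expect_equal(overlap_summary(toy_genome())$n_overlaps, 0L)
})

test_that("counts of positive and negative spacings partition the nonzero ones", {
  for (sp in c("filamentosus", "erythrourus", "decacanthus")) {
    g <- load_gerres(sp)
    adj <- adjacency_profile(g)
    expect_equal(igs_summary(g)$n_spacers + overlap_summary(g)$n_overlaps,
                 sum(adj$spacing != 0))
  }
})

test_that("tiling identity holds for the three fixtures", {
  for (sp in c("filamentosus", "erythrourus", "decacanthus")) {
    g <- load_gerres(sp)
    expect_equal(sum(features(g)$size) + igs_summary(g)$total_bp -
                   overlap_summary(g)$total_bp,
                 genome_length(g))
  }
})

test_that("the O_L spacer between tRNA-Asn and tRNA-Cys is located", {
  expect_equal(locate_ol(load_gerres("filamentosus"))$spacing, 35)
  expect_equal(locate_ol(load_gerres("erythrourus"))$spacing, 37)
  expect_equal(locate_ol(load_gerres("decacanthus"))$spacing, 36)
  no_cys <- mitogenome(
    features(load_gerres("filamentosus")) |>
      dplyr::filter(name != "tRNA-Cys"),
    length = 16673)
  expect_error(locate_ol(no_cys), "tRNA-Cys")
})

test_that("strand census matches the published gene distribution", {
  gf <- load_gerres("filamentosus")
  cen <- strand_census(gf)
  l <- cen |> dplyr::filter(strand == "L")
  expect_equal(sum(l$n), 9)  # ND6 + 8 light-strand tRNAs
  expect_equal(l$n[l$category == "PCG"], 1L)
  expect_equal(l$n[l$category == "tRNA"], 8L)
  empty <- suppressWarnings(
    mitogenome(tibble::tibble(name = character(), category = character(),
                              strand = character(), start = integer(),
                              end = integer()), length = 10))
  expect_equal(nrow(strand_census(empty)), 0)
})

test_that("protein-coding totals and genome share match the published values", {
  expect_equal(pcg_length_stats(load_gerres("filamentosus"))$total_bp, 11430)
  expect_equal(pcg_length_stats(load_gerres("decacanthus"))$percent, 67.74)
  whole <- mitogenome(tibble::tibble(name = "g", category = "PCG",
                                     strand = "H", start = 1, end = 300))
  expect_equal(pcg_length_stats(whole)$percent, 100)
})

test_that("nested features are excluded from the adjacency profile with a warning", {
  x <- mitogenome(tibble::tibble(
    name = c("outer", "inner", "next1"),
    category = c("rRNA", "tRNA", "rRNA"),
    strand = "H",
    start = c(1L, 10L, 201L), end = c(200L, 80L, 300L)
  ), length = 300)
  expect_warning(adj <- adjacency_profile(x), "nested")
  expect_false("inner" %in% c(adj$upstream, adj$downstream))
  expect_equal(suppressWarnings(igs_summary(x)$n_spacers), 0L)
})

test_that("gene sequences are extracted on the coding strand, with origin wrap", {
  seqs <- paste(rep("ATGCC", 12), collapse = "")  # 60 bp
  x <- toy_genome(sequence = seqs)
  expect_equal(gene_sequence(x, "geneA"), substr(seqs, 1, 20))
  xl <- mitogenome(tibble::tibble(name = "g", category = "PCG",
                                  strand = "L", start = 1, end = 9),
                   length = 9, sequence = "ATGCCCTAA")
  expect_equal(gene_sequence(xl, "g"), "TTAGGGCAT")
  # circular wrap: feature runs 55..6 across the origin
  xw <- mitogenome(tibble::tibble(name = "w", category = "control",
                                  strand = "H", start = 55, end = 6),
                   length = 60, circular = TRUE, sequence = seqs)
  expect_equal(gene_sequence(xw, "w"),
               paste0(substr(seqs, 55, 60), substr(seqs, 1, 6)))
  expect_error(gene_sequence(toy_genome(), "geneA"), "no sequence")
})

test_that("feature TSV round-trips losslessly", {
  gf <- load_gerres("filamentosus")
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_feature_tsv(gf, tf)
  back <- read_feature_tsv(tf)
  expect_equal(back$features, gf$features)
  expect_equal(back$label, gf$label)
  expect_equal(back$length, gf$length)
  expect_equal(back$circular, gf$circular)
})
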