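# Gene models: phases, site inference, exon notation algebra, splice sites.

test_that("intron_phase follows the codon-position definition", {
  expect_equal(intron_phase(153), 0L)  # between two codons
  expect_equal(intron_phase(154), 1L)  # after the first nt of a codon
  expect_equal(intron_phase(155), 2L)  # between second and third nt
  expect_equal(intron_phase(0), 0L)
  expect_error(intron_phase(-1), "non-negative")
})

sf9_model <- function() {
  gene_model("S_frugiperda",
             exon_lengths = c(119, 120, 210, 100, 130, 100, 132, 151, 174,
                              150, 150, 150),
             intron_lengths = c(3459, 344, 1645, 8467, 3290, 733, 1097,
                                989, 494, 601, 952))
}

test_that("site inference recovers the lepidopteran phase series", {
  sites <- infer_intron_sites(sf9_model())
  expect_equal(nrow(sites), 11L)
  expect_equal(sites$phase, c(2, 2, 2, 0, 1, 2, 2, 0, 0, 0, 0))
  expect_true(all(sites$cds_offset > 0 &
                    sites$cds_offset < sf9_model()$cds_length))
  # brute-force recount: phase must equal cumulative exon length mod 3
  cum <- cumsum(exon_lengths(sf9_model()))
  expect_equal(sites$phase, cum[1:11] %% 3)

  expect_equal(nrow(infer_intron_sites(gene_model("x", 300))), 0L)
  two <- gene_model("y", c(7, 11), 100)
  expect_equal(infer_intron_sites(two)$phase, 1L)  # 7 mod 3
})

test_that("gene summaries reproduce printed totals", {
  s <- summarize_gene(sf9_model())
  expect_equal(s$n_introns, 11L)
  expect_equal(s$total_intronic_bp, 22071L)
  cp <- gene_model("C_pipiens", c(911, 151, 624), c(62, 98))
  expect_equal(summarize_gene(cp)$total_intronic_bp, 160L)
  expect_equal(summarize_gene(cp)$n_introns, 2L)
  none <- summarize_gene(gene_model("L_salmonis", 1686))
  expect_equal(none$n_introns, 0L)
  expect_equal(none$total_intronic_bp, 0L)
  expect_equal(none$n_exons, 1L)
})

test_that("gene model invariants are enforced", {
  expect_error(gene_model("x", c(10, 0), 5), "1 nt")
  expect_error(gene_model("x", c(10, 10)), "junction")
  m <- sf9_model()
  expect_equal(unname(m$exons[1, "end"] - m$exons[1, "start"]), 119)
  expect_silent(validate_gene_model(m))
})

test_that("notation lengths match the enumerative layout oracle", {
  # published examples: exon 8 (1-51-0), exon 9 (0-58-0), shared 2-78-2
  cases <- list(c(1, 51, 0), c(0, 58, 0), c(2, 78, 2))
  for (cs in cases) {
    n <- exon_notation(cs[1], cs[2], cs[3])
    expect_equal(notation_to_length(n),
                 oracle_notation_length(cs[1], cs[2], cs[3]),
                 info = format(n))
  }
  expect_equal(notation_to_length(exon_notation(0, 58, 0)), 174L)
  # exon 8 sits between a phase-2 and a phase-0 intron, hence 151 nt
  n8 <- exon_notation(1, 51, 0)
  expect_equal(notation_to_length(n8), 151L)
  expect_equal(notation_phases(n8), c(upstream = 2L, downstream = 0L))
  set.seed(7)
  for (i in 1:40) {
    n <- random_notation()
    expect_equal(notation_to_length(n),
                 oracle_notation_length(n$u, n$codons, n$d))
  }
  expect_error(exon_notation(1, 1, 2), "too small")
})

test_that("merging exons across a lost intron matches the published fusion", {
  merged <- merge_exons(exon_notation(1, 51, 0), exon_notation(0, 58, 0))
  expect_equal(c(merged$u, merged$codons, merged$d), c(1, 109, 0))
  expect_equal(notation_to_length(merged), 151L + 174L)
  triv <- merge_exons(exon_notation(0, 10, 0), exon_notation(0, 5, 0))
  expect_equal(triv$codons, 15)
  # split codon at the boundary is counted once
  m2 <- merge_exons(exon_notation(2, 40, 1), exon_notation(2, 38, 2))
  expect_equal(c(m2$u, m2$codons, m2$d), c(2, 77, 2))
  expect_error(merge_exons(exon_notation(0, 10, 1), exon_notation(0, 5, 0)),
               "incompatible")
})

test_that("split is the exact inverse of merge", {
  pieces <- split_exon(exon_notation(1, 109, 0), 151)
  expect_equal(c(pieces[[1]]$u, pieces[[1]]$codons, pieces[[1]]$d),
               c(1, 51, 0))
  expect_equal(c(pieces[[2]]$u, pieces[[2]]$codons, pieces[[2]]$d),
               c(0, 58, 0))
  halves <- split_exon(exon_notation(0, 2, 0), 3)
  expect_equal(vapply(halves, `[[`, 1L, "codons"), c(1L, 1L))
  expect_error(split_exon(exon_notation(0, 2, 0), 6), "inside")
  set.seed(11)
  for (i in 1:200) {
    n <- random_notation()
    L <- notation_to_length(n)
    k <- sample(L - 1L, 1)
    pieces <- try(split_exon(n, k), silent = TRUE)
    if (inherits(pieces, "try-error")) next  # offset inside a flank codon
    back <- merge_exons(pieces[[1]], pieces[[2]])
    expect_equal(c(back$u, back$codons, back$d), c(n$u, n$codons, n$d))
    expect_equal(notation_to_length(pieces[[1]]), k)
  }
})

test_that("model exon notations are mutually consistent", {
  nots <- model_exon_notations(sf9_model())
  expect_length(nots, 12L)
  expect_equal(vapply(nots, notation_to_length, 1L),
               exon_lengths(sf9_model()))
  expect_equal(format(nots[[8]]), "1-51-0")
  expect_equal(format(nots[[9]]), "0-58-0")
  expect_equal(format(nots[[3]]), "1-71-2")  # 71 codons in Sf9 exon 3
})

test_that("splice-site validation checks GT..AG dinucleotides", {
  m <- gene_model("toy", c(6, 6), 10)
  seqs <- function(intron) paste0("ATGGCA", intron, "GCAGCATAA")
  good <- validate_splice_sites(m, seqs("GTAAGTTTAG"))
  expect_true(good$canonical)
  expect_equal(good$donor, "GT")
  bad <- validate_splice_sites(m, seqs("CTAAGTTTAC"))
  expect_false(bad$canonical)
  gc <- validate_splice_sites(m, seqs("GCAAGTTTAG"))
  expect_false(gc$canonical)  # non-canonical classes only get the flag
  expect_equal(nrow(validate_splice_sites(gene_model("x", 12),
                                          "ATGGCAGCATAA")), 0L)
  expect_error(validate_splice_sites(m, "ATG"), "shorter")
})

test_that("gene models round-trip through the TSV format", {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  models <- list(sf9_model(), gene_model("L_salmonis", 1686))
  write_gene_models_tsv(models, tmp)
  back <- read_gene_models_tsv(tmp)
  expect_equal(exon_lengths(back$S_frugiperda), exon_lengths(sf9_model()))
  expect_equal(back$S_frugiperda$intron_lengths,
               sf9_model()$intron_lengths)
  expect_equal(length(back$L_salmonis$intron_lengths), 0L)
})

test_that("GFF3 gene models are normalised to the coding strand", {
  skip_if_not_installed("rtracklayer")
  tmp <- tempfile(fileext = ".gff3")
  on.exit(unlink(tmp))
  # same gene on both strands: exons 9 + 12 nt with a 100 nt intron
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tmRNA\t101\t221\t.\t+\t.\tID=plus",
    "chr1\ttest\tCDS\t101\t109\t.\t+\t0\tID=c1;Parent=plus",
    "chr1\ttest\tCDS\t210\t221\t.\t+\t0\tID=c2;Parent=plus",
    "chr1\ttest\tmRNA\t301\t421\t.\t-\t.\tID=minus",
    "chr1\ttest\tCDS\t301\t312\t.\t-\t0\tID=c3;Parent=minus",
    "chr1\ttest\tCDS\t413\t421\t.\t-\t0\tID=c4;Parent=minus"),
    tmp)
  models <- read_gene_models_gff3(tmp)
  expect_equal(exon_lengths(models$plus), c(9L, 12L))
  expect_equal(models$plus$intron_lengths, 100L)
  # minus strand: 5' exon is the rightmost block
  expect_equal(exon_lengths(models$minus), c(9L, 12L))
  expect_equal(models$minus$intron_lengths, 100L)
  expect_equal(infer_intron_sites(models$minus)$phase, 0L)
})

test_that("gene models can be rebuilt from printed phase/length cells", {
  t4 <- read_site_table(fixture("sites_arthropoda_chordata.tsv"))
  row <- t4$cells[t4$cells$species == "B_mori" & t4$cells$present, ]
  m <- gene_model_from_sites("B_mori", row$phase, row$intron_length)
  s <- summarize_gene(m)
  expect_equal(s$total_intronic_bp, 20079L)
  expect_equal(s$n_introns, 11L)
  expect_equal(infer_intron_sites(m)$phase, row$phase)
})
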