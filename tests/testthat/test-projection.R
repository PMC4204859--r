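# Projection onto the alignment, clustering, labelling, near pairs,
# presence/absence, column profiles.

toy_sites <- function(species, offsets) {
  data.frame(species_id = species, cds_offset = offsets)
}

test_that("cds_to_residue splits an offset into residue and phase", {
  expect_equal(cds_to_residue(0), data.frame(residue_index = 0L, phase = 0L))
  expect_equal(cds_to_residue(152),
               data.frame(residue_index = 50L, phase = 2L))
  expect_equal(cds_to_residue(174),
               data.frame(residue_index = 58L, phase = 0L))
  expect_error(cds_to_residue(-3), "non-negative")
})

test_that("projection maps residues through gapped rows", {
  msa <- c(a = paste(rep("A", 60), collapse = ""),
           b = paste0("M-", paste(rep("C", 58), collapse = "")))
  # gapless row: identity mapping
  p <- project_site(list(species_id = "a", cds_offset = 152), msa)
  expect_equal(p$alignment_column, 50L)
  # one leading gap shifts all later residues by one column
  p2 <- project_site(list(species_id = "b", cds_offset = 3), msa)
  expect_equal(p2$residue_index, 1L)
  expect_equal(p2$alignment_column, 2L)
  expect_error(project_site(list(species_id = "b", cds_offset = 3 * 59), msa),
               "beyond the aligned sequence")
  expect_error(project_site(list(species_id = "zz", cds_offset = 3), msa),
               "not in the alignment")
})

test_that("round trip: column back to residue on gapless alignments", {
  msa <- c(x = paste(sample(c("A", "R", "N", "D"), 80, TRUE), collapse = ""))
  offs <- c(1, 2, 3, 40, 120, 239)
  pr <- project_sites(toy_sites(rep("x", length(offs)), offs), msa)
  expect_equal(pr$alignment_column, pr$residue_index)
  expect_equal(pr$alignment_column * 3 + pr$phase, offs)
})

test_that("clustering requires identical phase and respects tolerance", {
  s <- data.frame(species_id = c("a", "b"), alignment_column = c(10L, 10L),
                  phase = c(0L, 0L))
  expect_length(cluster_sites(s), 1L)
  expect_setequal(cluster_sites(s)[[1]]$members, c("a", "b"))
  # same column, different phase: non-homologous, two clusters
  s2 <- data.frame(species_id = c("a", "b"), alignment_column = c(10L, 10L),
                   phase = c(0L, 2L))
  expect_length(cluster_sites(s2), 2L)
  # tolerance joins nearby columns, and cluster count is non-increasing
  s3 <- data.frame(species_id = c("a", "b", "c"),
                   alignment_column = c(10L, 11L, 13L),
                   phase = c(1L, 1L, 1L))
  n_by_tol <- vapply(0:3, function(tol)
    length(cluster_sites(s3, column_tolerance = tol)), 1L)
  expect_equal(n_by_tol, c(3L, 2L, 1L, 1L))
  expect_true(all(diff(n_by_tol) <= 0))
  # phase homogeneity is a hard invariant of every cluster
  cl <- cluster_sites(rbind(s, s2, s3))
  for (c_ in cl) expect_length(unique(c_$sites$phase), 1L)
})

test_that("the packaged lepidoptera alignment clusters into 11 shared sites", {
  msa <- read_alignment_fasta(fixture("fut8_msa_synthetic.fasta"))
  models <- read_gene_models_tsv(fixture("fut8_gene_models_synthetic.tsv"))
  leps <- c("S_frugiperda", "B_mori")
  sites <- do.call(rbind, lapply(models[leps], infer_intron_sites))
  cl <- cluster_sites(project_sites(sites, msa))
  expect_length(cl, 11L)
  for (c_ in cl) expect_setequal(c_$members, leps)
})

test_that("lineage labelling numbers clusters in column order", {
  # hymenopteran pattern: the family-specific third site must take the
  # third ordinal even though the apid reference lacks it
  hym <- c("A_mellifera", "B_impatiens", "M_rotundata", "A_cephalotes",
           "S_invicta", "C_floridanus", "H_saltator")
  formicids <- hym[4:7]
  s <- rbind(toyframe <- do.call(rbind, list(
    data.frame(species_id = hym, alignment_column = 100L, phase = 2L),
    data.frame(species_id = hym, alignment_column = 200L, phase = 2L),
    data.frame(species_id = formicids, alignment_column = 300L, phase = 2L),
    data.frame(species_id = hym, alignment_column = 400L, phase = 0L))))
  cl <- label_clusters(cluster_sites(s), reference = hym, suffix = "h")
  labs <- vapply(cl, function(c_) c_$labels[1], character(1))
  expect_equal(labs, c("i1h", "i2h", "i3h", "i4h"))
  expect_setequal(get_cluster(cl, "i3h")$members, formicids)
  expect_false("A_mellifera" %in% get_cluster(cl, "i3h")$members)
  # single cluster, any reference member
  one <- label_clusters(cluster_sites(
    data.frame(species_id = "a", alignment_column = 5L, phase = 0L)),
    "a", "x")
  expect_equal(one[[1]]$labels, "i1x")
  expect_error(label_clusters(cl, "no_such_species", "z"), "not found")
})

test_that("chordate labelling on the packaged fixture yields i4c and i7c", {
  msa <- read_alignment_fasta(fixture("fut8_msa_synthetic.fasta"))
  models <- read_gene_models_tsv(fixture("fut8_gene_models_synthetic.tsv"))
  sites <- do.call(rbind, lapply(models, infer_intron_sites))
  cl <- cluster_sites(project_sites(sites, msa))
  cl <- label_clusters(cl, c("S_frugiperda", "B_mori"), "l")
  cl <- label_clusters(cl, c("H_sapiens", "B_taurus"), "c")
  i7c <- get_cluster(cl, "i7c")
  expect_setequal(i7c$members, c("H_sapiens", "B_taurus"))
  expect_equal(i7c$phase, 0L)
  # shared sites carry both lineage labels
  expect_equal(get_cluster(cl, "i3l")$labels, c("i3l", "i3c"))
  expect_equal(get_cluster(cl, "i7l")$labels, c("i7l", "i6c"))
  # the lepidopteran i8l cluster also contains the culicid gene
  expect_true("C_pipiens" %in% get_cluster(cl, "i8l")$members)
})

test_that("near intron pairs are detected at the published 24 nt distance", {
  msa <- read_alignment_fasta(fixture("fut8_msa_synthetic.fasta"))
  models <- read_gene_models_tsv(fixture("fut8_gene_models_synthetic.tsv"))
  sites <- do.call(rbind, lapply(models, infer_intron_sites))
  cl <- cluster_sites(project_sites(sites, msa))
  cl <- label_clusters(cl, c("S_frugiperda", "B_mori"), "l")
  cl <- label_clusters(cl, c("H_sapiens", "B_taurus"), "c")
  np <- near_intron_pairs(cl, max_nt_distance = 32)
  expect_equal(nrow(np), 1L)
  expect_setequal(c(np$label_a, np$label_b), c("i8l", "i7c"))
  expect_equal(np$nt_distance, 24L)
  # i4l and i4c are 51 nt apart: outside the default window
  wide <- near_intron_pairs(cl, max_nt_distance = 60)
  expect_true(any(wide$label_a == "i4l" & wide$label_b == "i4c" &
                    wide$nt_distance == 51L))
  expect_equal(nrow(near_intron_pairs(cl, max_nt_distance = 10)), 0L)
})

test_that("same-column same-phase sites are one cluster, not a pair", {
  s <- data.frame(species_id = c("a", "b"), alignment_column = 10L,
                  phase = 0L)
  cl <- label_clusters(cluster_sites(s), c("a", "b"), "x")
  expect_equal(nrow(near_intron_pairs(cl, 32)), 0L)
})

test_that("presence/absence marks members, absences and truncations", {
  s <- data.frame(species_id = c("a", "b", "a"),
                  alignment_column = c(10L, 10L, 40L), phase = 0L)
  cl <- label_clusters(cluster_sites(s), c("a", "b"), "x")
  pa <- presence_absence(cl, c("a", "b", "c"))
  expect_equal(pa["a", ], c(i1x = "present", i2x = "present"))
  expect_equal(pa["b", ], c(i1x = "present", i2x = "absent"))
  expect_equal(unname(pa["c", ]), c("absent", "absent"))
  # 5' truncation: unknown upstream of the truncation column
  pa2 <- presence_absence(cl, c("a", "b"),
                          truncation_columns = c(b = 20L))
  expect_equal(pa2["b", ], c(i1x = "present", i2x = "absent"))
  pa3 <- presence_absence(cl, c("a", "b"),
                          truncation_columns = c(b = 30L))
  expect_equal(unname(pa3["b", "i1x"]), "present")
  m_empty <- presence_absence(cl, character())
  expect_equal(nrow(m_empty), 0L)
})

test_that("column profiles give logo frequencies and information", {
  msa <- c(a = "RRK", b = "RKK", c = "RRK", d = "RKK")
  prof <- column_profile(msa)
  expect_equal(prof$information[1], log2(20))          # invariant column
  expect_equal(prof$information[2], log2(20) - 1)      # 50/50 two residues
  expect_equal(sum(prof$frequencies[, 2]), 1)
  # uniform over the 20 residues: zero information
  uni <- column_profile(stats::setNames(
    strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
    paste0("s", 1:20)))
  expect_equal(uni$information[1], 0)
  # all-gap column: information undefined
  gap <- column_profile(c(a = "-A", b = "-A"))
  expect_true(is.na(gap$information[1]))
  expect_equal(gap$gap_fraction[1], 1)
  expect_equal(gap$information[2], log2(20))
})
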