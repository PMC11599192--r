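cat10 <- load_catalog()
context_tb <- simulate_genome(seed = 7)$tables[[1]]

test_that("profile scoring implements the evidence point scheme", {
  sim <- simulate_family_protein("CD28H", divergence = 0, seed = 1)
  arch <- segment_protein(sim$record)
  hit <- marker_support(context_tb, "cd28h", cat10$CD28H$markers)
  sc <- score_profile(sim$record, arch, cat10$CD28H, synteny_hit = hit)
  # two REQUIRED motifs (2 each) + supporting EIPPP (1) + two markers (2)
  expect_gte(sc$score, 6)
  expect_true("SYNTENY" %in% sc$evidence$source)
  expect_length(sc$missing_required, 0)

  # no evidence at all scores zero
  sc0 <- score_profile(sim$record, arch, cat10$CD28HL3)
  expect_equal(sc0$score, 0)
  expect_true(length(sc0$missing_required) > 0)

  # PD1 exemplar: cytoplasmic motifs + markers score despite divergent IgV
  simp <- simulate_family_protein("PD1", divergence = 0, seed = 1)
  archp <- segment_protein(simp$record)
  expect_true(archp$igv_divergent)
  hitp <- marker_support(context_tb, "pd1", cat10$PD1$markers)
  scp <- score_profile(simp$record, archp, cat10$PD1, synteny_hit = hitp)
  expect_gte(scp$score, 5)
})

test_that("zero-divergence exemplars recover all nine family labels", {
  for (fam in names(FAMILY_GENE)) {
    sim <- simulate_family_protein(fam, divergence = 0, seed = 21)
    a <- classify_protein(sim$record, genome_context = context_tb,
                          gene_name = FAMILY_GENE[[fam]], catalog = cat10)
    expect_equal(a$label, fam)
    expect_true(a$architecture_pass)
    expect_gte(a$score - a$runner_up_score,
               if (fam %in% c("CD28", "CD28_CTLA4_CO_ORTHOLOG")) 2 else 2)
  }
})

test_that("chondrichthyan hybrid evidence resolves to the co-ortholog class", {
  # carries P-[P/L]-P + GxG + YxxxxT + EYxNM, classified without context
  sim <- simulate_family_protein("CD28_CTLA4_CO_ORTHOLOG", divergence = 0, seed = 5)
  a <- classify_protein(sim$record, catalog = cat10)
  expect_equal(a$label, "CD28_CTLA4_CO_ORTHOLOG")
  # with context and cassette genes, the position is annotated
  a2 <- classify_protein(sim$record, genome_context = context_tb,
                         gene_name = "ctla4", catalog = cat10,
                         cassette_genes = c("cd28", "ctla4", "icos"))
  expect_equal(a2$cassette_position, 2)
})

test_that("negatives and degenerate inputs yield UNCLASSIFIED", {
  # random sequence with a planted TM but no motifs
  set.seed(33)
  s <- paste0(paste(sample(c("S","T","N","Q","D","E"), 90, TRUE), collapse = ""),
              strrep("L", 21),
              paste(sample(c("S","T","N","Q","D","E"), 40, TRUE), collapse = ""))
  a <- classify_protein(protein_record("rand", s), catalog = cat10)
  expect_equal(a$label, "UNCLASSIFIED")

  # segmentation failure: architecture_pass is FALSE
  sol <- protein_record("sol", strrep("SQDNTE", 14))
  a2 <- classify_protein(sol, catalog = cat10)
  expect_equal(a2$label, "UNCLASSIFIED")
  expect_false(a2$architecture_pass)
})

test_that("criterion (2): no canonical label without synteny evidence in context", {
  # context where the candidate sits far from any catalog marker
  far_tb <- make_toy_table(c(sprintf("x%d", 1:10), "orphan", sprintf("y%d", 1:10)))
  for (fam in c("CD28", "CD28H", "PD1")) {
    sim <- simulate_family_protein(fam, divergence = 0, seed = 13)
    a <- classify_protein(sim$record, genome_context = far_tb,
                          gene_name = "orphan", catalog = cat10)
    expect_equal(a$label, "UNCLASSIFIED", info = fam)
  }
  # property: any canonical label assigned with context carries SYNTENY evidence
  for (fam in names(FAMILY_GENE)) {
    sim <- simulate_family_protein(fam, divergence = 0, seed = 14)
    a <- classify_protein(sim$record, genome_context = context_tb,
                          gene_name = FAMILY_GENE[[fam]], catalog = cat10)
    if (a$label != "UNCLASSIFIED") {
      expect_true(any(a$evidence$source == "SYNTENY"), info = fam)
    }
  }
})

test_that("catalog order only matters for exact ties", {
  set.seed(77)
  perm_catalog <- function(perm) {
    structure(cat10[perm], class = "family_catalog",
              catalog_version = attr(cat10, "catalog_version"))
  }
  for (i in 1:5) {
    fam <- sample(names(FAMILY_GENE), 1)
    sim <- simulate_family_protein(fam, divergence = 0.05,
                                   protect_motifs = TRUE, seed = 100 + i)
    a1 <- classify_protein(sim$record, genome_context = context_tb,
                           gene_name = FAMILY_GENE[[fam]], catalog = cat10)
    shuffled <- perm_catalog(sample(length(cat10)))
    a2 <- classify_protein(sim$record, genome_context = context_tb,
                           gene_name = FAMILY_GENE[[fam]], catalog = shuffled)
    tied <- sum(a1$all_scores == a1$score) > 1
    if (!tied) expect_equal(a2$label, a1$label)
  }
})
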