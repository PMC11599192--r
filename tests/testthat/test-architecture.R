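test_that("hydrophobic stretches are detected and hydrophilic ones are not", {
  # 21 leucines inside a polar scaffold
  s <- paste0(strrep("S", 20), strrep("L", 21), strrep("S", 19))
  tm <- detect_tm(s)
  expect_equal(nrow(tm), 1)
  expect_equal(tm$start, 21)
  expect_equal(tm$end, 41)

  expect_equal(nrow(detect_tm(strrep("S", 100))), 0)
  expect_equal(nrow(detect_tm("LLLLL")), 0)  # shorter than the window

  # planted TM of a zero-divergence exemplar overlaps the detected one by >= 15
  sim <- simulate_family_protein("CD28", divergence = 0, seed = 5)
  got <- detect_tm(sim$record$sequence)
  planted <- sim$truth$regions$tm
  overlap <- min(got$end, planted[2]) - max(got$start, planted[1]) + 1
  expect_gte(overlap, 15)
})

test_that("the IgV framework triple is found at canonical spacings", {
  base <- strsplit(strrep("S", 120), "")[[1]]
  base[23] <- "C"; base[41] <- "W"; base[88] <- "C"
  s <- paste(base, collapse = "")
  r <- check_igv(s, c(1, 120))
  expect_true(r$has_igv)
  expect_equal(c(r$cys1, r$cys2, r$trp), c(23, 88, 41))
  expect_false(r$divergent)

  # no cysteines at all: divergent when the span is IgV-sized
  r2 <- check_igv(strrep("S", 100), c(1, 100))
  expect_false(r2$has_igv)
  expect_true(r2$divergent)
  r3 <- check_igv(strrep("S", 30), c(1, 30))
  expect_false(r3$divergent)

  # leftmost-cys1 / smallest-cys2 tie-break
  base[95] <- "C"
  r4 <- check_igv(paste(base, collapse = ""), c(1, 120))
  expect_equal(r4$cys2, 88)

  sim <- simulate_family_protein("CD28H", divergence = 0, seed = 2)
  r5 <- check_igv(sim$record$sequence, c(19, 126))
  expect_true(r5$has_igv)
})

test_that("segmentation recovers the planted architecture", {
  sim <- simulate_family_protein("CD28", divergence = 0, seed = 3)
  arch <- segment_protein(sim$record)
  expect_true(arch$has_single_igv)
  expect_false(arch$igv_divergent)
  expect_setequal(names(arch$regions),
                  c("leader", "igv", "stalk", "tm", "cytoplasmic"))
  expect_equal(arch$igv_cys2, 106)

  # a soluble protein is rejected
  sol <- protein_record("sol", strrep("SQDNTE", 14))
  expect_error(segment_protein(sol), "not a candidate type-I membrane protein")

  # provided regions take precedence; inference fills the rest
  seqs <- sim$record$sequence
  rec <- protein_record("manual", seqs,
                        provided_regions = data.frame(region = "TM",
                                                      start = 127, end = 147))
  arch2 <- segment_protein(rec)
  expect_equal(arch2$tm_interval, c(127, 147))
  expect_true("cytoplasmic" %in% names(arch2$regions))
  expect_equal(arch2$cyt_length, nchar(seqs) - 147)
})

test_that("segmentation is deterministic, id-invariant, and non-overlapping", {
  for (fam in c("CD28", "CTLA4", "PD1")) {
    sim <- simulate_family_protein(fam, divergence = 0, seed = 9)
    a1 <- segment_protein(sim$record)
    a2 <- segment_protein(protein_record("renamed", sim$record$sequence))
    expect_equal(a1$regions, a2$regions)
    ivs <- do.call(rbind, a1$regions)
    ord <- order(ivs[, 1])
    ivs <- ivs[ord, , drop = FALSE]
    expect_true(all(ivs[-1, 1] > ivs[-nrow(ivs), 2]))  # disjoint, ordered
    expect_true(all(ivs >= 1 & ivs <= nchar(sim$record$sequence)))
  }
})

test_that("planted boundaries are recovered within 3 residues for all profiles", {
  fams <- c("CD28", "CTLA4", "ICOS", "CD28_CTLA4_CO_ORTHOLOG", "CD28H",
            "CD28HL1", "CD28HL2", "CD28HL3", "CD28X", "PD1")
  for (fam in fams) {
    for (seed in 1:10) {
      sim <- simulate_family_protein(fam, divergence = 0, seed = seed)
      arch <- segment_protein(sim$record)
      expect_lte(max(abs(arch$tm_interval - sim$truth$regions$tm)), 3)
      expect_lte(max(abs(arch$regions$leader - sim$truth$regions$leader)), 3)
      if (fam == "PD1") {
        expect_true(arch$igv_divergent)
      } else {
        expect_true(arch$has_single_igv)
        expect_equal(arch$igv_cys1, 41)
        expect_equal(arch$igv_cys2, 106)
      }
    }
  }
})

test_that("a second framework triple before the TM voids single-IgV status", {
  sim <- simulate_family_protein("CD28", divergence = 0, seed = 4)
  s <- strsplit(sim$record$sequence, "")[[1]]
  # graft a second IgV-like scaffold between IgV end and TM is impossible in
  # 190 aa; build a two-domain construct instead
  igv <- paste(s[19:118], collapse = "")
  twodom <- paste0(paste(s[1:118], collapse = ""), igv,
                   paste(s[119:190], collapse = ""))
  arch <- segment_protein(protein_record("twodom", twodom))
  expect_false(arch$has_single_igv)
})
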