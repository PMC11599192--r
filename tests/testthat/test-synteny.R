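test_that("marker support counts shared neighbors, insensitive to orientation", {
  tb <- make_toy_table(c("u1", "u2", "fsd1", "cand", "stap2", "u3", "u4"))
  hit <- marker_support(tb, "cand", c("fsd1", "stap2"))
  expect_equal(hit$shared_count, 2)
  expect_setequal(hit$shared_markers, c("fsd1", "stap2"))

  expect_equal(marker_support(tb, "cand", character())$shared_count, 0)
  expect_error(marker_support(tb, "nothere", "fsd1"), "not found")

  # reversing gene order leaves the count unchanged
  rev_tb <- make_toy_table(rev(tb$gene))
  expect_equal(marker_support(rev_tb, "cand", c("fsd1", "stap2"))$shared_count, 2)

  # strand flips are irrelevant
  flipped <- tb
  flipped$strand <- ifelse(tb$strand == "+", "-", "+")
  expect_equal(marker_support(flipped, "cand", c("fsd1", "stap2"))$shared_count, 2)

  # case-insensitive, suffix-tolerant matching
  tb2 <- make_toy_table(c("TACC3", "cand", "slbp.1", "tmem129-b"))
  hit2 <- marker_support(tb2, "cand", c("tacc3", "slbp", "tmem129"))
  expect_equal(hit2$shared_count, 3)

  # window half-width restricts the neighborhood
  tb3 <- make_toy_table(c("fsd1", "f1", "f2", "f3", "cand"))
  expect_equal(marker_support(tb3, "cand", "fsd1", k = 2)$shared_count, 0)
  expect_equal(marker_support(tb3, "cand", "fsd1", k = 4)$shared_count, 1)
})

test_that("cassette detection reports maximal runs of size >= 2", {
  fam <- c("coA", "coB", "coC")
  tb <- make_toy_table(c("m1", "coA", "coB", "coC", "m2"))
  calls <- detect_cassette(tb, fam)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$size, 3)
  expect_equal(calls[[1]]$member_genes, c("coA", "coB", "coC"))
  expect_setequal(calls[[1]]$flanking_markers, c("m1", "m2"))

  # singleton runs are not cassettes
  expect_length(detect_cassette(make_toy_table(c("m1", "coA", "m2")), fam), 0)

  # one interleaving non-family gene is allowed by default; two are not
  tb_gap1 <- make_toy_table(c("coA", "x1", "coB"))
  expect_length(detect_cassette(tb_gap1, fam), 1)
  tb_gap2 <- make_toy_table(c("coA", "x1", "x2", "coB"))
  expect_length(detect_cassette(tb_gap2, fam), 0)
  expect_length(detect_cassette(tb_gap2, fam, max_gap = 2), 1)

  # two separated runs give two calls; no gene is in two calls
  tb12 <- make_toy_table(c("m1", "coA", "coB", "x1", "x2", "x3", "m2",
                           "coC", "coA2", "m3", "x4", "x5"))
  calls2 <- detect_cassette(tb12, c(fam, "coA2"))
  expect_length(calls2, 2)
  expect_equal(vapply(calls2, `[[`, integer(1), "size"), c(2L, 2L))
  all_members <- unlist(lapply(calls2, `[[`, "member_genes"))
  expect_false(anyDuplicated(all_members) > 0)
})

test_that("paralogous region counting follows the 2^d WGD law", {
  blocks <- ancestral_blocks()
  mk <- blocks$cassette$markers
  base <- count_paralogous_regions(
    simulate_genome(blocks, wgd_events = 0, seed = 5)$tables, mk)
  expect_equal(base, 1L)
  for (d in 1:2) {
    g <- simulate_genome(blocks, wgd_events = d, loss_probability = 0, seed = 5)
    expect_equal(count_paralogous_regions(g$tables, mk), base * 2L^d)
  }

  # a region must reach min_shared distinct markers
  tb <- make_toy_table(c("raph1", "x1", "x2"))
  expect_equal(count_paralogous_regions(list(tb), mk, min_shared = 2), 0L)

  # far-apart clusters on one chromosome count separately
  genes <- c("raph1", "abi2", sprintf("f%d", 1:60), "cyp20a1", "wdr12")
  expect_equal(count_paralogous_regions(list(make_toy_table(genes)), mk), 2L)
  genes2 <- c("raph1", "abi2", sprintf("f%d", 1:10), "cyp20a1", "wdr12")
  expect_equal(count_paralogous_regions(list(make_toy_table(genes2)), mk), 1L)
})

test_that("gene-order table invariants are enforced", {
  expect_error(gene_order_table("s", "c",
    data.frame(gene = c("a", "b"), start = c(10, 5), end = c(20, 30),
               strand = c("+", "+"))), "strictly increasing")
  expect_error(gene_order_table("s", "c",
    data.frame(gene = "a", start = 10, end = 5, strand = "+")), "start > end")
  expect_error(gene_order_table("s", "c",
    data.frame(gene = "a", start = 1, end = 5, strand = "?")), "strand")
})
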