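test_that("global alignment matches exhaustive enumeration on short peptides", {
  data(BLOSUM62, package = "Biostrings", envir = environment())
  al <- align_global("PPP", "PAP")
  expect_equal(al$percent_identity, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(al$score, brute_align_score("PPP", "PAP", BLOSUM62))

  expect_equal(align_global("DYMNM", "DYMNM")$percent_identity, 100)

  set.seed(404)
  for (i in 1:40) {
    a <- random_protein(sample(2:6, 1))
    b <- random_protein(sample(2:6, 1))
    expect_equal(align_global(a, b)$score,
                 brute_align_score(a, b, BLOSUM62),
                 info = paste(a, b))
  }

  # two zero-divergence CD28 exemplars from different seeds: same planted
  # motifs, different scaffold -> identity strictly between chance and 100
  s1 <- simulate_family_protein("CD28", divergence = 0, seed = 1)$record$sequence
  s2 <- simulate_family_protein("CD28", divergence = 0, seed = 2)$record$sequence
  pid <- align_global(s1, s2)$percent_identity
  expect_lt(pid, 100)
  expect_gt(pid, 20)  # scaffold-only chance identity is ~1/6
})

test_that("similarity matrix is symmetric with unit diagonal and equivariant", {
  m <- similarity_matrix(c(a = "DYMNM", b = "DYMNM"))
  expect_equal(unname(m), matrix(100, 2, 2))

  seqs <- vapply(c(CD28 = 1, CTLA4 = 2, CD28H = 3, PD1 = 4), function(s)
    simulate_family_protein(names(which(c(CD28 = 1, CTLA4 = 2, CD28H = 3, PD1 = 4) == s)),
                            divergence = 0, seed = s)$record$sequence, character(1))
  m2 <- similarity_matrix(seqs)
  expect_equal(m2, t(m2))
  expect_equal(unname(diag(m2)), rep(100, 4))
  expect_true(all(m2[upper.tri(m2)] < 100))

  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  m3 <- similarity_matrix(seqs[perm])
  expect_equal(m3, m2[perm, perm])
})

test_that("neighbor joining is exact on additive matrices", {
  # 3 taxa: closed-form three-point solution
  d3 <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  expect_equal(ape::cophenetic.phylo(tr3)[c("a","b","c"), c("a","b","c")], d3)

  # known 4-leaf tree with distinct branch lengths
  tru <- ape::read.tree(text = "((a:1,b:2):3,(c:4,d:5):0);")
  d4 <- ape::cophenetic.phylo(tru)
  tr4 <- nj_tree(d4)
  expect_equal(ape::cophenetic.phylo(tr4)[rownames(d4), colnames(d4)], d4,
               tolerance = 1e-9)
  expect_true(clade_membership(tr4, "a", "b"))

  # random additive matrices up to 8 taxa reproduce path lengths
  set.seed(11)
  for (i in 1:30) {
    n <- sample(4:8, 1)
    tru_i <- ape::rtree(n, br = function(k) runif(k, 0.5, 3))
    d <- ape::cophenetic.phylo(tru_i)
    d <- d[order(rownames(d)), order(colnames(d))]
    tr <- nj_tree(d)
    expect_lt(max(abs(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)] - d)), 1e-9)
  }

  expect_error(nj_tree(matrix(c(0, 1, 2, 0, 0, 1, 0, 0, 0), 3)), "symmetric")
  # negative branch lengths are clamped to zero
  dneg <- matrix(c(0, 5, 9, 9, 5, 0, 10, 10, 9, 10, 0, 8, 9, 10, 8, 0), 4,
                 dimnames = list(letters[1:4], letters[1:4]))
  expect_true(all(nj_tree(dneg)$edge.length >= 0))
})

test_that("center-star MSA produces consistent gapped rows", {
  seqs <- c(a = "DYMNMST", b = "DYMNM", c = "DYMNMSTQQ")
  msa <- center_star_msa(seqs)
  expect_length(unique(nchar(msa)), 1)
  for (nm in names(seqs)) expect_equal(gsub("-", "", msa[[nm]]), seqs[[nm]])
})

test_that("bootstrap supports are seeded, order-invariant and sensible", {
  set.seed(55)
  mk_group <- function(base, n, tag) {
    out <- character(n)
    for (i in seq_len(n)) {
      s <- strsplit(base, "")[[1]]
      mut <- sample(length(s), 2)
      s[mut] <- sample(cd28family:::AA20, 2, replace = TRUE)
      out[i] <- paste(s, collapse = "")
    }
    stats::setNames(out, paste0(tag, seq_len(n)))
  }
  baseA <- random_protein(120); baseB <- random_protein(120)
  aln <- c(mk_group(baseA, 4, "A"), mk_group(baseB, 4, "B"))

  bs <- bootstrap_support(aln, n_reps = 100, seed = 9)
  # the A-vs-B split is in the tree with near-total support
  support_for <- function(bs, tips) {
    tr <- bs$tree
    ntip <- length(tr$tip.label)
    for (node in (ntip + 1):(ntip + tr$Nnode)) {
      desc <- ape::extract.clade(tr, node)$tip.label
      if (setequal(desc, tips) || setequal(desc, setdiff(tr$tip.label, tips)))
        return(bs$support[node - ntip])
    }
    NA_real_
  }
  sup <- support_for(bs, paste0("A", 1:4))
  expect_gte(sup, 95)

  # determinism under seed
  bs2 <- bootstrap_support(aln, n_reps = 100, seed = 9)
  expect_equal(bs$support, bs2$support)
  # taxon-order invariance
  bs3 <- bootstrap_support(aln[sample(length(aln))], n_reps = 100, seed = 9)
  expect_equal(support_for(bs3, paste0("A", 1:4)), sup)

  # single replicate: supports are 0 or 100
  bs1 <- bootstrap_support(aln, n_reps = 1, seed = 2)
  expect_true(all(bs1$support %in% c(0, 100)))

  # saturated pairs are capped with a warning
  sat <- c(x = "AAAAAAAAAA", y = "CCCCCCCCCC", z = "DDDDDDDDDD")
  expect_warning(poisson_distance(sat), "capped")
})

test_that("clade membership agrees with bipartition enumeration", {
  tt <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1,(e:1,f:1):1);")
  expect_true(clade_membership(tt, "a", "b"))
  expect_false(clade_membership(tt, "a", c("c", "d")))
  expect_true(clade_membership(tt, "a", c("b", "c", "d")))
  expect_error(clade_membership(tt, "zz", "a"), "not in tree")

  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1,e:1);")
  expect_false(clade_membership(star, "a", "b"))
  expect_false(clade_membership(star, "a", c("b", "c")))

  set.seed(21)
  for (i in 1:20) {
    tr <- ape::unroot(ape::rtree(10))
    tips <- tr$tip.label
    cand <- sample(tips, 1)
    refs <- sample(setdiff(tips, cand), sample(2:5, 1))
    expect_equal(clade_membership(tr, cand, refs),
                 brute_clade(tr, cand, refs),
                 info = paste(cand, paste(refs, collapse = ",")))
  }
})
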