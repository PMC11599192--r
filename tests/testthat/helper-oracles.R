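# Independent oracles used by the tests: brute-force implementations that
# share no code path with the package's engines.

# --- brute-force motif matcher -------------------------------------------
# Enumerates every (start, per-element length assignment) combination and
# checks the match linearly. Only for patterns without unbounded spacers.
brute_scan <- function(sequence, pattern) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(all(vapply(pattern$elements, function(e) is.finite(e$max_len), logical(1))))
  chars <- strsplit(sequence, "")[[1]]
  L <- length(chars)
  els <- pattern$elements
  len_choices <- lapply(els, function(e) e$min_len:e$max_len)
  grid <- expand.grid(len_choices)
  hits <- list()
  for (s in seq_len(max(L, 0L))) {
    for (g in seq_len(nrow(grid))) {
      lens <- as.integer(grid[g, ])
      total <- sum(lens)
      if (s + total - 1L > L) next
      pos <- s
      ok <- TRUE
      for (k in seq_along(els)) {
        e <- els[[k]]
        if (e$kind %in% c("FIXED", "CLASS")) {
          if (!(chars[pos] %in% e$residues)) { ok <- FALSE; break }
        }
        # WILDCARD/GAP accept anything including X
        pos <- pos + lens[k]
      }
      if (ok) hits[[length(hits) + 1L]] <- c(s, s + total - 1L)
    }
  }
  if (!length(hits)) return(data.frame(start = integer(), end = integer()))
  m <- unique(do.call(rbind, hits))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  data.frame(start = m[, 1], end = m[, 2])
}

# random bounded pattern for property tests
random_pattern <- function() {
  n_el <- sample(2:5, 1)
  toks <- character(n_el)
  for (i in seq_len(n_el)) {
    kind <- sample(c("fixed", "class", "wild", "gap"), 1,
                   prob = c(0.4, 0.25, 0.2, 0.15))
    toks[i] <- switch(kind,
      fixed = sample(cd28family:::AA20, 1),
      class = paste0("[", paste(sample(cd28family:::AA20, sample(2:4, 1)),
                                collapse = "/"), "]"),
      wild = if (runif(1) < 0.5) "x" else sprintf("x_%d", sample(1:3, 1)),
      gap = { lo <- sample(0:2, 1); sprintf("x_%d/%d", lo, lo + sample(1:3, 1)) })
  }
  paste(toks, collapse = "-")
}

random_protein <- function(len, with_x = FALSE) {
  alpha <- cd28family:::AA20
  if (with_x) alpha <- c(alpha, "X")
  paste(sample(alpha, len, replace = TRUE), collapse = "")
}

# --- exhaustive global-alignment enumeration ------------------------------
# Enumerates every monotone alignment path (diagonal / gap-in-b / gap-in-a)
# and scores it with affine gaps: a gap of length L costs
# gap_open + (L - 1) * gap_extend. Returns the optimal score.
brute_align_score <- function(a, b, submat, gap_open = -11, gap_extend = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  na <- length(ca); nb <- length(cb)
  best <- -Inf
  rec <- function(i, j, score, state) {
    if (i > na && j > nb) { best <<- max(best, score); return(invisible()) }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, score + submat[ca[i], cb[j]], "m")
    if (i <= na)  # a residue against gap in b
      rec(i + 1L, j, score + if (state == "ga") gap_extend else gap_open, "ga")
    if (j <= nb)
      rec(i, j + 1L, score + if (state == "gb") gap_extend else gap_open, "gb")
  }
  rec(1L, 1L, 0, "m")
  best
}

# --- bipartition-enumeration clade oracle ---------------------------------
# Removes every edge of the unrooted tree in turn (graph traversal, no ape
# clade machinery) and applies the definition: the candidate lies with a
# subset of the references on one side of some edge splitting >= 2 tips
# from >= 2 tips.
brute_clade <- function(tree, candidate, references) {
  tr <- ape::unroot(tree)
  edges <- tr$edge
  ntip <- length(tr$tip.label)
  target <- c(candidate, references)
  adj <- split(c(edges[, 2], edges[, 1]),
               c(seq_len(nrow(edges)), seq_len(nrow(edges))))
  for (e in seq_len(nrow(edges))) {
    # BFS from edges[e,2] avoiding edge e
    seen <- edges[e, 2]
    queue <- seen
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- c(edges[edges[, 1] == v & seq_len(nrow(edges)) != e, 2],
              edges[edges[, 2] == v & seq_len(nrow(edges)) != e, 1])
      new <- setdiff(nb, seen)
      seen <- c(seen, new); queue <- c(queue, new)
    }
    side <- tr$tip.label[seen[seen <= ntip]]
    other <- setdiff(tr$tip.label, side)
    if (length(side) < 2L || length(other) < 2L) next
    if (candidate %in% side && all(side %in% target)) return(TRUE)
    if (candidate %in% other && all(other %in% target)) return(TRUE)
  }
  FALSE
}

# --- shared fixtures -------------------------------------------------------
FAMILY_GENE <- c(CD28 = "cd28", CTLA4 = "ctla4", ICOS = "icos",
                 CD28_CTLA4_CO_ORTHOLOG = "ctla4", CD28H = "cd28h",
                 CD28HL1 = "cd28hl1", CD28HL2 = "cd28hl2",
                 CD28HL3 = "cd28hl3", CD28X = "cd28x", PD1 = "pd1")

# planted-layout region intervals (mirrors the generator's fixed layout,
# independent of the architecture module)
truth_region_intervals <- function() {
  list(CDR3_NEIGHBORHOOD = c(101L, 136L),
       G_STRAND = c(104L, 118L),
       E_STRAND = c(71L, 91L),
       TM = c(127L, 147L),
       CYTOPLASMIC = c(148L, 190L),
       CTERM = c(179L, 190L))
}

make_toy_table <- function(genes, chromosome = "chr1", species = "toy") {
  n <- length(genes)
  starts <- seq_len(n) * 1000
  gene_order_table(species, chromosome,
                   data.frame(gene = genes, start = starts, end = starts + 500,
                              strand = rep(c("+", "-"), length.out = n),
                              stringsAsFactors = FALSE))
}
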