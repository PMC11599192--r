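# Clustering support layer: pairwise global alignment and percent-identity
# matrices, neighbor-joining on Poisson-corrected distances with bootstrap
# support, and clade-membership tests on unrooted topologies. NJ with
# corrected distances is the package's documented, reproducible stand-in
# for likelihood-based tree inference.

POISSON_DISTANCE_CAP <- 10.0

#' Affine-gap global (Needleman-Wunsch) alignment of two proteins
#'
#' @param a,b amino-acid strings.
#' @param substitution_matrix name of a substitution matrix shipped with
#'   Biostrings (default "BLOSUM62") or a numeric matrix.
#' @param gap_open,gap_extend gap penalties, conventionally negative, with
#'   \code{gap_open <= gap_extend <= 0}; a gap of length L costs
#'   \code{gap_open + (L - 1) * gap_extend}.
#' @return list with \code{aligned_a}, \code{aligned_b} (equal-length gapped
#'   strings), \code{score}, and \code{percent_identity} (matches over
#'   aligned columns, terminal-gap columns excluded).
#' @examples
#' align_global("PPP", "PAP")$percent_identity  # 66.67
#' @export
align_global <- function(a, b, substitution_matrix = "BLOSUM62",
                         gap_open = -11, gap_extend = -1) {
  stopifnot(nzchar(a), nzchar(b), gap_open <= gap_extend, gap_extend <= 0)
  validate_protein_string(a); validate_protein_string(b)
  # Biostrings charges gapOpening + L * gapExtension for a gap of length L
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = substitution_matrix,
    gapOpening = abs(gap_open) - abs(gap_extend),
    gapExtension = abs(gap_extend))
  al_a <- as.character(Biostrings::alignedPattern(pa))
  al_b <- as.character(Biostrings::alignedSubject(pa))
  list(aligned_a = al_a, aligned_b = al_b,
       score = Biostrings::score(pa),
       percent_identity = percent_identity(al_a, al_b))
}

#' Percent identity of two gapped, equal-length aligned strings
#'
#' Matches over aligned columns; columns inside terminal gap runs of either
#' sequence are excluded.
#' @param al_a,al_b aligned strings of equal length.
#' @return numeric in [0, 100].
#' @export
percent_identity <- function(al_a, al_b) {
  ca <- strsplit(al_a, "")[[1]]; cb <- strsplit(al_b, "")[[1]]
  stopifnot(length(ca) == length(cb))
  n <- length(ca)
  core <- function(x) {
    ng <- which(x != "-")
    if (!length(ng)) return(rep(FALSE, n))
    seq_len(n) >= ng[1] & seq_len(n) <= ng[length(ng)]
  }
  keep <- core(ca) & core(cb)
  if (!any(keep)) return(0)
  100 * sum(ca[keep] == cb[keep]) / sum(keep)
}

#' Pairwise percent-identity matrix
#'
#' @param sequences named character vector (or list of
#'   \code{protein_record}s) of at least two sequences.
#' @param ... passed to \code{\link{align_global}}.
#' @return symmetric numeric matrix with 100 on the diagonal.
#' @export
similarity_matrix <- function(sequences, ...) {
  if (is.list(sequences) && all(vapply(sequences, inherits, logical(1), "protein_record"))) {
    nm <- vapply(sequences, `[[`, character(1), "id")
    sequences <- stats::setNames(vapply(sequences, `[[`, character(1), "sequence"), nm)
  }
  stopifnot(length(sequences) >= 2L)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  n <- length(sequences)
  m <- matrix(100, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      pid <- align_global(sequences[[i]], sequences[[j]], ...)$percent_identity
      m[i, j] <- pid; m[j, i] <- pid
    }
  }
  m
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Canonical NJ agglomeration (exact on additive distance matrices). Any
#' negative branch length is clamped to zero with the deficit transferred
#' to its sibling edge, preserving path lengths through the parent node.
#'
#' @param d symmetric numeric matrix with zero diagonal and row/column
#'   labels, at least 3 taxa.
#' @return an \pkg{ape} \code{phylo} tree with branch lengths.
#' @export
nj_tree <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  stopifnot(is.matrix(d), nrow(d) >= 3L, nrow(d) == ncol(d))
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric", call. = FALSE)
  if (any(!is.finite(d))) stop("distance matrix has non-finite entries", call. = FALSE)
  if (is.null(rownames(d))) rownames(d) <- colnames(d) <- sprintf("t%d", seq_len(nrow(d)))
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    parent <- tr$edge[e, 1]
    sibs <- setdiff(which(tr$edge[, 1] == parent), e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + tr$edge.length[e]
    }
    tr$edge.length[e] <- 0
  }
  tr
}

#' Poisson-corrected distance matrix from a multiple alignment
#'
#' Per pair, the mismatch fraction p over shared non-gap columns gives
#' d = -ln(1 - p). Pairs with p = 1 (or no shared columns) are set to a
#' cap of 10 with a warning.
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @return symmetric distance matrix.
#' @export
poisson_distance <- function(alignment) {
  rows <- do.call(rbind, strsplit(alignment, ""))
  n <- nrow(rows)
  d <- matrix(0, n, n, dimnames = list(names(alignment), names(alignment)))
  capped <- FALSE
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- rows[i, ] != "-" & rows[j, ] != "-"
      if (!any(shared)) { d[i, j] <- d[j, i] <- POISSON_DISTANCE_CAP; capped <- TRUE; next }
      p <- mean(rows[i, shared] != rows[j, shared])
      if (p >= 1) { d[i, j] <- d[j, i] <- POISSON_DISTANCE_CAP; capped <- TRUE; next }
      d[i, j] <- d[j, i] <- -log(1 - p)
    }
  }
  if (capped)
    warning("saturated pair(s): Poisson distance capped at ", POISSON_DISTANCE_CAP)
  d
}

#' Center-star progressive multiple alignment
#'
#' Picks the sequence with the highest total pairwise alignment score as
#' the center and merges all center-pairwise alignments under
#' "once a gap, always a gap". A deliberate simplification of full
#' progressive aligners, adequate at the scale used here.
#'
#' @param sequences named character vector of at least 2 sequences.
#' @param ... passed to \code{\link{align_global}}.
#' @return named character vector of equal-length gapped rows (input order).
#' @export
center_star_msa <- function(sequences, ...) {
  stopifnot(length(sequences) >= 2L)
  if (is.null(names(sequences)))
    names(sequences) <- sprintf("seq%d", seq_along(sequences))
  n <- length(sequences)
  if (n == 2L) {
    al <- align_global(sequences[[1]], sequences[[2]], ...)
    return(stats::setNames(c(al$aligned_a, al$aligned_b), names(sequences)))
  }
  score_sum <- numeric(n)
  pair_al <- vector("list", n)
  for (i in seq_len(n)) pair_al[[i]] <- vector("list", n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      al <- align_global(sequences[[i]], sequences[[j]], ...)
      score_sum[i] <- score_sum[i] + al$score
      score_sum[j] <- score_sum[j] + al$score
      pair_al[[i]][[j]] <- al
    }
  }
  ctr <- which.max(score_sum)

  # master gapping of the center; insert_counts[k] = gaps after center
  # residue k (k = 0 .. nchar(center))
  ctr_len <- nchar(sequences[[ctr]])
  inserts <- integer(ctr_len + 1L)
  aligned_pairs <- list()
  for (j in setdiff(seq_len(n), ctr)) {
    al <- if (ctr < j) pair_al[[ctr]][[j]] else {
      x <- pair_al[[j]][[ctr]]
      list(aligned_a = x$aligned_b, aligned_b = x$aligned_a)
    }
    aligned_pairs[[as.character(j)]] <- al
    # count gap runs in the center row after each center residue
    cc <- strsplit(al$aligned_a, "")[[1]]
    k <- 0L; run <- 0L
    for (ch in cc) {
      if (ch == "-") run <- run + 1L
      else {
        if (run > inserts[k + 1L]) inserts[k + 1L] <- run
        run <- 0L; k <- k + 1L
      }
    }
    if (run > inserts[k + 1L]) inserts[k + 1L] <- run
  }

  expand_row <- function(center_row, other_row) {
    cc <- strsplit(center_row, "")[[1]]
    oo <- strsplit(other_row, "")[[1]]
    out <- character()
    k <- 0L; i <- 1L
    while (k <= ctr_len) {
      # gaps in this pair's center row at slot k
      g <- 0L
      while (i <= length(cc) && cc[i] == "-") { out <- c(out, oo[i]); g <- g + 1L; i <- i + 1L }
      if (g < inserts[k + 1L]) out <- c(out, rep("-", inserts[k + 1L] - g))
      if (k < ctr_len) { out <- c(out, oo[i]); i <- i + 1L }
      k <- k + 1L
    }
    paste(out, collapse = "")
  }

  total_len <- ctr_len + sum(inserts)
  out <- character(n)
  ctr_plain <- strsplit(sequences[[ctr]], "")[[1]]
  ctr_row <- character()
  for (k in 0:ctr_len) {
    ctr_row <- c(ctr_row, rep("-", inserts[k + 1L]))
    if (k < ctr_len) ctr_row <- c(ctr_row, ctr_plain[k + 1L])
  }
  out[ctr] <- paste(ctr_row, collapse = "")
  for (j in setdiff(seq_len(n), ctr)) {
    al <- aligned_pairs[[as.character(j)]]
    out[j] <- expand_row(al$aligned_a, al$aligned_b)
  }
  stopifnot(all(nchar(out) == total_len))
  stats::setNames(out, names(sequences))
}

#' Neighbor-joining bootstrap on alignment columns
#'
#' Builds the NJ tree from Poisson-corrected distances on the full
#' alignment, then resamples columns with replacement \code{n_reps} times
#' (the resampling stream depends only on the seed and the column count,
#' so supports are invariant to taxon order) and reports, for each internal
#' edge of the original tree, the percentage of replicate trees containing
#' its bipartition.
#'
#' @param alignment named character vector of equal-length gapped rows.
#' @param n_reps number of bootstrap replicates (>= 1).
#' @param seed integer seed.
#' @return list with \code{tree} (original NJ \code{phylo}, node labels set
#'   to supports), \code{support} (per internal node, percentage 0-100) and
#'   \code{n_reps}.
#' @export
bootstrap_support <- function(alignment, n_reps = 100L, seed = 1L) {
  stopifnot(length(alignment) >= 3L, n_reps >= 1L)
  lens <- nchar(alignment)
  stopifnot(length(unique(lens)) == 1L)
  # canonical taxon order: sorted labels (restored in the returned tree)
  alignment <- alignment[order(names(alignment))]
  rows <- do.call(rbind, strsplit(alignment, ""))
  rownames(rows) <- names(alignment)
  ncol_aln <- ncol(rows)

  to_aln <- function(m) stats::setNames(apply(m, 1, paste, collapse = ""), rownames(m))
  main_tree <- nj_tree(suppressWarnings(poisson_distance(to_aln(rows))))

  set.seed(seed)
  rep_trees <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    cols <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    rep_trees[[r]] <- nj_tree(suppressWarnings(poisson_distance(to_aln(rows[, cols, drop = FALSE]))))
  }
  class(rep_trees) <- "multiPhylo"

  counts <- ape::prop.clades(main_tree, rep_trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- 100 * counts / n_reps
  main_tree$node.label <- support
  list(tree = main_tree, support = support, n_reps = n_reps)
}

tree_bipartitions <- function(tree) {
  # internal-edge bipartitions of an unrooted tree, as tip-label sets
  # (side not containing the first tip), |side| in [2, n-2]
  tr <- ape::unroot(tree)
  n <- length(tr$tip.label)
  bp <- ape::prop.part(tr)
  out <- list()
  for (cl in bp) {
    if (length(cl) < 2L || length(cl) > n - 2L) next
    side <- tr$tip.label[cl]
    out[[length(out) + 1L]] <- side
  }
  unique(out)
}

#' Does a candidate cluster inside a reference clade?
#'
#' TRUE iff some internal edge of the unrooted topology separates the
#' candidate together with (a subset of) the reference taxa from all other
#' leaves -- i.e. the candidate joins the references without intervening
#' outsiders. A star tree returns FALSE for any proper subset.
#'
#' @param tree a \code{phylo} object.
#' @param candidate_label one tip label.
#' @param reference_labels tip labels of the reference group.
#' @return logical.
#' @export
clade_membership <- function(tree, candidate_label, reference_labels) {
  tips <- tree$tip.label
  missing <- setdiff(c(candidate_label, reference_labels), tips)
  if (length(missing))
    stop("label(s) not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  target <- c(candidate_label, reference_labels)
  for (side in tree_bipartitions(tree)) {
    other <- setdiff(tips, side)
    if (candidate_label %in% side && all(side %in% target)) return(TRUE)
    if (candidate_label %in% other && all(other %in% target)) return(TRUE)
  }
  FALSE
}
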