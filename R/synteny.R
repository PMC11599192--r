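# Conserved-synteny evidence: marker support around a candidate gene,
# detection of consecutive-gene cassettes, and counting of WGD-derived
# paralogous marker regions on gene-order tables.

#' Construct a gene-order table
#'
#' @param species species label.
#' @param chromosome chromosome / linkage-group name.
#' @param genes data.frame with columns \code{gene}, \code{start},
#'   \code{end}, \code{strand}; starts must be strictly increasing,
#'   \code{start <= end}, strand one of \code{+}/\code{-}.
#' @return object of class \code{gene_order_table} (a data.frame with
#'   columns species, chromosome, gene, start, end, strand, in gene order).
#' @export
gene_order_table <- function(species, chromosome, genes) {
  stopifnot(all(c("gene", "start", "end", "strand") %in% names(genes)))
  if (nrow(genes) == 0L) stop("gene-order table is empty", call. = FALSE)
  if (any(!nzchar(genes$gene))) stop("empty gene name", call. = FALSE)
  if (any(genes$start > genes$end))
    stop("gene with start > end: ", genes$gene[which(genes$start > genes$end)[1]],
         call. = FALSE)
  if (is.unsorted(genes$start, strictly = TRUE)) {
    bad <- which(diff(genes$start) <= 0)[1] + 1L
    stop("gene starts not strictly increasing at gene '", genes$gene[bad], "'",
         call. = FALSE)
  }
  if (!all(genes$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'", call. = FALSE)
  out <- data.frame(species = species, chromosome = chromosome,
                    gene = genes$gene, start = as.numeric(genes$start),
                    end = as.numeric(genes$end), strand = genes$strand,
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_order_table", "data.frame")
  out
}

#' Normalize a gene symbol for synteny matching
#'
#' Lower-cases and strips trailing lineage/ohnolog suffixes matching
#' \code{[.-][0-9ab]+$} (e.g. "TACC3", "tacc3.1" and "tacc3-b" all
#' normalize to "tacc3").
#'
#' @param x character vector of gene symbols.
#' @return normalized character vector.
#' @export
normalize_gene_symbol <- function(x) {
  sub("[.-][0-9ab]+$", "", tolower(x))
}

#' Conserved-synteny marker support around a candidate gene
#'
#' Intersects a marker set with the names of the k genes on each side of
#' the candidate (window measured in gene ranks, not base pairs; matching
#' is case-insensitive and suffix-tolerant, orientation- and
#' strand-insensitive).
#'
#' @param table a \code{gene_order_table}.
#' @param candidate_gene gene name present in the table.
#' @param marker_set character vector of marker symbols.
#' @param k window half-width in genes (default 10).
#' @return object of class \code{synteny_hit}: \code{candidate_gene},
#'   \code{shared_markers}, \code{shared_count}, \code{window_interval}
#'   (gene-rank interval searched).
#' @export
marker_support <- function(table, candidate_gene, marker_set, k = 10L) {
  stopifnot(inherits(table, "gene_order_table"), k >= 1L)
  norm <- normalize_gene_symbol(table$gene)
  pos <- which(norm == normalize_gene_symbol(candidate_gene))
  if (!length(pos))
    stop("candidate gene '", candidate_gene, "' not found in table", call. = FALSE)
  pos <- pos[1]
  lo <- max(1L, pos - k); hi <- min(nrow(table), pos + k)
  neighbors <- norm[setdiff(lo:hi, pos)]
  mk <- normalize_gene_symbol(marker_set)
  shared <- unique(mk[mk %in% neighbors])
  structure(list(candidate_gene = candidate_gene,
                 shared_markers = shared,
                 shared_count = length(shared),
                 window_interval = c(lo, hi)),
            class = "synteny_hit")
}

#' Detect cassettes of consecutive family genes
#'
#' Finds maximal runs of family genes separated by at most \code{max_gap}
#' interleaving non-family genes. Runs of a single gene are not reported
#' (a cassette has size >= 2). Each reported cassette carries the
#' non-family genes immediately flanking the run.
#'
#' @param table a \code{gene_order_table}.
#' @param family_gene_names character vector of family gene names.
#' @param max_gap maximum interleaving non-family genes inside a run
#'   (default 1, since curated marker tables omit unconserved genes).
#' @return list of \code{cassette_call} objects (\code{member_genes},
#'   \code{size}, \code{flanking_markers}, \code{rank_interval}), sorted
#'   by position; genes never appear in two calls.
#' @export
detect_cassette <- function(table, family_gene_names, max_gap = 1L) {
  stopifnot(inherits(table, "gene_order_table"), max_gap >= 0L)
  norm <- normalize_gene_symbol(table$gene)
  fam <- normalize_gene_symbol(family_gene_names)
  idx <- which(norm %in% fam)
  if (!length(idx)) return(list())
  runs <- split(idx, cumsum(c(1L, diff(idx) - 1L > max_gap)))
  calls <- list()
  for (r in runs) {
    if (length(r) < 2L) next
    lo <- r[1]; hi <- r[length(r)]
    flanks <- c(if (lo > 1L) table$gene[lo - 1L],
                if (hi < nrow(table)) table$gene[hi + 1L])
    calls[[length(calls) + 1L]] <- structure(list(
      member_genes = table$gene[r],
      size = length(r),
      flanking_markers = flanks %||% character(),
      rank_interval = c(lo, hi),
      chromosome = table$chromosome[1]
    ), class = "cassette_call")
  }
  calls
}

#' Count paralogous conserved-synteny regions across chromosomes
#'
#' Counts, over a set of gene-order tables from one species, the distinct
#' regions whose intersection with a marker set reaches \code{min_shared}
#' distinct markers. At most one region is counted per chromosome unless
#' two marker clusters on the same chromosome are separated by more than
#' \code{max_rank_gap} genes. This is the quantity used to count block
#' copies retained after whole-genome duplications.
#'
#' @param tables list of \code{gene_order_table} objects.
#' @param marker_set character vector of marker symbols for the block.
#' @param min_shared minimum distinct markers per region (default 2).
#' @param max_rank_gap rank separation splitting two regions on one
#'   chromosome (default 50).
#' @return integer count of paralogous regions.
#' @export
count_paralogous_regions <- function(tables, marker_set, min_shared = 2L,
                                     max_rank_gap = 50L) {
  if (inherits(tables, "gene_order_table")) tables <- list(tables)
  stopifnot(min_shared >= 2L)
  mk <- normalize_gene_symbol(marker_set)
  total <- 0L
  for (tb in tables) {
    stopifnot(inherits(tb, "gene_order_table"))
    norm <- normalize_gene_symbol(tb$gene)
    idx <- which(norm %in% mk)
    if (!length(idx)) next
    clusters <- split(idx, cumsum(c(1L, diff(idx) > max_rank_gap)))
    for (cl in clusters) {
      if (length(unique(norm[cl])) >= min_shared) total <- total + 1L
    }
  }
  total
}

#' @export
print.synteny_hit <- function(x, ...) {
  cat(sprintf("<synteny_hit> %s: %d shared marker(s) [%s] in ranks %d..%d\n",
              x$candidate_gene, x$shared_count,
              paste(x$shared_markers, collapse = ","),
              x$window_interval[1], x$window_interval[2]))
  invisible(x)
}

#' @export
print.cassette_call <- function(x, ...) {
  cat(sprintf("<cassette_call> %s: %s (size %d), flanked by %s\n",
              x$chromosome, paste(x$member_genes, collapse = "-"), x$size,
              paste(x$flanking_markers, collapse = ",")))
  invisible(x)
}
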