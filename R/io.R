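# Readers and writers: FASTA protein records, gene-order tables (TSV and
# BED dialects), TSV reports for matches / assignments / synteny hits /
# similarity matrices, and Newick trees. TSV coordinates are 1-based
# inclusive; BED follows its own 0-based half-open standard, converted
# centrally here.

#' Read protein records from a FASTA file
#'
#' @param path FASTA file (LF or CRLF). The record id is the header up to
#'   the first whitespace.
#' @return list of \code{\link{protein_record}} objects.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readAAStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[[`, character(1), 1L)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  mapply(function(id, s) protein_record(id, s),
         ids, as.character(ss), SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Write protein records to FASTA (60-column wrapping)
#' @param records list of \code{protein_record}s (or named character vector).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    seqs <- records
  } else {
    seqs <- stats::setNames(vapply(records, `[[`, character(1), "sequence"),
                            vapply(records, `[[`, character(1), "id"))
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a gene-order table from TSV or BED
#'
#' TSV dialect: header line with columns species, chromosome, gene, start,
#' end, strand; 1-based inclusive coordinates. BED dialect: 6 columns
#' (chrom, start, end, name, score, strand), no header, 0-based half-open;
#' converted to 1-based inclusive on read.
#'
#' @param path input file.
#' @param format "tsv", "bed", or "auto" (by file extension, default tsv).
#' @param species species label for BED input (BED has no species column).
#' @return a \code{\link{gene_order_table}}.
#' @export
read_gene_table <- function(path, format = c("auto", "tsv", "bed"),
                            species = "unknown") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "tsv"
  if (format == "bed") {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6L) stop("BED file needs 6 columns: ", path, call. = FALSE)
    names(df)[1:6] <- c("chromosome", "start", "end", "gene", "score", "strand")
    df$start <- df$start + 1L  # 0-based half-open -> 1-based inclusive
    chrom <- unique(df$chromosome)
  } else {
    df <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
    need <- c("species", "chromosome", "gene", "start", "end", "strand")
    if (!all(need %in% names(df)))
      stop("TSV gene table needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    species <- df$species[1]
    chrom <- unique(df$chromosome)
  }
  if (length(chrom) != 1L)
    stop("gene table must hold a single chromosome; found: ",
         paste(chrom, collapse = ", "), call. = FALSE)
  if (is.unsorted(df$start, strictly = TRUE)) {
    bad <- which(diff(df$start) <= 0)[1] + 1L
    stop("unsorted coordinates at line ", bad, " (gene '", df$gene[bad], "')",
         call. = FALSE)
  }
  gene_order_table(species, chrom,
                   df[, c("gene", "start", "end", "strand")])
}

#' Write a gene-order table as TSV
#' @param table a \code{gene_order_table}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_gene_table <- function(table, path) {
  stopifnot(inherits(table, "gene_order_table"))
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write motif matches as TSV
#' @param matches data.frame from \code{\link{scan_motif}} with an added
#'   \code{sequence_id} column (or a list of such frames).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_matches_tsv <- function(matches, path) {
  if (is.list(matches) && !is.data.frame(matches))
    matches <- do.call(rbind, matches)
  cols <- c("sequence_id", "pattern_name", "start", "end", "matched_span")
  utils::write.table(matches[, intersect(cols, names(matches))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Flatten family assignments to a data.frame
#' @param assignments list of \code{family_assignment} objects.
#' @return data.frame with one row per assignment.
#' @export
assignments_table <- function(assignments) {
  if (inherits(assignments, "family_assignment")) assignments <- list(assignments)
  do.call(rbind, lapply(assignments, function(a) {
    data.frame(id = a$id, label = a$label, score = a$score,
               runner_up_label = a$runner_up_label,
               runner_up_score = a$runner_up_score,
               architecture_pass = a$architecture_pass,
               cassette_position = a$cassette_position %||% NA_integer_,
               stringsAsFactors = FALSE)
  }))
}

#' Write family assignments as TSV with a config echo
#' @param assignments list of \code{family_assignment}s.
#' @param path output path.
#' @param params optional named list echoed as \code{# key=value} comment
#'   lines (seed, thresholds, catalog version, ...).
#' @return \code{path}, invisibly.
#' @export
write_assignments_tsv <- function(assignments, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params))
    writeLines(sprintf("# %s=%s", names(params),
                       vapply(params, as.character, character(1))), con)
  df <- assignments_table(assignments)
  writeLines(paste(names(df), collapse = "\t"), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an assignments TSV back (comment lines skipped)
#' @param path file written by \code{\link{write_assignments_tsv}}.
#' @return data.frame as from \code{\link{assignments_table}}.
#' @export
read_assignments_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' Write a (supported) tree in Newick format
#' @param tree a \code{phylo} object, or the list from
#'   \code{\link{bootstrap_support}} (supports become internal node labels).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo") && !is.null(tree$tree))
    tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}
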