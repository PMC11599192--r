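# Evidence combination: score a protein against each family profile
# (motifs in their structural regions, conserved-synteny marker support)
# and emit a family assignment implementing the two-criterion acceptance
# rule: (1) IgV-TM-cytoplasmic architecture with conserved motifs, and
# (2) location in a region with conserved synteny markers when genomic
# context is available. Chondrichthyan-style hybrids of the cassette
# families resolve to the CD28/CTLA4 co-ortholog outcome.

REQUIRED_POINTS <- 2L
SUPPORTING_POINTS <- 1L
DEFAULT_SCORE_THRESHOLD <- 4L
DEFAULT_MARGIN <- 2L
CASSETTE_PROFILES <- c("CD28", "CTLA4", "ICOS", "CD28_CTLA4_CO_ORTHOLOG")

#' Score one protein against one family profile
#'
#' Motifs are evaluated with \code{\link{scan_motif}} restricted to the
#' region interval derived from the architecture call: REQUIRED motifs
#' matched in their region score 2 points, SUPPORTING motifs 1 point; a
#' missing REQUIRED motif subtracts nothing but is recorded. Synteny adds
#' 2 points when the hit shares at least two markers with the profile and
#' 1 point for exactly one. When the IgV domain is divergent (no framework
#' triple) the IgV-internal regions (CDR3 neighborhood, G and E strands)
#' carry no coordinates and their motifs are reported as unevaluated.
#'
#' @param record a \code{\link{protein_record}}.
#' @param arch the \code{architecture_call} produced from \code{record}.
#' @param profile a \code{family_profile}.
#' @param synteny_hit optional \code{synteny_hit} computed against this
#'   profile's marker set.
#' @return list with \code{score} (integer), \code{evidence} (data.frame
#'   source/detail/region/weight_points) and \code{missing_required}
#'   (character vector of unmatched REQUIRED notations).
#' @export
score_profile <- function(record, arch, profile, synteny_hit = NULL) {
  stopifnot(inherits(record, "protein_record"),
            inherits(arch, "architecture_call"),
            inherits(profile, "family_profile"))
  regions <- region_intervals(arch)
  score <- 0L
  ev <- list()
  missing_required <- character()

  for (m in profile$motifs) {
    iv <- regions[[m$region]]
    if (is.null(iv)) {
      if (m$weight == "REQUIRED") missing_required <- c(missing_required, m$notation)
      next
    }
    hits <- scan_motif(record$sequence, m$pattern, window = iv)
    if (nrow(hits) > 0L) {
      pts <- if (m$weight == "REQUIRED") REQUIRED_POINTS else SUPPORTING_POINTS
      score <- score + pts
      ev[[length(ev) + 1L]] <- data.frame(
        source = "MOTIF", detail = m$notation, region = m$region,
        weight_points = pts, stringsAsFactors = FALSE)
    } else if (m$weight == "REQUIRED") {
      missing_required <- c(missing_required, m$notation)
    }
  }

  if (!is.null(synteny_hit) && synteny_hit$shared_count > 0L) {
    pts <- if (synteny_hit$shared_count >= 2L) 2L else 1L
    score <- score + pts
    ev[[length(ev) + 1L]] <- data.frame(
      source = "SYNTENY",
      detail = paste(synteny_hit$shared_markers, collapse = ","),
      region = NA_character_, weight_points = pts, stringsAsFactors = FALSE)
  }

  evidence <- if (length(ev)) do.call(rbind, ev) else
    data.frame(source = character(), detail = character(),
               region = character(), weight_points = integer(),
               stringsAsFactors = FALSE)
  list(score = score, evidence = evidence, missing_required = missing_required)
}

#' Classify a protein into the CD28 family
#'
#' Runs architecture segmentation, scores every catalog profile and applies
#' the acceptance rule. A canonical label is assigned when the top profile
#' scores at least \code{score_threshold}, leads the runner-up by at least
#' \code{margin}, and -- when genomic context is supplied -- has at least
#' one synteny evidence item (criterion (2); without context the synteny
#' criterion is waived, as for transcript-only evidence). When the top two
#' profiles are cassette families (CD28/CTLA4/ICOS/co-ortholog) separated
#' by less than \code{margin}, the outcome is the unresolved
#' CD28_CTLA4_CO_ORTHOLOG class; any other sub-threshold or sub-margin
#' outcome is UNCLASSIFIED. Ties are broken by catalog order.
#'
#' @param record a \code{\link{protein_record}}.
#' @param genome_context optional \code{gene_order_table} holding the
#'   record's gene.
#' @param gene_name gene name of the record in \code{genome_context}
#'   (required with context; defaults to the record id).
#' @param catalog a \code{family_catalog}.
#' @param score_threshold minimum winning score (default 4).
#' @param margin minimum lead over the runner-up (default 2).
#' @param k synteny window half-width in genes.
#' @param cassette_genes optional gene names to test for a cassette in the
#'   context; if the candidate falls in one, its position is annotated.
#' @return object of class \code{family_assignment}: \code{label},
#'   \code{score}, \code{runner_up_label}, \code{runner_up_score},
#'   \code{evidence} (winning profile), \code{architecture_pass},
#'   \code{all_scores}, and optionally \code{cassette_position}.
#' @export
classify_protein <- function(record, genome_context = NULL, gene_name = NULL,
                             catalog = load_catalog(),
                             score_threshold = DEFAULT_SCORE_THRESHOLD,
                             margin = DEFAULT_MARGIN, k = 10L,
                             cassette_genes = NULL) {
  stopifnot(inherits(record, "protein_record"), inherits(catalog, "family_catalog"))
  if (!is.null(genome_context) && is.null(gene_name)) gene_name <- record$id

  empty_assignment <- function(reason) {
    structure(list(id = record$id, label = "UNCLASSIFIED", score = 0L,
                   runner_up_label = NA_character_, runner_up_score = 0L,
                   evidence = NULL, architecture_pass = FALSE,
                   all_scores = stats::setNames(integer(length(catalog)), names(catalog)),
                   note = reason),
              class = "family_assignment")
  }

  arch <- tryCatch(segment_protein(record), error = function(e) e)
  if (inherits(arch, "error")) return(empty_assignment(conditionMessage(arch)))

  results <- lapply(catalog, function(profile) {
    hit <- NULL
    if (!is.null(genome_context) && length(profile$markers)) {
      hit <- marker_support(genome_context, gene_name, profile$markers, k = k)
    }
    score_profile(record, arch, profile, synteny_hit = hit)
  })
  scores <- vapply(results, `[[`, integer(1), "score")

  # argmax with ties broken by catalog order
  ord <- order(-scores, seq_along(scores))
  top <- ord[1]; second <- ord[2]
  top_name <- names(catalog)[top]
  top_score <- scores[top]; runner_score <- scores[second]
  runner_name <- names(catalog)[second]

  architecture_pass <- arch$has_single_igv ||
    isTRUE(catalog[[top_name]]$allow_divergent_igv)

  has_synteny_evidence <- !is.null(results[[top_name]]$evidence) &&
    any(results[[top_name]]$evidence$source == "SYNTENY")

  label <- "UNCLASSIFIED"
  if (architecture_pass && top_score >= score_threshold) {
    if (top_score - runner_score >= margin) {
      if (is.null(genome_context) || has_synteny_evidence) label <- top_name
    } else if (top_name %in% CASSETTE_PROFILES && runner_name %in% CASSETTE_PROFILES) {
      co <- "CD28_CTLA4_CO_ORTHOLOG"
      co_syn_ok <- is.null(genome_context) ||
        any(results[[co]]$evidence$source == "SYNTENY")
      if (co_syn_ok) label <- co
    }
  }

  out <- structure(list(
    id = record$id, label = label,
    score = top_score,
    runner_up_label = runner_name, runner_up_score = runner_score,
    evidence = results[[if (label %in% names(catalog)) label else top_name]]$evidence,
    missing_required = results[[top_name]]$missing_required,
    architecture_pass = architecture_pass,
    all_scores = scores,
    note = NULL
  ), class = "family_assignment")

  if (!is.null(genome_context) && !is.null(cassette_genes) &&
      label %in% CASSETTE_PROFILES) {
    calls <- detect_cassette(genome_context, cassette_genes)
    gn <- normalize_gene_symbol(gene_name)
    for (cc in calls) {
      pos <- match(gn, normalize_gene_symbol(cc$member_genes))
      if (!is.na(pos)) out$cassette_position <- pos
    }
  }
  out
}

#' @export
print.family_assignment <- function(x, ...) {
  cat(sprintf("<family_assignment> %s -> %s (score %d; runner-up %s, %d)%s\n",
              x$id, x$label, x$score, x$runner_up_label, x$runner_up_score,
              if (x$architecture_pass) "" else "  [architecture failed]"))
  if (!is.null(x$cassette_position))
    cat(sprintf("  cassette position: %d\n", x$cassette_position))
  invisible(x)
}
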