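# Synthetic-data generators: single-IgV type-I membrane proteins carrying the
# family-diagnostic motifs at controlled sequence divergence, and gene-order
# tables with the per-family marker neighborhoods subjected to WGD and gene
# loss. Every emitted record comes with a truth entry so downstream stages
# can be tested without genome downloads.

# Scaffold residues are hydrophilic and exclude C, W, Y, P, G, M, L, I, V, F
# so that neither the IgV framework check nor any catalog motif (all of which
# need at least one of those letters) can fire on scaffold by accident.
SCAFFOLD_ALPHA <- c("S", "T", "N", "Q", "D", "E")
LEADER_ALPHA <- c("L", "V", "A", "I", "F")
TM_ALPHA <- c("L", "V", "I")
STALK_ALPHA <- c("G", "S", "T")  # hydropathy-neutral juxtamembrane linker

# planted domain layout (1-based, fixed across families):
# leader 1..18, IgV scaffold 19..118 with framework C41/W59/C106,
# stalk 119..126, TM 127..147, cytoplasmic tail 148..190
SIM_LAYOUT <- list(
  length = 190L,
  leader = c(1L, 18L),
  igv = c(19L, 118L),
  cys1 = 41L, trp = 59L, cys2 = 106L,
  stalk = c(119L, 126L),
  tm = c(127L, 147L),
  cyt = c(148L, 190L)
)

# Canonical exemplar strings per family. Wildcard/class positions are fixed
# (echoing named species sequences, e.g. the human ICOS cytoplasmic YMFM) so
# that a zero-divergence exemplar is always a valid member of its own family
# and never a better match for a sibling profile; per-seed variation comes
# from the random scaffold.
sim_family_plants <- function(family) {
  tmv <- list(str = "YLLLLT", start = 129L, region = "TM")  # dimerization motif
  plants <- switch(family,
    CD28 = list(
      list(str = "PPP", start = 108L, region = "CDR3_NEIGHBORHOOD"),
      tmv,
      list(str = "DYMNM", start = 154L, region = "CYTOPLASMIC")),
    CTLA4 = list(
      list(str = "MYPPPY", start = 107L, region = "CDR3_NEIGHBORHOOD"),
      list(str = "GQG", start = 114L, region = "G_STRAND"),
      list(str = "VNL", start = 79L, region = "E_STRAND"),
      list(str = "YENF", start = 182L, region = "CTERM")),
    ICOS = list(
      list(str = "PAP", start = 108L, region = "CDR3_NEIGHBORHOOD"),
      list(str = "GQG", start = 114L, region = "G_STRAND"),
      tmv,
      list(str = "EYMFM", start = 154L, region = "CYTOPLASMIC")),
    CD28_CTLA4_CO_ORTHOLOG = list(
      list(str = "PLP", start = 108L, region = "CDR3_NEIGHBORHOOD"),
      list(str = "GQG", start = 114L, region = "G_STRAND"),
      tmv,
      list(str = "EYSNM", start = 154L, region = "CYTOPLASMIC")),
    CD28H = list(
      list(str = "EIPPP", start = 108L, region = "CDR3_NEIGHBORHOOD"),
      list(str = "YENV", start = 154L, region = "CYTOPLASMIC")),
    CD28HL1 = list(
      list(str = "YSCEAGTEIP", start = 107L, region = "CDR3_NEIGHBORHOOD"),
      list(str = "YESF", start = 154L, region = "CYTOPLASMIC")),
    CD28HL2 = list(
      list(str = "YSCEAGTEIPAP", start = 107L, region = "CDR3_NEIGHBORHOOD"),
      list(str = "YQNS", start = 182L, region = "CTERM")),
    CD28HL3 = list(
      list(str = "YSCAGTSNIP", start = 107L, region = "CDR3_NEIGHBORHOOD"),
      list(str = "IEYSSL", start = 152L, region = "CYTOPLASMIC"),
      list(str = "VTYSSV", start = 162L, region = "CYTOPLASMIC")),
    CD28X = list(
      list(str = "YSCAGTSNQPPPASTNGQG", start = 107L, region = "CDR3_NEIGHBORHOOD"),
      tmv,
      list(str = "EYEDM", start = 154L, region = "CYTOPLASMIC")),
    PD1 = list(
      list(str = "IEYSSL", start = 152L, region = "CYTOPLASMIC"),
      list(str = "TEYSSV", start = 162L, region = "CYTOPLASMIC")),
    stop("unknown family: ", family, call. = FALSE)
  )
  plants
}

#' Simulate a CD28-family receptor protein with a truth entry
#'
#' Builds a type-I membrane protein with the planted layout: hydrophobic
#' 18-residue leader, IgV scaffold with the framework C/W/C triple at
#' canonical spacings (omitted for PD1, whose bony-fish V domains are
#' divergent), the family's diagnostic motifs inserted into their structural
#' regions, a 21-residue hydrophobic TM (carrying YxxxxT when the family
#' lists it) and a cytoplasmic tail with the family's signaling motifs.
#' Per-site substitutions are then applied at rate \code{divergence},
#' drawing replacements uniformly from the 19 alternatives; a stress
#' parameter, not an evolutionary model. With \code{protect_motifs} the
#' planted motif residues and the structural anchors (framework C/W/C) are
#' exempt, emulating purifying selection on the diagnostic positions.
#'
#' @param family profile name (one of the ten catalog profiles).
#' @param divergence per-site substitution probability in [0, 1).
#' @param protect_motifs exempt planted motif and framework positions.
#' @param seed integer seed; records are reproducible per seed.
#' @return list with \code{record} (a \code{\link{protein_record}}) and
#'   \code{truth} (family, planted region intervals, planted motif table,
#'   protected positions, \code{divergent_igv} flag).
#' @examples
#' sim <- simulate_family_protein("CD28H", divergence = 0, seed = 1)
#' substr(sim$record$sequence, 108, 112)  # "EIPPP"
#' @export
simulate_family_protein <- function(family, divergence = 0, protect_motifs = TRUE,
                                    seed = 1L) {
  if (!family %in% ALL_PROFILES)
    stop("unknown family: ", family, call. = FALSE)
  stopifnot(divergence >= 0, divergence < 1)
  set.seed(seed)
  ly <- SIM_LAYOUT
  chars <- character(ly$length)

  chars[ly$leader[1]:ly$leader[2]] <-
    sample(LEADER_ALPHA, diff(ly$leader) + 1L, replace = TRUE)
  chars[1L] <- "M"
  chars[ly$igv[1]:ly$igv[2]] <-
    sample(SCAFFOLD_ALPHA, diff(ly$igv) + 1L, replace = TRUE)
  chars[ly$stalk[1]:ly$stalk[2]] <-
    sample(STALK_ALPHA, diff(ly$stalk) + 1L, replace = TRUE)
  chars[ly$tm[1]:ly$tm[2]] <-
    sample(TM_ALPHA, diff(ly$tm) + 1L, replace = TRUE)
  chars[ly$cyt[1]:ly$cyt[2]] <-
    sample(SCAFFOLD_ALPHA, diff(ly$cyt) + 1L, replace = TRUE)

  divergent_igv <- identical(family, "PD1")
  framework <- integer()
  if (!divergent_igv) {
    chars[ly$cys1] <- "C"; chars[ly$trp] <- "W"; chars[ly$cys2] <- "C"
    framework <- c(ly$cys1, ly$trp, ly$cys2)
  }
  # structural anchors under purifying selection: the hydrophobic membrane
  # span must stay hydrophobic for the protein to be a type-I membrane
  # protein at all (the leader is dispensable for segmentation and mutates)
  anchors <- c(framework, ly$tm[1]:ly$tm[2])

  plants <- sim_family_plants(family)
  motif_rows <- list()
  protected <- anchors
  for (p in plants) {
    s <- strsplit(p$str, "")[[1]]
    idx <- p$start:(p$start + length(s) - 1L)
    chars[idx] <- s
    protected <- c(protected, idx)
    motif_rows[[length(motif_rows) + 1L]] <-
      data.frame(notation = p$str, region = p$region,
                 start = idx[1], end = idx[length(idx)],
                 stringsAsFactors = FALSE)
  }
  protected <- sort(unique(protected))

  if (divergence > 0) {
    eligible <- seq_len(ly$length)
    if (protect_motifs) eligible <- setdiff(eligible, protected)
    hit <- eligible[stats::runif(length(eligible)) < divergence]
    for (i in hit) chars[i] <- sample(setdiff(AA20, chars[i]), 1L)
  }

  id <- sprintf("%s_sim_seed%d", tolower(family), seed)
  list(
    record = protein_record(id, paste(chars, collapse = "")),
    truth = list(
      family = family,
      regions = ly[c("leader", "igv", "stalk", "tm", "cyt")],
      framework = if (length(framework)) framework else NULL,
      motifs = do.call(rbind, motif_rows),
      protected = protected,
      divergent_igv = divergent_igv,
      seed = seed, divergence = divergence
    )
  )
}

#' Ancestral marker blocks for the family loci
#'
#' One block per locus, taken from the catalog's marker sets: the cassette
#' block carries the three consecutive co-ortholog genes between its
#' markers; every other block carries its single family gene between half
#' of its markers on each side.
#'
#' @param catalog a \code{family_catalog}.
#' @return named list of blocks, each with \code{markers} and
#'   \code{family_genes}.
#' @export
ancestral_blocks <- function(catalog = load_catalog()) {
  cassette_markers <- catalog$CD28$markers
  blocks <- list(
    cassette = list(markers = cassette_markers,
                    family_genes = c("cd28", "ctla4", "icos"))
  )
  for (nm in c("CD28H", "CD28HL1", "CD28HL2", "CD28HL3", "CD28X", "PD1")) {
    blocks[[tolower(nm)]] <- list(markers = catalog[[nm]]$markers,
                                  family_genes = tolower(nm))
  }
  blocks
}

build_chromosome_genes <- function(blocks, filler_between = 12L) {
  genes <- character()
  block_of <- character()
  filler_i <- 0L
  add_filler <- function(n) {
    out <- sprintf("flr%d", filler_i + seq_len(n))
    filler_i <<- filler_i + n
    out
  }
  for (bi in seq_along(blocks)) {
    b <- blocks[[bi]]
    bname <- names(blocks)[bi]
    mk <- b$markers
    half <- ceiling(length(mk) / 2)
    before <- mk[seq_len(half)]
    after <- if (half < length(mk)) mk[(half + 1L):length(mk)] else character()
    bgenes <- c(before, b$family_genes, after)
    genes <- c(genes, bgenes)
    block_of <- c(block_of, rep(bname, length(bgenes)))
    if (bi < length(blocks)) {
      f <- add_filler(filler_between)
      genes <- c(genes, f)
      block_of <- c(block_of, rep(NA_character_, length(f)))
    }
  }
  list(genes = genes, block_of = block_of)
}

#' Simulate a genome as gene-order tables with WGD, loss and rearrangement
#'
#' Constructs one ancestral chromosome from marker blocks (by default the
#' family loci of the built-in catalog, including the three-gene
#' cd28/ctla4/icos cassette), then applies \code{wgd_events} full
#' duplications (each copy becomes a new chromosome), per-gene loss with
#' probability \code{loss_probability}, and random adjacent transpositions
#' at \code{rearrangement_rate} expected events per gene. The truth entry
#' records every gene's ancestral block and the surviving copy count per
#' block (chromosomes retaining at least \code{min_shared} of the block's
#' markers, and at least one family gene).
#'
#' @param blocks named list of blocks (see \code{\link{ancestral_blocks}}).
#' @param wgd_events integer >= 0, number of whole-genome duplications.
#' @param loss_probability per-gene loss probability in [0, 1].
#' @param loss_targets \code{"all"} genes or \code{"family"} genes only.
#' @param loss_chromosomes optional chromosome names to restrict loss to.
#' @param rearrangement_rate expected adjacent swaps per gene.
#' @param min_shared marker count defining a surviving block copy.
#' @param species species label written into the tables.
#' @param seed integer seed.
#' @return list with \code{tables} (list of \code{gene_order_table}) and
#'   \code{truth} (\code{ancestry} data.frame chromosome/gene/block;
#'   \code{surviving_copies} and \code{surviving_family_copies}, named by
#'   block).
#' @export
simulate_genome <- function(blocks = ancestral_blocks(),
                            wgd_events = 0L,
                            loss_probability = 0,
                            loss_targets = c("all", "family"),
                            loss_chromosomes = NULL,
                            rearrangement_rate = 0,
                            min_shared = 2L,
                            species = "synthetica",
                            seed = 1L) {
  loss_targets <- match.arg(loss_targets)
  stopifnot(wgd_events >= 0L, loss_probability >= 0, loss_probability <= 1,
            rearrangement_rate >= 0)
  set.seed(seed)

  anc <- build_chromosome_genes(blocks)
  family_genes <- unlist(lapply(blocks, `[[`, "family_genes"), use.names = FALSE)

  chroms <- list(chr1 = anc$genes)
  for (d in seq_len(wgd_events)) {
    dup <- list()
    for (nm in names(chroms)) {
      dup[[paste0(nm, "a")]] <- chroms[[nm]]
      dup[[paste0(nm, "b")]] <- chroms[[nm]]
    }
    chroms <- dup
  }

  if (loss_probability > 0) {
    for (nm in names(chroms)) {
      if (!is.null(loss_chromosomes) && !nm %in% loss_chromosomes) next
      g <- chroms[[nm]]
      eligible <- if (loss_targets == "family") g %in% family_genes else rep(TRUE, length(g))
      drop <- eligible & stats::runif(length(g)) < loss_probability
      chroms[[nm]] <- g[!drop]
    }
  }

  if (rearrangement_rate > 0) {
    for (nm in names(chroms)) {
      g <- chroms[[nm]]
      n_swap <- stats::rpois(1L, rearrangement_rate * length(g))
      for (s in seq_len(n_swap)) {
        i <- sample.int(length(g) - 1L, 1L)
        g[c(i, i + 1L)] <- g[c(i + 1L, i)]
      }
      chroms[[nm]] <- g
    }
  }

  tables <- lapply(names(chroms), function(nm) {
    g <- chroms[[nm]]
    n <- length(g)
    starts <- seq_len(n) * 10000L
    gene_order_table(
      species = species, chromosome = nm,
      genes = data.frame(gene = g, start = starts, end = starts + 5000L,
                         strand = sample(c("+", "-"), n, replace = TRUE),
                         stringsAsFactors = FALSE))
  })
  names(tables) <- names(chroms)

  ancestry <- do.call(rbind, lapply(names(chroms), function(nm) {
    g <- chroms[[nm]]
    data.frame(chromosome = nm, gene = g,
               block = anc$block_of[match(g, anc$genes)],
               stringsAsFactors = FALSE)
  }))

  surviving <- vapply(names(blocks), function(bn) {
    mk <- blocks[[bn]]$markers
    sum(vapply(chroms, function(g) sum(mk %in% g) >= min_shared, logical(1)))
  }, integer(1))
  surviving_family <- vapply(names(blocks), function(bn) {
    fg <- blocks[[bn]]$family_genes
    sum(vapply(chroms, function(g) any(fg %in% g), logical(1)))
  }, integer(1))

  list(tables = tables,
       truth = list(ancestry = ancestry,
                    surviving_copies = surviving,
                    surviving_family_copies = surviving_family,
                    seed = seed, wgd_events = wgd_events,
                    loss_probability = loss_probability))
}
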