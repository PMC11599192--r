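# Domain architecture: segment a receptor protein into leader / IgV / stalk /
# TM / cytoplasmic regions and check the IgV framework (canonical C23-style
# cysteine pair plus tryptophan). Hydropathy-based TM calling stands in for
# an external domain annotator; thresholds are stated so results are pinned.

# Kyte-Doolittle hydropathy scale; X (ambiguity) scored neutral
KD_SCALE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
              Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
              L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
              S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
              X =  0.0)

TM_WINDOW <- 19L
TM_THRESHOLD <- 1.6
LEADER_THRESHOLD <- 1.0
MIN_TM_LEN <- 15L

#' Kyte-Doolittle hydropathy values for a sequence
#' @param sequence amino-acid string.
#' @return numeric vector, one value per residue.
#' @export
kd_hydropathy <- function(sequence) {
  validate_protein_string(sequence)
  unname(KD_SCALE[strsplit(sequence, "")[[1]]])
}

#' Detect candidate transmembrane segments
#'
#' Slides a 19-residue window over the sequence; each window's mean
#' Kyte-Doolittle hydropathy is assigned to its center residue (the usual
#' hydropathy-plot convention, which keeps detected boundaries close to the
#' true segment instead of overshooting by half a window). Runs of center
#' residues with mean at least 1.6 are merged into maximal intervals;
#' intervals shorter than 15 residues are dropped.
#'
#' @param sequence amino-acid string.
#' @return data.frame with columns \code{start}, \code{end}, sorted by start;
#'   empty when the sequence is shorter than the window.
#' @export
detect_tm <- function(sequence) {
  h <- kd_hydropathy(sequence)
  L <- length(h)
  empty <- data.frame(start = integer(), end = integer())
  if (L < TM_WINDOW) return(empty)
  cs <- c(0, cumsum(h))
  nw <- L - TM_WINDOW + 1L
  means <- (cs[(TM_WINDOW + 1L):(L + 1L)] - cs[1L:nw]) / TM_WINDOW
  half <- (TM_WINDOW - 1L) %/% 2L
  flagged <- rep(FALSE, L)
  flagged[(1L:nw) + half] <- means >= TM_THRESHOLD
  if (!any(flagged)) return(empty)
  r <- rle(flagged)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= MIN_TM_LEN
  data.frame(start = starts[keep], end = ends[keep])
}

#' Check for an IgV framework (C/W/C triple) in an interval
#'
#' Searches for cysteines at positions p1 and p3 and a tryptophan at p2 with
#' the canonical V-set spacings p2 - p1 in [10, 25] and p3 - p1 in [50, 85]
#' (bracketing the C23/W41/C104-style framework). When several triples exist
#' the leftmost p1, then the smallest p3, then the smallest p2 is reported.
#'
#' @param sequence amino-acid string.
#' @param search_interval 1-based closed interval \code{c(a, b)}.
#' @return list with \code{has_igv}, \code{cys1}, \code{cys2}, \code{trp}
#'   (positions or NA) and \code{divergent}: TRUE when an IgV-sized span
#'   (>= 55 residues) exists without the framework triple.
#' @export
check_igv <- function(sequence, search_interval) {
  validate_protein_string(sequence)
  L <- nchar(sequence)
  a <- as.integer(search_interval[1]); b <- as.integer(search_interval[2])
  stopifnot(a >= 1L, b <= L, a <= b)
  chars <- strsplit(sequence, "")[[1]]
  idx <- a:b
  cys <- idx[chars[idx] == "C"]
  trp <- idx[chars[idx] == "W"]
  res <- list(has_igv = FALSE, cys1 = NA_integer_, cys2 = NA_integer_,
              trp = NA_integer_, divergent = FALSE)
  for (p1 in cys) {
    p3s <- cys[cys - p1 >= 50L & cys - p1 <= 85L]
    if (!length(p3s)) next
    for (p3 in sort(p3s)) {
      p2s <- trp[trp - p1 >= 10L & trp - p1 <= 25L & trp < p3]
      if (length(p2s)) {
        res$has_igv <- TRUE
        res$cys1 <- p1; res$cys2 <- p3; res$trp <- min(p2s)
        return(res)
      }
    }
  }
  if (b - a + 1L >= 55L) res$divergent <- TRUE
  res
}

#' Construct a protein record
#' @param id sequence identifier.
#' @param sequence amino-acid string (non-empty).
#' @param provided_regions optional data.frame with columns \code{region},
#'   \code{start}, \code{end} (1-based inclusive, non-overlapping) that take
#'   precedence over inference in \code{\link{segment_protein}}.
#' @return object of class \code{protein_record}.
#' @export
protein_record <- function(id, sequence, provided_regions = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(sequence))
  validate_protein_string(sequence)
  if (!is.null(provided_regions)) {
    stopifnot(all(c("region", "start", "end") %in% names(provided_regions)))
    L <- nchar(sequence)
    stopifnot(all(provided_regions$start >= 1L),
              all(provided_regions$end <= L),
              all(provided_regions$start <= provided_regions$end))
    ord <- order(provided_regions$start)
    pr <- provided_regions[ord, ]
    if (nrow(pr) > 1L && any(pr$start[-1L] <= pr$end[-nrow(pr)]))
      stop("provided_regions overlap", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence,
                 provided_regions = provided_regions),
            class = "protein_record")
}

#' Segment a protein into leader/IgV/stalk/TM/cytoplasmic regions
#'
#' Infers the type-I membrane architecture: the membrane anchor is the last
#' hydrophobic segment leaving at least 8 downstream residues; the leader is
#' the N-terminal 18 residues when residues 2-16 are hydrophobic on average;
#' the IgV domain is placed around the framework C/W/C triple between leader
#' and TM. Regions supplied in the record take precedence over inference.
#'
#' @param record a \code{\link{protein_record}}.
#' @return object of class \code{architecture_call}: \code{regions} (named
#'   list of \code{c(start, end)} intervals), \code{has_single_igv},
#'   \code{igv_cys1}, \code{igv_cys2}, \code{igv_trp}, \code{tm_interval},
#'   \code{cyt_length}, \code{igv_divergent}.
#' @export
segment_protein <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  seq <- record$sequence
  L <- nchar(seq)

  provided <- list()
  if (!is.null(record$provided_regions)) {
    for (i in seq_len(nrow(record$provided_regions))) {
      r <- record$provided_regions[i, ]
      provided[[tolower(r$region)]] <- c(as.integer(r$start), as.integer(r$end))
    }
  }

  # membrane anchor
  if (!is.null(provided$tm)) {
    tm <- provided$tm
  } else {
    cands <- detect_tm(seq)
    cands <- cands[L - cands$end >= 8L, , drop = FALSE]
    if (nrow(cands) == 0L)
      stop("not a candidate type-I membrane protein", call. = FALSE)
    tm <- c(cands$start[nrow(cands)], cands$end[nrow(cands)])
  }

  # leader
  leader <- provided$leader
  if (is.null(leader) && !("leader" %in% names(provided)) && L >= 16L) {
    if (mean(kd_hydropathy(substr(seq, 2L, 16L))) >= LEADER_THRESHOLD &&
        tm[1] > 18L + 1L) {
      leader <- c(1L, 18L)
    }
  }

  # IgV between leader end and TM start
  search_lo <- if (!is.null(leader)) leader[2] + 1L else 1L
  igv <- provided$igv
  igv_info <- list(has_igv = FALSE, cys1 = NA_integer_, cys2 = NA_integer_,
                   trp = NA_integer_, divergent = FALSE)
  has_single <- FALSE
  if (!is.null(igv)) {
    igv_info <- check_igv(seq, igv)
    igv_info$divergent <- FALSE
    has_single <- TRUE
  } else if (tm[1] - 1L >= search_lo) {
    igv_info <- check_igv(seq, c(search_lo, tm[1] - 1L))
    if (igv_info$has_igv) {
      igv <- c(max(search_lo, igv_info$cys1 - 22L),
               min(igv_info$cys2 + 12L, tm[1] - 1L))
      has_single <- TRUE
      # a second, disjoint framework triple downstream voids single-IgV status
      if (tm[1] - 1L - igv_info$cys2 >= 55L) {
        second <- check_igv(seq, c(igv_info$cys2 + 1L, tm[1] - 1L))
        if (second$has_igv) has_single <- FALSE
      }
    }
  }

  stalk <- NULL
  if (!is.null(igv) && tm[1] - igv[2] > 1L) stalk <- c(igv[2] + 1L, tm[1] - 1L)
  cyt <- if (tm[2] < L) c(tm[2] + 1L, L) else NULL

  regions <- list()
  if (!is.null(leader)) regions$leader <- leader
  if (!is.null(igv)) regions$igv <- igv
  if (!is.null(stalk)) regions$stalk <- stalk
  regions$tm <- tm
  if (!is.null(cyt)) regions$cytoplasmic <- cyt

  structure(list(
    regions = regions,
    has_single_igv = has_single,
    igv_cys1 = igv_info$cys1, igv_cys2 = igv_info$cys2, igv_trp = igv_info$trp,
    tm_interval = tm,
    cyt_length = L - tm[2],
    igv_divergent = igv_info$divergent,
    seq_length = L
  ), class = "architecture_call")
}

#' @export
print.architecture_call <- function(x, ...) {
  cat("<architecture_call>\n")
  for (nm in names(x$regions))
    cat(sprintf("  %-12s %d..%d\n", nm, x$regions[[nm]][1], x$regions[[nm]][2]))
  cat(sprintf("  single IgV: %s  divergent IgV: %s  cytoplasmic length: %d\n",
              x$has_single_igv, x$igv_divergent, x$cyt_length))
  invisible(x)
}

#' Motif-scanning intervals for the six catalog regions
#'
#' Localizes the structural vocabulary used by the family catalog on a
#' segmented protein: the CDR3 neighborhood follows the second framework
#' cysteine (\code{[cys2 - 5, cys2 + 30]}), the G strand is the last 15
#' residues of the IgV interval, the E strand is \code{[cys1 + 30,
#' cys1 + 50]}, and CTERM is the final 12 residues of the protein.
#'
#' @param arch an \code{architecture_call}.
#' @return named list of \code{c(start, end)} intervals (entries absent when
#'   the underlying region is absent), with names among
#'   CDR3_NEIGHBORHOOD, G_STRAND, E_STRAND, TM, CYTOPLASMIC, CTERM.
#' @export
region_intervals <- function(arch) {
  stopifnot(inherits(arch, "architecture_call"))
  L <- arch$seq_length
  clip <- function(iv) c(max(1L, iv[1]), min(L, iv[2]))
  out <- list()
  if (!is.na(arch$igv_cys2)) {
    out$CDR3_NEIGHBORHOOD <- clip(c(arch$igv_cys2 - 5L, arch$igv_cys2 + 30L))
    igv <- arch$regions$igv
    out$G_STRAND <- clip(c(igv[2] - 14L, igv[2]))
    out$E_STRAND <- clip(c(arch$igv_cys1 + 30L, arch$igv_cys1 + 50L))
  }
  out$TM <- arch$tm_interval
  if (!is.null(arch$regions$cytoplasmic)) out$CYTOPLASMIC <- arch$regions$cytoplasmic
  if (L >= 12L) out$CTERM <- c(L - 11L, L)
  out
}
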