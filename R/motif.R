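# Degenerate consensus-motif engine: parse the compact notation used in
# comparative immunogenetics (e.g. "[M/L/I]-[Y/F]-P-P-P-Y", "YxCx_6_PPPx_4/5_GxG",
# "[I,V]xYxxL (X)_n VTYxxV") and find all occurrences in protein sequences.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# polar residues used to expand shorthand classes like [E/K/Q/N-polar]
POLAR_SET <- c("S", "T", "N", "Q")

# matching bound for the unbounded gap "(X)_n": 0..60 residues, wide enough
# for any plausible ITIM-ITSM spacing in a cytoplasmic tail
UNBOUNDED_GAP_MAX <- 60L

pattern_element <- function(kind, residues = character(), min_len = 1L, max_len = 1L) {
  list(kind = kind, residues = residues,
       min_len = as.integer(min_len), max_len = max_len)
}

#' Compile a degenerate consensus motif
#'
#' Parses a motif written in the compact consensus dialect into a matchable
#' pattern. Tokens: single amino-acid letters (fixed positions); bracketed
#' residue classes \code{[A/B/C]} or \code{[A,B,C]} (the shorthand
#' \code{N-polar} inside a class expands to the named residue plus the polar
#' set S/T/N/Q); lower-case \code{x} for one arbitrary residue, \code{x_N}
#' for N arbitrary residues, \code{x_N/M} for N-to-M arbitrary residues; and
#' \code{(X)_n} for an unbounded spacer. Dashes and whitespace between tokens
#' are cosmetic.
#'
#' @param notation consensus string, e.g. \code{"[M/L/I]-[Y/F]-P-P-P-Y"}.
#' @param name optional pattern name; defaults to the notation itself.
#' @return an object of class \code{motif_pattern} with fields
#'   \code{elements}, \code{min_span} and \code{max_span} (the latter is
#'   \code{Inf} when the pattern contains an unbounded spacer).
#' @examples
#' p <- compile_pattern("YxCx_6_PPPx_4/5_GxG")
#' p$min_span  # 17
#' p$max_span  # 18
#' @export
compile_pattern <- function(notation, name = notation) {
  stopifnot(is.character(notation), length(notation) == 1L, nzchar(notation))
  chars <- strsplit(notation, "")[[1]]
  n <- length(chars)
  i <- 1L
  elements <- list()

  bad <- function(tok, pos) {
    stop(sprintf("malformed motif token '%s' at position %d in \"%s\"",
                 tok, pos, notation), call. = FALSE)
  }

  # parse an optional length suffix "_N", "_N/M" (with optional trailing "_")
  # starting at position j; returns list(min, max, next_pos) or NULL
  parse_len_suffix <- function(j) {
    if (j > n || chars[j] != "_") return(NULL)
    k <- j + 1L
    d1 <- ""
    while (k <= n && grepl("[0-9]", chars[k])) { d1 <- paste0(d1, chars[k]); k <- k + 1L }
    if (!nzchar(d1)) return(NULL)
    lo <- as.integer(d1); hi <- lo
    if (k <= n && chars[k] == "/") {
      k <- k + 1L
      d2 <- ""
      while (k <= n && grepl("[0-9]", chars[k])) { d2 <- paste0(d2, chars[k]); k <- k + 1L }
      if (!nzchar(d2)) bad(paste0("_", d1, "/"), j)
      hi <- as.integer(d2)
    }
    if (k <= n && chars[k] == "_") k <- k + 1L  # closing underscore is cosmetic
    list(min = lo, max = hi, next_pos = k)
  }

  while (i <= n) {
    ch <- chars[i]
    if (ch %in% c("-", " ", "\t")) { i <- i + 1L; next }

    if (ch == "[") {
      j <- i + 1L
      content <- ""
      while (j <= n && chars[j] != "]") { content <- paste0(content, chars[j]); j <- j + 1L }
      if (j > n) bad("[", i)
      parts <- strsplit(content, "[/,]")[[1]]
      parts <- trimws(parts)
      residues <- character()
      for (p in parts) {
        if (grepl("^[A-Z]$", p)) {
          residues <- c(residues, p)
        } else if (grepl("^[A-Z]-polar$", p)) {
          residues <- c(residues, substr(p, 1L, 1L), POLAR_SET)
        } else bad(p, i)
      }
      residues <- unique(residues)
      if (length(residues) < 2L) bad(content, i)
      if (!all(residues %in% AA20)) bad(content, i)
      elements[[length(elements) + 1L]] <- pattern_element("CLASS", residues)
      i <- j + 1L
      next
    }

    if (ch == "(") {
      # unbounded spacer "(X)_n"
      if (i + 2L <= n && chars[i + 1L] == "X" && chars[i + 2L] == ")") {
        j <- i + 3L
        if (j <= n && chars[j] == "_") {
          if (j + 1L <= n && chars[j + 1L] %in% c("n", "N")) {
            j <- j + 2L
            if (j <= n && chars[j] == "_") j <- j + 1L
          } else bad("(X)_", i)
        }
        elements[[length(elements) + 1L]] <-
          pattern_element("GAP", min_len = 0L, max_len = Inf)
        i <- j
        next
      }
      bad("(", i)
    }

    if (ch == "x") {
      suf <- parse_len_suffix(i + 1L)
      if (is.null(suf)) {
        elements[[length(elements) + 1L]] <- pattern_element("WILDCARD", min_len = 1L, max_len = 1L)
        i <- i + 1L
      } else if (suf$min == suf$max) {
        if (suf$min < 1L) bad("x_0", i)
        elements[[length(elements) + 1L]] <-
          pattern_element("WILDCARD", min_len = suf$min, max_len = suf$min)
        i <- suf$next_pos
      } else {
        if (suf$min > suf$max) bad(sprintf("x_%d/%d", suf$min, suf$max), i)
        elements[[length(elements) + 1L]] <-
          pattern_element("GAP", min_len = suf$min, max_len = suf$max)
        i <- suf$next_pos
      }
      next
    }

    if (grepl("^[A-Z]$", ch)) {
      if (!ch %in% AA20) bad(ch, i)
      elements[[length(elements) + 1L]] <- pattern_element("FIXED", ch)
      i <- i + 1L
      next
    }

    bad(ch, i)
  }

  if (length(elements) == 0L) bad("<empty>", 1L)

  mins <- vapply(elements, function(e) e$min_len, integer(1))
  maxs <- vapply(elements, function(e) as.numeric(e$max_len), numeric(1))
  structure(
    list(name = name, notation = notation, elements = elements,
         min_span = sum(mins),
         max_span = if (any(!is.finite(maxs))) Inf else as.integer(sum(maxs))),
    class = "motif_pattern")
}

#' @export
print.motif_pattern <- function(x, ...) {
  cat(sprintf("<motif_pattern> %s  (%d elements, span %s..%s)\n",
              x$notation, length(x$elements), x$min_span,
              if (is.finite(x$max_span)) x$max_span else "unbounded"))
  invisible(x)
}

validate_protein_string <- function(sequence, allow_x = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (!nzchar(sequence)) return(invisible(TRUE))
  ok <- paste0(AA20, collapse = "")
  if (allow_x) ok <- paste0(ok, "X")
  badpos <- regexpr(sprintf("[^%s]", ok), sequence)
  if (badpos > 0L) {
    stop(sprintf("invalid residue '%s' at position %d",
                 substr(sequence, badpos, badpos), badpos), call. = FALSE)
  }
  invisible(TRUE)
}

#' Scan a protein sequence for a compiled motif
#'
#' Reports every occurrence of a compiled degenerate pattern. Coordinates are
#' 1-based inclusive. All overlapping matches are reported; for patterns with
#' an unbounded spacer only the shortest match per start position is kept.
#' The ambiguity code X in the sequence matches wildcard and spacer positions
#' but never fixed or class positions, so gap-filled gene models cannot
#' create motif calls.
#'
#' @param sequence amino-acid string (20 standard letters plus X).
#' @param pattern a \code{motif_pattern} from \code{\link{compile_pattern}},
#'   or a notation string (compiled on the fly).
#' @param window optional 1-based closed interval \code{c(a, b)}; only
#'   matches fully contained in the window are returned.
#' @return data.frame with columns \code{pattern_name}, \code{start},
#'   \code{end}, \code{matched_span}, sorted by start then end.
#' @examples
#' scan_motif("DYMNM", compile_pattern("[D/E/V/I]-Y-M-[N/D]-[M/I/V/T]"))
#' @export
scan_motif <- function(sequence, pattern, window = NULL) {
  if (is.character(pattern)) pattern <- compile_pattern(pattern)
  stopifnot(inherits(pattern, "motif_pattern"))
  validate_protein_string(sequence)
  L <- nchar(sequence)

  empty <- data.frame(pattern_name = character(), start = integer(),
                      end = integer(), matched_span = character(),
                      stringsAsFactors = FALSE)
  if (L == 0L) return(empty)

  lo <- 1L; hi <- L
  if (!is.null(window)) {
    stopifnot(length(window) == 2L, window[1] >= 1L, window[2] <= L,
              window[1] <= window[2])
    lo <- as.integer(window[1]); hi <- as.integer(window[2])
  }

  chars <- strsplit(sequence, "")[[1]]
  els <- pattern$elements
  ne <- length(els)
  unbounded <- any(vapply(els, function(e) !is.finite(e$max_len), logical(1)))

  # minimal residues still needed from element ei onwards (pruning)
  tail_min <- rev(cumsum(rev(vapply(els, function(e) e$min_len, integer(1)))))
  tail_min <- c(tail_min, 0L)

  # returns all positions just after a match of elements ei..ne starting at pos
  match_from <- function(pos, ei) {
    if (ei > ne) return(pos)
    if (pos + tail_min[ei] - 1L > hi) return(integer())
    e <- els[[ei]]
    if (e$kind %in% c("FIXED", "CLASS")) {
      if (pos > hi) return(integer())
      if (chars[pos] %in% e$residues) return(match_from(pos + 1L, ei + 1L))
      return(integer())
    }
    if (e$kind == "WILDCARD") {
      if (pos + e$min_len - 1L > hi) return(integer())
      return(match_from(pos + e$min_len, ei + 1L))
    }
    # GAP
    gmax <- if (is.finite(e$max_len)) e$max_len else UNBOUNDED_GAP_MAX
    gmax <- min(gmax, hi - pos + 1L)
    if (gmax < e$min_len) return(integer())
    out <- integer()
    for (g in e$min_len:gmax) {
      out <- c(out, match_from(pos + g, ei + 1L))
    }
    out
  }

  starts <- integer(); ends <- integer()
  last <- hi - pattern$min_span + 1L
  if (last >= lo) {
    for (s in lo:last) {
      after <- unique(match_from(s, 1L))
      if (length(after)) {
        e_here <- sort(after) - 1L
        if (unbounded) e_here <- e_here[1L]  # minimal match per start
        starts <- c(starts, rep.int(s, length(e_here)))
        ends <- c(ends, e_here)
      }
    }
  }
  if (!length(starts)) return(empty)
  ord <- order(starts, ends)
  data.frame(pattern_name = pattern$name,
             start = starts[ord], end = ends[ord],
             matched_span = substring(sequence, starts[ord], ends[ord]),
             stringsAsFactors = FALSE)
}
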