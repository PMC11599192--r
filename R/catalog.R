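# Family evidence catalog: load, validate and serialize the machine-readable
# profiles (motifs per structural region, synteny markers, architecture
# flags) for the nine canonical CD28-family members and the chondrichthyan
# CD28/CTLA4 co-ortholog class.

CANONICAL_FAMILIES <- c("CD28", "CTLA4", "ICOS", "CD28H", "CD28HL1",
                        "CD28HL2", "CD28HL3", "CD28X", "PD1")
ALL_PROFILES <- c(CANONICAL_FAMILIES, "CD28_CTLA4_CO_ORTHOLOG")
CATALOG_REGIONS <- c("CDR3_NEIGHBORHOOD", "G_STRAND", "E_STRAND",
                     "TM", "CYTOPLASMIC", "CTERM")
EVIDENCE_WEIGHTS <- c("REQUIRED", "SUPPORTING")

#' Path of the built-in family catalog file
#' @return path to the YAML catalog shipped with the package.
#' @export
builtin_catalog_path <- function() {
  system.file("extdata", "cd28_family_catalog.yaml", package = "cd28family",
              mustWork = TRUE)
}

validate_profile <- function(p) {
  ctx <- function(field) sprintf("profile '%s', field '%s'", p$name, field)
  if (!p$name %in% ALL_PROFILES)
    stop("unknown profile name: ", p$name, call. = FALSE)
  if (length(p$motifs) == 0L && !(isTRUE(p$allow_divergent_igv) && length(p$markers)))
    stop(ctx("motifs"), ": profile has no evidence", call. = FALSE)
  n_required <- sum(vapply(p$motifs, function(m) m$weight == "REQUIRED", logical(1)))
  if (n_required == 0L && !(isTRUE(p$allow_divergent_igv) && length(p$markers) > 0L))
    stop(ctx("motifs"), ": needs a REQUIRED motif or allow_divergent_igv with markers",
         call. = FALSE)
  for (m in p$motifs) {
    if (!m$region %in% CATALOG_REGIONS)
      stop(ctx("region"), ": invalid region ", m$region, call. = FALSE)
    if (!m$weight %in% EVIDENCE_WEIGHTS)
      stop(ctx("weight"), ": invalid weight ", m$weight, call. = FALSE)
  }
  if (anyDuplicated(p$markers))
    stop(ctx("markers"), ": duplicated marker symbol", call. = FALSE)
  if (length(p$markers) && any(p$markers != tolower(p$markers)))
    stop(ctx("markers"), ": marker symbols must be lower case", call. = FALSE)
  invisible(TRUE)
}

#' Load the family evidence catalog
#'
#' Reads a catalog config (YAML), compiles every motif notation and
#' validates all invariants at load time. Without arguments the built-in
#' catalog of the ten profiles (nine canonical families plus the
#' chondrichthyan CD28/CTLA4 co-ortholog class) is returned.
#'
#' @param config_path optional path to a catalog YAML following the
#'   documented schema (profiles -> motifs[] \{notation, region, weight,
#'   lineage_note\}, markers[], allow_divergent_igv, notes).
#' @return object of class \code{family_catalog}: a named list of
#'   \code{family_profile} objects, with the catalog version as attribute.
#' @examples
#' cat10 <- load_catalog()
#' names(cat10)
#' cat10$CD28H$markers
#' @export
load_catalog <- function(config_path = NULL) {
  if (is.null(config_path)) config_path <- builtin_catalog_path()
  raw <- yaml::read_yaml(config_path)
  if (is.null(raw$profiles))
    stop("catalog config has no 'profiles' entry: ", config_path, call. = FALSE)
  profiles <- list()
  for (rp in raw$profiles) {
    motifs <- lapply(rp$motifs, function(m) {
      pat <- tryCatch(compile_pattern(m$notation),
                      error = function(e) stop(sprintf(
                        "profile '%s', motif '%s': %s",
                        rp$name, m$notation, conditionMessage(e)), call. = FALSE))
      list(notation = m$notation,
           pattern = pat,
           region = m$region,
           weight = m$weight,
           lineage_note = if (is.null(m$lineage_note)) "" else m$lineage_note,
           cassette_position = m$cassette_position)
    })
    p <- structure(list(
      name = rp$name,
      motifs = motifs,
      markers = tolower(unlist(rp$markers) %||% character()),
      allow_divergent_igv = isTRUE(rp$allow_divergent_igv),
      notes = if (is.null(rp$notes)) "" else rp$notes
    ), class = "family_profile")
    validate_profile(p)
    if (p$name %in% names(profiles))
      stop("duplicated profile: ", p$name, call. = FALSE)
    profiles[[p$name]] <- p
  }
  structure(profiles, class = "family_catalog",
            catalog_version = raw$catalog_version %||% "unversioned")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a catalog back to its YAML config format
#'
#' Writing the built-in catalog and reloading it yields an equal catalog
#' (round-trip stability).
#'
#' @param catalog a \code{family_catalog}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "family_catalog"))
  out <- list(
    catalog_version = attr(catalog, "catalog_version"),
    profiles = lapply(unname(catalog), function(p) {
      pr <- list(
        name = p$name,
        allow_divergent_igv = p$allow_divergent_igv,
        markers = as.list(p$markers),
        motifs = lapply(p$motifs, function(m) {
          mm <- list(notation = m$notation, region = m$region,
                     weight = m$weight, lineage_note = m$lineage_note)
          if (!is.null(m$cassette_position))
            mm$cassette_position <- m$cassette_position
          mm
        }),
        notes = p$notes)
      pr
    }))
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.family_catalog <- function(x, ...) {
  cat(sprintf("<family_catalog> %d profiles (version %s)\n",
              length(x), attr(x, "catalog_version")))
  for (p in x) {
    cat(sprintf("  %-22s %d motifs, markers: %s%s\n", p$name, length(p$motifs),
                if (length(p$markers)) paste(p$markers, collapse = ",") else "-",
                if (p$allow_divergent_igv) "  [divergent IgV allowed]" else ""))
  }
  invisible(x)
}
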