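# Domain types and coordinate arithmetic shared by all other modules.
# External coordinates are 1-based inclusive (GFF3 convention) throughout.

FEATURE_KINDS <- c("protein_gene", "rna_gene", "pseudogene",
                   "transcription_unit", "tss", "terminator", "tfbs",
                   "other_site")

# feature kinds that get book-style gene glyphs vs. small site glyphs
GENE_KINDS <- c("protein_gene", "rna_gene", "pseudogene")
SITE_KINDS <- c("tss", "terminator", "tfbs", "other_site")

#' Create an empty genome-feature table
#'
#' Features are kept as a plain data frame with one row per feature; all
#' higher-level containers ([replicon()]) and the layout engine consume this
#' shape.
#'
#' @return A zero-row data frame with the canonical feature columns.
#' @export
empty_features <- function() {
  data.frame(
    id = character(0), kind = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    name = character(0), product = character(0),
    operon_id = character(0), sigma_factor = character(0),
    bound_factor = character(0),
    stringsAsFactors = FALSE
  )
}

#' Create a single genome feature
#'
#' A located, stranded annotation: a gene of a given class, a transcription
#' unit (operon), or a site (transcription start site, terminator,
#' transcription-factor binding site). Sites may be point-like
#' (`start == end`). On circular replicons a feature with `start > end` is
#' interpreted as wrapping through the origin.
#'
#' @param id Unique feature identifier (accession).
#' @param kind One of `r paste0('"', FEATURE_KINDS, '"', collapse = ", ")`.
#' @param start,end 1-based inclusive genome coordinates.
#' @param strand `"+"` or `"-"`.
#' @param name Optional display name (e.g. gene symbol).
#' @param product Optional gene product description.
#' @param operon_id Optional transcription-unit membership identifier;
#'   adjacent genes sharing it are drawn in one color inside one gray box.
#' @param sigma_factor Optional sigma factor label (TSS features).
#' @param bound_factor Optional transcription-factor name (TFBS features).
#' @return A one-row feature data frame.
#' @export
genome_feature <- function(id, kind, start, end, strand = "+",
                           name = NA_character_, product = NA_character_,
                           operon_id = NA_character_,
                           sigma_factor = NA_character_,
                           bound_factor = NA_character_) {
  kind <- match.arg(kind, FEATURE_KINDS)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-', got '", strand, "'")
  }
  data.frame(
    id = as.character(id), kind = kind,
    start = as.integer(start), end = as.integer(end), strand = strand,
    name = as.character(name), product = as.character(product),
    operon_id = as.character(operon_id),
    sigma_factor = as.character(sigma_factor),
    bound_factor = as.character(bound_factor),
    stringsAsFactors = FALSE
  )
}

#' Create a replicon
#'
#' A replicon is a named DNA molecule (chromosome or plasmid) with a length,
#' a topology, optionally its sequence, and its annotated features. It is
#' the unit the basic browsing mode displays.
#'
#' @param id Replicon identifier.
#' @param length Replicon length in bases (>= 1).
#' @param topology `"linear"` or `"circular"`. On circular replicons,
#'   views, selections and features may span the origin.
#' @param sequence Optional DNA string over A/C/G/T/N of exactly `length`
#'   characters.
#' @param features Feature data frame as built by [genome_feature()] /
#'   `rbind`, or [empty_features()].
#' @return An object of class `"replicon"`.
#' @export
replicon <- function(id, length, topology = c("linear", "circular"),
                     sequence = NULL, features = empty_features()) {
  topology <- match.arg(topology)
  length <- as.integer(length)
  if (is.na(length) || length < 1L) stop("replicon length must be >= 1")
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != length) {
      stop("sequence length (", nchar(sequence),
           ") does not equal replicon length (", length, ")")
    }
    bad <- gsub("[ACGTN]", "", sequence)
    if (nzchar(bad)) {
      stop("sequence contains non-ACGTN characters: ",
           paste(unique(strsplit(bad, "")[[1]]), collapse = ", "))
    }
  }
  obj <- structure(
    list(id = as.character(id), length = length, topology = topology,
         sequence = sequence, features = features),
    class = "replicon"
  )
  validate_features(obj)
  obj
}

validate_features <- function(rep) {
  f <- rep$features
  if (nrow(f) == 0L) return(invisible(rep))
  bad <- f$start < 1L | f$start > rep$length | f$end < 1L | f$end > rep$length
  if (any(bad)) {
    stop("feature '", f$id[which(bad)[1]], "' has coordinates outside [1, ",
         rep$length, "]")
  }
  if (rep$topology == "linear" && any(f$start > f$end)) {
    i <- which(f$start > f$end)[1]
    stop("feature '", f$id[i],
         "' has start > end on a linear replicon (wrapping requires ",
         "circular topology)")
  }
  invisible(rep)
}

#' @export
print.replicon <- function(x, ...) {
  cat(sprintf("<replicon> %s: %s bp, %s, %d features, sequence %s\n",
              x$id, format(x$length, big.mark = ","), x$topology,
              nrow(x$features),
              if (is.null(x$sequence)) "absent" else "present"))
  invisible(x)
}

# map an arbitrary integer onto [1, L] (circular coordinate wrap)
wrap_coord <- function(x, L) ((x - 1L) %% L) + 1L

check_coord <- function(x, rep, what = "coordinate") {
  if (any(x < 1L | x > rep$length)) {
    stop(what, " ", x[which(x < 1L | x > rep$length)[1]],
         " is outside [1, ", rep$length, "] on replicon '", rep$id, "'")
  }
  invisible(x)
}

#' Span length of a (possibly origin-wrapping) region
#'
#' For linear replicons, or when `start <= end`, this is the ordinary
#' inclusive span `end - start + 1`. On circular replicons `start > end`
#' denotes a region running forward through the origin, and the length is
#' counted along that wrapped arc.
#'
#' @param start,end 1-based inclusive coordinates in `[1, length]`.
#' @param rep A [replicon()].
#' @return Positive integer span length in bases.
#' @examples
#' r <- replicon("chr", 1000, "circular")
#' circular_span_length(990, 10, r)  # 21: runs 990..1000 then 1..10
#' @export
circular_span_length <- function(start, end, rep) {
  start <- as.integer(start); end <- as.integer(end)
  check_coord(start, rep, "start coordinate")
  check_coord(end, rep, "end coordinate")
  if (start <= end) return(end - start + 1L)
  if (rep$topology != "circular") {
    stop("start (", start, ") > end (", end, ") on linear replicon '",
         rep$id, "'")
  }
  rep$length - start + 1L + end
}

#' Center coordinate of a feature
#'
#' The midpoint of the feature's span, with ties broken toward the start
#' (integer floor). For origin-wrapping features the midpoint is taken along
#' the wrapped span and reduced modulo the replicon length into
#' `[1, length]`. This is the anchor point used by the comparative mode.
#'
#' @param feature One-row feature data frame (or a list with `start`/`end`).
#' @param rep The [replicon()] the feature lies on.
#' @return A 1-based coordinate inside the feature's span.
#' @export
feature_center <- function(feature, rep) {
  span <- circular_span_length(feature$start, feature$end, rep)
  wrap_coord(as.integer(feature$start) + (span - 1L) %/% 2L, rep$length)
}

#' Per-kind display policy (legend tri-state)
#'
#' Every feature kind carries one of three settings: `"On"` and `"Off"` are
#' absolute; under `"Auto"` visibility is computed by the semantic-zooming
#' rules of the layout engine (see [visibility()]).
#'
#' @param ... Named overrides, e.g. `tfbs = "Off"`; names must be feature
#'   kinds, values one of `"On"`, `"Off"`, `"Auto"`.
#' @param default Setting applied to kinds not named in `...`.
#' @return Named character vector over all feature kinds, class
#'   `"display_policy"`.
#' @export
display_policy <- function(..., default = "Auto") {
  settings <- rep(default, length(FEATURE_KINDS))
  names(settings) <- FEATURE_KINDS
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), FEATURE_KINDS)
    if (length(bad)) stop("unknown feature kind(s): ", paste(bad, collapse = ", "))
    settings[names(over)] <- unlist(over)
  }
  if (!all(settings %in% c("On", "Off", "Auto"))) {
    stop("policy settings must be 'On', 'Off' or 'Auto'")
  }
  structure(settings, class = "display_policy")
}
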