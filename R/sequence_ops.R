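# Two-click region selection, origin-spanning extraction, CDS translation,
# and FASTA export. Sequence manipulation is delegated to Biostrings.

#' Select a genome region from two clicks
#'
#' Models the two-click selection gesture: zoom to the starting base, click,
#' zoom to the ending base, click. On a linear replicon the clicks are
#' order-free (the region is their min..max). On a circular replicon order
#' matters: the region runs forward from the first click, wrapping through
#' the origin when needed, so any arc — including origin-spanning ones —
#' is selectable. There is no limit on region size, up to the whole
#' replicon.
#'
#' @param first_click,second_click 1-based coordinates in `[1, length]`.
#' @param rep A [replicon()].
#' @param strand `"+"` or `"-"`; minus-strand extraction reverse-complements.
#' @return An object of class `"selected_region"` with `start > end`
#'   encoding an origin-spanning region.
#' @export
select_region <- function(first_click, second_click, rep, strand = "+") {
  first_click <- as.integer(first_click)
  second_click <- as.integer(second_click)
  check_coord(first_click, rep, "first click")
  check_coord(second_click, rep, "second click")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (rep$topology == "linear") {
    start <- min(first_click, second_click)
    end <- max(first_click, second_click)
  } else {
    start <- first_click
    end <- second_click
  }
  structure(list(replicon = rep, start = start, end = end, strand = strand),
            class = "selected_region")
}

#' Length of a selected region in bases
#' @param region A [select_region()] result.
#' @return Positive integer length.
#' @export
region_length <- function(region) {
  circular_span_length(region$start, region$end, region$replicon)
}

#' @export
print.selected_region <- function(x, ...) {
  cat(sprintf("<selection> %s:%d-%d(%s), %d bp%s\n", x$replicon$id, x$start,
              x$end, x$strand, region_length(x),
              if (x$start > x$end) " [spans origin]" else ""))
  invisible(x)
}

#' Extract the nucleotide sequence of a selected region
#'
#' Returns the bases in region order; origin-spanning regions concatenate
#' the tail and head of the circular sequence. Minus-strand selections
#' return the reverse complement.
#'
#' @param region A [select_region()] result; its replicon must carry a
#'   sequence.
#' @return DNA string.
#' @export
extract_nt <- function(region) {
  rep <- region$replicon
  if (is.null(rep$sequence)) {
    stop("replicon '", rep$id,
         "' has no sequence loaded; read one with read_fasta() and rebuild ",
         "the replicon with it")
  }
  s <- if (region$start <= region$end) {
    substr(rep$sequence, region$start, region$end)
  } else {
    paste0(substr(rep$sequence, region$start, rep$length),
           substr(rep$sequence, 1L, region$end))
  }
  if (region$strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  s
}

#' Translate a protein-coding gene
#'
#' Extracts the gene's span on its annotated strand and translates it with
#' the bacterial/archaeal genetic code (translation table 11) by default.
#' The terminal stop is dropped; internal stops render as `*`. When
#' `init_codon_as_met` is set (the default), a recognized alternative
#' initiator (e.g. GTG, TTG) translates as M.
#'
#' @param gene Feature id (string) or one-row feature data frame of kind
#'   `protein_gene`.
#' @param rep The [replicon()] carrying the gene and its sequence.
#' @param table NCBI genetic-code table identifier (default `"11"`).
#' @param init_codon_as_met Treat the first codon as an initiator.
#' @return Amino-acid string.
#' @export
translate_cds <- function(gene, rep, table = "11", init_codon_as_met = TRUE) {
  if (is.character(gene)) {
    hit <- rep$features[rep$features$id == gene, , drop = FALSE]
    if (nrow(hit) == 0L) stop("no feature with id '", gene, "'")
    gene <- hit[1, ]
  }
  if (gene$kind != "protein_gene") {
    stop("feature '", gene$id, "' is a ", gene$kind,
         ", not a protein-coding gene")
  }
  region <- structure(list(replicon = rep, start = gene$start,
                           end = gene$end, strand = gene$strand),
                      class = "selected_region")
  nt <- extract_nt(region)
  if (nchar(nt) %% 3L != 0L) {
    stop("gene '", gene$id, "' has span length ", nchar(nt),
         ", not divisible by 3")
  }
  code <- Biostrings::getGeneticCode(table)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(nt), genetic.code = code,
    no.init.codon = !init_codon_as_met))
  sub("\\*$", "", aa)
}

#' Format a selected region as FASTA text
#'
#' Single-record FASTA with a `replicon:start-end(strand)` header by
#' default and 60-column sequence wrapping; round trips through
#' [read_fasta()] restore the sequence.
#'
#' @param region A [select_region()] result.
#' @param header Header line content (without `>`); default
#'   `"<replicon>:<start>-<end>(<strand>)"`.
#' @param path Optional file to write to.
#' @return FASTA text (invisibly when `path` is given).
#' @export
region_to_fasta <- function(region, header = NULL, path = NULL) {
  if (is.null(header)) {
    header <- sprintf("%s:%d-%d(%s)", region$replicon$id, region$start,
                      region$end, region$strand)
  }
  seq <- extract_nt(region)
  lines <- substring(seq, seq(1L, nchar(seq), by = 60L),
                     pmin(seq(60L, nchar(seq) + 59L, by = 60L), nchar(seq)))
  text <- paste0(c(paste0(">", header), lines, ""), collapse = "\n")
  if (!is.null(path)) {
    writeLines(c(paste0(">", header), lines), path)
    return(invisible(text))
  }
  text
}
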