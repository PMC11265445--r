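# Readers/writers for GFF3 annotations, FASTA sequences, score-bearing GFF
# track data, and the ortholog table. GFF3 parsing/serialization goes
# through rtracklayer and FASTA through Biostrings; a light line-level
# pre-validation supplies line-numbered parse errors.

GFF3_TYPE_MAP <- c(
  gene = "protein_gene", CDS = "protein_gene",
  pseudogene = "pseudogene",
  mRNA = "transcription_unit", transcript = "transcription_unit",
  operon = "transcription_unit", transcription_unit = "transcription_unit",
  rRNA = "rna_gene", tRNA = "rna_gene", ncRNA = "rna_gene",
  tmRNA = "rna_gene", ncRNA_gene = "rna_gene",
  transcription_start_site = "tss", TSS = "tss",
  terminator = "terminator",
  TF_binding_site = "tfbs", TFBS = "tfbs", binding_site = "tfbs",
  protein_binding_site = "tfbs"
)

validate_gff_lines <- function(path, min_fields = 8L) {
  lines <- readLines(path, warn = FALSE)
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(ln) || startsWith(ln, "#")) next
    fields <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(fields) < min_fields) {
      stop("malformed GFF line ", i, " in '", path, "': expected at least ",
           min_fields, " tab-separated fields, found ", length(fields))
    }
    if (is.na(suppressWarnings(as.integer(fields[4]))) ||
        is.na(suppressWarnings(as.integer(fields[5])))) {
      stop("malformed GFF line ", i, " in '", path,
           "': non-integer coordinates '", fields[4], "'/'", fields[5], "'")
    }
    if (fields[6] != "." &&
        is.na(suppressWarnings(as.numeric(fields[6])))) {
      stop("malformed GFF line ", i, " in '", path,
           "': score column must be numeric or '.', found '", fields[6], "'")
    }
  }
  invisible(lines)
}

mcol_or_na <- function(m, col, n) {
  if (col %in% names(m)) {
    v <- as.character(m[[col]])
    v[!is.na(v) & !nzchar(v)] <- NA_character_
    v
  } else rep(NA_character_, n)
}

#' Read genome annotations from a GFF3 file
#'
#' Maps GFF3 feature types onto the browser's glyph vocabulary: `gene`
#' becomes a protein-coding gene (or an RNA gene when a `biotype` attribute
#' names an RNA class), `pseudogene` stays itself, transcript/operon types
#' become transcription units, and the Sequence Ontology site types map to
#' TSS / terminator / TF-binding-site features. Unmappable types are kept
#' as `other_site` and reported via a message. Sigma factor, bound factor
#' and operon membership are read from `sigma=`, `factor=` and `operon_id=`
#' attributes. Topology is circular when a `region` feature carries
#' `Is_circular=true`. Replicon length comes from the `##sequence-region`
#' directive (or the region feature), falling back to the maximum feature
#' end.
#'
#' @param path GFF3 file path.
#' @return A named list of [replicon()] objects, one per `seqid`.
#' @export
read_features_gff3 <- function(path) {
  lines <- validate_gff_lines(path, min_fields = 9L)
  # ##sequence-region seqid start end
  sr <- regmatches(lines, regexec(
    "^##sequence-region\\s+(\\S+)\\s+([0-9]+)\\s+([0-9]+)", lines))
  sr <- sr[lengths(sr) == 4L]
  declared_len <- stats::setNames(
    vapply(sr, function(m) as.integer(m[4]), integer(1)),
    vapply(sr, function(m) m[2], character(1)))
  gr <- rtracklayer::import(path, format = "gff3")
  m <- S4Vectors::mcols(gr)
  n <- length(gr)
  seqid <- as.character(GenomicRanges::seqnames(gr))
  type <- as.character(m$type)
  is_region <- type %in% c("region", "chromosome")
  circ_attr <- mcol_or_na(m, "Is_circular", n)
  kind <- unname(GFF3_TYPE_MAP[type])
  biotype <- mcol_or_na(m, "biotype", n)
  rna_bio <- !is.na(biotype) & grepl("RNA", biotype, ignore.case = TRUE)
  kind[!is.na(kind) & kind == "protein_gene" & rna_bio] <- "rna_gene"
  unmapped <- is.na(kind) & !is_region
  if (any(unmapped)) {
    message("read_features_gff3: retaining ", sum(unmapped),
            " feature(s) of unmapped type(s) [",
            paste(unique(type[unmapped]), collapse = ", "), "] as other_site")
    kind[unmapped] <- "other_site"
  }
  ids <- mcol_or_na(m, "ID", n)
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  strand <- as.character(BiocGenerics::strand(gr))
  strand[!strand %in% c("+", "-")] <- "+"
  feats <- data.frame(
    id = ids, kind = kind,
    start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
    strand = strand,
    name = mcol_or_na(m, "Name", n),
    product = mcol_or_na(m, "product", n),
    operon_id = mcol_or_na(m, "operon_id", n),
    sigma_factor = mcol_or_na(m, "sigma", n),
    bound_factor = mcol_or_na(m, "factor", n),
    stringsAsFactors = FALSE
  )
  out <- list()
  for (sid in unique(seqid)) {
    sel <- seqid == sid
    reg <- sel & is_region
    f <- feats[sel & !is_region, , drop = FALSE]
    rownames(f) <- NULL
    len <- if (sid %in% names(declared_len)) declared_len[[sid]]
           else if (any(reg)) max(feats$end[reg])
           else max(1L, max(f$end))
    if (nrow(f) && any(f$end > len)) {
      stop("feature '", f$id[which(f$end > len)[1]], "' on '", sid,
           "' exceeds the declared sequence-region length ", len)
    }
    circ <- any(reg & !is.na(circ_attr) &
                  tolower(circ_attr) == "true")
    out[[sid]] <- replicon(sid, len,
                           topology = if (circ) "circular" else "linear",
                           features = f)
  }
  out
}

#' Write a replicon's annotations as GFF3
#'
#' Inverse of [read_features_gff3()]; the pair round-trips the feature
#' table losslessly. Circular topology is recorded on a `region` feature
#' with `Is_circular=true`.
#'
#' @param rep A [replicon()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_features_gff3 <- function(rep, path) {
  f <- rep$features
  inv_map <- c(protein_gene = "gene", rna_gene = "gene",
               pseudogene = "pseudogene",
               transcription_unit = "transcription_unit",
               tss = "transcription_start_site", terminator = "terminator",
               tfbs = "TF_binding_site", other_site = "sequence_feature")
  if (nrow(f) && any(f$start > f$end)) {
    stop("GFF3 cannot encode origin-wrapping (start > end) features; ",
         "split feature '", f$id[which(f$start > f$end)[1]], "' first")
  }
  n <- nrow(f)
  gr <- GenomicRanges::GRanges(
    seqnames = rep(rep$id, n + 1L),
    ranges = IRanges::IRanges(start = c(1L, f$start), end = c(rep$length, f$end)),
    strand = c("*", f$strand)
  )
  m <- S4Vectors::DataFrame(
    source = rep("repliconview", n + 1L),
    type = c("region", unname(inv_map[f$kind])),
    ID = c(rep$id, f$id),
    Name = c(NA_character_, f$name),
    product = c(NA_character_, f$product),
    operon_id = c(NA_character_, f$operon_id),
    sigma = c(NA_character_, f$sigma_factor),
    factor = c(NA_character_, f$bound_factor),
    biotype = c(NA_character_,
                ifelse(f$kind == "rna_gene", "ncRNA",
                       ifelse(f$kind == "protein_gene", "protein_coding",
                              NA_character_)))
  )
  if (rep$topology == "circular") {
    m$Is_circular <- c("true", rep(NA_character_, n))
  }
  S4Vectors::mcols(gr) <- m
  GenomeInfoDb::seqlengths(gr) <- stats::setNames(rep$length, rep$id)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read quantitative track data from a GFF file
#'
#' Accepts the plain GFF dialect with an intensity value in the score
#' column (column 6); `.` denotes an absent score. Every record is
#' returned regardless of feature type.
#'
#' @param path GFF file path.
#' @return Data frame of track records: `seqid`, `start`, `end`, `score`
#'   (`NA` when absent), `name`.
#' @export
read_track_gff <- function(path) {
  lines <- validate_gff_lines(path, min_fields = 8L)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  if (!any(keep)) {
    return(data.frame(seqid = character(0), start = integer(0),
                      end = integer(0), score = numeric(0),
                      name = character(0), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  rec <- function(i) vapply(fields, `[`, character(1), i)
  score <- rec(6)
  start <- as.integer(rec(4)); end <- as.integer(rec(5))
  if (any(start > end)) {
    stop("track record with start > end at data line ", which(start > end)[1])
  }
  data.frame(
    seqid = rec(1), start = start, end = end,
    score = ifelse(score == ".", NA_real_,
                   suppressWarnings(as.numeric(score))),
    name = rec(3),
    stringsAsFactors = FALSE
  )
}

#' Read an ortholog table
#'
#' A tab-separated table with header columns `genome_id`, `gene_id`,
#' `group_id` mapping genes to ortholog groups across genomes; the
#' stand-in for an ortholog database. Each (genome, gene) pair may appear
#' once, and a group may hold at most one gene per genome — the comparative
#' mode needs a unique anchor per genome.
#'
#' @param path TSV file path.
#' @return Data frame of class `"ortholog_table"`.
#' @export
read_ortholog_table <- function(path) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character")
  as_ortholog_table(tab)
}

#' Validate a data frame as an ortholog table
#' @param tab Data frame with `genome_id`, `gene_id`, `group_id` columns.
#' @return The validated table, classed `"ortholog_table"`.
#' @export
as_ortholog_table <- function(tab) {
  need <- c("genome_id", "gene_id", "group_id")
  if (!all(need %in% names(tab))) {
    stop("ortholog table must have columns ", paste(need, collapse = ", "))
  }
  tab <- tab[, need, drop = FALSE]
  key <- paste(tab$genome_id, tab$gene_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tab[duplicated(key), ][1, ]
    stop("duplicate (genome, gene) pair: (", d$genome_id, ", ", d$gene_id, ")")
  }
  gk <- paste(tab$group_id, tab$genome_id, sep = "\r")
  if (anyDuplicated(gk)) {
    d <- tab[duplicated(gk), ][1, ]
    stop("group '", d$group_id, "' has more than one member in genome '",
         d$genome_id, "' (a unique anchor per genome is required)")
  }
  structure(tab, class = c("ortholog_table", "data.frame"))
}

#' Write an ortholog table as TSV
#' @param tab An `"ortholog_table"` data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ortholog_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a FASTA file into an id-to-sequence map
#'
#' @param path FASTA file path.
#' @return Named character vector mapping record ids (first word of each
#'   header) to uppercase sequences. Empty records and non-IUPAC symbols
#'   are errors.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", names(set))
  iupac <- c(names(Biostrings::IUPAC_CODE_MAP), "N")
  for (i in seq_along(seqs)) {
    if (nchar(seqs[i]) == 0L) {
      stop("FASTA record '", ids[i], "' has an empty sequence")
    }
    chars <- unique(strsplit(seqs[i], "")[[1]])
    bad <- setdiff(chars, iupac)
    if (length(bad)) {
      stop("FASTA record '", ids[i], "' contains non-IUPAC symbol(s): ",
           paste(bad, collapse = ", "))
    }
  }
  stats::setNames(seqs, ids)
}

#' Write sequences to a FASTA file
#'
#' @param sequences Named character vector (ids to sequences).
#' @param path Output file path; written with 60-column wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("sequences must be a named character vector")
  }
  if (any(nchar(sequences) == 0L)) {
    stop("refusing to write empty sequence for record '",
         names(sequences)[nchar(sequences) == 0L][1], "'")
  }
  set <- Biostrings::DNAStringSet(toupper(sequences))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
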