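# Ortholog-anchored comparative alignment: one unwrapped line per genome,
# all aligned at the center-point of the lead gene's orthologs, with a
# recycled 12-color palette keyed to ortholog groups.

lookup_group <- function(orthologs, genome_id, gene_id) {
  hit <- orthologs$group_id[orthologs$genome_id == genome_id &
                              orthologs$gene_id == gene_id]
  if (length(hit)) hit[1] else NA_character_
}

#' Build an ortholog-anchored comparative alignment
#'
#' Aligns several genomes at the center-point of the orthologs of a
#' user-chosen lead gene. The alignment includes the lead genome plus
#' every supplied genome that has an ortholog of the lead gene (same
#' ortholog group); genomes without one are listed in `excluded_genomes`.
#' Each replicon is drawn in one line — line wrapping is disabled — and all
#' rows share one scale, with each anchor gene's center mapping to the
#' same canvas pixel (the horizontal center).
#'
#' @param lead_gene Feature id of the lead gene.
#' @param genomes Named list of [replicon()] objects; names are genome ids
#'   matching the ortholog table. Row order follows this order with the
#'   lead genome first.
#' @param orthologs An `"ortholog_table"` (see [read_ortholog_table()]).
#' @param scale Shared scale in bases per pixel.
#' @param canvas_width Canvas width in pixels.
#' @param scale_min,scale_max Zoom bounds applied by [zoom_comparative()].
#' @return An object of class `"comparative_layout"`: `rows` (list of
#'   `genome_id`, `view`, `anchor_gene`, `anchor_center`), `color_map`
#'   (group id to 0-based palette index along the lead row),
#'   `excluded_genomes`, `anchor_x` and the lead identifiers.
#' @export
build_alignment <- function(lead_gene, genomes, orthologs, scale = 10,
                            canvas_width = 1000L,
                            scale_min = 0.1, scale_max = NULL) {
  stopifnot(is.list(genomes), !is.null(names(genomes)))
  lead_genome <- NULL
  for (gid in names(genomes)) {
    if (lead_gene %in% genomes[[gid]]$features$id) { lead_genome <- gid; break }
  }
  if (is.null(lead_genome)) {
    stop("lead gene '", lead_gene, "' not found in any supplied genome")
  }
  lead_group <- lookup_group(orthologs, lead_genome, lead_gene)
  if (is.na(lead_group)) {
    stop("lead gene '", lead_gene,
         "' is absent from the ortholog table; nothing to anchor on")
  }
  order_ids <- c(lead_genome, setdiff(names(genomes), lead_genome))
  anchor_x <- canvas_width / 2
  anchor_off <- as.integer(floor(anchor_x * scale))
  if (is.null(scale_max)) {
    scale_max <- max(vapply(genomes, function(r) r$length, numeric(1)) /
                       canvas_width)
  }
  rows <- list()
  excluded <- character(0)
  for (gid in order_ids) {
    rep <- genomes[[gid]]
    members <- orthologs[orthologs$genome_id == gid &
                           orthologs$group_id == lead_group, , drop = FALSE]
    anchor_id <- if (gid == lead_genome) lead_gene
                 else if (nrow(members)) members$gene_id[1] else NA_character_
    if (is.na(anchor_id) || !anchor_id %in% rep$features$id) {
      excluded <- c(excluded, gid)
      next
    }
    anchor <- rep$features[rep$features$id == anchor_id, ][1, ]
    center <- feature_center(anchor, rep)
    vs <- center - anchor_off
    if (rep$topology == "circular") vs <- wrap_coord(vs, rep$length)
    view <- view_state(rep, view_start = vs, scale = scale,
                       canvas_width = canvas_width, n_lines = 1L,
                       wrap = FALSE, scale_min = scale_min,
                       scale_max = scale_max)
    # linear replicons keep the unclamped start so the anchor stays centered
    view$view_start <- as.integer(vs)
    rows[[gid]] <- list(genome_id = gid, view = view,
                        anchor_gene = anchor_id, anchor_center = center)
  }
  lead_rep <- genomes[[lead_genome]]
  lead_view <- rows[[lead_genome]]$view
  color_map <- assign_ortholog_colors(
    groups_in_lead_order(lead_rep, lead_view, orthologs, lead_genome))
  structure(list(rows = rows, color_map = color_map,
                 excluded_genomes = excluded, lead_genome = lead_genome,
                 lead_gene = lead_gene, lead_group = lead_group,
                 anchor_x = anchor_x, orthologs = orthologs),
            class = "comparative_layout")
}

# ortholog groups of the lead genome's visible genes, in first-appearance
# order along the lead row (ascending offset from the row's left edge)
groups_in_lead_order <- function(lead_rep, lead_view, orthologs,
                                 lead_genome) {
  f <- lead_rep$features[lead_rep$features$kind %in% GENE_KINDS, ,
                         drop = FALSE]
  if (nrow(f) == 0L) return(character(0))
  off <- vapply(seq_len(nrow(f)), function(i) {
    o <- view_offset(lead_view, f$start[i])
    if (is.na(o)) Inf else as.numeric(o)
  }, numeric(1))
  f <- f[order(off, f$start), , drop = FALSE]
  groups <- vapply(f$id, function(id) lookup_group(orthologs, lead_genome, id),
                   character(1))
  unique(groups[!is.na(groups)])
}

#' Assign recycled palette colors to ortholog groups
#'
#' Only a dozen colors are available: group *i* (in first-appearance order
#' along the lead genome) receives palette index `(i - 1) mod 12`, so
#' colors are recycled after the dozen have been used and some same-color
#' genes are not orthologs. Genes with no group (or whose group has no
#' member in the lead row) are drawn gray by the renderer.
#'
#' @param groups Ordered character vector of ortholog group ids.
#' @param n_colors Palette size (default 12).
#' @return Named integer vector of 0-based palette indices.
#' @export
assign_ortholog_colors <- function(groups, n_colors = 12L) {
  if (!length(groups)) return(stats::setNames(integer(0), character(0)))
  stats::setNames((seq_along(groups) - 1L) %% as.integer(n_colors), groups)
}

#' All glyph-level orthologs of a gene in a comparative layout
#'
#' Static stand-in for hover highlighting: returns every (genome, gene)
#' pair in the layout whose feature shares the query gene's ortholog
#' group. The relation is symmetric; a gene with no group highlights only
#' itself.
#'
#' @param gene_id Feature id of the query gene.
#' @param layout A `"comparative_layout"`.
#' @return Data frame with `genome_id` and `gene_id` columns.
#' @export
ortholog_highlight <- function(gene_id, layout) {
  orthologs <- layout$orthologs
  own <- data.frame(genome_id = character(0), gene_id = character(0),
                    stringsAsFactors = FALSE)
  for (row in layout$rows) {
    if (gene_id %in% row$view$replicon$features$id) {
      own <- data.frame(genome_id = row$genome_id, gene_id = gene_id,
                        stringsAsFactors = FALSE)
      break
    }
  }
  if (nrow(own) == 0L) stop("gene '", gene_id, "' is not in the layout")
  grp <- lookup_group(orthologs, own$genome_id, gene_id)
  if (is.na(grp)) return(own)
  in_layout <- names(layout$rows)
  hits <- orthologs[orthologs$group_id == grp &
                      orthologs$genome_id %in% in_layout, , drop = FALSE]
  out <- hits[, c("genome_id", "gene_id")]
  rownames(out) <- NULL
  out
}

rebuild_alignment <- function(layout, scale) {
  genomes <- lapply(layout$rows, function(r) r$view$replicon)
  names(genomes) <- names(layout$rows)
  first <- layout$rows[[1]]$view
  build_alignment(layout$lead_gene, genomes, layout$orthologs,
                  scale = scale, canvas_width = first$canvas_width,
                  scale_min = first$scale_min, scale_max = first$scale_max)
}

#' Synchronized zoom of a comparative layout
#'
#' Applies one zoom factor to every row about the shared anchor column, so
#' all genomes zoom in lockstep and the anchor centers stay aligned.
#'
#' @param layout A `"comparative_layout"`.
#' @param factor Positive zoom factor.
#' @return A new `"comparative_layout"` at the clamped scale.
#' @export
zoom_comparative <- function(layout, factor) {
  stopifnot(factor > 0)
  v <- layout$rows[[1]]$view
  rebuild_alignment(layout, clamp(v$scale * factor, v$scale_min, v$scale_max))
}

#' Synchronized pan of a comparative layout
#'
#' Shifts every row by the same signed number of bases; relative alignment
#' between rows is preserved.
#'
#' @param layout A `"comparative_layout"`.
#' @param delta Signed base offset.
#' @return A new `"comparative_layout"`.
#' @export
pan_comparative <- function(layout, delta) {
  delta <- as.integer(delta)
  layout$rows <- lapply(layout$rows, function(row) {
    vs <- row$view$view_start + delta
    if (row$view$replicon$topology == "circular") {
      vs <- wrap_coord(vs, row$view$replicon$length)
    }
    row$view$view_start <- as.integer(vs)
    row
  })
  layout
}

#' @export
print.comparative_layout <- function(x, ...) {
  cat(sprintf(
    "<comparative> lead %s/%s (group %s): %d row(s), %d excluded, %d colored group(s)\n",
    x$lead_genome, x$lead_gene, x$lead_group, length(x$rows),
    length(x$excluded_genomes), length(x$color_map)))
  invisible(x)
}
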