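# SVG serialization of layouts. Rendering is a pure function of
# (layout, style, options): identical inputs yield byte-identical SVG.
# Every glyph is one <g class="glyph"> carrying machine-readable data-*
# attributes and a <title> with the tooltip text.

fmt <- function(x) {
  s <- formatC(x, format = "f", digits = 2)
  sub("\\.$", "", sub("0+$", "", s))
}

svg_doc <- function(width, height) {
  doc <- xml2::xml_new_root(
    "svg", xmlns = "http://www.w3.org/2000/svg",
    width = fmt(width), height = fmt(height),
    viewBox = paste(0, 0, fmt(width), fmt(height)))
  xml2::xml_add_child(doc, "rect", x = "0", y = "0", width = fmt(width),
                      height = fmt(height), fill = "#ffffff",
                      class = "background")
  doc
}

add_el <- function(parent, name, ...) {
  args <- list(...)
  args <- args[!vapply(args, is.null, logical(1))]
  do.call(xml2::xml_add_child,
          c(list(.x = parent, .value = name), lapply(args, as.character)))
}

#' Per-kind glyph style vocabulary
#'
#' The shape spec for each feature kind: protein-coding genes are
#' directional arrow blocks, RNA genes short colored blocks, pseudogenes
#' gray blocks with an X, transcription start sites bent arrows labeled
#' with their sigma factor, terminators stem ("lollipop") glyphs,
#' TF-binding sites small boxes labeled with the bound factor, and operons
#' gray background boxes.
#'
#' @param gene_height,site_height Glyph heights in pixels.
#' @param fills Named character vector of default fills per kind.
#' @return A list of class `"glyph_style"` with one entry per feature kind.
#' @export
glyph_style <- function(gene_height = 14, site_height = 10,
                        fills = c(protein_gene = "#4878a8",
                                  rna_gene = "#9467bd",
                                  pseudogene = "#9e9e9e",
                                  transcription_unit = "#d9d9d9",
                                  tss = "#333333",
                                  terminator = "#b22222",
                                  tfbs = "#2ca02c",
                                  other_site = "#777777")) {
  stopifnot(all(FEATURE_KINDS %in% names(fills)))
  structure(list(gene_height = gene_height, site_height = site_height,
                 fills = fills,
                 shapes = c(protein_gene = "arrow", rna_gene = "block",
                            pseudogene = "block_x",
                            transcription_unit = "box", tss = "bent_arrow",
                            terminator = "stem", tfbs = "labeled_box",
                            other_site = "block")),
            class = "glyph_style")
}

draw_glyph_shape <- function(g, row, y, style) {
  x1 <- row$x_start; x2 <- row$x_end; w <- x2 - x1
  fill <- if (!is.null(row$fill) && !is.na(row$fill)) row$fill
          else unname(style$fills[[row$kind]])
  gh <- style$gene_height; sh <- style$site_height
  if (row$kind == "protein_gene") {
    tip <- min(max(4, 0.25 * w), w)
    ym <- y + gh / 2
    pts <- if (row$strand == "+") {
      c(x1, y, x2 - tip, y, x2, ym, x2 - tip, y + gh, x1, y + gh)
    } else {
      c(x2, y, x1 + tip, y, x1, ym, x1 + tip, y + gh, x2, y + gh)
    }
    m <- matrix(pts, ncol = 2, byrow = TRUE)
    add_el(g, "polygon",
           points = paste(paste(fmt(m[, 1]), fmt(m[, 2]), sep = ","),
                          collapse = " "),
           fill = fill, stroke = "#222222", `stroke-width` = "0.5")
  } else if (row$kind %in% c("rna_gene", "pseudogene", "other_site")) {
    add_el(g, "rect", x = fmt(x1), y = fmt(y + 2), width = fmt(w),
           height = fmt(gh - 4), fill = fill, stroke = "#222222",
           `stroke-width` = "0.5")
    if (row$kind == "pseudogene" && w >= 6) {
      add_el(g, "line", x1 = fmt(x1), y1 = fmt(y + 2), x2 = fmt(x2),
             y2 = fmt(y + gh - 2), stroke = "#444444", `stroke-width` = "1")
      add_el(g, "line", x1 = fmt(x1), y1 = fmt(y + gh - 2), x2 = fmt(x2),
             y2 = fmt(y + 2), stroke = "#444444", `stroke-width` = "1")
    }
  } else if (row$kind == "tss") {
    # bent arrow: vertical stem then a horizontal arm in strand direction
    xs <- if (row$strand == "+") x1 else x2
    arm <- if (row$strand == "+") xs + max(w, 6) else xs - max(w, 6)
    add_el(g, "path",
           d = paste0("M", fmt(xs), " ", fmt(y + sh), " L", fmt(xs), " ",
                      fmt(y), " L", fmt(arm), " ", fmt(y)),
           fill = "none", stroke = fill, `stroke-width` = "1.2")
  } else if (row$kind == "terminator") {
    xc <- (x1 + x2) / 2
    add_el(g, "line", x1 = fmt(xc), y1 = fmt(y + sh), x2 = fmt(xc),
           y2 = fmt(y + 2), stroke = fill, `stroke-width` = "1.2")
    add_el(g, "line", x1 = fmt(xc - 3), y1 = fmt(y + 2), x2 = fmt(xc + 3),
           y2 = fmt(y + 2), stroke = fill, `stroke-width` = "1.2")
  } else if (row$kind == "tfbs") {
    add_el(g, "rect", x = fmt(x1), y = fmt(y + 2), width = fmt(w),
           height = fmt(sh - 2), fill = fill, stroke = "#222222",
           `stroke-width` = "0.5")
  } else {  # transcription_unit box
    add_el(g, "rect", x = fmt(x1), y = fmt(y), width = fmt(w),
           height = fmt(gh), fill = fill, `fill-opacity` = "0.5")
  }
}

add_glyph_group <- function(parent, row, y, style, extra_label = NULL) {
  g <- add_el(parent, "g", class = "glyph",
              `data-feature` = row$feature_id, `data-kind` = row$kind,
              `data-start` = row$seg_start, `data-end` = row$seg_end,
              `data-strand` = row$strand,
              `data-group` = if (!is.null(row$group) && !is.na(row$group))
                row$group else NULL)
  title <- add_el(g, "title")
  xml2::xml_text(title) <- row$tooltip
  draw_glyph_shape(g, row, y, style)
  if (isTRUE(row$show_name)) {
    txt <- row$label
    pl <- row$product_label %||% NA_character_
    if (isTRUE(row$show_product) && !is.na(pl)) txt <- paste(row$label, pl)
    t <- add_el(g, "text", x = fmt((row$x_start + row$x_end) / 2),
                y = fmt(y + style$gene_height - 3), `text-anchor` = "middle",
                `font-size` = "9", `font-family` = "monospace",
                fill = "#000000", class = "label")
    xml2::xml_text(t) <- txt
  }
  if (row$kind == "tss" && !is.na(row$site_label %||% NA_character_)) {
    t <- add_el(g, "text", x = fmt(row$x_start),
                y = fmt(y + style$site_height + 8), `font-size` = "7",
                `font-family` = "monospace", class = "sitelabel")
    xml2::xml_text(t) <- row$site_label
  }
  if (row$kind == "tfbs" && !is.na(row$site_label %||% NA_character_)) {
    t <- add_el(g, "text", x = fmt(row$x_start),
                y = fmt(y - 2), `font-size` = "7",
                `font-family` = "monospace", class = "sitelabel")
    xml2::xml_text(t) <- row$site_label
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# vertical extents of each wrapped line, given its stacked lane counts
line_geometry <- function(layout, style) {
  glyphs <- layout$glyphs
  seq_h <- if (layout$show_sequence_letters &&
               !is.null(layout$view$replicon$sequence)) 14 else 0
  do.call(rbind, lapply(layout$lines$line, function(l) {
    on_line <- glyphs[glyphs$line == l, , drop = FALSE]
    site <- on_line[on_line$lane_class %in% SITE_KINDS, , drop = FALSE]
    gene <- on_line[on_line$lane_class == "gene", , drop = FALSE]
    site_lanes <- if (nrow(site)) max(site$lane) + 1L else 1L
    gene_lanes <- if (nrow(gene)) max(gene$lane) + 1L else 1L
    data.frame(line = l,
               site_lanes = site_lanes, gene_lanes = gene_lanes,
               height = 14 + site_lanes * (style$site_height + 10) +
                 gene_lanes * (style$gene_height + 2) + seq_h + 6,
               seq_h = seq_h)
  }))
}

render_line_content <- function(parent, layout, style, geo, y0, fills = NULL,
                                groups = NULL) {
  glyphs <- layout$glyphs
  opts <- layout$opts
  view <- layout$view
  for (li in seq_len(nrow(geo))) {
    l <- geo$line[li]
    lr <- layout$lines[layout$lines$line == l, ]
    y_line <- y0 + if (li > 1) sum(geo$height[seq_len(li - 1)]) else 0
    y_sites <- y_line + 10
    y_genes <- y_sites + geo$site_lanes[li] * (style$site_height + 10)
    # line start-coordinate tick
    t <- add_el(parent, "text", x = "0", y = fmt(y_line + 8),
                `font-size` = "8", `font-family` = "monospace",
                fill = "#666666", class = "coord")
    xml2::xml_text(t) <- as.character(lr$start[1])
    # operon boxes sit behind the gene glyphs and never stack
    ob <- layout$operon_boxes[layout$operon_boxes$line == l, , drop = FALSE]
    for (bi in seq_len(nrow(ob))) {
      add_el(parent, "rect", x = fmt(ob$x_start[bi]), y = fmt(y_genes - 2),
             width = fmt(ob$x_end[bi] - ob$x_start[bi]),
             height = fmt(geo$gene_lanes[li] * (style$gene_height + 2) + 2),
             fill = "#d9d9d9", `fill-opacity` = "0.6", class = "operon-box",
             `data-operon` = ob$operon_id[bi])
    }
    on_line <- glyphs[glyphs$line == l, , drop = FALSE]
    for (gi in seq_len(nrow(on_line))) {
      row <- as.list(on_line[gi, ])
      row$site_label <- NA_character_
      f <- view$replicon$features
      frow <- f[f$id == row$feature_id, , drop = FALSE][1, ]
      if (row$kind == "tss") row$site_label <- frow$sigma_factor
      if (row$kind == "tfbs") row$site_label <- frow$bound_factor
      if (isTRUE(row$show_product)) row$product_label <- frow$product
      if (!is.null(fills)) row$fill <- fills[[row$feature_id]] %||% NA
      if (!is.null(groups)) row$group <- groups[[row$feature_id]] %||% NA
      y <- if (row$lane_class %in% SITE_KINDS) {
        y_sites + row$lane * (style$site_height + 10)
      } else {
        y_genes + row$lane * (style$gene_height + 2)
      }
      add_glyph_group(parent, row, y, style)
    }
    # nucleotide letters at sequence-level zoom
    if (geo$seq_h[li] > 0) {
      reg <- structure(list(replicon = view$replicon, start = lr$start[1],
                            end = lr$end[1], strand = "+"),
                       class = "selected_region")
      t <- add_el(parent, "text", x = "0",
                  y = fmt(y_line + geo$height[li] - 8), `font-size` = "10",
                  `font-family` = "monospace", class = "sequence",
                  textLength = fmt(view$canvas_width),
                  lengthAdjust = "spacingAndGlyphs")
      xml2::xml_text(t) <- extract_nt(reg)
    }
  }
}

#' Render the full-replicon overview bar
#'
#' A bar scaled to the canvas width representing the whole replicon, with
#' a red rectangle marking the region shown at higher resolution: its
#' fractional position is `view_start / length` and its fractional width
#' `visible_span / length`. A circular view spanning the origin draws two
#' red segments.
#'
#' @param rep A [replicon()].
#' @param view The current [view_state()].
#' @param canvas_width Bar width in pixels (defaults to the view's canvas).
#' @param height Bar height in pixels.
#' @return An `xml2` `<g class="overview">` node (standalone document).
#' @export
render_overview_bar <- function(rep, view, canvas_width = view$canvas_width,
                                height = 14) {
  g <- xml2::xml_new_root("g", class = "overview")
  add_el(g, "rect", x = "0", y = "0", width = fmt(canvas_width),
         height = fmt(height), fill = "#e8e8e8", stroke = "#888888",
         `stroke-width` = "0.5")
  L <- rep$length
  vs <- wrap_coord(max(view$view_start, 1L), L)
  span <- min(visible_span(view), L)
  px_per_base <- canvas_width / L
  x1 <- (vs - 1) * px_per_base
  w <- span * px_per_base
  seg <- function(x, wd) {
    add_el(g, "rect", x = fmt(x), y = "0", width = fmt(max(wd, 1)),
           height = fmt(height), fill = "none", stroke = "#d62728",
           `stroke-width` = "1.5", class = "view-marker")
  }
  if (rep$topology == "circular" && vs + span - 1L > L) {
    w1 <- (L - vs + 1) * px_per_base
    seg(x1, w1)
    seg(0, w - w1)
  } else {
    seg(x1, min(w, canvas_width - x1))
  }
  g
}

#' Render the legend of graphical conventions
#'
#' One row per feature kind showing its glyph sample and the current
#' On/Off/Auto setting — a static depiction of the legend's tri-state
#' checkboxes. Emitted only on request (see `include_legend` in
#' [render_svg()]).
#'
#' @param policy A [display_policy()].
#' @param style A [glyph_style()].
#' @return An `xml2` `<g class="legend">` node (standalone document).
#' @export
render_legend <- function(policy = display_policy(), style = glyph_style()) {
  g <- xml2::xml_new_root("g", class = "legend")
  kind_labels <- c(protein_gene = "protein-coding gene",
                   rna_gene = "RNA-coding gene", pseudogene = "pseudogene",
                   transcription_unit = "transcription unit (operon)",
                   tss = "transcription start site",
                   terminator = "terminator",
                   tfbs = "transcription factor binding site",
                   other_site = "other site")
  for (i in seq_along(FEATURE_KINDS)) {
    kind <- FEATURE_KINDS[i]
    y <- (i - 1) * 18
    row <- list(feature_id = paste0("legend_", kind), kind = kind,
                x_start = 0, x_end = 28, strand = "+",
                seg_start = 0, seg_end = 0, show_name = FALSE,
                show_product = FALSE, label = kind,
                tooltip = kind_labels[[kind]], fill = NA)
    entry <- add_el(g, "g", class = "legend-row", `data-kind` = kind,
                    `data-setting` = unclass(policy)[[kind]])
    draw_glyph_shape(entry, row, y, style)
    t <- add_el(entry, "text", x = "36", y = fmt(y + 11),
                `font-size` = "9", `font-family` = "sans-serif")
    xml2::xml_text(t) <- sprintf("%s [%s]", kind_labels[[kind]],
                                 unclass(policy)[[kind]])
  }
  g
}

copy_node_into <- function(parent, node, x = 0, y = 0) {
  holder <- add_el(parent, "g",
                   transform = sprintf("translate(%s %s)", fmt(x), fmt(y)))
  xml2::xml_add_child(holder, node)
  holder
}

#' Render a layout to SVG text
#'
#' Serializes a basic-mode [layout()], a comparative [build_alignment()]
#' layout, or a [compose_tracks_view()] result into a standalone SVG 1.1
#' document. Each glyph becomes one `<g class="glyph">` carrying
#' `data-feature`/`data-kind`/`data-start`/`data-end` (and `data-group`
#' for ortholog-colored genes) attributes plus a `<title>` tooltip, so
#' tooltips are available at all zoom levels. Output is deterministic:
#' the same layout renders to byte-identical text.
#'
#' @param x A `"layout_result"`, `"comparative_layout"` or `"tracks_view"`.
#' @param ... Passed to methods: `style` (a [glyph_style()]),
#'   `include_overview`, `include_legend`.
#' @return SVG document as a single character string.
#' @export
render_svg <- function(x, ...) UseMethod("render_svg")

#' @rdname render_svg
#' @param style A [glyph_style()].
#' @param include_overview Draw the full-replicon overview bar on top.
#' @param include_legend Append the legend (off unless requested).
#' @export
render_svg.layout_result <- function(x, style = glyph_style(),
                                     include_overview = TRUE,
                                     include_legend = FALSE, ...) {
  geo <- line_geometry(x, style)
  y0 <- if (include_overview) 26 else 4
  legend_h <- if (include_legend) 8 * 18 + 12 else 0
  total_h <- y0 + sum(geo$height) + legend_h + 4
  doc <- svg_doc(x$view$canvas_width, total_h)
  if (include_overview) {
    copy_node_into(doc, render_overview_bar(x$view$replicon, x$view), 0, 4)
  }
  # operon coloring: adjacent genes of one operon share a fill, operons
  # cycle through the recycled palette in order of appearance
  g <- x$glyphs
  og <- g[g$lane_class == "gene" & !is.na(g$operon_id) &
            g$kind != "pseudogene", , drop = FALSE]
  fills <- NULL
  if (nrow(og)) {
    ops <- unique(og$operon_id[order(og$line, og$x_start)])
    fills <- list()
    for (i in seq_len(nrow(og))) {
      idx <- (match(og$operon_id[i], ops) - 1L) %% length(x$opts$palette)
      fills[[og$feature_id[i]]] <- x$opts$palette[idx + 1L]
    }
  }
  render_line_content(doc, x, style, geo, y0, fills = fills)
  if (include_legend) {
    copy_node_into(doc, render_legend(x$policy, style), 8,
                   y0 + sum(geo$height) + 8)
  }
  as.character(doc)
}

#' @rdname render_svg
#' @param policy A [display_policy()] applied to every genome row.
#' @param opts A [render_options()].
#' @export
render_svg.comparative_layout <- function(x, style = glyph_style(),
                                          policy = display_policy(),
                                          opts = render_options(), ...) {
  row_gap <- 16
  rows <- x$rows
  layouts <- lapply(rows, function(r) layout(r$view, policy, opts))
  geos <- lapply(layouts, line_geometry, style = style)
  heights <- vapply(geos, function(g) sum(g$height) + row_gap, numeric(1))
  cw <- rows[[1]]$view$canvas_width
  doc <- svg_doc(cw, sum(heights) + 8)
  # shared anchor column marker
  add_el(doc, "line", x1 = fmt(x$anchor_x), y1 = "0", x2 = fmt(x$anchor_x),
         y2 = fmt(sum(heights) + 8), stroke = "#bbbbbb",
         `stroke-dasharray` = "4 3", class = "anchor-column")
  y <- 4
  for (i in seq_along(rows)) {
    gid <- rows[[i]]$genome_id
    t <- add_el(doc, "text", x = "2", y = fmt(y + 8), `font-size` = "9",
                `font-family` = "sans-serif", fill = "#333333",
                class = "genome-label")
    xml2::xml_text(t) <- gid
    # fills: palette by ortholog group along the lead row, gray otherwise
    feats <- rows[[i]]$view$replicon$features
    fills <- list(); groups <- list()
    for (fi in seq_len(nrow(feats))) {
      if (!feats$kind[fi] %in% GENE_KINDS) next
      grp <- lookup_group(x$orthologs, gid, feats$id[fi])
      groups[[feats$id[fi]]] <- grp
      fills[[feats$id[fi]]] <-
        if (!is.na(grp) && grp %in% names(x$color_map)) {
          opts$palette[(x$color_map[[grp]] %% length(opts$palette)) + 1L]
        } else {
          opts$gray_fill
        }
    }
    render_line_content(doc, layouts[[i]], style, geos[[i]], y + 10,
                        fills = fills, groups = groups)
    y <- y + heights[i]
  }
  as.character(doc)
}

#' @rdname render_svg
#' @export
render_svg.tracks_view <- function(x, style = glyph_style(), ...) {
  geo <- line_geometry(x$inline, style)
  strip_gap <- 22
  strip_heights <- vapply(x$strips, function(s)
    attr(s, "config")$height + strip_gap, numeric(1))
  y0 <- 4
  total_h <- y0 + sum(geo$height) + sum(strip_heights) + 8
  cw <- x$view$canvas_width
  doc <- svg_doc(cw, total_h)
  render_line_content(doc, x$inline, style, geo, y0)
  y <- y0 + sum(geo$height) + 8
  for (si in seq_along(x$strips)) {
    strip <- x$strips[[si]]
    cfg <- attr(strip, "config")
    sg <- add_el(doc, "g", class = "track", `data-style` = cfg$style,
                 `data-ymin` = fmt(cfg$y_min), `data-ymax` = fmt(cfg$y_max))
    add_el(sg, "rect", x = "0", y = fmt(y), width = fmt(cw),
           height = fmt(cfg$height), fill = "none", stroke = "#cccccc",
           `stroke-width` = "0.5")
    for (lbl in list(c(cfg$y_max, y + 8), c(cfg$y_min, y + cfg$height - 1))) {
      t <- add_el(sg, "text", x = "2", y = fmt(lbl[2]), `font-size` = "7",
                  `font-family` = "monospace", fill = "#666666",
                  class = "axis")
      xml2::xml_text(t) <- fmt(lbl[1])
    }
    for (ri in seq_len(nrow(strip))) {
      r <- strip[ri, ]
      g <- add_el(sg, "g", class = "track-glyph",
                  `data-score` = if (is.na(r$score)) "." else fmt(r$score))
      title <- add_el(g, "title")
      xml2::xml_text(title) <- sprintf("%s score=%s", r$name,
                                       if (is.na(r$score)) "." else
                                         fmt(r$score))
      if (r$style == "point_graph") {
        add_el(g, "circle", cx = fmt(r$x_start), cy = fmt(y + r$y),
               r = "2", fill = r$fill)
      } else {
        add_el(g, "rect", x = fmt(r$x_start), y = fmt(y + r$y),
               width = fmt(max(r$x_end - r$x_start, 0.5)),
               height = fmt(max(r$height, 0.5)), fill = r$fill)
      }
    }
    y <- y + strip_heights[si]
  }
  as.character(doc)
}
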