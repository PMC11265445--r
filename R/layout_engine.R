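# The layout engine: view geometry, book-style line wrapping, semantic-zoom
# visibility, genome<->canvas transforms, and greedy lane stacking. All
# pixel arithmetic is pure so rendered output is deterministic.

#' Create a view state
#'
#' The visible genome window plus scale and canvas geometry; the root of all
#' coordinate transforms. `scale` is in bases per pixel: smaller values are
#' finer zoom. With `wrap = TRUE` the view covers `n_lines` book-style
#' wrapped lines of `floor(canvas_width * scale)` bases each.
#'
#' @param rep A [replicon()].
#' @param view_start 1-based coordinate of the first visible base. On
#'   circular replicons any integer is wrapped into range; on linear
#'   replicons values outside `[1, length]` are allowed only for unwrapped
#'   single-line views (comparative margins).
#' @param scale Bases per pixel (positive; `canvas_width * scale >= 1`).
#' @param canvas_width Canvas width in pixels.
#' @param n_lines Number of wrapped lines (1 in comparative/tracks modes).
#' @param wrap Wrap lines book-style? Forced single-line when `FALSE`.
#' @param scale_min,scale_max Zoom clamp bounds in bases/pixel. The default
#'   coarse bound shows the whole replicon in one unwrapped screen; see
#'   [physical_zoom_preset()] for the published physical-units preset.
#' @return An object of class `"view_state"`.
#' @export
view_state <- function(rep, view_start = 1L, scale = 1, canvas_width = 1000L,
                       n_lines = 1L, wrap = TRUE,
                       scale_min = 0.1, scale_max = NULL) {
  stopifnot(inherits(rep, "replicon"), scale > 0, canvas_width >= 1,
            n_lines >= 1)
  if (floor(canvas_width * scale) < 1) {
    stop("canvas_width * scale must be >= 1 base per line")
  }
  if (is.null(scale_max)) {
    scale_max <- max(rep$length / canvas_width, scale_min)
  }
  view_start <- as.integer(round(view_start))
  if (rep$topology == "circular") view_start <- wrap_coord(view_start, rep$length)
  structure(list(
    replicon = rep, view_start = view_start, scale = scale,
    canvas_width = as.integer(canvas_width), n_lines = as.integer(n_lines),
    wrap = isTRUE(wrap), scale_min = scale_min, scale_max = scale_max
  ), class = "view_state")
}

#' @export
print.view_state <- function(x, ...) {
  cat(sprintf("<view> %s @%d, %.4g b/px, %d px, %d line(s)%s, span %d bp\n",
              x$replicon$id, x$view_start, x$scale, x$canvas_width,
              x$n_lines, if (x$wrap) " wrapped" else "", visible_span(x)))
  invisible(x)
}

#' Bases covered by one wrapped line
#' @param view A [view_state()].
#' @return Integer number of bases per line, `floor(canvas_width * scale)`.
#' @export
bases_per_line <- function(view) {
  max(1L, as.integer(floor(view$canvas_width * view$scale)))
}

# nominal (unclipped) span in bases covered by the view's lines
raw_span <- function(view) {
  bpl <- bases_per_line(view)
  if (view$wrap) view$n_lines * bpl else bpl
}

#' Number of visible bases in a view
#'
#' The wrapped line span clamped at the replicon: circular views wrap
#' modulo the length (never exceeding one full turn), linear views clip at
#' the replicon ends.
#' @param view A [view_state()].
#' @return Integer span in bases.
#' @export
visible_span <- function(view) {
  L <- view$replicon$length
  raw <- raw_span(view)
  if (view$replicon$topology == "circular") return(min(raw, L))
  lo <- max(view$view_start, 1L)
  hi <- min(view$view_start + raw - 1L, L)
  max(hi - lo + 1L, 0L)
}

#' Split a view into per-line genome ranges
#'
#' Book-style wrapping: `n_lines` consecutive ranges of `bases_per_line`
#' bases starting at `view_start`; the last line is clamped at a linear
#' replicon's end, and circular views wrap through the origin (a line
#' crossing the origin has `start > end` and `wraps = TRUE`).
#'
#' @param view A [view_state()].
#' @return Data frame with columns `line` (0-based), `start`, `end`
#'   (1-based inclusive genome coordinates) and `wraps`.
#' @export
wrap_view <- function(view) {
  bpl <- bases_per_line(view)
  L <- view$replicon$length
  n <- if (view$wrap) view$n_lines else 1L
  out <- vector("list", n)
  if (view$replicon$topology == "circular") {
    span <- min(raw_span(view), L)
    for (l in seq_len(n) - 1L) {
      o1 <- l * bpl
      o2 <- min((l + 1L) * bpl, span) - 1L
      if (o1 > o2) break
      s <- wrap_coord(view$view_start + o1, L)
      e <- wrap_coord(view$view_start + o2, L)
      out[[l + 1L]] <- data.frame(line = l, start = s, end = e,
                                  wraps = (o2 - o1 + 1L > 1L) && s > e)
    }
  } else {
    lo <- max(view$view_start, 1L)
    hi <- min(view$view_start + raw_span(view) - 1L, L)
    for (l in seq_len(n) - 1L) {
      s <- max(view$view_start + l * bpl, lo)
      e <- min(view$view_start + (l + 1L) * bpl - 1L, hi)
      if (s > e) next
      out[[l + 1L]] <- data.frame(line = l, start = s, end = e, wraps = FALSE)
    }
  }
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame(line = integer(0), start = integer(0),
                                      end = integer(0), wraps = logical(0))
  out
}

# forward offset (bases) of coord from view_start; NA when out of view
view_offset <- function(view, coord) {
  L <- view$replicon$length
  if (view$replicon$topology == "circular") {
    off <- (as.integer(coord) - view$view_start) %% L
    ifelse(off < min(raw_span(view), L), off, NA_integer_)
  } else {
    off <- as.integer(coord) - view$view_start
    ifelse(off >= 0L & off < raw_span(view) & coord >= 1L &
             coord <= L, off, NA_integer_)
  }
}

#' Map a genome coordinate to canvas position
#'
#' @param view A [view_state()].
#' @param coord 1-based genome coordinate.
#' @return List with `in_view` (logical), `line` (0-based line index) and
#'   `x` (pixels from the line's left edge); `line`/`x` are `NA` when the
#'   coordinate lies outside the visible span (caller clips).
#' @export
genome_to_canvas <- function(view, coord) {
  off <- view_offset(view, coord)
  if (is.na(off)) return(list(in_view = FALSE, line = NA_integer_, x = NA_real_))
  bpl <- bases_per_line(view)
  list(in_view = TRUE, line = as.integer(off %/% bpl),
       x = (off %% bpl) / view$scale)
}

#' Map a canvas position back to a genome coordinate
#'
#' Inverse of [genome_to_canvas()]; round trips are exact to within one
#' base (pixel positions inside one base all map to that base).
#'
#' @param view A [view_state()].
#' @param line 0-based line index.
#' @param x Pixels from the line's left edge.
#' @return 1-based genome coordinate.
#' @export
canvas_to_genome <- function(view, line, x) {
  off <- as.integer(line) * bases_per_line(view) +
    as.integer(floor(x * view$scale + 1e-9))
  coord <- view$view_start + off
  if (view$replicon$topology == "circular") {
    coord <- wrap_coord(coord, view$replicon$length)
  }
  coord
}

#' Semantic-zoom visibility directives for one feature
#'
#' Applies the legend tri-state and the semantic-zooming rules: `Off` is
#' absolute; `On` always draws (with a minimum glyph size); under `Auto`,
#' gene-like glyphs appear once their rendered width reaches a pixel
#' threshold and sites appear once the scale is fine enough. Name labels
#' appear when they fit in the glyph at a fixed character width, product
#' labels when name and product both fit, and sequence letters once there
#' are enough pixels per base.
#'
#' @param feature One-row feature data frame.
#' @param view A [view_state()].
#' @param policy A [display_policy()].
#' @param opts A [render_options()].
#' @return List with logicals `draw`, `show_name`, `show_product`,
#'   `show_sequence_letters`.
#' @export
visibility <- function(feature, view, policy = display_policy(),
                       opts = render_options()) {
  setting <- unclass(policy)[[feature$kind]]
  px <- circular_span_length(feature$start, feature$end, view$replicon) /
    view$scale
  draw <- if (setting == "Off") {
    FALSE
  } else if (setting == "On") {
    TRUE
  } else if (feature$kind %in% SITE_KINDS) {
    view$scale <= opts$site_scale_threshold
  } else {
    px >= opts$gene_px_threshold
  }
  nm <- feature$name
  show_name <- draw && !is.na(nm) && nzchar(nm) &&
    px >= nchar(nm) * opts$char_width
  pr <- feature$product
  show_product <- show_name && !is.na(pr) && nzchar(pr) &&
    px >= (nchar(nm) + 1L + nchar(pr)) * opts$char_width
  list(draw = draw, show_name = show_name, show_product = show_product,
       show_sequence_letters = (1 / view$scale) >= opts$seq_px_per_base)
}

#' Stack overlapping glyphs into lanes (greedy first-fit)
#'
#' Glyphs are processed in ascending `x_start` order (longer-first on ties)
#' and each takes the lowest lane whose occupied pixel extents it does not
#' overlap. The resulting lane count equals the maximum overlap depth of
#' the intervals (half-open `[x_start, x_end)`).
#'
#' @param glyphs Data frame with numeric `x_start` and `x_end` columns.
#' @return Integer vector of 0-based lane indices, parallel to the rows.
#' @export
assign_lanes <- function(glyphs) {
  n <- nrow(glyphs)
  if (n == 0L) return(integer(0))
  ord <- order(glyphs$x_start, -(glyphs$x_end - glyphs$x_start))
  lane_end <- numeric(0)
  lanes <- integer(n)
  for (i in ord) {
    fit <- which(lane_end <= glyphs$x_start[i] + 1e-9)
    if (length(fit)) {
      l <- fit[1L]
    } else {
      lane_end <- c(lane_end, -Inf)
      l <- length(lane_end)
    }
    lane_end[l] <- glyphs$x_end[i]
    lanes[i] <- l - 1L
  }
  lanes
}

lane_class <- function(kind) {
  ifelse(kind %in% GENE_KINDS, "gene",
         ifelse(kind == "transcription_unit", "operon", kind))
}

tooltip_text <- function(f) {
  label <- if (!is.na(f$name) && nzchar(f$name)) f$name else f$id
  extras <- c(
    if (!is.na(f$product) && nzchar(f$product)) f$product,
    if (!is.na(f$sigma_factor) && nzchar(f$sigma_factor)) f$sigma_factor,
    if (!is.na(f$bound_factor) && nzchar(f$bound_factor)) f$bound_factor
  )
  sprintf("%s [%s] %d-%d (%s)%s", label, f$kind, f$start, f$end, f$strand,
          if (length(extras)) paste0(": ", paste(extras, collapse = "; ")) else "")
}

# offset intervals (0-based, inclusive) a feature occupies within the view;
# circular features may enter the window from "before" view_start as well
feature_offset_intervals <- function(view, start, end) {
  rep <- view$replicon
  len <- circular_span_length(start, end, rep)
  if (rep$topology == "circular") {
    L <- rep$length
    a <- (as.integer(start) - view$view_start) %% L
    cand <- unique(c(a, a - L))
    lim <- c(0L, min(raw_span(view), L) - 1L)
  } else {
    cand <- as.integer(start) - view$view_start
    lim <- c(max(1L, view$view_start) - view$view_start,
             min(rep$length, view$view_start + raw_span(view) - 1L) -
               view$view_start)
  }
  out <- lapply(cand, function(a) {
    s <- max(a, lim[1]); e <- min(a + len - 1L, lim[2])
    if (s > e) NULL else c(s, e, a)  # a = unclipped feature-start offset
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Lay out a view into resolved glyph placements
#'
#' Composes line wrapping, semantic-zoom visibility, the genome-to-canvas
#' transform and lane stacking. Features straddling a line break are split
#' into per-line segments; segments after the first are flagged as
#' continuations and carry no labels. Operon extents are computed per line
#' as the pixel hull of same-operon gene glyphs and sit behind them (never
#' stacked).
#'
#' @param view A [view_state()].
#' @param policy A [display_policy()].
#' @param opts A [render_options()].
#' @param features Feature data frame; defaults to the view replicon's own.
#' @return An object of class `"layout_result"`: list with `glyphs` (one
#'   row per glyph segment: pixel extents, line, lane, labels, tooltip),
#'   `lines` (per-line genome ranges from [wrap_view()]), `operon_boxes`,
#'   and the originating `view`.
#' @export
layout <- function(view, policy = display_policy(), opts = render_options(),
                   features = view$replicon$features) {
  lines <- wrap_view(view)
  bpl <- bases_per_line(view)
  glyph_rows <- list()
  show_seq <- (1 / view$scale) >= opts$seq_px_per_base
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    vis <- visibility(f, view, policy, opts)
    if (!vis$draw) next
    ivs <- feature_offset_intervals(view, f$start, f$end)
    if (!length(ivs)) next
    seg_no <- 0L
    for (iv in ivs) {
      for (l in lines$line) {
        lo <- l * bpl
        hi <- min((l + 1L) * bpl, lo + bpl) - 1L
        s <- max(iv[1], lo); e <- min(iv[2], hi)
        if (s > e) next
        seg_no <- seg_no + 1L
        x1 <- (s - lo) / view$scale
        x2 <- (e + 1L - lo) / view$scale
        min_px <- if (f$kind %in% SITE_KINDS) opts$site_min_px else 1
        if (x2 - x1 < min_px) {
          x2 <- min(x1 + min_px, view$canvas_width)
          x1 <- max(x2 - min_px, 0)
        }
        first <- seg_no == 1L
        coords <- wrap_coord(view$view_start + c(s, e), view$replicon$length)
        glyph_rows[[length(glyph_rows) + 1L]] <- data.frame(
          feature_id = f$id, kind = f$kind, lane_class = lane_class(f$kind),
          line = l, lane = 0L, x_start = x1, x_end = x2,
          strand = f$strand, seg_start = coords[1], seg_end = coords[2],
          continuation = !first,
          show_name = vis$show_name && first,
          show_product = vis$show_product && first,
          label = if (!is.na(f$name) && nzchar(f$name)) f$name else f$id,
          operon_id = f$operon_id, tooltip = tooltip_text(f),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  glyphs <- if (length(glyph_rows)) do.call(rbind, glyph_rows) else
    data.frame(feature_id = character(0), kind = character(0),
               lane_class = character(0), line = integer(0), lane = integer(0),
               x_start = numeric(0), x_end = numeric(0), strand = character(0),
               seg_start = integer(0), seg_end = integer(0),
               continuation = logical(0), show_name = logical(0),
               show_product = logical(0), label = character(0),
               operon_id = character(0), tooltip = character(0),
               stringsAsFactors = FALSE)
  if (nrow(glyphs) && opts$lane_stacking) {
    for (grp in split(seq_len(nrow(glyphs)),
                      list(glyphs$line, glyphs$lane_class), drop = TRUE)) {
      if (glyphs$lane_class[grp[1]] == "operon") next  # boxes never stack
      glyphs$lane[grp] <- assign_lanes(glyphs[grp, , drop = FALSE])
    }
  }
  ob <- glyphs[glyphs$lane_class == "gene" & !is.na(glyphs$operon_id), ,
               drop = FALSE]
  operon_boxes <- if (nrow(ob)) {
    agg <- do.call(rbind, lapply(
      split(ob, list(ob$line, ob$operon_id), drop = TRUE),
      function(d) data.frame(line = d$line[1], operon_id = d$operon_id[1],
                             x_start = min(d$x_start), x_end = max(d$x_end),
                             stringsAsFactors = FALSE)))
    agg[order(agg$line, agg$x_start), , drop = FALSE]
  } else {
    data.frame(line = integer(0), operon_id = character(0),
               x_start = numeric(0), x_end = numeric(0))
  }
  structure(list(view = view, glyphs = glyphs, lines = lines,
                 operon_boxes = operon_boxes,
                 show_sequence_letters = show_seq,
                 policy = policy, opts = opts),
            class = "layout_result")
}

#' @export
print.layout_result <- function(x, ...) {
  cat(sprintf("<layout> %d line(s), %d glyph(s), %d operon box(es)\n",
              nrow(x$lines), nrow(x$glyphs), nrow(x$operon_boxes)))
  invisible(x)
}
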