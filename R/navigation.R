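# Zoom/pan arithmetic with anchor preservation, named zoom levels, and the
# search box. All operations are pure: each returns a new view_state.

#' Physical-units zoom preset
#'
#' The browser's published working range runs from 10 bases per inch at the
#' finest zoom to about 15 kilobases per inch at the coarsest — a ratio of
#' roughly 1,500. Converted at a given screen density this yields concrete
#' bases-per-pixel bounds.
#'
#' @param dpi Screen density in pixels per inch (default 96).
#' @return List with `scale_min`, `scale_max` (bases/pixel) and `ratio`.
#' @export
physical_zoom_preset <- function(dpi = 96) {
  scale_min <- 10 / dpi
  scale_max <- 15000 / dpi
  list(scale_min = scale_min, scale_max = scale_max,
       ratio = scale_max / scale_min)
}

clamp <- function(x, lo, hi) min(max(x, lo), hi)

clamp_view_start <- function(view_start, rep, raw) {
  if (rep$topology == "circular") return(wrap_coord(view_start, rep$length))
  as.integer(clamp(view_start, 1L, max(1L, rep$length - raw + 1L)))
}

rebuild_view <- function(view, view_start, scale) {
  view_state(view$replicon, view_start = view_start, scale = scale,
             canvas_width = view$canvas_width, n_lines = view$n_lines,
             wrap = view$wrap, scale_min = view$scale_min,
             scale_max = view$scale_max)
}

#' Zoom, keeping an anchor coordinate fixed on screen
#'
#' Multiplies the scale by `factor` (clamped to the view's
#' `[scale_min, scale_max]` bounds — clamping, never failure) and shifts the
#' window so the anchor coordinate maps to the same line and pixel before
#' and after, to within one base. This models wheel zooming about the
#' mouse-pointer position; continuous zoom is a chain of small-factor
#' calls (see `render_options()$zoom_step`).
#'
#' @param view A [view_state()].
#' @param anchor Genome coordinate currently inside the visible span.
#' @param factor Positive zoom factor (> 1 zooms out, < 1 zooms in).
#' @return A new [view_state()].
#' @export
zoom_about_anchor <- function(view, anchor, factor) {
  stopifnot(factor > 0)
  pos <- genome_to_canvas(view, anchor)
  if (!pos$in_view) {
    stop("anchor ", anchor, " is outside the visible span")
  }
  eff_max <- view$scale_max
  if (view$replicon$topology == "circular") {
    # never wrap past one full turn: beyond that the anchor pixel is not
    # preservable (the same coordinate would occupy several screen lines)
    n <- if (view$wrap) view$n_lines else 1L
    eff_max <- max(view$scale_min,
                   min(eff_max, view$replicon$length /
                         (view$canvas_width * n)))
  }
  new_scale <- clamp(view$scale * factor, view$scale_min, eff_max)
  if (floor(view$canvas_width * new_scale) < 1) {
    new_scale <- 1 / view$canvas_width
  }
  new_bpl <- max(1L, as.integer(floor(view$canvas_width * new_scale)))
  off <- pos$line * new_bpl + as.integer(round(pos$x * new_scale))
  raw <- if (view$wrap) view$n_lines * new_bpl else new_bpl
  vs <- clamp_view_start(as.integer(anchor) - off, view$replicon, raw)
  rebuild_view(view, vs, new_scale)
}

#' Pan a view horizontally
#'
#' Shifts the window by a signed number of bases: clamped at the ends of a
#' linear replicon, wrapped modulo the length on a circular one.
#'
#' @param view A [view_state()].
#' @param delta Signed base offset (positive pans toward higher coordinates).
#' @return A new [view_state()].
#' @export
pan <- function(view, delta) {
  vs <- clamp_view_start(view$view_start + as.integer(delta), view$replicon,
                         raw_span(view))
  rebuild_view(view, vs, view$scale)
}

#' Jump to a named zoom level
#'
#' Sets the scale to the level's configured value, keeping the current view
#' center: `"sequence"` zooms to where nucleotide letters are legible,
#' `"gene"` to where typical genes carry name labels, `"operon"` to the
#' coarsest scale at which sites are still drawn, and `"overview"` fits the
#' whole replicon on one screen.
#'
#' @param view A [view_state()].
#' @param level One of `"sequence"`, `"gene"`, `"operon"`, `"overview"`.
#' @param opts A [render_options()] (supplies the sequence-letter and site
#'   thresholds the levels are derived from).
#' @return A new [view_state()].
#' @export
jump_to_level <- function(view, level = c("sequence", "gene", "operon",
                                          "overview"),
                          opts = render_options()) {
  level <- match.arg(level)
  L <- view$replicon$length
  if (level == "overview") {
    # whole replicon on one screen: round the per-line base count up so the
    # floor in bases_per_line cannot shave off the replicon's tail
    bpl_needed <- ceiling(L / view$n_lines)
    scale <- max((bpl_needed + 0.5) / view$canvas_width, view$scale_min)
  } else {
    scale <- switch(level,
      sequence = 1 / opts$seq_px_per_base,
      gene = 2,
      operon = opts$site_scale_threshold
    )
    scale <- clamp(scale, view$scale_min, view$scale_max)
  }
  if (floor(view$canvas_width * scale) < 1) scale <- 1 / view$canvas_width
  center <- view$view_start + visible_span(view) %/% 2L
  bpl <- max(1L, as.integer(floor(view$canvas_width * scale)))
  raw <- if (view$wrap) view$n_lines * bpl else bpl
  vs <- clamp_view_start(center - raw %/% 2L, view$replicon, raw)
  rebuild_view(view, vs, scale)
}

#' Search a replicon by name, accession, product, or coordinates
#'
#' Queries resolve in a fixed priority order: (1) a numeric range
#' `"a..b"`/`"a-b"` gives a view of exactly that region; (2) a bare integer
#' centers the view on that base; (3) a case-insensitive exact gene-name
#' match; (4) an exact accession (feature id) match; (5) a case-insensitive
#' substring match against product names, returning every hit. The
#' resolved view centers (and the renderer highlights) the first hit. No
#' match yields an empty result, not an error; an out-of-range coordinate
#' is a domain error.
#'
#' @param query Nonempty query string.
#' @param rep A [replicon()].
#' @param view Template [view_state()] supplying scale/canvas geometry;
#'   a default one-line 1000-px view of `rep` when omitted.
#' @return An object of class `"search_result"`: list with `query`,
#'   `matches` (data frame of `feature_id`, `match_kind`) and `view` (the
#'   resolved view, or the template when there is no hit).
#' @export
search_replicon <- function(query, rep, view = NULL) {
  stopifnot(is.character(query), nzchar(query))
  if (is.null(view)) {
    view <- view_state(rep, 1L, scale = max(2, rep$length / 4000),
                       canvas_width = 1000L, n_lines = 4L)
  }
  query <- trimws(query)
  no_hit <- data.frame(feature_id = character(0), match_kind = character(0),
                       stringsAsFactors = FALSE)
  result <- function(matches, rview) {
    structure(list(query = query, matches = matches, view = rview),
              class = "search_result")
  }
  center_on <- function(coord) {
    raw <- raw_span(view)
    rebuild_view(view, clamp_view_start(as.integer(coord) - raw %/% 2L,
                                        rep, raw), view$scale)
  }
  # (1) coordinate range "a..b" or "a-b"
  m <- regmatches(query, regexec("^([0-9]+)\\s*(?:\\.\\.|-)\\s*([0-9]+)$",
                                 query))[[1]]
  if (length(m) == 3L) {
    a <- as.integer(m[2]); b <- as.integer(m[3])
    check_coord(c(a, b), rep)
    lo <- min(a, b); hi <- max(a, b)
    scale <- clamp(max((hi - lo + 1) / view$canvas_width,
                       1 / view$canvas_width), view$scale_min, view$scale_max)
    rview <- view_state(rep, lo, scale = scale,
                        canvas_width = view$canvas_width, n_lines = 1L,
                        wrap = view$wrap, scale_min = view$scale_min,
                        scale_max = view$scale_max)
    return(result(data.frame(feature_id = NA_character_,
                             match_kind = "range"), rview))
  }
  # (2) single base coordinate
  if (grepl("^[0-9]+$", query)) {
    coord <- as.integer(query)
    check_coord(coord, rep)
    return(result(data.frame(feature_id = NA_character_,
                             match_kind = "coordinate"), center_on(coord)))
  }
  f <- rep$features
  hit_result <- function(ids, kind) {
    first <- f[f$id == ids[1], ][1, ]
    result(data.frame(feature_id = ids, match_kind = kind,
                      stringsAsFactors = FALSE),
           center_on(feature_center(first, rep)))
  }
  # (3) exact gene name, case-insensitive
  hits <- f$id[!is.na(f$name) & tolower(f$name) == tolower(query)]
  if (length(hits)) return(hit_result(hits, "gene_name"))
  # (4) exact accession
  hits <- f$id[f$id == query]
  if (length(hits)) return(hit_result(hits, "accession"))
  # (5) product substring, case-insensitive, all hits
  hits <- f$id[!is.na(f$product) &
                 grepl(tolower(query), tolower(f$product), fixed = TRUE)]
  if (length(hits)) return(hit_result(hits, "product_substring"))
  result(no_hit, view)
}

#' @export
print.search_result <- function(x, ...) {
  cat(sprintf("<search> '%s': %d hit(s)\n", x$query, nrow(x$matches)))
  invisible(x)
}
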