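# Tracks mode: quantitative GFF tracks drawn under an unwrapped in-line
# diagram in three styles (intensity-colored bars, bar graph, point graph)
# with a per-track Y-axis scale, all sharing one genome-to-pixel transform.

#' Configure one track strip
#'
#' @param style `"bars"` (horizontal intensity-colored rectangles),
#'   `"bar_graph"` (vertical bars on a zero baseline) or `"point_graph"`
#'   (one marker per record).
#' @param y_min,y_max Y-axis scale; scores are normalized linearly between
#'   them and clipped. The default (`NULL`) uses the track's global
#'   min/max, which is not appropriate for every region — hence the
#'   override.
#' @param height Strip height in pixels (>= 10).
#' @param colormap Two colors for the bars-style intensity ramp; defaults
#'   to the white-to-red ramp in [render_options()].
#' @return A list of class `"track_config"`.
#' @export
track_config <- function(style = c("bars", "bar_graph", "point_graph"),
                         y_min = NULL, y_max = NULL, height = 60,
                         colormap = NULL) {
  style <- match.arg(style)
  if (height < 10) stop("track height must be at least 10 px")
  if (!is.null(y_min) && !is.null(y_max) && y_min >= y_max) {
    stop("y_min must be strictly less than y_max")
  }
  structure(list(style = style, y_min = y_min, y_max = y_max,
                 height = height, colormap = colormap),
            class = "track_config")
}

# fill in default y range from the data's global min/max
resolve_track_range <- function(records, cfg) {
  sc <- records$score[is.finite(records$score)]
  if (is.null(cfg$y_min)) {
    cfg$y_min <- if (length(sc)) min(sc) else 0
  }
  if (is.null(cfg$y_max)) {
    cfg$y_max <- if (length(sc)) max(sc) else 1
  }
  if (cfg$y_max <= cfg$y_min) cfg$y_max <- cfg$y_min + 1
  cfg
}

#' Normalize a track score onto the unit interval
#'
#' Linear map `(score - y_min) / (y_max - y_min)`, clipped to `[0, 1]`.
#' Monotone in the score and invariant under a joint affine rescaling of
#' scores and Y bounds.
#'
#' @param score Numeric score(s).
#' @param cfg A [track_config()] with resolved `y_min`/`y_max`.
#' @return Values in `[0, 1]` (`NA` for absent scores).
#' @export
normalize_intensity <- function(score, cfg) {
  if (is.null(cfg$y_min) || is.null(cfg$y_max)) {
    stop("track_config y range unresolved; call resolve against the data ",
         "or set y_min/y_max explicitly")
  }
  pmin(pmax((score - cfg$y_min) / (cfg$y_max - cfg$y_min), 0), 1)
}

track_ramp <- function(cfg, opts) {
  cols <- if (!is.null(cfg$colormap)) cfg$colormap else opts$track_colormap
  ramp <- grDevices::colorRamp(cols)
  function(v) {
    rgb <- ramp(v)
    grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
}

#' Lay out one track strip against a view
#'
#' Emits one glyph per record intersecting the (unwrapped) view: in `bars`
#' style a rectangle over the record's clipped pixel extent filled from
#' the intensity colormap (neutral gray when the score is absent); in
#' `bar_graph` style a vertical bar whose height is the normalized score
#' times the strip height; in `point_graph` style a marker at the record's
#' center pixel and normalized height. Records without a score are skipped
#' by the two graph styles (they have no Y value). Records outside the
#' view are omitted.
#'
#' @param records Track record data frame from [read_track_gff()].
#' @param cfg A [track_config()].
#' @param view A single-line [view_state()] (`wrap = FALSE`).
#' @param opts A [render_options()].
#' @return Data frame of track glyphs with resolved pixel geometry and
#'   fills; the resolved config is attached as attribute `"config"`.
#' @export
layout_track <- function(records, cfg, view, opts = render_options()) {
  stopifnot(inherits(cfg, "track_config"))
  cfg <- resolve_track_range(records, cfg)
  fill_fun <- track_ramp(cfg, opts)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    s <- max(1L, r$start); e <- min(view$replicon$length, r$end)
    if (s > e) next  # record entirely off the replicon
    ivs <- feature_offset_intervals(view, s, e)
    if (!length(ivs)) next
    iv <- ivs[[1]]
    x1 <- iv[1] / view$scale
    x2 <- (iv[2] + 1L) / view$scale
    norm <- if (is.na(r$score)) NA_real_ else
      normalize_intensity(r$score, cfg)
    if (cfg$style == "bars") {
      fill <- if (is.na(norm)) opts$gray_fill else fill_fun(norm)
      rows[[length(rows) + 1L]] <- data.frame(
        style = "bars", x_start = x1, x_end = x2, y = 0,
        height = cfg$height, fill = fill, score = r$score, norm = norm,
        name = r$name, stringsAsFactors = FALSE)
    } else if (cfg$style == "bar_graph") {
      if (is.na(norm)) next
      h <- norm * cfg$height
      rows[[length(rows) + 1L]] <- data.frame(
        style = "bar_graph", x_start = x1, x_end = x2,
        y = cfg$height - h, height = h, fill = fill_fun(1)[1],
        score = r$score, norm = norm, name = r$name,
        stringsAsFactors = FALSE)
    } else {
      if (is.na(norm)) next
      xc <- (x1 + x2) / 2
      rows[[length(rows) + 1L]] <- data.frame(
        style = "point_graph", x_start = xc, x_end = xc,
        y = cfg$height - norm * cfg$height, height = 0,
        fill = fill_fun(1)[1], score = r$score, norm = norm, name = r$name,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(style = character(0), x_start = numeric(0),
               x_end = numeric(0), y = numeric(0), height = numeric(0),
               fill = character(0), score = numeric(0), norm = numeric(0),
               name = character(0), stringsAsFactors = FALSE)
  attr(out, "config") <- cfg
  out
}

#' Compose the in-line diagram with data tracks below it
#'
#' Switches the display to a single unwrapped line and stacks the supplied
#' tracks underneath in input order. The in-line diagram and every track
#' strip share one genome-to-pixel transform, so zooming and panning the
#' composed view (via [zoom_about_anchor()] / [pan()] on `view`) stay
#' synchronized by construction.
#'
#' @param rep A [replicon()].
#' @param tracks List of `list(records = <track records>, config =
#'   <track_config>)` entries; one record set may appear under several
#'   configs to render the same data in multiple styles.
#' @param view A [view_state()]; coerced to `wrap = FALSE`, `n_lines = 1`.
#' @param policy A [display_policy()].
#' @param opts A [render_options()].
#' @return An object of class `"tracks_view"`: the in-line
#'   `"layout_result"` plus a list of laid-out track strips.
#' @export
compose_tracks_view <- function(rep, tracks, view,
                                policy = display_policy(),
                                opts = render_options()) {
  view <- view_state(rep, view$view_start, view$scale, view$canvas_width,
                     n_lines = 1L, wrap = FALSE,
                     scale_min = view$scale_min, scale_max = view$scale_max)
  inline <- layout(view, policy, opts)
  strips <- lapply(tracks, function(t) {
    stopifnot(is.list(t), !is.null(t$records), !is.null(t$config))
    layout_track(t$records, t$config, view, opts)
  })
  structure(list(view = view, inline = inline, strips = strips,
                 opts = opts),
            class = "tracks_view")
}

#' @export
print.tracks_view <- function(x, ...) {
  cat(sprintf("<tracks view> inline %d glyph(s) + %d track strip(s)\n",
              nrow(x$inline$glyphs), length(x$strips)))
  invisible(x)
}
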