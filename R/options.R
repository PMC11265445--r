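# Rendering configuration: semantic-zoom thresholds, font metrics, palette.
# All thresholds live here so golden tests can pin them explicitly.

# 12 qualitative hues; the comparative mode recycles them after the dozen
# have been used, and the basic mode keys operon fills off the same set.
PALETTE12 <- c(
  "#1f77b4", "#ff7f0e", "#2ca02c", "#d62728", "#9467bd", "#8c564b",
  "#e377c2", "#bcbd22", "#17becf", "#aec7e8", "#ffbb78", "#98df8a"
)

#' Rendering and semantic-zoom options
#'
#' One bag of tunables shared by the layout engine and the SVG renderer.
#' The zoom thresholds implement semantic zooming: which feature classes
#' and labels appear at which scales (scale is measured in bases per pixel;
#' smaller is finer).
#'
#' @param gene_px_threshold Minimum rendered width in pixels for a
#'   gene/operon glyph to be drawn under the Auto policy (default 3).
#' @param site_scale_threshold Sites (TSS, terminators, TFBS) are drawn
#'   under Auto once the scale is at least this fine, i.e.
#'   `scale <= site_scale_threshold` bases/pixel (default 20).
#' @param site_min_px Minimum glyph width in pixels enforced for sites and
#'   for features forced On (default 5).
#' @param char_width Fixed label character width in pixels (default 7); a
#'   name is shown once the glyph is at least `nchar(name) * char_width`
#'   wide, and the product once name + product fit.
#' @param seq_px_per_base Nucleotide letters appear at
#'   `>= seq_px_per_base` pixels per base (default 8, i.e. scale <= 0.125).
#' @param aa_px_per_codon Amino-acid letters appear at
#'   `>= aa_px_per_codon` pixels per codon (default 8, i.e. scale <= 0.375).
#' @param lane_stacking Stack overlapping same-class glyphs into lanes
#'   (default `TRUE`); when `FALSE`, overlapping glyphs are drawn on top of
#'   one another (glyph count is unchanged).
#' @param palette Character vector of recycled glyph colors (12 by default).
#' @param gray_fill Fill used for pseudogenes and for comparative-mode genes
#'   with no ortholog in the lead strain.
#' @param track_colormap Two colors defining the linear intensity ramp for
#'   track bars (default white to red).
#' @param zoom_step Multiplicative factor of one continuous-zoom increment
#'   (default 1.1 per wheel notch).
#' @return A named list of class `"render_options"`.
#' @export
render_options <- function(gene_px_threshold = 3,
                           site_scale_threshold = 20,
                           site_min_px = 5,
                           char_width = 7,
                           seq_px_per_base = 8,
                           aa_px_per_codon = 8,
                           lane_stacking = TRUE,
                           palette = PALETTE12,
                           gray_fill = "#9e9e9e",
                           track_colormap = c("#ffffff", "#d62728"),
                           zoom_step = 1.1) {
  structure(list(
    gene_px_threshold = gene_px_threshold,
    site_scale_threshold = site_scale_threshold,
    site_min_px = site_min_px,
    char_width = char_width,
    seq_px_per_base = seq_px_per_base,
    aa_px_per_codon = aa_px_per_codon,
    lane_stacking = isTRUE(lane_stacking),
    palette = palette,
    gray_fill = gray_fill,
    track_colormap = track_colormap,
    zoom_step = zoom_step
  ), class = "render_options")
}
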