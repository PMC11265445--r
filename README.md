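# repliconview

Wrapped in-line genome diagrams for bacterial replicons, with semantic
zooming, ortholog-anchored comparative alignment, and quantitative data
tracks — rendered as deterministic SVG.

## What problem this solves, and for whom

Genome browsers built around parallel tracks spend a full strip of
vertical space on every feature class, so one screen shows one short,
unwrapped slice of genome. `repliconview` implements the alternative
*in-line* organization: genes, transcription start sites (TSS),
terminators and transcription-factor binding sites are drawn adjacent to
one another in a single band, and that band wraps vertically like the
lines of a book. Ten wrapped lines of 240 bases put 2,400 bases of
sequence-level context on a screen where an unwrapped display fits one
line.

The package is a library plus CLI for microbial genomics workflows that
need reproducible, scriptable genome figures: regulatory-region overviews
with promoters and binding sites in place, cross-strain gene-conservation
panels anchored at orthologs, and ChIP-style intensity tracks aligned
under the annotation. Everything interactive in a point-and-click browser
(wheel zoom about the pointer, drag pan, hover highlighting) exists here
as a pure function over an explicit view, so any view is reconstructible
from parameters alone.

## The core model

* **View geometry.** A view is `(view_start, scale, canvas_width,
  n_lines)` with `scale` in bases/pixel. Each line covers
  `floor(canvas_width × scale)` bases; per-line ranges partition the
  visible span exactly, wrapping modulo length on circular replicons.
  The supported zoom range mirrors the published physical preset — 10
  bases/inch up to ~15 kB/inch, a ~1,500-fold ratio
  (`physical_zoom_preset()`).
* **Semantic zooming.** Each feature kind is `On`/`Off`/`Auto`. Under
  `Auto`, genes appear once their rendered width reaches 3 px, sites once
  the scale reaches 20 b/px, names once they fit at 7 px/character,
  nucleotide letters at ≥ 8 px/base. Visibility is monotone in zoom.
* **Stacking.** Overlapping same-class glyphs go into lanes by greedy
  first-fit over sorted pixel intervals; the lane count equals the
  maximum overlap depth.
* **Anchor-preserving zoom.** `zoom_about_anchor(view, anchor, f)`
  multiplies the scale by `f` and re-solves `view_start` so the anchor
  keeps its screen position to within one base.
* **Comparative mode.** `build_alignment(lead_gene, genomes, orthologs,
  …)` draws one unwrapped line per genome having an ortholog of the lead
  gene, every anchor center mapped to the same canvas-center pixel;
  ortholog groups are colored from a 12-color palette recycled in order
  of appearance (group 13 reuses color 1), non-orthologs gray.
* **Tracks mode.** GFF records with a column-6 intensity render as
  colored bars, bar graphs, or point graphs under the unwrapped in-line
  diagram, normalized per track by `(score − y_min)/(y_max − y_min)` and
  sharing the genome→pixel transform.

## Worked example

```r
library(repliconview)

# a seeded synthetic genome: operons, promoters, terminators, TFBS
fx <- generate_synthetic_genome(fixture_spec(seed = 42), dir = "demo")
r  <- fx$replicon
r
#> <replicon> synth1: 31,985 bp, circular, 138 features, sequence present

v   <- view_state(r, view_start = 1, scale = 10, canvas_width = 960,
                  n_lines = 6)
lay <- layout(v)
lay
#> <layout> 4 line(s), 144 glyph(s), 23 operon box(es)
```

Four lines suffice here because six lines at 9,600 bases each would
exceed the replicon, so the wrap clamps at one full turn; the 144 glyphs
are the features visible at 10 b/px (genes, operons and sites, with
continuation segments where a feature straddles a line break), and each
operon's genes share a fill inside one of the 23 gray boxes.

```r
search_replicon("kinase", r)$matches[1:3, ]
#>       feature_id        match_kind
#> 1 synth1_op02_g1 product_substring
#> 2 synth1_op04_g2 product_substring
#> 3 synth1_op07_g2 product_substring

translate_cds("synth1_op01_g1", r)       # table 11, stop dropped
#> "MGAYIYHRSAGSNPCTHEWGIASKLPPTLGEIEMRFLNSI..."

select_region(31976, 10, r)              # two clicks across the origin
#> <selection> synth1:31976-10(+), 20 bp [spans origin]

svg <- render_svg(lay, include_legend = TRUE)   # deterministic SVG text
writeLines(svg, "view.svg")
```

The same operations drive the CLI:

```sh
Rscript inst/cli/repliconview.R fixtures --seed 42 --dir demo
Rscript inst/cli/repliconview.R render --gff3 demo/synth1.gff3 \
    --fasta demo/synth1.fasta --scale 10 --width 960 --lines 6 \
    --legend --out view.svg
Rscript inst/cli/repliconview.R compare --lead-gene strain1_op01_g1 \
    --genomes demo/strain1.gff3,demo/strain2.gff3 \
    --orthologs demo/orthologs.tsv --out compare.svg
```

Subcommands: `render`, `compare`, `tracks`, `extract-seq`, `search`,
`fixtures`; `--config` accepts a YAML file whose keys override
`render_options()` (thresholds, palette, colormap), and errors exit with
status 2.

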