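---
title: "Wrapped in-line genome diagrams: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wrapped in-line genome diagrams: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repliconview)
```

# The display model

`repliconview` is a deterministic layout and rendering engine for bacterial
genome browsing. Its central idea is the *in-line display*: genes,
transcription start sites (TSS), terminators and transcription-factor
binding sites (TFBS) are drawn adjacent to one another inside the same
rectangular band, and that band wraps vertically line after line, the way
text wraps in a book. Compared with the parallel-track organization most
genome browsers use, in-line wrapping spends far less vertical space per
feature class, so a screen of fixed size shows much more genome context —
ten wrapped lines of 240 bases each put 2,400 bases of sequence-level
detail on one screen where an unwrapped display fits a single line.

Three modes share one coordinate engine:

* **basic mode** — one replicon, wrapped lines, semantic zooming;
* **comparative mode** — several genomes, one unwrapped line each, aligned
  at the center of the orthologs of a chosen *lead gene*;
* **tracks mode** — one unwrapped line with quantitative data strips
  stacked beneath it, all sharing the genome-to-pixel transform.

The package renders static SVG. The interactive gestures of a browser
(wheel zoom, drag pan, hover highlight) are exposed as pure functions over
an explicit `view_state`, and hover metadata is embedded in the SVG as
`data-*` attributes and `<title>` tooltips instead of live event handlers.

## Coordinates and circular arithmetic

External coordinates are 1-based inclusive, the GFF3 convention, so file
I/O is bit-compatible with annotation sources. A circular replicon admits
features, views and selections that span the origin; these are encoded as
a single record with `start > end` rather than split records, which keeps
two-click selection and sequence extraction single-segment
(`circular_span_length()`, `select_region()`, `extract_nt()`).

The midpoint of a span of length $n$ starting at $s$ is
$s + \lfloor (n-1)/2 \rfloor$, reduced modulo the replicon length. Ties
break toward the start (integer floor) — a deterministic choice matching
integer division. How the original browser centers an origin-wrapping gene
is not documented anywhere we know of; the modular rule here is this
package's own convention, chosen so the center always lies inside the
wrapped span.

## The view and the wrap

A `view_state` is `(view_start, scale, canvas_width, n_lines, wrap)` with
`scale` in bases per pixel (smaller = finer). Each wrapped line covers
`floor(canvas_width × scale)` bases; the visible span is the concatenation
of `n_lines` such ranges, clipped at the ends of a linear replicon and
wrapped modulo length on a circular one. The invariant the tests enforce
is *coverage conservation*: the union of the per-line ranges equals the
visible span exactly, with no gaps or duplicates, including across the
origin.

Features that straddle a line break are split into per-line glyph
segments; segments after the first are flagged as continuations and carry
no labels, so a long gene is labeled once per view. Whether the original
product re-labels continuations is unknown; labeling once is our choice.

# Semantic zooming

Semantic zooming reveals feature classes and labels progressively as the
scale gets finer, instead of scaling geometry alone. The legend gives each
feature kind a tri-state setting: `On` and `Off` are absolute; under
`Auto` the layout engine decides. The published description of the
original browser states the behavior but none of its thresholds, so the
defaults below are declared package parameters (all configurable through
`render_options()`), chosen to reproduce the qualitative progression from
a 200-kb overview down to sequence level:

| parameter | default | meaning |
|---|---|---|
| `gene_px_threshold` | 3 px | Auto genes/operons appear at this rendered width |
| `site_scale_threshold` | 20 b/px | Auto sites appear once `scale` is at least this fine |
| `site_min_px` | 5 px | minimum site glyph width (also for forced-On glyphs) |
| `char_width` | 7 px | fixed label character width |
| `seq_px_per_base` | 8 px | nucleotide letters appear at ≥ 8 px/base (`scale ≤ 0.125`) |
| `aa_px_per_codon` | 8 px | amino-acid letters at ≥ 8 px/codon (`scale ≤ 0.375`) |

A name label is shown once the glyph is at least `nchar(name) ×
char_width` wide; the product is added once name and product both fit.
Because every Auto rule is monotone in rendered width (or scale), the set
of visible features at one scale is a subset of the set at any finer
scale — a property the suite asserts over a scale ladder.

## Zoom bounds

The working range of the original browser is stated in physical units: 10
bases per inch at the finest to roughly 15 kB per inch at the coarsest, a
ratio of about 1,500. Screens differ, so the package exposes that preset
through `physical_zoom_preset(dpi = 96)` (yielding `scale_min ≈ 0.104`,
`scale_max ≈ 156.25` b/px) and otherwise defaults to `scale_min = 0.1`
b/px with `scale_max` set so one unwrapped screen shows the whole
replicon. Zooming clamps to the bounds and never fails. On circular
replicons zoom-out is additionally capped where the wrapped view would
exceed one full turn: beyond that point a coordinate would occupy several
screen positions at once and no anchor pixel could be preserved.

## Anchor-preserving zoom

`zoom_about_anchor()` models wheel zooming about the mouse pointer: the
scale is multiplied by a factor and the new `view_start` is solved so the
anchor coordinate maps to the same line and pixel as before. Because base
offsets are integers, the anchor can drift by at most half a base per
step; the suite checks < 1 base-equivalent over random zoom chains.
Continuous zoom is modeled as a chain of small-factor calls
(`zoom_step = 1.1` per notch by default).

# Lane stacking

Overlapping same-class glyphs (genes; TSS; TFBS; …) are stacked into
lanes by greedy first-fit: glyphs sorted by ascending pixel start
(longer-first on ties) each take the lowest lane they fit in. First-fit on
sorted intervals is optimal for interval graphs, so the lane count equals
the maximum overlap depth — the suite verifies this against an
independent sweep-line oracle on random intervals. Sorting plus a fixed
tie-break makes the assignment deterministic, which golden SVG tests rely
on. Stacking can be disabled per `render_options(lane_stacking = FALSE)`,
in which case overlapping glyphs are simply drawn on top of one another;
the glyph count is unchanged either way. Operon boxes never stack: they
are background hulls of the same-operon gene glyphs on each line.

# Comparative mode

`build_alignment()` aligns genomes at ortholog centers rather than by
sequence. Orthology arrives as a plain three-column table (genome, gene,
group) with at most one member per genome per group, standing in for an
ortholog database. Every supplied genome holding a group-mate of the lead
gene gets a row — one unwrapped line at the shared scale, positioned so
the anchor gene's center maps to the canvas horizontal center; the rest
are listed as excluded. Where the alignment column sits on screen is not
specified by the original description; center matches its published
appearance. Because all rows subtract the same integer anchor offset, the
anchor centers align exactly (0 px spread), and rebuilding rows on zoom
keeps them aligned under synchronized zoom and pan.

Ortholog groups are colored from a recycled 12-color palette in order of
first appearance along the lead row (a deterministic order); group 13
reuses group 1's color. Genes with no group, or whose group has no member
in the lead row, are gray. The palette's twelve specific hues are package
defaults — only the count is prescribed. Hover highlighting becomes
`ortholog_highlight()`, the symmetric orbit of a gene's group, and is
embedded in the SVG as a shared `data-group` attribute.

Row order preserves the user-supplied genome order with the lead genome
first; nothing in the source material fixes that order.

# Tracks mode

Track records are GFF lines whose column 6 carries an optional intensity.
Scores are normalized linearly onto `[0, 1]` between a per-track
`y_min`/`y_max` (defaulting to the track's global min/max — a default that
is deliberately overridable because one global range rarely suits every
region). Three styles: `bars` (rectangles over the record extent, filled
from a white→red ramp by default; neutral gray when no score),
`bar_graph` (vertical bars on a zero baseline, height = normalized score ×
strip height — the simplest reading of the published figure, even when
`y_min > 0`), and `point_graph` (a marker per record). Records without a
score are skipped by the two graph styles, which need a Y value. Every
record is rendered — no downsampling — and strips stack in input order
beneath the unwrapped in-line line, sharing its transform, so a gene and
a track record with the same coordinates land on the same x pixel.

# Sequence operations

Selection is two clicks: on a linear replicon the order is irrelevant
(min..max); on a circular one the region runs forward from the first
click, wrapping if needed — order matters there because that is the only
way an origin-spanning arc is expressible, and we honor it only where it
can matter. Extraction returns region-order bases, reverse-complemented
for minus-strand selections (delegated to Biostrings). Translation uses
NCBI table 11 (bacterial) by default, reflecting the package's bacterial
focus; a recognized alternative initiator (GTG/TTG) translates as M
unless `init_codon_as_met = FALSE`, the terminal stop is dropped, and a
span not divisible by three is an error naming the gene. FASTA export
wraps at 60 columns and round-trips through `read_fasta()`.

# The synthetic-data generator

`generate_synthetic_genome()` emulates a bacterial chromosome at the
level this renderer cares about: operons of 1–4 consecutive same-strand
genes (default 20 operons), gene lengths 300–900 b rounded to whole
codons, intergenic gaps of 50–300 b, one TSS with a sigma factor from a
five-member set and one terminator per operon, and 0–2 TFBS near each
promoter. Protein-coding spans carry a real ATG…sense…stop codon
structure spliced into random background sequence, so translation
succeeds on every generated gene. Defaults were chosen once as a
realistic small bacterial neighborhood (operon density and gap scales in
the *E. coli* ballpark) and are not tuned against test outcomes.

`generate_strain_family()` derives strains from one sampled architecture:
the lead strain keeps everything; each other strain loses genes
independently (default probability 0.15), re-lays out its coordinates
with Gaussian gap jitter (σ = 25 b), and with small probability gains a
novel gene. The gain step is an addition beyond plain loss+jitter: novel
genes are deliberately absent from the ortholog table so the
gray-no-ortholog rendering path is reachable from fixtures. The ortholog
table links surviving copies (one group per ancestral gene).

What the generator does **not** emulate: realistic codon usage or GC
content, overlapping genes, horizontal transfer beyond single-gene gain,
rearrangements/inversions (strains stay colinear), multi-replicon
genomes, and intron/exon structure (out of scope for the renderer too).
Passing tests therefore demonstrate geometric and bookkeeping
correctness, not robustness to every messiness of real annotation files.

Generation is a pure function of the spec's seed — the RNG state is saved
and restored around it — so fixtures→layout→SVG is reproducible
byte-for-byte.

# Numerical and degenerate-input choices

* Pixel extents are half-open `[x_start, x_end)`; lane fitting and the
  sweep-line oracle share that convention, with a `1e-9` slack against
  floating-point jitter.
* `canvas_to_genome` floors `x × scale` (with `1e-9` guard), making the
  transform pair round-trip within one base.
* SVG numbers are printed with at most two decimals, trailing zeros
  stripped, never scientific notation — determinism across platforms.
* Degenerate inputs: zero-operon genomes produce valid empty files;
  empty feature lists still lay out line ranges; zero-width sites are
  widened to a 5-px minimum glyph; an empty search result is not an
  error, but an out-of-range coordinate query is.
* Problem sizes in the test suite (genomes of 5–20 operons, 200-interval
  lane checks, 10–20-step zoom chains, 20-seed loss calibration) were
  chosen as the smallest sizes at which the properties are
  non-trivially exercised.

# Known limitations

* GFF3 cannot encode a `start > end` origin-wrapping feature, so the
  writer rejects them; wrapped features exist in memory only.
* Font metrics are a fixed 7 px/character; proportional-font label
  fitting is out of scope.
* The terminator glyph is a stem ("lollipop") shape; the original's exact
  glyph is not described in text.
* One replicon per basic-mode view; multi-replicon genomes are rendered
  one replicon at a time.
* No BigWig/BED readers; tracks are GFF-with-score only.
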