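test_that("a 2,400-base sequence-level view wraps into 10 lines", {
  r <- toy_replicon("linear", 5000L)
  # 240 bases per line at 0.25 b/px on a 960-px canvas
  v <- view_state(r, 1, scale = 0.25, canvas_width = 960, n_lines = 10)
  expect_identical(bases_per_line(v), 240L)
  expect_identical(visible_span(v), 2400L)
  lines <- wrap_view(v)
  expect_identical(nrow(lines), 10L)
  expect_true(all(lines$end - lines$start + 1L == 240L))
})

test_that("unwrapped views are a single range equal to the visible span", {
  r <- toy_replicon("linear", 5000L)
  v <- view_state(r, 101, scale = 2, canvas_width = 500, wrap = FALSE)
  lines <- wrap_view(v)
  expect_identical(nrow(lines), 1L)
  expect_identical(lines$end - lines$start + 1L, visible_span(v))
})

test_that("circular wrapping covers exactly the visible coordinates", {
  r <- toy_replicon("circular", 1000L)
  v <- view_state(r, 901, scale = 1, canvas_width = 150, n_lines = 2)
  lines <- wrap_view(v)
  covered <- unlist(lapply(seq_len(nrow(lines)), function(i)
    range_coords(lines$start[i], lines$end[i], 1000L)))
  expect_identical(length(covered), 300L)
  expect_identical(length(unique(covered)), 300L)
  expect_identical(sort(covered),
                   sort(range_coords(901, 200, 1000L)))
})

test_that("coverage conservation holds over random views (incl. wrap)", {
  set.seed(40)
  for (i in 1:20) {
    topo <- sample(c("linear", "circular"), 1)
    L <- sample(500:3000, 1)
    r <- replicon("r", L, topo)
    v <- view_state(r, sample(L, 1), scale = runif(1, 0.5, 10),
                    canvas_width = sample(100:500, 1),
                    n_lines = sample(1:6, 1))
    lines <- wrap_view(v)
    covered <- unlist(lapply(seq_len(nrow(lines)), function(j)
      range_coords(lines$start[j], lines$end[j], L)))
    expect_identical(length(covered), length(unique(covered)))
    expect_identical(length(covered), as.integer(visible_span(v)))
    # consecutive, starting at view_start
    expect_identical(covered[1], v$view_start)
  }
})

test_that("genome_to_canvas maps the origin and wrap boundary exactly", {
  r <- toy_replicon("linear", 5000L)
  v <- view_state(r, 101, scale = 2, canvas_width = 300, n_lines = 3)
  bpl <- bases_per_line(v)
  expect_equal(genome_to_canvas(v, 101), list(in_view = TRUE, line = 0L, x = 0))
  expect_equal(genome_to_canvas(v, 101 + bpl),
               list(in_view = TRUE, line = 1L, x = 0))
  expect_false(genome_to_canvas(v, 50)$in_view)
  expect_false(genome_to_canvas(v, 101 + 3 * bpl)$in_view)
})

test_that("canvas/genome transforms round trip within one base", {
  set.seed(41)
  for (topo in c("linear", "circular")) {
    r <- replicon("r", 4000L, topo)
    v <- view_state(r, 3500, scale = 3.7, canvas_width = 257, n_lines = 4)
    coords <- if (topo == "circular") sample(4000, 1000, replace = TRUE)
              else sample(3500:4000, 300, replace = TRUE)
    for (coord in coords) {
      p <- genome_to_canvas(v, coord)
      if (!p$in_view) next
      back <- canvas_to_genome(v, p$line, p$x)
      d <- abs(back - coord)
      if (topo == "circular") d <- min(d, 4000 - d)
      expect_lte(d, 1)
    }
  }
})

test_that("visibility honors Off/On absolutely and Auto thresholds", {
  r <- toy_replicon("linear", 5000L)
  gene <- genome_feature("g", "protein_gene", 1001, 1900, "+", name = "trpA")
  site <- genome_feature("s", "tfbs", 1500, 1510)

  vfine <- view_state(r, 1, scale = 1, canvas_width = 1000, n_lines = 5)
  off <- display_policy(tfbs = "Off")
  expect_false(visibility(site, vfine, off)$draw)
  vcoarse <- view_state(r, 1, scale = 100, canvas_width = 1000)
  on <- display_policy(tfbs = "On")
  expect_true(visibility(site, vcoarse, on)$draw)
  # Auto: sites appear once scale <= 20 b/px
  expect_false(visibility(site, vcoarse, display_policy())$draw)
  expect_true(visibility(site, vfine, display_policy())$draw)

  # 900-base gene at 1 b/px: 900 px >= 4 chars * 7 px, name shown
  vis <- visibility(gene, view_state(r, 1, 1, 1000), display_policy())
  expect_true(vis$draw && vis$show_name)
  # at 50 b/px the glyph is 18 px: drawn (>= 3 px) but unlabeled
  vis <- visibility(gene, view_state(r, 1, 50, 1000), display_policy())
  expect_true(vis$draw)
  expect_false(vis$show_name)
  # at 400 b/px the glyph is 2.25 px: below the 3-px Auto threshold
  vis <- visibility(gene, view_state(r, 1, 400, 1000), display_policy())
  expect_false(vis$draw)
})

test_that("Auto visibility is monotone along a decreasing-scale ladder", {
  r <- small_fixture(seed = 13)
  scales <- c(200, 50, 20, 5, 1, 0.2)
  pol <- display_policy()
  visible_sets <- lapply(scales, function(s) {
    v <- view_state(r, 1, scale = s, canvas_width = 500, n_lines = 2)
    f <- r$features
    f$id[vapply(seq_len(nrow(f)), function(i)
      visibility(f[i, ], v, pol)$draw, logical(1))]
  })
  for (i in seq_len(length(scales) - 1)) {
    expect_true(all(visible_sets[[i]] %in% visible_sets[[i + 1]]),
                info = sprintf("scale %g -> %g", scales[i], scales[i + 1]))
  }
})

test_that("lane assignment is first-fit and matches sweep-line depth", {
  two <- data.frame(x_start = c(0, 50), x_end = c(40, 90))
  expect_identical(assign_lanes(two), c(0L, 0L))
  clique <- data.frame(x_start = c(0, 5, 10), x_end = c(30, 35, 40))
  expect_identical(sort(assign_lanes(clique)), 0:2)

  set.seed(42)
  xs <- runif(200, 0, 900)
  g <- data.frame(x_start = xs, x_end = xs + runif(200, 5, 120))
  lanes <- assign_lanes(g)
  expect_identical(max(lanes) + 1L, sweep_max_depth(g$x_start, g$x_end))
  # no two same-lane glyphs overlap
  for (l in unique(lanes)) {
    d <- g[lanes == l, ]
    d <- d[order(d$x_start), ]
    if (nrow(d) > 1) expect_true(all(d$x_start[-1] >= d$x_end[-nrow(d)] - 1e-9))
  }
})

test_that("layout emits in-bounds, lane-consistent glyphs at all scales", {
  r <- small_fixture(seed = 17)
  for (scale in c(2, 10, 40)) {
    lay <- layout(view_state(r, 101, scale = scale, canvas_width = 400,
                             n_lines = 4))
    g <- lay$glyphs
    expect_gt(nrow(g), 0)
    expect_true(all(g$x_start >= -1e-9 & g$x_end <= 400 + 1e-9))
    for (key in split(seq_len(nrow(g)),
                      list(g$line, g$lane_class, g$lane), drop = TRUE)) {
      d <- g[key, ]
      if (d$lane_class[1] == "operon" || nrow(d) < 2) next
      d <- d[order(d$x_start), ]
      expect_true(all(d$x_start[-1] >= d$x_end[-nrow(d)] - 1e-9))
    }
  }
})

test_that("features straddling line breaks split into continuation segments", {
  r <- toy_replicon("linear", 2000L)
  r$features <- genome_feature("g1", "protein_gene", 90, 260, "+",
                               name = "spanA")
  v <- view_state(r, 1, scale = 1, canvas_width = 100, n_lines = 4)
  lay <- layout(v)
  g <- lay$glyphs[lay$glyphs$feature_id == "g1", ]
  expect_identical(nrow(g), 3L)  # lines 0 (90-100), 1 (101-200), 2 (201-260)
  expect_identical(g$line, 0:2)
  expect_identical(g$continuation, c(FALSE, TRUE, TRUE))
  expect_identical(sum(g$show_name), 1L)
  # segments cover the feature exactly
  covered <- unlist(lapply(seq_len(nrow(g)), function(i)
    seq.int(g$seg_start[i], g$seg_end[i])))
  expect_identical(sort(covered), 90:260)
})

test_that("empty feature lists still produce line ranges", {
  r <- replicon("bare", 1000L, "linear")
  lay <- layout(view_state(r, 1, 2, 100, n_lines = 3))
  expect_identical(nrow(lay$glyphs), 0L)
  expect_identical(nrow(lay$lines), 3L)
})

test_that("operon boxes hull same-operon genes and never stack", {
  f <- rbind(
    genome_feature("a", "protein_gene", 100, 400, "+", operon_id = "TU1"),
    genome_feature("b", "protein_gene", 420, 800, "+", operon_id = "TU1"),
    genome_feature("c", "protein_gene", 900, 1200, "+", operon_id = "TU2"))
  r <- replicon("r", 2000L, "linear", features = f)
  lay <- layout(view_state(r, 1, scale = 2, canvas_width = 1000))
  ob <- lay$operon_boxes
  expect_identical(nrow(ob), 2L)
  tu1 <- ob[ob$operon_id == "TU1", ]
  g <- lay$glyphs
  expect_equal(tu1$x_start, min(g$x_start[g$feature_id %in% c("a", "b")]))
  expect_equal(tu1$x_end, max(g$x_end[g$feature_id %in% c("a", "b")]))
})

test_that("disabling lane stacking draws overlaps on top, same glyph count", {
  f <- rbind(
    genome_feature("a", "tfbs", 100, 160),
    genome_feature("b", "tfbs", 120, 180),
    genome_feature("c", "tfbs", 140, 200))
  r <- replicon("r", 1000L, "linear", features = f)
  v <- view_state(r, 1, scale = 1, canvas_width = 1000)
  stacked <- layout(v, opts = render_options(lane_stacking = TRUE))
  flat <- layout(v, opts = render_options(lane_stacking = FALSE))
  expect_identical(nrow(flat$glyphs), nrow(stacked$glyphs))
  expect_true(all(flat$glyphs$lane == 0L))
  expect_identical(sort(unique(stacked$glyphs$lane)), 0:2)
})
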