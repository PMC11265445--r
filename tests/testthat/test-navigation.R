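test_that("the physical zoom preset spans a ~1,500-fold range", {
  preset <- physical_zoom_preset()
  expect_equal(preset$ratio, 1500)
  # density-independent: the ratio is a property of the physical bounds
  expect_equal(physical_zoom_preset(dpi = 120)$ratio, 1500)
  expect_equal(preset$scale_min, 10 / 96)
  expect_equal(preset$scale_max, 15000 / 96)
})

test_that("zooming about an anchor keeps its pixel position", {
  r <- toy_replicon("circular", 20000L)
  v <- view_state(r, 5001, scale = 4, canvas_width = 500, n_lines = 3)
  anchor <- 7000L
  before <- genome_to_canvas(v, anchor)
  v2 <- zoom_about_anchor(v, anchor, 2)
  after <- genome_to_canvas(v2, anchor)
  expect_true(after$in_view)
  expect_identical(before$line, after$line)
  # drift under one base-equivalent
  expect_lt(abs(after$x - before$x) * v2$scale, 1)
  expect_equal(v2$scale, 8)
  # factor 1 is the identity
  v1 <- zoom_about_anchor(v, anchor, 1)
  expect_identical(v1$view_start, v$view_start)
  expect_identical(v1$scale, v$scale)
})

test_that("anchor drift stays under one base per step over random chains", {
  set.seed(50)
  r <- toy_replicon("circular", 50000L)
  for (rep_i in 1:10) {
    v <- view_state(r, sample(50000, 1), scale = 10, canvas_width = 600,
                    n_lines = 2)
    anchor <- canvas_to_genome(v, sample(0:1, 1), runif(1, 0, 500))
    for (step in 1:8) {
      before <- genome_to_canvas(v, anchor)
      v <- zoom_about_anchor(v, anchor, runif(1, 0.4, 2.5))
      after <- genome_to_canvas(v, anchor)
      expect_true(after$in_view)
      expect_identical(after$line, before$line)
      expect_lt(abs(after$x - before$x) * v$scale, 1 + 1e-9)
      expect_gte(v$scale, v$scale_min)
      expect_lte(v$scale, v$scale_max)
    }
  }
})

test_that("scale clamps to bounds under extreme factor sequences", {
  r <- toy_replicon("linear", 10000L)
  v <- view_state(r, 5000, scale = 1, canvas_width = 500)
  for (i in 1:5) v <- zoom_about_anchor(v, v$view_start, 100)
  expect_equal(v$scale, v$scale_max)
  anchor <- v$view_start
  for (i in 1:8) {
    anchor <- v$view_start
    v <- zoom_about_anchor(v, anchor, 0.001)
  }
  expect_equal(v$scale, v$scale_min)
})

test_that("panning wraps on circles, clamps on lines, and inverts", {
  circ <- toy_replicon("circular", 1000L)
  v <- view_state(circ, 500, scale = 1, canvas_width = 100)
  expect_identical(pan(v, 0)$view_start, 500L)
  expect_identical(pan(v, 1000)$view_start, 500L)
  set.seed(51)
  for (k in sample(-2000:2000, 20)) {
    expect_identical(pan(pan(v, k), -k)$view_start, 500L)
  }
  lin <- toy_replicon("linear", 1000L)
  vl <- view_state(lin, 500, scale = 1, canvas_width = 100)
  expect_identical(pan(vl, -10000)$view_start, 1L)
  expect_identical(pan(vl, 10000)$view_start, 901L)  # length - span + 1
})

test_that("named zoom levels are idempotent and meet their contracts", {
  r <- small_fixture(seed = 19)
  v <- view_state(r, r$length %/% 3, scale = 10, canvas_width = 800,
                  n_lines = 4)
  opts <- render_options()
  vseq <- jump_to_level(v, "sequence", opts)
  expect_gte(1 / vseq$scale, opts$seq_px_per_base)
  expect_identical(jump_to_level(vseq, "sequence", opts)$view_start,
                   vseq$view_start)
  vover <- jump_to_level(v, "overview", opts)
  expect_gte(raw_span_for_test(vover), r$length)
  vgene <- jump_to_level(v, "gene", opts)
  expect_identical(jump_to_level(vgene, "gene", opts)$scale, vgene$scale)
})

test_that("search resolves ranges, coordinates, names and products in order", {
  f <- rbind(
    genome_feature("b0001", "protein_gene", 1000, 1900, "+", name = "yidA",
                   product = "sugar phosphatase"),
    genome_feature("b0002", "protein_gene", 2000, 2900, "+", name = "thrB",
                   product = "homoserine kinase"),
    genome_feature("b0003", "protein_gene", 3000, 3900, "-", name = "kinC",
                   product = "sensor kinase"))
  r <- replicon("chr", 10000L, "linear", features = f)

  res <- search_replicon("100-200", r)
  expect_identical(res$matches$match_kind, "range")
  expect_identical(res$view$view_start, 100L)
  expect_gte(res$view$view_start + visible_span(res$view) - 1L, 200L)

  res <- search_replicon("2500", r)
  expect_identical(res$matches$match_kind, "coordinate")
  expect_true(genome_to_canvas(res$view, 2500)$in_view)
  expect_error(search_replicon("99999", r), "outside")

  # case-insensitive exact gene name beats product substring
  res <- search_replicon("yida", r)
  expect_identical(res$matches$feature_id, "b0001")
  expect_identical(res$matches$match_kind, "gene_name")
  expect_true(genome_to_canvas(res$view, 1450)$in_view)

  res <- search_replicon("b0002", r)
  expect_identical(res$matches$match_kind, "accession")

  # all and only the kinase products, in feature order
  res <- search_replicon("kinase", r)
  expect_identical(res$matches$feature_id, c("b0002", "b0003"))
  expect_identical(unique(res$matches$match_kind), "product_substring")

  # a gene *named* kinC is found by name, not product, first
  res <- search_replicon("kinC", r)
  expect_identical(res$matches$match_kind, "gene_name")

  expect_identical(nrow(search_replicon("nothing-here", r)$matches), 0L)
})
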