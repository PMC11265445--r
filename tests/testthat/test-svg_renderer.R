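test_that("rendered SVG is well-formed with one group per glyph", {
  r <- small_fixture(seed = 29)
  lay <- layout(view_state(r, 1, scale = 10, canvas_width = 600,
                           n_lines = 4))
  svg <- render_svg(lay)
  doc <- xml2::read_xml(svg)  # errors if not well-formed XML
  ns <- xml2::xml_ns(doc)
  glyph_groups <- xml2::xml_find_all(doc, "//d1:g[@class='glyph']", ns)
  expect_identical(length(glyph_groups), nrow(lay$glyphs))
  # every glyph group carries machine-readable coords and a tooltip title
  for (g in glyph_groups[seq_len(min(5, length(glyph_groups)))]) {
    expect_false(is.na(xml2::xml_attr(g, "data-feature")))
    expect_false(is.na(xml2::xml_attr(g, "data-start")))
    title <- xml2::xml_find_first(g, "./d1:title", ns)
    expect_gt(nchar(xml2::xml_text(title)), 0)
  }
})

test_that("an empty layout still renders a valid background-only document", {
  r <- replicon("bare", 1000L, "linear")
  svg <- render_svg(layout(view_state(r, 1, 2, 200, n_lines = 2)))
  doc <- xml2::read_xml(svg)
  ns <- xml2::xml_ns(doc)
  expect_identical(length(xml2::xml_find_all(doc, "//d1:g[@class='glyph']",
                                             ns)), 0L)
  expect_identical(
    length(xml2::xml_find_all(doc, "//d1:rect[@class='background']", ns)), 1L)
})

test_that("rendering the same layout twice is byte-identical", {
  r <- small_fixture(seed = 29)
  lay <- layout(view_state(r, 501, scale = 5, canvas_width = 500,
                           n_lines = 3))
  expect_identical(render_svg(lay, include_legend = TRUE),
                   render_svg(lay, include_legend = TRUE))
  fam <- generate_strain_family(fixture_spec(seed = 31, n_operons = 8))
  lead <- fam$orthologs$gene_id[fam$orthologs$genome_id == "strain1"][1]
  cl <- build_alignment(lead, fam$replicons, fam$orthologs, 10, 800)
  expect_identical(render_svg(cl), render_svg(cl))
})

test_that("the overview bar marks the viewed fraction in red", {
  r <- toy_replicon("linear", 10000L)
  # full-replicon view: the marker covers the whole bar
  vfull <- view_state(r, 1, scale = 10, canvas_width = 1000, wrap = FALSE)
  g <- render_overview_bar(r, vfull)
  marks <- xml2::xml_find_all(g, "//rect[@class='view-marker']")
  expect_identical(length(marks), 1L)
  expect_equal(as.numeric(xml2::xml_attr(marks[[1]], "width")), 1000)

  # 10% view: marker width is 10% of the bar (+- 1 px)
  v10 <- view_state(r, 4001, scale = 1, canvas_width = 1000, wrap = FALSE)
  marks <- xml2::xml_find_all(render_overview_bar(r, v10),
                              "//rect[@class='view-marker']")
  expect_equal(as.numeric(xml2::xml_attr(marks[[1]], "width")), 100,
               tolerance = 1 / 100)
  expect_equal(as.numeric(xml2::xml_attr(marks[[1]], "x")), 400,
               tolerance = 1 / 100)

  # origin-spanning circular view draws exactly two segments
  circ <- toy_replicon("circular", 10000L)
  vwrap <- view_state(circ, 9501, scale = 1, canvas_width = 1000,
                      wrap = FALSE)
  marks <- xml2::xml_find_all(render_overview_bar(circ, vwrap),
                              "//rect[@class='view-marker']")
  expect_identical(length(marks), 2L)
})

test_that("the legend reflects the tri-state policy and Off kinds vanish", {
  pol <- display_policy(tfbs = "Off")
  leg <- render_legend(pol)
  rows <- xml2::xml_find_all(leg, "//g[@class='legend-row']")
  expect_identical(length(rows), 8L)
  settings <- xml2::xml_attr(rows, "data-setting")
  kinds <- xml2::xml_attr(rows, "data-kind")
  expect_identical(settings[kinds == "tfbs"], "Off")
  expect_identical(unique(settings[kinds != "tfbs"]), "Auto")

  # cross-check: Off kinds are absent from the rendered main area
  r <- small_fixture(seed = 29)
  lay <- layout(view_state(r, 1, scale = 5, canvas_width = 600, n_lines = 4),
                policy = pol)
  expect_false(any(lay$glyphs$kind == "tfbs"))
  doc <- xml2::read_xml(render_svg(lay, include_legend = TRUE))
  ns <- xml2::xml_ns(doc)
  expect_identical(length(xml2::xml_find_all(
    doc, "//d1:g[@class='glyph'][@data-kind='tfbs']", ns)), 0L)

  # legend only appears on request
  doc2 <- xml2::read_xml(render_svg(lay))
  expect_identical(length(xml2::xml_find_all(
    doc2, "//d1:g[@class='legend']", ns)), 0L)
})

test_that("basic-mode operon coloring separates different operons", {
  r <- small_fixture(seed = 29)
  lay <- layout(view_state(r, 1, scale = 10, canvas_width = 800,
                           n_lines = 6))
  doc <- xml2::read_xml(render_svg(lay))
  ns <- xml2::xml_ns(doc)
  genes <- xml2::xml_find_all(
    doc, "//d1:g[@class='glyph'][@data-kind='protein_gene']", ns)
  fills <- vapply(genes, function(g) {
    shp <- xml2::xml_find_first(g, "./d1:polygon | ./d1:rect", ns)
    xml2::xml_attr(shp, "fill")
  }, character(1))
  ids <- xml2::xml_attr(genes, "data-feature")
  ops <- r$features$operon_id[match(ids, r$features$id)]
  # same-operon genes share a fill
  for (op in unique(ops)) {
    expect_identical(length(unique(fills[ops == op])), 1L)
  }
  # adjacent distinct operons do not share a fill (palette cycles by 12)
  uop <- unique(ops)
  for (i in seq_len(length(uop) - 1)) {
    expect_false(fills[match(uop[i], ops)] == fills[match(uop[i + 1], ops)])
  }
})

test_that("comparative SVG grays non-orthologs and tags groups", {
  fam <- generate_strain_family(fixture_spec(seed = 53, n_operons = 8,
                                             gain_prob = 1))
  lead <- fam$orthologs$gene_id[fam$orthologs$genome_id == "strain1"][1]
  cl <- build_alignment(lead, fam$replicons, fam$orthologs, 20, 900)
  doc <- xml2::read_xml(render_svg(cl))
  ns <- xml2::xml_ns(doc)
  genes <- xml2::xml_find_all(
    doc, "//d1:g[@class='glyph'][@data-kind='protein_gene']", ns)
  novel <- genes[grepl("novel", xml2::xml_attr(genes, "data-feature"))]
  expect_gt(length(novel), 0)
  for (g in novel) {
    shp <- xml2::xml_find_first(g, "./d1:polygon", ns)
    expect_identical(xml2::xml_attr(shp, "fill"),
                     render_options()$gray_fill)
    expect_true(is.na(xml2::xml_attr(g, "data-group")))
  }
  # orthologs of the lead gene share a data-group attribute
  hl <- ortholog_highlight(lead, cl)
  tagged <- xml2::xml_find_all(doc, sprintf(
    "//d1:g[@data-group='%s']",
    fam$orthologs$group_id[fam$orthologs$gene_id == lead][1]), ns)
  expect_identical(length(tagged), nrow(hl))
})
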