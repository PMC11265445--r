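family_fixture <- function(seed = 31, n_operons = 10, n_strains = 5,
                           loss_prob = 0.15) {
  generate_strain_family(fixture_spec(seed = seed, n_operons = n_operons,
                                      n_strains = n_strains,
                                      loss_prob = loss_prob))
}

lead_gene_of <- function(fam) {
  # a lead gene every strain retains, so all rows are included
  leads <- fam$orthologs[fam$orthologs$genome_id == "strain1", ]
  counts <- table(fam$orthologs$group_id)
  shared <- names(counts)[counts == length(fam$replicons)]
  leads$gene_id[match(shared[1], leads$group_id)]
}

test_that("two orthologs align their centers to the same anchor pixel", {
  f1 <- genome_feature("gA", "protein_gene", 100, 200, "+")
  f2 <- genome_feature("gB", "protein_gene", 1100, 1300, "+")
  r1 <- replicon("G1", 5000L, "linear", features = f1)
  r2 <- replicon("G2", 5000L, "linear", features = f2)
  tab <- as_ortholog_table(data.frame(
    genome_id = c("G1", "G2"), gene_id = c("gA", "gB"),
    group_id = c("og1", "og1")))
  cl <- build_alignment("gA", list(G1 = r1, G2 = r2), tab, scale = 10,
                        canvas_width = 1000)
  expect_identical(length(cl$rows), 2L)
  for (row in cl$rows) {
    p <- genome_to_canvas(row$view, row$anchor_center)
    expect_true(p$in_view)
    expect_equal(p$x, 500, tolerance = 1e-9)
    expect_false(row$view$wrap)
    expect_identical(row$view$n_lines, 1L)
  }
  expect_identical(cl$rows$G1$anchor_center, 150L)
  expect_identical(cl$rows$G2$anchor_center, 1200L)
})

test_that("genomes without the lead group are excluded, rows share scale", {
  fam <- family_fixture()
  lead <- lead_gene_of(fam)
  cl <- build_alignment(lead, fam$replicons, fam$orthologs, scale = 8,
                        canvas_width = 900)
  expect_identical(sort(c(names(cl$rows), cl$excluded_genomes)),
                   sort(names(fam$replicons)))
  expect_identical(length(cl$rows), 5L)  # shared group: all strains row up
  expect_true(all(vapply(cl$rows, function(r) r$view$scale, numeric(1)) == 8))
  expect_identical(names(cl$rows)[1], "strain1")

  # a genome provably lacking the group drops out of the rows
  tab2 <- fam$orthologs[fam$orthologs$genome_id != "strain3" |
                          fam$orthologs$group_id !=
                            fam$orthologs$group_id[
                              fam$orthologs$gene_id == lead][1], ]
  cl2 <- build_alignment(lead, fam$replicons, as_ortholog_table(tab2),
                         scale = 8, canvas_width = 900)
  expect_true("strain3" %in% cl2$excluded_genomes)
  expect_false("strain3" %in% names(cl2$rows))

  expect_error(
    build_alignment(lead, fam$replicons,
                    as_ortholog_table(fam$orthologs[0, ]), 8, 900),
    "absent from the ortholog table")
})

test_that("anchor centers stay aligned within a pixel across strains", {
  set.seed(70)
  for (seed in c(101, 202, 303)) {
    fam <- family_fixture(seed = seed)
    lead <- lead_gene_of(fam)
    cl <- build_alignment(lead, fam$replicons, fam$orthologs,
                          scale = runif(1, 2, 30), canvas_width = 1000)
    xs <- vapply(cl$rows, function(r)
      genome_to_canvas(r$view, r$anchor_center)$x, numeric(1))
    expect_lt(max(xs) - min(xs), 1)
  }
})

test_that("synchronized zoom and pan preserve the alignment", {
  fam <- family_fixture()
  lead <- lead_gene_of(fam)
  cl <- build_alignment(lead, fam$replicons, fam$orthologs, scale = 10,
                        canvas_width = 1000)
  smax <- cl$rows[[1]]$view$scale_max
  for (factor in c(0.25, 0.5, 2, 4)) {
    cl2 <- zoom_comparative(cl, factor)
    xs <- vapply(cl2$rows, function(r)
      genome_to_canvas(r$view, r$anchor_center)$x, numeric(1))
    expect_lt(max(xs) - min(xs), 1)
    expect_equal(cl2$rows[[1]]$view$scale, min(10 * factor, smax))
  }
  cl3 <- pan_comparative(cl, 500)
  shifts <- mapply(function(a, b) b$view$view_start - a$view$view_start,
                   cl$rows, cl3$rows)
  expect_true(all(shifts %% cl$rows[[1]]$view$replicon$length == 500))
})

test_that("ortholog colors recycle with period 12", {
  groups <- paste0("og", 1:13)
  cols <- assign_ortholog_colors(groups)
  expect_identical(length(unique(cols[1:12])), 12L)
  expect_identical(unname(cols["og13"]), unname(cols["og1"]))
  expect_identical(unname(assign_ortholog_colors("solo")), 0L)
  # exact periodicity over a longer run
  many <- assign_ortholog_colors(paste0("g", 1:40))
  expect_identical(unname(many), (0:39) %% 12L)
})

test_that("ortholog highlight returns the symmetric group orbit", {
  fam <- family_fixture()
  lead <- lead_gene_of(fam)
  cl <- build_alignment(lead, fam$replicons, fam$orthologs, scale = 10,
                        canvas_width = 1000)
  hl <- ortholog_highlight(lead, cl)
  expect_identical(nrow(hl), 5L)  # one ortholog per strain
  # symmetry: b in highlight(a) <=> a in highlight(b)
  other <- hl$gene_id[hl$genome_id == "strain2"]
  back <- ortholog_highlight(other, cl)
  expect_true(lead %in% back$gene_id)
  expect_identical(sort(back$gene_id), sort(hl$gene_id))
  # a gene absent from the table highlights only itself
  r1 <- cl$rows$strain1$view$replicon
  tu <- r1$features$id[r1$features$kind == "transcription_unit"][1]
  solo <- ortholog_highlight(tu, cl)
  expect_identical(nrow(solo), 1L)
  expect_identical(solo$gene_id, tu)
})
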