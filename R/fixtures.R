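# Seeded synthetic bacterial genome generator: operons of same-strand genes
# with promoters (TSS + sigma factor, 0-2 TFBS), terminators, real
# ATG..stop coding structure, and derived strain families with an ortholog
# table. Generation is a pure function of the fixture spec: one seed, one
# genome, byte-identical files.

with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

#' Specification for synthetic genome fixtures
#'
#' Describes the emulated genome architecture: how many operons, how many
#' genes per operon, gene and intergenic-gap length ranges, regulatory-site
#' densities (one TSS with a random sigma factor and one terminator per
#' operon, 0-2 TF binding sites per promoter), replicon topology, and — for
#' strain families — the number of strains and per-strain perturbation
#' rates.
#'
#' @param seed Integer RNG seed; the generator is a pure function of it.
#' @param n_operons Number of operons.
#' @param genes_per_operon Integer range `c(min, max)`.
#' @param gene_length Length range in bases (protein genes are rounded to
#'   whole codons).
#' @param intergenic_gap Gap range between operons, in bases.
#' @param intra_gap Gap range between genes within an operon.
#' @param tfbs_per_promoter Range of TF-binding sites per promoter.
#' @param sigma_factors Sigma factor names sampled for TSS labels.
#' @param rna_gene_prob,pseudogene_prob Per-gene probabilities of emitting
#'   an RNA gene or pseudogene instead of a protein-coding gene.
#' @param topology Replicon topology.
#' @param n_strains Number of strains in a family (lead strain included).
#' @param loss_prob Per-gene loss probability in each derived strain.
#' @param jitter_sd Standard deviation (bases) of the gap-length jitter
#'   applied when re-laying-out a derived strain.
#' @param gain_prob Per-operon probability that a derived strain gains a
#'   novel gene absent from the ortholog table (renders gray in
#'   comparative mode).
#' @return A list of class `"fixture_spec"`.
#' @export
fixture_spec <- function(seed = 1L, n_operons = 20L,
                         genes_per_operon = c(1L, 4L),
                         gene_length = c(300L, 900L),
                         intergenic_gap = c(50L, 300L),
                         intra_gap = c(15L, 60L),
                         tfbs_per_promoter = c(0L, 2L),
                         sigma_factors = c("Sigma70", "Sigma38", "Sigma54",
                                           "Sigma32", "Sigma24"),
                         rna_gene_prob = 0.08, pseudogene_prob = 0.05,
                         topology = c("circular", "linear"),
                         n_strains = 5L, loss_prob = 0.15, jitter_sd = 25,
                         gain_prob = 0.05) {
  structure(list(
    seed = as.integer(seed), n_operons = as.integer(n_operons),
    genes_per_operon = as.integer(genes_per_operon),
    gene_length = as.integer(gene_length),
    intergenic_gap = as.integer(intergenic_gap),
    intra_gap = as.integer(intra_gap),
    tfbs_per_promoter = as.integer(tfbs_per_promoter),
    sigma_factors = sigma_factors, rna_gene_prob = rna_gene_prob,
    pseudogene_prob = pseudogene_prob, topology = match.arg(topology),
    n_strains = as.integer(n_strains), loss_prob = loss_prob,
    jitter_sd = jitter_sd, gain_prob = gain_prob
  ), class = "fixture_spec")
}

rand_int <- function(range, n = 1L) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  STOP_CODONS)

rand_cds <- function(len) {
  n_codons <- len %/% 3L
  paste0("ATG",
         paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         sample(STOP_CODONS, 1L))
}

PRODUCT_ADJ <- c("putative", "ATP-binding", "membrane", "periplasmic",
                 "DNA-binding", "hypothetical")
PRODUCT_NOUN <- c("kinase", "transporter", "regulator", "hydrolase",
                  "synthase", "permease", "protein")

# sample the architecture + sequences of every operon once; strains are
# re-laid-out from this shared plan so orthologs carry identical CDSs
sample_genome_plan <- function(spec) {
  lapply(seq_len(spec$n_operons), function(o) {
    strand <- sample(c("+", "-"), 1L)
    n_genes <- rand_int(spec$genes_per_operon)
    genes <- lapply(seq_len(n_genes), function(j) {
      u <- stats::runif(1)
      kind <- if (u < spec$rna_gene_prob) "rna_gene"
              else if (u < spec$rna_gene_prob + spec$pseudogene_prob)
                "pseudogene" else "protein_gene"
      len <- if (kind == "rna_gene") rand_int(c(80L, 200L)) else {
        l <- rand_int(spec$gene_length); (l %/% 3L) * 3L
      }
      coding <- if (kind == "rna_gene") rand_dna(len) else rand_cds(len)
      name <- paste0(paste(sample(letters, 3L, replace = TRUE),
                           collapse = ""), LETTERS[j])
      list(base_id = sprintf("op%02d_g%d", o, j), kind = kind, len = len,
           coding = coding, name = name,
           product = paste(sample(PRODUCT_ADJ, 1L),
                           sample(PRODUCT_NOUN, 1L)))
    })
    n_tfbs <- rand_int(spec$tfbs_per_promoter)
    list(operon = o, strand = strand, genes = genes,
         sigma = sample(spec$sigma_factors, 1L),
         tfbs_widths = if (n_tfbs > 0) rand_int(c(8L, 16L), n_tfbs)
                       else integer(0),
         tf_names = if (n_tfbs > 0)
           paste0(toupper(substr(sapply(seq_len(n_tfbs), function(i)
             paste(sample(letters, 3L), collapse = "")), 1, 1)),
             substr(sapply(seq_len(n_tfbs), function(i)
               paste(sample(letters, 2L), collapse = "")), 1, 2), "R")
           else character(0),
         intra_gaps = if (n_genes > 1) rand_int(spec$intra_gap, n_genes - 1L)
                      else integer(0),
         gap_before = rand_int(spec$intergenic_gap))
  })
}

# materialize a plan (possibly with genes dropped/added) into a replicon
materialize_genome <- function(plan, spec, genome_id, prefix,
                               jitter = FALSE) {
  feats <- list()
  splices <- list()   # coordinate -> coding sequence overlays
  cursor <- 1L
  jit <- function(g) {
    if (!jitter) return(g)
    max(5L, as.integer(round(g + stats::rnorm(1, 0, spec$jitter_sd))))
  }
  for (op in plan) {
    if (!length(op$genes)) next
    cursor <- cursor + jit(op$gap_before)
    promoter <- 60L
    op_id <- sprintf("%s_TU%02d", prefix, op$operon)
    add <- function(f) feats[[length(feats) + 1L]] <<- f
    if (op$strand == "+") {
      tss_pos <- cursor + promoter - 10L
      add(genome_feature(sprintf("%s_tss%02d", prefix, op$operon), "tss",
                         tss_pos, tss_pos, "+", sigma_factor = op$sigma,
                         operon_id = op_id))
      toff <- 0L
      for (k in seq_along(op$tfbs_widths)) {
        w <- op$tfbs_widths[k]
        s <- cursor + toff
        add(genome_feature(sprintf("%s_tfbs%02d_%d", prefix, op$operon, k),
                           "tfbs", s, s + w - 1L, "+",
                           bound_factor = op$tf_names[k]))
        toff <- toff + w + 4L
      }
      gpos <- cursor + promoter
    } else {
      term_pos <- cursor + 6L
      add(genome_feature(sprintf("%s_term%02d", prefix, op$operon),
                         "terminator", term_pos, term_pos, "-",
                         operon_id = op_id))
      gpos <- cursor + 12L
    }
    gene_start1 <- gpos
    for (j in seq_along(op$genes)) {
      gn <- op$genes[[j]]
      s <- gpos; e <- gpos + gn$len - 1L
      add(genome_feature(paste0(prefix, "_", gn$base_id), gn$kind, s, e,
                         op$strand, name = gn$name, product = gn$product,
                         operon_id = op_id))
      splices[[length(splices) + 1L]] <- list(
        start = s,
        seq = if (op$strand == "+" || gn$kind == "rna_gene") gn$coding
              else as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(gn$coding))))
      gpos <- e + 1L
      if (j < length(op$genes)) gpos <- gpos + jit(op$intra_gaps[j])
    }
    gene_end <- gpos - 1L
    add(genome_feature(op_id, "transcription_unit", gene_start1, gene_end,
                       op$strand, operon_id = op_id))
    if (op$strand == "+") {
      term_pos <- gene_end + 6L
      add(genome_feature(sprintf("%s_term%02d", prefix, op$operon),
                         "terminator", term_pos, term_pos, "+",
                         operon_id = op_id))
      cursor <- gene_end + 12L
    } else {
      tss_pos <- gene_end + 10L
      add(genome_feature(sprintf("%s_tss%02d", prefix, op$operon), "tss",
                         tss_pos, tss_pos, "-", sigma_factor = op$sigma,
                         operon_id = op_id))
      toff <- 14L
      for (k in seq_along(op$tfbs_widths)) {
        w <- op$tfbs_widths[k]
        s <- gene_end + toff
        add(genome_feature(sprintf("%s_tfbs%02d_%d", prefix, op$operon, k),
                           "tfbs", s, s + w - 1L, "-",
                           bound_factor = op$tf_names[k]))
        toff <- toff + w + 4L
      }
      cursor <- gene_end + promoter
    }
  }
  L <- cursor + rand_int(spec$intergenic_gap) - 1L
  seq <- strsplit(rand_dna(L), "")[[1]]
  for (sp in splices) {
    idx <- sp$start + seq_len(nchar(sp$seq)) - 1L
    seq[idx] <- strsplit(sp$seq, "")[[1]]
  }
  f <- if (length(feats)) do.call(rbind, feats) else empty_features()
  rownames(f) <- NULL
  replicon(genome_id, L, topology = spec$topology,
           sequence = paste(seq, collapse = ""), features = f)
}

#' Generate a synthetic annotated genome
#'
#' Emits one replicon of operons of consecutive same-strand genes, each
#' operon with an upstream TSS (random sigma factor), a downstream
#' terminator, and 0-2 TF-binding sites near the promoter. Protein-coding
#' genes carry a real ATG..stop codon structure in the sequence, so
#' [translate_cds()] succeeds on every one. Output is a pure function of
#' the spec's seed.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory; when given, writes `<genome_id>.gff3`
#'   and `<genome_id>.fasta` there.
#' @param genome_id Replicon/genome identifier.
#' @return List with `replicon` and, when `dir` is given, `gff3` and
#'   `fasta` file paths.
#' @export
generate_synthetic_genome <- function(spec = fixture_spec(), dir = NULL,
                                      genome_id = "synth1") {
  rep <- with_seed(spec$seed, {
    plan <- sample_genome_plan(spec)
    materialize_genome(plan, spec, genome_id, genome_id, jitter = FALSE)
  })
  out <- list(replicon = rep)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    out$gff3 <- file.path(dir, paste0(genome_id, ".gff3"))
    out$fasta <- file.path(dir, paste0(genome_id, ".fasta"))
    write_features_gff3(rep, out$gff3)
    write_fasta(stats::setNames(rep$sequence, rep$id), out$fasta)
  }
  out
}

#' Generate a family of related strains plus their ortholog table
#'
#' Derives `n_strains` strains from one sampled genome architecture: the
#' lead strain keeps every gene; each other strain loses genes
#' independently with probability `loss_prob`, re-lays-out its coordinates
#' with jittered gap lengths, and occasionally gains a novel gene. The
#' ortholog table links surviving copies of each ancestral gene across
#' strains (one group per ancestral gene); novel genes are absent from the
#' table and therefore render gray in comparative mode.
#'
#' @param spec A [fixture_spec()].
#' @param dir Optional directory for per-strain GFF3/FASTA files and
#'   `orthologs.tsv`.
#' @return List with `replicons` (named list, lead strain first),
#'   `orthologs` (an `"ortholog_table"`), and file paths when `dir` is
#'   given.
#' @export
generate_strain_family <- function(spec = fixture_spec(), dir = NULL) {
  res <- with_seed(spec$seed, {
    plan <- sample_genome_plan(spec)
    reps <- list()
    ortho <- list()
    for (s in seq_len(spec$n_strains)) {
      sid <- sprintf("strain%d", s)
      splan <- plan
      if (s > 1L) {
        novel_n <- 0L
        splan <- lapply(plan, function(op) {
          keep <- stats::runif(length(op$genes)) >= spec$loss_prob
          op$genes <- op$genes[keep]
          op$intra_gaps <- if (sum(keep) > 1L)
            rep(op$intra_gaps, length.out = sum(keep) - 1L) else integer(0)
          if (stats::runif(1) < spec$gain_prob) {
            novel_n <<- novel_n + 1L
            len <- (rand_int(spec$gene_length) %/% 3L) * 3L
            op$genes <- c(op$genes, list(list(
              base_id = sprintf("novel%02d", novel_n),
              kind = "protein_gene", len = len, coding = rand_cds(len),
              name = sprintf("nov%s", LETTERS[novel_n]),
              product = "strain-specific protein")))
            if (length(op$genes) > 1L)
              op$intra_gaps <- c(op$intra_gaps, rand_int(spec$intra_gap))
          }
          op
        })
      }
      reps[[sid]] <- materialize_genome(splan, spec, sid, sid,
                                        jitter = s > 1L)
      for (op in splan) {
        for (gn in op$genes) {
          if (startsWith(gn$base_id, "novel")) next
          ortho[[length(ortho) + 1L]] <- data.frame(
            genome_id = sid, gene_id = paste0(sid, "_", gn$base_id),
            group_id = paste0("og_", gn$base_id), stringsAsFactors = FALSE)
        }
      }
    }
    list(replicons = reps,
         orthologs = as_ortholog_table(do.call(rbind, ortho)))
  })
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    res$files <- list()
    for (sid in names(res$replicons)) {
      rep <- res$replicons[[sid]]
      g <- file.path(dir, paste0(sid, ".gff3"))
      f <- file.path(dir, paste0(sid, ".fasta"))
      write_features_gff3(rep, g)
      write_fasta(stats::setNames(rep$sequence, rep$id), f)
      res$files[[sid]] <- c(gff3 = g, fasta = f)
    }
    res$files$orthologs <- file.path(dir, "orthologs.tsv")
    write_ortholog_table(res$orthologs, res$files$orthologs)
  }
  res
}
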