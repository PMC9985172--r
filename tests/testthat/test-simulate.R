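test_that("ancestral genomes have the configured size and are seed-deterministic", {
  cfg <- sim_config(seed = 4, n_chromosomes = 2, genes_per_chromosome = 50,
                    seq_length = 300)
  anc <- simulate_ancestor(cfg)
  expect_equal(nrow(anc$genes), 100L)
  expect_equal(length(anc$seqs), 100L)
  expect_true(all(nchar(anc$seqs) == 300L))

  anc2 <- simulate_ancestor(cfg)
  expect_identical(anc$seqs, anc2$seqs)
  expect_identical(anc$genes, anc2$genes)

  # different seeds give different sequence content
  hashes <- vapply(1:5, function(s) {
    a <- simulate_ancestor(sim_config(seed = s, n_chromosomes = 1,
                                      genes_per_chromosome = 5,
                                      seq_length = 200))
    paste(a$seqs, collapse = "")
  }, "")
  expect_equal(length(unique(hashes)), 5L)

  expect_error(sim_config(seed = 1, n_chromosomes = 0), "at least one gene")
})

test_that("a lineage with zero events preserves the ancestral gene order", {
  cfg <- sim_config(seed = 9, n_chromosomes = 2, genes_per_chromosome = 30,
                    n_inversions = 0, n_translocations = 0, n_tandem_dups = 0,
                    n_dispersed_dups = 0, n_losses = 0)
  anc <- simulate_ancestor(cfg, sequences = FALSE)
  lin <- evolve_lineage(anc, cfg, "A")
  expect_equal(nrow(lin$event_log), 0L)
  expect_equal(sub("^A_", "", lin$genes$gene_id), anc$genes$gene_id)
  expect_equal(lin$genes$rank, anc$genes$rank)
  expect_equal(lin$genes$strand, anc$genes$strand)
})

test_that("inversions reverse the logged gene run and flip strands", {
  cfg <- sim_config(seed = 31, n_chromosomes = 1, genes_per_chromosome = 40,
                    n_inversions = 1, n_translocations = 0, n_tandem_dups = 0,
                    n_dispersed_dups = 0, n_losses = 0,
                    inversion_length = c(10L, 10L))
  anc <- simulate_ancestor(cfg, sequences = FALSE)
  lin <- evolve_lineage(anc, cfg, "A")
  log <- lin$event_log
  expect_equal(log$type, "inversion")
  seg <- (log$position + 1L):(log$position + log$length)
  expected <- anc$genes$gene_id
  expected[seg] <- rev(expected[seg])
  expect_equal(sub("^A_", "", lin$genes$gene_id), expected)
  expect_equal(lin$genes$strand[seg], rep("-", 10L))
  expect_equal(lin$genes$strand[-seg], rep("+", 30L))
})

test_that("event logs carry every configured event and gene counts balance", {
  cfg <- sim_config(seed = 12, n_chromosomes = 3, genes_per_chromosome = 40,
                    n_inversions = 5, n_translocations = 2, n_tandem_dups = 3,
                    n_dispersed_dups = 2, n_losses = 4)
  sim <- simulate_genomes(cfg, sequences = FALSE)
  for (lid in c("A", "B")) {
    log <- sim$lineages[[lid]]$event_log
    expect_equal(nrow(log), 16L)
    expect_equal(sum(log$type == "inversion"), 5L)
    expect_equal(sum(log$type == "translocation"), 2L)
    expect_equal(sum(log$type == "tandem_duplication"), 3L)
    expect_equal(sum(log$type == "dispersed_duplication"), 2L)
    expect_equal(sum(log$type == "loss"), 4L)
    # conservation: out = in + duplications - losses
    expect_equal(nrow(sim$lineages[[lid]]$genes), 120L + 5L - 4L)
  }
  # anchors are single-copy: each gene at most once
  expect_false(anyDuplicated(sim$anchors$gene_a) > 0)
  expect_false(anyDuplicated(sim$anchors$gene_b) > 0)
  # identical config reproduces identical output
  sim2 <- simulate_genomes(cfg, sequences = FALSE)
  expect_identical(sim$lineages$A$genes, sim2$lineages$A$genes)
  expect_identical(sim$event_log, sim2$event_log)
})

test_that("TE copy simulation realizes the configured burst structure", {
  cfg0 <- sim_config(seed = 5, te_bursts = list(
    list(mode = 0, sd = 0, n_copies = 5L, family = "fam1",
         superfamily = "Ty3/Gypsy", copy_length = 400L)))
  te0 <- simulate_te_copies(cfg0)
  expect_true(all(te0$copies == te0$consensus[["fam1"]]))
  expect_true(all(is.na(te0$hits$divergence_pct)))

  cfg2 <- sim_config(seed = 6, te_bursts = list(
    list(mode = 5, sd = 1, n_copies = 200L, family = "fam1",
         superfamily = "Ty3/Gypsy", copy_length = 300L),
    list(mode = 25, sd = 1, n_copies = 200L, family = "fam1",
         superfamily = "Ty3/Gypsy", copy_length = 300L),
    list(mode = 10, sd = 1, n_copies = 0L, family = "fam2",
         superfamily = "Ty1/Copia", copy_length = 300L)))
  te2 <- simulate_te_copies(cfg2)
  expect_equal(nrow(te2$truth), 400L)         # n_copies = 0 burst omitted
  expect_false("fam2" %in% te2$truth$family)
  # truth divergences are bimodal around the two configured modes
  lo <- te2$truth$true_divergence_pct[te2$truth$true_divergence_pct < 15]
  hi <- te2$truth$true_divergence_pct[te2$truth$true_divergence_pct >= 15]
  expect_equal(length(lo), 200L)
  expect_equal(length(hi), 200L)
  expect_lt(abs(mean(lo) - 5), 0.5)
  expect_lt(abs(mean(hi) - 25), 0.5)

  expect_error(sim_config(seed = 1, te_bursts = list(
    list(mode = 80, sd = 1, n_copies = 10L, family = "f",
         superfamily = "Ty3/Gypsy", copy_length = 100L))), "saturation")
})

test_that("sex-locus simulation places U/V copies by sex and encodes translocations", {
  cfg <- sim_config(seed = 8, gametolog = list(
    n_gametolog_pairs = 20L, n_pseudoautosomal = 0L,
    n_translocated_U_loci = 4L, locus_length = 500L))
  sx <- simulate_sex_loci(cfg)
  tr_loci <- unique(sx$truth$locus[sx$truth$translocated])
  expect_equal(length(tr_loci), 4L)
  for (l in sx$loci) {
    if (l$translocated) {
      # present in both sexes, V copy gone: the male copy is U-descended
      expect_true(find_in_genome(l$lc_f, sx$female_genome)$present)
      expect_true(find_in_genome(l$lc_f, sx$male_genome)$present)
      expect_gt(bryostruct:::alignment_identity(l$lc_f, l$lc_m), 0.98)
    }
  }
  # with zero translocations every U-descended sequence is female-only
  cfg0 <- sim_config(seed = 8, gametolog = list(
    n_gametolog_pairs = 6L, n_pseudoautosomal = 0L,
    n_translocated_U_loci = 0L, locus_length = 500L))
  sx0 <- simulate_sex_loci(cfg0)
  for (l in sx0$loci)
    expect_false(find_in_genome(l$lc_f, sx0$male_genome)$present)

  expect_error(sim_config(seed = 1, gametolog = list(
    n_gametolog_pairs = 2L, n_translocated_U_loci = 3L)),
    "n_translocated_U_loci")
})

test_that("pseudoautosomal loci are near-identical between the sexes", {
  cfg <- sim_config(seed = 14, gametolog = list(
    n_gametolog_pairs = 1L, n_pseudoautosomal = 8L,
    n_translocated_U_loci = 0L, locus_length = 1000L))
  sx <- simulate_sex_loci(cfg)
  par_loci <- Filter(function(l) l$kind == "pseudoautosomal", sx$loci)
  ident <- vapply(par_loci, function(l)
    bryostruct:::alignment_identity(l$lc_f, l$lc_m), 0)
  # two-sided drift at 0.004 subs/site -> expected identity about 99.2%
  expect_gt(mean(ident), 0.99)
  # and the homologous autosomal scaffolds exceed the 99% criterion
  expect_gt(scaffold_identity(sx$female_genome[["scfA_1"]],
                              sx$male_genome[["scfA_1"]]), 99)
})

test_that("emitted files round-trip through the readers", {
  cfg <- sim_config(seed = 17, n_chromosomes = 2, genes_per_chromosome = 10,
                    n_inversions = 1, n_translocations = 0,
                    n_tandem_dups = 1, n_dispersed_dups = 0, n_losses = 1,
                    seq_length = 300,
                    te_bursts = list(list(mode = 5, sd = 1, n_copies = 12L,
                                          family = "fam1",
                                          superfamily = "Ty3/Gypsy",
                                          copy_length = 200L)),
                    gametolog = list(n_gametolog_pairs = 2L,
                                     n_pseudoautosomal = 1L,
                                     n_translocated_U_loci = 0L,
                                     locus_length = 300L))
  sim <- simulate_genomes(cfg)
  te <- simulate_te_copies(cfg)
  sx <- simulate_sex_loci(cfg)
  outdir <- withr::local_tempdir()
  emit_simulation(sim, outdir, te = te, sex = sx)

  back <- rank_genes(read_gff3(file.path(outdir, "lineage_A.gff3")))
  expect_equal(back$gene_id, sim$lineages$A$genes$gene_id)
  expect_equal(back$start, sim$lineages$A$genes$start)

  anc_tab <- read_anchor_table(file.path(outdir, "anchors.tsv"))
  expect_equal(nrow(anc_tab), nrow(sim$anchors))

  hits <- read_repeatmasker_out(file.path(outdir, "repeats.out"))
  expect_equal(nrow(hits), 12L)  # one row per simulated copy
  expect_equal(hits$superfamily, rep("Ty3/Gypsy", 12L))

  fg <- read_fasta(file.path(outdir, "female_genome.fasta"))
  expect_identical(unname(fg), unname(sx$female_genome))
})
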