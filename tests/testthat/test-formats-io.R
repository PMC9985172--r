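test_that("GFF3 reading converts coordinates and picks the longest mRNA", {
  path <- write_gff3_fixture(withr::local_tempfile(fileext = ".gff3"))
  expect_warning(gt <- read_gff3(path), regexp = NA)
  expect_s3_class(gt, "gene_table")
  expect_equal(nrow(gt), 3L)
  g1 <- gt[gt$gene_id == "g1", ]
  expect_equal(c(g1$start, g1$end), c(0L, 300L))  # 1..300 -> [0,300)
  # g2 has mRNAs of 900 bp (two exons) and 600 bp; the 900 bp one wins
  g2e <- gt$exons[gt$gene_id == "g2"][[1]]
  expect_equal(unname(g2e), cbind(c(1000L, 1500L), c(1400L, 2000L)),
               ignore_attr = TRUE)
  expect_equal(gt$cds_length[gt$gene_id == "g2"], 900L)
  expect_equal(gt$protein_length[gt$gene_id == "g2"], 300L)
  expect_equal(gt$strand[gt$gene_id == "g2"], "-")
})

test_that("malformed GFF3 lines and CDS-less genes are handled", {
  bad <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scf1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
               "scf1\tsrc\tmRNA\t1\t300"), bad)
  expect_error(read_gff3(bad), "line 3")

  nocds <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scf1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
               "scf1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
               "scf1\tsrc\texon\t1\t300\t.\t+\t.\tParent=g1.t1",
               "scf1\tsrc\tCDS\t1\t300\t.\t+\t.\tParent=g1.t1",
               "scf1\tsrc\tgene\t400\t600\t.\t+\t.\tID=g2",
               "scf1\tsrc\tmRNA\t400\t600\t.\t+\t.\tID=g2.t1;Parent=g2",
               "scf1\tsrc\texon\t400\t600\t.\t+\t.\tParent=g2.t1"), nocds)
  expect_warning(gt <- read_gff3(nocds), "without CDS")
  expect_equal(gt$gene_id, "g1")
})

test_that("GFF3 writing round-trips gene records", {
  cfg <- sim_config(seed = 21, n_chromosomes = 2, genes_per_chromosome = 8,
                    n_inversions = 1, n_translocations = 0,
                    n_tandem_dups = 1, n_dispersed_dups = 0, n_losses = 1)
  sim <- simulate_genomes(cfg, sequences = FALSE)
  genes <- sim$lineages$A$genes
  path <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(genes, path)
  back <- rank_genes(read_gff3(path))
  expect_equal(back$gene_id, genes$gene_id)
  expect_equal(back$start, genes$start)
  expect_equal(back$end, genes$end)
  expect_equal(back$strand, genes$strand)
  expect_equal(back$rank, genes$rank)
  expect_equal(lapply(back$exons, unname), lapply(genes$exons, unname))
})

test_that("gene ranking is per-scaffold, tie-broken, idempotent and order-free", {
  gt <- make_genes(c("a", "b", "c"), "s1", c(10L, 500L, 900L),
                   c(100L, 600L, 1000L))
  r <- rank_genes(gt)
  expect_equal(r$rank[match(c("a", "b", "c"), r$gene_id)], c(0L, 1L, 2L))

  # equal starts: ordered by end then id
  tie <- make_genes(c("z", "y"), "s1", c(10L, 10L), c(400L, 300L))
  r2 <- rank_genes(tie)
  expect_equal(r2$gene_id[r2$rank == 0L], "y")

  two <- make_genes(c("a", "b", "c", "d"), c("s1", "s2", "s1", "s2"),
                    c(10L, 5L, 300L, 700L), c(20L, 15L, 400L, 800L))
  r3 <- rank_genes(two)
  # brute-force per-scaffold sort
  for (sc in unique(two$scaffold)) {
    sub <- two[two$scaffold == sc, ]
    expected <- sub$gene_id[order(sub$start)]
    expect_equal(r3$gene_id[r3$scaffold == sc][order(r3$rank[r3$scaffold == sc])],
                 expected)
    expect_equal(sort(r3$rank[r3$scaffold == sc]), seq_len(nrow(sub)) - 1L)
  }
  expect_equal(rank_genes(r3), r3)               # idempotent
  perm <- r3[sample(nrow(r3)), ]
  expect_equal(rank_genes(perm), r3)             # permutation-invariant
  expect_error(rank_genes(rbind(gt, gt)), "duplicate gene_id")
})

test_that("annotation statistics match hand computation", {
  one <- make_genes("g", "s1", 0L, 300L)
  st <- annotation_stats(one)
  expect_equal(st$mean_gene_length, 300)
  expect_equal(st$exons_per_mrna, 1)
  expect_equal(st$mean_intron_length, 0)
  expect_false(st$has_introns)

  two_exon <- gene_table("g", "s1", 0L, 350L, "+",
                         exons = list(cbind(c(0L, 150L), c(100L, 350L))))
  st2 <- annotation_stats(two_exon)
  expect_equal(st2$mean_exon_length, 150)
  expect_equal(st2$mean_intron_length, 50)
  expect_equal(st2$exons_per_mrna, 2)

  expect_error(annotation_stats(one[0, ]), "at least one gene")
})

test_that("annotation statistics agree with an independent re-summation", {
  set.seed(404)
  n <- 10L
  exlist <- list(); starts <- ends <- integer(n)
  for (i in 1:n) {
    k <- sample(1:4, 1)
    bounds <- sort(sample(0:2000, 2 * k))
    ex <- cbind(bounds[seq(1, 2 * k, 2)], bounds[seq(2, 2 * k, 2)])
    exlist[[i]] <- ex
    starts[i] <- ex[1, 1]; ends[i] <- ex[k, 2]
  }
  gt <- gene_table(sprintf("g%02d", 1:n), "s1", starts, ends, "+", exlist)
  st <- annotation_stats(gt)
  # spreadsheet-style recomputation
  all_ex <- do.call(rbind, exlist)
  exp_exon <- mean(all_ex[, 2] - all_ex[, 1])
  introns <- unlist(lapply(exlist, function(e)
    if (nrow(e) > 1) e[-1, 1] - e[-nrow(e), 2] else NULL))
  expect_equal(st$mean_gene_length, mean(ends - starts))
  expect_equal(st$mean_exon_length, exp_exon)
  expect_equal(st$mean_intron_length, mean(introns))
  expect_equal(st$exons_per_mrna, nrow(all_ex) / n)
  expect_equal(st$mean_cds_length, mean(sapply(exlist, function(e)
    sum(e[, 2] - e[, 1]))))
  # replicating every gene k times leaves all means unchanged
  gt3 <- rank_genes(do.call(rbind, lapply(1:3, function(k) {
    g <- gt; g$gene_id <- paste0(g$gene_id, "_", k); g
  })))
  st3 <- annotation_stats(gt3)
  for (f in c("mean_gene_length", "mean_cds_length", "mean_intron_length",
              "mean_exon_length", "exons_per_mrna"))
    expect_equal(st3[[f]], st[[f]])
})

test_that("RepeatMasker .out parsing handles the fixed dialect", {
  hdr_only <- withr::local_tempfile(fileext = ".out")
  writeLines(rm_out_header, hdr_only)
  expect_equal(nrow(read_repeatmasker_out(hdr_only)), 0L)

  f <- withr::local_tempfile(fileext = ".out")
  writeLines(c(rm_out_header,
    "  263 10.5  0.0  0.0  scf1   1001  1500 (0) + rep1  LTR/Gypsy  1 500 (0) 1",
    "  100  2.0  0.0  0.0  scf1   2001  2300 (0) C rep2  LTR/Copia  1 300 (0) 2",
    "   90  7.5  0.0  0.0  scf2    501   800 (0) + rep3  DNA/hAT    1 300 (0) 3"), f)
  hits <- read_repeatmasker_out(f)
  expect_equal(nrow(hits), 3L)
  expect_equal(hits$scaffold, c("scf1", "scf1", "scf2"))
  expect_equal(hits$start, c(1000L, 2000L, 500L))   # 1-based -> 0-based
  expect_equal(hits$end, c(1500L, 2300L, 800L))
  expect_equal(hits$strand, c("+", "-", "+"))
  expect_equal(hits$family, c("rep1", "rep2", "rep3"))
  expect_equal(hits$superfamily, c("Ty3/Gypsy", "Ty1/Copia", "DNA"))
  expect_equal(hits$divergence_pct, c(10.5, 2.0, 7.5))

  unk <- withr::local_tempfile(fileext = ".out")
  writeLines(c(rm_out_header,
    "  263 10.5  0.0  0.0  scf1   1  500 (0) + rep1  Weird/Thing  1 500 (0) 1"), unk)
  expect_warning(h <- read_repeatmasker_out(unk), "unrecognised")
  expect_equal(h$superfamily, "other")

  trunc <- withr::local_tempfile(fileext = ".out")
  writeLines(c(rm_out_header, "  263 10.5  0.0"), trunc)
  expect_error(read_repeatmasker_out(trunc), "truncated")
})

test_that("anchor tables parse with defaulted similarity", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(character(), empty)
  expect_equal(nrow(read_anchor_table(empty)), 0L)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("a%d\tb%d\t0.%d", 1:5, 1:5, 1:5), f3)
  t3 <- read_anchor_table(f3)
  expect_equal(nrow(t3), 5L)
  expect_equal(t3$similarity, (1:5) / 10)

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(sprintf("a%d\tb%d", 1:4, 1:4), f2)
  t2 <- read_anchor_table(f2)
  expect_equal(t2$similarity, rep(1.0, 4))
  expect_equal(t2$gene_a, paste0("a", 1:4))  # file order preserved
})
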