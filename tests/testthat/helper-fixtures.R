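# Shared fixture builders (everything is generated in code at test time).

# minimal gene table: single-exon genes spanning [start, end)
make_genes <- function(gene_id, scaffold, start, end,
                       strand = rep("+", length(gene_id)),
                       protein_length = NULL) {
  gt <- gene_table(gene_id = gene_id, scaffold = scaffold, start = start,
                   end = end, strand = strand,
                   exons = mapply(function(s, e) cbind(s, e), start, end,
                                  SIMPLIFY = FALSE))
  if (!is.null(protein_length)) gt$protein_length <- as.integer(protein_length)
  gt
}

# anchors on one scaffold pair directly from rank vectors
anchors_from_ranks <- function(rank_a, rank_b,
                               scaffold_a = "s1", scaffold_b = "s2") {
  data.frame(gene_a = paste0("a", seq_along(rank_a)),
             gene_b = paste0("b", seq_along(rank_a)),
             scaffold_a = scaffold_a, scaffold_b = scaffold_b,
             rank_a = rank_a, rank_b = rank_b, stringsAsFactors = FALSE)
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# substitute exactly k positions of a sequence with a different letter
substitute_k <- function(seq, k, alphabet = c("A", "C", "G", "T")) {
  v <- strsplit(seq, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) v[p] <- sample(setdiff(alphabet, v[p]), 1)
  paste(v, collapse = "")
}

# GFF3 text for a small fixture annotation (1-based inclusive coordinates)
write_gff3_fixture <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "scf1\tsrc\tgene\t1\t300\t.\t+\t.\tID=g1",
    "scf1\tsrc\tmRNA\t1\t300\t.\t+\t.\tID=g1.t1;Parent=g1",
    "scf1\tsrc\texon\t1\t300\t.\t+\t.\tParent=g1.t1",
    "scf1\tsrc\tCDS\t1\t300\t.\t+\t.\tParent=g1.t1",
    "scf1\tsrc\tgene\t1001\t2000\t.\t-\t.\tID=g2",
    "scf1\tsrc\tmRNA\t1001\t2000\t.\t-\t.\tID=g2.t1;Parent=g2",
    "scf1\tsrc\texon\t1001\t1400\t.\t-\t.\tParent=g2.t1",
    "scf1\tsrc\texon\t1501\t2000\t.\t-\t.\tParent=g2.t1",
    "scf1\tsrc\tCDS\t1001\t1400\t.\t-\t.\tParent=g2.t1",
    "scf1\tsrc\tCDS\t1501\t2000\t.\t-\t.\tParent=g2.t1",
    "scf1\tsrc\tmRNA\t1001\t1600\t.\t-\t.\tID=g2.t2;Parent=g2",
    "scf1\tsrc\texon\t1001\t1600\t.\t-\t.\tParent=g2.t2",
    "scf1\tsrc\tCDS\t1001\t1600\t.\t-\t.\tParent=g2.t2",
    "scf2\tsrc\tgene\t51\t350\t.\t+\t.\tID=g3",
    "scf2\tsrc\tmRNA\t51\t350\t.\t+\t.\tID=g3.t1;Parent=g3",
    "scf2\tsrc\texon\t51\t350\t.\t+\t.\tParent=g3.t1",
    "scf2\tsrc\tCDS\t51\t350\t.\t+\t.\tParent=g3.t1"
  ), path)
  path
}

rm_out_header <- c(
  "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
  "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
  "")
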