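#' Read a GFF3 gene annotation into a gene table
#'
#' Parses gene/mRNA/exon/CDS features (via [rtracklayer::readGFF()]) and
#' builds one [gene_table()] row per gene.  When a gene has several mRNAs
#' the one with the largest total exon length is chosen as representative
#' (ties broken by mRNA ID); its exon structure and CDS length are stored.
#' GFF3 1-based inclusive coordinates are converted to the internal
#' 0-based half-open convention.  Genes without any CDS are skipped with a
#' warning; protein length is `cds_length %/% 3`.
#'
#' @param path path to a GFF3 file.
#' @return A [gene_table()] (ranks unset; see [rank_genes()]).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nfield <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nfield != 9L))
    stop("malformed GFF3 line ", which(body)[nfield != 9L][1L],
         " in ", path, ": expected 9 tab-separated fields")
  g <- rtracklayer::readGFF(path)
  g$type <- as.character(g$type)
  g$Parent <- vapply(as.list(g$Parent),
                     function(p) if (length(p)) p[[1L]] else NA_character_, "")
  is_gene <- g$type == "gene"
  is_mrna <- g$type %in% c("mRNA", "transcript")
  is_exon <- g$type == "exon"
  is_cds <- g$type == "CDS"
  mrna_parent <- setNames(g$Parent[is_mrna], g$ID[is_mrna])
  exon_by_mrna <- split(which(is_exon), g$Parent[is_exon])
  cds_by_mrna <- split(which(is_cds), g$Parent[is_cds])

  rows <- list()
  skipped <- character()
  for (i in which(is_gene)) {
    gid <- g$ID[i]
    mrnas <- names(mrna_parent)[mrna_parent == gid]
    # representative = mRNA with the largest total exon (fallback CDS) length
    best <- NULL; best_len <- -1L
    for (m in sort(mrnas)) {
      idx <- exon_by_mrna[[m]]
      if (is.null(idx)) idx <- cds_by_mrna[[m]]
      if (is.null(idx)) next
      len <- sum(g$end[idx] - g$start[idx] + 1L)
      if (len > best_len) { best <- m; best_len <- len }
    }
    cds_idx <- if (!is.null(best)) cds_by_mrna[[best]] else NULL
    if (is.null(cds_idx)) { skipped <- c(skipped, gid); next }
    exon_idx <- exon_by_mrna[[best]]
    if (is.null(exon_idx)) exon_idx <- cds_idx
    ex <- cbind(g$start[exon_idx] - 1L, g$end[exon_idx])
    ex <- ex[order(ex[, 1L]), , drop = FALSE]
    rows[[gid]] <- list(scaffold = as.character(g$seqid[i]),
                        start = g$start[i] - 1L, end = g$end[i],
                        strand = as.character(g$strand[i]),
                        exons = ex,
                        cds_length = sum(g$end[cds_idx] - g$start[cds_idx] + 1L))
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " gene(s) without CDS: ",
            paste(head(skipped, 5L), collapse = ", "))
  if (!length(rows)) stop("no genes with CDS found in ", path)
  gene_table(gene_id = names(rows),
             scaffold = vapply(rows, `[[`, "", "scaffold"),
             start = vapply(rows, `[[`, 0L, "start"),
             end = vapply(rows, `[[`, 0L, "end"),
             strand = vapply(rows, `[[`, "", "strand"),
             exons = lapply(rows, `[[`, "exons"),
             cds_length = vapply(rows, `[[`, 0L, "cds_length"))
}

#' Write a gene table as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (one mRNA per gene, CDS
#' mirroring the exon structure, as appropriate for coding-exon-only
#' annotations such as the simulator's) with coordinates converted back to
#' 1-based inclusive.  `read_gff3(write_gff3(x))` reproduces `x`.
#'
#' @param genes a [gene_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    gid <- genes$gene_id[i]
    sc <- genes$scaffold[i]; st <- genes$strand[i]
    writeLines(sprintf("%s\tbryostruct\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       sc, genes$start[i] + 1L, genes$end[i], st, gid), con)
    mid <- paste0(gid, ".t1")
    writeLines(sprintf("%s\tbryostruct\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       sc, genes$start[i] + 1L, genes$end[i], st, mid, gid), con)
    e <- genes$exons[[i]]
    for (k in seq_len(nrow(e))) {
      writeLines(sprintf("%s\tbryostruct\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
                         sc, e[k, 1L] + 1L, e[k, 2L], st, mid), con)
      writeLines(sprintf("%s\tbryostruct\tCDS\t%d\t%d\t.\t%s\t0\tParent=%s",
                         sc, e[k, 1L] + 1L, e[k, 2L], st, mid), con)
    }
  }
  invisible(path)
}

# class/family strings as printed by RepeatMasker -> superfamily labels
.superfamily_map <- function(classfam) {
  out <- character(length(classfam))
  low <- tolower(classfam)
  out[grepl("gypsy", low)] <- "Ty3/Gypsy"
  out[grepl("copia", low)] <- "Ty1/Copia"
  out[out == "" & grepl("^line", low)] <- "LINE"
  out[out == "" & grepl("^dna", low)] <- "DNA"
  out[out == "" & grepl("^(unknown|unspecified)", low)] <- "unknown"
  unknownish <- out == ""
  if (any(unknownish)) {
    warning("unrecognised repeat class string(s): ",
            paste(unique(classfam[unknownish]), collapse = ", "),
            "; using superfamily 'other'")
    out[unknownish] <- "other"
  }
  out
}

#' Read a RepeatMasker .out table
#'
#' Parses the whitespace-aligned RepeatMasker `.out` dialect (two header
#' lines plus a blank line, then one row per alignment).  The repeat
#' class/family column is mapped to one of the superfamilies
#' `Ty3/Gypsy`, `Ty1/Copia`, `LINE`, `DNA`, `unknown`; unrecognised
#' strings become `other` with a warning.  The `div` column is stored as
#' `divergence_pct`; query coordinates are converted to 0-based half-open.
#'
#' @param path path to a RepeatMasker `.out` file.
#' @return A `data.frame` of repeat hits with columns `scaffold`, `start`,
#'   `end`, `strand`, `family`, `superfamily`, `divergence_pct`.
#' @export
read_repeatmasker_out <- function(path) {
  lines <- readLines(path)
  if (length(lines) > 3L) lines <- lines[-(1:3)] else lines <- character()
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(scaffold = character(), start = integer(),
                      end = integer(), strand = character(),
                      family = character(), superfamily = character(),
                      divergence_pct = numeric(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  short <- lengths(fields) < 11L
  if (any(short))
    stop("truncated RepeatMasker line ", which(short)[1L] + 3L, " in ", path)
  get <- function(k) vapply(fields, `[[`, "", k)
  hits <- data.frame(
    scaffold = get(5L),
    start = as.integer(get(6L)) - 1L,
    end = as.integer(get(7L)),
    strand = ifelse(get(9L) == "C", "-", "+"),
    family = get(10L),
    superfamily = .superfamily_map(get(11L)),
    divergence_pct = as.numeric(get(2L)),
    stringsAsFactors = FALSE
  )
  if (anyNA(hits$start) || anyNA(hits$end) || anyNA(hits$divergence_pct))
    stop("unparseable numeric field in RepeatMasker file ", path)
  if (any(hits$end <= hits$start)) stop("repeat hit with end <= start")
  hits
}

#' Write repeat hits in RepeatMasker .out layout
#'
#' Companion writer for [read_repeatmasker_out()]; used by the simulator to
#' emit its TE copies in the standard dialect.  `NA` divergences are
#' written as 0.0.
#'
#' @param hits data.frame as returned by [read_repeatmasker_out()], with a
#'   `classfam` column optionally overriding the class/family string.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker_out <- function(hits, path) {
  classfam <- hits$classfam
  if (is.null(classfam)) {
    classfam <- c("Ty3/Gypsy" = "LTR/Gypsy", "Ty1/Copia" = "LTR/Copia",
                  "LINE" = "LINE/L1", "DNA" = "DNA/hAT",
                  "unknown" = "Unknown", "other" = "Other")[hits$superfamily]
  }
  div <- ifelse(is.na(hits$divergence_pct), 0, hits$divergence_pct)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "   SW  perc perc perc  query      position in query           matching       repeat              position in  repeat",
    "score  div. del. ins.  sequence    begin     end    (left)    repeat         class/family         begin  end (left)   ID",
    ""), con)
  for (i in seq_len(nrow(hits))) {
    writeLines(sprintf(
      "%5d %5.1f  0.0  0.0  %s %8d %8d (0) %s %-16s %-18s %6d %6d (0) %d",
      1000L, div[i], hits$scaffold[i], hits$start[i] + 1L, hits$end[i],
      ifelse(hits$strand[i] == "-", "C", "+"), hits$family[i], classfam[i],
      1L, hits$end[i] - hits$start[i], i), con)
  }
  invisible(path)
}

#' Read an ortholog/anchor pair table
#'
#' Plain TSV with two or three columns: gene id in genome A, gene id in
#' genome B, and an optional similarity which defaults to 1.0.  Row order
#' is preserved.
#'
#' @param path path to the TSV (no header).
#' @return data.frame with columns `gene_a`, `gene_b`, `similarity`.
#' @export
read_anchor_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(data.frame(gene_a = character(), gene_b = character(),
                      similarity = numeric(), stringsAsFactors = FALSE))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 2L))
    stop("anchor table row with fewer than 2 columns in ", path)
  data.frame(
    gene_a = vapply(fields, `[[`, "", 1L),
    gene_b = vapply(fields, `[[`, "", 2L),
    similarity = vapply(fields, function(f)
      if (length(f) >= 3L) as.numeric(f[[3L]]) else 1.0, 0),
    stringsAsFactors = FALSE
  )
}

#' Read/write FASTA as a named character vector
#'
#' Thin wrappers around [Biostrings::readDNAStringSet()] and
#' [Biostrings::writeXStringSet()]; the package carries sequences as plain
#' named character vectors.
#'
#' @param path file path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(seqs)), path)
  invisible(path)
}
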