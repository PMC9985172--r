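#' Simulation configuration
#'
#' Bundles every knob of the genome-evolution simulator.  Two haploid
#' lineages ("A" and "B") are evolved from a common ancestral gene order
#' through a fixed number of inversions, translocations, tandem and
#' dispersed duplications and gene losses per lineage (fixed counts, not
#' rates, so ground truth is exact); gene sequences evolve under
#' Jukes-Cantor with no indels.  TE copy populations are generated from
#' family consensus sequences with divergences drawn per burst episode.
#' Gametolog pairs descend from ancestral loci that stopped recombining at
#' `sexchrom_depth` (expected substitutions/site from the U/V split to
#' each present-day tip), with speciation at `speciation_depth`;
#' `sexchrom_depth > speciation_depth` encodes ancestrally nonrecombining
#' loci.  Pseudoautosomal loci instead split at speciation, with a recent
#' within-species U/V divergence on the reference side, so their true
#' phylogenetic label is "O".
#'
#' @param seed integer seed; a fixed config (including seed) reproduces
#'   byte-identical output.
#' @param n_chromosomes,genes_per_chromosome ancestral genome dimensions.
#' @param n_inversions,n_translocations,n_tandem_dups,n_dispersed_dups,n_losses
#'   event counts applied to each lineage.
#' @param inversion_length integer range (min, max) of inversion length in
#'   genes.
#' @param seq_length gene (CDS) length in bp.
#' @param intergenic_length spacing between genes when laying out
#'   coordinates.
#' @param dup_divergence expected divergence (subs/site) of a fresh
#'   duplicate copy from its source.
#' @param te_bursts list of burst episodes; each a list with elements
#'   `mode` (modal divergence, percent), `sd` (percent), `n_copies`,
#'   `family`, `superfamily`, `copy_length` (bp).
#' @param gametolog list with `n_gametolog_pairs`, `n_pseudoautosomal`,
#'   `n_translocated_U_loci`, `speciation_depth`, `sexchrom_depth`,
#'   `outgroup_depth`, `within_species_depth`, `recent_uv_depth`,
#'   `locus_length`; missing entries take the defaults below.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 5L, genes_per_chromosome = 200L,
                       n_inversions = 10L, n_translocations = 2L,
                       n_tandem_dups = 5L, n_dispersed_dups = 5L,
                       n_losses = 5L,
                       inversion_length = c(2L, 20L),
                       seq_length = 999L, intergenic_length = 200L,
                       dup_divergence = 0.05,
                       te_bursts = list(
                         list(mode = 5, sd = 2, n_copies = 1000L,
                              family = "Gypsy-1", superfamily = "Ty3/Gypsy",
                              copy_length = 1000L),
                         list(mode = 25, sd = 2, n_copies = 1000L,
                              family = "Gypsy-1", superfamily = "Ty3/Gypsy",
                              copy_length = 1000L)),
                       gametolog = list()) {
  gam_default <- list(n_gametolog_pairs = 20L, n_pseudoautosomal = 5L,
                      n_translocated_U_loci = 2L,
                      speciation_depth = 0.1, sexchrom_depth = 0.2,
                      outgroup_depth = 0.4, within_species_depth = 0.004,
                      recent_uv_depth = NULL, locus_length = 1000L)
  gam <- utils::modifyList(gam_default, gametolog)
  if (is.null(gam$recent_uv_depth))
    gam$recent_uv_depth <- gam$speciation_depth / 2
  counts <- c(n_inversions, n_translocations, n_tandem_dups,
              n_dispersed_dups, n_losses, gam$n_gametolog_pairs,
              gam$n_pseudoautosomal, gam$n_translocated_U_loci)
  if (any(counts < 0)) stop("event and locus counts must be >= 0")
  if (gam$sexchrom_depth <= gam$speciation_depth)
    stop("sexchrom_depth must exceed speciation_depth (ancestrally nonrecombining loci)")
  if (gam$n_translocated_U_loci > gam$n_gametolog_pairs)
    stop("n_translocated_U_loci > n_gametolog_pairs")
  for (b in te_bursts)
    if (b$mode >= 75) stop("burst mode >= 75% is beyond Jukes-Cantor saturation")
  if (n_chromosomes < 1L || genes_per_chromosome < 1L)
    stop("genome must have at least one gene")
  structure(list(seed = as.integer(seed),
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 n_inversions = as.integer(n_inversions),
                 n_translocations = as.integer(n_translocations),
                 n_tandem_dups = as.integer(n_tandem_dups),
                 n_dispersed_dups = as.integer(n_dispersed_dups),
                 n_losses = as.integer(n_losses),
                 inversion_length = as.integer(inversion_length),
                 seq_length = as.integer(seq_length),
                 intergenic_length = as.integer(intergenic_length),
                 dup_divergence = dup_divergence,
                 te_bursts = te_bursts, gametolog = gam),
            class = "sim_config")
}

# lay out genes on chromosomes: fixed spacing, single coding exon per gene
.layout_genome <- function(chroms, strands, cfg) {
  ids <- unlist(lapply(chroms, `[[`, "gene_id"), use.names = FALSE)
  scaf <- rep(names(chroms), vapply(chroms, nrow, 0L))
  idx <- unlist(lapply(chroms, function(d) seq_len(nrow(d)) - 1L),
                use.names = FALSE)
  start <- idx * (cfg$seq_length + cfg$intergenic_length)
  end <- start + cfg$seq_length
  gene_table(gene_id = ids, scaffold = scaf, start = start, end = end,
             strand = unlist(lapply(chroms, `[[`, "strand"),
                             use.names = FALSE),
             exons = mapply(function(s, e) cbind(s, e), start, end,
                            SIMPLIFY = FALSE),
             cds_length = cfg$seq_length)
}

#' Simulate the ancestral genome
#'
#' `n_chromosomes x genes_per_chromosome` genes with unique ids, evenly
#' spaced single-exon gene models, and (optionally) random nucleotide
#' sequences of `seq_length` bp.
#'
#' @param cfg a [sim_config()].
#' @param sequences generate nucleotide sequences?  Disable for
#'   gene-order-only experiments, which run much faster.
#' @return list of class `"sim_genome"`: `genes` (a ranked
#'   [gene_table()]) and `seqs` (named character vector or `NULL`).
#' @export
simulate_ancestor <- function(cfg, sequences = TRUE) {
  set.seed(cfg$seed)
  n <- cfg$n_chromosomes * cfg$genes_per_chromosome
  ids <- sprintf("G%05d", seq_len(n))
  chroms <- split(ids, rep(sprintf("chr%d", seq_len(cfg$n_chromosomes)),
                           each = cfg$genes_per_chromosome))
  chroms <- lapply(chroms, function(g)
    data.frame(gene_id = g, ancestor_id = g, strand = "+",
               stringsAsFactors = FALSE))
  genes <- rank_genes(.layout_genome(chroms, NULL, cfg))
  seqs <- NULL
  if (sequences)
    seqs <- setNames(vapply(ids, function(i) random_dna(cfg$seq_length), ""),
                     ids)
  structure(list(genes = genes, seqs = seqs, chroms = chroms, cfg = cfg),
            class = "sim_genome")
}

# --- event primitives (operate on the per-chromosome gene lists) ---------

.ev_inversion <- function(chroms, cfg) {
  sizes <- vapply(chroms, nrow, 0L)
  # segment length drawn from the configured range, capped at the largest
  # chromosome; unsatisfiable only if even the minimum does not fit
  max_len <- min(cfg$inversion_length[2L], max(sizes))
  if (cfg$inversion_length[1L] > max_len)
    stop("unsatisfiable inversion: no chromosome with >= ",
         cfg$inversion_length[1L], " genes")
  len <- if (cfg$inversion_length[1L] == max_len) max_len else
    sample(cfg$inversion_length[1L]:max_len, 1L)
  ok <- names(chroms)[sizes >= len]
  ch <- if (length(ok) == 1L) ok else sample(ok, 1L)
  d <- chroms[[ch]]
  from <- sample.int(nrow(d) - len + 1L, 1L)
  seg <- from:(from + len - 1L)
  inv <- d[rev(seg), ]
  inv$strand <- ifelse(inv$strand == "+", "-", "+")
  d[seg, ] <- inv
  chroms[[ch]] <- d
  list(chroms = chroms,
       log = list(type = "inversion", scaffold = ch, position = from - 1L,
                  length = len, scaffold_to = ch, position_to = from - 1L,
                  genes = paste(inv$gene_id, collapse = ";")))
}

.ev_translocation <- function(chroms, cfg) {
  if (length(chroms) < 2L)
    stop("unsatisfiable translocation: need >= 2 chromosomes")
  sizes <- vapply(chroms, nrow, 0L)
  ok <- names(chroms)[sizes >= 2L]
  if (!length(ok)) stop("unsatisfiable translocation: no donor chromosome")
  src <- if (length(ok) == 1L) ok else sample(ok, 1L)
  len <- sample.int(min(5L, nrow(chroms[[src]]) - 1L), 1L)
  from <- sample.int(nrow(chroms[[src]]) - len + 1L, 1L)
  seg <- from:(from + len - 1L)
  moved <- chroms[[src]][seg, ]
  chroms[[src]] <- chroms[[src]][-seg, ]
  dests <- setdiff(names(chroms), src)
  dst <- if (length(dests) == 1L) dests else sample(dests, 1L)
  at <- sample.int(nrow(chroms[[dst]]) + 1L, 1L) - 1L  # 0 = front
  d <- chroms[[dst]]
  chroms[[dst]] <- rbind(d[seq_len(at), , drop = FALSE], moved,
                         d[seq_len(nrow(d)) > at, , drop = FALSE])
  list(chroms = chroms,
       log = list(type = "translocation", scaffold = src,
                  position = from - 1L, length = len, scaffold_to = dst,
                  position_to = at,
                  genes = paste(moved$gene_id, collapse = ";")))
}

.pick_dup_source <- function(chroms, used) {
  # sources are ancestor-descended genes, sampled without replacement, so
  # each planted duplication contributes exactly two distinct paralogs
  all_ids <- unlist(lapply(chroms, function(d)
    d$gene_id[!is.na(d$ancestor_id)]), use.names = FALSE)
  avail <- setdiff(all_ids, used)
  if (!length(avail)) stop("unsatisfiable duplication: no unused source gene")
  if (length(avail) == 1L) avail else sample(avail, 1L)
}

.locate <- function(chroms, id) {
  for (ch in names(chroms)) {
    i <- match(id, chroms[[ch]]$gene_id)
    if (!is.na(i)) return(list(ch = ch, i = i))
  }
  stop("gene not found: ", id)
}

.insert_row <- function(chroms, ch, at, row) {  # insert after position `at`
  d <- chroms[[ch]]
  chroms[[ch]] <- rbind(d[seq_len(at), , drop = FALSE], row,
                        d[seq_len(nrow(d)) > at, , drop = FALSE])
  chroms
}

.ev_duplication <- function(chroms, cfg, kind, dup_id, used) {
  src_id <- .pick_dup_source(chroms, used)
  loc <- .locate(chroms, src_id)
  row <- chroms[[loc$ch]][loc$i, ]
  row$gene_id <- dup_id
  row$ancestor_id <- NA_character_
  if (kind == "tandem") {
    chroms <- .insert_row(chroms, loc$ch, loc$i, row)
    dst <- loc$ch; at <- loc$i
  } else {
    # dispersed: land at least 10 genes away from the source
    for (try in 1:200) {
      dst <- sample(names(chroms), 1L)
      at <- sample.int(nrow(chroms[[dst]]) + 1L, 1L) - 1L
      if (dst != loc$ch || abs(at - loc$i) > 10L) break
      if (try == 200L) stop("unsatisfiable dispersed duplication")
    }
    chroms <- .insert_row(chroms, dst, at, row)
  }
  list(chroms = chroms, source = src_id,
       log = list(type = paste0(kind, "_duplication"), scaffold = loc$ch,
                  position = loc$i - 1L, length = 1L, scaffold_to = dst,
                  position_to = at, genes = paste(src_id, dup_id, sep = ";")))
}

.ev_loss <- function(chroms) {
  sizes <- vapply(chroms, nrow, 0L)
  if (sum(sizes) <= 1L) stop("unsatisfiable loss: would empty the genome")
  ch <- sample(names(chroms), 1L, prob = sizes)
  i <- sample.int(nrow(chroms[[ch]]), 1L)
  lost <- chroms[[ch]]$gene_id[i]
  chroms[[ch]] <- chroms[[ch]][-i, ]
  list(chroms = chroms,
       log = list(type = "loss", scaffold = ch, position = i - 1L,
                  length = 1L, scaffold_to = NA_character_,
                  position_to = NA_integer_, genes = lost))
}

#' Evolve one lineage from the ancestral genome
#'
#' Applies the configured numbers of inversions (reverse a contiguous gene
#' run and flip strands), translocations (move a run to another
#' chromosome), tandem and dispersed duplications (insert a mutated copy
#' adjacent to, or at least 10 genes away from, its source; sources are
#' sampled without replacement) and losses, in a random order, logging
#' every event.  Unsatisfiable events raise an error rather than being
#' skipped.  Surviving sequences are then further mutated to the
#' per-lineage depth `gametolog$speciation_depth` under Jukes-Cantor, so
#' ortholog pairs between two lineages sit at about twice that depth.
#'
#' @param ancestor a `"sim_genome"` from [simulate_ancestor()].
#' @param cfg the [sim_config()].
#' @param lineage_id short label, e.g. `"A"`; prefixes gene ids and decides
#'   the lineage's RNG stream.
#' @return list of class `"sim_lineage"`: `genes` (ranked gene table with
#'   lineage-prefixed ids), `seqs`, `event_log` (data.frame), and
#'   `ortholog_map` (`ancestor_id` -> `gene_id`).
#' @export
evolve_lineage <- function(ancestor, cfg, lineage_id) {
  set.seed((cfg$seed + sum(utf8ToInt(lineage_id)) * 1009L) %%
             .Machine$integer.max)
  chroms <- ancestor$chroms
  events <- rep(c("inversion", "translocation", "tandem", "dispersed",
                  "loss"),
                c(cfg$n_inversions, cfg$n_translocations, cfg$n_tandem_dups,
                  cfg$n_dispersed_dups, cfg$n_losses))
  if (length(events) > 1L) events <- sample(events)
  dup_seqs <- character()
  used_sources <- character()
  n_dup <- 0L
  log_rows <- list()
  for (ev in events) {
    if (ev == "inversion") {
      r <- .ev_inversion(chroms, cfg)
    } else if (ev == "translocation") {
      r <- .ev_translocation(chroms, cfg)
    } else if (ev %in% c("tandem", "dispersed")) {
      n_dup <- n_dup + 1L
      dup_id <- sprintf("dup%03d", n_dup)
      r <- .ev_duplication(chroms, cfg, ev, dup_id, used_sources)
      used_sources <- c(used_sources, r$source)
      if (!is.null(ancestor$seqs)) {
        src_seq <- if (r$source %in% names(dup_seqs))
          dup_seqs[[r$source]] else ancestor$seqs[[r$source]]
        dup_seqs[[dup_id]] <- mutate_jc(src_seq, cfg$dup_divergence)
      }
    } else {
      r <- .ev_loss(chroms)
    }
    chroms <- r$chroms
    r$log$lineage <- lineage_id
    log_rows[[length(log_rows) + 1L]] <- as.data.frame(r$log,
                                                       stringsAsFactors = FALSE)
  }
  event_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(type = character(), scaffold = character(),
               position = integer(), length = integer(),
               scaffold_to = character(), position_to = integer(),
               genes = character(), lineage = character(),
               stringsAsFactors = FALSE)

  # rename to lineage-prefixed ids and lay out coordinates
  old_ids <- unlist(lapply(chroms, `[[`, "gene_id"), use.names = FALSE)
  anc_ids <- unlist(lapply(chroms, `[[`, "ancestor_id"), use.names = FALSE)
  new_ids <- paste0(lineage_id, "_", old_ids)
  rename <- setNames(new_ids, old_ids)
  chroms <- lapply(chroms, function(d) {
    d$gene_id <- rename[d$gene_id]; d
  })
  genes <- rank_genes(.layout_genome(chroms, NULL, cfg))
  seqs <- NULL
  if (!is.null(ancestor$seqs)) {
    base <- c(ancestor$seqs, dup_seqs)[old_ids]
    seqs <- setNames(vapply(base, mutate_jc, "",
                            d = cfg$gametolog$speciation_depth), new_ids)
  }
  structure(list(genes = genes, seqs = seqs, event_log = event_log,
                 ortholog_map = data.frame(
                   ancestor_id = anc_ids[!is.na(anc_ids)],
                   gene_id = new_ids[!is.na(anc_ids)],
                   stringsAsFactors = FALSE)),
            class = "sim_lineage")
}

#' Simulate a pair of diverged genomes with ground truth
#'
#' Convenience wrapper: one ancestor, two evolved lineages `"A"` and
#' `"B"`, plus the true single-copy ortholog anchor table (ancestor genes
#' surviving exactly once in each lineage).
#'
#' @inheritParams simulate_ancestor
#' @return list of class `"genome_sim"`: `ancestor`, `lineages` (list
#'   `A`, `B`), `anchors` (data.frame `gene_a`, `gene_b`, `similarity`),
#'   `event_log`, `cfg`.
#' @export
simulate_genomes <- function(cfg, sequences = TRUE) {
  anc <- simulate_ancestor(cfg, sequences = sequences)
  lin_a <- evolve_lineage(anc, cfg, "A")
  lin_b <- evolve_lineage(anc, cfg, "B")
  shared <- intersect(lin_a$ortholog_map$ancestor_id,
                      lin_b$ortholog_map$ancestor_id)
  shared <- sort(shared)
  anchors <- data.frame(
    gene_a = lin_a$ortholog_map$gene_id[
      match(shared, lin_a$ortholog_map$ancestor_id)],
    gene_b = lin_b$ortholog_map$gene_id[
      match(shared, lin_b$ortholog_map$ancestor_id)],
    similarity = 1.0, stringsAsFactors = FALSE)
  structure(list(ancestor = anc, lineages = list(A = lin_a, B = lin_b),
                 anchors = anchors,
                 event_log = rbind(lin_a$event_log, lin_b$event_log),
                 cfg = cfg),
            class = "genome_sim")
}

#' Simulate TE copy populations from burst episodes
#'
#' For each configured burst, `n_copies` sequences are generated by
#' mutating the family consensus to a divergence drawn from
#' Normal(`mode`, `sd`) truncated at zero (Jukes-Cantor substitutions).
#' The emitted repeat hits leave `divergence_pct` unset - estimating it is
#' the landscape module's job - while the truth table records the realized
#' target divergence of every copy.
#'
#' @param cfg a [sim_config()] with at least one burst in `te_bursts`.
#' @return list of class `"te_sim"`: `hits` (repeat-hit data.frame with
#'   `divergence_pct = NA`), `copies` (named character vector),
#'   `consensus` (one per family), `truth` (data.frame `copy_id`,
#'   `family`, `superfamily`, `true_divergence_pct`, `length_bp`).
#' @export
simulate_te_copies <- function(cfg) {
  bursts <- Filter(function(b) b$n_copies > 0L, cfg$te_bursts)
  if (!length(bursts)) stop("need at least one burst with n_copies > 0")
  set.seed((cfg$seed + 7919L) %% .Machine$integer.max)
  consensus <- character()
  copies <- character()
  truth <- list()
  pos <- 0L
  hits <- list()
  n_copy <- 0L
  for (b in bursts) {
    if (!(b$family %in% names(consensus)))
      consensus[[b$family]] <- random_dna(b$copy_length)
    for (i in seq_len(b$n_copies)) {
      n_copy <- n_copy + 1L
      d <- max(0, rnorm(1L, b$mode, b$sd)) / 100
      id <- sprintf("te%05d", n_copy)
      copies[[id]] <- mutate_jc(consensus[[b$family]], d)
      truth[[id]] <- data.frame(copy_id = id, family = b$family,
                                superfamily = b$superfamily,
                                true_divergence_pct = 100 * d,
                                length_bp = b$copy_length,
                                stringsAsFactors = FALSE)
      hits[[id]] <- data.frame(scaffold = "te_contig", start = pos,
                               end = pos + b$copy_length, strand = "+",
                               family = b$family, superfamily = b$superfamily,
                               divergence_pct = NA_real_,
                               stringsAsFactors = FALSE)
      pos <- pos + b$copy_length + 100L
    }
  }
  structure(list(hits = do.call(rbind, c(hits, make.row.names = FALSE)),
                 copies = copies, consensus = consensus,
                 truth = do.call(rbind, c(truth, make.row.names = FALSE))),
            class = "te_sim")
}

.assemble_scaffold <- function(pieces) paste(pieces, collapse = "")

#' Simulate gametolog loci and sex-specific genomes
#'
#' Each gametolog pair descends from an ancestral locus whose U and V
#' copies split at `sexchrom_depth`, each then splitting into a
#' reference-side and a query-side copy at `speciation_depth`; U-descended
#' query copies are placed only in the female genome and V-descended ones
#' only in the male genome.  Pseudoautosomal loci split at speciation only
#' (the reference U/V copies diverge recently), are placed on homologous
#' autosomal scaffolds of both sexes, and ground-truth as phylogenetic
#' "O".  For `n_translocated_U_loci` randomly chosen gametolog pairs the
#' query U copy is additionally placed on an autosomal scaffold of the
#' male genome and the query V copy is deleted, emulating a U-to-autosome
#' translocation with V loss.  An outgroup sequence diverging at
#' `outgroup_depth` is attached to every locus.
#'
#' @param cfg a [sim_config()].
#' @return list of class `"sex_loci_sim"`: `loci` (list; each with `name`,
#'   `kind`, `mp_u`, `mp_v`, `lc_f`, `lc_m`, `outgroup`, `translocated`),
#'   `female_genome`, `male_genome` (named character vectors of
#'   scaffolds), `truth` (one row per query sequence: `locus`, `seq_id`,
#'   `sex`, `true_phylo`, `true_genomic`, `translocated`).
#' @export
simulate_sex_loci <- function(cfg) {
  gam <- cfg$gametolog
  set.seed((cfg$seed + 104729L) %% .Machine$integer.max)
  if (gam$within_species_depth >= gam$speciation_depth)
    stop("within_species_depth must be below speciation_depth")
  L <- gam$locus_length
  d_int <- gam$sexchrom_depth - gam$speciation_depth
  trans <- if (gam$n_translocated_U_loci > 0L)
    sort(sample.int(gam$n_gametolog_pairs, gam$n_translocated_U_loci))
  else integer()
  loci <- list()
  truth <- list()
  add_truth <- function(locus, sex, phylo, genomic, translocated) {
    truth[[length(truth) + 1L]] <<- data.frame(
      locus = locus,
      seq_id = paste0(locus, if (sex == "female") "_lcF" else "_lcM"),
      sex = sex, true_phylo = phylo, true_genomic = genomic,
      translocated = translocated, stringsAsFactors = FALSE)
  }
  for (i in seq_len(gam$n_gametolog_pairs)) {
    name <- sprintf("gam%03d", i)
    anc <- random_dna(L)
    u_mid <- mutate_jc(anc, d_int)
    v_mid <- mutate_jc(anc, d_int)
    mp_u <- mutate_jc(u_mid, gam$speciation_depth)
    lc_u <- mutate_jc(u_mid, gam$speciation_depth)
    mp_v <- mutate_jc(v_mid, gam$speciation_depth)
    lc_v <- mutate_jc(v_mid, gam$speciation_depth)
    out <- mutate_jc(anc, gam$outgroup_depth)
    if (i %in% trans) {
      lc_f <- mutate_jc(lc_u, gam$within_species_depth)
      lc_m <- mutate_jc(lc_u, gam$within_species_depth)
      add_truth(name, "female", "U", "autosomal", TRUE)
      add_truth(name, "male", "U", "autosomal", TRUE)
      loci[[name]] <- list(name = name, kind = "gametolog", mp_u = mp_u,
                           mp_v = mp_v, lc_f = lc_f, lc_m = lc_m,
                           outgroup = out, translocated = TRUE)
    } else {
      add_truth(name, "female", "U", "U-linked", FALSE)
      add_truth(name, "male", "V", "V-linked", FALSE)
      loci[[name]] <- list(name = name, kind = "gametolog", mp_u = mp_u,
                           mp_v = mp_v, lc_f = lc_u, lc_m = lc_v,
                           outgroup = out, translocated = FALSE)
    }
  }
  for (i in seq_len(gam$n_pseudoautosomal)) {
    name <- sprintf("par%03d", i)
    anc <- random_dna(L)
    lc_base <- mutate_jc(anc, gam$speciation_depth - gam$within_species_depth)
    lc_f <- mutate_jc(lc_base, gam$within_species_depth)
    lc_m <- mutate_jc(lc_base, gam$within_species_depth)
    mp_base <- mutate_jc(anc, gam$speciation_depth - gam$recent_uv_depth)
    mp_u <- mutate_jc(mp_base, gam$recent_uv_depth)
    mp_v <- mutate_jc(mp_base, gam$recent_uv_depth)
    out <- mutate_jc(anc, gam$outgroup_depth)
    add_truth(name, "female", "O", "autosomal", FALSE)
    add_truth(name, "male", "O", "autosomal", FALSE)
    loci[[name]] <- list(name = name, kind = "pseudoautosomal", mp_u = mp_u,
                         mp_v = mp_v, lc_f = lc_f, lc_m = lc_m,
                         outgroup = out, translocated = FALSE)
  }

  # scaffolds: sex-specific U/V scaffolds plus homologous autosomes whose
  # female and male versions differ only by within-species drift
  per_scaf <- 4L
  female <- character(); male <- character()
  u_loci <- Filter(function(l) l$kind == "gametolog" && !l$translocated, loci)
  auto_loci <- Filter(function(l) l$kind == "pseudoautosomal" ||
                        l$translocated, loci)
  chunk <- function(x) if (length(x)) split(x, (seq_along(x) - 1L) %/% per_scaf)
    else list()
  for (ci in seq_along(chunk(u_loci))) {
    grp <- chunk(u_loci)[[ci]]
    fpieces <- mpieces <- character()
    for (l in grp) {
      sp <- random_dna(150L)
      fpieces <- c(fpieces, sp, l$lc_f)
      mpieces <- c(mpieces, sp, l$lc_m)
    }
    female[[sprintf("scfU_%d", ci)]] <- .assemble_scaffold(fpieces)
    male[[sprintf("scfV_%d", ci)]] <- .assemble_scaffold(mpieces)
  }
  for (ci in seq_along(chunk(auto_loci))) {
    grp <- chunk(auto_loci)[[ci]]
    fpieces <- mpieces <- character()
    for (l in grp) {
      sp <- random_dna(150L)
      fpieces <- c(fpieces, mutate_jc(sp, gam$within_species_depth), l$lc_f)
      mpieces <- c(mpieces, mutate_jc(sp, gam$within_species_depth), l$lc_m)
    }
    female[[sprintf("scfA_%d", ci)]] <- .assemble_scaffold(fpieces)
    male[[sprintf("scfA_%d", ci)]] <- .assemble_scaffold(mpieces)
  }
  truth <- do.call(rbind, c(truth, make.row.names = FALSE))
  structure(list(loci = loci, female_genome = female, male_genome = male,
                 truth = truth, cfg = cfg),
            class = "sex_loci_sim")
}

#' Write a simulation to files in the standard formats
#'
#' Emits, under `outdir`: per-lineage GFF3 annotations plus CDS and
#' protein FASTA; the true single-copy anchor table (TSV); TE copies and
#' consensus FASTA plus a RepeatMasker-style `.out` (its `div` column
#' carries the simulator's realized divergence, as RepeatMasker would
#' report its own estimate); female/male genome FASTA; and the truth
#' tables (event log, ortholog map, TE truth, gametolog truth) as TSV.
#'
#' @param sim a `"genome_sim"` from [simulate_genomes()].
#' @param outdir output directory (created if needed).
#' @param te optional `"te_sim"` ([simulate_te_copies()]).
#' @param sex optional `"sex_loci_sim"` ([simulate_sex_loci()]).
#' @return `outdir`, invisibly.
#' @export
emit_simulation <- function(sim, outdir, te = NULL, sex = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  tsv <- function(d, f) write.table(d, p(f), sep = "\t", quote = FALSE,
                                    row.names = FALSE)
  for (lid in names(sim$lineages)) {
    lin <- sim$lineages[[lid]]
    write_gff3(lin$genes, p(sprintf("lineage_%s.gff3", lid)))
    if (!is.null(lin$seqs)) {
      write_fasta(lin$seqs, p(sprintf("lineage_%s_cds.fasta", lid)))
      prot <- vapply(lin$seqs, translate_cds, "")
      write_fasta2 <- function(x, path) {
        Biostrings::writeXStringSet(Biostrings::AAStringSet(x), path)
      }
      write_fasta2(prot, p(sprintf("lineage_%s_proteins.fasta", lid)))
    }
    tsv(lin$ortholog_map, sprintf("ortholog_map_%s.tsv", lid))
  }
  write.table(sim$anchors, p("anchors.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  tsv(sim$event_log, "event_log.tsv")
  if (!is.null(te)) {
    write_fasta(te$copies, p("te_copies.fasta"))
    write_fasta(te$consensus, p("te_consensus.fasta"))
    hits <- te$hits
    hits$divergence_pct <- te$truth$true_divergence_pct
    write_repeatmasker_out(hits, p("repeats.out"))
    tsv(te$truth, "te_truth.tsv")
  }
  if (!is.null(sex)) {
    write_fasta(sex$female_genome, p("female_genome.fasta"))
    write_fasta(sex$male_genome, p("male_genome.fasta"))
    tsv(sex$truth, "gametolog_truth.tsv")
    for (l in sex$loci) {
      seqs <- c(mp_u = l$mp_u, mp_v = l$mp_v, outgroup = l$outgroup,
                lc_f = l$lc_f)
      if (!is.null(l$lc_m) && !is.na(l$lc_m)) seqs <- c(seqs, lc_m = l$lc_m)
      write_fasta(seqs, p(sprintf("locus_%s.fasta", l$name)))
    }
  }
  invisible(outdir)
}
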