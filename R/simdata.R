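# Synthetic genome-pair simulator with known ground truth: an ancestor
# genome diverges into a query lineage (transcripts, ESTs, genetic map)
# and a target lineage (predicted genes, pseudo-chromosomes, optional
# rearrangements), so orthology, physical positions and map positions are
# all known exactly.

# fixed 40-mer "cloning vector" prepended to contaminated reads
VECTOR_SEQ <- "GTTTTCCCAGTCACGACGTTGTAAAACGACGGCCAGTGCC"

#' Simulation configuration
#'
#' All random draws are fixed by `seed` (each simulation stage reseeds
#' deterministically from it), so identical configurations reproduce
#' identical data.
#'
#' @param seed Integer seed.
#' @param n_chromosomes,genes_per_chromosome Genome layout.
#' @param gene_length_bp,intergenic_bp Ranges (length-2 integer vectors)
#'   for gene lengths and intergenic gaps.
#' @param divergence Expected per-site substitution divergence between the
#'   two genomes; each lineage mutates independently at `divergence / 2`.
#' @param indel_rate Per-site indel probability per lineage (indels of
#'   1-3 bp, half insertions, half deletions).
#' @param n_inversions,n_translocations Number of rearrangements applied
#'   to the target lineage.
#' @param inversion_spans Optional explicit inversion spans: a list of
#'   `list(chrom = i, from = j, to = k)` gene-index spans (overrides the
#'   random draw).
#' @param gene_loss_rate,tandem_dup_rate Per-gene loss / tandem
#'   duplication probability in the target lineage.
#' @param marker_fraction Fraction of query genes that become genetic-map
#'   markers.
#' @param cm_per_mb Recombination rate: a single number (constant), or a
#'   list with one data.frame (`from_bp`, `rate`) per chromosome for a
#'   piecewise-constant rate.
#' @param tc_fraction Fraction of target genes also emitted as transcript
#'   contigs.
#' @param est_per_gene Range of EST reads simulated per query gene.
#' @param est_len_frac Range of the read length as a fraction of the gene
#'   length (`c(1, 1)` gives full-length reads).
#' @param est_error_rate Per-base EST read error probability.
#' @param polyA_prob Probability that a read carries a poly-A tail.
#' @param vector_prob Probability that a read is prefixed by the 40-mer
#'   vector sequence.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 2L,
                       genes_per_chromosome = 50L,
                       gene_length_bp = c(900L, 1100L),
                       intergenic_bp = c(2000L, 10000L),
                       divergence = 0.10,
                       indel_rate = 0.002,
                       n_inversions = 0L,
                       n_translocations = 0L,
                       inversion_spans = NULL,
                       gene_loss_rate = 0,
                       tandem_dup_rate = 0,
                       marker_fraction = 0.2,
                       cm_per_mb = 3.3,
                       tc_fraction = 0,
                       est_per_gene = c(1L, 3L),
                       est_len_frac = c(0.5, 1),
                       est_error_rate = 0.01,
                       polyA_prob = 0.3,
                       vector_prob = 0.1) {
  rates <- c(divergence, indel_rate, gene_loss_rate, tandem_dup_rate,
             marker_fraction, tc_fraction, est_error_rate, polyA_prob,
             vector_prob)
  stopifnot(all(rates >= 0), all(rates <= 1),
            n_chromosomes >= 1, genes_per_chromosome >= 1,
            length(gene_length_bp) == 2, length(intergenic_bp) == 2,
            gene_length_bp[1] <= gene_length_bp[2],
            intergenic_bp[1] <= intergenic_bp[2],
            length(est_len_frac) == 2, est_len_frac[1] > 0,
            est_len_frac[2] <= 1, est_len_frac[1] <= est_len_frac[2],
            n_inversions >= 0, n_translocations >= 0)
  structure(list(seed = as.integer(seed) %% .Machine$integer.max,
                 n_chromosomes = as.integer(n_chromosomes),
                 genes_per_chromosome = as.integer(genes_per_chromosome),
                 gene_length_bp = as.integer(gene_length_bp),
                 intergenic_bp = as.integer(intergenic_bp),
                 divergence = divergence, indel_rate = indel_rate,
                 n_inversions = as.integer(n_inversions),
                 n_translocations = as.integer(n_translocations),
                 inversion_spans = inversion_spans,
                 gene_loss_rate = gene_loss_rate,
                 tandem_dup_rate = tandem_dup_rate,
                 marker_fraction = marker_fraction,
                 cm_per_mb = cm_per_mb,
                 tc_fraction = tc_fraction,
                 est_per_gene = as.integer(est_per_gene),
                 est_len_frac = est_len_frac,
                 est_error_rate = est_error_rate,
                 polyA_prob = polyA_prob, vector_prob = vector_prob),
            class = "sim_config")
}

sim_seed_ <- function(cfg, offset) {
  set.seed((cfg$seed %% 2000000000L) + offset)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitutions then short indels, both per-site Bernoulli
mutate_seq <- function(s, sub_rate, indel_rate) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  hit <- which(stats::runif(n) < sub_rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    for (i in hit) ch[i] <- sample(setdiff(bases, ch[i]), 1L)
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(n) < indel_rate)
    if (length(ev)) {
      pieces <- as.list(ch)
      for (i in ev) {
        len <- sample(1:3, 1L)
        if (stats::runif(1) < 0.5) {
          pieces[i:min(n, i + len - 1L)] <- list("")  # deletion
        } else {
          pieces[[i]] <- paste0(ch[i], random_dna(len))  # insertion after i
        }
      }
      return(paste(unlist(pieces), collapse = ""))
    }
  }
  paste(ch, collapse = "")
}

# integral of a piecewise-constant cM/Mb rate from 0 to bp
cm_at_bp <- function(bp, rates) {
  if (is.numeric(rates) && length(rates) == 1L) {
    return(rates * bp / 1e6)
  }
  stopifnot(is.data.frame(rates), rates$from_bp[1] == 0)
  bounds <- c(rates$from_bp, Inf)
  total <- 0
  for (i in seq_len(nrow(rates))) {
    lo <- bounds[i]
    hi <- min(bp, bounds[i + 1L])
    if (hi > lo) total <- total + rates$rate[i] * (hi - lo) / 1e6
  }
  total
}

chrom_rates_ <- function(cfg, chrom_index) {
  if (is.list(cfg$cm_per_mb) && !is.data.frame(cfg$cm_per_mb)) {
    cfg$cm_per_mb[[chrom_index]]
  } else {
    cfg$cm_per_mb
  }
}

# lay ordered genes on a chromosome with random intergenic gaps; returns
# the chromosome sequence and 0-based half-open gene coordinates
layout_chromosome <- function(gene_seqs, strands, chrom, gap_range) {
  n <- length(gene_seqs)
  gaps <- sample(gap_range[1]:gap_range[2], n + 1L, replace = TRUE)
  parts <- character(2L * n + 1L)
  coords <- data.frame(gene_id = names(gene_seqs), chrom = chrom,
                       start = integer(n), end = integer(n),
                       strand = strands, stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_len(n)) {
    parts[2L * i - 1L] <- random_dna(gaps[i])
    pos <- pos + gaps[i]
    placed <- if (strands[i] == "-") revcomp_chr(gene_seqs[[i]])
              else gene_seqs[[i]]
    parts[2L * i] <- placed
    coords$start[i] <- pos
    pos <- pos + nchar(placed)
    coords$end[i] <- pos
  }
  parts[2L * n + 1L] <- random_dna(gaps[n + 1L])
  list(seq = paste(parts, collapse = ""), coords = coords)
}

#' Simulate an ancestral genome
#'
#' @param cfg A [sim_config()].
#' @return A list with `genes` (named character vector, order = gene order
#'   per chromosome) and `layout` (data.frame gene_id, chrom_index,
#'   order).  Deterministic for a fixed seed.
#' @export
simulate_ancestor <- function(cfg) {
  sim_seed_(cfg, 0L)
  genes <- character(0)
  layout <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    ids <- sprintf("c%dg%03d", ci, seq_len(cfg$genes_per_chromosome))
    lens <- sample(cfg$gene_length_bp[1]:cfg$gene_length_bp[2],
                   cfg$genes_per_chromosome, replace = TRUE)
    seqs <- vapply(lens, random_dna, "")
    names(seqs) <- ids
    genes <- c(genes, seqs)
    layout[[ci]] <- data.frame(gene_id = ids, chrom_index = ci,
                               order = seq_along(ids),
                               stringsAsFactors = FALSE)
  }
  list(genes = genes, layout = do.call(rbind, layout), cfg = cfg)
}

draw_spans_ <- function(n_spans, n_chrom, genes_per_chrom, span_range) {
  spans <- list()
  used <- lapply(seq_len(n_chrom), function(i) logical(genes_per_chrom))
  tries <- 0L
  while (length(spans) < n_spans && tries < 200L) {
    tries <- tries + 1L
    ci <- sample.int(n_chrom, 1L)
    len <- sample(span_range[1]:span_range[2], 1L)
    if (len >= genes_per_chrom) next
    from <- sample.int(genes_per_chrom - len, 1L)
    idx <- from:(from + len - 1L)
    if (any(used[[ci]][idx])) next
    used[[ci]][idx] <- TRUE
    spans[[length(spans) + 1L]] <- list(chrom = ci, from = from,
                                        to = from + len - 1L)
  }
  spans
}

#' Evolve the ancestor into a query and a target genome
#'
#' Substitutions and indels are applied independently to each lineage at
#' half the configured divergence.  The target lineage additionally
#' receives gene losses, tandem duplications, inversions (reversing both
#' gene order and strand) and translocations, all recorded in the truth
#' tables.
#'
#' @param ancestor Output of [simulate_ancestor()].
#' @param cfg A [sim_config()].
#' @return A list with `query` (genes + chromosome layout), `target`
#'   (genes, transcript contigs, pseudo-chromosome sequences, gene
#'   positions) and `truth` (ortholog pairs, rearrangement log).
#' @export
evolve_genomes <- function(ancestor, cfg) {
  sim_seed_(cfg, 1L)
  anc <- ancestor$genes
  q_genes <- vapply(anc, mutate_seq, "", sub_rate = cfg$divergence / 2,
                    indel_rate = cfg$indel_rate)
  names(q_genes) <- paste0("q_", names(anc))
  t_genes <- vapply(anc, mutate_seq, "", sub_rate = cfg$divergence / 2,
                    indel_rate = cfg$indel_rate)
  names(t_genes) <- paste0("t_", names(anc))

  # query genome keeps the ancestral order
  q_coords <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    ids <- ancestor$layout$gene_id[ancestor$layout$chrom_index == ci]
    lay <- layout_chromosome(q_genes[paste0("q_", ids)],
                             rep("+", length(ids)),
                             paste0("qchr", ci), cfg$intergenic_bp)
    q_coords[[ci]] <- lay$coords
  }
  q_coords <- do.call(rbind, q_coords)

  # target gene order per chromosome, then rearrangements
  order_by_chrom <- lapply(seq_len(cfg$n_chromosomes), function(ci) {
    ids <- ancestor$layout$gene_id[ancestor$layout$chrom_index == ci]
    data.frame(gene_id = paste0("t_", ids), strand = "+",
               stringsAsFactors = FALSE)
  })
  log <- list()

  if (cfg$gene_loss_rate > 0) {
    for (ci in seq_along(order_by_chrom)) {
      keep <- stats::runif(nrow(order_by_chrom[[ci]])) >= cfg$gene_loss_rate
      lost <- order_by_chrom[[ci]]$gene_id[!keep]
      if (length(lost)) {
        log[[length(log) + 1L]] <- data.frame(
          type = "loss", chrom = paste0("tchr", ci),
          genes = paste(lost, collapse = ","), stringsAsFactors = FALSE)
      }
      order_by_chrom[[ci]] <- order_by_chrom[[ci]][keep, , drop = FALSE]
    }
  }
  dup_of <- character(0)
  if (cfg$tandem_dup_rate > 0) {
    for (ci in seq_along(order_by_chrom)) {
      oc <- order_by_chrom[[ci]]
      out <- list()
      for (i in seq_len(nrow(oc))) {
        out[[length(out) + 1L]] <- oc[i, ]
        if (stats::runif(1) < cfg$tandem_dup_rate) {
          did <- paste0(oc$gene_id[i], "_d")
          t_genes[[did]] <- mutate_seq(t_genes[[oc$gene_id[i]]],
                                       cfg$divergence / 2, cfg$indel_rate)
          dup_of[did] <- oc$gene_id[i]
          out[[length(out) + 1L]] <- data.frame(gene_id = did, strand = "+",
                                                stringsAsFactors = FALSE)
          log[[length(log) + 1L]] <- data.frame(
            type = "tandem_dup", chrom = paste0("tchr", ci),
            genes = did, stringsAsFactors = FALSE)
        }
      }
      order_by_chrom[[ci]] <- do.call(rbind, out)
    }
  }
  spans <- cfg$inversion_spans
  if (is.null(spans) && cfg$n_inversions > 0) {
    spans <- draw_spans_(cfg$n_inversions, cfg$n_chromosomes,
                         min(vapply(order_by_chrom, nrow, 0L)), c(3L, 8L))
  }
  for (sp in spans) {
    oc <- order_by_chrom[[sp$chrom]]
    idx <- sp$from:sp$to
    seg <- oc[rev(idx), , drop = FALSE]
    seg$strand <- ifelse(seg$strand == "+", "-", "+")
    oc[idx, ] <- seg
    order_by_chrom[[sp$chrom]] <- oc
    log[[length(log) + 1L]] <- data.frame(
      type = "inversion", chrom = paste0("tchr", sp$chrom),
      genes = paste(seg$gene_id, collapse = ","), stringsAsFactors = FALSE)
  }
  if (cfg$n_translocations > 0) {
    for (tr in seq_len(cfg$n_translocations)) {
      if (cfg$n_chromosomes < 2L) break
      src <- sample.int(cfg$n_chromosomes, 1L)
      dst <- sample(setdiff(seq_len(cfg$n_chromosomes), src), 1L)
      oc <- order_by_chrom[[src]]
      if (nrow(oc) < 6L) next
      len <- sample(2:4, 1L)
      from <- sample.int(nrow(oc) - len, 1L)
      seg <- oc[from:(from + len - 1L), , drop = FALSE]
      order_by_chrom[[src]] <- oc[-(from:(from + len - 1L)), , drop = FALSE]
      od <- order_by_chrom[[dst]]
      at <- sample.int(nrow(od) + 1L, 1L)
      order_by_chrom[[dst]] <- rbind(
        if (at > 1L) od[seq_len(at - 1L), , drop = FALSE],
        seg,
        if (at <= nrow(od)) od[at:nrow(od), , drop = FALSE])
      log[[length(log) + 1L]] <- data.frame(
        type = "translocation", chrom = paste0("tchr", dst),
        genes = paste(seg$gene_id, collapse = ","), stringsAsFactors = FALSE)
    }
  }

  t_coords <- list()
  t_chrom_seqs <- character(cfg$n_chromosomes)
  for (ci in seq_len(cfg$n_chromosomes)) {
    oc <- order_by_chrom[[ci]]
    lay <- layout_chromosome(t_genes[oc$gene_id], oc$strand,
                             paste0("tchr", ci), cfg$intergenic_bp)
    t_coords[[ci]] <- lay$coords
    t_chrom_seqs[ci] <- lay$seq
  }
  t_coords <- do.call(rbind, t_coords)
  names(t_chrom_seqs) <- paste0("tchr", seq_len(cfg$n_chromosomes))
  surviving <- t_coords$gene_id

  tcs <- character(0)
  if (cfg$tc_fraction > 0) {
    picked <- surviving[stats::runif(length(surviving)) < cfg$tc_fraction]
    if (length(picked)) {
      tcs <- vapply(picked, function(g) {
        s <- t_genes[[g]]
        n <- nchar(s)
        substr(s, max(1L, round(0.1 * n)), round(0.9 * n))
      }, "")
      names(tcs) <- paste0("tc_", sub("^t_", "", picked))
    }
  }

  base <- sub("_d$", "", surviving)
  orth <- data.frame(
    query_gene = paste0("q_", sub("^t_", "", names(anc))),
    target_gene = NA_character_, stringsAsFactors = FALSE)
  anc_ids <- names(anc)
  primary <- match(paste0("t_", anc_ids), surviving)
  orth$target_gene <- ifelse(is.na(primary), NA_character_,
                             surviving[primary])
  rearr <- if (length(log)) do.call(rbind, log) else
    data.frame(type = character(), chrom = character(), genes = character(),
               stringsAsFactors = FALSE)

  list(query = list(genes = q_genes, coords = q_coords),
       target = list(genes = setNames(t_genes[surviving], surviving),
                     transcript_contigs = tcs,
                     chromosomes = t_chrom_seqs,
                     coords = t_coords,
                     duplicate_of = dup_of),
       truth = list(orthologs = orth, rearrangements = rearr))
}

#' Simulate a genetic map over the query genome
#'
#' A random `marker_fraction` of query genes become markers; the true cM
#' of every query gene is the integral of the (piecewise-constant) cM/Mb
#' rate from the chromosome start to the gene midpoint.
#'
#' @param genomes Output of [evolve_genomes()].
#' @param cfg A [sim_config()].
#' @return A list with `map` (a [genetic_map()]), `marker_seqs` (named
#'   character vector), `assoc` (marker_id / seq_id association) and
#'   `truth_cm` (true cM of every query gene).
#' @export
simulate_genetic_map <- function(genomes, cfg) {
  sim_seed_(cfg, 2L)
  qc <- genomes$query$coords
  chrom_index <- as.integer(sub("^qchr", "", qc$chrom))
  mid <- (qc$start + qc$end) / 2
  true_cm <- vapply(seq_len(nrow(qc)), function(i) {
    cm_at_bp(mid[i], chrom_rates_(cfg, chrom_index[i]))
  }, 0)
  truth_cm <- data.frame(gene_id = qc$gene_id,
                         linkage_group = paste0("LG", chrom_index),
                         true_cM = true_cm, stringsAsFactors = FALSE)
  is_marker <- stats::runif(nrow(qc)) < cfg$marker_fraction
  # every linkage group needs at least two anchors to be usable
  for (ci in unique(chrom_index)) {
    rows <- which(chrom_index == ci)
    if (sum(is_marker[rows]) < 2L) {
      is_marker[rows[order(mid[rows])][c(1L, length(rows))]] <- TRUE
    }
  }
  marker_rows <- which(is_marker)
  map <- genetic_map(data.frame(
    marker_id = paste0("M_", qc$gene_id[marker_rows]),
    linkage_group = truth_cm$linkage_group[marker_rows],
    position_cM = truth_cm$true_cM[marker_rows],
    stringsAsFactors = FALSE))
  marker_seqs <- genomes$query$genes[qc$gene_id[marker_rows]]
  names(marker_seqs) <- paste0("M_", qc$gene_id[marker_rows])
  assoc <- data.frame(marker_id = names(marker_seqs),
                      seq_id = qc$gene_id[marker_rows],
                      stringsAsFactors = FALSE)
  list(map = map, marker_seqs = marker_seqs, assoc = assoc,
       truth_cm = truth_cm)
}

#' Simulate EST reads from the query genes
#'
#' Per gene, 1 or more reads from random subintervals with per-base error
#' `est_error_rate`; a poly-A tail is appended with probability
#' `polyA_prob` and the 40-mer vector is prepended with probability
#' `vector_prob`.
#'
#' @param genomes Output of [evolve_genomes()].
#' @param cfg A [sim_config()].
#' @return A list with `reads` (named character vector) and `truth`
#'   (read_id / gene_id table).
#' @export
simulate_ests <- function(genomes, cfg) {
  sim_seed_(cfg, 3L)
  reads <- character(0)
  truth <- list()
  for (g in names(genomes$query$genes)) {
    s <- genomes$query$genes[[g]]
    L <- nchar(s)
    n <- sample(cfg$est_per_gene[1]:cfg$est_per_gene[2], 1L)
    for (i in seq_len(n)) {
      len <- min(L, max(150L, round(stats::runif(1, cfg$est_len_frac[1],
                                                 cfg$est_len_frac[2]) * L)))
      start <- sample.int(L - len + 1L, 1L)
      read <- substr(s, start, start + len - 1L)
      if (cfg$est_error_rate > 0) {
        read <- mutate_seq(read, cfg$est_error_rate, 0)
      }
      if (stats::runif(1) < cfg$polyA_prob) {
        read <- paste0(read, strrep("A", sample(12:30, 1L)))
      }
      if (stats::runif(1) < cfg$vector_prob) {
        read <- paste0(VECTOR_SEQ, read)
      }
      rid <- sprintf("e_%s_%02d", g, i)
      reads[rid] <- read
      truth[[rid]] <- data.frame(read_id = rid, gene_id = g,
                                 stringsAsFactors = FALSE)
    }
  }
  list(reads = reads, truth = do.call(rbind, c(truth,
                                               list(make.row.names = FALSE))))
}

#' Simulate a complete input bundle
#'
#' Runs the whole simulator and assembles the inputs the toolkit consumes
#' (EST FASTA, target genome bundle, genetic map, marker associations)
#' together with every truth table.  When `dir` is given the bundle is
#' also written to disk (FASTA / GFF3 / TSV).
#'
#' @param cfg A [sim_config()].
#' @param dir Optional output directory.
#' @return A list of class `sim_bundle` with elements `ests`,
#'   `query_genes`, `target` (a [target_genome()]), `map`, `marker_seqs`,
#'   `assoc`, `truth` (orthologs, positions, cM, reads, rearrangements)
#'   and `cfg`.
#' @export
simulate_bundle <- function(cfg = sim_config(), dir = NULL) {
  anc <- simulate_ancestor(cfg)
  genomes <- evolve_genomes(anc, cfg)
  gm <- simulate_genetic_map(genomes, cfg)
  ests <- simulate_ests(genomes, cfg)
  target <- target_genome(
    predicted_genes = Biostrings::DNAStringSet(genomes$target$genes),
    transcript_contigs = Biostrings::DNAStringSet(
      genomes$target$transcript_contigs),
    genomic_seqs = Biostrings::DNAStringSet(genomes$target$chromosomes),
    gene_positions = genomes$target$coords[,
      c("gene_id", "chrom", "start", "end", "strand")],
    coverage_fraction = 1)
  bundle <- structure(list(
    ests = Biostrings::DNAStringSet(ests$reads),
    query_genes = Biostrings::DNAStringSet(genomes$query$genes),
    query_coords = genomes$query$coords,
    target = target,
    map = gm$map,
    marker_seqs = Biostrings::DNAStringSet(gm$marker_seqs),
    assoc = gm$assoc,
    vector_lib = Biostrings::DNAStringSet(c(univec40 = VECTOR_SEQ)),
    truth = list(orthologs = genomes$truth$orthologs,
                 rearrangements = genomes$truth$rearrangements,
                 target_positions = genomes$target$coords,
                 cm = gm$truth_cm,
                 reads = ests$truth),
    cfg = cfg), class = "sim_bundle")
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

#' Write a simulated bundle to disk
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$ests, file.path(dir, "query_ests.fasta"))
  write_fasta(bundle$query_genes, file.path(dir, "query_genes.fasta"))
  write_fasta(bundle$target$predicted_genes,
              file.path(dir, "target_genes.fasta"))
  if (length(bundle$target$transcript_contigs)) {
    write_fasta(bundle$target$transcript_contigs,
                file.path(dir, "target_tcs.fasta"))
  }
  write_fasta(bundle$target$genomic_seqs,
              file.path(dir, "target_genome.fasta"))
  write_positions_gff3(bundle$target$gene_positions,
                       file.path(dir, "target_genes.gff3"))
  write_tsv(data.frame(marker_id = bundle$map$marker_id,
                       linkage_group = bundle$map$linkage_group,
                       position_cM = bundle$map$position_cM),
            file.path(dir, "genetic_map.tsv"))
  write_tsv(bundle$assoc, file.path(dir, "marker_assoc.tsv"))
  write_fasta(bundle$marker_seqs, file.path(dir, "marker_seqs.fasta"))
  write_fasta(bundle$vector_lib, file.path(dir, "vector.fasta"))
  write_tsv(bundle$truth$orthologs, file.path(dir, "truth_orthologs.tsv"))
  write_tsv(bundle$truth$cm, file.path(dir, "truth_cm.tsv"))
  write_tsv(bundle$truth$reads, file.path(dir, "truth_reads.tsv"))
  write_tsv(bundle$truth$target_positions,
            file.path(dir, "truth_target_positions.tsv"))
  write_tsv(bundle$truth$rearrangements,
            file.path(dir, "truth_rearrangements.tsv"))
  invisible(dir)
}
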