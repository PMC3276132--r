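# Simulator: determinism, genome layout, divergence calibration,
# rearrangement bookkeeping, genetic-map integration and EST generation.

test_that("identical seeds reproduce identical bundles", {
  cfg <- sim_config(seed = 81, n_chromosomes = 1, genes_per_chromosome = 5,
                    est_per_gene = c(1, 2))
  b1 <- simulate_bundle(cfg)
  b2 <- simulate_bundle(cfg)
  expect_identical(as.character(b1$ests), as.character(b2$ests))
  expect_identical(as.character(b1$target$genomic_seqs),
                   as.character(b2$target$genomic_seqs))
  expect_identical(b1$map$position_cM, b2$map$position_cM)
  expect_identical(b1$truth$orthologs, b2$truth$orthologs)
})

test_that("genome layout obeys the configuration", {
  cfg <- sim_config(seed = 82, n_chromosomes = 2, genes_per_chromosome = 50,
                    gene_length_bp = c(900, 1100))
  anc <- simulate_ancestor(cfg)
  expect_equal(length(anc$genes), 100)
  expect_true(all(nchar(anc$genes) >= 900 & nchar(anc$genes) <= 1100))
  g <- evolve_genomes(anc, cfg)
  # gene coordinates are non-overlapping, 0-based half-open
  for (cc in unique(g$target$coords$chrom)) {
    co <- g$target$coords[g$target$coords$chrom == cc, ]
    co <- co[order(co$start), ]
    expect_true(all(co$end > co$start))
    expect_true(all(utils::head(co$end, -1) <= utils::tail(co$start, -1)))
  }
  # chromosome sequence embeds each gene at its stated coordinates
  chrom1 <- g$target$chromosomes[["tchr1"]]
  co1 <- g$target$coords[g$target$coords$chrom == "tchr1", ][1, ]
  embedded <- substr(chrom1, co1$start + 1, co1$end)
  gene_seq <- g$target$genes[[co1$gene_id]]
  if (co1$strand == "-") {
    gene_seq <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(gene_seq)))
  }
  expect_equal(embedded, gene_seq)
})

test_that("zero divergence gives identical genomes; 10% gives ~90% identity", {
  cfg0 <- sim_config(seed = 83, n_chromosomes = 1,
                     genes_per_chromosome = 6, divergence = 0,
                     indel_rate = 0)
  g0 <- evolve_genomes(simulate_ancestor(cfg0), cfg0)
  expect_equal(unname(g0$query$genes), unname(g0$target$genes))
  expect_true(all(!is.na(g0$truth$orthologs$target_gene)))

  cfg1 <- sim_config(seed = 84, n_chromosomes = 1,
                     genes_per_chromosome = 10, divergence = 0.10,
                     indel_rate = 0)
  g1 <- evolve_genomes(simulate_ancestor(cfg1), cfg1)
  ids <- vapply(seq_along(g1$query$genes), function(i) {
    a <- strsplit(g1$query$genes[[i]], "")[[1]]
    b <- strsplit(g1$target$genes[[i]], "")[[1]]
    mean(a == b)
  }, 0)
  expect_equal(mean(ids), 0.90, tolerance = 0.02)
})

test_that("explicit inversions reverse order and strand and are logged", {
  cfg <- sim_config(seed = 85, n_chromosomes = 1, genes_per_chromosome = 20,
                    divergence = 0, indel_rate = 0, n_inversions = 1,
                    inversion_spans = list(list(chrom = 1, from = 10,
                                                to = 15)))
  g <- evolve_genomes(simulate_ancestor(cfg), cfg)
  co <- g$target$coords
  expect_equal(co$gene_id[10:15], paste0("t_c1g", sprintf("%03d", 15:10)))
  expect_true(all(co$strand[10:15] == "-"))
  expect_true(all(co$strand[-(10:15)] == "+"))
  expect_equal(g$truth$rearrangements$type, "inversion")
})

test_that("gene count is conserved up to losses and duplications", {
  cfg <- sim_config(seed = 86, n_chromosomes = 2, genes_per_chromosome = 25,
                    gene_loss_rate = 0.1, tandem_dup_rate = 0.1)
  g <- evolve_genomes(simulate_ancestor(cfg), cfg)
  log <- g$truth$rearrangements
  n_lost <- sum(vapply(strsplit(log$genes[log$type == "loss"], ","),
                       length, 0L))
  n_dup <- sum(log$type == "tandem_dup")
  expect_equal(nrow(g$target$coords), 50 - n_lost + n_dup)
  # lost ancestors have NA orthologs
  expect_equal(sum(is.na(g$truth$orthologs$target_gene)), n_lost)
})

test_that("cM truth integrates the piecewise-constant rate", {
  expect_equal(legumap:::cm_at_bp(3e6, 2), 6)
  pw <- data.frame(from_bp = c(0, 2e6), rate = c(1, 4))
  expect_equal(legumap:::cm_at_bp(3e6, pw), 1 * 2 + 4 * 1)
  expect_equal(legumap:::cm_at_bp(1e6, pw), 1)
  cfg <- sim_config(seed = 87, n_chromosomes = 1, genes_per_chromosome = 10,
                    marker_fraction = 1, cm_per_mb = list(pw))
  g <- evolve_genomes(simulate_ancestor(cfg), cfg)
  gm <- simulate_genetic_map(g, cfg)
  expect_equal(nrow(gm$map), 10)  # every gene a marker
  mid <- (g$query$coords$start + g$query$coords$end) / 2
  want <- vapply(mid, function(b) legumap:::cm_at_bp(b, pw), 0)
  expect_equal(gm$truth_cm$true_cM, want)
  # map positions are the marker subset of the truth
  expect_equal(sort(gm$map$position_cM), sort(want))
})

test_that("EST reads reflect the error, poly-A and vector settings", {
  cfg <- sim_config(seed = 88, n_chromosomes = 1, genes_per_chromosome = 5,
                    est_per_gene = c(1, 1), est_len_frac = c(1, 1),
                    est_error_rate = 0, polyA_prob = 0, vector_prob = 0)
  g <- evolve_genomes(simulate_ancestor(cfg), cfg)
  reads <- simulate_ests(g, cfg)
  expect_equal(unname(reads$reads[paste0("e_", names(g$query$genes), "_01")]),
               unname(g$query$genes))

  cfgA <- sim_config(seed = 89, n_chromosomes = 1, genes_per_chromosome = 5,
                     est_per_gene = c(1, 2), polyA_prob = 1)
  readsA <- simulate_ests(evolve_genomes(simulate_ancestor(cfgA), cfgA),
                          cfgA)
  expect_true(all(grepl("A{12,}$", readsA$reads)))

  cfgV <- sim_config(seed = 90, n_chromosomes = 1, genes_per_chromosome = 5,
                     est_per_gene = c(1, 1), vector_prob = 1)
  readsV <- simulate_ests(evolve_genomes(simulate_ancestor(cfgV), cfgV),
                          cfgV)
  expect_true(all(startsWith(unname(readsV$reads), legumap:::VECTOR_SEQ)))
})

test_that("overlapping error-free reads cluster back to one unigene per gene", {
  cfg <- sim_config(seed = 91, n_chromosomes = 1, genes_per_chromosome = 8,
                    est_per_gene = c(3, 3), est_len_frac = c(0.7, 0.9),
                    est_error_rate = 0, polyA_prob = 0, vector_prob = 0)
  b <- simulate_bundle(cfg)
  ug <- cluster_unigenes(b$ests)
  expect_equal(length(ug$representatives), 8)
  # members of each cluster come from a single source gene
  src <- b$truth$reads$gene_id[match(ug$members$member_id,
                                     b$truth$reads$read_id)]
  expect_true(all(tapply(src, ug$members$unigene_id,
                         function(x) length(unique(x))) == 1))
})
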