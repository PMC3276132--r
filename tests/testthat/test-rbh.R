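# Reciprocal-best-homolog logic: reciprocity, the genomic flanking
# window, position resolution, paralog handling, summary arithmetic,
# and equivalence with an all-pairs full-DP score matrix.

make_pair_target <- function(genes, tcs = character(0),
                             genomic = character(0), positions = NULL) {
  target_genome(predicted_genes = dna(genes),
                transcript_contigs = dna(tcs),
                genomic_seqs = dna(genomic),
                gene_positions = positions)
}

test_that("mutual best hits are reciprocal; one-sided bests are not", {
  set.seed(51)
  g1 <- rand_seq(400)
  g2 <- rand_seq(400)
  target <- make_pair_target(c(tg1 = mutate_rate(g1, 0.05),
                               tg2 = mutate_rate(g2, 0.05)))
  unis <- dna(c(u1 = g1, u2 = g2))
  r <- rbh_search(unis, target)
  expect_equal(r$subject_id[r$unigene_id == "u1"], "tg1")
  expect_equal(r$subject_id[r$unigene_id == "u2"], "tg2")
  expect_true(all(r$is_reciprocal))
  expect_true(all(r$category == "predicted_gene"))

  # u_frag's best forward hit is tg1, but tg1's best reverse hit is the
  # full-length u1 -> u_frag must not be called reciprocal
  unis2 <- dna(c(u1 = g1, u_frag = substr(g1, 1, 150)))
  r2 <- rbh_search(unis2, target)
  expect_true(r2$is_reciprocal[r2$unigene_id == "u1"])
  fr <- r2[r2$unigene_id == "u_frag", ]
  expect_equal(fr$subject_id, "tg1")
  expect_false(fr$is_reciprocal)
  expect_equal(fr$reverse_subject, "u1")
})

test_that("genomic hits use a clamped +/- 2 kb window for the reverse query", {
  set.seed(52)
  gene <- rand_seq(400)
  chrom <- paste0(rand_seq(500), gene, rand_seq(300))  # 1200 bp entry
  target <- target_genome(predicted_genes = dna(c(dummy = rand_seq(300))),
                          genomic_seqs = dna(c(bac1 = chrom)))
  unis <- dna(c(u1 = gene))
  r <- rbh_search(unis, target, window_bp = 2000)
  expect_equal(r$category, "genomic")
  expect_equal(r$subject_id, "bac1")
  expect_true(r$s_start >= 450 && r$s_end <= 950)
  expect_true(r$is_reciprocal)
  # window of +/- 2 kb around the hit clamps to the whole 1200 bp entry
  rq <- legumap:::reverse_query_(r[1, ], target, 2000L)
  expect_equal(nchar(rq), 1200)
})

test_that("cross-database ties prefer predicted genes over genomic copies", {
  set.seed(53)
  gene <- rand_seq(400)
  # same sequence present verbatim in both dbs, same total db length so
  # the E-values tie exactly
  target <- target_genome(predicted_genes = dna(c(pg = gene)),
                          genomic_seqs = dna(c(gs = gene)))
  r <- rbh_search(dna(c(u = gene)), target)
  expect_equal(r$category, "predicted_gene")
})

test_that("positions resolve by gene midpoint, window midpoint and TC relay", {
  set.seed(54)
  gene <- rand_seq(400)
  chrom <- paste0(rand_seq(1000), gene, rand_seq(600))
  positions <- data.frame(gene_id = "pg", chrom = "chr5",
                          start = 1000L, end = 1400L, strand = "+",
                          stringsAsFactors = FALSE)
  target <- target_genome(predicted_genes = dna(c(pg = gene)),
                          transcript_contigs = dna(c(tc = gene)),
                          genomic_seqs = dna(c(chr5 = chrom)),
                          gene_positions = positions)
  r <- rbh_search(dna(c(u = gene)), target)
  r <- resolve_position(r, target)
  expect_equal(r$position_method, "direct")
  expect_equal(r$chromosome, "chr5")
  expect_equal(r$position_bp, 1200)

  # transcript-contig subject relays through its best predicted gene
  target_tc <- target_genome(predicted_genes = dna(c(pg = rand_seq(380))),
                             transcript_contigs = dna(c(tc = gene)),
                             gene_positions = data.frame(
                               gene_id = "pg", chrom = "chr5",
                               start = 0L, end = 380L, strand = "+",
                               stringsAsFactors = FALSE))
  r2 <- rbh_search(dna(c(u = gene)), target_tc)
  expect_equal(r2$category, "transcript_contig")
  r2 <- resolve_position(r2, target_tc)
  # tc has no qualifying predicted-gene homolog -> unplaced
  expect_equal(r2$position_method, "unplaced")

  target_tc2 <- target_genome(predicted_genes = dna(c(pg = gene)),
                              transcript_contigs = dna(
                                c(tc = paste0(gene, rand_seq(50)))),
                              gene_positions = positions)
  r3 <- rbh_search(dna(c(u = paste0(gene, rand_seq(49)))), target_tc2)
  if (r3$category == "transcript_contig" && r3$is_reciprocal) {
    r3 <- resolve_position(r3, target_tc2)
    expect_equal(r3$position_method, "tc_relay")
    expect_equal(r3$position_bp, 1200)
  }
})

test_that("an extra-diverged paralog never displaces the true ortholog", {
  set.seed(55)
  g <- rand_seq(400)
  ortho <- mutate_rate(g, 0.03)
  paralog <- mutate_rate(ortho, 0.08)
  target <- make_pair_target(c(t_ortho = ortho, t_para = paralog))
  r <- rbh_search(dna(c(u = g, decoy = rand_seq(400))), target)
  ru <- r[r$unigene_id == "u", ]
  expect_equal(ru$subject_id, "t_ortho")
  expect_true(ru$is_reciprocal)
})

test_that("identical duplicated subjects are handled by the strict-best rule", {
  set.seed(56)
  g <- rand_seq(400)
  t <- mutate_rate(g, 0.05)
  # two identical unigenes: the reverse best is tied -> ambiguous -> reject
  r <- rbh_search(dna(c(aa = g, bb = g)), make_pair_target(c(tg = t)))
  expect_false(any(r$is_reciprocal))
})

test_that("raising e_max never decreases unidirectional coverage", {
  set.seed(57)
  genes <- stats::setNames(vapply(rep(300, 6), rand_seq, ""),
                           paste0("g", 1:6))
  target <- make_pair_target(vapply(genes, mutate_rate, "", rate = 0.12))
  names(target$predicted_genes) <- paste0("t", 1:6)
  unis <- dna(genes)
  strict <- rbh_search(unis, target, e_max = 1e-40)
  loose <- rbh_search(unis, target, e_max = 1e-10)
  n_uni_strict <- sum(strict$category != "none")
  n_uni_loose <- sum(loose$category != "none")
  expect_lte(n_uni_strict, n_uni_loose)
  expect_lte(sum(strict$is_reciprocal), n_uni_strict)
  expect_lte(sum(loose$is_reciprocal), n_uni_loose)
})

test_that("RBH pairs equal mutual bests of an all-pairs DP score matrix", {
  set.seed(58)
  n <- 10
  qs <- stats::setNames(vapply(rep(90, n), rand_seq, ""), paste0("q", 1:n))
  ts <- stats::setNames(vapply(qs, mutate_rate, "", rate = 0.05),
                        paste0("t", 1:n))
  scores <- matrix(0, n, n, dimnames = list(names(qs), names(ts)))
  for (i in 1:n) {
    for (j in 1:n) scores[i, j] <- sw_oracle(qs[[i]], ts[[j]])$score
  }
  # oracle mutual bests (strict argmax both ways)
  oracle_pairs <- character(0)
  for (i in 1:n) {
    j <- which.max(scores[i, ])
    if (sum(scores[i, ] == scores[i, j]) == 1 &&
          which.max(scores[, j]) == i &&
          sum(scores[, j] == scores[i, j]) == 1) {
      oracle_pairs[names(qs)[i]] <- colnames(scores)[j]
    }
  }
  r <- rbh_search(dna(qs), make_pair_target(ts))
  impl_pairs <- stats::setNames(r$subject_id[r$is_reciprocal],
                                r$unigene_id[r$is_reciprocal])
  expect_equal(impl_pairs[sort(names(impl_pairs))],
               oracle_pairs[sort(names(oracle_pairs))])
})

test_that("summary arithmetic uses half-up integer percentages", {
  expect_equal(hit_rate_pct(5888, 13747), 43)
  expect_equal(estimated_hit_rate_pct(5888, 13747, 0.60), 71)
  expect_equal(hit_rate_pct(0, 13747), 0)
  expect_equal(estimated_hit_rate_pct(0, 10, 0.5), 0)
  # half-up, not banker's rounding
  expect_equal(hit_rate_pct(45, 1000), 5)   # 4.5 -> 5
  expect_equal(hit_rate_pct(35, 1000), 4)   # 3.5 -> 4 (round() would give 4 too; 4.5 is the discriminating case)
})

test_that("summarize_rbh counts categories consistently", {
  set.seed(59)
  g1 <- rand_seq(300); g2 <- rand_seq(300); g3 <- rand_seq(300)
  target <- make_pair_target(c(t1 = mutate_rate(g1, 0.05),
                               t2 = mutate_rate(g2, 0.05)))
  r <- rbh_search(dna(c(u1 = g1, u2 = g2, u3 = g3)), target)
  s <- summarize_rbh(r, coverage_fraction = 0.5)
  expect_equal(s$total_unigenes, 3)
  expect_equal(s$unidirectional, 2)
  expect_equal(s$reciprocal, 2)
  expect_lte(s$reciprocal, s$unidirectional)
  expect_equal(sum(s$reciprocal_by_category), s$reciprocal)
  expect_equal(s$hit_rate_pct, hit_rate_pct(2, 3))
  expect_equal(s$estimated_hit_rate_pct, estimated_hit_rate_pct(2, 3, 0.5))
})
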