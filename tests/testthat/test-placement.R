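# Map placement: anchor construction, piecewise-linear interpolation,
# extrapolation and clamping, and the two query modes.

mk_anchors <- function(...) {
  df <- data.frame(..., stringsAsFactors = FALSE)
  df[order(df$chromosome, df$bp, df$marker_id), ]
}

two_anchor_set <- function(cm = c(10, 20)) {
  mk_anchors(marker_id = c("m1", "m2"), linkage_group = "LG1",
             cM = cm, chromosome = "chr1", bp = c(1e6, 2e6))
}

test_that("anchor table is built sorted, skipping unusable markers", {
  map <- genetic_map(data.frame(marker_id = c("m1", "m2", "m3"),
                                linkage_group = "LG1",
                                position_cM = c(5, 10, 20)))
  rbh <- data.frame(unigene_id = c("m2", "m1", "m3", "m_unknown"),
                    is_reciprocal = c(TRUE, TRUE, FALSE, TRUE),
                    chromosome = c("chr1", "chr1", "chr1", "chr1"),
                    position_bp = c(2e6, 1e6, 3e6, 4e6),
                    stringsAsFactors = FALSE)
  expect_warning(expect_warning(a <- build_anchor_table(map, rbh),
                                "not in the genetic map"),
                 "without a resolved")
  expect_equal(a$marker_id, c("m1", "m2"))
  expect_equal(a$bp, c(1e6, 2e6))
  # two markers at the same bp keep a stable order by marker id
  rbh2 <- data.frame(unigene_id = c("m2", "m1"),
                     is_reciprocal = TRUE, chromosome = "chr1",
                     position_bp = c(1e6, 1e6), stringsAsFactors = FALSE)
  a2 <- build_anchor_table(map, rbh2)
  expect_equal(a2$marker_id, c("m1", "m2"))
})

test_that("linear interpolation between flanking anchors, both orientations", {
  p <- infer_map_position("chr1", 1.5e6, two_anchor_set(c(10, 20)))
  expect_equal(p$status, "interpolated")
  expect_equal(p$cM, 15)
  expect_equal(p$linkage_group, "LG1")
  expect_equal(p$left_anchor, "m1")
  expect_equal(p$right_anchor, "m2")
  # local inversion: decreasing cM along bp is handled by the same formula
  p2 <- infer_map_position("chr1", 1.5e6, two_anchor_set(c(20, 10)))
  expect_equal(p2$cM, 15)
})

test_that("positions outside the anchor span extrapolate and clamp", {
  a <- two_anchor_set(c(10, 20))  # local rate: 10 cM / Mb
  lg_len <- c(LG1 = 40)
  p <- infer_map_position("chr1", 2.5e6, a, lg_lengths = lg_len)
  expect_equal(p$status, "extrapolated")
  expect_equal(p$cM, 25)
  # far beyond the end clamps to the linkage-group length
  p2 <- infer_map_position("chr1", 9e6, a, lg_lengths = lg_len)
  expect_equal(p2$cM, 40)
  # before the first anchor, clamped at 0
  p3 <- infer_map_position("chr1", 0, a, lg_lengths = lg_len)
  expect_equal(p3$status, "extrapolated")
  expect_equal(p3$cM, 0)
})

test_that("degenerate and ambiguous anchor configurations are flagged", {
  # two anchors at the same bp: mean of their cM
  a <- mk_anchors(marker_id = c("m1", "m2"), linkage_group = "LG1",
                  cM = c(10, 14), chromosome = "chr1", bp = c(1e6, 1e6))
  p <- infer_map_position("chr1", 1e6, a)
  expect_equal(p$cM, 12)
  # a single anchor cannot orient an interval
  p2 <- infer_map_position("chr1", 5e5,
                           mk_anchors(marker_id = "m1",
                                      linkage_group = "LG1", cM = 10,
                                      chromosome = "chr1", bp = 1e6))
  expect_equal(p2$status, "chromosome_only")
  # flanking anchors from different linkage groups
  a3 <- mk_anchors(marker_id = c("m1", "m2"),
                   linkage_group = c("LG1", "LG2"),
                   cM = c(10, 3), chromosome = "chr2", bp = c(1e6, 2e6))
  p3 <- infer_map_position("chr2", 1.5e6, a3)
  expect_equal(p3$status, "chromosome_only")
  expect_true(grepl("LG1", p3$lg_candidates) && grepl("LG2", p3$lg_candidates))
  # no anchors on the chromosome at all
  p4 <- infer_map_position("chrX", 1e6, a3)
  expect_equal(p4$status, "unplaced")
})

test_that("querying an anchor's own bp returns its own cM exactly", {
  set.seed(61)
  for (rep in 1:10) {
    n <- sample(3:8, 1)
    bp <- sort(sample.int(5e6, n))
    cm <- sort(runif(n, 0, 100))
    a <- mk_anchors(marker_id = sprintf("m%02d", 1:n),
                    linkage_group = "LG1", cM = cm,
                    chromosome = "chr1", bp = bp)
    for (i in seq_len(n)) {
      p <- infer_map_position("chr1", bp[i], a)
      expect_identical(p$cM, cm[i])
    }
  }
})

test_that("inferred cM is monotone in bp within collinear anchors", {
  set.seed(62)
  bp <- sort(sample.int(5e6, 6))
  cm <- sort(runif(6, 0, 80))
  a <- mk_anchors(marker_id = sprintf("m%d", 1:6), linkage_group = "LG1",
                  cM = cm, chromosome = "chr1", bp = bp)
  qs <- sort(sample.int(5e6, 40))
  cms <- vapply(qs, function(q) infer_map_position("chr1", q, a)$cM, 0)
  expect_true(all(diff(cms) >= -1e-9))
  # interpolated values stay inside the flanking anchors' cM range
  inside <- qs >= min(bp) & qs <= max(bp)
  expect_true(all(cms[inside] >= min(cm) - 1e-9 &
                    cms[inside] <= max(cm) + 1e-9))
})

test_that("place_all orders placements and carries unplaced rows", {
  a <- two_anchor_set(c(10, 20))
  rbh <- data.frame(
    unigene_id = c("u3", "u1", "u2"),
    is_reciprocal = c(TRUE, TRUE, FALSE),
    chromosome = c("chr1", "chr1", NA),
    position_bp = c(1.8e6, 1.2e6, NA),
    stringsAsFactors = FALSE)
  pl <- place_all(rbh, a)
  expect_equal(nrow(pl), 3)
  expect_equal(pl$unigene_id, c("u1", "u3", "u2"))  # by cM, unplaced last
  expect_equal(pl$cM[1:2], c(12, 18))
  expect_equal(pl$status[3], "unplaced")
  # nothing positioned -> everything unplaced
  pl2 <- place_all(rbh[3, , drop = FALSE], a)
  expect_true(all(pl2$status == "unplaced"))
})

test_that("block-restricted placement beats chromosome-wide with an inversion", {
  # chromosome with 12 anchors; target order carries an inverted middle
  n <- 12
  true_cm <- seq(2, 46, by = 4)
  bp <- seq(1e5, 1.2e6, length.out = n)
  inv <- 5:8
  cm_on_target <- true_cm
  cm_on_target[inv] <- rev(true_cm[inv])
  a <- mk_anchors(marker_id = sprintf("m%02d", 1:n), linkage_group = "LG1",
                  cM = cm_on_target, chromosome = "chr1", bp = bp)
  pts <- make_dotplot_table(anchors = a)
  blocks <- detect_blocks(pts, block_config(min_pairs = 3))
  # queries inside the inverted segment, between anchors
  qbp <- (bp[5:7] + bp[6:8]) / 2
  qcm_true <- (cm_on_target[5:7] + cm_on_target[6:8]) / 2
  err_plain <- abs(vapply(qbp, function(q)
    infer_map_position("chr1", q, a)$cM, 0) - qcm_true)
  err_block <- abs(vapply(qbp, function(q)
    infer_map_position("chr1", q, a, blocks = blocks)$cM, 0) - qcm_true)
  expect_lte(mean(err_block), mean(err_plain))
})

test_that("forward query returns at most five placed best hits", {
  set.seed(63)
  gene <- rand_seq(300)
  near <- vapply(1:7, function(i) mutate_every(gene, 40 + i), "")
  unis <- dna(stats::setNames(c(gene, near), paste0("u", 1:8)))
  placements <- data.frame(
    unigene_id = paste0("u", 1:8), linkage_group = "LG1",
    cM = seq(5, 40, by = 5), status = "interpolated",
    stringsAsFactors = FALSE)
  hits <- query_position_for_sequence(gene, unis, placements, k = 5)
  expect_equal(nrow(hits), 5)
  expect_equal(hits$unigene_id[1], "u1")
  expect_equal(hits$cM[1], 5)
  # a random sequence has no qualifying hit
  expect_equal(nrow(query_position_for_sequence(rand_seq(300), unis,
                                                placements)), 0)
  # hits without placements are listed but flagged
  hits2 <- query_position_for_sequence(gene, unis, placements[-1, ], k = 5)
  expect_equal(hits2$status[1], "unplaced")
})

test_that("reverse candidate query uses closed intervals and windows", {
  map <- genetic_map(data.frame(marker_id = c("mA", "mB", "mC"),
                                linkage_group = c("LG1", "LG1", "LG2"),
                                position_cM = c(10, 20, 7)))
  placements <- data.frame(
    unigene_id = paste0("u", 1:4), linkage_group = "LG1",
    cM = c(9, 12, 18, 21), status = "interpolated",
    stringsAsFactors = FALSE)
  got <- query_candidates_near(placements, map, marker = "mA",
                               marker2 = "mB")
  expect_equal(got$unigene_id, c("u2", "u3"))   # 9 and 21 excluded
  got2 <- query_candidates_near(placements, lg = "LG1", cm = 15,
                                window_cM = 5)
  expect_equal(got2$unigene_id, c("u2", "u3"))  # [10, 20] closed
  got3 <- query_candidates_near(placements, lg = "LG1", cm = 100,
                                window_cM = 2)
  expect_equal(nrow(got3), 0)
  expect_error(query_candidates_near(placements, map, marker = "mA",
                                     marker2 = "mC"),
               "same linkage group")
  expect_error(query_candidates_near(placements, map, marker = "nope"),
               "not in the genetic map")
})
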