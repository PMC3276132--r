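# In-silico map placement: anchor markers tie the genetic map (LG, cM) to
# the target genome (chromosome, bp); unmapped genes are placed by
# piecewise-linear interpolation of cM against bp between same-LG flanking
# anchors, with rate-continuation extrapolation beyond terminal anchors.

#' Build the anchor table linking genetic and physical coordinates
#'
#' An anchor is a genetic-map marker whose reciprocal homolog has a
#' resolved position on a target pseudo-chromosome.
#'
#' @param map A [genetic_map()].
#' @param marker_rbh An `rbh_result` for the marker sequences, after
#'   [resolve_position()]; `unigene_id` must be the marker id unless
#'   `assoc` is given.
#' @param assoc Optional data.frame (`marker_id`, `seq_id`) associating map
#'   markers with the sequence ids used in `marker_rbh`.
#' @return data.frame of anchors (marker_id, linkage_group, cM,
#'   chromosome, bp) sorted by (chromosome, bp, marker_id).  Markers
#'   without a resolved position, or absent from the map, are skipped with
#'   a warning.
#' @export
build_anchor_table <- function(map, marker_rbh, assoc = NULL) {
  res <- as.data.frame(marker_rbh)
  if (!is.null(assoc)) {
    j <- match(res$unigene_id, assoc$seq_id)
    res$unigene_id <- ifelse(is.na(j), res$unigene_id, assoc$marker_id[j])
  }
  in_map <- res$unigene_id %in% map$marker_id
  if (any(!in_map)) {
    warning(sum(!in_map), " marker sequence(s) not in the genetic map; skipped")
  }
  res <- res[in_map, , drop = FALSE]
  positioned <- res$is_reciprocal & !is.na(res$position_bp)
  if (any(!positioned)) {
    warning(sum(!positioned),
            " marker(s) without a resolved target position; skipped")
  }
  res <- res[positioned, , drop = FALSE]
  j <- match(res$unigene_id, map$marker_id)
  anchors <- data.frame(marker_id = res$unigene_id,
                        linkage_group = map$linkage_group[j],
                        cM = map$position_cM[j],
                        chromosome = res$chromosome,
                        bp = res$position_bp,
                        stringsAsFactors = FALSE)
  anchors <- anchors[order(anchors$chromosome, anchors$bp,
                           anchors$marker_id), ]
  rownames(anchors) <- NULL
  anchors
}

unplaced_row_ <- function(id = NA_character_, chrom = NA_character_,
                          bp = NA_real_, status = "unplaced",
                          lg = NA_character_, cM = NA_real_,
                          left = NA_character_, right = NA_character_,
                          ndist = NA_real_, lgs = NA_character_) {
  data.frame(unigene_id = id, linkage_group = lg, cM = cM, status = status,
             left_anchor = left, right_anchor = right,
             chromosome = chrom, bp = bp,
             nearest_anchor_distance_bp = ndist,
             lg_candidates = lgs, stringsAsFactors = FALSE)
}

# extrapolate beyond the terminal anchor of an LG using the local rate of
# the nearest anchor interval, clamped to [0, lg_length]
extrapolate_ <- function(a_lg, pos, lg_length) {
  a_lg <- a_lg[order(a_lg$bp, a_lg$marker_id), ]
  n <- nrow(a_lg)
  if (pos > a_lg$bp[n]) {
    i2 <- n; i1 <- n - 1L
    base <- n
  } else {
    i1 <- 1L; i2 <- 2L
    base <- 1L
  }
  dbp <- a_lg$bp[i2] - a_lg$bp[i1]
  rate <- if (dbp > 0) (a_lg$cM[i2] - a_lg$cM[i1]) / dbp else 0
  cm <- a_lg$cM[base] + rate * (pos - a_lg$bp[base])
  list(cM = max(0, min(lg_length, cm)),
       left = if (base == n) a_lg$marker_id[n] else NA_character_,
       right = if (base == 1L) a_lg$marker_id[1] else NA_character_)
}

#' Infer a genetic-map position from a physical position
#'
#' Candidate anchors are those on the query's chromosome, restricted to
#' the synteny block containing the position when `blocks` are supplied.
#' The flanking anchors left and right of the position are located; when
#' they belong to the same linkage group the cM position is linearly
#' interpolated between them (`interpolated`).  A position outside the
#' anchor span is extrapolated with the nearest interval's local cM/bp
#' rate, clamped to `[0, LG length]` (`extrapolated`).  Flanking anchors
#' on different linkage groups, or a single available anchor, give
#' `chromosome_only` with the candidate linkage groups reported.
#'
#' @param chrom Chromosome of the query position.
#' @param bp Physical position (bp).
#' @param anchors Anchor table from [build_anchor_table()].
#' @param blocks Optional synteny blocks from [detect_blocks()].
#' @param lg_lengths Named numeric vector of linkage-group lengths (cM);
#'   defaults to the maximum anchor cM per group.
#' @return One-row data.frame (linkage_group, cM, status, left_anchor,
#'   right_anchor, chromosome, bp, nearest_anchor_distance_bp,
#'   lg_candidates).
#' @export
infer_map_position <- function(chrom, bp, anchors, blocks = NULL,
                               lg_lengths = NULL) {
  a <- anchors[anchors$chromosome == chrom, , drop = FALSE]
  if (!nrow(a)) return(unplaced_row_(chrom = chrom, bp = bp))
  if (is.null(lg_lengths)) {
    lg_lengths <- c(tapply(anchors$cM, anchors$linkage_group, max))
  }
  if (!is.null(blocks) && nrow(blocks)) {
    bl <- blocks[blocks$chromosome == chrom & blocks$bp_start <= bp &
                   blocks$bp_end >= bp, , drop = FALSE]
    if (nrow(bl)) {
      # narrowest containing block wins
      bl <- bl[order(bl$bp_end - bl$bp_start), ][1, ]
      ab <- a[a$linkage_group == bl$linkage_group & a$bp >= bl$bp_start &
                a$bp <= bl$bp_end, , drop = FALSE]
      if (nrow(ab)) a <- ab
    }
  }
  a <- a[order(a$bp, a$marker_id), ]
  ndist <- min(abs(a$bp - bp))
  lgs <- unique(a$linkage_group)
  if (nrow(a) == 1L) {
    return(unplaced_row_(chrom = chrom, bp = bp, status = "chromosome_only",
                         ndist = ndist, lgs = a$linkage_group))
  }
  iL <- which(a$bp <= bp)
  iR <- which(a$bp >= bp)
  if (length(iL) && length(iR)) {
    L <- a[max(iL), ]
    R <- a[min(iR), ]
    if (L$linkage_group != R$linkage_group) {
      return(unplaced_row_(chrom = chrom, bp = bp,
                           status = "chromosome_only", ndist = ndist,
                           lgs = paste(unique(c(L$linkage_group,
                                                R$linkage_group)),
                                       collapse = ",")))
    }
    cm <- if (R$bp == L$bp) {
      mean(c(L$cM, R$cM))
    } else {
      L$cM + (R$cM - L$cM) * (bp - L$bp) / (R$bp - L$bp)
    }
    return(unplaced_row_(chrom = chrom, bp = bp, status = "interpolated",
                         lg = L$linkage_group, cM = cm,
                         left = L$marker_id, right = R$marker_id,
                         ndist = ndist, lgs = L$linkage_group))
  }
  # outside the anchor span: extrapolate within the nearest anchor's LG
  near <- a[which.min(abs(a$bp - bp)), ]
  a_lg <- a[a$linkage_group == near$linkage_group, , drop = FALSE]
  if (nrow(a_lg) < 2L) {
    return(unplaced_row_(chrom = chrom, bp = bp, status = "chromosome_only",
                         ndist = ndist, lgs = near$linkage_group))
  }
  ex <- extrapolate_(a_lg, bp, unname(lg_lengths[near$linkage_group]))
  unplaced_row_(chrom = chrom, bp = bp, status = "extrapolated",
                lg = near$linkage_group, cM = ex$cM,
                left = ex$left, right = ex$right, ndist = ndist,
                lgs = near$linkage_group)
}

#' Place all positioned Unigenes on the genetic map
#'
#' @param unigene_rbh An `rbh_result` after [resolve_position()].
#' @param anchors Anchor table from [build_anchor_table()].
#' @param blocks Optional synteny blocks from [detect_blocks()].
#' @param lg_lengths Optional named vector of linkage-group lengths (cM).
#' @return data.frame of map placements, one row per Unigene, ordered by
#'   (linkage_group, cM, unigene_id) with unplaced rows last.
#' @export
place_all <- function(unigene_rbh, anchors, blocks = NULL,
                      lg_lengths = NULL) {
  res <- as.data.frame(unigene_rbh)
  rows <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    if (is.na(res$position_bp[i])) {
      rows[[i]] <- unplaced_row_(id = res$unigene_id[i])
    } else {
      p <- infer_map_position(res$chromosome[i], res$position_bp[i],
                              anchors, blocks, lg_lengths)
      p$unigene_id <- res$unigene_id[i]
      rows[[i]] <- p
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(is.na(out$cM), out$linkage_group, out$cM,
                   out$unigene_id), ]
  rownames(out) <- NULL
  out
}

#' Forward query: map position of an arbitrary sequence
#'
#' The sequence is searched against the Unigene database at `e_max`; the
#' placements of the (up to) `k` best hits are returned.  Hits whose
#' Unigene has no placement are still listed, flagged `unplaced`.
#'
#' @param seq Query nucleotide sequence (character or `DNAString`).
#' @param unigenes Named `DNAStringSet` of Unigene representatives (or a
#'   `unigene_set`).
#' @param placements Placement table from [place_all()].
#' @param scoring An [align_scoring()] object.
#' @param e_max E-value threshold.
#' @param k Maximum number of hits reported (default 5).
#' @return data.frame of ranked hits with their placements.
#' @export
query_position_for_sequence <- function(seq, unigenes, placements,
                                        scoring = align_scoring(),
                                        e_max = 1e-20, k = 5L) {
  if (inherits(unigenes, "unigene_set")) unigenes <- unigenes$representatives
  hits <- best_hits(seq, unigenes, scoring, e_max = e_max, k = k)
  if (!nrow(hits)) {
    return(data.frame(rank = integer(), unigene_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      identity_pct = numeric(), linkage_group = character(),
                      cM = numeric(), status = character(),
                      stringsAsFactors = FALSE))
  }
  j <- match(hits$subject_id, placements$unigene_id)
  data.frame(rank = seq_len(nrow(hits)),
             unigene_id = hits$subject_id,
             evalue = hits$evalue, bitscore = hits$bitscore,
             identity_pct = hits$identity_pct,
             linkage_group = ifelse(is.na(j), NA_character_,
                                    placements$linkage_group[j]),
             cM = ifelse(is.na(j), NA_real_, placements$cM[j]),
             status = ifelse(is.na(j), "unplaced", placements$status[j]),
             stringsAsFactors = FALSE)
}

#' Reverse query: candidate genes near a genetic locus
#'
#' The locus is one marker (window of +/- `window_cM` around it), two
#' markers on the same linkage group (the closed cM interval between
#' them), or an explicit (linkage group, cM) position (window of +/-
#' `window_cM`).  Placed Unigenes within the closed interval are returned
#' sorted by cM then id.
#'
#' @param placements Placement table from [place_all()].
#' @param map A [genetic_map()] (needed for marker queries).
#' @param marker,marker2 Marker ids.
#' @param lg,cm Explicit linkage group and cM position.
#' @param window_cM Half-width of the point-query window (cM).
#' @return data.frame (unigene_id, linkage_group, cM, status).
#' @export
query_candidates_near <- function(placements, map = NULL, marker = NULL,
                                  marker2 = NULL, lg = NULL, cm = NULL,
                                  window_cM = 5) {
  locate <- function(m) {
    j <- match(m, map$marker_id)
    if (is.na(j)) stop("marker not in the genetic map: ", m)
    list(lg = map$linkage_group[j], cm = map$position_cM[j])
  }
  if (!is.null(marker) && !is.null(marker2)) {
    m1 <- locate(marker); m2 <- locate(marker2)
    if (m1$lg != m2$lg) stop("markers not on the same linkage group")
    lg <- m1$lg
    lo <- min(m1$cm, m2$cm)
    hi <- max(m1$cm, m2$cm)
  } else if (!is.null(marker)) {
    m1 <- locate(marker)
    lg <- m1$lg
    lo <- m1$cm - window_cM
    hi <- m1$cm + window_cM
  } else if (!is.null(lg) && !is.null(cm)) {
    lo <- cm - window_cM
    hi <- cm + window_cM
  } else {
    stop("give a marker, two markers, or lg + cm")
  }
  hit <- !is.na(placements$cM) & placements$linkage_group == lg &
    placements$cM >= lo & placements$cM <= hi
  out <- placements[hit, c("unigene_id", "linkage_group", "cM", "status")]
  out <- out[order(out$cM, out$unigene_id), ]
  rownames(out) <- NULL
  out
}
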