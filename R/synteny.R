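# Synteny: dot-plot point sets (LG/cM vs chromosome/bp) and block
# detection.  A block is a run of homolog points from one linkage group
# along a chromosome, tolerant of a few intruding points from other
# groups, split into consistently-oriented (monotone-cM) segments so that
# an inversion shows up as its own block of opposite orientation.

#' Build the dot-plot point table
#'
#' One point per homolog pair carrying both coordinate systems: the
#' genetic position (linkage group, cM) and the physical position
#' (chromosome, bp).
#'
#' @param anchors Optional anchor table from [build_anchor_table()].
#' @param placements Optional placement table from [place_all()]; only
#'   rows with a cM position and a physical position contribute points.
#' @param pairs Optional pre-built data.frame with columns `id`,
#'   `linkage_group`, `cM`, `chromosome`, `bp`.
#' @return data.frame of points sorted by (chromosome, bp, id); inputs
#'   without a physical position are excluded with a warning.
#' @export
make_dotplot_table <- function(anchors = NULL, placements = NULL,
                               pairs = NULL) {
  parts <- list()
  if (!is.null(anchors) && nrow(anchors)) {
    parts$anchors <- data.frame(id = anchors$marker_id,
                                linkage_group = anchors$linkage_group,
                                cM = anchors$cM,
                                chromosome = anchors$chromosome,
                                bp = anchors$bp, stringsAsFactors = FALSE)
  }
  if (!is.null(placements) && nrow(placements)) {
    parts$placements <- data.frame(id = placements$unigene_id,
                                   linkage_group = placements$linkage_group,
                                   cM = placements$cM,
                                   chromosome = placements$chromosome,
                                   bp = placements$bp,
                                   stringsAsFactors = FALSE)
  }
  if (!is.null(pairs) && nrow(pairs)) {
    parts$pairs <- pairs[, c("id", "linkage_group", "cM", "chromosome", "bp")]
  }
  if (!length(parts)) {
    return(data.frame(id = character(), linkage_group = character(),
                      cM = numeric(), chromosome = character(),
                      bp = numeric(), stringsAsFactors = FALSE))
  }
  pts <- do.call(rbind, c(parts, list(make.row.names = FALSE)))
  bad <- is.na(pts$bp) | is.na(pts$cM) | is.na(pts$chromosome)
  if (any(bad)) {
    warning(sum(bad), " homolog(s) without both coordinates; excluded")
    pts <- pts[!bad, , drop = FALSE]
  }
  pts <- pts[order(pts$chromosome, pts$bp, pts$id), ]
  rownames(pts) <- NULL
  pts
}

# split one LG run (sorted by bp) into maximal monotone-cM segments;
# a segment closes at the point before a strict direction flip
monotone_segments <- function(run) {
  n <- nrow(run)
  if (n == 1L) return(list(run))
  segs <- list()
  start <- 1L
  dir <- 0L
  for (i in 2:n) {
    d <- sign(run$cM[i] - run$cM[i - 1L])
    if (d != 0 && dir == 0) {
      dir <- d
    } else if (d != 0 && d != dir) {
      segs <- c(segs, list(run[start:(i - 1L), , drop = FALSE]))
      start <- i
      dir <- 0L
    }
  }
  c(segs, list(run[start:n, , drop = FALSE]))
}

segment_orientation <- function(seg) {
  d <- diff(seg$cM)
  if (!length(d) || all(d == 0)) return("mixed")
  if (all(d >= 0)) return("plus")
  if (all(d <= 0)) return("minus")
  "mixed"
}

#' Detect synteny blocks
#'
#' Points are scanned per chromosome in bp order.  For each linkage
#' group, a candidate run is a maximal succession of its points tolerating
#' at most `max_intruders` consecutive points from other linkage groups
#' (intruders are not block members).  Runs are further broken at
#' physical or genetic gaps exceeding `max_gap_bp` / `max_gap_cM`, and at
#' changes of cM direction, so that each block is consistently oriented:
#' `plus` when cM increases with bp, `minus` when it decreases (cM ties
#' are tolerated inside either), `mixed` only when all members share one
#' cM.  Segments with fewer than `min_pairs` points are discarded.
#'
#' @param points Dot-plot table from [make_dotplot_table()].
#' @param cfg A [block_config()].
#' @return data.frame of blocks (block_id, linkage_group, chromosome,
#'   n_points, cM_start, cM_end, bp_start, bp_end, orientation) with a
#'   `members` attribute (data.frame block_id, id) listing member points.
#' @export
detect_blocks <- function(points, cfg = block_config()) {
  empty <- data.frame(block_id = character(), linkage_group = character(),
                      chromosome = character(), n_points = integer(),
                      cM_start = numeric(), cM_end = numeric(),
                      bp_start = numeric(), bp_end = numeric(),
                      orientation = character(), stringsAsFactors = FALSE)
  attr(empty, "members") <- data.frame(block_id = character(),
                                       id = character(),
                                       stringsAsFactors = FALSE)
  if (is.null(points) || !nrow(points)) return(empty)
  pts <- points[order(points$chromosome, points$bp, points$id), ]
  segs <- list()
  for (chrom in unique(pts$chromosome)) {
    pc <- pts[pts$chromosome == chrom, , drop = FALSE]
    for (lgv in unique(pc$linkage_group)) {
      idx <- which(pc$linkage_group == lgv)
      gap <- c(0L, diff(idx) - 1L)                # intruding points between
      run_id <- cumsum(gap > cfg$max_intruders)
      for (r in split(idx, run_id)) {
        run <- pc[r, , drop = FALSE]
        # break at oversized physical / genetic gaps
        brk <- cumsum(c(FALSE, diff(run$bp) > cfg$max_gap_bp |
                          abs(diff(run$cM)) > cfg$max_gap_cM))
        for (piece in split(run, brk)) {
          segs <- c(segs, monotone_segments(piece))
        }
      }
    }
  }
  segs <- Filter(function(s) nrow(s) >= cfg$min_pairs, segs)
  if (!length(segs)) return(empty)
  ord <- order(vapply(segs, function(s) s$chromosome[1], ""),
               vapply(segs, function(s) min(s$bp), 0),
               vapply(segs, function(s) s$linkage_group[1], ""))
  segs <- segs[ord]
  width <- max(3L, nchar(length(segs)))
  rows <- list()
  members <- list()
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    bid <- sprintf(paste0("B%0", width, "d"), i)
    rows[[i]] <- data.frame(
      block_id = bid, linkage_group = s$linkage_group[1],
      chromosome = s$chromosome[1], n_points = nrow(s),
      cM_start = min(s$cM), cM_end = max(s$cM),
      bp_start = min(s$bp), bp_end = max(s$bp),
      orientation = segment_orientation(s), stringsAsFactors = FALSE)
    members[[i]] <- data.frame(block_id = bid, id = s$id,
                               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "members") <- do.call(rbind, members)
  out
}

#' Summarize detected blocks
#'
#' @param blocks Block table from [detect_blocks()].
#' @return A list with `per_pair` (one row per (linkage group,
#'   chromosome): block count, sizes, spans, orientations) and `per_lg`
#'   (totals per linkage group).
#' @export
block_summary <- function(blocks) {
  if (is.null(blocks) || !nrow(blocks)) {
    return(list(
      per_pair = data.frame(linkage_group = character(),
                            chromosome = character(), n_blocks = integer(),
                            n_points = integer(), sizes = character(),
                            orientations = character(),
                            cM_span = numeric(), bp_span = numeric(),
                            stringsAsFactors = FALSE),
      per_lg = data.frame(linkage_group = character(), n_blocks = integer(),
                          n_chromosomes = integer(), n_points = integer(),
                          stringsAsFactors = FALSE)))
  }
  key <- paste(blocks$linkage_group, blocks$chromosome, sep = "\r")
  per_pair <- do.call(rbind, lapply(split(blocks, key), function(b) {
    data.frame(linkage_group = b$linkage_group[1],
               chromosome = b$chromosome[1],
               n_blocks = nrow(b), n_points = sum(b$n_points),
               sizes = paste(b$n_points, collapse = ","),
               orientations = paste(b$orientation, collapse = ","),
               cM_span = sum(b$cM_end - b$cM_start),
               bp_span = sum(b$bp_end - b$bp_start),
               stringsAsFactors = FALSE)
  }))
  per_pair <- per_pair[order(per_pair$linkage_group, per_pair$chromosome), ]
  rownames(per_pair) <- NULL
  per_lg <- do.call(rbind, lapply(split(blocks, blocks$linkage_group),
                                  function(b) {
    data.frame(linkage_group = b$linkage_group[1], n_blocks = nrow(b),
               n_chromosomes = length(unique(b$chromosome)),
               n_points = sum(b$n_points), stringsAsFactors = FALSE)
  }))
  rownames(per_lg) <- NULL
  list(per_pair = per_pair, per_lg = per_lg)
}

#' Export dot-plot and block views
#'
#' Writes `dotplot.tsv` (the point table), `blocks.tsv`, and
#' `pairing.tsv` (one row per block pairing an LG segment with a
#' chromosome segment).  With `plot = TRUE` (and ggplot2 installed) a
#' faceted dot-plot is written to `dotplot.pdf`.
#'
#' @param points Dot-plot table.
#' @param blocks Block table from [detect_blocks()].
#' @param dir Output directory (created if absent).
#' @param plot Also draw the dot-plot?
#' @return Character vector of the files written, invisibly.
#' @export
export_views <- function(points, blocks, dir, plot = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- c(dotplot = file.path(dir, "dotplot.tsv"),
             blocks = file.path(dir, "blocks.tsv"),
             pairing = file.path(dir, "pairing.tsv"))
  write_tsv(points, files["dotplot"])
  write_tsv(blocks, files["blocks"])
  pairing <- if (nrow(blocks)) {
    data.frame(block_id = blocks$block_id,
               linkage_group = blocks$linkage_group,
               cM_start = blocks$cM_start, cM_end = blocks$cM_end,
               chromosome = blocks$chromosome,
               bp_start = blocks$bp_start, bp_end = blocks$bp_end,
               orientation = blocks$orientation, stringsAsFactors = FALSE)
  } else {
    data.frame(block_id = character(), linkage_group = character(),
               cM_start = numeric(), cM_end = numeric(),
               chromosome = character(), bp_start = numeric(),
               bp_end = numeric(), orientation = character(),
               stringsAsFactors = FALSE)
  }
  write_tsv(pairing, files["pairing"])
  if (plot && requireNamespace("ggplot2", quietly = TRUE) && nrow(points)) {
    p <- ggplot2::ggplot(points,
                         ggplot2::aes(x = bp / 1e6, y = cM,
                                      colour = linkage_group)) +
      ggplot2::geom_point(size = 0.8) +
      ggplot2::facet_grid(linkage_group ~ chromosome, scales = "free") +
      ggplot2::labs(x = "chromosome position (Mb)",
                    y = "map position (cM)", colour = "LG") +
      ggplot2::theme_bw()
    pdf_file <- file.path(dir, "dotplot.pdf")
    ggplot2::ggsave(pdf_file, p, width = 8, height = 6)
    files <- c(files, plot = pdf_file)
  }
  invisible(files)
}
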