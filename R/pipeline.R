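# End-to-end pipeline: clean -> cluster -> (annotate) -> reciprocal
# search -> position resolution -> anchor building -> map placement ->
# synteny -> summary, with every stage's table written to disk and a
# deterministic run manifest.  Rerunning with identical inputs and
# configuration reproduces identical files.

#' Read an input bundle from a directory
#'
#' Expects the file layout written by [write_bundle()]:
#' `query_ests.fasta`, `target_genes.fasta`, `target_genome.fasta`,
#' `target_genes.gff3`, `genetic_map.tsv`, `marker_assoc.tsv`,
#' `marker_seqs.fasta`, plus optional `target_tcs.fasta` and
#' `vector.fasta` / `repeats.fasta` libraries.
#'
#' @param dir Bundle directory.
#' @return A list shaped like a `sim_bundle` (without truth tables).
#' @export
read_bundle <- function(dir) {
  need <- c("query_ests.fasta", "target_genes.fasta", "target_genome.fasta",
            "target_genes.gff3", "genetic_map.tsv", "marker_assoc.tsv",
            "marker_seqs.fasta")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing)) {
    stop("input bundle at ", dir, " is missing: ",
         paste(missing, collapse = ", "),
         " (nothing has been run)")
  }
  opt_fasta <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) read_fasta(p) else Biostrings::DNAStringSet()
  }
  target <- target_genome(
    predicted_genes = read_fasta(file.path(dir, "target_genes.fasta")),
    transcript_contigs = opt_fasta("target_tcs.fasta"),
    genomic_seqs = read_fasta(file.path(dir, "target_genome.fasta")),
    gene_positions = read_positions(file.path(dir, "target_genes.gff3"),
                                    "gff3"))
  list(ests = read_fasta(file.path(dir, "query_ests.fasta")),
       target = target,
       map = read_genetic_map(file.path(dir, "genetic_map.tsv")),
       marker_seqs = read_fasta(file.path(dir, "marker_seqs.fasta")),
       assoc = utils::read.delim(file.path(dir, "marker_assoc.tsv"),
                                 stringsAsFactors = FALSE),
       vector_lib = opt_fasta("vector.fasta"),
       repeat_lib = opt_fasta("repeats.fasta"))
}

#' Run the full translational-mapping pipeline
#'
#' @param bundle A `sim_bundle` from [simulate_bundle()], or a bundle
#'   directory path readable by [read_bundle()].
#' @param config A [toolkit_config()].
#' @param out_dir Output directory; every stage writes its table there
#'   and a `manifest.json` records package version, configuration hash
#'   and stage outputs.
#' @param hits_in Optional precomputed forward/reverse hit tables (a list
#'   with elements `forward` and `reverse`, see [read_blast_tsv()]); when
#'   supplied the built-in alignment stage of the reciprocal search is
#'   skipped and the manifest records it.
#' @return A list with the unigene set, reciprocal results, anchors,
#'   placements, blocks and summary, invisibly.
#' @export
run_pipeline <- function(bundle, config = toolkit_config(), out_dir,
                         hits_in = NULL) {
  if (is.character(bundle)) bundle <- read_bundle(bundle)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scoring <- config$scoring

  cleaned <- clean_sequences(bundle$ests,
                             repeat_lib = bundle$repeat_lib,
                             vector_lib = bundle$vector_lib,
                             cfg = config$cleaning, scoring = scoring)
  write_tsv(cleaned$report, file.path(out_dir, "cleaning_report.tsv"))
  write_fasta(cleaned$seqs, file.path(out_dir, "cleaned.fasta"))

  unigenes <- cluster_unigenes(cleaned$seqs, config$clustering, scoring)
  write_tsv(unigenes$members, file.path(out_dir, "unigene_members.tsv"))
  write_fasta(unigenes$representatives,
              file.path(out_dir, "unigenes.fasta"))

  if (is.null(hits_in)) {
    rbh <- rbh_search(unigenes, bundle$target, scoring,
                      e_max = config$e_max, window_bp = config$window_bp)
  } else {
    rbh <- rbh_from_hits(hits_in$forward, hits_in$reverse,
                         e_max = config$e_max)
  }
  rbh <- resolve_position(rbh, bundle$target, scoring, config$e_max)
  write_tsv(rbh_table_(rbh), file.path(out_dir, "rbh.tsv"))

  marker_rbh <- rbh_search(bundle$marker_seqs, bundle$target, scoring,
                           e_max = config$e_max,
                           window_bp = config$window_bp)
  marker_rbh <- resolve_position(marker_rbh, bundle$target, scoring,
                                 config$e_max)
  anchors <- suppressWarnings(
    build_anchor_table(bundle$map, marker_rbh, bundle$assoc))
  write_tsv(anchors, file.path(out_dir, "anchors.tsv"))

  points <- make_dotplot_table(anchors = anchors)
  blocks <- detect_blocks(points, config$blocks)
  export_views(points, blocks, out_dir)

  placements <- place_all(rbh, anchors, blocks,
                          lg_lengths = attr(bundle$map, "lg_lengths"))
  write_tsv(placements, file.path(out_dir, "placements.tsv"), digits = 1)

  summary <- summarize_rbh(rbh,
                           coverage_fraction =
                             bundle$target$coverage_fraction)
  write_tsv(summary_table_(summary), file.path(out_dir, "summary.tsv"))

  manifest <- list(
    package = "legumap",
    version = as.character(utils::packageVersion("legumap")),
    config_hash = config_hash_(config),
    seed = if (!is.null(bundle$cfg)) bundle$cfg$seed else NA,
    alignment_stage = if (is.null(hits_in)) "builtin" else "precomputed",
    n_input_sequences = length(bundle$ests),
    n_unigenes = length(unigenes$representatives),
    n_reciprocal = sum(rbh$is_reciprocal),
    n_anchors = nrow(anchors),
    n_placed = sum(!is.na(placements$cM)),
    n_blocks = nrow(blocks),
    outputs = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(unigenes = unigenes, rbh = rbh, anchors = anchors,
                 placements = placements, points = points, blocks = blocks,
                 summary = summary, manifest = manifest))
}

rbh_table_ <- function(rbh) {
  data.frame(unigene_id = rbh$unigene_id, category = rbh$category,
             subject_id = rbh$subject_id, evalue = rbh$evalue,
             bitscore = round(rbh$bitscore, 2),
             identity_pct = round(rbh$identity_pct, 2),
             reciprocal = ifelse(rbh$is_reciprocal, "Y", "N"),
             chromosome = rbh$chromosome, position_bp = rbh$position_bp,
             position_method = rbh$position_method,
             stringsAsFactors = FALSE)
}

summary_table_ <- function(s) {
  cats <- names(s$unidirectional_by_category)
  data.frame(
    row = c("unidirectional", "unidirectional_pct", "reciprocal",
            "reciprocal_pct", "estimated_pct"),
    total = c(s$unidirectional, s$unidirectional_pct, s$reciprocal,
              s$hit_rate_pct, s$estimated_hit_rate_pct),
    rbind(s$unidirectional_by_category,
          hit_rate_pct(s$unidirectional_by_category, s$total_unigenes),
          s$reciprocal_by_category,
          hit_rate_pct(s$reciprocal_by_category, s$total_unigenes),
          rep(NA, length(cats))),
    stringsAsFactors = FALSE, row.names = NULL)
}

config_hash_ <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

#' Read a 12-column blast-style tabular hit file
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore (1-based inclusive coordinates; subject
#' minus-strand hits have sstart > send).  Coordinates are normalized to
#' the internal 0-based half-open, forward-strand convention.
#'
#' @param path Path to the TSV (no header).
#' @return A hits data.frame compatible with [local_align()] output.
#' @export
read_blast_tsv <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12) stop("expected 12 columns in ", path)
  names(df)[1:12] <- c("qseqid", "sseqid", "pident", "length", "mismatch",
                       "gapopen", "qstart", "qend", "sstart", "send",
                       "evalue", "bitscore")
  minus <- df$sstart > df$send
  data.frame(query_id = df$qseqid, subject_id = df$sseqid,
             score = NA_real_, bitscore = df$bitscore, evalue = df$evalue,
             identity_pct = df$pident, align_len = df$length,
             q_start = df$qstart - 1L, q_end = df$qend,
             s_start = ifelse(minus, df$send, df$sstart) - 1L,
             s_end = ifelse(minus, df$sstart, df$send),
             strand = ifelse(minus, "-", "+"), stringsAsFactors = FALSE)
}

#' Reciprocal best hits from precomputed hit tables
#'
#' Computes best reciprocal pairs from externally produced forward
#' (query vs target) and reverse (target vs query) hit tables, applying
#' the same ranking and strict-best tie rules as [rbh_search()].  The
#' forward table may carry a `category` column (`predicted_gene`,
#' `transcript_contig`, `genomic`); absent, all hits are treated as
#' predicted genes.
#'
#' @param forward,reverse Hit tables from [read_blast_tsv()] (or
#'   [local_align()]).
#' @param e_max E-value threshold applied to both tables.
#' @return An `rbh_result` data.frame (positions unresolved).
#' @export
rbh_from_hits <- function(forward, reverse, e_max = 1e-20) {
  if (is.null(forward$category)) forward$category <- "predicted_gene"
  fwd <- forward[forward$evalue <= e_max, , drop = FALSE]
  rev <- reverse[reverse$evalue <= e_max, , drop = FALSE]
  fwd <- fwd[order(fwd$query_id, fwd$evalue, -fwd$bitscore,
                   CATEGORY_ORDER[fwd$category], fwd$subject_id), ]
  best_fwd <- fwd[!duplicated(fwd$query_id), , drop = FALSE]
  rev <- rev[order(rev$query_id, rev$evalue, -rev$bitscore,
                   rev$subject_id), ]
  rows <- lapply(seq_len(nrow(best_fwd)), function(i) {
    f <- best_fwd[i, ]
    row <- empty_rbh_row(f$query_id)
    row$category <- f$category
    row$subject_id <- f$subject_id
    row$evalue <- f$evalue
    row$bitscore <- f$bitscore
    row$identity_pct <- f$identity_pct
    row$strand <- f$strand
    row$s_start <- f$s_start
    row$s_end <- f$s_end
    rv <- rev[rev$query_id == f$subject_id, , drop = FALSE]
    if (nrow(rv)) {
      row$reverse_subject <- rv$subject_id[1]
      row$reverse_evalue <- rv$evalue[1]
      tie <- nrow(rv) >= 2 && rv$evalue[1] == rv$evalue[2] &&
        rv$bitscore[1] == rv$bitscore[2] &&
        rv$subject_id[1] != rv$subject_id[2]
      row$is_reciprocal <- identical(rv$subject_id[1], f$query_id) && !tie
    }
    row
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("rbh_result", "data.frame")
  res
}
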