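# Best-reciprocal-homolog search against a target genome made of three
# sequence databases (predicted genes, transcript contigs, genomic
# pseudo-chromosomes/BACs), with the flanking-window rule for genomic
# subjects, pseudo-chromosome position resolution and summary statistics.

CATEGORY_ORDER <- c(predicted_gene = 1L, transcript_contig = 2L,
                    genomic = 3L)

#' Bundle a target genome for reciprocal homology search
#'
#' @param predicted_genes Named `DNAStringSet` of predicted gene sequences.
#' @param transcript_contigs Named `DNAStringSet` of transcript contigs
#'   (may be empty).
#' @param genomic_seqs Named `DNAStringSet` of genomic sequences
#'   (pseudo-chromosomes and/or BACs; may be empty).
#' @param gene_positions data.frame from [read_positions()] mapping
#'   predicted-gene ids to (chrom, start, end, strand), 0-based half-open.
#' @param coverage_fraction Fraction of the genome represented by the
#'   available sequence (used for the estimated hit rate).
#' @param pseudochromosomes Names of `genomic_seqs` entries that are
#'   chromosome-scale (hits on them are positionable); defaults to all.
#' @return An object of class `target_genome`.
#' @export
target_genome <- function(predicted_genes,
                          transcript_contigs = Biostrings::DNAStringSet(),
                          genomic_seqs = Biostrings::DNAStringSet(),
                          gene_positions = NULL,
                          coverage_fraction = 1,
                          pseudochromosomes = names(genomic_seqs)) {
  stopifnot(length(predicted_genes) > 0, !is.null(names(predicted_genes)),
            coverage_fraction > 0, coverage_fraction <= 1)
  if (!is.null(gene_positions)) {
    missing <- setdiff(gene_positions$gene_id, names(predicted_genes))
    if (length(missing)) {
      stop("positioned gene id(s) absent from predicted_genes: ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
  }
  structure(list(predicted_genes = predicted_genes,
                 transcript_contigs = transcript_contigs,
                 genomic_seqs = genomic_seqs,
                 gene_positions = gene_positions,
                 coverage_fraction = coverage_fraction,
                 pseudochromosomes = pseudochromosomes),
            class = "target_genome")
}

empty_rbh_row <- function(uid) {
  data.frame(unigene_id = uid, category = "none",
             subject_id = NA_character_, evalue = NA_real_,
             bitscore = NA_real_, identity_pct = NA_real_,
             strand = NA_character_,
             s_start = NA_integer_, s_end = NA_integer_,
             is_reciprocal = FALSE,
             reverse_subject = NA_character_, reverse_evalue = NA_real_,
             chromosome = NA_character_, position_bp = NA_real_,
             position_method = "unplaced", stringsAsFactors = FALSE)
}

# forward best hit of one query over the union of the three dbs
forward_best <- function(q, target, scoring, e_max, indexes, qid) {
  dbs <- list(predicted_gene = target$predicted_genes,
              transcript_contig = target$transcript_contigs,
              genomic = target$genomic_seqs)
  parts <- list()
  for (cat in names(dbs)) {
    if (!length(dbs[[cat]])) next
    h <- best_hits(q, dbs[[cat]], scoring, e_max = e_max, k = 1L,
                   index = indexes[[cat]], query_id = qid)
    if (nrow(h)) {
      h$category <- cat
      parts[[cat]] <- h[1, ]
    }
  }
  if (!length(parts)) return(NULL)
  df <- do.call(rbind, parts)
  # cross-db precedence on exact ties: predicted gene > TC > genomic
  df <- df[order(df$evalue, -df$bitscore, CATEGORY_ORDER[df$category],
                 df$subject_id), ]
  df[1, ]
}

#' Best reciprocal homolog search
#'
#' For each Unigene the forward best hit is taken over the union of the
#' three target databases (E-value threshold `e_max`; exact ties across
#' databases resolved predicted gene > transcript contig > genomic).  The
#' reverse query is the full subject sequence for predicted-gene and
#' transcript-contig hits, and the matched genomic interval extended by
#' `window_bp` on each side (clamped to the sequence) for genomic hits.
#' The pair is reciprocal iff the unique best reverse hit at `e_max` is
#' the original Unigene; a reverse tie between the original Unigene and
#' another sequence is rejected as ambiguous.
#'
#' @param unigenes Named `DNAStringSet` of Unigene representative
#'   sequences (the reverse-search database), or a `unigene_set`.
#' @param target A [target_genome()].
#' @param scoring An [align_scoring()] object.
#' @param e_max E-value threshold for both search directions.
#' @param window_bp Flanking window added to genomic hits before the
#'   reverse search.
#' @param progress Print a dot every 20 queries?
#' @return An object of class `rbh_result`: a data.frame with one row per
#'   Unigene (category, subject, E-values, reciprocity, and after
#'   [resolve_position()] a chromosome/bp position).
#' @export
rbh_search <- function(unigenes, target, scoring = align_scoring(),
                       e_max = 1e-20, window_bp = 2000L,
                       progress = FALSE) {
  if (inherits(unigenes, "unigene_set")) unigenes <- unigenes$representatives
  stopifnot(inherits(target, "target_genome"), length(unigenes) > 0)
  uni_chr <- as_named_chr(unigenes)
  kk <- scoring$kmer
  indexes <- list(
    predicted_gene = kmer_index(target$predicted_genes, kk),
    transcript_contig = if (length(target$transcript_contigs))
      kmer_index(target$transcript_contigs, kk) else NULL,
    genomic = if (length(target$genomic_seqs))
      kmer_index(target$genomic_seqs, kk) else NULL)
  uni_index <- kmer_index(uni_chr, kk)
  rows <- vector("list", length(uni_chr))
  for (i in seq_along(uni_chr)) {
    uid <- names(uni_chr)[i]
    if (progress && i %% 20L == 0L) cat(".")
    row <- empty_rbh_row(uid)
    fwd <- forward_best(uni_chr[[i]], target, scoring, e_max, indexes, uid)
    if (!is.null(fwd)) {
      row$category <- fwd$category
      row$subject_id <- fwd$subject_id
      row$evalue <- fwd$evalue
      row$bitscore <- fwd$bitscore
      row$identity_pct <- fwd$identity_pct
      row$strand <- fwd$strand
      row$s_start <- fwd$s_start
      row$s_end <- fwd$s_end
      rev_query <- reverse_query_(fwd, target, window_bp)
      rh <- best_hits(rev_query, uni_chr, scoring, e_max = e_max, k = 2L,
                      index = uni_index, query_id = fwd$subject_id)
      if (nrow(rh)) {
        row$reverse_subject <- rh$subject_id[1]
        row$reverse_evalue <- rh$evalue[1]
        tie <- nrow(rh) >= 2 && rh$evalue[1] == rh$evalue[2] &&
          rh$bitscore[1] == rh$bitscore[2]
        row$is_reciprocal <- identical(rh$subject_id[1], uid) && !tie
      }
    }
    rows[[i]] <- row
  }
  if (progress) cat("\n")
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  class(res) <- c("rbh_result", "data.frame")
  res
}

reverse_query_ <- function(fwd, target, window_bp) {
  if (fwd$category == "predicted_gene") {
    as.character(target$predicted_genes[[fwd$subject_id]])
  } else if (fwd$category == "transcript_contig") {
    as.character(target$transcript_contigs[[fwd$subject_id]])
  } else {
    s <- as.character(target$genomic_seqs[[fwd$subject_id]])
    a <- max(0L, fwd$s_start - window_bp)
    b <- min(nchar(s), fwd$s_end + window_bp)
    substr(s, a + 1L, b)
  }
}

#' Resolve pseudo-chromosome positions of reciprocal homologs
#'
#' Predicted-gene subjects take the midpoint of the gene's interval
#' (method `direct`).  Genomic subjects take the midpoint of the forward
#' hit interval when the subject is a pseudo-chromosome, else stay
#' unplaced (method `window`).  Transcript-contig subjects are aligned
#' against the predicted genes and relay the best gene's position when
#' its E-value passes `e_max` (method `tc_relay`), else stay unplaced.
#'
#' @param results An `rbh_result` from [rbh_search()].
#' @param target The [target_genome()] used for the search.
#' @param scoring An [align_scoring()] object.
#' @param e_max E-value threshold for the transcript-contig relay search.
#' @return The `rbh_result` with `chromosome`, `position_bp` and
#'   `position_method` filled for positionable reciprocal rows.
#' @export
resolve_position <- function(results, target, scoring = align_scoring(),
                             e_max = 1e-20) {
  pos <- target$gene_positions
  gene_index <- kmer_index(target$predicted_genes, scoring$kmer)
  for (i in which(results$is_reciprocal)) {
    cat <- results$category[i]
    if (cat == "predicted_gene") {
      j <- match(results$subject_id[i], pos$gene_id)
      if (is.na(j)) {
        warning("no position for predicted gene ", results$subject_id[i])
        next
      }
      results$chromosome[i] <- pos$chrom[j]
      results$position_bp[i] <- (pos$start[j] + pos$end[j]) / 2
      results$position_method[i] <- "direct"
    } else if (cat == "genomic") {
      if (results$subject_id[i] %in% target$pseudochromosomes) {
        results$chromosome[i] <- results$subject_id[i]
        results$position_bp[i] <- (results$s_start[i] + results$s_end[i]) / 2
        results$position_method[i] <- "window"
      }
    } else if (cat == "transcript_contig") {
      tc <- as.character(target$transcript_contigs[[results$subject_id[i]]])
      h <- best_hits(tc, target$predicted_genes, scoring, e_max = e_max,
                     k = 1L, index = gene_index,
                     query_id = results$subject_id[i])
      if (nrow(h)) {
        j <- match(h$subject_id[1], pos$gene_id)
        if (!is.na(j)) {
          results$chromosome[i] <- pos$chrom[j]
          results$position_bp[i] <- (pos$start[j] + pos$end[j]) / 2
          results$position_method[i] <- "tc_relay"
        }
      }
    }
  }
  results
}

#' Round half-up to integer (4.5 -> 5), as used for printed percentages
#' @noRd
round_half_up <- function(x) floor(x + 0.5)

#' Hit rate as an integer percentage
#'
#' `round_half_up(100 * hits / total)`.
#'
#' @param hits Number of (reciprocal) hits.
#' @param total Total number of query Unigenes.
#' @return Integer percent.
#' @export
hit_rate_pct <- function(hits, total) {
  stopifnot(total >= 1)
  round_half_up(100 * hits / total)
}

#' Estimated hit rate at full genome coverage
#'
#' The unrounded hit ratio divided by the covered genome fraction, then
#' rounded half-up to an integer percent: the estimate of the hit rate had
#' 100% of the target genome been available.
#'
#' @param hits Number of reciprocal hits.
#' @param total Total number of query Unigenes.
#' @param coverage_fraction Fraction of the genome represented.
#' @return Integer percent.
#' @export
estimated_hit_rate_pct <- function(hits, total, coverage_fraction) {
  stopifnot(total >= 1, coverage_fraction > 0, coverage_fraction <= 1)
  round_half_up(100 * hits / total / coverage_fraction)
}

#' Summarize a reciprocal-homology search
#'
#' @param results An `rbh_result`.
#' @param total_unigenes Total number of query Unigenes (defaults to the
#'   number of rows).
#' @param coverage_fraction Genome coverage used for the estimated rate
#'   (defaults to 1).
#' @return A list of class `rbh_summary` with total/per-category
#'   unidirectional and reciprocal counts, the integer hit-rate percent
#'   and the estimated hit-rate percent at full coverage.
#' @export
summarize_rbh <- function(results, total_unigenes = nrow(results),
                          coverage_fraction = 1) {
  stopifnot(total_unigenes >= 1)
  uni <- results$category != "none"
  rec <- results$is_reciprocal
  cats <- names(CATEGORY_ORDER)
  per_cat <- function(mask) {
    vapply(cats, function(cc) sum(mask & results$category == cc), 0L)
  }
  structure(list(
    total_unigenes = total_unigenes,
    unidirectional = sum(uni),
    reciprocal = sum(rec),
    unidirectional_by_category = per_cat(uni),
    reciprocal_by_category = per_cat(rec),
    unidirectional_pct = hit_rate_pct(sum(uni), total_unigenes),
    hit_rate_pct = hit_rate_pct(sum(rec), total_unigenes),
    estimated_hit_rate_pct = estimated_hit_rate_pct(sum(rec), total_unigenes,
                                                    coverage_fraction),
    coverage_fraction = coverage_fraction), class = "rbh_summary")
}

#' @export
print.rbh_summary <- function(x, ...) {
  cat("rbh_summary:", x$reciprocal, "reciprocal /", x$unidirectional,
      "unidirectional /", x$total_unigenes, "Unigenes\n")
  cat("  hit rate:", x$hit_rate_pct, "%  estimated at full coverage:",
      x$estimated_hit_rate_pct, "%\n")
  invisible(x)
}
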