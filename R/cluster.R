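# Unigene construction: single-linkage clustering over the pairwise
# overlap graph (edge = local alignment with >= 95% identity over >= 40
# aligned bp, by default), plus tiered functional annotation.

# candidate overlapping pairs via shared exact k-mers (either strand)
candidate_pairs <- function(seqs_chr, k, min_shared = 2L) {
  ids <- names(seqs_chr)
  idx <- kmer_index(seqs_chr, k)
  parts <- list()
  for (i in seq_along(ids)) {
    q <- seqs_chr[[i]]
    sf <- query_seeds(q, idx, k)
    sr <- query_seeds(revcomp_chr(q), idx, k)
    sid <- c(sf$subject_id, sr$subject_id)
    sid <- sid[sid != ids[i]]
    if (!length(sid)) next
    counts <- table(sid)
    hit <- names(counts)[counts >= min_shared]
    if (length(hit)) {
      parts[[length(parts) + 1L]] <-
        data.frame(a = ids[i], b = hit, stringsAsFactors = FALSE)
    }
  }
  if (!length(parts)) {
    return(data.frame(a = character(), b = character(),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, parts)
  lo <- pmin(df$a, df$b)
  hi <- pmax(df$a, df$b)
  unique(data.frame(a = lo, b = hi, stringsAsFactors = FALSE))
}

#' Cluster cleaned sequences into Unigenes
#'
#' Single-linkage clustering over the overlap graph: an edge joins two
#' sequences iff they share a local alignment (either strand) with
#' identity at least `min_overlap_identity` over at least
#' `min_overlap_len` aligned columns.  Each connected component is one
#' Unigene; the representative sequence is the longest member (ties broken
#' by lexicographically smallest id).  Every input sequence belongs to
#' exactly one Unigene, so depths sum to the number of inputs.
#'
#' @param seqs Named `DNAStringSet` of cleaned, length-filtered sequences.
#' @param ccfg A [cluster_config()].
#' @param scoring An [align_scoring()] object.
#' @param prefix Unigene id prefix (ids are `<prefix>0001`, ... assigned in
#'   order of first-seen member).
#' @return An object of class `unigene_set`: list with `members`
#'   (data.frame: unigene_id, member_id, depth, is_contig),
#'   `representatives` (named `DNAStringSet`, one per Unigene) and
#'   `annotation` (filled by [annotate_unigenes()]).
#' @export
cluster_unigenes <- function(seqs, ccfg = cluster_config(),
                             scoring = align_scoring(), prefix = "UG") {
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  x <- as_named_chr(seqs)
  ids <- names(x)
  pairs <- candidate_pairs(x, scoring$kmer)
  edges <- pairs[0, ]
  if (nrow(pairs)) {
    ok <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      hits <- local_align(x[[pairs$a[i]]], x[[pairs$b[i]]], scoring)
      ok[i] <- any(hits$identity_pct >= 100 * ccfg$min_overlap_identity &
                     hits$align_len >= ccfg$min_overlap_len)
    }
    edges <- pairs[ok, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = ids, stringsAsFactors = FALSE))
  comp <- igraph::components(g)$membership[ids]
  # stable unigene numbering: order of first appearance in the input
  first <- tapply(seq_along(ids), comp, min)
  rank <- rank(first)
  ug_num <- rank[as.character(comp)]
  width <- max(4L, nchar(as.character(max(ug_num))))
  ug_id <- sprintf(paste0(prefix, "%0", width, "d"), ug_num)
  depth <- as.integer(table(ug_id)[ug_id])
  members <- data.frame(unigene_id = ug_id, member_id = ids,
                        depth = depth, is_contig = depth >= 2L,
                        stringsAsFactors = FALSE)
  members <- members[order(members$unigene_id, members$member_id), ]
  rownames(members) <- NULL
  reps <- vapply(split(members$member_id, members$unigene_id),
                 function(mids) {
                   w <- nchar(x[mids])
                   mids[order(-w, mids)][1]
                 }, "")
  rep_seqs <- Biostrings::DNAStringSet(unname(x[reps]))
  names(rep_seqs) <- names(reps)
  structure(list(members = members, representatives = rep_seqs,
                 representative_member = reps, annotation = NULL),
            class = "unigene_set")
}

#' @export
print.unigene_set <- function(x, ...) {
  n_ug <- length(x$representatives)
  n_contig <- sum(tapply(x$members$depth, x$members$unigene_id, max) >= 2)
  cat("unigene_set:", n_ug, "Unigenes (", n_contig, "contigs,",
      n_ug - n_contig, "singletons ) from", nrow(x$members),
      "input sequences\n")
  invisible(x)
}

# six-frame translation of a nucleotide query (X at fuzzy codons)
six_frame <- function(q_chr) {
  d <- Biostrings::DNAString(q_chr)
  r <- Biostrings::reverseComplement(d)
  frames <- list()
  for (f in 0:2) {
    for (s in list(d, r)) {
      n <- length(s) - f
      n <- n - n %% 3
      if (n >= 3) {
        frames[[length(frames) + 1L]] <- as.character(
          Biostrings::translate(Biostrings::subseq(s, f + 1L, f + n),
                                if.fuzzy.codon = "X"))
      }
    }
  }
  frames
}

# best protein-level hit of a nucleotide query against a protein db
best_hit_translated <- function(q_chr, db, scoring = protein_scoring()) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  mat <- get("BLOSUM62", envir = environment())
  best <- NULL
  n_total <- sum(nchar(as.character(db)))
  for (fr in six_frame(q_chr)) {
    fr <- gsub("\\*", "X", fr)
    for (sid in names(db)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(fr), Biostrings::AAString(as.character(db[[sid]])),
        type = "local", substitutionMatrix = mat,
        gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
      sc <- Biostrings::score(aln)
      if (sc <= 0) next
      ni <- Biostrings::nindel(aln)
      alen <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln) +
        Biostrings::insertion(ni)[2] + Biostrings::deletion(ni)[2]
      hit <- data.frame(
        subject_id = sid, score = sc,
        evalue = evalue(sc, nchar(fr), n_total, scoring),
        identity_pct = 100 * Biostrings::nmatch(aln) / alen,
        stringsAsFactors = FALSE)
      if (is.null(best) || hit$evalue < best$evalue) best <- hit
    }
  }
  best
}

#' Annotate Unigenes against an ordered list of databases
#'
#' Databases are searched in priority order; the first database yielding a
#' hit with E-value at most `annot_e` and identity at least
#' `min_identity_pct` supplies the annotation.  The annotation tier is
#' `highly_similar` when E < 1e-50, `very_similar` when E < 1e-20, and
#' `similar` otherwise.  The identity floor applies to hit acceptance
#' only, not to tier assignment.
#'
#' @param unigenes A `unigene_set` from [cluster_unigenes()].
#' @param dbs Ordered list of databases; each element is a list with
#'   `name`, `seqs` (named `DNAStringSet`) and `mode` (`"nucleotide"` or
#'   `"translated"`; translated databases hold protein sequences searched
#'   with six-frame query translations).
#' @param annot_e Acceptance E-value threshold.
#' @param min_identity_pct Identity floor (percent) for acceptance.
#' @param tier_very,tier_highly Tier E-value boundaries.
#' @param scoring Nucleotide [align_scoring()].
#' @return The `unigene_set` with an `annotation` data.frame
#'   (unigene_id, db_name, subject_id, evalue, identity_pct, tier;
#'   unannotated Unigenes have NA fields).
#' @export
annotate_unigenes <- function(unigenes, dbs, annot_e = 1e-15,
                              min_identity_pct = 70,
                              tier_very = 1e-20, tier_highly = 1e-50,
                              scoring = align_scoring()) {
  stopifnot(inherits(unigenes, "unigene_set"))
  if (!length(dbs)) {
    warning("empty database list; Unigenes left unannotated")
  }
  indexes <- lapply(dbs, function(d) {
    if (identical(d$mode, "translated")) NULL else kmer_index(d$seqs, scoring$kmer)
  })
  rows <- list()
  for (uid in names(unigenes$representatives)) {
    q <- as.character(unigenes$representatives[[uid]])
    ann <- data.frame(unigene_id = uid, db_name = NA_character_,
                      subject_id = NA_character_, evalue = NA_real_,
                      identity_pct = NA_real_, tier = NA_character_,
                      stringsAsFactors = FALSE)
    for (j in seq_along(dbs)) {
      d <- dbs[[j]]
      if (identical(d$mode, "translated")) {
        h <- best_hit_translated(q, d$seqs)
        hit <- if (is.null(h)) NULL else h
      } else {
        hh <- best_hits(q, d$seqs, scoring, e_max = Inf, k = 1L,
                        index = indexes[[j]], query_id = uid)
        hit <- if (nrow(hh)) hh[1, ] else NULL
      }
      if (!is.null(hit) && hit$evalue <= annot_e &&
            hit$identity_pct >= min_identity_pct) {
        tier <- if (hit$evalue < tier_highly) "highly_similar"
                else if (hit$evalue < tier_very) "very_similar"
                else "similar"
        ann$db_name <- d$name
        ann$subject_id <- hit$subject_id
        ann$evalue <- hit$evalue
        ann$identity_pct <- hit$identity_pct
        ann$tier <- tier
        break
      }
    }
    rows[[uid]] <- ann
  }
  unigenes$annotation <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  unigenes
}
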