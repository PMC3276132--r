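# Local alignment: exact k-mer seeding + Smith-Waterman extension.
# Biostrings::pairwiseAlignment does the dynamic programming; seeding
# narrows the search to candidate subjects / subject windows so that
# chromosome-scale subjects stay tractable.

# substitution matrix over the ACGTN alphabet; N never matches anything
nuc_matrix <- function(scoring) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(scoring$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch
  m
}

# as.character that keeps names (base as.character drops them on
# character input)
as_named_chr <- function(x) {
  nm <- names(x)
  x <- as.character(x)
  names(x) <- nm
  x
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# all k-mers of a string as a character vector (positions 1-based)
kmers_of <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, 1:(n - k + 1L), k:n)
}

#' Build a k-mer seed index over a sequence database
#'
#' @param db Named `DNAStringSet` (or named character vector).
#' @param k Word size.
#' @return A keyed `data.table` of (kmer, subject_id, spos) used by
#'   [best_hits()] and [local_align()]; k-mers containing N are skipped.
#' @export
kmer_index <- function(db, k = 11L) {
  db <- as_named_chr(db)
  stopifnot(!is.null(names(db)))
  parts <- lapply(names(db), function(id) {
    km <- kmers_of(db[[id]], k)
    if (!length(km)) return(NULL)
    keep <- !grepl("N", km, fixed = TRUE)
    if (!any(keep)) return(NULL)
    data.table::data.table(kmer = km[keep], subject_id = id,
                           spos = which(keep))
  })
  idx <- data.table::rbindlist(parts)
  if (!nrow(idx)) {
    idx <- data.table::data.table(kmer = character(), subject_id = character(),
                                  spos = integer())
  }
  data.table::setkey(idx, kmer)
  structure(idx, k = as.integer(k))
}

# seeds of query against an index: data.table(subject_id, qpos, spos)
query_seeds <- function(query_chr, idx, k) {
  qk <- kmers_of(query_chr, k)
  if (!length(qk)) {
    return(data.table::data.table(subject_id = character(), qpos = integer(),
                                  spos = integer()))
  }
  keep <- !grepl("N", qk, fixed = TRUE)
  qdt <- data.table::data.table(kmer = qk[keep], qpos = which(keep))
  if (!nrow(qdt) || !nrow(idx)) {
    return(data.table::data.table(subject_id = character(), qpos = integer(),
                                  spos = integer()))
  }
  hits <- idx[qdt, on = "kmer", nomatch = NULL, allow.cartesian = TRUE]
  hits[, list(subject_id, qpos, spos)]
}

# one pairwiseAlignment call -> hit row (or NULL); coords on given strings
align_pair_ <- function(q_chr, s_chr, mat, scoring) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(q_chr), Biostrings::DNAString(s_chr),
    type = "local", substitutionMatrix = mat,
    gapOpening = scoring$gap_open, gapExtension = scoring$gap_extend)
  sc <- Biostrings::score(aln)
  if (sc <= 0) return(NULL)
  nm <- Biostrings::nmatch(aln)
  ni <- Biostrings::nindel(aln)
  # aligned columns = matches + mismatches + gap positions on both sides
  alen <- nm + Biostrings::nmismatch(aln) +
    Biostrings::insertion(ni)[2] + Biostrings::deletion(ni)[2]
  list(score = sc,
       identity_pct = 100 * nm / alen,
       align_len = alen,
       q_start = Biostrings::start(Biostrings::pattern(aln)) - 1L,
       q_end = Biostrings::end(Biostrings::pattern(aln)),
       s_start = Biostrings::start(Biostrings::subject(aln)) - 1L,
       s_end = Biostrings::end(Biostrings::subject(aln)))
}

# group seeds of one (query, subject, strand) into diagonal bands
seed_bands <- function(seeds, band_width = 32L, max_spos_gap = 5000L) {
  seeds$diag <- seeds$spos - seeds$qpos
  seeds <- seeds[order(seeds$diag, seeds$spos), ]
  newband <- c(TRUE, diff(seeds$diag) > band_width)
  band <- cumsum(newband)
  # split bands with large subject-position jumps (repeated words far apart)
  out <- list()
  for (b in split(seeds, band)) {
    b <- b[order(b$spos), ]
    sub <- cumsum(c(TRUE, diff(b$spos) > max_spos_gap))
    out <- c(out, split(b, sub))
  }
  out
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             score = numeric(), bitscore = numeric(), evalue = numeric(),
             identity_pct = numeric(), align_len = integer(),
             q_start = integer(), q_end = integer(),
             s_start = integer(), s_end = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

#' Karlin-Altschul E-value of a raw local-alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`: strictly decreasing in the score and
#' linear in each search-space dimension.
#'
#' @param score Raw alignment score(s).
#' @param m Effective query length.
#' @param n Effective database length.
#' @param scoring An [align_scoring()] object supplying `lambda` and `K`.
#' @return Numeric E-value(s).
#' @export
evalue <- function(score, m, n, scoring = align_scoring()) {
  stopifnot(m > 0, n > 0)
  scoring$K * m * n * exp(-scoring$lambda * score)
}

bitscore_ <- function(score, scoring) {
  (scoring$lambda * score - log(scoring$K)) / log(2)
}

# cheap ungapped extension of one word match along its diagonal; returns
# the best ungapped score through the seed (BLAST-style pre-filter)
ungapped_extend_ <- function(qq, s_chr, qpos, spos, k, scoring,
                             span = 300L) {
  ext <- function(qs, ss, rev) {
    if (!nchar(qs) || !nchar(ss)) return(0)
    a <- strsplit(qs, "")[[1]]
    b <- strsplit(ss, "")[[1]]
    if (rev) { a <- rev(a); b <- rev(b) }
    n <- min(length(a), length(b))
    if (!n) return(0)
    sc <- ifelse(a[1:n] == b[1:n], scoring$match, scoring$mismatch)
    max(0, cummax(cumsum(sc))[n])
  }
  left <- ext(substr(qq, max(1L, qpos - span), qpos - 1L),
              substr(s_chr, max(1L, spos - span), spos - 1L), rev = TRUE)
  right <- ext(substr(qq, qpos + k, qpos + k + span - 1L),
               substr(s_chr, spos + k, spos + k + span - 1L), rev = FALSE)
  k * scoring$match + left + right
}

# align (already strand-adjusted) query against each seeded window of the
# subject; seeds is a data.frame(qpos, spos) on the given strings.
# min_ungapped > 0 drops bands whose best seed fails a cheap ungapped
# extension (chance word matches never extend; homologous loci always do)
seeded_rows_ <- function(qq, s_chr, seeds, scoring, mat,
                         min_ungapped = 0) {
  qlen <- nchar(qq)
  slen <- nchar(s_chr)
  k <- scoring$kmer
  rows <- list()
  bands <- seed_bands(seeds)
  # isolated single-word bands are almost always chance matches; drop them
  # unless nothing better is seeded
  solid <- Filter(function(b) nrow(b) >= 2L, bands)
  if (length(solid)) bands <- solid
  # extend only the best-seeded bands (chance bands carry a word or two,
  # a real homologous locus carries tens to hundreds)
  if (length(bands) > 8L) {
    ord <- order(-vapply(bands, nrow, 0L),
                 vapply(bands, function(b) min(b$spos), 0L))
    bands <- bands[ord[1:8]]
  }
  if (min_ungapped > 0) {
    bands <- Filter(function(b) {
      mid <- b[(nrow(b) + 1L) %/% 2L, ]
      ungapped_extend_(qq, s_chr, mid$qpos, mid$spos, scoring$kmer,
                       scoring) >= min_ungapped
    }, bands)
  }
  # window per band from its seeded diagonals: where a full-length
  # alignment of the query through these seeds could reach, plus slack
  w0 <- vapply(bands, function(b) max(1L, min(b$spos - b$qpos) - 100L), 0L)
  w1 <- vapply(bands, function(b)
    min(slen, max(b$spos + (qlen - b$qpos)) + k + 100L), 0L)
  merged <- IRanges::reduce(IRanges::IRanges(w0, w1))
  for (i in seq_along(merged)) {
    a <- IRanges::start(merged)[i]
    z <- IRanges::end(merged)[i]
    h <- align_pair_(qq, substr(s_chr, a, z), mat, scoring)
    if (!is.null(h)) {
      h$s_start <- h$s_start + a - 1L
      h$s_end <- h$s_end + a - 1L
      rows <- c(rows, list(h))
    }
  }
  rows
}

# hits of query vs one subject on one strand ("+"/"-"), possibly seeded.
# Returned coordinates are 0-based half-open on the forward strands.
# `seeds`, when given, are precomputed (qpos, spos) word matches of the
# strand-adjusted query on the forward subject.
align_one_strand <- function(q_chr, s_chr, strand, scoring, mat,
                             direct_limit = 1e6, seeds = NULL,
                             min_ungapped = 0) {
  qlen <- nchar(q_chr)
  slen <- nchar(s_chr)
  qq <- if (strand == "-") revcomp_chr(q_chr) else q_chr
  rows <- list()
  if (!is.null(seeds)) {
    if (nrow(seeds)) {
      rows <- seeded_rows_(qq, s_chr, seeds, scoring, mat, min_ungapped)
    }
  } else if (as.double(qlen) * slen <= direct_limit) {
    h <- align_pair_(qq, s_chr, mat, scoring)
    if (!is.null(h)) rows <- list(h)
  } else {
    k <- scoring$kmer
    idx <- kmer_index(stats::setNames(s_chr, "s"), k)
    seeds <- as.data.frame(query_seeds(qq, idx, k))
    if (nrow(seeds)) {
      rows <- seeded_rows_(qq, s_chr, seeds, scoring, mat)
    }
  }
  if (!length(rows)) return(NULL)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  if (strand == "-") {
    qs <- qlen - df$q_end
    qe <- qlen - df$q_start
    df$q_start <- qs
    df$q_end <- qe
  }
  df$strand <- strand
  unique(df)
}

#' Local alignment of two nucleotide sequences
#'
#' Finds local alignments of `query` against `subject` on both subject
#' strands, best-first by score.  Small problems are solved by full
#' Smith-Waterman; large subjects are first seeded with exact k-mers and
#' each seeded diagonal band is then aligned exactly within a window, so a
#' subject can contain several reported hits.  Identity is computed over
#' aligned columns with gap columns counted as mismatches.
#'
#' @param query,subject Nucleotide sequences (character or `DNAString`).
#' @param scoring An [align_scoring()] object.
#' @param query_id,subject_id Ids used in the output table.
#' @param search_m,search_n Effective search-space sizes for the E-value
#'   (default: the two sequence lengths).
#' @param both_strands Search the minus strand too?
#' @return A data.frame of hits with raw score, bit score, E-value,
#'   identity percent, aligned length, and 0-based half-open coordinates on
#'   the forward strands (`strand` is the subject strand).
#' @export
local_align <- function(query, subject, scoring = align_scoring(),
                        query_id = "query", subject_id = "subject",
                        search_m = NULL, search_n = NULL,
                        both_strands = TRUE) {
  q_chr <- toupper(as.character(query))
  s_chr <- toupper(as.character(subject))
  if (nchar(q_chr) == 0 || nchar(s_chr) == 0) {
    stop("local_align needs non-empty sequences")
  }
  mat <- nuc_matrix(scoring)
  strands <- if (both_strands) c("+", "-") else "+"
  parts <- list()
  for (st in strands) {
    p <- align_one_strand(q_chr, s_chr, st, scoring, mat)
    if (!is.null(p)) parts[[st]] <- p
  }
  if (!length(parts)) return(empty_hits())
  df <- do.call(rbind, parts)
  m <- if (is.null(search_m)) nchar(q_chr) else search_m
  n <- if (is.null(search_n)) nchar(s_chr) else search_n
  df$bitscore <- bitscore_(df$score, scoring)
  df$evalue <- evalue(df$score, m, n, scoring)
  df$query_id <- query_id
  df$subject_id <- subject_id
  df <- df[order(-df$score, df$strand == "-", df$s_start), ]
  rownames(df) <- NULL
  df[, names(empty_hits())]
}

#' Best database hits of a query sequence
#'
#' BLAST-like ranked search of one query against a sequence database:
#' candidate subjects are located by shared exact k-mers, each candidate is
#' aligned with [local_align()], and hits are filtered at `e_max` and
#' ranked by (E-value, bit score descending, subject id).
#'
#' @param query Query sequence (character or `DNAString`).
#' @param db Named `DNAStringSet` / named character vector.
#' @param scoring An [align_scoring()] object.
#' @param e_max E-value threshold (hits above it are dropped).
#' @param k Maximum number of hits returned (`Inf` for all).
#' @param index Optional prebuilt [kmer_index()] of `db` (reused across
#'   queries).
#' @param min_seed_hits Minimum shared k-mers for a subject to be aligned;
#'   short queries (< 3 words) fall back to aligning every subject.
#' @param max_candidates Maximum number of seeded subjects extended per
#'   query (the best-seeded ones are kept).
#' @param query_id Id used in the output table.
#' @return A data.frame of hits (same columns as [local_align()]), at most
#'   one row block per subject, best-first.
#' @export
best_hits <- function(query, db, scoring = align_scoring(), e_max = 1e-20,
                      k = Inf, index = NULL, min_seed_hits = 2L,
                      max_candidates = 8L, query_id = "query") {
  db_chr <- as_named_chr(db)
  if (!length(db_chr)) return(empty_hits())
  stopifnot(!is.null(names(db_chr)))
  q_chr <- toupper(as.character(query))
  n_total <- sum(nchar(db_chr))
  kk <- scoring$kmer
  seeds_f <- seeds_r <- NULL
  if (nchar(q_chr) < 3L * kk) {
    cand <- names(db_chr)
  } else {
    if (is.null(index)) index <- kmer_index(db_chr, kk)
    seeds_f <- as.data.frame(query_seeds(q_chr, index, kk))
    seeds_r <- as.data.frame(query_seeds(revcomp_chr(q_chr), index, kk))
    counts <- table(c(seeds_f$subject_id, seeds_r$subject_id))
    cand <- sort(names(counts)[counts >= min_seed_hits])
    # extend only the best-seeded subjects; true homologs share far more
    # words than chance matches, so a generous cap loses nothing
    if (length(cand) > max_candidates) {
      cand <- cand[order(-counts[cand], cand)][seq_len(max_candidates)]
    }
  }
  if (!length(cand)) return(empty_hits())
  mat <- nuc_matrix(scoring)
  parts <- list()
  for (sid in cand) {
    sub_seeds <- list(
      "+" = if (!is.null(seeds_f))
        seeds_f[seeds_f$subject_id == sid, c("qpos", "spos")],
      "-" = if (!is.null(seeds_r))
        seeds_r[seeds_r$subject_id == sid, c("qpos", "spos")])
    sp <- list()
    for (st in c("+", "-")) {
      ss <- sub_seeds[[st]]
      if (!is.null(ss) && !nrow(ss)) next  # nothing seeded here
      p <- align_one_strand(q_chr, db_chr[[sid]], st, scoring, mat,
                            seeds = ss,
                            min_ungapped = 2L * scoring$kmer)
      if (!is.null(p)) sp[[st]] <- p
    }
    if (!length(sp)) next
    dd <- do.call(rbind, sp)
    dd$bitscore <- bitscore_(dd$score, scoring)
    dd$evalue <- evalue(dd$score, nchar(q_chr), n_total, scoring)
    dd$query_id <- query_id
    dd$subject_id <- sid
    parts[[sid]] <- dd[, names(empty_hits())]
  }
  if (!length(parts)) return(empty_hits())
  df <- do.call(rbind, parts)
  df <- df[df$evalue <= e_max, , drop = FALSE]
  if (!nrow(df)) return(empty_hits())
  df <- df[order(df$evalue, -df$bitscore, df$subject_id, df$s_start), ]
  rownames(df) <- NULL
  utils::head(df, if (is.finite(k)) k else nrow(df))
}
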