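# Sequence cleaning: poly-tail / low-complexity trimming, repeat masking
# against a library, vector screening, and the minimum-length filter.
# Operators act on named DNAStringSets and are individually idempotent.

strip_run_3p <- function(x, base, min_run) {
  n <- attr(regexpr(paste0(base, "+$"), x), "match.length")
  if (n >= min_run) substr(x, 1L, nchar(x) - n) else x
}

strip_run_5p <- function(x, base, min_run) {
  n <- attr(regexpr(paste0("^", base, "+"), x), "match.length")
  if (n >= min_run) substring(x, n + 1L) else x
}

#' Trim terminal poly-A / poly-T runs
#'
#' Removes a 3' homopolymer run of A (a poly-A tail) or a 5' run of T (a
#' reverse-complemented tail) when the run is at least `polyA_min_run` bp.
#' Interior runs are never touched and the operation is idempotent.  Runs
#' are strict homopolymers: a single interrupting base ends the run.
#'
#' @param seqs Named `DNAStringSet` (or character vector).
#' @param cfg A [cleaning_config()].
#' @return A `DNAStringSet` with the same names.
#' @export
trim_poly_tails <- function(seqs, cfg = cleaning_config()) {
  x <- as_named_chr(seqs)
  run <- cfg$polyA_min_run
  x <- vapply(x, strip_run_3p, "", base = "A", min_run = run)
  x <- vapply(x, strip_run_5p, "", base = "T", min_run = run)
  out <- Biostrings::DNAStringSet(unname(x))
  names(out) <- names(seqs)
  out
}

shannon_entropy <- function(x) {
  tab <- table(strsplit(x, "")[[1]])
  p <- tab / sum(tab)
  -sum(p * log2(p))
}

# trim terminal windows whose Shannon entropy is below threshold
trim_low_complexity_one <- function(x, window, threshold) {
  repeat {
    n <- nchar(x)
    if (n < window) return(x)
    if (shannon_entropy(substr(x, n - window + 1L, n)) < threshold) {
      x <- substr(x, 1L, n - window)
    } else break
  }
  repeat {
    n <- nchar(x)
    if (n < window) return(x)
    if (shannon_entropy(substr(x, 1L, window)) < threshold) {
      x <- substring(x, window + 1L)
    } else break
  }
  x
}

trim_low_complexity <- function(seqs, cfg = cleaning_config()) {
  x <- vapply(as_named_chr(seqs), trim_low_complexity_one, "",
              window = cfg$entropy_window, threshold = cfg$entropy_threshold)
  out <- Biostrings::DNAStringSet(unname(x))
  names(out) <- names(seqs)
  out
}

# library hits in seq passing identity/length thresholds, iterating so that
# multiple copies of a repeat are all found (found spans are masked before
# re-searching).
library_hits <- function(seq_chr, lib, scoring, min_identity, min_len,
                         max_rounds = 5L) {
  spans <- list()
  cur <- seq_chr
  for (round in seq_len(max_rounds)) {
    found <- FALSE
    for (rid in names(lib)) {
      hits <- local_align(lib[[rid]], cur, scoring, query_id = rid)
      hits <- hits[hits$identity_pct >= 100 * min_identity &
                     hits$align_len >= min_len, , drop = FALSE]
      if (nrow(hits)) {
        found <- TRUE
        for (i in seq_len(nrow(hits))) {
          spans <- c(spans, list(c(hits$s_start[i], hits$s_end[i])))
          substr(cur, hits$s_start[i] + 1L, hits$s_end[i]) <-
            strrep("N", hits$s_end[i] - hits$s_start[i])
        }
      }
    }
    if (!found) break
  }
  spans
}

#' Mask repeat-library matches with N
#'
#' Every local alignment of a sequence against any repeat in the library
#' with identity at least `repeat_mask_min_identity` and aligned length at
#' least `min_hit_len` has its interval replaced by N.  Sequence lengths
#' are unchanged; masked spans are recorded in the cleaning report.
#'
#' @param seqs Named `DNAStringSet`.
#' @param repeat_lib Named `DNAStringSet` of repeat elements (an empty
#'   library is the identity operation).
#' @param cfg A [cleaning_config()].
#' @param scoring An [align_scoring()] object.
#' @return A list with `seqs` (masked `DNAStringSet`) and `report`
#'   (data.frame: seq_id, action, span_start, span_end, reason; 0-based
#'   half-open spans).
#' @export
mask_repeats <- function(seqs, repeat_lib, cfg = cleaning_config(),
                         scoring = align_scoring()) {
  x <- as_named_chr(seqs)
  report <- list()
  if (length(repeat_lib)) {
    lib <- as_named_chr(repeat_lib)
    for (id in names(x)) {
      spans <- library_hits(x[[id]], lib, scoring,
                            cfg$repeat_mask_min_identity, cfg$min_hit_len)
      for (sp in spans) {
        substr(x[[id]], sp[1] + 1L, sp[2]) <- strrep("N", sp[2] - sp[1])
        report <- c(report, list(data.frame(
          seq_id = id, action = "mask", span_start = sp[1], span_end = sp[2],
          reason = "repeat_library", stringsAsFactors = FALSE)))
      }
    }
  }
  out <- Biostrings::DNAStringSet(unname(x))
  names(out) <- names(seqs)
  list(seqs = out, report = clean_report_(report))
}

#' Trim terminal vector contamination
#'
#' Vector-library matches whose interval lies within
#' `vector_terminal_margin` bp of a sequence end are trimmed off together
#' with everything outward of them; internal vector hits are only flagged
#' in the report (with a warning), not cut.
#'
#' @inheritParams mask_repeats
#' @param vector_lib Named `DNAStringSet` of vector sequences.
#' @return A list with `seqs` and `report` as in [mask_repeats()].
#' @export
screen_vector <- function(seqs, vector_lib, cfg = cleaning_config(),
                          scoring = align_scoring()) {
  x <- as_named_chr(seqs)
  report <- list()
  if (length(vector_lib)) {
    lib <- as_named_chr(vector_lib)
    for (id in names(x)) {
      spans <- library_hits(x[[id]], lib, scoring,
                            cfg$vector_trim_min_identity, cfg$min_hit_len)
      if (!length(spans)) next
      n <- nchar(x[[id]])
      lead <- 0L   # trim everything before this point
      trail <- n   # trim everything from this point on
      for (sp in spans) {
        if (sp[1] <= cfg$vector_terminal_margin) {
          lead <- max(lead, sp[2])
          report <- c(report, list(data.frame(
            seq_id = id, action = "trim", span_start = sp[1],
            span_end = sp[2], reason = "vector_5prime",
            stringsAsFactors = FALSE)))
        } else if (n - sp[2] <= cfg$vector_terminal_margin) {
          trail <- min(trail, sp[1])
          report <- c(report, list(data.frame(
            seq_id = id, action = "trim", span_start = sp[1],
            span_end = sp[2], reason = "vector_3prime",
            stringsAsFactors = FALSE)))
        } else {
          warning("internal vector hit in ", id, " at [", sp[1], ",",
                  sp[2], "); flagged but not trimmed")
          report <- c(report, list(data.frame(
            seq_id = id, action = "flag", span_start = sp[1],
            span_end = sp[2], reason = "vector_internal",
            stringsAsFactors = FALSE)))
        }
      }
      if (lead > 0L || trail < n) {
        x[[id]] <- if (lead < trail) substr(x[[id]], lead + 1L, trail) else ""
      }
    }
  }
  out <- Biostrings::DNAStringSet(unname(x))
  names(out) <- names(seqs)
  list(seqs = out, report = clean_report_(report))
}

#' Remove sequences under the minimum length
#'
#' Keeps exactly the sequences whose length is at least `min_length`
#' (a sequence of exactly `min_length` bp is retained), preserving input
#' order.
#'
#' @inheritParams mask_repeats
#' @return A `DNAStringSet`.
#' @export
filter_length <- function(seqs, cfg = cleaning_config()) {
  seqs[Biostrings::width(seqs) >= cfg$min_length]
}

clean_report_ <- function(parts) {
  if (!length(parts)) {
    return(data.frame(seq_id = character(), action = character(),
                      span_start = integer(), span_end = integer(),
                      reason = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, parts)
}

#' Run the full cleaning pipeline
#'
#' Vector screening, repeat masking, poly-tail and low-complexity trimming,
#' then the minimum-length filter.  The pipeline is idempotent: cleaning an
#' already-clean set is the identity.
#'
#' @param seqs Named `DNAStringSet` of raw transcript/EST sequences.
#' @param repeat_lib,vector_lib Optional named `DNAStringSet` libraries.
#' @param cfg A [cleaning_config()].
#' @param scoring An [align_scoring()] object.
#' @return A list with `seqs` (cleaned, length-filtered `DNAStringSet`)
#'   and `report` (cleaning actions; removed sequences appear with action
#'   `"remove"`).
#' @export
clean_sequences <- function(seqs, repeat_lib = NULL, vector_lib = NULL,
                            cfg = cleaning_config(),
                            scoring = align_scoring()) {
  reports <- list()
  if (!is.null(vector_lib) && length(vector_lib)) {
    v <- screen_vector(seqs, vector_lib, cfg, scoring)
    seqs <- v$seqs
    reports <- c(reports, list(v$report))
  }
  if (!is.null(repeat_lib) && length(repeat_lib)) {
    r <- mask_repeats(seqs, repeat_lib, cfg, scoring)
    seqs <- r$seqs
    reports <- c(reports, list(r$report))
  }
  seqs <- trim_poly_tails(seqs, cfg)
  seqs <- trim_low_complexity(seqs, cfg)
  kept <- filter_length(seqs, cfg)
  dropped <- setdiff(names(seqs), names(kept))
  if (length(dropped)) {
    reports <- c(reports, list(data.frame(
      seq_id = dropped, action = "remove", span_start = 0L,
      span_end = Biostrings::width(seqs)[match(dropped, names(seqs))],
      reason = "min_length", stringsAsFactors = FALSE)))
  }
  list(seqs = kept,
       report = clean_report_(reports))
}
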