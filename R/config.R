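#' Sequence-cleaning parameters
#'
#' Bundles the thresholds used by the cleaning operators
#' ([trim_poly_tails()], [mask_repeats()], [screen_vector()],
#' [filter_length()]).
#'
#' @param min_length Minimum sequence length kept after cleaning (bp).
#'   Sequences under this length are removed; a sequence of exactly
#'   `min_length` bp is retained.
#' @param polyA_min_run Minimum terminal homopolymer run (bp) that is
#'   treated as a poly-A tail (3' A run) or poly-T head (5' T run).
#' @param entropy_window Window (bp) used when trimming low-complexity
#'   sequence ends.
#' @param entropy_threshold Shannon entropy (bits) below which a terminal
#'   window counts as low complexity.
#' @param repeat_mask_min_identity Minimum alignment identity (fraction)
#'   for a repeat-library hit to be masked.
#' @param vector_trim_min_identity Minimum alignment identity (fraction)
#'   for a vector-library hit to be trimmed.
#' @param vector_terminal_margin Distance from a sequence end (bp) within
#'   which a vector hit is considered terminal and trimmed; internal vector
#'   hits are only flagged.
#' @param min_hit_len Minimum aligned length (bp) for repeat/vector hits.
#' @return A list of class `cleaning_config`.
#' @export
cleaning_config <- function(min_length = 100L,
                            polyA_min_run = 12L,
                            entropy_window = 20L,
                            entropy_threshold = 0.5,
                            repeat_mask_min_identity = 0.8,
                            vector_trim_min_identity = 0.9,
                            vector_terminal_margin = 50L,
                            min_hit_len = 20L) {
  stopifnot(min_length >= 1, polyA_min_run >= 1,
            repeat_mask_min_identity > 0, repeat_mask_min_identity <= 1,
            vector_trim_min_identity > 0, vector_trim_min_identity <= 1,
            entropy_window >= 1, entropy_threshold >= 0,
            vector_terminal_margin >= 0, min_hit_len >= 1)
  structure(list(min_length = as.integer(min_length),
                 polyA_min_run = as.integer(polyA_min_run),
                 entropy_window = as.integer(entropy_window),
                 entropy_threshold = entropy_threshold,
                 repeat_mask_min_identity = repeat_mask_min_identity,
                 vector_trim_min_identity = vector_trim_min_identity,
                 vector_terminal_margin = as.integer(vector_terminal_margin),
                 min_hit_len = as.integer(min_hit_len)),
            class = "cleaning_config")
}

#' Unigene clustering parameters
#'
#' @param min_overlap_identity Minimum identity (fraction) over the aligned
#'   overlap for two sequences to be joined into the same cluster.
#' @param min_overlap_len Minimum aligned overlap length (bp).
#' @return A list of class `cluster_config`.
#' @export
cluster_config <- function(min_overlap_identity = 0.95,
                           min_overlap_len = 40L) {
  stopifnot(min_overlap_identity > 0, min_overlap_identity <= 1,
            min_overlap_len >= 1)
  structure(list(min_overlap_identity = min_overlap_identity,
                 min_overlap_len = as.integer(min_overlap_len)),
            class = "cluster_config")
}

#' Local-alignment scoring scheme
#'
#' Nucleotide scoring used by the built-in local aligner together with the
#' Karlin-Altschul parameters that convert a raw score into an E-value
#' (`E = K * m * n * exp(-lambda * S)`).  Defaults approximate a BLASTN-like
#' nucleotide search so that E-value thresholds such as 1e-20 are
#' operationally meaningful.
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening penalty (non-negative cost; a gap of length L
#'   costs `gap_open + L * gap_extend`).
#' @param gap_extend Gap extension penalty per gap position (non-negative).
#' @param lambda,K Karlin-Altschul parameters.
#' @param kmer Seed word size for the seed-and-extend search.
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 1, mismatch = -2,
                          gap_open = 5, gap_extend = 2,
                          lambda = 1.28, K = 0.46,
                          kmer = 11L) {
  stopifnot(match > 0, mismatch < 0, gap_open >= 0, gap_extend >= 0,
            lambda > 0, K > 0, kmer >= 4)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K, kmer = as.integer(kmer)),
            class = "align_scoring")
}

#' Protein scoring used for translated (tblastn-like) annotation searches.
#' @noRd
protein_scoring <- function() {
  structure(list(match = NA, mismatch = NA, gap_open = 11, gap_extend = 1,
                 lambda = 0.267, K = 0.041, kmer = 4L,
                 matrix = "BLOSUM62"),
            class = "align_scoring")
}

#' Synteny-block detection parameters
#'
#' @param min_pairs Minimum number of homolog pairs in a block.
#' @param max_intruders Maximum number of consecutive points from other
#'   linkage groups tolerated inside a block without breaking it.
#' @param max_gap_bp Optional maximum physical gap (bp) between consecutive
#'   block members; `Inf` disables the check.
#' @param max_gap_cM Optional maximum genetic gap (cM) between consecutive
#'   block members; `Inf` disables the check.
#' @return A list of class `block_config`.
#' @export
block_config <- function(min_pairs = 3L, max_intruders = 2L,
                         max_gap_bp = Inf, max_gap_cM = Inf) {
  stopifnot(min_pairs >= 2, max_intruders >= 0,
            max_gap_bp > 0, max_gap_cM > 0)
  structure(list(min_pairs = as.integer(min_pairs),
                 max_intruders = as.integer(max_intruders),
                 max_gap_bp = max_gap_bp, max_gap_cM = max_gap_cM),
            class = "block_config")
}

#' Toolkit-wide configuration
#'
#' Collects every threshold used across the toolkit with its default value:
#' reciprocal-search E-value cutoff 1e-20, annotation cutoff 1e-15 with a
#' 70% identity floor and tier boundaries at 1e-20 / 1e-50, clustering
#' identity 95%, minimum sequence length 100 bp, genomic flanking window
#' 2000 bp, minimum synteny-block size 3 pairs, 5 hits returned by the
#' forward position query and a +/- 5 cM default window for the reverse
#' candidate query.
#'
#' @param e_max E-value threshold for homology searches (both directions).
#' @param annot_e E-value threshold for Unigene annotation.
#' @param tier_very,tier_highly E-value boundaries for the "very similar"
#'   and "highly similar" annotation tiers.
#' @param annot_min_identity Minimum identity percent for annotation hits.
#' @param window_bp Flanking window (bp) added on each side of a genomic
#'   hit before the reverse search.
#' @param top_k Number of hits reported by the forward position query.
#' @param window_cM Half-width (cM) of the reverse candidate-gene query.
#' @param cleaning,clustering,blocks,scoring Component configurations.
#' @return A list of class `toolkit_config`.
#' @export
toolkit_config <- function(e_max = 1e-20,
                           annot_e = 1e-15,
                           tier_very = 1e-20,
                           tier_highly = 1e-50,
                           annot_min_identity = 70,
                           window_bp = 2000L,
                           top_k = 5L,
                           window_cM = 5,
                           cleaning = cleaning_config(),
                           clustering = cluster_config(),
                           blocks = block_config(),
                           scoring = align_scoring()) {
  stopifnot(e_max > 0, annot_e > 0, tier_very > 0, tier_highly > 0,
            annot_min_identity >= 0, annot_min_identity <= 100,
            window_bp >= 0, top_k >= 1, window_cM > 0)
  structure(list(e_max = e_max, annot_e = annot_e,
                 tier_very = tier_very, tier_highly = tier_highly,
                 annot_min_identity = annot_min_identity,
                 window_bp = as.integer(window_bp),
                 top_k = as.integer(top_k), window_cM = window_cM,
                 cleaning = cleaning, clustering = clustering,
                 blocks = blocks, scoring = scoring),
            class = "toolkit_config")
}
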