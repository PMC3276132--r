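# Independent Smith-Waterman oracle: plain quadratic dynamic programming
# with affine gaps (gap of length L costs open + L * extend), written
# without any alignment library so it can stand as the reference for the
# package's seeded aligner.  Identity counts gap columns as mismatches.

sw_oracle <- function(q, s, match = 1, mismatch = -2,
                      gap_open = 5, gap_extend = 2) {
  a <- strsplit(toupper(q), "")[[1]]
  b <- strsplit(toupper(s), "")[[1]]
  n <- length(a)
  m <- length(b)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)  # gap in query (move along subject)
  F <- matrix(-Inf, n + 1, m + 1)  # gap in subject (move along query)
  go <- gap_open + gap_extend
  best <- 0
  bi <- bj <- 0L
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - gap_extend)
      F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - gap_extend)
      sub <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) {
        best <- H[i, j]
        bi <- i
        bj <- j
      }
    }
  }
  if (best <= 0) {
    return(list(score = 0, identity_pct = NA_real_, align_len = 0L,
                q_start = NA, q_end = NA, s_start = NA, s_end = NA))
  }
  # traceback for identity / span
  i <- bi; j <- bj
  cols <- 0L
  matches <- 0L
  state <- "H"
  while (i > 1 || j > 1) {
    if (state == "H") {
      if (H[i, j] == 0) break
      sub <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
      if (i > 1 && j > 1 && H[i, j] == H[i - 1, j - 1] + sub) {
        cols <- cols + 1L
        if (a[i - 1] == b[j - 1] && a[i - 1] != "N") matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (H[i, j] == E[i, j]) {
        state <- "E"
      } else {
        state <- "F"
      }
    } else if (state == "E") {
      cols <- cols + 1L
      if (E[i, j] == H[i, j - 1] - go) state <- "H"
      j <- j - 1L
    } else {
      cols <- cols + 1L
      if (F[i, j] == H[i - 1, j] - go) state <- "H"
      i <- i - 1L
    }
  }
  list(score = best, identity_pct = 100 * matches / cols, align_len = cols,
       q_start = i - 1L, q_end = bi - 1L, s_start = j - 1L, s_end = bj - 1L)
}

# brute-force single-linkage components from a symmetric edge predicate
brute_components <- function(ids, edge_fun) {
  parent <- stats::setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      if (edge_fun(ids[i], ids[j])) {
        parent[[find(ids[i])]] <- find(ids[j])
      }
    }
  }
  vapply(ids, find, "")
}
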