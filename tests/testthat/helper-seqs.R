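# small deterministic sequence factories used across tests

rand_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute every step-th base (deterministic divergence)
mutate_every <- function(s, step) {
  ch <- strsplit(s, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  idx <- seq(step, length(ch), by = step)
  ch[idx] <- rot[ch[idx]]
  paste(ch, collapse = "")
}

# random per-site substitutions at a given rate
mutate_rate <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  hit <- which(stats::runif(length(ch)) < rate)
  ch[hit] <- rot[ch[hit]]
  paste(ch, collapse = "")
}

dna <- function(x) Biostrings::DNAStringSet(x)
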