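# Independent reference implementations used only to cross-check the
# package's alignment kernels. Deliberately naive: quadratic DP in plain R
# and brute-force enumeration over substrings via utils::adist.

# affine-gap local alignment score; gap of length L costs go + (L - 1) * ge
oracle_sw_score <- function(subject, pattern, match = 2, mismatch = 3,
                            go = 4, ge = 2) {
  s <- strsplit(subject, "")[[1]]
  p <- strsplit(pattern, "")[[1]]
  n <- length(s)
  m <- length(p)
  NEG <- -1e9
  H <- matrix(0, m + 1, n + 1)
  E <- matrix(NEG, m + 1, n + 1)
  F <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in seq_len(m) + 1) {
    for (j in seq_len(n) + 1) {
      E[i, j] <- max(H[i, j - 1] - go, E[i, j - 1] - ge)
      F[i, j] <- max(H[i - 1, j] - go, F[i - 1, j] - ge)
      sc <- if (p[i - 1] == s[j - 1]) match else -mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + sc, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# best edit distance of pattern against any substring of read, by exhaustive
# enumeration of substrings (lengths 0 .. 2 * pattern length)
oracle_infix_edit <- function(read, pattern) {
  n <- nchar(read)
  m <- nchar(pattern)
  subs <- "" # empty substring: distance m
  for (i in seq_len(n)) {
    ends <- i:min(n, i + 2 * m - 1)
    subs <- c(subs, substring(read, i, ends))
  }
  min(adist(pattern, unique(subs)))
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# mutate a sequence with k random substitutions
mutate_subs <- function(seq, k) {
  b <- strsplit(seq, "")[[1]]
  pos <- sample(length(b), k)
  for (p in pos) b[p] <- sample(setdiff(c("A", "C", "G", "T"), b[p]), 1)
  paste(b, collapse = "")
}
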