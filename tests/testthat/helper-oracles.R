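# Independent oracles: a standalone motif-notation parser and positional
# scanner (no regex, shared with nothing in the package), and an exhaustive
# hypergeometric tail by enumeration of all draws. Used to cross-check the
# package's regex-based scanner and stats::phyper-based tail.

AA20_ORACLE <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# parse notation into a list of allowed-residue character vectors
oracle_parse <- function(notation) {
  toks <- regmatches(notation,
                     gregexpr("\\[\\^?[A-Z]+\\]|.", notation))[[1]]
  lapply(toks, function(t) {
    if (t == "x") c(AA20_ORACLE, "X")
    else if (startsWith(t, "[^")) {
      setdiff(AA20_ORACLE, strsplit(substr(t, 3, nchar(t) - 1), "")[[1]])
    } else if (startsWith(t, "[")) {
      strsplit(substr(t, 2, nchar(t) - 1), "")[[1]]
    } else t
  })
}

# all match start positions of the notation in seq (reverse = reversed token
# order), by direct per-position membership tests
oracle_scan <- function(seq, notation, reverse = FALSE) {
  allowed <- oracle_parse(notation)
  if (reverse) allowed <- rev(allowed)
  s <- strsplit(seq, "")[[1]]
  L <- length(s)
  m <- length(allowed)
  if (L < m) return(integer())
  n_start <- L - m + 1L
  res <- rep(TRUE, n_start)
  for (p in seq_len(m)) {
    ok <- s %in% allowed[[p]]
    res <- res & ok[p:(p + n_start - 1L)]
  }
  which(res)
}

# P(X >= k) by enumerating every size-n draw from an urn of N with K successes
oracle_hyper_tail <- function(k, n, K, N) {
  urn <- c(rep(1L, K), rep(0L, N - K))
  if (n == 0) return(if (k <= 0) 1 else 0)
  draws <- utils::combn(N, n)
  counts <- colSums(matrix(urn[draws], nrow = n))
  mean(counts >= k)
}

random_protein <- function(len, seed = NULL) {
  paste(sample(AA20_ORACLE, len, replace = TRUE), collapse = "")
}

tier_rank <- c("uninformative" = 0, "splicing-candidate" = 1,
               "RIP-possible" = 2, "RIP-candidate" = 3)
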