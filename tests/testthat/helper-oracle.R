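# Independent oracles used across the suite.

# Gotoh local alignment with affine gaps (gap of length L costs
# open + extend * L), coded independently of the package's alignment path.
# Returns the best score plus match/column/gap accounting from a traceback.
sw_affine <- function(a, b, match = 2, mismatch = -3, open = 5, extend = 2) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (av[i] == bv[j]) match else mismatch
      M[i + 1, j + 1] <- max(0, M[i, j] + s, X[i, j] + s, Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  best <- which(M == max(M), arr.ind = TRUE)[1, ]
  score <- max(M)
  # traceback from the best M cell
  i <- best[1] - 1L
  j <- best[2] - 1L
  state <- "M"
  matches <- 0L
  columns <- 0L
  gaps_in_b <- 0L
  while (i > 0 && j > 0) {
    if (state == "M") {
      if (M[i + 1, j + 1] == 0) break
      s <- if (av[i] == bv[j]) match else mismatch
      columns <- columns + 1L
      if (av[i] == bv[j]) matches <- matches + 1L
      prev <- M[i + 1, j + 1] - s
      state <- if (abs(prev - M[i, j]) < 1e-9) "M"
        else if (abs(prev - X[i, j]) < 1e-9) "X" else "Y"
      i <- i - 1L
      j <- j - 1L
    } else if (state == "X") {
      columns <- columns + 1L
      gaps_in_b <- gaps_in_b + 1L
      state <- if (abs(X[i + 1, j + 1] - (M[i, j + 1] - open - extend)) < 1e-9)
        "M" else "X"
      i <- i - 1L
    } else {
      columns <- columns + 1L
      state <- if (abs(Y[i + 1, j + 1] - (M[i + 1, j] - open - extend)) < 1e-9)
        "M" else "Y"
      j <- j - 1L
    }
  }
  list(score = score, matches = matches, columns = columns,
       gaps_in_b = gaps_in_b)
}

# brute-force MHI evaluation, any log base
mhi_oracle <- function(counts, r_per_env, total, base = exp(1)) {
  counts <- counts[counts > 0]
  w <- log(total / r_per_env[names(counts)]) / log(base)
  raw <- counts * w
  100 * raw / sum(raw)
}

# random ACGT sequence
rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute exactly k positions with a different base
mutate_seq <- function(x, k) {
  v <- strsplit(x, "")[[1]]
  pos <- sample(length(v), k)
  for (p in pos) {
    v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  }
  paste(v, collapse = "")
}

# a small labelled store built directly from given sequences
store_from_seqs <- function(seqs_by_env) {
  rows <- lapply(names(seqs_by_env), function(e) {
    data.frame(env = e, ordinal = seq_along(seqs_by_env[[e]]),
               residues = seqs_by_env[[e]], stringsAsFactors = FALSE)
  })
  reference_store(do.call(rbind, rows))
}
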