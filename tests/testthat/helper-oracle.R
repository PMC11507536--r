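# Brute-force oracles, independent of the package's counting path.

# O-information evaluated term by term from the fully materialized
# empirical joint probability array (base::table over factors with
# explicit levels, margins via apply).
oracleOinfo <- function(labels, card) {
  N <- nrow(labels)
  n <- ncol(labels)
  f <- lapply(seq_len(n), function(j) {
    factor(labels[, j], levels = 0:(card[j] - 1))
  })
  joint <- do.call(table, f) / N
  h <- function(p) {
    p <- as.vector(p)
    p <- p[p > 0]
    -sum(p * log2(p))
  }
  acc <- (n - 2) * h(joint)
  for (j in seq_len(n)) {
    acc <- acc + h(apply(joint, j, sum)) -
      h(apply(joint, setdiff(seq_len(n), j), sum))
  }
  acc
}

# Plug-in entropy from an explicitly materialized probability vector.
oracleEntropy <- function(counts) {
  p <- counts / sum(counts)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Exhaustive canonical label matrices at common cardinality K.
copyMatrix <- function(K) {
  cbind(X1 = 0:(K - 1), X2 = 0:(K - 1), X3 = 0:(K - 1))
}
modMatrix <- function(K) {
  g <- as.matrix(expand.grid(0:(K - 1), 0:(K - 1)))
  cbind(X1 = g[, 1], X2 = g[, 2], X3 = (g[, 1] + g[, 2]) %% K)
}
productMatrix <- function(K) {
  g <- as.matrix(expand.grid(0:(K - 1), 0:(K - 1), 0:(K - 1)))
  colnames(g) <- c("X1", "X2", "X3")
  g
}

randomBinned <- function(nrows, n, card, seed) {
  set.seed(seed)
  labels <- sapply(seq_len(n), function(j) {
    sample.int(card[j], nrows, replace = TRUE) - 1L
  })
  BinnedMatrix(matrix(as.integer(labels), nrows, n), as.integer(card))
}
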