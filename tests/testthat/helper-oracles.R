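# Independent oracles used to check package computations. These stay
# deliberately naive: brute force and textbook dynamic programming, never
# sharing code with the implementation they verify.

# Unit-cost edit distance by the full DP table.
lev_dp <- function(a, b) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  d <- matrix(0L, n + 1L, m + 1L)
  d[, 1] <- 0:n; d[1, ] <- 0:m
  for (i in seq_len(n)) for (j in seq_len(m))
    d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                           d[i, j] + (x[i] != y[j]))
  d[n + 1, m + 1]
}

# AUC by exhaustive pairwise comparison, ties counted half.
auc_brute <- function(prob, truth) {
  pos <- prob[truth == 1]; neg <- prob[truth == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

random_peptide <- function(n = 1, len = NULL) {
  vapply(seq_len(n), function(i) {
    l <- if (is.null(len)) sample(8:11, 1) else len
    paste(sample(AA_ALPHABET20, l, replace = TRUE), collapse = "")
  }, "")
}

random_cdr3b <- function(n = 1, len = NULL) {
  vapply(seq_len(n), function(i) {
    l <- if (is.null(len)) sample(8:19, 1) else len
    paste(sample(AA_ALPHABET20, l, replace = TRUE), collapse = "")
  }, "")
}

# Small labelled pair table with balanced classes (no planted signal).
toy_records <- function(n = 20, seed = 42) {
  set.seed(seed)
  pair_records(random_cdr3b(n), random_peptide(n),
               label = rep_len(c(1L, 0L), n), source = "toy")
}

# A learnable repertoire split into train/test halves.
split_repertoire <- function(rep, train_frac = 0.7, seed = 1) {
  set.seed(seed)
  n <- nrow(rep$records)
  tr <- sort(sample(n, round(train_frac * n)))
  list(train = rep$records[tr, ], test = rep$records[-tr, ])
}
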