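# Independent brute-force oracles used across tests. These deliberately
# avoid the package's own counting code paths.

naive_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

naive_gdc_pair <- function(s, pair, gap) {
  v <- strsplit(s, "")[[1]]
  L <- length(v)
  n_win <- L - gap - 1L
  hits <- 0L
  for (i in seq_len(n_win))
    if (v[i] == substr(pair, 1, 1) && v[i + gap + 1L] == substr(pair, 2, 2))
      hits <- hits + 1L
  hits / n_win
}

naive_kmer_counts <- function(s, k) {
  L <- nchar(s)
  if (L < k) return(table(character(0)))
  table(substring(s, seq_len(L - k + 1L), seq_len(L - k + 1L) + k - 1L))
}

random_dna <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")

# Standard-notation MCC with the 0-denominator -> 0 convention.
standard_mcc <- function(tp, fp, tn, fn) {
  den <- sqrt((tp + fp)) * sqrt((tp + fn)) * sqrt((tn + fp)) * sqrt((tn + fn))
  if (den == 0) return(0)
  (tp * tn - fp * fn) / den
}

# Linearly separable toy problem for classifier tests.
separable_toy <- function(n = 40, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), each = n / 2)
  X <- cbind(f1 = ifelse(y == 0, -2, 2) + rnorm(n, sd = 0.2),
             f2 = rnorm(n))
  rownames(X) <- paste0("s", seq_len(n))
  list(X = X, y = y)
}

# Small labeled dataset for pipeline-level tests.
tiny_dataset <- function(n_per = 15, L = 60, effect = 0.5, seed = 7) {
  generate_synthetic_dataset(simulation_spec(
    n_pos = n_per, n_neg = n_per, length_low = L, length_high = L,
    effect = effect, planted_kmers = c("AAA", "TTT"), seed = seed))
}
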