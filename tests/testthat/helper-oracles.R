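# Independent brute-force oracles used to pin down expected values.
# These deliberately avoid the package's own code paths: dictionary
# counting for k-mers, naive recursion (no memoization) over all global
# alignments, per-seed exhaustive extension for the local aligner, and the
# rank-based Mann-Whitney statistic for AUC.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

all_kmers <- function(k) {
  do.call(paste0, rev(expand.grid(rep(list(c("A", "C", "G", "T")), k),
                                  stringsAsFactors = FALSE)))
}

oracle_kmer_freq <- function(seq, k = 4) {
  kmers <- sort(all_kmers(k))
  counts <- stats::setNames(numeric(length(kmers)), kmers)
  n <- nchar(seq)
  n_windows <- 0
  for (i in seq_len(n - k + 1)) {
    w <- substr(seq, i, i + k - 1)
    if (grepl("^[ACGT]+$", w)) {
      counts[w] <- counts[w] + 1
      n_windows <- n_windows + 1
    }
  }
  counts / n_windows
}

oracle_af <- function(s1, s2, k = 4) {
  sqrt(sum((oracle_kmer_freq(s1, k) - oracle_kmer_freq(s2, k))^2)) / sqrt(2)
}

# exhaustive enumeration of all global alignments by plain recursion
oracle_nw <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  rec <- function(n, m) {
    if (n == 0) return(m * gap)
    if (m == 0) return(n * gap)
    sub <- if (substr(a, n, n) == substr(b, m, m)) match else mismatch
    max(rec(n - 1, m - 1) + sub, rec(n - 1, m) + gap, rec(n, m - 1) + gap)
  }
  rec(nchar(a), nchar(b))
}

# best gapped extension of two prefixes, enumerated recursively; the empty
# extension (score 0) is always allowed
oracle_extension <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  best <- 0
  for (p in 0:nchar(a)) {
    for (q in 0:nchar(b)) {
      if (p + q > 0) {
        s <- oracle_nw(substr(a, 1, p), substr(b, 1, q),
                       match, mismatch, gap)
        best <- max(best, s)
      }
    }
  }
  best
}

reverse_string <- function(s) {
  paste(rev(strsplit(s, "")[[1]]), collapse = "")
}

# seed-and-extend over every shared word occurrence pair
oracle_local <- function(a, b, w = 4, match = 1, mismatch = -1, gap = -1) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i in seq_len(max(0, n - w + 1))) {
    for (j in seq_len(max(0, m - w + 1))) {
      wa <- substr(a, i, i + w - 1)
      if (wa == substr(b, j, j + w - 1) && grepl("^[ACGT]+$", wa)) {
        left <- oracle_extension(reverse_string(substr(a, 1, i - 1)),
                                 reverse_string(substr(b, 1, j - 1)),
                                 match, mismatch, gap)
        right <- oracle_extension(substr(a, i + w, n), substr(b, j + w, m),
                                  match, mismatch, gap)
        best <- max(best, w * match + left + right)
      }
    }
  }
  best
}

# AUC as the Mann-Whitney U statistic (low predictor value = positive call)
oracle_auc_mw <- function(d1, d2, alpha) {
  pos <- d2[d1 <= alpha]
  neg <- d2[d1 > alpha]
  if (length(pos) == 0 || length(neg) == 0) return(NA_real_)
  cmp <- outer(pos, neg, function(p, q) (p < q) + 0.5 * (p == q))
  mean(cmp)
}

# bare pair table with the target in `bt` and the predictor in `af`
pair_df_acc <- function(d1, d2) {
  data.frame(id1 = paste0("a", seq_along(d1)),
             id2 = paste0("b", seq_along(d1)),
             bt = d1, nw = rep(NA_real_, length(d1)),
             bl = rep(NA_real_, length(d1)), af = d2,
             stringsAsFactors = FALSE)
}

# small deterministic read set with one placement per read
toy_reads <- function() {
  data.frame(
    id = c("a", "b", "c", "d"),
    seq = c("ACGTACGTAC", "ACGTACGTAC", "AAAACCCCGG", "TTTTGGGGAA"),
    ref = "chr1",
    start = c(0L, 0L, 50L, 100L),
    end = c(10L, 10L, 60L, 110L),
    strand = "+",
    stringsAsFactors = FALSE)
}

toy_sample <- function(pairs_idx = rbind(c(1, 2), c(1, 3), c(3, 4))) {
  reads <- toy_reads()
  structure(list(
    label = "toy",
    pairs = data.frame(id1 = reads$id[pairs_idx[, 1]],
                       id2 = reads$id[pairs_idx[, 2]],
                       bt = rep(NA_real_, nrow(pairs_idx)),
                       nw = rep(NA_real_, nrow(pairs_idx)),
                       bl = rep(NA_real_, nrow(pairs_idx)),
                       af = rep(NA_real_, nrow(pairs_idx)),
                       stringsAsFactors = FALSE),
    reads = reads), class = "pair_sample")
}
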