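#' k-mer relative frequency vector of a read
#'
#' Counts every window of `k` consecutive bases (positions 1 to n - k + 1)
#' and normalizes by the number of valid windows, giving the 4^k-dimensional
#' frequency profile used by the alignment-free distance. Windows containing
#' a letter outside `A,C,G,T` are skipped and excluded from the normalizing
#' denominator. With the default `k = 4` the vector has 4^4 = 256 entries,
#' one per tetramer in lexicographic order.
#'
#' @param seq A single sequence (character string).
#' @param k Word length (default 4, tetramers).
#' @return A named numeric vector of length `4^k` summing to 1, with
#'   attributes `k` and `n_windows` (number of valid windows counted).
#' @examples
#' v <- kmer_frequency_vector("ACGTACGT")
#' v[v > 0]
#' @export
kmer_frequency_vector <- function(seq, k = 4) {
  stopifnot(length(seq) == 1L, k >= 1)
  n <- nchar(seq)
  if (n < k) {
    stop("read of length ", n, " is shorter than k = ", k)
  }
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAString(seq), width = k, step = 1)
  n_windows <- sum(counts)
  if (n_windows == 0L) {
    stop("no valid window of length ", k,
         " (every window contains a non-ACGT character)")
  }
  structure(counts / n_windows, k = k, n_windows = n_windows)
}

# frequency matrix for many reads at once; rows with no valid window are NA
kmer_frequency_matrix <- function(seqs, k = 4) {
  counts <- Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = k, step = 1)
  nw <- rowSums(counts)
  freq <- counts / ifelse(nw > 0, nw, NA_real_)
  attr(freq, "n_windows") <- nw
  freq
}

#' Alignment-free distance between two reads
#'
#' Euclidean distance between the k-mer frequency vectors of the two reads,
#' divided by `sqrt(2)` (the largest possible Euclidean distance between two
#' frequency vectors, attained by disjoint one-hot profiles) so that the
#' result lies in `[0, 1]`. Identical sequences have distance 0. Runs in
#' time linear in the read lengths.
#'
#' @param seq1,seq2 Sequences (character strings) with at least one valid
#'   window each.
#' @param k Word length (default 4).
#' @return A number in `[0, 1]`.
#' @export
af_distance <- function(seq1, seq2, k = 4) {
  v1 <- kmer_frequency_vector(seq1, k)
  v2 <- kmer_frequency_vector(seq2, k)
  min(1, sqrt(sum((v1 - v2)^2)) / sqrt(2))
}

nw_substitution_matrix <- function(match, mismatch) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m) <- match
  m["N", "N"] <- mismatch  # an ambiguous base never matches anything
  m
}

#' Global (Needleman-Wunsch) alignment score of two reads
#'
#' Optimal global alignment score under the balanced scheme +1 per match,
#' -1 per mismatch, -1 per gapped position (linear gap cost), computed by
#' dynamic programming in O(n*m). Alongside the score, the attainable
#' bounds for the two lengths are returned: a perfect alignment scores
#' `min(l1, l2) - |l1 - l2|` (the length difference forces gaps), and the
#' worst alignment, everything gapped, scores `-(l1 + l2)`.
#'
#' @param seq1,seq2 Non-empty sequences.
#' @param match,mismatch,gap Scoring parameters (defaults +1/-1/-1).
#' @return A list with `score`, `max_score`, `min_score`.
#' @export
nw_align <- function(seq1, seq2, match = 1, mismatch = -1, gap = -1) {
  l1 <- nchar(seq1); l2 <- nchar(seq2)
  if (l1 == 0L || l2 == 0L) stop("nw_align: empty read")
  score <- Biostrings::pairwiseAlignment(
    seq1, seq2, type = "global",
    substitutionMatrix = nw_substitution_matrix(match, mismatch),
    gapOpening = 0, gapExtension = -gap, scoreOnly = TRUE)
  list(score = score,
       max_score = min(l1, l2) * match + abs(l1 - l2) * gap,
       min_score = (l1 + l2) * gap)
}

#' Global-alignment distance between two reads
#'
#' The alignment score is subtracted from its maximum attainable value for
#' the two lengths (so equal sequences get distance 0) and divided by the
#' score range, mapping it to `[0, 1]`.
#'
#' @inheritParams nw_align
#' @return A number in `[0, 1]`.
#' @export
nw_distance <- function(seq1, seq2, match = 1, mismatch = -1, gap = -1) {
  a <- nw_align(seq1, seq2, match, mismatch, gap)
  (a$max_score - a$score) / (a$max_score - a$min_score)
}

#' Word-seeded local alignment score of two reads
#'
#' Score of the best local alignment that contains an exact shared word of
#' `word_size` consecutive matching bases (the seed), extended in both
#' directions with the same +1/-1/-1 match/mismatch/gap scheme, with no
#' low-complexity masking or filtering. If the two reads share no word of
#' that length the score is 0. The maximum attainable score is
#' `min(l1, l2)` (a full-length exact match of the shorter read); the
#' minimum is 0 (empty alignment).
#'
#' @param seq1,seq2 Non-empty sequences.
#' @param word_size Seed word length (default 4).
#' @param match,mismatch,gap Scoring parameters (defaults +1/-1/-1).
#' @return A list with `score`, `max_score`, `min_score`.
#' @export
local_align <- function(seq1, seq2, word_size = 4, match = 1, mismatch = -1,
                        gap = -1) {
  l1 <- nchar(seq1); l2 <- nchar(seq2)
  if (l1 == 0L || l2 == 0L) stop("local_align: empty read")
  score <- seeded_local_score_cpp(seq1, seq2, as.integer(word_size),
                                  match, mismatch, gap)
  list(score = score, max_score = min(l1, l2) * match, min_score = 0)
}

#' Local-alignment distance between two reads
#'
#' The seeded local alignment score is subtracted from its maximum value and
#' normalized to `[0, 1]`: identical reads get 0, reads sharing no word of
#' `word_size` bases get 1.
#'
#' @inheritParams local_align
#' @return A number in `[0, 1]`.
#' @export
bl_distance <- function(seq1, seq2, word_size = 4, match = 1, mismatch = -1,
                        gap = -1) {
  a <- local_align(seq1, seq2, word_size, match, mismatch, gap)
  (a$max_score - a$score) / a$max_score
}

#' Reference-overlap ("Bowtie") distance between two placed reads
#'
#' The target distance derived from read placements on a reference genome:
#' for single placements, `1 - 2 * overlap / (l1 + l2)` where `overlap` is
#' the number of reference positions covered by both placements (0 when the
#' references differ) and `l1`, `l2` are the reference widths of the two
#' placements. Reads placed on disjoint intervals get the maximum distance
#' 1; equal-length reads placed identically get 0. If either read has
#' several placements, the average over all placement combinations is used.
#' Placement strand is ignored: overlap on the reference is positional.
#'
#' @param p1,p2 Placement data frames (columns `ref`, `start`, `end`; one
#'   row per placement, at least one row each) as returned by [read_sam()]
#'   or the simulator.
#' @return A number in `[0, 1]`.
#' @export
bt_distance <- function(p1, p2) {
  if (NROW(p1) == 0L || NROW(p2) == 0L) {
    stop("bt_distance: read without placements")
  }
  i <- rep(seq_len(nrow(p1)), times = nrow(p2))
  j <- rep(seq_len(nrow(p2)), each = nrow(p1))
  l1 <- p1$end[i] - p1$start[i]
  l2 <- p2$end[j] - p2$start[j]
  ov <- pmax(0, pmin(p1$end[i], p2$end[j]) - pmax(p1$start[i], p2$start[j]))
  ov[p1$ref[i] != p2$ref[j]] <- 0
  mean(1 - 2 * ov / (l1 + l2))
}

# vectorized single-placement BT for two aligned placement tables
bt_distance_vec <- function(ref1, s1, e1, ref2, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  ov[ref1 != ref2] <- 0
  1 - 2 * ov / ((e1 - s1) + (e2 - s2))
}

#' Compute the read-pair distances of a pair sample
#'
#' Fills the requested distance columns (`bt`, `nw`, `bl`, `af`) of a
#' `pair_sample`'s pair table. Sequences come from the sample's read table;
#' placements for the overlap distance default to the same table (the
#' simulator's truth) but can be overridden with aligner output from
#' [read_sam()]. A pair whose distance cannot be computed (for example a
#' read whose every window contains an ambiguous base) is left `NA` and
#' counted in a summary message; the run continues.
#'
#' @param sample A `pair_sample` (see [sample_pairs()]).
#' @param which Distances to compute, subset of `c("bt","nw","bl","af")`.
#' @param k Word length of the alignment-free distance.
#' @param match,mismatch,gap Alignment scoring parameters.
#' @param word_size Seed length of the local aligner.
#' @param placements Optional placement table (`id`, `ref`, `start`, `end`)
#'   replacing the sample's own placements for the overlap distance.
#' @return The sample with the requested distance columns populated.
#' @export
compute_distances <- function(sample, which = c("bt", "nw", "bl", "af"),
                              k = 4, match = 1, mismatch = -1, gap = -1,
                              word_size = 4, placements = NULL) {
  stopifnot(inherits(sample, "pair_sample"))
  which <- match.arg(which, several.ok = TRUE)
  pairs <- sample$pairs
  if (nrow(pairs) == 0L) return(sample)
  reads <- sample$reads
  i1 <- match(pairs$id1, reads$id)
  i2 <- match(pairs$id2, reads$id)
  if (anyNA(i1) || anyNA(i2)) {
    stop("pair references unknown read id: '",
         c(pairs$id1[is.na(i1)], pairs$id2[is.na(i2)])[1], "'")
  }
  flagged <- 0L

  if ("bt" %in% which) {
    pl <- if (is.null(placements)) reads else placements
    if (anyDuplicated(pl$id) == 0L) {
      j1 <- match(pairs$id1, pl$id); j2 <- match(pairs$id2, pl$id)
      ok <- !is.na(j1) & !is.na(j2)
      pairs$bt <- NA_real_
      pairs$bt[ok] <- bt_distance_vec(pl$ref[j1[ok]], pl$start[j1[ok]],
                                      pl$end[j1[ok]], pl$ref[j2[ok]],
                                      pl$start[j2[ok]], pl$end[j2[ok]])
    } else {
      by_id <- split(seq_len(nrow(pl)), pl$id)
      pairs$bt <- vapply(seq_len(nrow(pairs)), function(p) {
        r1 <- by_id[[pairs$id1[p]]]; r2 <- by_id[[pairs$id2[p]]]
        if (is.null(r1) || is.null(r2)) return(NA_real_)
        bt_distance(pl[r1, , drop = FALSE], pl[r2, , drop = FALSE])
      }, numeric(1))
    }
    flagged <- flagged + sum(is.na(pairs$bt))
  }

  if ("af" %in% which) {
    freq <- kmer_frequency_matrix(reads$seq, k)
    d <- numeric(nrow(pairs))
    chunk <- 20000L
    for (from in seq(1, nrow(pairs), by = chunk)) {
      to <- min(from + chunk - 1L, nrow(pairs))
      diff <- freq[i1[from:to], , drop = FALSE] -
        freq[i2[from:to], , drop = FALSE]
      d[from:to] <- pmin(1, sqrt(rowSums(diff^2)) / sqrt(2))
    }
    pairs$af <- d
    flagged <- flagged + sum(is.na(d))
  }

  if ("nw" %in% which) {
    sm <- nw_substitution_matrix(match, mismatch)
    l1 <- nchar(reads$seq[i1]); l2 <- nchar(reads$seq[i2])
    score <- vapply(seq_len(nrow(pairs)), function(p) {
      tryCatch(Biostrings::pairwiseAlignment(
        reads$seq[i1[p]], reads$seq[i2[p]], type = "global",
        substitutionMatrix = sm, gapOpening = 0, gapExtension = -gap,
        scoreOnly = TRUE), error = function(e) NA_real_)
    }, numeric(1))
    max_s <- pmin(l1, l2) * match + abs(l1 - l2) * gap
    min_s <- (l1 + l2) * gap
    pairs$nw <- (max_s - score) / (max_s - min_s)
    flagged <- flagged + sum(is.na(pairs$nw))
  }

  if ("bl" %in% which) {
    l1 <- nchar(reads$seq[i1]); l2 <- nchar(reads$seq[i2])
    score <- vapply(seq_len(nrow(pairs)), function(p) {
      tryCatch(seeded_local_score_cpp(reads$seq[i1[p]], reads$seq[i2[p]],
                                      as.integer(word_size),
                                      match, mismatch, gap),
               error = function(e) NA_real_)
    }, numeric(1))
    pairs$bl <- (pmin(l1, l2) * match - score) / (pmin(l1, l2) * match)
    flagged <- flagged + sum(is.na(pairs$bl))
  }

  if (flagged > 0L) {
    message("compute_distances: ", flagged,
            " pair distance(s) could not be computed and were left NA")
  }
  sample$pairs <- pairs
  sample
}
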