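#' Reverse complement of nucleotide sequences
#'
#' @param seq Character vector of sequences over `A,C,G,T,N`.
#' @return Character vector of reverse complements.
#' @export
reverse_complement <- function(seq) {
  if (length(seq) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Generate a random reference sequence
#'
#' Bases are i.i.d. uniform over `A,C,G,T`; the same seed reproduces the
#' same sequence. Stands in for a real reference chromosome when simulating
#' reads with known placements.
#'
#' @param length Genome length in bp (>= 1).
#' @param seed Integer RNG seed.
#' @return A single character string of the requested length.
#' @export
random_genome <- function(length, seed) {
  if (length < 1) stop("genome length must be >= 1, got ", length)
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Sample reads with known placements from a reference
#'
#' Draws `n_reads` forward reads at uniform random start positions, with
#' lengths rounded from a Normal(`read_length_mean`, `read_length_sd`) and
#' clipped to `[4, nchar(genome)]`. For every forward read a
#' reverse-complemented copy (id suffixed `_rc`, strand `-`) is added with
#' the same reference interval: both orientations cover the same genomic
#' positions, as an aligner would report for the two strands. The output
#' therefore has `2 * n_reads` rows, each carrying its single true placement.
#'
#' @param genome Reference sequence (character string).
#' @param n_reads Number of forward reads to draw (> 0); total output is
#'   twice this.
#' @param read_length_mean,read_length_sd Read length distribution in bp.
#' @param seed Integer RNG seed.
#' @param ref Reference name recorded in the placements.
#' @return A data frame with columns `id`, `seq`, `ref`, `start` (0-based),
#'   `end` (exclusive), `strand`.
#' @export
sample_reads <- function(genome, n_reads, read_length_mean = 100,
                         read_length_sd = 6, seed = 1, ref = "chr1") {
  if (n_reads <= 0) stop("n_reads must be positive, got ", n_reads)
  gl <- nchar(genome)
  if (gl < read_length_mean) {
    warning("genome shorter than the mean read length; lengths will be clipped")
  }
  set.seed(seed)
  len <- pmin(pmax(round(stats::rnorm(n_reads, read_length_mean,
                                      read_length_sd)), 4L), gl)
  start <- floor(stats::runif(n_reads) * (gl - len + 1))  # 0-based
  fwd_seq <- substring(genome, start + 1, start + len)
  id <- sprintf("r%0*d", nchar(as.character(n_reads)), seq_len(n_reads))
  fwd <- data.frame(id = id, seq = fwd_seq, ref = ref,
                    start = as.integer(start), end = as.integer(start + len),
                    strand = "+", stringsAsFactors = FALSE)
  rev <- fwd
  rev$id <- paste0(fwd$id, "_rc")
  rev$seq <- reverse_complement(fwd$seq)
  rev$strand <- "-"
  rbind(fwd, rev)
}

# All ordered index pairs (i < j) of reads whose placements share >= 1
# reference position, with the overlap width. Sweep over starts: O(n * depth).
overlapping_index_pairs <- function(reads) {
  res_i <- integer(0); res_j <- integer(0)
  for (r in unique(reads$ref)) {
    idx <- which(reads$ref == r)
    ord <- idx[order(reads$start[idx], reads$end[idx])]
    s <- reads$start[ord]; e <- reads$end[ord]
    n <- length(ord)
    if (n < 2L) next
    # for each read k, partners are the following reads starting before e[k]
    last <- findInterval(e[-n] - 1L, s)      # s sorted; start <= e[k]-1
    first <- seq_len(n - 1L) + 1L
    cnt <- pmax(0L, last - first + 1L)
    i <- rep.int(ord[-n], cnt)
    j <- ord[sequence(cnt, from = first, by = 1L)]
    res_i <- c(res_i, i); res_j <- c(res_j, j)
  }
  ov <- pmin(reads$end[res_i], reads$end[res_j]) -
    pmax(reads$start[res_i], reads$start[res_j])
  data.frame(i = res_i, j = res_j, overlap = ov)
}

#' Sample a controlled-overlap set of read pairs
#'
#' Builds one experimental pair sample: `round(rp * overlap_fraction)` pairs
#' whose reference placements overlap by at least one base and the remaining
#' pairs with zero placement overlap. The overlapping half is stratified into
#' 10 equal bins of overlap degree (fraction of the shorter placement,
#' (0,0.1], ..., (0.9,1]) so that the whole overlap range is represented;
#' bins short of candidates are topped up with the unused candidates nearest
#' in overlap degree. Overlapping pairs are drawn from same-orientation reads
#' (both `+` or both `-`), so that positional overlap is accompanied by
#' sequence overlap in the orientation the reads are stored in; see the
#' package vignette for the rationale. No unordered pair is repeated.
#'
#' @param reads Read table from [sample_reads()] (or any table with `id`,
#'   `seq`, `ref`, `start`, `end`, `strand`).
#' @param rp Number of pairs to draw.
#' @param overlap_fraction Fraction of pairs that must overlap (0.5 mirrors
#'   the half/half experimental design).
#' @param seed Integer RNG seed.
#' @param label Sample label (e.g. `"A"`).
#' @return A `pair_sample`: list with `label`, `pairs` (data frame `id1`,
#'   `id2`, `bt`, `nw`, `bl`, `af`, distances `NA` until computed) and
#'   `reads`.
#' @export
sample_pairs <- function(reads, rp, overlap_fraction = 0.5, seed = 1,
                         label = "A") {
  stopifnot(rp >= 1, overlap_fraction >= 0, overlap_fraction <= 1)
  set.seed(seed)
  n_ov <- round(rp * overlap_fraction)
  n_dis <- rp - n_ov

  ov_idx <- data.frame(i = integer(0), j = integer(0), overlap = integer(0))
  if (n_ov > 0L) {
    cand <- overlapping_index_pairs(reads)
    cand <- cand[reads$strand[cand$i] == reads$strand[cand$j] &
                   reads$id[cand$i] != reads$id[cand$j], , drop = FALSE]
    if (nrow(cand) < n_ov) {
      stop("insufficient overlapping pair candidates: need ", n_ov,
           ", have ", nrow(cand))
    }
    shorter <- pmin(reads$end[cand$i] - reads$start[cand$i],
                    reads$end[cand$j] - reads$start[cand$j])
    degree <- cand$overlap / shorter
    stratum <- pmin(ceiling(degree * 10), 10L)   # (0,0.1] -> 1, ..., -> 10
    target <- rep(n_ov %/% 10L, 10L)
    extra <- n_ov - sum(target)
    if (extra > 0L) target[seq_len(extra)] <- target[seq_len(extra)] + 1L
    perm <- sample.int(nrow(cand))
    cand <- cand[perm, , drop = FALSE]
    degree <- degree[perm]
    stratum <- stratum[perm]
    rownames(cand) <- NULL
    take <- logical(nrow(cand))
    for (b in 1:10) {
      in_b <- which(stratum == b)
      take[in_b[seq_len(min(length(in_b), target[b]))]] <- TRUE
      deficit <- target[b] - min(length(in_b), target[b])
      if (deficit > 0L) {
        pool <- which(!take)
        near <- pool[order(abs(degree[pool] - (b - 0.5) / 10))]
        take[near[seq_len(deficit)]] <- TRUE
      }
    }
    ov_idx <- cand[take, , drop = FALSE]
  }

  dis_i <- integer(0); dis_j <- integer(0)
  if (n_dis > 0L) {
    n <- nrow(reads)
    seen <- character(0)
    attempts <- 0L
    while (length(dis_i) < n_dis) {
      attempts <- attempts + 1L
      if (attempts > 200L) {
        stop("insufficient non-overlapping pair candidates: found ",
             length(dis_i), " of ", n_dis)
      }
      m <- (n_dis - length(dis_i)) * 2L
      a <- sample.int(n, m, replace = TRUE)
      b <- sample.int(n, m, replace = TRUE)
      lo <- pmin(a, b); hi <- pmax(a, b)
      ok <- lo != hi & reads$id[lo] != reads$id[hi] &
        (reads$ref[lo] != reads$ref[hi] |
           pmin(reads$end[lo], reads$end[hi]) <=
           pmax(reads$start[lo], reads$start[hi]))
      key <- paste(lo, hi)
      ok <- ok & !duplicated(key) & !(key %in% seen)
      keep <- which(ok)
      if (length(keep) > 0L) {
        keep <- keep[seq_len(min(length(keep), n_dis - length(dis_i)))]
        dis_i <- c(dis_i, lo[keep]); dis_j <- c(dis_j, hi[keep])
        seen <- c(seen, key[keep])
      }
    }
  }

  i <- c(ov_idx$i, dis_i); j <- c(ov_idx$j, dis_j)
  lo <- pmin(i, j); hi <- pmax(i, j)
  if (anyDuplicated(paste(lo, hi))) stop("internal error: duplicated pair")
  pairs <- data.frame(id1 = reads$id[lo], id2 = reads$id[hi],
                      bt = NA_real_, nw = NA_real_, bl = NA_real_,
                      af = NA_real_, stringsAsFactors = FALSE)
  structure(list(label = label, pairs = pairs, reads = reads),
            class = "pair_sample")
}

#' @export
print.pair_sample <- function(x, ...) {
  done <- vapply(c("bt", "nw", "bl", "af"),
                 function(d) sum(!is.na(x$pairs[[d]])), numeric(1))
  cat("pair_sample '", x$label, "': ", nrow(x$pairs), " pairs over ",
      nrow(x$reads), " reads\n", sep = "")
  cat("  distances computed:",
      paste(sprintf("%s=%d", names(done), as.integer(done)), collapse = " "),
      "\n")
  invisible(x)
}

#' Draw several independent pair samples from one read set
#'
#' Mirrors the experimental design of drawing six controlled subsets of read
#' pairs from a single selection of reads: each subset gets its own RNG seed
#' derived from `seed`, and labels `A`, `B`, ... prefixed with `prefix`.
#' The number of pairs shared between subsets is reported with a message.
#'
#' @inheritParams sample_pairs
#' @param n_subsets Number of samples (6 in the reference design).
#' @param prefix Label prefix (e.g. `"Y"` for yeast-like naming `YA..YF`).
#' @return A list of `pair_sample` objects.
#' @export
make_subsets <- function(reads, rp, overlap_fraction = 0.5, seed = 1,
                         n_subsets = 6, prefix = "") {
  samples <- lapply(seq_len(n_subsets), function(f) {
    sample_pairs(reads, rp, overlap_fraction, seed = seed + f,
                 label = paste0(prefix, LETTERS[f]))
  })
  keys <- lapply(samples, function(s) paste(s$pairs$id1, s$pairs$id2))
  shared <- sum(duplicated(unlist(keys)))
  message("make_subsets: ", n_subsets, " samples of ", rp,
          " pairs; ", shared, " pair(s) shared between samples")
  samples
}
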