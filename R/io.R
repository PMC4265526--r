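#' Read a FASTA file into a read table
#'
#' Parses a (possibly multi-line) FASTA file into a data frame with one row
#' per record. Sequences are uppercased on ingestion; non-ACGT letters (for
#' example `N`) are kept as-is, and downstream operations decide locally how
#' to treat them.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns `id` (first whitespace-delimited token of
#'   the header line) and `seq` (uppercase sequence). Zero rows for an empty
#'   file.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">r1", "ac", "gt", ">r2", "TTTT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  is_header <- startsWith(lines, ">")
  first_content <- which(nzchar(trimws(lines)))[1]
  if (!is.na(first_content) && !is_header[first_content]) {
    stop("malformed FASTA at line ", first_content,
         ": sequence text before first '>' header")
  }
  rec <- cumsum(is_header)
  ids <- sub("^>\\s*", "", lines[is_header])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1), 1)
  seqs <- vapply(split(lines[!is_header], rec[!is_header]),
                 paste0, character(1), collapse = "")
  # records with no sequence line at all drop out of split(); re-align
  full <- character(sum(is_header))
  names(full) <- as.character(seq_along(full))
  full[names(seqs)] <- seqs
  empty <- which(!nzchar(full))
  if (length(empty) > 0L) {
    stop("malformed FASTA at line ", which(is_header)[empty[1]],
         ": record '", ids[empty[1]], "' has an empty sequence")
  }
  data.frame(id = ids, seq = toupper(unname(full)), stringsAsFactors = FALSE)
}

#' Read a 4-line-per-record FASTQ file into a read table
#'
#' Quality strings are validated (same length as the sequence) and then
#' discarded: no distance in this package uses base qualities.
#'
#' @param path Path to a Sanger FASTQ file.
#' @return A data frame with columns `id` and `seq` (uppercase), in file order.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!(seq_along(lines) == length(lines) & lines == "")]
  if (length(lines) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ: ", length(lines),
         " lines is not a multiple of 4 (truncated record?)")
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- lines[seq(2, length(lines), by = 4)]
  plus <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ at line ", (bad[1] - 1L) * 4L + 1L,
         ": header does not start with '@'")
  }
  bad <- which(!startsWith(plus, "+"))
  if (length(bad) > 0L) {
    stop("malformed FASTQ at line ", (bad[1] - 1L) * 4L + 3L,
         ": separator line does not start with '+'")
  }
  bad <- which(nchar(qual) != nchar(seqs))
  if (length(bad) > 0L) {
    stop("malformed FASTQ at line ", (bad[1] - 1L) * 4L + 4L,
         ": quality length differs from sequence length")
  }
  ids <- vapply(strsplit(sub("^@", "", hdr), "\\s+"), `[`, character(1), 1)
  data.frame(id = ids, seq = toupper(seqs), stringsAsFactors = FALSE)
}

# Reference-consumed length of a CIGAR string; errors name the offending read.
cigar_reference_width <- function(cigar, id) {
  ops <- gsub("[0-9]", "", cigar)
  bad <- grepl("[^MIDNSHP=X]", ops)
  if (any(bad)) {
    stop("unsupported CIGAR opcode in record '", id[bad][1], "': ",
         cigar[bad][1])
  }
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Read a SAM file into a placement table
#'
#' Ingests aligner output (text SAM, with or without header). Unmapped
#' records (FLAG bit 0x4) are dropped with a message reporting the count.
#' SAM's 1-based POS is converted to the package's 0-based half-open
#' convention; the end coordinate is POS - 1 plus the reference-consumed
#' length of the CIGAR (M/=/X/D/N consume reference, I/S/H/P do not). A read
#' with several mapped records contributes several placements, in file order.
#'
#' @param path Path to a SAM file.
#' @return A data frame with one row per mapped record: columns `id`, `ref`,
#'   `start` (0-based), `end` (exclusive), `strand` (`"+"` or `"-"` from FLAG
#'   bit 0x10).
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  empty <- data.frame(id = character(0), ref = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed SAM record (fewer than 11 fields) at alignment line ",
         which(nf < 11L)[1])
  }
  id <- vapply(fields, `[`, character(1), 1)
  flag <- as.integer(vapply(fields, `[`, character(1), 2))
  ref <- vapply(fields, `[`, character(1), 3)
  pos <- as.integer(vapply(fields, `[`, character(1), 4))
  cigar <- vapply(fields, `[`, character(1), 6)
  mapped <- bitwAnd(flag, 4L) == 0L
  if (any(!mapped)) {
    message("read_sam: dropped ", sum(!mapped), " unmapped record(s)")
  }
  if (!any(mapped)) return(empty)
  id <- id[mapped]; flag <- flag[mapped]; ref <- ref[mapped]
  pos <- pos[mapped]; cigar <- cigar[mapped]
  if (any(is.na(pos) | pos == 0L)) {
    stop("mapped SAM record with POS=0 (read '",
         id[which(is.na(pos) | pos == 0L)[1]], "')")
  }
  width <- cigar_reference_width(cigar, id)
  data.frame(id = id, ref = ref, start = pos - 1L,
             end = pos - 1L + as.integer(width),
             strand = ifelse(bitwAnd(flag, 16L) == 16L, "-", "+"),
             stringsAsFactors = FALSE)
}

#' Write / read a tabular pair-distance file
#'
#' The pair table is the exchange format between simulation, distance
#' computation and evaluation: a TSV with header `id1 id2 bt nw bl af`,
#' `NA` for distances not yet computed, `.` as decimal separator, and at
#' least 10 significant digits so a round trip preserves the values.
#'
#' @param pairs A data frame with columns `id1`, `id2`, `bt`, `nw`, `bl`, `af`.
#' @param path Output (or input) file path.
#' @return `write_pairs` returns `path` invisibly; `read_pairs` returns the
#'   pair data frame.
#' @export
write_pairs <- function(pairs, path) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("id1", "id2") %in% names(pairs)))
  for (col in c("bt", "nw", "bl", "af")) {
    if (is.null(pairs[[col]])) pairs[[col]] <- NA_real_
  }
  pairs <- pairs[, c("id1", "id2", "bt", "nw", "bl", "af")]
  check_pair_values(pairs)
  out <- pairs
  for (col in c("bt", "nw", "bl", "af")) {
    v <- sprintf("%.12g", out[[col]])
    v[is.na(out[[col]])] <- "NA"
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_pairs
#' @export
read_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", quote = "",
                           stringsAsFactors = FALSE)
  expected <- c("id1", "id2", "bt", "nw", "bl", "af")
  if (!identical(names(tab), expected)) {
    stop("pair table has columns [", paste(names(tab), collapse = ", "),
         "]; expected [", paste(expected, collapse = ", "), "]")
  }
  for (col in c("bt", "nw", "bl", "af")) {
    v <- tab[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & v != "NA")
    if (length(bad) > 0L) {
      stop("non-numeric value '", v[bad[1]], "' in column '", col,
           "' of ", path)
    }
    tab[[col]] <- num
  }
  check_pair_values(tab)
  tab
}

check_pair_values <- function(pairs) {
  if (any(pairs$id1 == pairs$id2)) {
    stop("pair table contains a self-pair (id1 == id2): '",
         pairs$id1[pairs$id1 == pairs$id2][1], "'")
  }
  for (col in c("bt", "nw", "bl", "af")) {
    v <- pairs[[col]]
    bad <- which(!is.na(v) & (v < 0 | v > 1))
    if (length(bad) > 0L) {
      stop("distance '", col, "' outside [0,1] at row ", bad[1],
           ": ", v[bad[1]])
    }
  }
  invisible(TRUE)
}

#' Write reads as FASTA or FASTQ
#'
#' FASTQ output uses constant dummy qualities (`I`), as the package carries
#' no per-base quality information.
#'
#' @param reads A data frame with columns `id` and `seq` (a genome can be
#'   written by passing a one-row frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_fastq <- function(reads, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n",
                    strrep("I", nchar(reads$seq))), con)
  invisible(path)
}

#' Write simulated truth placements as SAM
#'
#' Emits a minimal SAM file (one `@SQ` line per reference, one alignment line
#' per placement) so the simulator's truth can round-trip through
#' [read_sam()]. Per the SAM convention, the SEQ column of a minus-strand
#' record is the reverse complement of the stored read sequence.
#'
#' @param reads A data frame with columns `id`, `seq`, `ref`, `start`, `end`,
#'   `strand` (0-based half-open coordinates).
#' @param path Output path.
#' @param ref_lengths Named integer vector of reference lengths; defaults to
#'   the maximum `end` per reference.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, ref_lengths = NULL) {
  if (is.null(ref_lengths)) {
    ref_lengths <- tapply(reads$end, reads$ref, max)
  }
  seq_out <- reads$seq
  neg <- reads$strand == "-"
  seq_out[neg] <- reverse_complement(seq_out[neg])
  lines <- c(
    "@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths), as.integer(ref_lengths)),
    sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s",
            reads$id, ifelse(neg, 16L, 0L), reads$ref,
            as.integer(reads$start) + 1L,
            as.integer(reads$end - reads$start), seq_out,
            strrep("I", nchar(seq_out)))
  )
  writeLines(lines, path)
  invisible(path)
}
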