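#' Trim the 3' adapter from raw reads
#'
#' Removes the longest read suffix that matches a prefix of the adapter with
#' an overlap of at least 7 nt and at most one mismatch per 7 nt of overlap
#' (i.e. `floor(overlap / 7)` mismatches). A full internal adapter
#' occurrence therefore also truncates the read. Reads sharing less than
#' 7 nt with the adapter are returned unchanged and flagged untrimmed.
#'
#' @param reads Character vector of raw reads.
#' @param adapter3 3' adapter sequence (non-empty).
#' @return A list with `insert` (trimmed sequences) and `trimmed` (logical).
#' @export
trim_adapter <- function(reads, adapter3) {
  stopifnot(nzchar(adapter3))
  adapter3 <- toupper(adapter3)
  achars <- strsplit(adapter3, "")[[1]]
  alen <- length(achars)
  n <- length(reads)
  if (n == 0L) return(list(insert = character(0), trimmed = logical(0)))
  reads <- toupper(reads)
  lens <- nchar(reads)
  maxlen <- max(lens)
  # fixed-width character matrix (rows = reads), padded with spaces
  mat <- matrix(" ", nrow = n, ncol = maxlen)
  sp <- strsplit(reads, "")
  for (i in seq_len(n)) mat[i, seq_len(lens[i])] <- sp[[i]]

  cut <- rep(NA_integer_, n) # first read position belonging to the adapter
  for (p in seq_len(maxlen)) {
    open <- is.na(cut) & (lens - p + 1L >= 7L)
    if (!any(open)) break
    k <- pmin(lens - p + 1L, alen) # compared overlap per read
    kmax <- max(k[open])
    mism <- integer(n)
    for (j in seq_len(kmax)) {
      within <- open & (j <= k)
      mism[within] <- mism[within] + (mat[within, p + j - 1L] != achars[j])
    }
    hit <- open & (mism <= k %/% 7L)
    cut[hit] <- p
  }
  insert <- reads
  trimmed <- !is.na(cut)
  insert[trimmed] <- substr(reads[trimmed], 1L, cut[trimmed] - 1L)
  list(insert = insert, trimmed = trimmed)
}

#' Filter trimmed reads by length, ambiguity and quality
#'
#' Keeps reads whose insert length lies in `[min_len, max_len]` (inclusive),
#' contains no ambiguous base, and (when qualities are supplied) whose bases
#' over the insert are all at or above `min_q`. The rejection tally
#' partitions discarded reads by the first failing cause, checked in the
#' order low_quality, ambiguous, too_short, too_long.
#'
#' @param inserts Character vector of trimmed inserts.
#' @param quals Optional character vector of Phred+33 quality strings for the
#'   raw reads (at least as long as each insert).
#' @param min_len,max_len Inclusive length window (defaults 18 and 30).
#' @param min_q Minimum per-base Phred quality (default 10).
#' @return A list with `keep` (logical), `reads` (surviving inserts) and
#'   `tally` (named integer vector of rejection causes).
#' @export
filter_reads <- function(inserts, quals = NULL, min_len = 18L, max_len = 30L,
                         min_q = 10L) {
  n <- length(inserts)
  lens <- nchar(inserts)
  cause <- rep(NA_character_, n)
  if (!is.null(quals)) {
    minq <- vapply(seq_len(n), function(i) {
      if (lens[i] == 0L) return(Inf)
      min(utf8ToInt(substr(quals[i], 1L, lens[i]))) - 33
    }, numeric(1))
    cause[is.na(cause) & minq < min_q] <- "low_quality"
  }
  cause[is.na(cause) & grepl("[^ACGT]", inserts)] <- "ambiguous"
  cause[is.na(cause) & lens < min_len] <- "too_short"
  cause[is.na(cause) & lens > max_len] <- "too_long"
  keep <- is.na(cause)
  tally <- table(factor(cause[!keep],
                        levels = c("low_quality", "ambiguous", "too_short", "too_long")))
  list(keep = keep, reads = inserts[keep],
       tally = stats::setNames(as.integer(tally), names(tally)))
}

#' Collapse clean reads into unique tags with per-library counts
#'
#' @param reads_by_library Named list of character vectors of clean inserts,
#'   one per library (canonically WT1, WT2, MT1, MT2).
#' @return A data.frame with column `sequence` and one integer count column
#'   per library; per-library column sums equal the clean read totals.
#' @export
collapse_tags <- function(reads_by_library) {
  stopifnot(is.list(reads_by_library), !is.null(names(reads_by_library)))
  all_seqs <- sort(unique(unlist(reads_by_library, use.names = FALSE)))
  out <- data.frame(sequence = all_seqs, stringsAsFactors = FALSE)
  for (lib in names(reads_by_library)) {
    tb <- table(reads_by_library[[lib]])
    cnt <- integer(length(all_seqs))
    idx <- match(names(tb), all_seqs)
    cnt[idx] <- as.integer(tb)
    out[[lib]] <- cnt
  }
  out
}

#' Read-weighted length distribution of a library's tags
#'
#' @param tags A collapsed tag data.frame from [collapse_tags()].
#' @param library Library column name.
#' @param lengths Length grid to report (default 18:30).
#' @return Named numeric vector of proportions summing to 1.
#' @export
length_distribution <- function(tags, library, lengths = 18:30) {
  if (!library %in% names(tags)) stop("unknown library: ", library)
  counts <- tags[[library]]
  total <- sum(counts)
  if (total == 0L) stop("library ", library, " has no reads")
  len <- nchar(tags$sequence)
  prop <- vapply(lengths, function(L) sum(counts[len == L]) / total, numeric(1))
  stats::setNames(prop, lengths)
}

#' Clean one raw library: 5' contaminant removal, adapter trimming, filtering
#'
#' Applies, in order: quality screening (any base below `min_q` over the raw
#' read drops it once trimmed), 5' contaminant removal (reads whose first
#' 10 nt exactly match the 5' adapter prefix), 3' adapter trimming
#' ([trim_adapter()]; untrimmed reads are discarded as adapter-less), and
#' length/ambiguity filtering ([filter_reads()]).
#'
#' @param seqs,quals Raw read sequences and Phred+33 quality strings (quals
#'   may be NULL).
#' @param adapter3 3' adapter. `adapter5` optional 5' adapter for
#'   contaminant screening.
#' @param min_len,max_len,min_q Passed to [filter_reads()].
#' @return A list with `reads` (clean inserts) and `stats` (raw, clean,
#'   unique totals and the rejection tally).
#' @export
clean_library <- function(seqs, quals = NULL, adapter3, adapter5 = NULL,
                          min_len = 18L, max_len = 30L, min_q = 10L) {
  raw <- length(seqs)
  n_contam <- 0L
  if (!is.null(adapter5) && nchar(adapter5) >= 10L) {
    pre <- substr(adapter5, 1L, 10L)
    contam <- substr(seqs, 1L, 10L) == pre
    n_contam <- sum(contam)
    seqs <- seqs[!contam]
    if (!is.null(quals)) quals <- quals[!contam]
  }
  tr <- trim_adapter(seqs, adapter3)
  n_untrimmed <- sum(!tr$trimmed)
  seqs <- tr$insert[tr$trimmed]
  if (!is.null(quals)) quals <- quals[tr$trimmed]
  fl <- filter_reads(seqs, quals, min_len = min_len, max_len = max_len, min_q = min_q)
  tally <- c(contaminant_5p = n_contam, untrimmed = n_untrimmed, fl$tally)
  list(reads = fl$reads,
       stats = list(raw = raw, clean = length(fl$reads),
                    unique = length(unique(fl$reads)), tally = tally))
}

#' Read a FASTQ file into sequences and quality strings
#'
#' @param path FASTQ path (Phred+33).
#' @return A list with `seq` and `qual` character vectors.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readQualityScaledDNAStringSet(path)
  list(seq = as.character(x), qual = as.character(Biostrings::quality(x)))
}

#' Write collapsed tags as annotated FASTA
#'
#' Headers follow `>tag<N>_WT1:<c1>_WT2:<c2>_MT1:<c3>_MT2:<c4>`.
#'
#' @param tags Collapsed tag data.frame with the four library columns.
#' @param path Output FASTA path.
#' @export
write_tags_fasta <- function(tags, path) {
  hdr <- sprintf("tag%d_%s", seq_len(nrow(tags)),
                 apply(tags[, LIBRARIES, drop = FALSE], 1L, function(r) {
                   paste(sprintf("%s:%d", LIBRARIES, as.integer(r)), collapse = "_")
                 }))
  x <- Biostrings::DNAStringSet(tags$sequence)
  names(x) <- hdr
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
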