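#' Map unique tags to a genome with at most one mismatch
#'
#' Ungapped, substitution-only alignment of each tag against both strands of
#' every scaffold, equivalent to a brute-force scan of all offsets. Minus
#' strand hits are reported at their plus-strand coordinates (leftmost
#' position). Tags with more loci than `max_hits` are flagged
#' hyper-repetitive; their hits beyond the cap are not reported and such
#' tags are excluded from miRNA candidacy downstream.
#'
#' @param tags Character vector of tag sequences, or a collapsed tag
#'   data.frame with a `sequence` column.
#' @param genome A [Biostrings::DNAStringSet] (or FASTA path).
#' @param max_mismatch 0 or 1.
#' @param max_hits Multiplicity cap (default 20).
#' @return A data.frame with columns `tag`, `scaffold`, `start`, `end`
#'   (1-based inclusive), `strand`, `mismatches`, `multiplicity` and
#'   `hyper`.
#' @export
map_tags <- function(tags, genome, max_mismatch = 1L, max_hits = 20L) {
  if (is.data.frame(tags)) tags <- tags$sequence
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (length(genome) == 0L || sum(Biostrings::width(genome)) == 0L) {
    stop("empty genome")
  }
  stopifnot(max_mismatch %in% c(0L, 1L))
  tags <- unique(tags)
  lens <- nchar(tags)
  scaffolds <- names(genome)

  # seed-and-verify: any hit with <= 1 substitution has an exact occurrence
  # of the tag's left or right half; halves are scanned with a PDict (one
  # per half width) and candidate placements verified by mismatch count.
  # This is exactly equivalent to a brute-force all-offsets scan.
  scaf_chars <- lapply(seq_along(genome), function(i) as.character(genome[[i]]))
  names(scaf_chars) <- scaffolds
  batches <- list()

  count_mismatches <- function(a, b) { # equal-length string pairs
    vapply(seq_along(a), function(z) {
      sum(charToRaw(a[z]) != charToRaw(b[z]))
    }, integer(1))
  }

  for (strand in c("+", "-")) {
    pats <- if (strand == "+") tags else
      as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(tags)))
    half <- lens %/% 2L
    seeds <- data.frame(
      tag = rep(tags, 2L), pat = rep(pats, 2L), len = rep(lens, 2L),
      seq = c(substr(pats, 1L, half), substr(pats, half + 1L, lens)),
      offset = c(rep(0L, length(tags)), half), # seed start within pattern
      stringsAsFactors = FALSE)
    seeds$w <- nchar(seeds$seq)
    for (w in unique(seeds$w)) {
      sd <- seeds[seeds$w == w, , drop = FALSE]
      pd <- Biostrings::PDict(Biostrings::DNAStringSet(sd$seq))
      for (sc in scaffolds) {
        subject <- genome[[sc]]
        m <- Biostrings::startIndex(Biostrings::matchPDict(pd, subject))
        n_hits <- lengths(m)
        if (sum(n_hits) == 0L) next
        which_pat <- rep(seq_along(m), n_hits)
        seed_start <- unlist(m, use.names = FALSE)
        full_start <- seed_start - sd$offset[which_pat]
        full_len <- sd$len[which_pat]
        ok <- full_start >= 1L & full_start + full_len - 1L <= length(subject)
        if (!any(ok)) next
        which_pat <- which_pat[ok]
        full_start <- full_start[ok]
        full_len <- full_len[ok]
        gsub_seq <- substring(scaf_chars[[sc]], full_start, full_start + full_len - 1L)
        mm <- count_mismatches(sd$pat[which_pat], gsub_seq)
        keep <- mm <= max_mismatch
        if (!any(keep)) next
        batches[[length(batches) + 1L]] <- data.frame(
          tag = sd$tag[which_pat][keep], scaffold = sc,
          start = full_start[keep], end = (full_start + full_len - 1L)[keep],
          strand = strand, mismatches = mm[keep], stringsAsFactors = FALSE)
      }
    }
  }

  if (length(batches) == 0L) {
    return(data.frame(tag = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0), strand = character(0),
                      mismatches = integer(0), multiplicity = integer(0),
                      hyper = logical(0)))
  }
  out <- do.call(rbind, batches)
  out <- out[!duplicated(out[, c("tag", "scaffold", "start", "strand")]), , drop = FALSE]
  out <- out[order(match(out$tag, tags), out$scaffold, out$start), , drop = FALSE]
  mult <- table(out$tag)
  out$multiplicity <- as.integer(mult[out$tag])
  out$hyper <- out$multiplicity > max_hits
  # report at most max_hits loci per tag
  keep <- unlist(lapply(split(seq_len(nrow(out)), out$tag), function(ix) {
    ix[seq_len(min(length(ix), max_hits))]
  }), use.names = FALSE)
  out <- out[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# precedence order for category assignment; earlier wins
CATEGORY_PRECEDENCE <- c("rRNA", "tRNA", "snRNA", "snoRNA", "other_ncRNA",
                         "repeat", "miRNA_candidate")
CATEGORIES <- c(CATEGORY_PRECEDENCE, "unannotated", "unmapped")

# map annotation feature types onto categories
feature_category <- function(type) {
  type <- as.character(type)
  out <- rep(NA_character_, length(type))
  out[type %in% c("rRNA", "rRNA_gene")] <- "rRNA"
  out[type %in% c("tRNA", "tRNA_gene")] <- "tRNA"
  out[type %in% c("snRNA", "snRNA_gene")] <- "snRNA"
  out[type %in% c("snoRNA", "snoRNA_gene")] <- "snoRNA"
  out[type %in% c("repeat", "repeat_region", "transposable_element",
                  "dispersed_repeat")] <- "repeat"
  out[type %in% c("miRNA", "miRNA_primary_transcript", "pre_miRNA")] <- "miRNA_candidate"
  unknown <- is.na(out)
  if (any(unknown)) {
    warning("unknown feature type(s) treated as other ncRNA: ",
            paste(unique(type[unknown]), collapse = ", "))
    out[unknown] <- "other_ncRNA"
  }
  out
}

#' Classify mapped tags against structural-RNA / repeat annotation
#'
#' Each tag receives exactly one category by the precedence
#' rRNA > tRNA > snRNA > snoRNA > other ncRNA > repeat > miRNA candidate >
#' unannotated; a tag inherits a feature's category when at least half of
#' the tag's length overlaps the feature (at any of its genomic loci). Tags
#' without any alignment are `unmapped`. Unknown feature types are treated
#' as other ncRNA with a warning. Per-library read tallies over the
#' categories partition the library totals.
#'
#' @param alignments Alignment data.frame from [map_tags()].
#' @param annotation A [GenomicRanges::GRanges] with a `type` metadata
#'   column, or a GFF3/BED path.
#' @param tags Collapsed tag data.frame (sequence + library counts).
#' @return A list with `labels` (per-tag data.frame: sequence, category) and
#'   `tally` (category x library read-count matrix, plus a `tags` column of
#'   distinct-tag counts).
#' @export
classify_tags <- function(alignments, annotation, tags) {
  if (is.character(annotation)) annotation <- rtracklayer::import(annotation)
  libs <- setdiff(names(tags), "sequence")

  cat_per_tag <- stats::setNames(rep("unmapped", nrow(tags)), tags$sequence)
  mapped <- unique(alignments$tag[!alignments$hyper])
  hyper <- unique(alignments$tag[alignments$hyper])
  cat_per_tag[names(cat_per_tag) %in% c(mapped, hyper)] <- "unannotated"

  if (length(annotation) > 0L && nrow(alignments) > 0L) {
    feat_type <- annotation$type
    if (is.null(feat_type)) feat_type <- annotation$name # 6-column BED
    feat_cat <- feature_category(feat_type)
    aln_gr <- GenomicRanges::GRanges(alignments$scaffold,
                                     IRanges::IRanges(alignments$start, alignments$end))
    ov <- GenomicRanges::findOverlaps(aln_gr, annotation, ignore.strand = TRUE)
    if (length(ov) > 0L) {
      qh <- S4Vectors::queryHits(ov)
      sh <- S4Vectors::subjectHits(ov)
      inter <- IRanges::pintersect(IRanges::ranges(aln_gr)[qh],
                                   IRanges::ranges(annotation)[sh])
      frac <- IRanges::width(inter) / IRanges::width(IRanges::ranges(aln_gr)[qh])
      keep <- frac >= 0.5
      if (any(keep)) {
        hit_tag <- alignments$tag[qh[keep]]
        hit_cat <- feat_cat[sh[keep]]
        rank <- match(hit_cat, CATEGORY_PRECEDENCE)
        best <- tapply(rank, hit_tag, min)
        assigned <- CATEGORY_PRECEDENCE[best]
        cat_per_tag[names(best)] <- assigned
      }
    }
  }

  labels <- data.frame(sequence = tags$sequence,
                       category = unname(cat_per_tag[tags$sequence]),
                       stringsAsFactors = FALSE)
  tally <- matrix(0L, nrow = length(CATEGORIES), ncol = length(libs),
                  dimnames = list(CATEGORIES, libs))
  ntags <- integer(length(CATEGORIES))
  names(ntags) <- CATEGORIES
  for (cc in CATEGORIES) {
    idx <- labels$category == cc
    ntags[cc] <- sum(idx)
    for (lib in libs) tally[cc, lib] <- sum(tags[[lib]][idx])
  }
  list(labels = labels, tally = cbind(as.data.frame(tally), tags = ntags))
}

#' Tags eligible for miRNA discovery
#'
#' Mapped, non-hyper-repetitive tags whose category is unannotated or miRNA
#' candidate; repeat-derived tags are excluded by default.
#'
#' @param labels Per-tag labels from [classify_tags()].
#' @param alignments Alignments from [map_tags()].
#' @param include_repeats Include repeat-derived tags (default FALSE).
#' @return Character vector of candidate tag sequences.
#' @export
candidate_tags <- function(labels, alignments, include_repeats = FALSE) {
  ok_cat <- c("unannotated", "miRNA_candidate")
  if (include_repeats) ok_cat <- c(ok_cat, "repeat")
  cand <- labels$sequence[labels$category %in% ok_cat]
  hyper <- unique(alignments$tag[alignments$hyper])
  setdiff(intersect(cand, alignments$tag), hyper)
}
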