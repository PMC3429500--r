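#' Assign tags to known mature miRNAs by homology
#'
#' Ungapped comparison of each tag against a reference set of mature
#' miRNAs: references within 2 nt of the tag's length are compared over
#' every full-overlap offset (the shorter sequence slid inside the longer),
#' and the minimum mismatch count over offsets is taken. The best
#' assignment is the reference with the fewest mismatches (ties broken by
#' sorted reference id); assignments above `max_mismatch` are dropped.
#'
#' @param tags Character vector of tag sequences (T/U equivalent).
#' @param reference Named character vector of mature reference sequences
#'   (names are miRNA ids), or a FASTA path in the miRBase mature dialect.
#' @param max_mismatch Maximum allowed mismatches (default 3).
#' @return A data.frame with columns `tag`, `ref_id`, `mismatches`; one row
#'   per assigned tag.
#' @export
match_known <- function(tags, reference, max_mismatch = 3L) {
  if (length(reference) == 1L && is.character(reference) && file.exists(reference)) {
    x <- Biostrings::readBStringSet(reference)
    reference <- stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
  }
  stopifnot(length(reference) > 0L, !is.null(names(reference)))
  reference <- reference[order(names(reference))]
  refs <- toupper(chartr("U", "T", reference))
  tags_dna <- toupper(chartr("U", "T", tags))

  mismatch_count <- function(a, b) {
    # min mismatches over all full-overlap ungapped offsets
    la <- nchar(a); lb <- nchar(b)
    if (abs(la - lb) > 2L) return(NA_integer_)
    if (la > lb) { tmp <- a; a <- b; b <- tmp; tmp <- la; la <- lb; lb <- tmp }
    av <- strsplit(a, "")[[1]]
    best <- la
    for (off in 0:(lb - la)) {
      bv <- strsplit(substr(b, off + 1L, off + la), "")[[1]]
      best <- min(best, sum(av != bv))
    }
    best
  }

  out <- list()
  for (i in seq_along(tags_dna)) {
    mm <- vapply(refs, mismatch_count, integer(1), a = tags_dna[i])
    ok <- which(!is.na(mm) & mm <= max_mismatch)
    if (length(ok) == 0L) next
    best <- ok[which.min(mm[ok])] # ties: first in sorted id order
    out[[length(out) + 1L]] <- data.frame(tag = tags[i],
                                          ref_id = names(refs)[best],
                                          mismatches = as.integer(mm[best]),
                                          stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(tag = character(0), ref_id = character(0),
                      mismatches = integer(0)))
  }
  do.call(rbind, out)
}

#' Excise candidate precursor windows around expressed tag clusters
#'
#' Alignments of candidate tags are merged into clusters (gap up to
#' `cluster_gap` nt on a scaffold); for each cluster two anchored windows
#' are emitted per strand: one extending `flank` nt upstream and one
#' extending `flank` nt downstream of the cluster, covering hairpins whose
#' mature arm is 3' or 5' respectively. Window lengths are clipped to
#' [50, 400] and to scaffold bounds (with a warning at scaffold edges).
#'
#' @param alignments Alignments of candidate tags ([map_tags()] rows).
#' @param genome A [Biostrings::DNAStringSet].
#' @param flank Flank length in nt (default 250).
#' @param cluster_gap Maximum gap between alignments merged into one
#'   cluster (default 30).
#' @return A data.frame of windows: `scaffold`, `start`, `end`, `strand`,
#'   `anchor` (`"up"` or `"down"`), `cluster_start`, `cluster_end`.
#' @export
excise_candidates <- function(alignments, genome, flank = 250L, cluster_gap = 30L) {
  aln <- alignments[!alignments$hyper, , drop = FALSE]
  if (nrow(aln) == 0L) {
    return(data.frame(scaffold = character(0), start = integer(0), end = integer(0),
                      strand = character(0), anchor = character(0),
                      cluster_start = integer(0), cluster_end = integer(0)))
  }
  scaf_len <- stats::setNames(Biostrings::width(genome), names(genome))
  out <- list()
  for (sc in unique(aln$scaffold)) {
    d <- aln[aln$scaffold == sc, , drop = FALSE]
    gr <- IRanges::reduce(IRanges::IRanges(d$start, d$end), min.gapwidth = cluster_gap + 1L)
    for (ci in seq_along(gr)) {
      cs <- IRanges::start(gr)[ci]
      ce <- IRanges::end(gr)[ci]
      for (anchor in c("up", "down")) {
        ws <- if (anchor == "up") cs - flank else cs - 20L
        we <- if (anchor == "up") ce + 20L else ce + flank
        clipped <- ws < 1L || we > scaf_len[[sc]]
        ws <- max(1L, ws)
        we <- min(scaf_len[[sc]], we)
        if (clipped) warning("window near scaffold edge clipped: ", sc, ":", ws, "-", we)
        if (we - ws + 1L > 400L) { # clip the flank side to 400 nt
          if (anchor == "up") ws <- we - 399L else we <- ws + 399L
        }
        if (we - ws + 1L < 50L) { # grow symmetrically to the 50 nt minimum
          pad <- 50L - (we - ws + 1L)
          ws <- max(1L, ws - ceiling(pad / 2))
          we <- min(scaf_len[[sc]], ws + 49L)
        }
        for (strand in c("+", "-")) {
          out[[length(out) + 1L]] <- data.frame(
            scaffold = sc, start = as.integer(ws), end = as.integer(we),
            strand = strand, anchor = anchor,
            cluster_start = cs, cluster_end = ce, stringsAsFactors = FALSE)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# place alignments into window-local coordinates (window read 5'->3' on its
# strand); returns tag, start, end (1-based within window)
tags_in_window <- function(alignments, window) {
  d <- alignments[alignments$scaffold == window$scaffold &
                    alignments$strand == window$strand &
                    alignments$start >= window$start &
                    alignments$end <= window$end, , drop = FALSE]
  if (nrow(d) == 0L) {
    return(data.frame(tag = character(0), start = integer(0), end = integer(0)))
  }
  if (window$strand == "+") {
    data.frame(tag = d$tag, start = d$start - window$start + 1L,
               end = d$end - window$start + 1L, stringsAsFactors = FALSE)
  } else {
    data.frame(tag = d$tag, start = window$end - d$end + 1L,
               end = window$end - d$start + 1L, stringsAsFactors = FALSE)
  }
}

#' Validate a candidate precursor window as a novel miRNA hairpin
#'
#' Implements the community annotation criteria for plant miRNAs: the
#' window must fold into a hairpin in which the mature tag (the most
#' abundant expressed 20-24 nt tag in the window) sits on one arm, a
#' sequenced star tag sits on the opposite arm, and the mature/star duplex
#' inferred from the predicted pairing shows 2-nt 3' overhangs on both
#' strands (+/- 1 nt tolerance), with at most 4 unpaired mature bases in
#' the duplex and at most 2 nt of bulge asymmetry. The precursor (the
#' hairpin span, grown into the window to at least 50 nt) must fold with
#' MFE at or below `mfe_max` and be at most 400 nt.
#'
#' @param window_seq Window sequence, 5'->3' on the window's strand.
#' @param window_tags data.frame of expressed tags placed in window-local
#'   coordinates: columns `tag`, `start`, `end`, `count` (summed read count
#'   across libraries).
#' @param mfe_max Maximum (least negative) acceptable precursor MFE in
#'   kcal/mol; default -18.
#' @param overhang_tol Tolerance around the canonical 2-nt overhang
#'   (default 1).
#' @param fold_fun Folding engine; defaults to [fold()].
#' @return A list: `accepted` (logical); on acceptance `mature`, `star`
#'   (sequences), `mature_range`, `star_range` (window-local), `precursor`
#'   (sequence), `precursor_range`, `mfe`, `structure`; on rejection
#'   `reason` (one of `"unsupported"`, `"no mature"`, `"no star"`,
#'   `"overhang"`, `"duplex pairing"`, `"asymmetry"`, `"mfe"`, `"length"`).
#' @export
validate_hairpin <- function(window_seq, window_tags, mfe_max = -18,
                             overhang_tol = 1L, fold_fun = fold) {
  reject <- function(reason) list(accepted = FALSE, reason = reason)
  if (nrow(window_tags) == 0L) return(reject("unsupported"))
  wlen <- nchar(window_seq)

  wt <- window_tags[nchar(window_tags$tag) >= 20L & nchar(window_tags$tag) <= 24L, ,
                    drop = FALSE]
  if (nrow(wt) == 0L) return(reject("no mature"))
  wt <- wt[order(-wt$count, wt$start), , drop = FALSE]
  mat <- wt[1L, ]
  ms <- mat$start; me <- mat$end

  fb <- fold_fun(window_seq)
  pt <- fb$partner

  m_len <- me - ms + 1L
  if (sum(pt[ms:me] > 0L) < 2L) return(reject("duplex pairing"))

  # candidate star tags: expressed tags not overlapping the mature; the
  # duplex is evaluated against each star tag directly, so stray pairs from
  # the mature into flanking sequence count as unpaired rather than
  # corrupting the arm inference
  others <- window_tags[window_tags$start != ms | window_tags$end != me, , drop = FALSE]
  star_cand <- others[pmax(others$start, ms) > pmin(others$end, me), , drop = FALSE]
  if (nrow(star_cand) == 0L) return(reject("no star"))
  star_cand <- star_cand[order(-star_cand$count), , drop = FALSE]

  ok_star <- NULL
  fail_reason <- "no star"
  for (si in seq_len(nrow(star_cand))) {
    st <- star_cand[si, ]
    ss <- st$start; se <- st$end
    # mature bases paired into this star tag; 2 nt of slack at either end
    # tolerates duplex-end breathing (the overhang test below still pins
    # the geometry)
    into <- which(pt[ms:me] >= ss - 2L & pt[ms:me] <= se + 2L) + ms - 1L
    if (length(into) < 2L) next
    if (m_len - length(into) > 4L) { # > 4 mature bases unpaired in the duplex
      fail_reason <- "duplex pairing"
      next
    }
    i1 <- min(into); i2 <- max(into)
    if (abs((i2 - i1) - (pt[i1] - pt[i2])) > 2L) { # bulge asymmetry
      fail_reason <- "asymmetry"
      next
    }
    # 2-nt 3' overhangs: the star 5' end pairs 2 nt inside the mature 3'
    # end, and symmetrically for the mature 5' end against the star 3' end
    ssp <- ss; while (ssp <= se && !(pt[ssp] >= ms && pt[ssp] <= me)) ssp <- ssp + 1L
    o_m <- (me - pt[ssp]) - (ssp - ss) # mature 3' overhang
    o_s <- (se - pt[i1]) - (i1 - ms)   # star 3' overhang
    if (abs(o_m - 2L) > overhang_tol || abs(o_s - 2L) > overhang_tol) {
      fail_reason <- "overhang"
      next
    }
    ok_star <- st
    break
  }
  if (is.null(ok_star)) return(reject(fail_reason))

  # precursor: hairpin span grown into the window to >= 50 nt
  ps <- min(ms, ok_star$start); pe <- max(me, ok_star$end)
  if (pe - ps + 1L < 50L) {
    pad <- 50L - (pe - ps + 1L)
    ps <- max(1L, ps - ceiling(pad / 2))
    pe <- min(wlen, ps + 49L)
    ps <- max(1L, pe - 49L)
  }
  if (pe - ps + 1L > 400L) return(reject("length"))
  prec_seq <- substr(window_seq, ps, pe)
  prec_fold <- fold_fun(prec_seq)
  if (prec_fold$mfe > mfe_max) return(reject("mfe"))

  list(accepted = TRUE,
       mature = mat$tag, star = ok_star$tag,
       mature_range = c(ms, me), star_range = c(ok_star$start, ok_star$end),
       precursor = prec_seq, precursor_range = c(ps, pe),
       mfe = prec_fold$mfe, structure = prec_fold$structure)
}

#' Discover novel miRNAs from mapped tags
#'
#' Runs hairpin excision ([excise_candidates()]) and validation
#' ([validate_hairpin()]) over all candidate tag clusters and deduplicates
#' accepted hairpins by mature sequence (keeping the lowest-MFE precursor).
#' Novel ids are assigned `Novel01`, `Novel02`, ... in discovery order.
#'
#' @param tags Collapsed tag data.frame (sequence + library counts).
#' @param alignments Alignments from [map_tags()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param candidates Character vector of candidate tag sequences (e.g. from
#'   [candidate_tags()]); defaults to all non-hyper mapped tags.
#' @param flank,mfe_max,overhang_tol,fold_fun Passed to the excision and
#'   validation steps.
#' @return A data.frame of novel calls: `id`, `mature`, `star`, `scaffold`,
#'   `start`, `end`, `strand` (precursor interval, 1-based inclusive),
#'   `mfe`, `structure`, plus one count column per library.
#' @export
discover_novel <- function(tags, alignments, genome, candidates = NULL,
                           flank = 250L, mfe_max = -18, overhang_tol = 1L,
                           fold_fun = fold) {
  libs <- setdiff(names(tags), "sequence")
  if (is.null(candidates)) candidates <- unique(alignments$tag[!alignments$hyper])
  cand_aln <- alignments[alignments$tag %in% candidates & !alignments$hyper, , drop = FALSE]
  windows <- excise_candidates(cand_aln, genome, flank = flank)
  if (nrow(windows) == 0L) windows <- windows[0L, , drop = FALSE]

  counts <- stats::setNames(rowSums(tags[, libs, drop = FALSE]), tags$sequence)
  calls <- list()
  for (wi in seq_len(nrow(windows))) {
    w <- windows[wi, ]
    placed <- tags_in_window(alignments, w)
    if (nrow(placed) == 0L) next
    placed$count <- unname(counts[placed$tag])
    placed <- placed[!is.na(placed$count), , drop = FALSE]
    # the mature must come from the candidate set
    if (!any(placed$tag %in% candidates)) next
    seq_plus <- as.character(Biostrings::subseq(genome[[w$scaffold]], w$start, w$end))
    wseq <- if (w$strand == "+") seq_plus else revcomp(seq_plus)
    v <- validate_hairpin(wseq, placed, mfe_max = mfe_max,
                          overhang_tol = overhang_tol, fold_fun = fold_fun)
    if (!isTRUE(v$accepted)) next
    if (!v$mature %in% candidates) next
    # precursor interval back on genome coordinates
    if (w$strand == "+") {
      gs <- w$start + v$precursor_range[1L] - 1L
      ge <- w$start + v$precursor_range[2L] - 1L
    } else {
      ge <- w$end - v$precursor_range[1L] + 1L
      gs <- w$end - v$precursor_range[2L] + 1L
    }
    calls[[length(calls) + 1L]] <- data.frame(
      mature = v$mature, star = v$star, scaffold = w$scaffold,
      start = gs, end = ge, strand = w$strand, mfe = v$mfe,
      structure = v$structure, stringsAsFactors = FALSE)
  }
  if (length(calls) == 0L) {
    out <- data.frame(id = character(0), mature = character(0), star = character(0),
                      scaffold = character(0), start = integer(0), end = integer(0),
                      strand = character(0), mfe = numeric(0), structure = character(0))
    for (lib in libs) out[[lib]] <- integer(0)
    return(out)
  }
  d <- do.call(rbind, calls)
  # deduplicate by mature sequence, keeping the most stable precursor
  d <- d[order(d$mature, d$mfe), , drop = FALSE]
  d <- d[!duplicated(d$mature), , drop = FALSE]
  # one call per genomic locus: overlapping precursor intervals (either
  # strand) are the same hairpin seen from mirrored windows; keep the call
  # whose mature has the strongest read support
  d$support <- unname(counts[d$mature])
  gr <- GenomicRanges::GRanges(d$scaffold, IRanges::IRanges(d$start, d$end))
  grp <- GenomicRanges::findOverlaps(gr, GenomicRanges::reduce(gr, ignore.strand = TRUE),
                                     ignore.strand = TRUE)
  d$locus_group <- S4Vectors::subjectHits(grp)[match(seq_len(nrow(d)),
                                                     S4Vectors::queryHits(grp))]
  d <- d[order(d$locus_group, -d$support, d$mfe), , drop = FALSE]
  d <- d[!duplicated(d$locus_group), , drop = FALSE]
  d$support <- NULL
  d$locus_group <- NULL
  d <- d[order(d$scaffold, d$start), , drop = FALSE]
  d$id <- sprintf("Novel%02d", seq_len(nrow(d)))
  idx <- match(d$mature, tags$sequence)
  for (lib in libs) d[[lib]] <- tags[[lib]][idx]
  rownames(d) <- NULL
  d[, c("id", "mature", "star", "scaffold", "start", "end", "strand",
        "mfe", "structure", libs)]
}

#' Summarize precursor lengths and folding energies
#'
#' Works on a novel-miRNA catalog (columns `start`, `end`, `mfe`; lengths
#' from 1-based inclusive coordinates as end - start + 1) or on any
#' data.frame with `length` and `mfe` columns.
#'
#' @param records Catalog or candidate data.frame.
#' @return A list with `count`, `length` (min/max/mean) and `mfe`
#'   (min/max/mean).
#' @export
summarize_precursors <- function(records) {
  if (nrow(records) == 0L) stop("empty record set")
  len <- if ("length" %in% names(records)) records$length else records$end - records$start + 1L
  list(count = nrow(records),
       length = c(min = min(len), max = max(len), mean = mean(len)),
       mfe = c(min = min(records$mfe), max = max(records$mfe), mean = mean(records$mfe)))
}

# family label: strip a trailing star flag, a species prefix and letter
# suffixes (miR166e -> miR166, csi-miR482a* -> miR482)
mirna_family <- function(id) {
  core <- sub("\\*$", "", id)
  core <- sub("^[A-Za-z]{2,4}-", "", core)
  fam <- sub("([a-z]+)$", "", core)
  fam
}

#' Compose the miRNA catalog from conserved and novel calls
#'
#' Conserved calls are grouped into families by their reference ids with
#' trailing letter variants stripped (miR166a and miR166e both join family
#' miR166); star references are tracked with a star flag on the same
#' family. If the same mature sequence is called both conserved and novel,
#' the conserved call wins with a warning.
#'
#' @param conserved data.frame from [match_known()] joined with counts:
#'   columns `tag`, `ref_id`, `mismatches` (and optionally library counts).
#' @param novel data.frame from [discover_novel()].
#' @return A data.frame catalog: `id`, `class` (`conserved` or `novel`),
#'   `family`, `mature`, `star_flag`, `mismatches_to_reference`.
#' @export
compose_catalog <- function(conserved, novel) {
  rows <- list()
  if (!is.null(conserved) && nrow(conserved) > 0L) {
    rows[[1L]] <- data.frame(
      id = conserved$ref_id, class = "conserved",
      family = mirna_family(conserved$ref_id), mature = conserved$tag,
      star_flag = grepl("\\*$", conserved$ref_id),
      mismatches_to_reference = conserved$mismatches, stringsAsFactors = FALSE)
  }
  if (!is.null(novel) && nrow(novel) > 0L) {
    nv <- data.frame(
      id = novel$id, class = "novel", family = novel$id, mature = novel$mature,
      star_flag = FALSE, mismatches_to_reference = NA_integer_,
      stringsAsFactors = FALSE)
    if (length(rows) && any(nv$mature %in% rows[[1L]]$mature)) {
      clash <- nv$mature %in% rows[[1L]]$mature
      warning("mature sequence(s) called both conserved and novel; keeping conserved: ",
              paste(nv$id[clash], collapse = ", "))
      nv <- nv[!clash, , drop = FALSE]
    }
    rows[[length(rows) + 1L]] <- nv
  }
  if (length(rows) == 0L) {
    return(data.frame(id = character(0), class = character(0), family = character(0),
                      mature = character(0), star_flag = logical(0),
                      mismatches_to_reference = integer(0)))
  }
  out <- do.call(rbind, rows)
  out <- out[!duplicated(out$mature), , drop = FALSE]
  rownames(out) <- NULL
  out
}
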