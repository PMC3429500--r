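#' Score a miRNA against an equal-length candidate site
#'
#' Positions are indexed from the miRNA 5' end; position i of the miRNA is
#' compared against position `L + 1 - i` of the site (the site is given
#' 5'->3' in transcript orientation, and the duplex is antiparallel).
#' Watson-Crick pairs score 0 (`|`), G:U wobbles 0.5 (`o`), and mismatches
#' 1.0 (`x`); the penalty is the per-position sum. No gaps are modelled.
#'
#' @param mirna miRNA sequence 5'->3' (RNA or DNA alphabet).
#' @param site Site sequence 5'->3' on the transcript, same length.
#' @return A list with `pattern` (string over `|`, `o`, `x`, indexed by
#'   miRNA position) and `penalty`.
#' @export
score_site <- function(mirna, site) {
  mirna <- toupper(chartr("U", "T", mirna))
  site <- toupper(chartr("U", "T", site))
  L <- nchar(mirna)
  if (nchar(site) != L) stop("site length must equal miRNA length")
  mb <- strsplit(mirna, "")[[1]]
  sb <- rev(strsplit(site, "")[[1]]) # antiparallel
  sym <- character(L)
  for (i in seq_len(L)) {
    p <- paste0(mb[i], sb[i])
    sym[i] <- if (p %in% c("AT", "TA", "GC", "CG")) "|"
    else if (p %in% c("GT", "TG")) "o"
    else "x"
  }
  penalty <- sum((sym == "o") * 0.5 + (sym == "x") * 1.0)
  list(pattern = paste(sym, collapse = ""), penalty = penalty)
}

#' Positional mismatch constraints for a scored miRNA/site alignment
#'
#' Accepts an alignment iff all of the following hold: total penalty at
#' most `penalty_max` (default 2, with G:U wobbles scoring 0.5); at most
#' one mismatch over miRNA positions 2-11; no mismatch at the cleavage
#' site (positions 10 and 11); at most three mismatches over positions
#' 12-21 with no run of more than two consecutive mismatches there; and at
#' most four mismatches overall. Position 12 is counted in the 12-21
#' regime only. Gapped alignments are not represented at all.
#'
#' @param alignment A list with `pattern` and `penalty` from
#'   [score_site()], or a pattern string.
#' @param penalty_max Penalty cap (default 2).
#' @return A list with `accept` (logical) and `reason` (`NA` on
#'   acceptance; otherwise one of `"penalty"`, `"cleavage site"`,
#'   `"seed mismatches"`, `"3' mismatches"`, `"consecutive"`, `"total
#'   mismatches"`).
#' @export
positional_constraints <- function(alignment, penalty_max = 2) {
  if (is.character(alignment)) {
    pat <- alignment
    penalty <- sum(strsplit(pat, "")[[1]] == "o") * 0.5 +
      sum(strsplit(pat, "")[[1]] == "x")
  } else {
    pat <- alignment$pattern
    penalty <- alignment$penalty
  }
  v <- strsplit(pat, "")[[1]]
  L <- length(v)
  x <- v == "x"
  fail <- function(reason) list(accept = FALSE, reason = reason)
  if (any(x[intersect(10:11, seq_len(L))])) return(fail("cleavage site"))
  if (sum(x[intersect(2:11, seq_len(L))]) > 1L) return(fail("seed mismatches"))
  reg <- intersect(12:21, seq_len(L))
  if (sum(x[reg]) > 3L) return(fail("3' mismatches"))
  if (length(reg) > 0L) {
    r <- rle(x[reg])
    if (any(r$values & r$lengths > 2L)) return(fail("consecutive"))
  }
  if (sum(x) > 4L) return(fail("total mismatches"))
  if (penalty > penalty_max) return(fail("penalty"))
  list(accept = TRUE, reason = NA_character_)
}

#' Duplex hybridization energy and energy ratio
#'
#' Applies the folding module's stacking energies to the ungapped duplex:
#' each paired position contributes its pair energy (G-C -3, A-U -2,
#' G-U -1 kcal/mol) once for every adjacent position that is also paired
#' counted on its 3' side. The energy ratio divides by the energy of the
#' perfect Watson-Crick duplex of the same miRNA, so it lies in [0, 1] and
#' is monotone non-increasing as pairs are lost.
#'
#' @param alignment A list with `pattern` from [score_site()].
#' @param mirna The miRNA sequence (5'->3').
#' @return A list with `delta_g` (kcal/mol, <= 0) and `energy_ratio`.
#' @export
duplex_energy <- function(alignment, mirna) {
  mirna <- toupper(chartr("U", "T", mirna))
  mb <- strsplit(mirna, "")[[1]]
  pat <- strsplit(alignment$pattern, "")[[1]]
  L <- length(mb)
  pair_e <- function(i, sym) {
    if (sym == "o") return(-1)
    if (mb[i] %in% c("G", "C")) -3 else -2
  }
  stack_sum <- function(symbols) {
    e <- 0
    for (i in seq_len(L - 1L)) {
      if (symbols[i] != "x" && symbols[i + 1L] != "x") {
        e <- e + pair_e(i, symbols[i])
      }
    }
    e
  }
  dg <- stack_sum(pat)
  dg_perfect <- stack_sum(rep("|", L))
  ratio <- if (dg_perfect == 0) 0 else dg / dg_perfect
  list(delta_g = dg, energy_ratio = ratio)
}

#' Scan a transcript for miRNA target sites
#'
#' Tests every window of miRNA length with [score_site()] and
#' [positional_constraints()]; accepted windows are annotated with their
#' region (5'UTR, ORF or 3'UTR by the window midpoint against the coding
#' region boundaries) and duplex energy. Multiple sites per transcript are
#' allowed.
#'
#' @param mirna miRNA sequence (5'->3').
#' @param transcript Transcript sequence (5'->3'), at least as long as the
#'   miRNA.
#' @param cds_start,cds_end 1-based first/last coding positions; when
#'   missing all sites are labelled ORF with a warning.
#' @param penalty_max Penalty cap passed to [positional_constraints()].
#' @return A data.frame of sites: `start`, `end`, `region`, `pattern`,
#'   `penalty`, `delta_g`, `energy_ratio`.
#' @export
scan_transcript <- function(mirna, transcript, cds_start = NA, cds_end = NA,
                            penalty_max = 2) {
  mirna <- toupper(chartr("U", "T", mirna))
  transcript <- toupper(chartr("U", "T", transcript))
  L <- nchar(mirna)
  Tn <- nchar(transcript)
  if (Tn < L) stop("transcript shorter than miRNA")
  no_utr <- is.na(cds_start) || is.na(cds_end)
  if (no_utr) warning("missing UTR annotation: all sites labelled ORF")

  mb <- strsplit(mirna, "")[[1]]
  tb <- strsplit(transcript, "")[[1]]
  nw <- Tn - L + 1L
  # vectorized per miRNA position across all windows
  penalty <- numeric(nw)
  xmat <- matrix(FALSE, nrow = nw, ncol = L)
  omat <- matrix(FALSE, nrow = nw, ncol = L)
  for (i in seq_len(L)) {
    sc <- tb[seq_len(nw) + (L - i)] # site base opposite miRNA position i
    p <- paste0(mb[i], sc)
    is_pair <- p %in% c("AT", "TA", "GC", "CG")
    is_wob <- p %in% c("GT", "TG")
    omat[, i] <- is_wob
    xmat[, i] <- !(is_pair | is_wob)
  }
  penalty <- rowSums(xmat) + 0.5 * rowSums(omat)

  out <- list()
  for (w in which(penalty <= penalty_max)) { # acceptance requires this anyway
    sym <- ifelse(xmat[w, ], "x", ifelse(omat[w, ], "o", "|"))
    aln <- list(pattern = paste(sym, collapse = ""), penalty = penalty[w])
    ok <- positional_constraints(aln, penalty_max = penalty_max)
    if (!ok$accept) next
    mid <- w + (L - 1L) / 2
    region <- if (no_utr) "ORF"
    else if (mid < cds_start) "5'UTR"
    else if (mid > cds_end) "3'UTR"
    else "ORF"
    en <- duplex_energy(aln, mirna)
    out[[length(out) + 1L]] <- data.frame(
      start = w, end = w + L - 1L, region = region, pattern = aln$pattern,
      penalty = aln$penalty, delta_g = en$delta_g,
      energy_ratio = en$energy_ratio, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(0), end = integer(0), region = character(0),
                      pattern = character(0), penalty = numeric(0),
                      delta_g = numeric(0), energy_ratio = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Aggregate predicted target sites per gene and per miRNA
#'
#' @param sites A data.frame with at least `mirna_id` and `gene_id` columns
#'   (one row per predicted site).
#' @return A list with `sites_per_gene`, `genes_per_mirna` (named integer
#'   vectors), `multi_site_genes` (genes with >= 2 sites) and
#'   `multi_mirna_genes` (genes targeted by >= 2 distinct miRNAs).
#' @export
aggregate_targets <- function(sites) {
  if (nrow(sites) == 0L) {
    return(list(sites_per_gene = integer(0), genes_per_mirna = integer(0),
                multi_site_genes = character(0), multi_mirna_genes = character(0)))
  }
  spg <- table(sites$gene_id)
  gpm <- vapply(split(sites$gene_id, sites$mirna_id),
                function(g) length(unique(g)), integer(1))
  mpg <- vapply(split(sites$mirna_id, sites$gene_id),
                function(m) length(unique(m)), integer(1))
  list(sites_per_gene = stats::setNames(as.integer(spg), names(spg)),
       genes_per_mirna = gpm,
       multi_site_genes = names(spg)[spg >= 2L],
       multi_mirna_genes = names(mpg)[mpg >= 2L])
}
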