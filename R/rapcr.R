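#' Region ratios for regional-amplification qPCR (RA-PCR)
#'
#' RA-PCR quantifies three amplicons of a candidate target mRNA (5',
#' middle containing the predicted target site, and 3'). After
#' miRNA-guided cleavage, poly(T)-primed reverse transcription only copies
#' the 3' fragment, so the middle (and 5') amplicons are depleted relative
#' to the 3' amplicon. Ratios are middle/3' and 5'/3'; a missing 5'
#' quantity (site in the 5' UTR) yields the middle ratio only.
#'
#' @param q5 Relative quantity of the 5' amplicon (may be `NA`).
#' @param qmid,q3 Relative quantities of the middle and 3' amplicons;
#'   `q3` must be positive.
#' @return A list with `mid_3p` and `five_3p` (NA when `q5` is missing).
#' @export
region_ratios <- function(q5, qmid, q3) {
  if (any(q3 <= 0)) stop("3' quantity must be positive for ratio computation")
  stopifnot(all(qmid >= 0), all(is.na(q5) | q5 >= 0))
  list(mid_3p = qmid / q3, five_3p = ifelse(is.na(q5), NA_real_, q5 / q3))
}

#' Call miRNA-guided cleavage support from RA-PCR quantities
#'
#' A transcript is supported iff the middle/3' ratio is below `threshold`
#' in every provided sample; the observed min-max ratio range is reported.
#'
#' @param quant A data.frame with columns `transcript`, `sample`, `q5`
#'   (may be NA), `qmid`, `q3`.
#' @param threshold Support threshold on middle/3' (default 0.6, above the
#'   largest ratio reported for cleaved targets and below 1).
#' @return A data.frame per transcript: `transcript`, `n_samples`,
#'   `supported`, `ratio_min`, `ratio_max`.
#' @export
cleavage_call <- function(quant, threshold = 0.6) {
  stopifnot(nrow(quant) >= 1L)
  out <- lapply(split(quant, quant$transcript), function(d) {
    r <- region_ratios(d$q5, d$qmid, d$q3)$mid_3p
    data.frame(transcript = d$transcript[1L], n_samples = nrow(d),
               supported = all(r < threshold),
               ratio_min = min(r), ratio_max = max(r), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read RA-PCR region quantities from TSV
#'
#' Expected columns: transcript, sample, q5, qmid, q3.
#'
#' @param path TSV path.
#' @return A data.frame.
#' @export
read_region_quant <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript", "sample", "q5", "qmid", "q3")
  if (!all(need %in% names(x))) {
    stop("region quantity table missing columns: ",
         paste(setdiff(need, names(x)), collapse = ", "))
  }
  x
}
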