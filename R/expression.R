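#' Reads-per-million normalization
#'
#' RPM(i, lib) = count(i, lib) * 1e6 / library_size(lib). Raw counts are
#' retained alongside.
#'
#' @param counts Matrix or data.frame of non-negative counts (rows = miRNA
#'   ids, columns = libraries WT1, WT2, MT1, MT2).
#' @param library_sizes Named numeric vector of library sizes (> 0), in the
#'   same column order; defaults to the column sums.
#' @return A list of class `expression_matrix` with `counts`, `rpm` and
#'   `library_sizes`.
#' @export
normalize_rpm <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  stopifnot(length(library_sizes) == ncol(counts))
  rpm <- sweep(counts, 2L, library_sizes, function(c, n) c * 1e6 / n)
  structure(list(counts = counts, rpm = rpm, library_sizes = library_sizes),
            class = "expression_matrix")
}

#' Stage-wise regulation call for one genotype
#'
#' For each row, compares stage 1 (juvenile) against stage 2 (adult):
#' direction is `down` when stage 2 < stage 1, `up` when stage 2 > stage 1,
#' `unchanged` when equal; a zero in exactly one stage yields the
#' stage-only classes and zeros in both yield `absent`. The differential
#' flag marks ratios (stage2/stage1) above `fold` or below `1/fold`, and
#' every stage-only class.
#'
#' @param stage1,stage2 Non-negative expression values (RPM or raw counts)
#'   of the two stages.
#' @param fold Fold-change threshold (default 2).
#' @param ids Optional row ids.
#' @return A data.frame with `id`, `direction`, `ratio`, `differential`.
#' @export
regulation_call <- function(stage1, stage2, fold = 2, ids = NULL) {
  stopifnot(length(stage1) == length(stage2), all(stage1 >= 0), all(stage2 >= 0))
  n <- length(stage1)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  direction <- character(n)
  direction[stage2 < stage1] <- "down"
  direction[stage2 > stage1] <- "up"
  direction[stage2 == stage1] <- "unchanged"
  direction[stage1 == 0 & stage2 > 0] <- "stage2-only"
  direction[stage1 > 0 & stage2 == 0] <- "stage1-only"
  direction[stage1 == 0 & stage2 == 0] <- "absent"
  ratio <- ifelse(stage1 == 0 & stage2 == 0, NaN, stage2 / stage1)
  differential <- (is.finite(ratio) & (ratio > fold | ratio < 1 / fold)) |
    direction %in% c("stage1-only", "stage2-only")
  data.frame(id = ids, direction = direction, ratio = ratio,
             differential = differential, stringsAsFactors = FALSE)
}

#' Genotype presence/absence pattern across the four libraries
#'
#' Partitions rows into MT-only (both WT libraries zero, some MT reads),
#' WT-only (symmetric), shared (reads in both genotypes) and absent.
#'
#' @param counts Matrix or data.frame with columns WT1, WT2, MT1, MT2.
#' @return A factor with levels `MT-only`, `WT-only`, `shared`, `absent`.
#' @export
presence_pattern <- function(counts) {
  counts <- as.matrix(counts[, LIBRARIES, drop = FALSE])
  wt <- counts[, "WT1"] + counts[, "WT2"]
  mt <- counts[, "MT1"] + counts[, "MT2"]
  out <- ifelse(wt == 0 & mt > 0, "MT-only",
                ifelse(mt == 0 & wt > 0, "WT-only",
                       ifelse(mt > 0 & wt > 0, "shared", "absent")))
  factor(out, levels = c("MT-only", "WT-only", "shared", "absent"))
}

#' miRNAs with inverse regulation between genotypes
#'
#' Returns the ids whose stage-wise direction is `up` in one genotype and
#' `down` in the other; stage-only, unchanged and absent rows are excluded.
#'
#' @param call_mt,call_wt Regulation calls from [regulation_call()] for the
#'   MT and WT genotype, aligned by row.
#' @return Character vector of ids.
#' @export
inverse_pattern <- function(call_mt, call_wt) {
  stopifnot(nrow(call_mt) == nrow(call_wt))
  inv <- (call_mt$direction == "up" & call_wt$direction == "down") |
    (call_mt$direction == "down" & call_wt$direction == "up")
  call_mt$id[inv]
}

#' Stage-wise regulation for both genotypes of an expression matrix
#'
#' @param em An `expression_matrix` from [normalize_rpm()].
#' @param fold Fold-change threshold.
#' @param use Use `"rpm"` (default) or `"counts"` for the ratios.
#' @return A list with `MT` and `WT` regulation call data.frames and
#'   `inverse` (ids with opposite directions).
#' @export
genotype_regulation <- function(em, fold = 2, use = c("rpm", "counts")) {
  use <- match.arg(use)
  m <- em[[use]]
  ids <- rownames(m)
  mt <- regulation_call(m[, "MT1"], m[, "MT2"], fold = fold, ids = ids)
  wt <- regulation_call(m[, "WT1"], m[, "WT2"], fold = fold, ids = ids)
  list(MT = mt, WT = wt, inverse = inverse_pattern(mt, wt))
}

#' Export a log2(RPM + 1) matrix for external clustering/heatmaps
#'
#' @param em An `expression_matrix`.
#' @param path Optional TSV output path.
#' @return The log2(RPM + 1) matrix, invisibly if written to `path`.
#' @export
clustering_export <- function(em, path = NULL) {
  m <- log2(em$rpm + 1)
  if (!is.null(path)) {
    utils::write.table(data.frame(id = rownames(m), m, check.names = FALSE),
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(m))
  }
  m
}
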