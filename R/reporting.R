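#' Roll up functional annotation terms over a target gene list
#'
#' Counts, within each namespace (biological process, cellular component,
#' molecular function, or e.g. "pathway" for KEGG-style rollups), how many
#' genes of the input list carry each term. A gene with several terms
#' counts once per term; genes absent from the mapping are tallied as
#' `unannotated`.
#'
#' @param genes Character vector of gene ids.
#' @param mapping A data.frame with columns `gene`, `term`, `namespace`, or
#'   a TSV path with those columns (gene TAB term TAB namespace).
#' @param namespace Optional namespace filter.
#' @return A list per namespace of data.frames (`term`, `count`) sorted by
#'   descending count, plus an `unannotated` count.
#' @export
go_rollup <- function(genes, mapping, namespace = NULL) {
  if (is.character(mapping)) mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "term", "namespace") %in% names(mapping)))
  genes <- unique(genes)
  m <- mapping[mapping$gene %in% genes, , drop = FALSE]
  m <- unique(m[, c("gene", "term", "namespace")])
  if (!is.null(namespace)) m <- m[m$namespace %in% namespace, , drop = FALSE]
  out <- lapply(split(m, m$namespace), function(d) {
    tb <- sort(table(d$term), decreasing = TRUE)
    data.frame(term = names(tb), count = as.integer(tb), stringsAsFactors = FALSE)
  })
  out$unannotated <- sum(!genes %in% mapping$gene)
  out
}

validate_config <- function(config) {
  defaults <- list(
    seed = 1L, adapter3 = "TCGTATGCCGTCTTCTGCTTG", adapter5 = NULL,
    total_reads = 10000L, error_rate = 0.001,
    min_len = 18L, max_len = 30L, min_q = 10L,
    max_mismatch = 1L, max_hits = 20L,
    flank = 250L, mfe_max = -18, overhang_tol = 1L,
    fold_threshold = 2, penalty_max = 2, rapcr_threshold = 0.6,
    reference = NULL, transcripts = NULL, rapcr_quant = NULL,
    go_mapping = NULL, fixture = FALSE, out_dir = NULL)
  config <- utils::modifyList(defaults, config)
  with(config, {
    stopifnot(error_rate >= 0, error_rate <= 0.05,
              max_mismatch %in% c(0L, 1L),
              mfe_max < 0, penalty_max > 0,
              rapcr_threshold > 0, rapcr_threshold <= 1,
              fold_threshold > 1,
              min_len >= 1L, max_len >= min_len)
  })
  config
}

#' Run the full pipeline from a configuration list
#'
#' Executes, in dependency order: simulation (or FASTQ loading), cleanup
#' and collapsing, mapping, classification, novel (and optionally
#' conserved) miRNA discovery, expression profiling, and - when the
#' corresponding inputs are present in the configuration - target
#' prediction, RA-PCR cleavage calls, annotation rollup and the packaged
#' catalog census. The run is deterministic for a fixed `seed`; every
#' threshold used is echoed into the report.
#'
#' @param config A named list. Core fields: either `genome_loci` +
#'   `scaffold_lengths` (simulation) or `fastq` (named list/vector of four
#'   FASTQ paths) + `genome` (FASTA path or DNAStringSet) + `annotation`
#'   (GFF3 path or GRanges). Optional: `reference` (known mature miRNA
#'   FASTA or named vector), `rapcr_quant` (TSV path or data.frame),
#'   `go_mapping`, `fixture` (TRUE to include the packaged catalog
#'   census), `out_dir` (write TSV/JSON outputs), plus thresholds (`seed`,
#'   `adapter3`, `total_reads`, `error_rate`, `min_len`, `max_len`,
#'   `min_q`, `max_mismatch`, `max_hits`, `flank`, `mfe_max`,
#'   `fold_threshold`, `penalty_max`, `rapcr_threshold`).
#' @return A report list with per-stage blocks (`library_stats`, `tags`,
#'   `classification`, `novel`, `conserved`, `expression`, and optional
#'   `targets`, `rapcr`, `go`, `fixture_summary`), and `thresholds`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  report <- list(thresholds = config[c("seed", "adapter3", "total_reads",
                                       "error_rate", "min_len", "max_len", "min_q",
                                       "max_mismatch", "max_hits", "flank", "mfe_max",
                                       "fold_threshold", "penalty_max",
                                       "rapcr_threshold")])

  # --- inputs: simulate or load ------------------------------------------
  if (!is.null(config$genome_loci)) {
    gen <- generate_genome(config$genome_loci, config$scaffold_lengths,
                           seed = config$seed)
    sim <- simulate_libraries(gen, adapter3 = config$adapter3,
                              total_reads = config$total_reads,
                              error_rate = config$error_rate, seed = config$seed)
    raw <- lapply(sim$reads, function(x) list(seq = x$seq, qual = x$qual))
    genome <- gen$genome
    annotation <- annotation_features(gen)
    report$truth <- sim$truth
  } else {
    if (is.null(config$fastq) || is.null(config$genome)) {
      stop("config must provide either genome_loci/scaffold_lengths or fastq + genome")
    }
    raw <- lapply(config$fastq, read_fastq)
    names(raw) <- LIBRARIES
    genome <- if (is.character(config$genome)) {
      Biostrings::readDNAStringSet(config$genome)
    } else config$genome
    annotation <- if (is.character(config$annotation)) {
      rtracklayer::import(config$annotation)
    } else config$annotation
  }

  # --- cleanup and collapsing --------------------------------------------
  cleaned <- lapply(raw, function(x) {
    clean_library(x$seq, x$qual, adapter3 = config$adapter3,
                  adapter5 = config$adapter5, min_len = config$min_len,
                  max_len = config$max_len, min_q = config$min_q)
  })
  names(cleaned) <- LIBRARIES
  report$library_stats <- lapply(cleaned, `[[`, "stats")
  tags <- collapse_tags(lapply(cleaned, `[[`, "reads"))
  report$tags <- tags

  # --- mapping and classification ----------------------------------------
  aln <- map_tags(tags, genome, max_mismatch = config$max_mismatch,
                  max_hits = config$max_hits)
  cls <- classify_tags(aln, annotation, tags)
  report$classification <- cls$tally
  cand <- candidate_tags(cls$labels, aln)

  # --- discovery ----------------------------------------------------------
  novel <- discover_novel(tags, aln, genome, candidates = cand,
                          flank = config$flank, mfe_max = config$mfe_max)
  report$novel <- novel
  conserved <- NULL
  if (!is.null(config$reference)) {
    conserved <- match_known(cand, config$reference)
    report$conserved <- conserved
  }
  report$catalog <- compose_catalog(conserved, novel)

  # --- expression profiling ----------------------------------------------
  if (nrow(novel) > 0L) {
    cm <- as.matrix(novel[, LIBRARIES, drop = FALSE])
    rownames(cm) <- novel$id
    lib_sizes <- vapply(cleaned, function(x) max(1L, x$stats$clean), numeric(1))
    em <- normalize_rpm(cm, lib_sizes)
    report$expression <- list(
      matrix = em,
      regulation = genotype_regulation(em, fold = config$fold_threshold),
      presence = table(presence_pattern(cm)))
  }

  # --- optional stages -----------------------------------------------------
  if (!is.null(config$rapcr_quant)) {
    q <- if (is.character(config$rapcr_quant)) read_region_quant(config$rapcr_quant)
    else config$rapcr_quant
    report$rapcr <- cleavage_call(q, threshold = config$rapcr_threshold)
  }
  if (!is.null(config$go_mapping) && !is.null(config$target_genes)) {
    report$go <- go_rollup(config$target_genes, config$go_mapping)
  }
  if (isTRUE(config$fixture)) {
    cat75 <- load_novel_catalog()
    report$fixture_summary <- list(
      precursors = summarize_precursors(cat75),
      presence = table(presence_pattern(stats::setNames(
        cat75[, c("wt1", "wt2", "mt1", "mt2")], LIBRARIES))),
      max_count = max(cat75$wt1, cat75$wt2, cat75$mt1, cat75$mt2))
  }

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(report$tags, file.path(out_dir, "tags.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$novel, file.path(out_dir, "novel_mirnas.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(report$classification, file.path(out_dir, "categories.tsv"),
                     sep = "\t", quote = FALSE, row.names = TRUE)
  stats_json <- lapply(report$library_stats, function(s) {
    s$tally <- as.list(s$tally)
    s
  })
  jsonlite::write_json(stats_json, file.path(out_dir, "library_stats.json"),
                       auto_unbox = TRUE)
  invisible(out_dir)
}
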