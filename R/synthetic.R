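#' Construct a designed hairpin precursor around a mature miRNA
#'
#' Builds a precursor of length `2 * nchar(mature) + loop_len` whose 5' arm
#' is the mature sequence and whose 3' arm is a (possibly mismatched) star
#' strand positioned so that the excised mature/star duplex carries the
#' canonical 2-nt 3' overhang on both strands: the mature's two 3'-terminal
#' bases are unpaired next to the loop and the star's two 3'-terminal bases
#' dangle at the precursor end.
#'
#' @param mature Mature miRNA sequence, 20-24 nt (RNA or DNA alphabet).
#' @param loop_len Hairpin loop length in nt, at least 3.
#' @param n_mismatches Number of substitutions to introduce into the star
#'   strand (0-4), at interior duplex positions.
#' @param seed Integer seed controlling mismatch placement.
#' @return A list with `precursor` (DNA string), `mature`, `star`,
#'   and 1-based precursor coordinates `mature_start`, `mature_end`,
#'   `star_start`, `star_end`.
#' @export
build_hairpin_precursor <- function(mature, loop_len, n_mismatches = 0L, seed = 1L) {
  mature <- toupper(chartr("U", "T", mature))
  m <- nchar(mature)
  stopifnot(m >= 20L, m <= 24L)
  if (loop_len < 3L) stop("loop_len must be >= 3 (cannot form a hairpin loop)")
  if (n_mismatches > 4L) stop("n_mismatches must be <= 4")
  mb <- strsplit(mature, "")[[1]]

  # star core pairs mature[1..m-2]; star's own 2-nt 3' overhang appended
  star <- strsplit(revcomp(substr(mature, 1L, m - 2L)), "")[[1]]

  # overhang bases chosen not to extend the stem (avoid pairing with the
  # mature 5' end, which would shift the duplex register)
  pick_overhang <- function(opposite) {
    score <- vapply(c("A", "C", "G", "T"), function(b) {
      sum(vapply(opposite, function(o) {
        if (comp_base(o) == b) 2 else if (can_pair(o, b)) 1 else 0
      }, numeric(1)))
    }, numeric(1))
    names(score)[which.min(score)]
  }
  star <- c(star, pick_overhang(mb[1:2]), pick_overhang(mb[1:2]))

  if (n_mismatches > 0L) {
    with_seed(seed, {
      # spread mismatches >= 3 nt apart over the stem interior (duplex ends
      # kept intact): adjacent mismatches would isolate single base pairs,
      # which the stacking energy model treats as free and may leave open,
      # making the designed structure ill-defined
      anchors <- seq(4, m - 5L, length.out = n_mismatches + 2L)
      pos <- round(anchors[-c(1L, n_mismatches + 2L)]) +
        sample(-1:1, n_mismatches, replace = TRUE)
      pos <- sort(pmin(pmax(pos, 3L), m - 4L))
      if (n_mismatches > 1L) {
        while (any(diff(pos) < 3L)) pos[which(diff(pos) < 3L) + 1L] <-
            pos[which(diff(pos) < 3L) + 1L] + 1L
      }
      for (p in pos) {
        partner <- mb[m - 1L - p] # mature base this star position pairs with
        choices <- setdiff(c("A", "C", "G", "T"), star[p])
        ok <- choices[!vapply(choices, function(b) can_pair(partner, b), logical(1))]
        star[p] <- if (length(ok)) ok[1] else choices[1]
      }
    })
  }

  loop <- with_seed(seed + 104729L, {
    # loop drawn A/C-biased so it does not pair with itself or the stem ends
    paste(sample(c("A", "C"), loop_len, replace = TRUE), collapse = "")
  })

  star <- paste(star, collapse = "")
  precursor <- paste0(mature, loop, star)
  list(precursor = precursor, mature = mature, star = star,
       mature_start = 1L, mature_end = m,
       star_start = m + loop_len + 1L,
       star_end = nchar(precursor))
}

#' Describe one locus to embed in a synthetic genome
#'
#' @param locus_id Unique identifier.
#' @param kind One of `"miRNA"`, `"rRNA"`, `"tRNA"`, `"snRNA"`, `"repeat"`,
#'   `"random"`.
#' @param scaffold Scaffold name.
#' @param start 1-based start of the locus on the scaffold.
#' @param strand `"+"` or `"-"`.
#' @param length Locus length in bp (ignored for miRNA loci, whose length is
#'   `2 * nchar(mature_seq) + loop_len`).
#' @param mature_seq Mature miRNA sequence (miRNA loci only), 20-24 nt.
#' @param loop_len,designed_mismatches Hairpin design parameters passed to
#'   [build_hairpin_precursor()].
#' @param per_library_abundance Non-negative expected read weights for
#'   libraries WT1, WT2, MT1, MT2.
#' @param star_fraction Fraction of this locus's miRNA reads emitted from the
#'   star strand; must be below 0.5.
#' @return A list of class `embedded_locus`.
#' @export
embedded_locus <- function(locus_id, kind, scaffold, start, strand = "+",
                           length = 120L, mature_seq = NULL, loop_len = 15L,
                           designed_mismatches = 0L,
                           per_library_abundance = c(1, 1, 1, 1),
                           star_fraction = 0.1) {
  kind <- match.arg(kind, c("miRNA", "rRNA", "tRNA", "snRNA", "repeat", "random"))
  stopifnot(length(per_library_abundance) == 4L, all(per_library_abundance >= 0))
  if (kind == "miRNA") {
    stopifnot(!is.null(mature_seq))
    n <- nchar(mature_seq)
    if (n < 20L || n > 24L) stop("mature_seq must be 20-24 nt")
    if (star_fraction >= 0.5) stop("star_fraction must be < 0.5")
    length <- 2L * n + as.integer(loop_len)
  }
  structure(list(locus_id = locus_id, kind = kind, scaffold = scaffold,
                 start = as.integer(start), end = as.integer(start) + as.integer(length) - 1L,
                 strand = strand, mature_seq = mature_seq, loop_len = as.integer(loop_len),
                 designed_mismatches = as.integer(designed_mismatches),
                 per_library_abundance = stats::setNames(as.numeric(per_library_abundance), LIBRARIES),
                 star_fraction = star_fraction),
            class = "embedded_locus")
}

#' Draw per-library expected abundances from a log-normal model
#'
#' Convenience sampler for simulation studies: expected read weights per
#' locus and library are drawn as `rlnorm(meanlog = mu, sdlog = sigma)`.
#'
#' @param n Number of loci.
#' @param mu,sigma Log-normal parameters (defaults 3 and 1.5).
#' @param seed Integer seed.
#' @return An `n` x 4 matrix of expectations (columns WT1, WT2, MT1, MT2).
#' @export
sample_abundances <- function(n, mu = 3, sigma = 1.5, seed = 1L) {
  with_seed(seed, {
    matrix(stats::rlnorm(4L * n, meanlog = mu, sdlog = sigma), nrow = n,
           dimnames = list(NULL, LIBRARIES))
  })
}

#' Generate a synthetic genome with embedded truth loci
#'
#' Builds random scaffolds, embeds each locus (miRNA loci as designed
#' hairpin precursors via [build_hairpin_precursor()]; other kinds keep the
#' random background sequence at their coordinates), and returns the genome
#' with a truth annotation. Deterministic for a fixed seed.
#'
#' @param loci List of [embedded_locus()] specifications; overlapping loci
#'   are rejected.
#' @param scaffold_lengths Named integer vector of scaffold lengths.
#' @param seed Integer seed.
#' @return A list of class `synthetic_genome` with `genome`
#'   (a [Biostrings::DNAStringSet]), `features` (a
#'   [GenomicRanges::GRanges] with metadata columns `type` and `locus_id`)
#'   and `loci` (the input list, with hairpin designs attached to miRNA
#'   loci).
#' @export
generate_genome <- function(loci, scaffold_lengths, seed = 1L) {
  stopifnot(length(loci) > 0L, !is.null(names(scaffold_lengths)))
  ids <- vapply(loci, `[[`, character(1), "locus_id")
  if (anyDuplicated(ids)) stop("duplicate locus ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  # overlap / bounds checks
  df <- data.frame(id = ids,
                   scaffold = vapply(loci, `[[`, character(1), "scaffold"),
                   start = vapply(loci, `[[`, integer(1), "start"),
                   end = vapply(loci, `[[`, integer(1), "end"))
  for (sc in unique(df$scaffold)) {
    if (!sc %in% names(scaffold_lengths)) stop("unknown scaffold: ", sc)
    d <- df[df$scaffold == sc, , drop = FALSE]
    if (any(d$end > scaffold_lengths[[sc]]) || any(d$start < 1L)) {
      stop("loci outside scaffold bounds: ",
           paste(d$id[d$end > scaffold_lengths[[sc]] | d$start < 1L], collapse = ", "))
    }
    d <- d[order(d$start), , drop = FALSE]
    if (nrow(d) > 1L) {
      bad <- which(d$start[-1L] <= d$end[-nrow(d)])
      if (length(bad)) {
        stop("overlapping loci: ",
             paste(paste(d$id[bad], d$id[bad + 1L], sep = "/"), collapse = ", "))
      }
    }
  }

  scaffolds <- with_seed(seed, {
    lapply(scaffold_lengths, function(L) {
      sample(c("A", "C", "G", "T"), L, replace = TRUE)
    })
  })

  for (k in seq_along(loci)) {
    lc <- loci[[k]]
    if (lc$kind == "miRNA") {
      hp <- build_hairpin_precursor(lc$mature_seq, lc$loop_len,
                                    lc$designed_mismatches, seed = seed + k)
      seqv <- strsplit(hp$precursor, "")[[1]]
      if (lc$strand == "-") seqv <- strsplit(revcomp(hp$precursor), "")[[1]]
      scaffolds[[lc$scaffold]][lc$start:lc$end] <- seqv
      loci[[k]]$hairpin <- hp
    }
  }

  genome <- Biostrings::DNAStringSet(vapply(scaffolds, paste, character(1), collapse = ""))
  names(genome) <- names(scaffold_lengths)

  features <- GenomicRanges::GRanges(
    seqnames = df$scaffold,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = vapply(loci, `[[`, character(1), "strand"),
    type = vapply(loci, `[[`, character(1), "kind"),
    locus_id = ids
  )
  structure(list(genome = genome, features = features, loci = loci),
            class = "synthetic_genome")
}

#' Structural-RNA / repeat annotation view of a synthetic genome
#'
#' Returns the features an annotation file would provide to
#' [classify_tags()]: structural RNA and repeat loci only. miRNA and random
#' loci are truth, not annotation.
#'
#' @param gen A `synthetic_genome`.
#' @return A [GenomicRanges::GRanges].
#' @export
annotation_features <- function(gen) {
  gr <- gen$features
  gr[gr$type %in% c("rRNA", "tRNA", "snRNA", "snoRNA", "repeat")]
}

#' Write a synthetic genome to FASTA and GFF3
#'
#' @param gen A `synthetic_genome`.
#' @param fasta,gff3 Output paths.
#' @return Invisibly, the paths.
#' @export
write_genome <- function(gen, fasta, gff3) {
  Biostrings::writeXStringSet(gen$genome, fasta)
  gr <- gen$features
  gr$ID <- gr$locus_id
  rtracklayer::export(gr, gff3, format = "gff3")
  invisible(c(fasta = fasta, gff3 = gff3))
}

#' Simulate four small RNA libraries from a synthetic genome
#'
#' Reads are allocated to loci by a multinomial draw proportional to each
#' locus's per-library abundance, so each library sums exactly to its
#' requested total. miRNA loci emit mature reads and, at `star_fraction`,
#' star reads; structural, repeat and random loci shed uniformly positioned
#' 18-30 nt degradation fragments. Every read carries the 3' adapter
#' (possibly truncated at the read length) and substitution errors at
#' `error_rate` per base. Qualities are fixed at Q40.
#'
#' @param gen A `synthetic_genome` from [generate_genome()].
#' @param adapter3 3' adapter sequence (DNA).
#' @param total_reads Reads per library (scalar, or length-4 vector in the
#'   order WT1, WT2, MT1, MT2).
#' @param error_rate Per-base substitution error rate, in [0, 0.05].
#' @param read_length Raw read length, default 40 so that a 30-nt insert still retains a 7-nt adapter overlap (inserts are padded with adapter and A).
#' @param seed Integer seed.
#' @return A list of class `simulated_libraries` with `reads` (per library:
#'   list with `seq` and `qual` character vectors) and `truth` (data.frame of
#'   emitted insert counts per locus, role and library).
#' @export
simulate_libraries <- function(gen, adapter3 = "TCGTATGCCGTCTTCTGCTTG",
                               total_reads = 10000L, error_rate = 0.001,
                               read_length = 40L, seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.05)
  if (length(gen$loci) == 0L) stop("empty truth: no loci to simulate")
  if (length(total_reads) == 1L) total_reads <- rep(total_reads, 4L)
  stopifnot(length(total_reads) == 4L)

  ab <- t(vapply(gen$loci, `[[`, numeric(4), "per_library_abundance"))
  if (any(colSums(ab) <= 0)) stop("abundances not normalizable: a library has zero total weight")

  locus_seq <- function(lc) {
    s <- as.character(Biostrings::subseq(gen$genome[[lc$scaffold]], lc$start, lc$end))
    if (lc$strand == "-") revcomp(s) else s
  }

  with_seed(seed, {
    libs <- vector("list", 4L)
    names(libs) <- LIBRARIES
    truth <- list()
    for (l in seq_len(4L)) {
      counts <- as.vector(stats::rmultinom(1L, total_reads[l], ab[, l]))
      inserts <- character(0)
      for (k in seq_along(gen$loci)) {
        nk <- counts[k]
        if (nk == 0L) next
        lc <- gen$loci[[k]]
        if (lc$kind == "miRNA") {
          hp <- lc$hairpin
          n_star <- stats::rbinom(1L, nk, lc$star_fraction)
          ins <- c(rep(hp$mature, nk - n_star), rep(hp$star, n_star))
          truth[[length(truth) + 1L]] <- data.frame(
            locus_id = lc$locus_id, library = LIBRARIES[l],
            role = c("mature", "star"), insert = c(hp$mature, hp$star),
            count = c(nk - n_star, n_star))
        } else {
          s <- locus_seq(lc)
          L <- nchar(s)
          flen <- sample(18:30, nk, replace = TRUE)
          flen <- pmin(flen, L)
          fstart <- vapply(flen, function(fl) sample.int(L - fl + 1L, 1L), integer(1))
          ins <- substring(s, fstart, fstart + flen - 1L)
          tb <- table(ins)
          truth[[length(truth) + 1L]] <- data.frame(
            locus_id = lc$locus_id, library = LIBRARIES[l],
            role = "fragment", insert = names(tb), count = as.integer(tb))
        }
        inserts <- c(inserts, ins)
      }
      reads <- substr(paste0(inserts, adapter3,
                             strrep("A", read_length)), 1L, read_length)
      if (error_rate > 0) {
        nerr <- stats::rbinom(length(reads), read_length, error_rate)
        idx <- which(nerr > 0L)
        for (i in idx) {
          pos <- sample.int(read_length, nerr[i])
          rb <- strsplit(reads[i], "")[[1]]
          for (p in pos) rb[p] <- sample(setdiff(c("A", "C", "G", "T"), rb[p]), 1L)
          reads[i] <- paste(rb, collapse = "")
        }
      }
      ord <- sample.int(length(reads)) # shuffle locus blocks
      libs[[l]] <- list(seq = reads[ord],
                        qual = rep(strrep("I", read_length), length(reads)))
    }
    truth <- do.call(rbind, truth)
    truth <- truth[truth$count > 0L, , drop = FALSE]
    rownames(truth) <- NULL
    structure(list(reads = libs, truth = truth, adapter3 = adapter3),
              class = "simulated_libraries")
  })
}

#' Write simulated libraries as FASTQ (Phred+33)
#'
#' @param sim A `simulated_libraries` object.
#' @param dir Output directory; files are named `<library>.fastq`.
#' @return Invisibly, the file paths.
#' @export
write_libraries <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (lib in names(sim$reads)) {
    x <- Biostrings::DNAStringSet(sim$reads[[lib]]$seq)
    names(x) <- sprintf("%s_r%06d", lib, seq_along(x))
    p <- file.path(dir, paste0(lib, ".fastq"))
    Biostrings::writeXStringSet(x, p, format = "fastq",
                                qualities = Biostrings::BStringSet(sim$reads[[lib]]$qual))
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Load the packaged novel miRNA catalog
#'
#' Reads a tab-separated catalog of novel miRNAs (default: the 75-entry
#' catalog shipped with the package) with columns `mirna_id`, `location`
#' (`scaffold:start:end`, 1-based inclusive), `mfe` (kcal/mol), `arm5`,
#' `arm3` (DNA arm sequences as catalogued) and the four library read counts
#' `wt1`, `wt2`, `mt1`, `mt2`. Each record is validated; malformed lines are
#' reported with their line number.
#'
#' @param path Path to a catalog TSV. Defaults to the packaged catalog.
#' @return A data.frame with the columns above plus parsed `scaffold`,
#'   `start`, `end` and `length` (end - start + 1).
#' @export
load_novel_catalog <- function(path = system.file("extdata", "novel_mirna_catalog.tsv",
                                                  package = "hairpinseq")) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "location", "mfe", "arm5", "arm3", "wt1", "wt2", "mt1", "mt2")
  if (!all(need %in% names(x))) {
    stop("catalog is missing columns: ", paste(setdiff(need, names(x)), collapse = ", "))
  }
  loc <- strsplit(x$location, ":", fixed = TRUE)
  bad <- which(lengths(loc) != 3L)
  if (length(bad)) stop("malformed location at line ", bad[1] + 1L, ": ", x$location[bad[1]])
  x$scaffold <- vapply(loc, `[[`, character(1), 1L)
  x$start <- as.integer(vapply(loc, `[[`, character(1), 2L))
  x$end <- as.integer(vapply(loc, `[[`, character(1), 3L))
  for (i in seq_len(nrow(x))) {
    line <- i + 1L
    if (is.na(x$start[i]) || is.na(x$end[i]) || x$end[i] <= x$start[i]) {
      stop("invalid coordinates at line ", line, ": ", x$location[i])
    }
    if (is.na(x$mfe[i]) || x$mfe[i] >= 0) stop("MFE must be negative at line ", line)
    if (grepl("[^ACGT]", x$arm5[i]) || grepl("[^ACGT]", x$arm3[i])) {
      stop("non-DNA arm sequence at line ", line)
    }
    if (any(is.na(c(x$wt1[i], x$wt2[i], x$mt1[i], x$mt2[i]))) ||
        any(c(x$wt1[i], x$wt2[i], x$mt1[i], x$mt2[i]) < 0)) {
      stop("invalid counts at line ", line)
    }
  }
  x$length <- x$end - x$start + 1L
  x
}

#' Write a novel miRNA catalog TSV
#'
#' Inverse of [load_novel_catalog()]; writing and re-loading reproduces all
#' records field for field.
#'
#' @param catalog A catalog data.frame.
#' @param path Output path.
#' @export
write_novel_catalog <- function(catalog, path) {
  out <- catalog[, c("mirna_id", "location", "mfe", "arm5", "arm3",
                     "wt1", "wt2", "mt1", "mt2")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
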