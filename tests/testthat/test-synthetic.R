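test_that("designed precursors have the stated geometry", {
  mature <- "UCUUGCUCAAAUGAGUAUUCCA" # 22 nt
  hp <- build_hairpin_precursor(mature, loop_len = 15, n_mismatches = 0)
  expect_equal(nchar(hp$precursor), 59L) # 2 * 22 + 15
  # 3' arm core = reverse complement of the mature shifted by the 2-nt
  # overhang rule: star[1..20] pairs mature[1..20]
  expect_equal(substr(hp$star, 1, 20), oracle_revcomp(substr(hp$mature, 1, 20)))
  expect_equal(hp$star_end - hp$star_start + 1L, 22L)
  # folded by the built-in engine, >= 20 of 22 mature bases pair
  f <- fold(hp$precursor)
  expect_gte(sum(f$partner[1:22] > 0), 20L)

  expect_error(build_hairpin_precursor(mature, loop_len = 2), "loop")
  expect_error(build_hairpin_precursor(mature, 10, n_mismatches = 5), "mismatch")
})

test_that("precursor lengths track the designed mature/loop sizes", {
  set.seed(31)
  # 75 designs with total lengths drawn uniformly in [74, 343]
  lens <- integer(75)
  for (i in 1:75) {
    m <- sample(20:24, 1L)
    target <- sample(74:343, 1L)
    loop <- max(3L, target - 2L * m)
    hp <- build_hairpin_precursor(rand_seq(m), loop, sample(0:2, 1L), seed = i)
    lens[i] <- nchar(hp$precursor)
  }
  expect_true(all(lens >= 74 & lens <= 343))
})

test_that("generated genomes embed loci retrievably and deterministically", {
  loci <- list(embedded_locus("m1", "miRNA", "s1", 100,
                              mature_seq = "ACGTACGTACGTACGTACGTA", loop_len = 12))
  gen <- generate_genome(loci, c(s1 = 1000L), seed = 5)
  l <- gen$loci[[1]]
  expect_equal(as.character(Biostrings::subseq(gen$genome[["s1"]], l$start, l$end)),
               l$hairpin$precursor)

  # same seed twice: byte-identical FASTA and GFF3
  gen2 <- generate_genome(loci, c(s1 = 1000L), seed = 5)
  d <- tempfile()
  dir.create(d)
  write_genome(gen, file.path(d, "a.fa"), file.path(d, "a.gff3"))
  write_genome(gen2, file.path(d, "b.fa"), file.path(d, "b.gff3"))
  expect_identical(readLines(file.path(d, "a.fa")), readLines(file.path(d, "b.fa")))
  expect_identical(readLines(file.path(d, "a.gff3")), readLines(file.path(d, "b.gff3")))

  # mixed kinds preserved in the truth annotation
  kinds <- c("miRNA", "rRNA", "tRNA", "snRNA", "repeat", "random",
             "rRNA", "repeat", "random", "tRNA")
  loci10 <- lapply(1:10, function(i) {
    embedded_locus(paste0("L", i), kinds[i], "s1", 100L + 120L * (i - 1L),
                   length = 80L, mature_seq = "ACGTACGTACGTACGTACGTA",
                   loop_len = 12L)
  })
  g10 <- generate_genome(loci10, c(s1 = 2000L), seed = 1)
  expect_equal(length(g10$features), 10L)
  expect_equal(g10$features$type, kinds)

  # overlapping loci rejected with ids
  bad <- list(embedded_locus("a", "random", "s1", 100, length = 100L),
              embedded_locus("b", "random", "s1", 150, length = 100L))
  expect_error(generate_genome(bad, c(s1 = 1000L)), "overlap.*a/b")
})

test_that("simulated libraries conserve totals and emit designed reads", {
  loci <- list(embedded_locus("m1", "miRNA", "s1", 100,
                              mature_seq = "ACGTTGCAACGTACGTACGTA", loop_len = 12,
                              per_library_abundance = c(1, 1, 1, 1),
                              star_fraction = 0))
  gen <- generate_genome(loci, c(s1 = 1000L), seed = 5)
  sim <- simulate_libraries(gen, total_reads = 100L, error_rate = 0, seed = 2)
  # error-free single-locus run: every insert is the mature sequence
  tr <- trim_adapter(sim$reads$WT1$seq, sim$adapter3)
  expect_true(all(tr$trimmed))
  expect_true(all(tr$insert == gen$loci[[1]]$hairpin$mature))
  expect_equal(length(sim$reads$WT1$seq), 100L)

  # read-count conservation at scale
  gen2 <- benchmark_genome()
  sim2 <- simulate_libraries(gen2, total_reads = 50000L, error_rate = 0, seed = 3)
  expect_true(all(vapply(sim2$reads, function(x) length(x$seq), integer(1)) == 50000L))

  # star emission is binomial around star_fraction
  loci_s <- list(embedded_locus("m1", "miRNA", "s1", 100,
                                mature_seq = "ACGTTGCAACGTACGTACGTA", loop_len = 12,
                                star_fraction = 0.1))
  gen_s <- generate_genome(loci_s, c(s1 = 1000L), seed = 5)
  sim_s <- simulate_libraries(gen_s, total_reads = 1000L, error_rate = 0, seed = 4)
  star_ct <- sim_s$truth$count[sim_s$truth$library == "WT1" &
                                sim_s$truth$role == "star"]
  expect_true(abs(star_ct - 100) <= 3 * sqrt(1000 * 0.1 * 0.9))

  expect_error(simulate_libraries(gen, error_rate = 0.2), "error_rate")

  # determinism: same seed, identical reads
  sim_a <- simulate_libraries(gen2, total_reads = 5000L, seed = 7)
  sim_b <- simulate_libraries(gen2, total_reads = 5000L, seed = 7)
  expect_identical(sim_a$reads, sim_b$reads)
  expect_identical(sim_a$truth, sim_b$truth)
})

test_that("every designed hairpin validates at default thresholds", {
  # property promised by the generator: n_mismatches <= 2, loop <= 20
  set.seed(55)
  cases <- expand.grid(mlen = c(20L, 22L, 24L), loop = c(3L, 10L, 20L),
                       mm = 0:2)
  for (r in seq_len(nrow(cases))) {
    m <- rand_seq(cases$mlen[r])
    hp <- build_hairpin_precursor(m, cases$loop[r], cases$mm[r], seed = r)
    # pad with neutral flanks so the precursor can reach the 50-nt minimum
    wseq <- paste0(rand_seq(30), hp$precursor, rand_seq(30))
    tags <- data.frame(
      tag = c(hp$mature, hp$star),
      start = 30L + c(hp$mature_start, hp$star_start),
      end = 30L + c(hp$mature_end, hp$star_end),
      count = c(100, 10))
    v <- validate_hairpin(wseq, tags)
    expect_true(v$accepted,
                info = sprintf("mlen=%d loop=%d mm=%d reason=%s", cases$mlen[r],
                               cases$loop[r], cases$mm[r],
                               if (v$accepted) "" else v$reason))
  }
})

test_that("the packaged novel miRNA catalog loads, validates and round-trips", {
  cat75 <- load_novel_catalog()
  expect_equal(nrow(cat75), 75L)
  n24 <- cat75[cat75$mirna_id == "Novel24", ]
  expect_equal(n24$scaffold, "scaffold_14")
  expect_equal(n24$length, 74L)
  n56 <- cat75[cat75$mirna_id == "Novel56", ]
  expect_equal(c(n56$wt1, n56$wt2, n56$mt1, n56$mt2),
               c(3993830L, 1867066L, 4155155L, 2288840L))
  expect_true(all(cat75$mfe < 0))
  expect_true(all(cat75$end > cat75$start))

  tmp <- tempfile(fileext = ".tsv")
  write_novel_catalog(cat75, tmp)
  again <- load_novel_catalog(tmp)
  expect_identical(cat75[, names(again)], again)

  # malformed lines are rejected with a line number
  bad <- cat75
  bad$location[3] <- "scaffold_1:100"
  tmp3 <- tempfile(fileext = ".tsv")
  write_novel_catalog(bad, tmp3)
  expect_error(load_novel_catalog(tmp3), "line 4")
})
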