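# Shared synthetic benchmark: 20 embedded miRNA loci among structural-RNA,
# repeat and random loci on three 25-kb scaffolds; four libraries of 20,000
# reads at 0.1% substitution error. Built once per test run.

.bench_cache <- new.env(parent = emptyenv())

benchmark_genome <- function() {
  if (!is.null(.bench_cache$gen)) return(.bench_cache$gen)
  set.seed(99)
  n_mir <- 20L
  scaffs <- c("sc1", "sc2", "sc3")
  matures <- vapply(seq_len(n_mir), function(i) rand_seq(sample(20:24, 1L)),
                    character(1))
  ab <- sample_abundances(n_mir, mu = 5, sigma = 0.8, seed = 3)
  loci <- list()
  pos <- c(sc1 = 1000L, sc2 = 1000L, sc3 = 1000L)
  for (i in seq_len(n_mir)) {
    sc <- scaffs[(i %% 3L) + 1L]
    loci[[length(loci) + 1L]] <- embedded_locus(
      sprintf("mir%02d", i), "miRNA", sc, pos[[sc]],
      mature_seq = matures[i], loop_len = sample(8:20, 1L),
      designed_mismatches = sample(0:2, 1L),
      per_library_abundance = pmax(ab[i, ], 50), star_fraction = 0.12)
    pos[[sc]] <- pos[[sc]] + 800L
  }
  kinds <- c("rRNA", "tRNA", "snRNA", "repeat", "random")
  for (k in 1:15) {
    sc <- scaffs[(k %% 3L) + 1L]
    loci[[length(loci) + 1L]] <- embedded_locus(
      sprintf("dec%02d", k), kinds[(k %% 5L) + 1L], sc, pos[[sc]],
      length = 300L, per_library_abundance = c(200, 200, 200, 200))
    pos[[sc]] <- pos[[sc]] + 800L
  }
  gen <- generate_genome(loci, c(sc1 = 25000L, sc2 = 25000L, sc3 = 25000L),
                         seed = 11)
  .bench_cache$gen <- gen
  gen
}

benchmark_run <- function() {
  if (!is.null(.bench_cache$run)) return(.bench_cache$run)
  gen <- benchmark_genome()
  sim <- simulate_libraries(gen, total_reads = 20000L, error_rate = 0.001,
                            seed = 12)
  cleaned <- lapply(sim$reads, function(x) {
    clean_library(x$seq, x$qual, adapter3 = sim$adapter3)
  })
  tags <- collapse_tags(lapply(cleaned, `[[`, "reads"))
  aln <- map_tags(tags, gen$genome)
  cls <- classify_tags(aln, annotation_features(gen), tags)
  run <- list(gen = gen, sim = sim, cleaned = cleaned, tags = tags,
              aln = aln, cls = cls)
  .bench_cache$run <- run
  run
}

benchmark_truth <- function(gen) {
  is_mir <- vapply(gen$loci, function(l) l$kind == "miRNA", logical(1))
  do.call(rbind, lapply(gen$loci[is_mir], function(l) {
    data.frame(locus_id = l$locus_id, mature = l$hairpin$mature,
               star = l$hairpin$star, scaffold = l$scaffold,
               start = l$start, end = l$end, stringsAsFactors = FALSE)
  }))
}
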