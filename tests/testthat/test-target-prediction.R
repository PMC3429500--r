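test_that("site scoring applies pair, wobble and mismatch weights", {
  mir <- "TGGAGTGTGACAATGGTGTTTG"
  site <- oracle_revcomp(mir)
  s <- score_site(mir, site)
  expect_equal(s$penalty, 0)
  expect_equal(s$pattern, strrep("|", nchar(mir)))

  # single G:U wobble at miRNA position 15 (site base C -> T against G)
  mir2 <- "AAAAAAAAAAAAAAGAAAAAA"
  site2 <- oracle_revcomp(mir2)
  pos_in_site <- nchar(mir2) + 1 - 15
  substr(site2, pos_in_site, pos_in_site) <- "T"
  s2 <- score_site(mir2, site2)
  expect_equal(s2$penalty, 0.5)
  expect_equal(substr(s2$pattern, 15, 15), "o")

  expect_error(score_site("ACGT", "ACGTA"), "length")

  # random pairs agree with a position-by-position tally
  set.seed(81)
  for (i in 1:30) {
    m <- rand_seq(21)
    st <- rand_seq(21)
    s <- score_site(m, st)
    mb <- strsplit(m, "")[[1]]
    sb <- rev(strsplit(st, "")[[1]])
    pen <- 0
    for (p in seq_len(21)) {
      pr <- paste0(mb[p], sb[p])
      pen <- pen + if (pr %in% c("AT", "TA", "GC", "CG")) 0
      else if (pr %in% c("GT", "TG")) 0.5 else 1
    }
    expect_equal(s$penalty, pen, info = paste(m, st))
  }
})

test_that("positional constraints implement the printed rule set", {
  pat <- function(x_at, L = 21, o_at = integer(0)) {
    v <- rep("|", L)
    v[x_at] <- "x"
    v[o_at] <- "o"
    paste(v, collapse = "")
  }
  # mismatch at the cleavage site
  expect_equal(positional_constraints(pat(10))$reason, "cleavage site")
  expect_equal(positional_constraints(pat(11))$reason, "cleavage site")
  # three consecutive mismatches in 12-21
  expect_equal(positional_constraints(pat(13:15))$reason, "consecutive")
  # x at 3, 16, 18, 20: four mismatches, penalty 4 > 2
  expect_equal(positional_constraints(pat(c(3, 16, 18, 20)))$reason, "penalty")
  # softening to one mismatch plus two wobbles lands exactly on the
  # penalty-2.0 boundary: accepted
  ok <- positional_constraints(pat(3, o_at = c(18, 20)))
  expect_true(ok$accept)
  # one more wobble tips the penalty over 2
  expect_equal(positional_constraints(pat(3, o_at = c(16, 18, 20)))$reason,
               "penalty")
  # two seed mismatches rejected even at low penalty
  expect_equal(positional_constraints(pat(c(3, 5)))$reason, "seed mismatches")
  # more than three x in 12-21
  expect_equal(positional_constraints(pat(c(12, 14, 16, 18)))$reason,
               "3' mismatches")
  expect_true(positional_constraints(strrep("|", 21))$accept)
})

test_that("acceptance is monotone: extra mismatches never rescue a pattern", {
  set.seed(82)
  for (i in 1:40) {
    v <- sample(c("|", "o", "x"), 21, replace = TRUE, prob = c(0.85, 0.1, 0.05))
    base <- paste(v, collapse = "")
    ok_base <- positional_constraints(base)$accept
    p <- sample(which(v != "x"), 1)
    v[p] <- "x"
    worse <- paste(v, collapse = "")
    if (positional_constraints(worse)$accept) expect_true(ok_base)
  }
})

test_that("transcript scanning equals the exhaustive window oracle", {
  set.seed(83)
  # planted near-perfect sites plus random background
  for (i in 1:100) {
    mir <- rand_seq(21)
    tx <- rand_seq(300)
    if (i %% 2 == 0) { # plant a site with up to 2 edits
      site <- oracle_revcomp(mir)
      for (k in seq_len(sample(0:2, 1))) {
        p <- sample(21, 1)
        substr(site, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      at <- sample(280, 1)
      substr(tx, at, at + 20) <- site
    }
    got <- suppressWarnings(scan_transcript(mir, tx))
    expect_equal(got$start, oracle_scan(mir, tx), info = paste(i, mir))
  }
})

test_that("sites are labelled by region with midpoint boundaries", {
  mir <- "TGGAGTGTGACAATGGTGTTTG"
  site <- oracle_revcomp(mir)
  tx <- paste0(strrep("A", 50), site, strrep("A", 30), site, strrep("A", 200),
               site, strrep("A", 20))
  # CDS from 90 to 290: first site in 5'UTR, second in ORF, third in 3'UTR
  got <- scan_transcript(mir, tx, cds_start = 90, cds_end = 290)
  expect_equal(got$region, c("5'UTR", "ORF", "3'UTR"))
  expect_warning(scan_transcript(mir, tx), "UTR")
})

test_that("duplex energies are maximal for perfect sites and monotone", {
  mir <- "TGGAGTGTGACAATGGTGTTTG"
  perfect <- score_site(mir, oracle_revcomp(mir))
  e <- duplex_energy(perfect, mir)
  expect_equal(e$energy_ratio, 1)
  expect_lt(e$delta_g, 0)

  allx <- list(pattern = strrep("x", nchar(mir)))
  e0 <- duplex_energy(allx, mir)
  expect_equal(e0$delta_g, 0)
  expect_equal(e0$energy_ratio, 0)

  # adding a mismatch to a duplex never increases the ratio
  set.seed(84)
  for (i in 1:20) {
    v <- sample(c("|", "o"), 22, replace = TRUE, prob = c(0.9, 0.1))
    k <- sample(3:6, 1)
    drop <- sample(22, k)
    ratios <- numeric(k + 1)
    ratios[1] <- duplex_energy(list(pattern = paste(v, collapse = "")), mir)$energy_ratio
    for (j in seq_len(k)) {
      v[drop[j]] <- "x"
      ratios[j + 1] <- duplex_energy(list(pattern = paste(v, collapse = "")), mir)$energy_ratio
    }
    expect_true(all(diff(ratios) <= 1e-12))
  }
})

test_that("target aggregation matches a brute-force recount", {
  sites <- data.frame(
    mirna_id = c("Novel27", "Novel59", "Novel53", "Novel53", "Novel01"),
    gene_id = c("g2420", "g2420", "g2772", "g2772", "g0001"))
  agg <- aggregate_targets(sites)
  expect_equal(unname(agg$sites_per_gene[["g2772"]]), 2L)
  expect_true("g2420" %in% agg$multi_mirna_genes)  # hit by two miRNAs
  expect_true("g2772" %in% agg$multi_site_genes)   # two sites, one miRNA
  expect_false("g0001" %in% agg$multi_site_genes)

  set.seed(85)
  big <- data.frame(mirna_id = sample(paste0("m", 1:8), 60, TRUE),
                    gene_id = sample(paste0("g", 1:15), 60, TRUE))
  agg2 <- aggregate_targets(big)
  for (g in names(agg2$sites_per_gene)) {
    expect_equal(unname(agg2$sites_per_gene[[g]]), sum(big$gene_id == g))
  }
  for (m in names(agg2$genes_per_mirna)) {
    expect_equal(unname(agg2$genes_per_mirna[[m]]),
                 length(unique(big$gene_id[big$mirna_id == m])))
  }
})
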