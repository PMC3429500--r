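test_that("homology matching respects the three-mismatch threshold", {
  ref <- c(miR166a = "TCGGACCAGGCTTCATTCCCC",
           miR156a = "TGACAGAAGAGAGTGAGCAC",
           miR159x = "TTTGGATTGAAGGGAGCTCTA")
  # identical tag
  m <- match_known("TCGGACCAGGCTTCATTCCCC", ref)
  expect_equal(m$ref_id, "miR166a")
  expect_equal(m$mismatches, 0L)
  # exactly three substitutions: still assigned
  tag3 <- "TCGGACCAGGCTTCATTCCCC"
  substr(tag3, 2, 2) <- "A"; substr(tag3, 9, 9) <- "T"; substr(tag3, 20, 20) <- "A"
  m <- match_known(tag3, ref)
  expect_equal(m$ref_id, "miR166a")
  expect_equal(m$mismatches, 3L)
  # four substitutions: none
  substr(tag3, 15, 15) <- "G"
  expect_equal(nrow(match_known(tag3, ref)), 0L)
  # length difference up to 2 nt allowed over the aligned overlap
  m <- match_known(substr(ref[["miR156a"]], 1, 18), ref)
  expect_equal(m$ref_id, "miR156a")
  expect_equal(m$mismatches, 0L)
})

test_that("mismatch counting is symmetric", {
  set.seed(41)
  for (i in 1:25) {
    a <- rand_seq(sample(20:24, 1))
    b <- rand_seq(sample(20:24, 1))
    if (abs(nchar(a) - nchar(b)) > 2) next
    ma <- match_known(a, c(ref = b), max_mismatch = nchar(a))
    mb <- match_known(b, c(ref = a), max_mismatch = nchar(b))
    expect_equal(ma$mismatches, mb$mismatches, info = paste(a, b))
  }
})

test_that("excision emits anchored, clipped windows on both strands", {
  genome <- Biostrings::DNAStringSet(c(s1 = rand_seq(2000)))
  aln <- data.frame(tag = "T", scaffold = "s1", start = 1000L, end = 1021L,
                    strand = "+", mismatches = 0L, multiplicity = 1L,
                    hyper = FALSE)
  w <- excise_candidates(aln, genome)
  expect_equal(nrow(w), 4L) # 2 anchors x 2 strands
  expect_setequal(unique(w$strand), c("+", "-"))
  expect_true(all(w$end - w$start + 1L >= 50L & w$end - w$start + 1L <= 400L))
  # upstream window reaches flank nt before the tag
  up <- w[w$anchor == "up" & w$strand == "+", ]
  expect_equal(up$start, 750L)

  # near the scaffold edge the window is clipped with a warning
  aln$start <- 30L; aln$end <- 51L
  expect_warning(wc <- excise_candidates(aln, genome), "clipped")
  expect_true(all(wc$start >= 1L))
})

test_that("hairpin validation enforces star support and overhang geometry", {
  mature <- "TGAGGTAGTAGGTTGTATAGTT" # 22 nt
  hp <- build_hairpin_precursor(mature, loop_len = 14, n_mismatches = 0)
  pad <- 30L
  wseq <- paste0(rand_seq(pad), hp$precursor, rand_seq(pad))
  mk_tags <- function(star_start, star_end, star_seq = hp$star) {
    data.frame(tag = c(hp$mature, star_seq),
               start = c(pad + 1L, star_start), end = c(pad + 22L, star_end),
               count = c(100, 10))
  }
  true_ss <- pad + hp$star_start
  true_se <- pad + hp$star_end

  v <- validate_hairpin(wseq, mk_tags(true_ss, true_se))
  expect_true(v$accepted)
  expect_equal(v$mature, hp$mature)
  expect_equal(v$star, hp$star)
  expect_lte(v$mfe, -18)
  expect_gte(v$precursor_range[2] - v$precursor_range[1] + 1L, 50L)

  # star shifted so that the duplex has a 0-nt 3' overhang: rejected
  shift <- 4L
  star_shift <- substr(wseq, true_ss + shift, true_se + shift)
  v0 <- validate_hairpin(wseq, mk_tags(true_ss + shift, true_se + shift, star_shift))
  expect_false(v0$accepted)
  expect_equal(v0$reason, "overhang")

  # no expressed tag at all
  v1 <- validate_hairpin(wseq, data.frame(tag = character(0), start = integer(0),
                                          end = integer(0), count = numeric(0)))
  expect_equal(v1$reason, "unsupported")

  # no tag on the opposite arm
  v2 <- validate_hairpin(wseq, mk_tags(true_ss, true_se)[1, ])
  expect_equal(v2$reason, "no star")

  # a duplex with six unpaired mature bases is rejected on pairing
  hp4 <- build_hairpin_precursor(mature, loop_len = 14, n_mismatches = 4, seed = 2)
  w4 <- paste0(rand_seq(pad), hp4$precursor, rand_seq(pad))
  f4 <- fold(w4)
  unpaired <- sum(f4$partner[(pad + 1):(pad + 22)] == 0)
  if (unpaired > 4) { # 4 designed mismatches + 2-nt overhang
    t4 <- data.frame(tag = c(hp4$mature, hp4$star),
                     start = c(pad + 1L, pad + hp4$star_start),
                     end = c(pad + 22L, pad + hp4$star_end),
                     count = c(100, 10))
    v4 <- validate_hairpin(w4, t4)
    expect_false(v4$accepted)
    expect_equal(v4$reason, "duplex pairing")
  }

  # accepted candidates re-validate: running the check again on the stored
  # precursor with the same tag placements reproduces the decision
  off <- v$precursor_range[1] - 1L
  tags2 <- mk_tags(true_ss, true_se)
  tags2$start <- tags2$start - off
  tags2$end <- tags2$end - off
  v2 <- validate_hairpin(v$precursor, tags2)
  expect_true(v2$accepted)
  expect_equal(v2$mfe, v$mfe)
})

test_that("excised windows around a simulated locus contain its precursor", {
  run <- benchmark_run()
  truth <- benchmark_truth(run$gen)
  cand <- candidate_tags(run$cls$labels, run$aln)
  cand_aln <- run$aln[run$aln$tag %in% cand & !run$aln$hyper, ]
  w <- excise_candidates(cand_aln, run$gen$genome)
  for (r in sample(nrow(truth), 5)) {
    covering <- w[w$scaffold == truth$scaffold[r] &
                    w$start <= truth$start[r] & w$end >= truth$end[r], ]
    expect_gte(nrow(covering), 1L)
  }
})

test_that("precursor summaries report lengths and MFE from coordinates", {
  cat75 <- load_novel_catalog()
  s <- summarize_precursors(cat75)
  expect_equal(s$count, 75L)
  expect_equal(unname(s$length["min"]), 74)
  expect_equal(unname(s$length["max"]), 343)
  expect_equal(round(unname(s$length["mean"])), 132)
  expect_equal(unname(s$mfe["min"]), -140.2)
  expect_equal(unname(s$mfe["max"]), -18)

  one <- data.frame(start = 10L, end = 109L, mfe = -30)
  s1 <- summarize_precursors(one)
  expect_equal(unname(s1$length), c(100, 100, 100))
  expect_error(summarize_precursors(cat75[0, ]), "empty")
})

test_that("catalog composition groups families and resolves conflicts", {
  conserved <- data.frame(tag = c("AAAACCCCGGGGTTTTAAAA", "AAAACCCCGGGGTTTTAAAC"),
                          ref_id = c("miR166a", "miR166e"),
                          mismatches = c(0L, 1L))
  novel <- data.frame(id = c("Novel01", "Novel02"),
                      mature = c("CCCCGGGGAAAATTTTCCCC", "GGGGAAAACCCCTTTTGGGG"),
                      stringsAsFactors = FALSE)
  cat1 <- compose_catalog(conserved, novel)
  expect_equal(nrow(cat1), 4L)
  expect_equal(unique(cat1$family[cat1$class == "conserved"]), "miR166")
  expect_equal(sum(cat1$family == "miR166"), 2L)

  # star references keep the family with a star flag
  cons2 <- data.frame(tag = "TTTTGGGGCCCCAAAATTTT", ref_id = "csi-miR482a*",
                      mismatches = 0L)
  cat2 <- compose_catalog(cons2, NULL)
  expect_equal(cat2$family, "miR482")
  expect_true(cat2$star_flag)

  # a mature called both conserved and novel: conserved wins with a warning
  novel_clash <- data.frame(id = "Novel01", mature = conserved$tag[1],
                            stringsAsFactors = FALSE)
  expect_warning(cat3 <- compose_catalog(conserved, novel_clash), "conserved")
  expect_equal(sum(cat3$mature == conserved$tag[1]), 1L)
  expect_equal(cat3$class[cat3$mature == conserved$tag[1]], "conserved")
})

test_that("mature references load from FASTA in the miRBase dialect", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">ptr-miR156a MIMAT0000001 mature sequence",
               "UGACAGAAGAGAGUGAGCAC",
               ">ptr-miR166a another description",
               "UCGGACCAGGCUUCAUUCCCC"), fa)
  m <- match_known("TGACAGAAGAGAGTGAGCAC", fa)
  expect_equal(m$ref_id, "ptr-miR156a")
  expect_equal(m$mismatches, 0L)
})
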