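# Independent oracles used to check package computations. These are written
# directly from the stated rules (brute force / exhaustive enumeration) and
# deliberately share no code with the implementation.

oracle_revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", U = "A")
  paste(rev(comp[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

oracle_can_pair <- function(a, b) {
  p <- paste0(sub("U", "T", a), sub("U", "T", b))
  p %in% c("AT", "TA", "GC", "CG", "GT", "TG")
}

# energy of a complete structure given as a partner vector, scored straight
# from the model definition: stack energy per pair whose immediate inner
# neighbour is also a pair, +3 per hairpin loop
oracle_score <- function(bases, partner) {
  stack <- c(GC = -3, CG = -3, AT = -2, TA = -2, GT = -1, TG = -1)
  e <- 0
  n <- length(bases)
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > i) {
      if (j - i > 2 && partner[i + 1] == j - 1) {
        e <- e + stack[[paste0(bases[i], bases[j])]]
      }
      inner <- if (j - i > 1) partner[(i + 1):(j - 1)] else integer(0)
      if (all(inner == 0)) e <- e + 3
    }
  }
  e
}

# exhaustive enumeration of all nested structures (min loop 3) of a short
# sequence; returns the minimum energy (empty structure = 0 is admissible)
oracle_mfe <- function(seq) {
  bases <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  n <- length(bases)
  best <- 0
  # depth-first over leftmost-position decisions
  rec <- function(i, partner) {
    if (i > n) {
      best <<- min(best, oracle_score(bases, partner))
      return(invisible())
    }
    if (partner[i] != 0) { # already paired from the left
      rec(i + 1L, partner)
      return(invisible())
    }
    rec(i + 1L, partner) # i unpaired
    lim <- partner_limit(i, partner, n)
    ks <- seq_len(n)
    ks <- ks[ks >= i + 4L & ks <= lim]
    for (k in ks) {
      if (partner[k] == 0 && oracle_can_pair(bases[i], bases[k])) {
        p2 <- partner
        p2[i] <- k
        p2[k] <- i
        rec(i + 1L, p2)
      }
    }
    invisible()
  }
  # nesting limit: i cannot pair beyond the closing partner of any enclosing
  # pair already fixed to the left
  partner_limit <- function(i, partner, n) {
    lim <- n
    for (a in seq_len(i - 1L)) {
      if (partner[a] > i) lim <- min(lim, partner[a] - 1L)
    }
    lim
  }
  rec(1L, integer(n))
  best
}

# brute-force all-offsets mapper (substitutions only, both strands)
oracle_map <- function(tag, genome_chr, max_mismatch = 1L) {
  hits <- list()
  for (sc in names(genome_chr)) {
    g <- genome_chr[[sc]]
    L <- nchar(g)
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") toupper(tag) else oracle_revcomp(tag)
      pv <- strsplit(pat, "")[[1]]
      w <- length(pv)
      if (w > L) next
      for (s in 1:(L - w + 1L)) {
        gv <- strsplit(substr(g, s, s + w - 1L), "")[[1]]
        mm <- sum(pv != gv)
        if (mm <= max_mismatch) {
          hits[[length(hits) + 1L]] <- data.frame(
            tag = tag, scaffold = sc, start = s, end = s + w - 1L,
            strand = strand, mismatches = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(tag = character(0), scaffold = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  do.call(rbind, hits)
}

# brute-force target scanner applying the printed rules per window
oracle_scan <- function(mirna, transcript, penalty_max = 2) {
  mirna <- toupper(chartr("U", "T", mirna))
  transcript <- toupper(chartr("U", "T", transcript))
  mb <- strsplit(mirna, "")[[1]]
  L <- length(mb)
  accepted <- integer(0)
  for (w in seq_len(nchar(transcript) - L + 1L)) {
    sb <- rev(strsplit(substr(transcript, w, w + L - 1L), "")[[1]])
    sym <- character(L)
    for (i in seq_len(L)) {
      pr <- paste0(mb[i], sb[i])
      sym[i] <- if (pr %in% c("AT", "TA", "GC", "CG")) "|"
      else if (pr %in% c("GT", "TG")) "o"
      else "x"
    }
    pen <- sum(sym == "x") + 0.5 * sum(sym == "o")
    x <- sym == "x"
    ok <- pen <= penalty_max &&
      !any(x[intersect(10:11, 1:L)]) &&
      sum(x[intersect(2:11, 1:L)]) <= 1 &&
      sum(x[intersect(12:21, 1:L)]) <= 3 &&
      sum(x) <= 4
    if (ok && L >= 12) {
      reg <- x[12:min(21, L)]
      r <- rle(reg)
      if (any(r$values & r$lengths > 2)) ok <- FALSE
    }
    if (ok) accepted <- c(accepted, w)
  }
  accepted
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
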