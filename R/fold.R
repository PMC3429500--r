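#' Fold an RNA sequence into its minimum-energy nested structure
#'
#' Predicts a pseudoknot-free secondary structure under a compact,
#' deterministic energy model: a base pair contributes a stacking energy only
#' when the pair immediately inside it is also paired (G-C/C-G -3.0,
#' A-U/U-A -2.0, G-U/U-G -1.0 kcal/mol), each hairpin-loop closure costs
#' +3.0 kcal/mol, and hairpin loops span at least 3 unpaired bases. Interior
#' loops, bulges and multiloops carry no explicit penalty. The empty
#' structure is always admissible, so the reported minimum free energy (MFE)
#' is never positive.
#'
#' The model is intentionally simple: it recovers stem/loop geometry (arm
#' placement, duplex pairing, overhangs) reliably, which is what hairpin
#' validation needs, but its absolute energies are not comparable to full
#' nearest-neighbour (Turner) energies. An external folding engine with the
#' same return contract can be substituted wherever a `fold_fun` argument is
#' accepted.
#'
#' @param sequence A single RNA or DNA string (A/C/G/U/T, case-insensitive).
#'   T and U are equivalent.
#' @return An object of class `hairpin_structure`: a list with elements
#'   `sequence`, `structure` (dot-bracket), `mfe` (kcal/mol, <= 0), `pairs`
#'   (two-column matrix of 1-based base-pair indices) and `partner` (integer
#'   vector, 0 for unpaired positions).
#' @examples
#' fold("GGGAAACCC")
#' @export
fold <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, nzchar(sequence))
  if (grepl("[^ACGUTacgut]", sequence)) {
    stop("sequence contains characters outside the RNA/DNA alphabet")
  }
  res <- .fold_engine(toupper(sequence))
  structure(
    list(sequence = toupper(sequence), structure = res$structure,
         mfe = res$mfe, pairs = res$pairs, partner = res$partner),
    class = "hairpin_structure"
  )
}

#' @export
print.hairpin_structure <- function(x, ...) {
  cat(x$sequence, "\n", x$structure, "\n", sep = "")
  cat(sprintf("MFE: %.2f kcal/mol (%d base pairs)\n", x$mfe, nrow(x$pairs)))
  invisible(x)
}

#' Energy of a given nested structure
#'
#' Scores an explicit dot-bracket structure under the same energy model as
#' [fold()]. Used to re-validate folded structures: the energy of the
#' structure returned by [fold()] must equal its reported MFE.
#'
#' @param sequence RNA/DNA string.
#' @param structure Dot-bracket string of the same length (characters
#'   `(`, `)`, `.`).
#' @return Energy in kcal/mol.
#' @export
structure_energy <- function(sequence, structure) {
  stopifnot(nchar(sequence) == nchar(structure))
  s <- strsplit(toupper(chartr("U", "T", sequence)), "")[[1]]
  db <- strsplit(structure, "")[[1]]
  n <- length(s)
  partner <- integer(n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (db[i] == "(") {
      stack <- c(stack, i)
    } else if (db[i] == ")") {
      if (length(stack) == 0L) stop("unbalanced structure")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  if (length(stack)) stop("unbalanced structure")
  pair_e <- function(a, b) {
    p <- paste0(a, b)
    if (p %in% c("GC", "CG")) return(-3)
    if (p %in% c("AT", "TA")) return(-2)
    if (p %in% c("GT", "TG")) return(-1)
    stop("unpairable bases ", p, " in structure")
  }
  e <- 0
  for (i in seq_len(n)) {
    j <- partner[i]
    if (j > i) {
      if (j - i - 1 < 3) stop("hairpin loop shorter than 3 nt")
      # stacking contribution when the immediately inner pair exists
      if (j - i > 2 && partner[i + 1] == j - 1 && partner[j - 1] == i + 1) {
        e <- e + pair_e(s[i], s[j])
      }
      # hairpin loop: no paired base strictly inside
      inside <- if (j - i > 1) partner[(i + 1):(j - 1)] else integer(0)
      if (all(inside == 0L)) e <- e + 3
    }
  }
  e
}
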