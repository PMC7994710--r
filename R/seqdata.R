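# Data model and I/O for paired alignments, pairings and species partitions.

.normalizeChars <- function(x) {
  x <- toupper(x)
  x <- chartr(".", "-", x)
  # anything outside the 20 amino acids and '-' (B, Z, X, U, O, J, '*', ...)
  # collapses to the gap so that Q stays fixed at 21
  gsub(sprintf("[^%s]", paste(OMEGA[-21], collapse = "")), "-", x)
}

#' Read an aligned FASTA file
#'
#' Reads an alignment, uppercases residues and maps every character outside
#' the 21-letter alphabet (ambiguity codes B/Z/X, U, O, '.', '*') to the gap
#' symbol, keeping the alphabet size at Q = 21.
#'
#' @param path path to an aligned FASTA file.
#' @return An `AAStringSet` with one row per record, in file order.
#' @export
readAlignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  msa <- Biostrings::readAAStringSet(path)
  if (length(msa) == 0L) stop("empty alignment file: ", path)
  seqs <- .normalizeChars(as.character(msa))
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) {
    bad <- which(w != w[1])[1]
    stop(sprintf("ragged alignment in %s: record %d ('%s') has length %d, expected %d",
                 path, bad, names(msa)[bad], w[bad], w[1]))
  }
  Biostrings::AAStringSet(setNames(seqs, names(msa)))
}

#' Write an alignment to FASTA
#'
#' @param msa an `AAStringSet`.
#' @param path output path.
#' @export
writeAlignment <- function(msa, path) {
  Biostrings::writeXStringSet(msa, path)
  invisible(path)
}

#' Assemble an AlignmentPair
#'
#' Characters outside the 21-letter alphabet are normalized to the gap, as
#' on file load. Row k of MSA A is taken as the native partner of row k of
#' MSA B unless `native` says otherwise.
#'
#' @param msaA,msaB `AAStringSet` alignments (or character vectors) with the
#'   same number of rows.
#' @param native optional [Pairing-class]; defaults to the identity.
#' @param species optional character vector of per-row species labels
#'   (paralog mode); the native pairing must stay within species.
#' @return An [AlignmentPair-class].
#' @examples
#' ap <- alignmentPair(c("ACDE", "ACDF"), c("KLMN", "KLMQ"))
#' nRows(ap)
#' @export
alignmentPair <- function(msaA, msaB, native = NULL, species = NULL) {
  asSet <- function(x) {
    if (is.character(x)) x <- Biostrings::AAStringSet(x)
    Biostrings::AAStringSet(setNames(.normalizeChars(as.character(x)), names(x)))
  }
  msaA <- asSet(msaA); msaB <- asSet(msaB)
  if (is.null(native)) native <- identityPairing(length(msaA))
  new("AlignmentPair", msaA = msaA, msaB = msaB, native = native,
      species = if (is.null(species)) character(0) else as.character(species))
}

#' Concatenate the two alignments under a pairing
#'
#' Joins row k of MSA A with row `perm(z)[k]` of MSA B, the paired alignment
#' whose column statistics all interface MI quantities condition on.
#'
#' @param pair an [AlignmentPair-class].
#' @param z a [Pairing-class] (defaults to the native pairing).
#' @return Character vector of M sequences of length L_A + L_B.
#' @export
concatenateRows <- function(pair, z = nativePairing(pair)) {
  stopifnot(length(perm(z)) == nRows(pair))
  paste0(as.character(pair@msaA), as.character(pair@msaB)[perm(z)])
}

#' Sample a scrambled pairing
#'
#' Draws a uniformly random permutation of `1:M`, optionally constrained to
#' be a derangement (no row keeps its native partner) or to permute only
#' within species blocks (the paralog move set).
#'
#' @param M number of rows (or of species labels).
#' @param mode one of `"permutation"`, `"derangement"`, `"within_species"`.
#' @param species character labels, required for `within_species`.
#' @param seed optional integer; when given, the draw is reproducible and
#'   the caller's RNG state is untouched.
#' @return A [Pairing-class].
#' @export
scramblePairing <- function(M, mode = c("permutation", "derangement", "within_species"),
                            species = NULL, seed = NULL) {
  mode <- match.arg(mode)
  M <- as.integer(M)
  if (M < 2L && mode != "within_species") stop("need M >= 2 to scramble")
  if (mode == "derangement" && M < 2L) stop("no derangement exists for M < 2")
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  p <- switch(mode,
    permutation = .fyPermutation(M),
    derangement = {
      repeat {
        cand <- .fyPermutation(M)
        if (!any(cand == seq_len(M))) break
      }
      cand
    },
    within_species = {
      if (is.null(species)) stop("within_species mode needs species labels")
      if (length(species) != M) stop("species labels must have length M")
      .fyWithinSpecies(species)
    })
  Pairing(p)
}

# Uniform draws shared with the compiled GA core: randInt(n) in 1..n from one
# runif consumption, Fisher-Yates built on it. Keeping the draw order
# identical in R and C++ makes seeded runs bit-comparable across both paths.
.randInt <- function(n) min(floor(runif(1) * n), n - 1L) + 1L

.fyPermutation <- function(M) {
  v <- seq_len(M)
  if (M >= 2L) for (i in M:2) {
    j <- .randInt(i)
    tmp <- v[i]; v[i] <- v[j]; v[j] <- tmp
  }
  v
}

.fyWithinSpecies <- function(species) {
  out <- seq_along(species)
  for (s in unique(species)) {       # blocks in order of first appearance
    idx <- which(species == s)
    if (length(idx) >= 2L) out[idx] <- idx[.fyPermutation(length(idx))]
  }
  out
}

#' Serialize a pairing as a two-column TSV of matched identifiers
#'
#' @param pair an [AlignmentPair-class] supplying row identifiers.
#' @param z the [Pairing-class] to write.
#' @param path output path.
#' @export
writePairing <- function(pair, z, path) {
  ids_a <- names(msaA(pair)); ids_b <- names(msaB(pair))
  if (is.null(ids_a)) ids_a <- paste0("A", seq_len(nRows(pair)))
  if (is.null(ids_b)) ids_b <- paste0("B", seq_len(nRows(pair)))
  write.table(data.frame(id_a = ids_a, id_b = ids_b[perm(z)]),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pairing written by [writePairing()]
#'
#' @param pair the [AlignmentPair-class] whose row identifiers resolve the map.
#' @param path TSV path with columns `id_a`, `id_b`.
#' @return A [Pairing-class].
#' @export
readPairing <- function(pair, path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  ids_a <- names(msaA(pair)); ids_b <- names(msaB(pair))
  k <- match(tab$id_a, ids_a); l <- match(tab$id_b, ids_b)
  if (anyNA(k) || anyNA(l)) stop("pairing file contains unknown identifiers")
  p <- integer(nRows(pair)); p[k] <- l
  Pairing(p)
}

# integer encoding of an alignment over OMEGA (M x L matrix, values 1..21)
.encodeMSA <- function(msa) {
  m <- matrix(match(unlist(strsplit(as.character(msa), "")), OMEGA),
              nrow = length(msa), byrow = TRUE)
  if (anyNA(m)) stop("alignment contains characters outside the alphabet")
  storage.mode(m) <- "integer"
  m
}
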