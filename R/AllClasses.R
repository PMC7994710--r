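#' @import methods
#' @importFrom Biostrings AAStringSet readAAStringSet writeXStringSet width
#' @importClassesFrom Biostrings AAStringSet
#' @importFrom stats cor quantile runif setNames var
#' @importFrom utils head read.delim write.table
#' @useDynLib coevopair, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' The 21-letter alphabet: 20 amino acids plus the gap symbol
#'
#' All frequency counts run over this fixed alphabet of size Q = 21; the gap
#' is a first-class symbol, so pseudocount denominators are Q and Q^2
#' throughout.
#'
#' @format A character vector of length 21.
#' @export
OMEGA <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

#' Pairing: a permutation matching rows of family A to rows of family B
#'
#' A pairing (the genetic algorithm's genome) assigns to each row k of the
#' family-A alignment the row `perm(z)[k]` of the family-B alignment. The
#' native pairing of a curated row-matched alignment pair is the identity.
#'
#' @slot perm integer permutation of `1:M` (1-based).
#' @export
setClass("Pairing", representation(perm = "integer"), validity = function(object) {
  p <- object@perm
  if (length(p) < 1L) return("empty permutation")
  if (anyNA(p) || !setequal(p, seq_along(p)))
    return("perm must be a permutation of 1:M")
  TRUE
})

#' Construct a Pairing
#'
#' @param perm integer vector, a permutation of `1:M`.
#' @return A [Pairing-class] object.
#' @examples
#' Pairing(c(2L, 1L, 3L))
#' @export
Pairing <- function(perm) new("Pairing", perm = as.integer(perm))

#' Extract the permutation from a Pairing
#' @param z a [Pairing-class].
#' @return Integer vector: `perm(z)[k]` is the B-row matched to A-row k.
#' @export
perm <- function(z) z@perm

#' Identity pairing on M rows
#' @param M number of rows.
#' @export
identityPairing <- function(M) Pairing(seq_len(M))

#' Invert a pairing
#' @param z a [Pairing-class].
#' @return The inverse [Pairing-class] (B-to-A map as an A-to-B pairing).
#' @export
invertPairing <- function(z) Pairing(order(z@perm))

setMethod("show", "Pairing", function(object) {
  M <- length(object@perm)
  cat("Pairing over", M, "rows;", sum(object@perm == seq_len(M)),
      "fixed point(s)\n")
})

#' AlignmentPair: two row-matched family alignments
#'
#' Bundles the MSAs of two interacting protein families together with the
#' native pairing and, for paralogous families, a species label per row. By
#' convention row k of MSA A is the native partner of row k of MSA B
#' (identity pairing); any other ground truth must be given explicitly.
#'
#' @slot msaA,msaB `AAStringSet` alignments, equal row count M, each
#'   internally of constant width.
#' @slot native the ground-truth [Pairing-class].
#' @slot species character vector of length M (or length 0 when absent);
#'   in paralog mode the native pairing never crosses species.
#' @export
setClass("AlignmentPair",
  representation(msaA = "AAStringSet", msaB = "AAStringSet",
                 native = "Pairing", species = "character"),
  validity = function(object) {
    M <- length(object@msaA)
    if (length(object@msaB) != M)
      return(sprintf("msaA has %d rows but msaB has %d", M, length(object@msaB)))
    if (M > 0 && length(unique(width(object@msaA))) != 1L)
      return("msaA rows differ in length")
    if (M > 0 && length(unique(width(object@msaB))) != 1L)
      return("msaB rows differ in length")
    if (length(object@native@perm) != M)
      return("native pairing length != M")
    bad <- !strsplit(paste(c(as.character(object@msaA),
                             as.character(object@msaB)), collapse = ""), "")[[1]] %in% OMEGA
    if (any(bad))
      return("alignment contains characters outside the 21-letter alphabet")
    if (length(object@species) > 0) {
      if (length(object@species) != M)
        return("species labels must cover every row")
      if (any(object@species[object@native@perm] != object@species))
        return("native pairing crosses species blocks")
    }
    TRUE
  })

setMethod("show", "AlignmentPair", function(object) {
  cat("AlignmentPair: M =", length(object@msaA),
      "| L_A =", if (length(object@msaA)) width(object@msaA)[1] else 0,
      "| L_B =", if (length(object@msaB)) width(object@msaB)[1] else 0)
  if (length(object@species))
    cat(" |", length(unique(object@species)), "species")
  cat("\n")
})

#' @describeIn AlignmentPair-class accessor for the family-A alignment.
#' @param pair an `AlignmentPair`.
#' @export
msaA <- function(pair) pair@msaA

#' @describeIn AlignmentPair-class accessor for the family-B alignment.
#' @export
msaB <- function(pair) pair@msaB

#' @describeIn AlignmentPair-class accessor for the native pairing.
#' @export
nativePairing <- function(pair) pair@native

#' @describeIn AlignmentPair-class accessor for species labels (`NULL` when absent).
#' @export
speciesLabels <- function(pair) if (length(pair@species)) pair@species else NULL

#' @describeIn AlignmentPair-class number of rows M.
#' @export
nRows <- function(pair) length(pair@msaA)

#' ContactMap: interface contacts as pairs of alignment columns
#'
#' Each of the N interface contacts links one column of the family-A
#' alignment to one column of the family-B alignment. Columns are 1-based.
#'
#' @slot pairs integer N x 2 matrix, columns `colA`, `colB`.
#' @slot meta data.frame of per-contact provenance (residue numbers,
#'   distances) when derived from a structure; may have zero columns.
#' @export
setClass("ContactMap",
  representation(pairs = "matrix", meta = "data.frame"),
  validity = function(object) {
    p <- object@pairs
    if (!is.numeric(p) || ncol(p) != 2L) return("pairs must be an N x 2 matrix")
    if (nrow(p) < 1L) return("a contact map needs at least one contact")
    if (anyNA(p) || any(p < 1)) return("column indices must be positive")
    if (anyDuplicated(paste(p[, 1], p[, 2]))) return("duplicate contact pair")
    TRUE
  })

#' Construct a ContactMap
#'
#' @param colA,colB integer vectors of equal length: the MSA-A and MSA-B
#'   columns of each contact.
#' @param meta optional data.frame of per-contact annotations.
#' @return A [ContactMap-class].
#' @export
ContactMap <- function(colA, colB, meta = data.frame()) {
  m <- cbind(colA = as.integer(colA), colB = as.integer(colB))
  new("ContactMap", pairs = m, meta = meta)
}

#' @describeIn ContactMap-class the N x 2 matrix of column pairs.
#' @param cmap a `ContactMap`.
#' @export
contactPairs <- function(cmap) cmap@pairs

#' @describeIn ContactMap-class the number of contacts N.
#' @export
nContacts <- function(cmap) nrow(cmap@pairs)

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@pairs), "contacts; A columns",
      min(object@pairs[, 1]), "-", max(object@pairs[, 1]), ", B columns",
      min(object@pairs[, 2]), "-", max(object@pairs[, 2]), "\n")
})

#' MIResult: interface mutual information under one pairing
#'
#' Per-contact Shannon MI (nats) of the interface column pairs under a given
#' pairing, together with the per-contact joint entropies, their mean
#' (`iHatAB`), the total (fitness of the genetic algorithm), and the
#' entropy-regularised sum of per-contact ratios I_i/H_i.
#'
#' @slot perContact numeric length-N vector of I(X_i; Y_i | z), nats.
#' @slot perContactEntropy numeric length-N vector of H(X_i, Y_i | z), nats.
#' @slot iHatAB mean per-contact MI (nats/contact).
#' @slot total N * iHatAB, the GA fitness.
#' @slot regularized sum over contacts of I_i / H_i (dimensionless).
#' @slot lambda pseudocount used.
#' @export
setClass("MIResult",
  representation(perContact = "numeric", perContactEntropy = "numeric",
                 iHatAB = "numeric", total = "numeric",
                 regularized = "numeric", lambda = "numeric"),
  validity = function(object) {
    if (length(object@perContact) != length(object@perContactEntropy))
      return("MI and entropy vectors differ in length")
    if (any(object@perContact < -1e-9))
      return("strongly negative per-contact MI")
    TRUE
  })

#' @describeIn MIResult-class per-contact MI vector (nats).
#' @param mi an `MIResult`.
#' @export
perContactMI <- function(mi) mi@perContact

#' @describeIn MIResult-class per-contact joint entropy vector (nats).
#' @export
perContactEntropy <- function(mi) mi@perContactEntropy

#' @describeIn MIResult-class mean per-contact MI (nats/contact).
#' @export
iHatAB <- function(mi) mi@iHatAB

#' @describeIn MIResult-class total interface MI (N times the mean).
#' @export
totalMI <- function(mi) mi@total

setMethod("show", "MIResult", function(object) {
  cat(sprintf("MIResult: N = %d | I^_AB = %.4f nats/contact | total = %.4f | I/H sum = %.4f\n",
              length(object@perContact), object@iHatAB, object@total,
              object@regularized))
})

#' GATrajectory: one genetic-algorithm optimization replicate
#'
#' Records the best population fitness (total interface MI, nats) at every
#' generation, the same series normalised by the native total when a native
#' reference was supplied, and the final best pairing.
#'
#' @slot bestFitness numeric, length generations + 1 (entry 1 is the initial
#'   population); non-decreasing by elitism.
#' @slot relative bestFitness / native total MI (length 0 without reference).
#' @slot finalPairing the best [Pairing-class] at the last generation.
#' @slot replicateId,seed integers identifying the replicate.
#' @slot nativeTotal the native reference total MI (NA when absent).
#' @export
setClass("GATrajectory",
  representation(bestFitness = "numeric", relative = "numeric",
                 finalPairing = "Pairing", replicateId = "integer",
                 seed = "integer", nativeTotal = "numeric"))

#' @describeIn GATrajectory-class best total interface MI per generation.
#' @param traj a `GATrajectory`.
#' @export
bestFitness <- function(traj) traj@bestFitness

#' @describeIn GATrajectory-class best fitness relative to the native total.
#' @export
relativeFitness <- function(traj) {
  if (!length(traj@relative))
    stop("trajectory has no native reference; relative series undefined")
  traj@relative
}

#' @describeIn GATrajectory-class final best pairing.
#' @export
finalPairing <- function(traj) traj@finalPairing

setMethod("show", "GATrajectory", function(object) {
  g <- length(object@bestFitness) - 1L
  cat(sprintf("GATrajectory: replicate %d, seed %d, %d generations, final fitness %.4f",
              object@replicateId, object@seed, g,
              object@bestFitness[length(object@bestFitness)]))
  if (length(object@relative))
    cat(sprintf(" (relative %.4f)", object@relative[length(object@relative)]))
  cat("\n")
})
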