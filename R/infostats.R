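# Per-contact frequencies, Shannon MI, joint entropy, regularization and the
# evolutive/coevolutive decomposition. All logarithms are natural (nats).

#' FrequencyTables: smoothed empirical frequencies at the interface
#'
#' Single-column and joint (pairing-conditional) amino-acid frequencies at
#' the N contact column pairs, after pseudocount smoothing. Singles are mixed
#' with lambda/Q and joints with lambda/Q^2, each applied to the raw
#' empirical frequencies independently; smoothed marginals are deliberately
#' not rederived from the smoothed joint.
#'
#' @slot singleA,singleB N x 21 matrices of smoothed column frequencies.
#' @slot joint 21 x 21 x N array of smoothed joint frequencies under z.
#' @slot lambda pseudocount weight in [0, 1).
#' @export
setClass("FrequencyTables",
  representation(singleA = "matrix", singleB = "matrix", joint = "array",
                 lambda = "numeric"),
  validity = function(object) {
    if (max(abs(rowSums(object@singleA) - 1)) > 1e-9 ||
        max(abs(rowSums(object@singleB) - 1)) > 1e-9)
      return("single-column frequencies must sum to 1")
    if (max(abs(apply(object@joint, 3, sum) - 1)) > 1e-9)
      return("joint frequencies must sum to 1")
    TRUE
  })

.Q <- 21L

# raw (unsmoothed) per-contact count tables; singles do not depend on z
.contactCounts <- function(pair, cmap, z) {
  cp <- contactPairs(cmap)
  encA <- .encodeMSA(msaA(pair))
  encB <- .encodeMSA(msaB(pair))
  M <- nrow(encA); N <- nrow(cp)
  xa <- encA[, cp[, 1], drop = FALSE]
  yb <- encB[perm(z), cp[, 2], drop = FALSE]
  # linear index chosen so the 441-vector reshapes column-major into a
  # 21 x 21 [x, y] table
  jointIdx <- (yb - 1L) * .Q + xa
  list(
    M = M, N = N,
    countsA = t(vapply(seq_len(N), function(i) tabulate(xa[, i], .Q), integer(.Q))),
    countsB = t(vapply(seq_len(N), function(i) tabulate(encB[, cp[i, 2]], .Q), integer(.Q))),
    jointCounts = vapply(seq_len(N), function(i) tabulate(jointIdx[, i], .Q * .Q),
                         integer(.Q * .Q))  # 441 x N
  )
}

#' Count and smooth interface frequencies
#'
#' Tallies single-column frequencies of the contact columns (independent of
#' the pairing) and joint frequencies of each contact column pair under the
#' pairing `z`, then applies the pseudocount mix
#' `f <- (1 - lambda) f + lambda / Q` to singles and
#' `f <- (1 - lambda) f + lambda / Q^2` to joints.
#'
#' @param pair an [AlignmentPair-class].
#' @param cmap a [ContactMap-class].
#' @param z a [Pairing-class]; defaults to the native pairing.
#' @param lambda pseudocount in `[0, 1)`; default 0.001.
#' @return A [FrequencyTables-class].
#' @export
countFrequencies <- function(pair, cmap, z = nativePairing(pair), lambda = 0.001) {
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
  cc <- .contactCounts(pair, cmap, z)
  sA <- (1 - lambda) * cc$countsA / cc$M + lambda / .Q
  sB <- (1 - lambda) * cc$countsB / cc$M + lambda / .Q
  J <- (1 - lambda) * cc$jointCounts / cc$M + lambda / .Q^2
  new("FrequencyTables", singleA = sA, singleB = sB,
      joint = array(J, dim = c(.Q, .Q, cc$N)), lambda = lambda)
}

#' Mutual information of one contact
#'
#' Computes `sum_{x,y} f(x,y|z) ln( f(x,y|z) / (f(x) f(y)) )` over the
#' 21 x 21 alphabet for contact `i`; cells with zero joint frequency
#' contribute nothing.
#'
#' @param tables a [FrequencyTables-class].
#' @param i contact index.
#' @return MI in nats.
#' @export
contactMI <- function(tables, i) {
  J <- tables@joint[, , i]
  denom <- outer(tables@singleA[i, ], tables@singleB[i, ])
  pos <- J > 0
  sum(J[pos] * log(J[pos] / denom[pos]))
}

#' Joint entropy of one contact
#'
#' Shannon joint entropy `-sum f(x,y|z) ln f(x,y|z)` of the smoothed joint
#' distribution of contact `i`.
#'
#' @inheritParams contactMI
#' @return Entropy in nats.
#' @export
contactJointEntropy <- function(tables, i) {
  J <- tables@joint[, , i]
  pos <- J > 0
  -sum(J[pos] * log(J[pos]))
}

#' Interface mutual information under a pairing
#'
#' The central score: per-contact MI of every interface column pair given
#' the pairing `z`, its mean over contacts (nats/contact), the total (the
#' genetic algorithm's fitness) and the entropy-regularised sum of ratios
#' `sum_i I_i / H_i`. Tiny negative per-contact values that the independent
#' smoothing of marginals and joints can produce are kept as computed.
#'
#' @inheritParams countFrequencies
#' @return An [MIResult-class].
#' @examples
#' ap <- alignmentPair(c("AC", "CA", "AA", "CC"), c("DK", "KD", "DD", "KK"))
#' cm <- ContactMap(1:2, 1:2)
#' interfaceMI(ap, cm, lambda = 0)
#' @export
interfaceMI <- function(pair, cmap, z = nativePairing(pair), lambda = 0.001) {
  if (nContacts(cmap) == 0L) stop("contact map is empty")
  tabs <- countFrequencies(pair, cmap, z, lambda)
  N <- nContacts(cmap)
  I <- vapply(seq_len(N), function(i) contactMI(tabs, i), numeric(1))
  H <- vapply(seq_len(N), function(i) contactJointEntropy(tabs, i), numeric(1))
  ratio <- ifelse(H > 0, I / H, 0)
  if (any(H <= 0))
    warning(sum(H <= 0), " contact(s) with zero joint entropy; ratio set to 0")
  new("MIResult", perContact = I, perContactEntropy = H,
      iHatAB = mean(I), total = sum(I), regularized = sum(ratio),
      lambda = lambda)
}

#' Entropy-regularised interface MI
#'
#' The sum over contacts of the per-contact ratio I(X_i;Y_i|z)/H(X_i,Y_i|z)
#' (a sum of ratios, not a ratio of sums).
#'
#' @param mi an [MIResult-class].
#' @return Dimensionless sum of per-contact ratios.
#' @export
regularizedMI <- function(mi) mi@regularized

#' Pearson correlation between two per-contact MI vectors
#'
#' Used to place an optimized solution in the nativelikeness plane: the
#' correlation between its per-contact MI vector and the native one.
#'
#' @param v,vNative numeric vectors of equal length (>= 2).
#' @return Pearson r, or `NA` (with a warning) when either vector is constant.
#' @export
miCorrelation <- function(v, vNative) {
  if (length(v) != length(vNative)) stop("vectors differ in length")
  if (length(v) < 2L) stop("need at least two contacts")
  if (var(v) == 0 || var(vNative) == 0) {
    warning("constant MI vector; correlation undefined")
    return(NA_real_)
  }
  cor(v, vNative)
}

#' Decompose interface MI into evolutive and coevolutive components
#'
#' The evolutive (phylogenetic) component is the MI carried by arbitrary
#' inter-family column pairs: `nBackground` non-contact (A-column, B-column)
#' pairs are sampled uniformly without replacement and scored with the same
#' MI machinery under the same pairing. The coevolutive component of each
#' contact is its MI surplus over the mean background MI, so that
#' mean(interface MI) = mean(evolutive) + mean(coevolutive).
#'
#' @inheritParams countFrequencies
#' @param nBackground number of background column pairs to sample; when more
#'   than available, all non-contact pairs are used (with a warning).
#' @param seed integer seed for the background sample.
#' @return A list with numeric vectors `evolutive` (length `nBackground`)
#'   and `coevolutive` (length N), plus `backgroundMean`.
#' @export
decomposeMI <- function(pair, cmap, z = nativePairing(pair), lambda = 0.001,
                        nBackground = max(nContacts(cmap), 500L), seed = 1L) {
  LA <- width(msaA(pair))[1]; LB <- width(msaB(pair))[1]
  cp <- contactPairs(cmap)
  contactKeys <- (cp[, 1] - 1L) * LB + cp[, 2]
  allKeys <- seq_len(LA * LB)
  poolKeys <- setdiff(allKeys, contactKeys)
  if (length(poolKeys) < nBackground) {
    warning("only ", length(poolKeys), " non-contact column pairs available; using all")
    nBackground <- length(poolKeys)
  }
  if (nBackground < 1L) stop("no non-contact column pairs to sample")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  keys <- sample(poolKeys, nBackground)
  bg <- ContactMap((keys - 1L) %/% LB + 1L, (keys - 1L) %% LB + 1L)
  evol <- perContactMI(interfaceMI(pair, bg, z, lambda))
  intf <- perContactMI(interfaceMI(pair, cmap, z, lambda))
  list(evolutive = evol, coevolutive = intf - mean(evol),
       backgroundMean = mean(evol))
}

#' Write a per-contact MI report as TSV
#'
#' One row per contact (columns, I_i, H_i, I_i/H_i) followed by a summary
#' row with the mean, total and regularised sums.
#'
#' @param mi an [MIResult-class].
#' @param cmap the matching [ContactMap-class].
#' @param path output path.
#' @export
writeMIReport <- function(mi, cmap, path) {
  cp <- contactPairs(cmap)
  H <- mi@perContactEntropy
  tab <- data.frame(col_a = cp[, 1], col_b = cp[, 2],
                    I = mi@perContact, H = H,
                    I_over_H = ifelse(H > 0, mi@perContact / H, 0))
  sm <- data.frame(col_a = NA, col_b = NA, I = mi@iHatAB, H = mi@total,
                   I_over_H = mi@regularized)
  write.table(rbind(tab, sm), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
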