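# Accuracy assessment of pairing solutions: raw and mismatch-discounted TP
# rates, type-(i)/(ii) classification, KNN nativelikeness separation, group
# assignment and cross-system correlations.

#' True-positive rate of a pairing
#'
#' Fraction of rows assigned their native partner.
#'
#' @param z,native [Pairing-class] objects over the same M rows.
#' @return Fraction in `[0, 1]`.
#' @export
tpRate <- function(z, native) {
  if (length(perm(z)) != length(perm(native))) stop("pairings differ in length")
  mean(perm(z) == perm(native))
}

#' Normalized Hamming distance between two aligned sequences
#'
#' Fraction of positions whose symbols differ; the gap counts as an ordinary
#' symbol.
#'
#' @param s1,s2 aligned sequences (equal length).
#' @return Distance in `[0, 1]`.
#' @export
hammingDistance <- function(s1, s2) {
  s1 <- as.character(s1); s2 <- as.character(s2)
  if (nchar(s1) != nchar(s2)) stop("sequences differ in length")
  a <- strsplit(s1, "")[[1]]; b <- strsplit(s2, "")[[1]]
  mean(a != b)
}

#' All pairwise normalized Hamming distances within an alignment
#'
#' @param msa an `AAStringSet` (or character vector) alignment.
#' @return Symmetric M x M matrix of distances.
#' @export
pairwiseHamming <- function(msa) {
  if (is.character(msa)) msa <- Biostrings::AAStringSet(msa)
  .hammingMatrix(.encodeMSA(msa))
}

#' Hamming-distance percentile cutoff of family B
#'
#' The stated percentile (linear interpolation between order statistics) of
#' the M(M-1)/2 pairwise distances within the family-B alignment; mismatch
#' discounting forgives errors below this cutoff.
#'
#' @param msaB the family-B alignment (`AAStringSet` or character vector).
#' @param percentile percent in `[0, 100]` (default 20).
#' @param distances optional precomputed matrix from [pairwiseHamming()].
#' @return The distance threshold.
#' @export
percentileCutoff <- function(msaB, percentile = 20, distances = NULL) {
  if (is.null(distances)) distances <- pairwiseHamming(msaB)
  d <- distances[upper.tri(distances)]
  if (!length(d)) stop("need at least two rows")
  unname(quantile(d, percentile / 100, type = 7))
}

#' Mismatch-discounted true-positive rate
#'
#' Counts a row as correct when it is paired with its native partner or with
#' a partner whose Hamming distance to the native one does not exceed
#' `cutoff`.
#'
#' @inheritParams tpRate
#' @param msaB the family-B alignment.
#' @param cutoff distance threshold, typically from [percentileCutoff()].
#' @param distances optional precomputed [pairwiseHamming()] matrix.
#' @return Fraction in `[0, 1]`.
#' @export
tpRateDiscounted <- function(z, native, msaB, cutoff, distances = NULL) {
  if (is.null(distances)) distances <- pairwiseHamming(msaB)
  got <- perm(z); want <- perm(native)
  mean(got == want | distances[cbind(got, want)] <= cutoff)
}

#' TP rate as a function of the discount percentile
#'
#' @inheritParams tpRateDiscounted
#' @param percentiles percent values to evaluate (default 0 to 100 by 5).
#' @return data.frame with columns `percentile`, `cutoff`, `tpDiscounted`
#'   (non-decreasing in percentile).
#' @export
tpVsPercentileCurve <- function(z, native, msaB, percentiles = seq(0, 100, by = 5),
                                distances = NULL) {
  if (is.null(distances)) distances <- pairwiseHamming(msaB)
  percentiles <- sort(percentiles)
  cuts <- vapply(percentiles, function(p)
    percentileCutoff(msaB, p, distances), numeric(1))
  tp <- vapply(cuts, function(ct)
    tpRateDiscounted(z, native, msaB, ct, distances), numeric(1))
  data.frame(percentile = percentiles, cutoff = cuts, tpDiscounted = tp)
}

#' Assess one pairing solution
#'
#' Bundles everything the downstream classification needs: raw and
#' 20th-percentile-discounted TP rates, the relative interface MI, the
#' per-contact MI vector and its Pearson correlation with the native vector,
#' and the type label under the 30\% rule.
#'
#' @param pair an [AlignmentPair-class].
#' @param cmap a [ContactMap-class].
#' @param z the [Pairing-class] to assess.
#' @param nativeMI [MIResult-class] under the native pairing (computed when
#'   missing).
#' @param lambda pseudocount (default 0.001).
#' @param percentile discount percentile (default 20).
#' @param threshold type-(i)/(ii) boundary on the discounted TP rate
#'   (default 0.30, strict).
#' @param kind `"optimized"` solutions receive a type label; `"native"` and
#'   `"random"` pass through as their own labels.
#' @param distances optional precomputed [pairwiseHamming()] of MSA B.
#' @return A list with elements `tpRaw`, `tpDiscounted`, `relativeMI`,
#'   `miVector`, `rNative`, `type`, `percentileUsed`, `cutoff`.
#' @export
assessSolution <- function(pair, cmap, z, nativeMI = NULL, lambda = 0.001,
                           percentile = 20, threshold = 0.30,
                           kind = c("optimized", "native", "random"),
                           distances = NULL) {
  kind <- match.arg(kind)
  if (is.null(nativeMI))
    nativeMI <- interfaceMI(pair, cmap, nativePairing(pair), lambda)
  if (is.null(distances)) distances <- pairwiseHamming(msaB(pair))
  mi <- interfaceMI(pair, cmap, z, lambda)
  cutoff <- percentileCutoff(msaB(pair), percentile, distances)
  sol <- list(
    tpRaw = tpRate(z, nativePairing(pair)),
    tpDiscounted = tpRateDiscounted(z, nativePairing(pair), msaB(pair),
                                    cutoff, distances),
    relativeMI = totalMI(mi) / totalMI(nativeMI),
    miVector = perContactMI(mi),
    rNative = miCorrelation(perContactMI(mi), perContactMI(nativeMI)),
    percentileUsed = percentile, cutoff = cutoff, kind = kind)
  sol$type <- classifySolution(sol, threshold)
  sol
}

#' Type-(i)/(ii) classification of an assessed solution
#'
#' An optimized solution is type (i) when its discounted TP rate strictly
#' exceeds the threshold (errors mostly among similar sequences, hence
#' forgiven) and type (ii) otherwise; native and random solutions keep
#' their own labels.
#'
#' @param assessment list from [assessSolution()], or a bare discounted TP
#'   rate.
#' @param threshold boundary (default 0.30); the boundary itself is type (ii).
#' @return One of `"type_i"`, `"type_ii"`, `"native"`, `"random"`.
#' @export
classifySolution <- function(assessment, threshold = 0.30) {
  if (is.numeric(assessment)) assessment <- list(tpDiscounted = assessment,
                                                 kind = "optimized")
  if (assessment$kind %in% c("native", "random")) return(assessment$kind)
  if (assessment$tpDiscounted > threshold) "type_i" else "type_ii"
}

#' Tabulate a list of solution assessments
#'
#' @param assessments list of [assessSolution()] results.
#' @return data.frame with one row per solution (`tpRaw`, `tpDiscounted`,
#'   `relativeMI`, `rNative`, `type`, `kind`).
#' @export
solutionTable <- function(assessments) {
  do.call(rbind, lapply(assessments, function(a)
    data.frame(tpRaw = a$tpRaw, tpDiscounted = a$tpDiscounted,
               relativeMI = a$relativeMI, rNative = a$rNative,
               type = a$type, kind = a$kind)))
}

# k nearest training neighbours of each row of `query` (Euclidean);
# majority vote with ties broken toward the first class in label order
.knnVote <- function(train, labels, query, k, classes) {
  votes <- apply(query, 1, function(q) {
    d <- sqrt(colSums((t(train) - q)^2))
    nb <- labels[order(d)[seq_len(k)]]
    tally <- vapply(classes, function(cl) sum(nb == cl), numeric(1))
    classes[which.max(tally)]
  })
  unname(votes)
}

#' KNN separation of type-(i) and type-(ii) solutions
#'
#' Fits a k-nearest-neighbour majority vote (Euclidean distance, raw
#' unscaled features) on the type-(i)/(ii) solutions and reports the
#' training-set accuracy: the fraction of training points whose
#' k-neighbourhood (the point itself included, as in the usual
#' training-score convention) votes for their own label. Native and random
#' solutions are never trained on; project them afterwards with the
#' returned `predict` function.
#'
#' @param solutions data.frame from [solutionTable()] (or compatible) with a
#'   `type` column.
#' @param k number of neighbours (default 10); must be smaller than the
#'   number of training points.
#' @param features character vector of feature column names, default
#'   `c("relativeMI", "rNative")`.
#' @return List with `trainingAccuracy`, `predictions`, `predict(newdata)`,
#'   `k`, `features`.
#' @export
knnSeparation <- function(solutions, k = 10L,
                          features = c("relativeMI", "rNative")) {
  train <- solutions[solutions$type %in% c("type_i", "type_ii"), , drop = FALSE]
  X <- as.matrix(train[, features, drop = FALSE])
  if (any(!is.finite(X))) stop("non-finite feature values")
  y <- as.character(train$type)
  if (k >= nrow(X)) stop("k must be smaller than the number of training points")
  classes <- sort(unique(y))
  pred <- .knnVote(X, y, X, k, classes)
  list(trainingAccuracy = mean(pred == y), predictions = pred,
       predict = function(newdata) {
         Xn <- as.matrix(newdata[, features, drop = FALSE])
         .knnVote(X, y, Xn, k, classes)
       },
       k = k, features = features)
}

#' Assign a system to degeneracy group G1-G5
#'
#' G5 when the optimized solutions do not differentiate from the scrambled
#' baseline (mean discounted TP within `delta` of it); otherwise G1 with
#' only type-(i) replicates, G2 with a majority, G3 with an even split and
#' G4 with a minority.
#'
#' @param assessments list of replicate [assessSolution()] results
#'   (typically 6).
#' @param randomBaseline an [assessSolution()] result for a scrambled
#'   pairing.
#' @param delta margin on the discounted TP difference for G5 (default 0.05).
#' @return One of `"G1" ... "G5"`.
#' @export
assignGroup <- function(assessments, randomBaseline, delta = 0.05) {
  tps <- vapply(assessments, `[[`, numeric(1), "tpDiscounted")
  types <- vapply(assessments, `[[`, character(1), "type")
  if (mean(tps) - randomBaseline$tpDiscounted <= delta) return("G5")
  fi <- mean(types == "type_i")
  if (fi == 1) "G1" else if (fi > 0.5) "G2" else if (fi == 0.5) "G3" else "G4"
}

#' Cross-system correlations of TP rate with information content
#'
#' Pearson correlations of the per-system mean discounted TP rate against
#' native interface MI, its entropy-regularised form, the contact count N
#' and the alignment depth M, plus the regularised MI against N.
#'
#' @param perSystem data.frame with columns `tp`, `I_AB`, `I_over_H`, `N`,
#'   `M` (one row per system, >= 3 rows).
#' @return Named numeric vector of Pearson r (NA for constant columns).
#' @export
systemCorrelations <- function(perSystem) {
  need <- c("tp", "I_AB", "I_over_H", "N", "M")
  if (!all(need %in% names(perSystem))) stop("missing columns")
  if (nrow(perSystem) < 3) stop("need at least three systems")
  safeCor <- function(a, b) {
    if (var(a) == 0 || var(b) == 0) {
      warning("constant column; correlation undefined")
      return(NA_real_)
    }
    cor(a, b)
  }
  with(perSystem, c(
    tp_vs_I_AB = safeCor(tp, I_AB),
    tp_vs_I_over_H = safeCor(tp, I_over_H),
    tp_vs_N = safeCor(tp, N),
    tp_vs_M = safeCor(tp, M),
    I_over_H_vs_N = safeCor(I_over_H, N)))
}

#' Mean TP rate by paralog count
#'
#' For paralogous families the pairing is resolved within species; this
#' computes the TP rate inside each species and averages it over species
#' sharing the same paralog count.
#'
#' @param z,native [Pairing-class] objects.
#' @param species character label per row.
#' @return data.frame with columns `paralogs`, `meanTP`, `nSpecies`.
#' @export
paralogTPByCount <- function(z, native, species) {
  got <- perm(z); want <- perm(native)
  bySp <- split(seq_along(species), species)
  counts <- vapply(bySp, length, integer(1))
  tp <- vapply(bySp, function(idx) mean(got[idx] == want[idx]), numeric(1))
  agg <- tapply(tp, counts, mean)
  data.frame(paralogs = as.integer(names(agg)), meanTP = as.numeric(agg),
             nSpecies = as.integer(table(counts)), row.names = NULL)
}
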