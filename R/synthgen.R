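# Synthetic coevolved alignment pairs: per-contact coupled columns,
# independent background columns, optional similarity clusters (the trivial
# type-(i) error source) and optional species blocks (paralog mode).

#' Specification of a synthetic coevolved alignment pair
#'
#' @param M number of row pairs.
#' @param N number of interface contacts (one coupled column pair each).
#' @param LbgA,LbgB background (non-contact) columns per family.
#' @param epsilon per-contact coupling strength in `[0, 1]`: 0 gives
#'   independent columns, 1 a deterministic one-to-one symbol pairing.
#' @param qEff effective number of symbols per column (2..20; drawn from the
#'   amino-acid alphabet, never the gap).
#' @param nClusters similarity-cluster count; 0 means cluster-free (every
#'   row drawn independently). Cluster centroids form a divergence chain
#'   (a ladderized phylogeny), so clusters carry a graded relatedness
#'   structure, and the clusters are coherent across the two families:
#'   partners of similar B rows have similar A rows.
#' @param withinClusterDivergence per-position probability that a cluster
#'   member deviates from its centroid at a background column. Contact
#'   columns are inherited unchanged within a cluster: interface positions
#'   are conserved among close homologs, which is what makes cluster
#'   members interchangeable for the MI score (the trivial error source).
#' @param betweenClusterDivergence per-position substitution probability
#'   applied at each step of the centroid chain, at contact and background
#'   columns alike (contact cells are redrawn jointly from the contact's
#'   coupled model, preserving the coupling).
#' @param speciesSizes optional integer vector summing to M: species block
#'   sizes for paralog mode.
#' @param seed RNG seed; generation is fully reproducible.
#' @return A validated list of class `"SynthSpec"`.
#' @export
synthSpec <- function(M, N, LbgA = 50L, LbgB = 50L, epsilon = 0.8,
                      qEff = 8L, nClusters = 0L,
                      withinClusterDivergence = 0.1,
                      betweenClusterDivergence = 0.25, speciesSizes = NULL,
                      seed = 1L) {
  spec <- list(M = as.integer(M), N = as.integer(N), LbgA = as.integer(LbgA),
               LbgB = as.integer(LbgB), epsilon = epsilon,
               qEff = as.integer(qEff), nClusters = as.integer(nClusters),
               withinClusterDivergence = withinClusterDivergence,
               betweenClusterDivergence = betweenClusterDivergence,
               speciesSizes = if (is.null(speciesSizes)) NULL
                              else as.integer(speciesSizes),
               seed = as.integer(seed))
  if (spec$M < 2) stop("M must be >= 2")
  if (spec$N < 1) stop("N must be >= 1")
  if (spec$epsilon < 0 || spec$epsilon > 1) stop("epsilon must lie in [0, 1]")
  if (spec$qEff < 2 || spec$qEff > 20) stop("qEff must lie in 2..20")
  if (spec$nClusters < 0 || spec$nClusters > spec$M) stop("bad nClusters")
  if (spec$withinClusterDivergence < 0 || spec$withinClusterDivergence > 1)
    stop("withinClusterDivergence must lie in [0, 1]")
  if (spec$betweenClusterDivergence < 0 || spec$betweenClusterDivergence > 1)
    stop("betweenClusterDivergence must lie in [0, 1]")
  if (!is.null(spec$speciesSizes)) {
    if (any(spec$speciesSizes < 1) || sum(spec$speciesSizes) != spec$M)
      stop("speciesSizes must be positive and sum to M")
  }
  class(spec) <- "SynthSpec"
  spec
}

# symmetric-Dirichlet(1) marginal over q symbols
.randomMarginal <- function(q) {
  w <- -log(runif(q))
  w / sum(w)
}

#' Coupled joint distribution for one contact
#'
#' The mixture `P = epsilon * C + (1 - epsilon) * (px %o% py)` over a random
#' `qEff`-symbol support, where `C` puts mass 1/qEff on the cells of a random
#' one-to-one symbol coupling and `px`, `py` are random marginals over the
#' same symbols. `epsilon = 0` gives independence (zero MI); `epsilon = 1`
#' a deterministic pairing with MI `ln(qEff)`. Draws come from the current
#' RNG state.
#'
#' @param epsilon coupling strength in `[0, 1]`.
#' @param qEff number of supported symbols per side.
#' @return A list: `symX`, `symY` (alphabet indices of the support), `joint`
#'   (qEff x qEff matrix summing to 1) and `mi` (the model MI in nats).
#' @export
coupledPairModel <- function(epsilon, qEff) {
  symX <- sort(sample.int(20L, qEff))
  symY <- sort(sample.int(20L, qEff))
  sigma <- sample.int(qEff)
  C <- matrix(0, qEff, qEff)
  C[cbind(seq_len(qEff), sigma)] <- 1 / qEff
  px <- .randomMarginal(qEff); py <- .randomMarginal(qEff)
  J <- epsilon * C + (1 - epsilon) * outer(px, py)
  list(symX = symX, symY = symY, joint = J, mi = distributionMI(J))
}

#' Mutual information of a joint distribution table
#'
#' `sum p(x, y) ln( p(x, y) / (p(x) p(y)) )` with marginals taken from the
#' table itself; zero cells contribute nothing.
#'
#' @param joint a non-negative matrix summing to 1.
#' @return MI in nats.
#' @export
distributionMI <- function(joint) {
  px <- rowSums(joint); py <- colSums(joint)
  denom <- outer(px, py)
  pos <- joint > 0
  sum(joint[pos] * log(joint[pos] / denom[pos]))
}

# draw n cells (1..q^2) from a joint table
.sampleCells <- function(joint, n) {
  sample.int(length(joint), n, replace = TRUE, prob = as.vector(joint))
}

#' Generate a synthetic coevolved alignment pair
#'
#' Native rows are drawn column-wise: each of the N contact column pairs
#' from its own coupled joint model, each background column from an
#' independent random marginal. With `nClusters = 0` every row is an
#' independent draw (the high-specificity, cluster-free regime). With
#' `nClusters > 0`, cluster centroids form a divergence chain — each
#' centroid is the previous one with `betweenClusterDivergence` of its
#' positions resampled (contact cells jointly, from the coupled model) —
#' and rows copy their centroid, resampling background positions at rate
#' `withinClusterDivergence` while inheriting contact cells unchanged.
#' This plants the similar-sequence (type-(i)) error source: cluster
#' members are distinguishable in sequence but interchangeable for the
#' interface MI score. Contact columns are appended after the background
#' columns and indexed by the returned contact map. The native pairing is
#' the identity.
#'
#' @param spec a [synthSpec()] object.
#' @return A list: `pair` ([AlignmentPair-class]), `cmap`
#'   ([ContactMap-class]), `truth` (per-contact models and model MI,
#'   cluster assignment, the generating specification).
#' @export
generateSyntheticPair <- function(spec) {
  stopifnot(inherits(spec, "SynthSpec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  M <- spec$M; N <- spec$N; q <- spec$qEff
  models <- lapply(seq_len(N), function(i) coupledPairModel(spec$epsilon, q))
  bgA <- lapply(seq_len(spec$LbgA), function(j)
    list(sym = sort(sample.int(20L, q)), p = .randomMarginal(q)))
  bgB <- lapply(seq_len(spec$LbgB), function(j)
    list(sym = sort(sample.int(20L, q)), p = .randomMarginal(q)))

  encA <- matrix(0L, M, spec$LbgA + N)
  encB <- matrix(0L, M, spec$LbgB + N)

  if (spec$nClusters == 0L) {
    cluster <- seq_len(M)  # every row an independent draw
    for (j in seq_len(spec$LbgA))
      encA[, j] <- bgA[[j]]$sym[.sampleCells(bgA[[j]]$p, M)]
    for (j in seq_len(spec$LbgB))
      encB[, j] <- bgB[[j]]$sym[.sampleCells(bgB[[j]]$p, M)]
    for (i in seq_len(N)) {
      cell <- .sampleCells(models[[i]]$joint, M)
      encA[, spec$LbgA + i] <- models[[i]]$symX[(cell - 1L) %% q + 1L]
      encB[, spec$LbgB + i] <- models[[i]]$symY[(cell - 1L) %/% q + 1L]
    }
  } else {
    K <- spec$nClusters
    sizes <- rep(M %/% K, K)
    extra <- M - sum(sizes)
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    cluster <- rep(seq_len(K), sizes)
    dW <- spec$withinClusterDivergence
    dB <- spec$betweenClusterDivergence
    # centroid chain: contact cells (K x N) and background symbol indices
    cells <- matrix(0L, K, N)
    cenA <- matrix(0L, K, spec$LbgA); cenB <- matrix(0L, K, spec$LbgB)
    cells[1, ] <- vapply(models, function(m) .sampleCells(m$joint, 1L), integer(1))
    cenA[1, ] <- vapply(bgA, function(m) .sampleCells(m$p, 1L), integer(1))
    cenB[1, ] <- vapply(bgB, function(m) .sampleCells(m$p, 1L), integer(1))
    if (K > 1) for (k in 2:K) {
      cells[k, ] <- cells[k - 1, ]
      f <- which(runif(N) < dB)
      cells[k, f] <- vapply(f, function(i) .sampleCells(models[[i]]$joint, 1L),
                            integer(1))
      cenA[k, ] <- cenA[k - 1, ]
      f <- which(runif(spec$LbgA) < dB)
      cenA[k, f] <- vapply(f, function(j) .sampleCells(bgA[[j]]$p, 1L), integer(1))
      cenB[k, ] <- cenB[k - 1, ]
      f <- which(runif(spec$LbgB) < dB)
      cenB[k, f] <- vapply(f, function(j) .sampleCells(bgB[[j]]$p, 1L), integer(1))
    }
    for (j in seq_len(spec$LbgA)) {
      col <- cenA[cluster, j]
      fresh <- runif(M) < dW
      col[fresh] <- .sampleCells(bgA[[j]]$p, sum(fresh))
      encA[, j] <- bgA[[j]]$sym[col]
    }
    for (j in seq_len(spec$LbgB)) {
      col <- cenB[cluster, j]
      fresh <- runif(M) < dW
      col[fresh] <- .sampleCells(bgB[[j]]$p, sum(fresh))
      encB[, j] <- bgB[[j]]$sym[col]
    }
    for (i in seq_len(N)) {
      cell <- cells[cluster, i]  # inherited unchanged within a cluster
      encA[, spec$LbgA + i] <- models[[i]]$symX[(cell - 1L) %% q + 1L]
      encB[, spec$LbgB + i] <- models[[i]]$symY[(cell - 1L) %/% q + 1L]
    }
  }

  toSeqs <- function(enc, prefix) {
    s <- apply(enc, 1, function(r) paste(OMEGA[r], collapse = ""))
    setNames(s, sprintf("%s%04d", prefix, seq_len(nrow(enc))))
  }
  species <- if (!is.null(spec$speciesSizes))
    rep(sprintf("sp%03d", seq_along(spec$speciesSizes)), spec$speciesSizes)
  pair <- alignmentPair(toSeqs(encA, "A"), toSeqs(encB, "B"), species = species)
  cmap <- ContactMap(spec$LbgA + seq_len(N), spec$LbgB + seq_len(N))
  list(pair = pair, cmap = cmap,
       truth = list(models = models, modelMI = vapply(models, `[[`, numeric(1), "mi"),
                    cluster = cluster, spec = spec))
}

#' Compare estimated per-contact MI with the generative model
#'
#' Estimates per-contact MI under the native pairing of a generated dataset
#' and reports the per-contact error against the model MI values, its bias
#' and RMSE. Finite-M sampling and the pseudocount give the estimator a
#' positive floor at `epsilon = 0`; the bias shrinks as M grows.
#'
#' @param spec a [synthSpec()] object.
#' @param lambda pseudocount for the estimate (default 0.001).
#' @return A list: `perContact` data.frame (`model`, `estimate`, `error`),
#'   `bias`, `rmse`.
#' @export
parameterRecoveryCheck <- function(spec, lambda = 0.001) {
  dat <- generateSyntheticPair(spec)
  est <- perContactMI(interfaceMI(dat$pair, dat$cmap, lambda = lambda))
  err <- est - dat$truth$modelMI
  list(perContact = data.frame(model = dat$truth$modelMI, estimate = est,
                               error = err),
       bias = mean(err), rmse = sqrt(mean(err^2)))
}

#' Write a generated dataset to a directory
#'
#' Emits `msa_a.fasta`, `msa_b.fasta`, `contacts.tsv`, `species.tsv` (when
#' present) and `truth.json` (spec and per-contact model MI).
#'
#' @param dat result of [generateSyntheticPair()].
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
writeSyntheticPair <- function(dat, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeAlignment(msaA(dat$pair), file.path(dir, "msa_a.fasta"))
  writeAlignment(msaB(dat$pair), file.path(dir, "msa_b.fasta"))
  writeContactMap(dat$cmap, file.path(dir, "contacts.tsv"))
  sp <- speciesLabels(dat$pair)
  if (!is.null(sp))
    write.table(data.frame(id = names(msaA(dat$pair)), species = sp),
                file.path(dir, "species.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  truth <- unclass(dat$truth$spec)
  truth$modelMI <- dat$truth$modelMI
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}
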