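test_that("TP rate counts native matches", {
  native <- identityPairing(4)
  expect_equal(tpRate(native, native), 1.0)
  expect_equal(tpRate(scramblePairing(6, "derangement", seed = 2),
                      identityPairing(6)), 0.0)
  expect_equal(tpRate(Pairing(c(1L, 2L, 4L, 3L)), native), 0.5)
  expect_error(tpRate(identityPairing(3), native), "length")
})

test_that("Hamming distance treats the gap as an ordinary symbol", {
  expect_equal(hammingDistance("ACDE", "ACDE"), 0)
  expect_equal(hammingDistance("AAAA", "CCCC"), 1)
  expect_equal(hammingDistance("AC-D", "ACED"), 0.25)
  expect_error(hammingDistance("AC", "ACD"), "length")
})

test_that("pairwise distance matrix matches a double loop", {
  seqs <- c("ACDE", "ACDF", "KLMN", "A-DE")
  D <- pairwiseHamming(seqs)
  for (i in 1:4) for (j in 1:4)
    expect_equal(D[i, j], if (i == j) 0 else hammingDistance(seqs[i], seqs[j]))
})

test_that("percentile cutoff uses linear interpolation of order statistics", {
  # engineered alignment whose pairwise distances are known
  seqs <- c("AAAAAAAAAA", "AAAAAAAAAC", "AAAAAAACCC", "AAAACCCCCC")
  D <- pairwiseHamming(seqs)
  d <- D[upper.tri(D)]
  expect_equal(percentileCutoff(seqs, 100), max(d))
  expect_equal(percentileCutoff(seqs, 20), unname(quantile(d, 0.2, type = 7)))
  # direct check of the interpolation rule on the 20th percentile
  expect_equal(unname(quantile(c(0.1, 0.2, 0.3, 0.4, 0.5), 0.2, type = 7)), 0.18)
  same <- c("AACC", "CCAA", "AACC")  # d(1,3)=0 though; use equal-distance set
  expect_equal(percentileCutoff(c("AC", "CA"), 50), 1)
})

test_that("discounted TP forgives mismatches within the cutoff", {
  msaB <- c("AAAA", "AAAC", "CCCC")  # d(1,2)=0.25, others >= 0.75
  native <- identityPairing(3)
  z <- Pairing(c(2L, 1L, 3L))  # rows 1 and 2 swapped between similar seqs
  expect_equal(tpRateDiscounted(z, native, msaB, cutoff = 0), 1 / 3)
  expect_equal(tpRateDiscounted(z, native, msaB, cutoff = 0.25), 1.0)
  expect_equal(tpRateDiscounted(z, native, msaB, cutoff = 1), 1.0)
  # one wrong partner beyond the cutoff, two forgiven or correct
  msaB2 <- c("AAAA", "AAAC", "AACC")  # d(1,2) = d(2,3) = 0.25, d(1,3) = 0.5
  z2 <- Pairing(c(2L, 3L, 1L))
  expect_equal(tpRateDiscounted(z2, native, msaB2, cutoff = 0.25), 2 / 3)
  # cutoff 0 with distinct rows equals the raw TP rate
  expect_equal(tpRateDiscounted(z2, native, msaB2, 0), tpRate(z2, native))
})

test_that("TP-versus-percentile curves are non-decreasing and start above raw", {
  set.seed(3)
  dat <- generateSyntheticPair(synthSpec(M = 40, N = 10, LbgA = 20, LbgB = 20,
                                         epsilon = 0.8, qEff = 6, nClusters = 5,
                                         seed = 3))
  z <- scramblePairing(40, seed = 4)
  curve <- tpVsPercentileCurve(z, nativePairing(dat$pair), msaB(dat$pair))
  expect_true(all(diff(curve$tpDiscounted) >= 0))
  expect_gte(curve$tpDiscounted[1], tpRate(z, nativePairing(dat$pair)))
  expect_equal(curve$tpDiscounted[nrow(curve)], 1.0)
})

test_that("the 30 percent rule classifies solutions with a strict boundary", {
  expect_equal(classifySolution(0.7), "type_i")
  expect_equal(classifySolution(0.05), "type_ii")
  expect_equal(classifySolution(0.30), "type_ii")  # boundary goes to type (ii)
  expect_equal(classifySolution(list(tpDiscounted = 0.9, kind = "native")), "native")
  expect_equal(classifySolution(list(tpDiscounted = 0.1, kind = "random")), "random")
})

test_that("solution assessment bundles consistent quantities", {
  dat <- generateSyntheticPair(synthSpec(M = 30, N = 8, LbgA = 10, LbgB = 10,
                                         epsilon = 0.8, qEff = 5, nClusters = 5,
                                         seed = 6))
  nat <- interfaceMI(dat$pair, dat$cmap)
  sol <- assessSolution(dat$pair, dat$cmap, nativePairing(dat$pair), nat,
                        kind = "native")
  expect_equal(sol$tpRaw, 1.0)
  expect_equal(sol$relativeMI, 1.0)
  expect_equal(sol$rNative, 1.0)
  expect_equal(sol$type, "native")
  z <- scramblePairing(30, "derangement", seed = 2)
  rnd <- assessSolution(dat$pair, dat$cmap, z, nat, kind = "random")
  expect_equal(rnd$tpRaw, 0)
  expect_gte(rnd$tpDiscounted, rnd$tpRaw)
  tab <- solutionTable(list(sol, rnd))
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$type, c("native", "random"))
})

test_that("KNN separation reproduces brute-force majority votes", {
  set.seed(11)
  X <- cbind(relativeMI = c(rnorm(12, 1, 0.3), rnorm(12, 0, 0.3)),
             rNative = c(rnorm(12, 0.8, 0.2), rnorm(12, 0.2, 0.2)))
  sols <- data.frame(X, type = rep(c("type_i", "type_ii"), each = 12))
  for (k in c(1L, 3L, 10L)) {
    fit <- knnSeparation(sols, k = k)
    want <- oracleKnn(as.matrix(sols[, 1:2]), sols$type, k)
    expect_equal(fit$predictions, want)
    expect_equal(fit$trainingAccuracy, mean(want == sols$type))
  }
  # k = 1 is perfect by the self-neighbor convention
  expect_equal(knnSeparation(sols, k = 1L)$trainingAccuracy, 1.0)
  expect_error(knnSeparation(sols, k = 24L), "smaller")
})

test_that("KNN cross-checks against class::knn away from vote ties", {
  skip_if_not_installed("class")
  set.seed(21)
  X <- cbind(relativeMI = runif(30), rNative = runif(30))
  sols <- data.frame(X, type = sample(rep(c("type_i", "type_ii"), 15)))
  fit <- knnSeparation(sols, k = 5L)
  ref <- as.character(class::knn(X, X, factor(sols$type), k = 5))
  # class::knn resolves exact-distance ties randomly; none exist here
  expect_equal(fit$predictions, ref)
})

test_that("KNN separation is invariant under common feature rescaling", {
  set.seed(12)
  sols <- data.frame(relativeMI = runif(20), rNative = runif(20),
                     type = rep(c("type_i", "type_ii"), 10))
  a1 <- knnSeparation(sols, k = 4L)$trainingAccuracy
  scaled <- transform(sols, relativeMI = 3.7 * relativeMI, rNative = 3.7 * rNative)
  expect_equal(knnSeparation(scaled, k = 4L)$trainingAccuracy, a1)
})

test_that("projection of held-out points uses the trained neighbourhood", {
  sols <- data.frame(relativeMI = c(0, 0.1, 0.2, 1, 1.1, 1.2),
                     rNative = c(0, 0.1, 0.2, 1, 1.1, 1.2),
                     type = rep(c("type_ii", "type_i"), each = 3))
  fit <- knnSeparation(sols, k = 3L)
  proj <- fit$predict(data.frame(relativeMI = c(0.05, 1.15),
                                 rNative = c(0.05, 1.15)))
  expect_equal(proj, c("type_ii", "type_i"))
})

test_that("group assignment follows the composition and baseline rules", {
  mk <- function(tp, type) list(tpDiscounted = tp, type = type)
  base <- mk(0.1, "random")
  six_i <- replicate(6, mk(0.8, "type_i"), simplify = FALSE)
  expect_equal(assignGroup(six_i, base), "G1")
  mix42 <- c(replicate(4, mk(0.6, "type_i"), simplify = FALSE),
             replicate(2, mk(0.2, "type_ii"), simplify = FALSE))
  expect_equal(assignGroup(mix42, base), "G2")
  mix33 <- c(replicate(3, mk(0.6, "type_i"), simplify = FALSE),
             replicate(3, mk(0.2, "type_ii"), simplify = FALSE))
  expect_equal(assignGroup(mix33, base), "G3")
  mix15 <- c(replicate(1, mk(0.6, "type_i"), simplify = FALSE),
             replicate(5, mk(0.2, "type_ii"), simplify = FALSE))
  expect_equal(assignGroup(mix15, base), "G4")
  flat <- replicate(6, mk(0.12, "type_i"), simplify = FALSE)
  expect_equal(assignGroup(flat, base), "G5")  # no gain over scrambled
})

test_that("cross-system correlations match the textbook formula", {
  tab <- data.frame(tp = c(0.2, 0.4, 0.6, 0.8, 1.0),
                    I_AB = c(1, 2, 3, 4, 5),
                    I_over_H = c(0.1, 0.3, 0.2, 0.5, 0.4),
                    N = c(50, 120, 200, 320, 400),
                    M = c(300, 250, 280, 260, 310))
  r <- systemCorrelations(tab)
  expect_equal(unname(r["tp_vs_I_AB"]), 1.0)  # tp is a scaled copy of I_AB
  handCor <- function(x, y) sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(r["tp_vs_I_over_H"]), handCor(tab$tp, tab$I_over_H))
  expect_equal(unname(r["I_over_H_vs_N"]), handCor(tab$I_over_H, tab$N))
  expect_warning(r2 <- systemCorrelations(transform(tab, M = 300)), "constant")
  expect_true(is.na(r2["tp_vs_M"]))
  expect_error(systemCorrelations(tab[1:2, ]), "three")
})

test_that("permuted predictors decorrelate on a large synthetic panel", {
  set.seed(31)
  x <- runif(200)
  tab <- data.frame(tp = x, I_AB = x * 2, I_over_H = x, N = sample(200),
                    M = rnorm(200))
  r <- systemCorrelations(tab)
  expect_lt(abs(r["tp_vs_N"]), 0.2)
})

test_that("paralog TP aggregates by species size with the right limits", {
  sp <- c("a", "b", "b", "c", "c", "c")
  native <- identityPairing(6)
  # species a forced correct; species b swapped; species c identity
  z <- Pairing(c(1L, 3L, 2L, 4L, 5L, 6L))
  tab <- paralogTPByCount(z, native, sp)
  expect_equal(tab$paralogs, c(1L, 2L, 3L))
  expect_equal(tab$meanTP, c(1, 0, 1))
  expect_equal(tab$nSpecies, c(1L, 1L, 1L))
})

test_that("random within-species pairing has expected TP near 1/n", {
  sp <- rep(sprintf("s%02d", 1:40), each = 5)   # 40 species of 5 paralogs
  native <- identityPairing(200)
  set.seed(17)
  tps <- replicate(40, {
    z <- scramblePairing(200, "within_species", species = sp)
    paralogTPByCount(z, native, sp)$meanTP
  })
  expect_equal(mean(tps), 1 / 5, tolerance = 0.03)
})
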