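tinySystem <- function(M = 8, N = 3, seed = 1) {
  dat <- generateSyntheticPair(synthSpec(M = M, N = N, LbgA = 4, LbgB = 4,
                                         epsilon = 0.7, qEff = 4, seed = seed))
  dat
}

test_that("config validation enforces the population invariants", {
  expect_error(gaConfig(populationSize = 1), "populationSize")
  expect_error(gaConfig(eliteFraction = 1), "eliteFraction")
  expect_error(gaConfig(eliteFraction = 0.01), "elite count")
  expect_error(gaConfig(mutationsPerOffspring = 0), "mutation")
  cfg <- gaConfig()
  expect_equal(cfg@populationSize, 8L)
  expect_equal(cfg@eliteFraction, 0.5)
  expect_equal(cfg@generations, 50000L)
  expect_equal(cfg@lambda, 0.001)
})

test_that("initial populations are reproducible and respect species blocks", {
  dat <- tinySystem()
  cfg <- gaConfig(generations = 0L, seed = 7)
  p1 <- initPopulation(dat$pair, cfg)
  p2 <- initPopulation(dat$pair, cfg)
  expect_identical(lapply(p1, perm), lapply(p2, perm))
  expect_equal(length(p1), 8L)

  sp <- rep(c("s1", "s2", "s3"), times = c(3, 3, 2))
  app <- alignmentPair(as.character(msaA(dat$pair)), as.character(msaB(dat$pair)),
                       species = sp)
  cfgW <- gaConfig(seed = 7, mode = "within_species")
  for (z in initPopulation(app, cfgW))
    expect_true(all(sp[perm(z)] == sp))
})

test_that("global populations on large M have near-zero expected TP", {
  set.seed(3)
  ap <- alignmentPair(replicate(100, "AA"), replicate(100, "CC"))
  cfg <- gaConfig(seed = 11)
  pop <- initPopulation(ap, cfg)
  expect_equal(length(unique(lapply(pop, perm))), 8L)
  fp <- vapply(pop, function(z) sum(perm(z) == 1:100), numeric(1))
  expect_lt(mean(fp), 4)  # expected 1 fixed point per permutation
})

test_that("mutation is a partner swap preserving the permutation", {
  cfg <- gaConfig(seed = 1)
  set.seed(5)
  z <- mutatePairing(identityPairing(2), cfg)
  expect_equal(perm(z), c(2L, 1L))
  set.seed(6)
  for (i in 1:20) {
    z0 <- scramblePairing(12)
    z1 <- mutatePairing(z0, cfg)
    expect_equal(sort(perm(z1)), 1:12)
    expect_equal(sum(perm(z1) != perm(z0)), 2L)
  }
})

test_that("within-species mutation picks eligible species uniformly", {
  sp <- rep(c("a", "b", "c", "d"), times = c(4, 3, 1, 2))  # c ineligible
  cfg <- gaConfig(mode = "within_species")
  set.seed(8)
  touched <- character(1000)
  for (i in 1:1000) {
    z1 <- mutatePairing(identityPairing(10), cfg, species = sp)
    moved <- which(perm(z1) != 1:10)
    expect_true(all(sp[moved] == sp[moved][1]))  # swap stays inside one species
    touched[i] <- sp[moved][1]
  }
  counts <- table(touched)
  expect_setequal(names(counts), c("a", "b", "d"))
  expect_true(all(abs(counts / 1000 - 1 / 3) < 0.06))
  expect_error(mutatePairing(identityPairing(3), cfg,
                             species = c("x", "y", "z")), "two members")
})

test_that("selection keeps the elite, cycles parents and breaks ties stably", {
  cfg <- gaConfig(populationSize = 4, seed = 1)
  pop <- lapply(list(1:3, c(2L, 1L, 3L), c(3L, 2L, 1L), c(1L, 3L, 2L)), Pairing)
  set.seed(2)
  nxt <- stepGeneration(pop, c(5, 7, 7, 1), cfg)
  # rank order: fitness 7 (index 2), 7 (index 3, tie -> later), 5, 1
  expect_equal(perm(nxt[[1]]), c(2L, 1L, 3L))
  expect_equal(perm(nxt[[2]]), c(3L, 2L, 1L))
  # offspring 1 mutates elite 1, offspring 2 mutates elite 2 (one swap each)
  expect_equal(sum(perm(nxt[[3]]) != perm(nxt[[1]])), 2L)
  expect_equal(sum(perm(nxt[[4]]) != perm(nxt[[2]])), 2L)
  # all-equal fitness: elite = first half in original order
  set.seed(2)
  nxt2 <- stepGeneration(pop, rep(1, 4), cfg)
  expect_equal(perm(nxt2[[1]]), perm(pop[[1]]))
  expect_equal(perm(nxt2[[2]]), perm(pop[[2]]))
})

test_that("zero generations returns the best of the initial population", {
  dat <- tinySystem()
  cfg <- gaConfig(generations = 0L, seed = 3)
  tr <- runGA(dat$pair, dat$cmap, cfg)
  pop <- initPopulation(dat$pair, cfg)
  fits <- vapply(pop, function(z)
    totalMI(interfaceMI(dat$pair, dat$cmap, z, cfg@lambda)), numeric(1))
  expect_equal(length(bestFitness(tr)), 1L)
  expect_equal(bestFitness(tr)[1], max(fits), tolerance = 1e-9)
  expect_equal(perm(finalPairing(tr)), perm(pop[[which.max(fits)]]))
})

test_that("compiled and reference engines produce the same seeded run", {
  # with per-generation refresh the compiled fitness is bit-identical to
  # full recomputation, so even exact fitness ties order the same way
  for (seed in c(2, 9)) {
    dat <- tinySystem(M = 8, N = 3, seed = seed)
    nat <- interfaceMI(dat$pair, dat$cmap)
    cfg <- gaConfig(generations = 50L, seed = seed)
    tC <- runGA(dat$pair, dat$cmap, cfg, nat, engine = "cpp", refreshEvery = 1L)
    tR <- runGA(dat$pair, dat$cmap, cfg, nat, engine = "R")
    expect_identical(bestFitness(tC), bestFitness(tR))
    expect_identical(perm(finalPairing(tC)), perm(finalPairing(tR)))
  }
})

test_that("incremental fitness equals full recomputation after a long run", {
  dat <- generateSyntheticPair(synthSpec(M = 60, N = 20, LbgA = 10, LbgB = 10,
                                         epsilon = 0.7, qEff = 6, seed = 2))
  cfg <- gaConfig(generations = 3000L, seed = 4)
  tr <- runGA(dat$pair, dat$cmap, cfg)
  full <- totalMI(interfaceMI(dat$pair, dat$cmap, finalPairing(tr), cfg@lambda))
  expect_equal(bestFitness(tr)[3001], full, tolerance = 1e-9)
})

test_that("elitism makes the best fitness non-decreasing in every run", {
  dat <- tinySystem(M = 12, N = 3, seed = 6)
  for (seed in 1:3) {
    tr <- runGA(dat$pair, dat$cmap, gaConfig(generations = 300L, seed = seed))
    expect_true(all(diff(bestFitness(tr)) >= -1e-9))
  }
})

test_that("seeded runs are exactly reproducible", {
  dat <- tinySystem(M = 10, N = 3, seed = 8)
  cfg <- gaConfig(generations = 200L, seed = 13)
  t1 <- runGA(dat$pair, dat$cmap, cfg)
  t2 <- runGA(dat$pair, dat$cmap, cfg)
  expect_identical(bestFitness(t1), bestFitness(t2))
  expect_identical(perm(finalPairing(t1)), perm(finalPairing(t2)))
})

test_that("within-species optimization never crosses species blocks", {
  sizes <- c(4, 3, 5)
  dat <- generateSyntheticPair(synthSpec(M = 12, N = 4, LbgA = 6, LbgB = 6,
                                         epsilon = 0.8, qEff = 4,
                                         speciesSizes = sizes, seed = 3))
  sp <- speciesLabels(dat$pair)
  cfg <- gaConfig(generations = 100L, seed = 5, mode = "within_species")
  # walk the reference engine so every individual of every generation is seen
  set.seed(cfg@seed)
  population <- initPopulation(dat$pair, cfg)
  fitn <- vapply(population, function(z)
    totalMI(interfaceMI(dat$pair, dat$cmap, z, cfg@lambda)), numeric(1))
  for (g in 1:30) {
    population <- stepGeneration(population, fitn, cfg, sp)
    for (z in population) expect_true(all(sp[perm(z)] == sp))
    fitn <- vapply(population, function(z)
      totalMI(interfaceMI(dat$pair, dat$cmap, z, cfg@lambda)), numeric(1))
  }
  # and the compiled engine's final pairing respects blocks too
  tr <- runGA(dat$pair, dat$cmap, cfg)
  expect_true(all(sp[perm(finalPairing(tr))] == sp))
})

test_that("trajectory derivatives recover slopes and call convergence", {
  mk <- function(rel) new("GATrajectory", bestFitness = rel * 2, relative = rel,
                          finalPairing = identityPairing(2), replicateId = 1L,
                          seed = 1L, nativeTotal = 2)
  flat <- mk(rep(0.9, 101))
  d <- trajectoryDerivative(flat, window = 20)
  expect_true(all(d$slope == 0))
  expect_true(d$converged)
  lin <- mk(seq(0, 1, length.out = 101))  # slope 0.01 per generation
  d2 <- trajectoryDerivative(lin, window = 25)
  expect_equal(d2$slope, rep(0.01, 4), tolerance = 1e-12)
  expect_false(d2$converged)
  stair <- mk(c(rep(0.2, 51), rep(0.8, 50)))
  d3 <- trajectoryDerivative(stair, window = 50)
  expect_equal(d3$slope, c((stair@relative[51] - stair@relative[1]) / 50,
                           (stair@relative[101] - stair@relative[51]) / 50))
  expect_error(trajectoryDerivative(flat, window = 200), "window")
  noRef <- new("GATrajectory", bestFitness = 1:5 / 5, relative = numeric(0),
               finalPairing = identityPairing(2), replicateId = 1L,
               seed = 1L, nativeTotal = NA_real_)
  expect_error(trajectoryDerivative(noRef), "native")
})

test_that("replicates use consecutive root seeds and carry the native reference", {
  dat <- tinySystem(M = 10, N = 3, seed = 1)
  cfg <- gaConfig(generations = 100L, seed = 20)
  trs <- runReplicates(dat$pair, dat$cmap, cfg, replicates = 3)
  expect_equal(vapply(trs, function(t) t@seed, integer(1)), c(20L, 21L, 22L))
  one <- runGA(dat$pair, dat$cmap, gaConfig(generations = 100L, seed = 21),
               interfaceMI(dat$pair, dat$cmap))
  expect_identical(bestFitness(trs[[2]]), bestFitness(one))
  expect_true(all(lengths(lapply(trs, relativeFitness)) == 101))
})
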