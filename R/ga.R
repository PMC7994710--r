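# Mutation-only elitist genetic algorithm maximizing total interface MI over
# the space of row pairings. Two engines share one stream of primitive RNG
# draws: a compiled core with incremental fitness updates (the default) and
# a plain R reference used in equivalence tests; under the same seed the two
# produce the same run.

#' GAConfig: genetic-algorithm settings
#'
#' Defaults follow the study design for single-copy families: population of
#' 8, top-50\% elite, one partner swap per offspring, pseudocount 0.001 and
#' a 50,000-generation budget (paralog runs use 100,000 generations and the
#' `within_species` move set).
#'
#' @slot populationSize number of individuals (>= 2).
#' @slot eliteFraction fraction kept unchanged each generation (0, 1).
#' @slot mutationsPerOffspring partner swaps applied to each offspring.
#' @slot generations generation budget.
#' @slot lambda pseudocount for the MI fitness.
#' @slot seed root RNG seed of the run.
#' @slot mode `"global"` (any two rows may swap partners) or
#'   `"within_species"` (swaps confined to one species block at a time).
#' @export
setClass("GAConfig",
  representation(populationSize = "integer", eliteFraction = "numeric",
                 mutationsPerOffspring = "integer", generations = "integer",
                 lambda = "numeric", seed = "integer", mode = "character"),
  validity = function(object) {
    if (object@populationSize < 2L) return("populationSize must be >= 2")
    if (object@eliteFraction <= 0 || object@eliteFraction >= 1)
      return("eliteFraction must lie strictly between 0 and 1")
    e <- round(object@eliteFraction * object@populationSize)
    if (e < 1 || e >= object@populationSize)
      return("elite count must be >= 1 and leave room for offspring")
    if (object@mutationsPerOffspring < 1L) return("need >= 1 mutation per offspring")
    if (object@generations < 0L) return("generations must be >= 0")
    if (object@lambda < 0 || object@lambda >= 1) return("lambda must lie in [0, 1)")
    if (!object@mode %in% c("global", "within_species")) return("unknown mode")
    TRUE
  })

#' Construct a GAConfig
#'
#' @param populationSize,eliteFraction,mutationsPerOffspring,generations,lambda,seed,mode
#'   see [GAConfig-class].
#' @return A validated [GAConfig-class].
#' @export
gaConfig <- function(populationSize = 8L, eliteFraction = 0.5,
                     mutationsPerOffspring = 1L, generations = 50000L,
                     lambda = 0.001, seed = 1L,
                     mode = c("global", "within_species")) {
  new("GAConfig", populationSize = as.integer(populationSize),
      eliteFraction = eliteFraction,
      mutationsPerOffspring = as.integer(mutationsPerOffspring),
      generations = as.integer(generations), lambda = lambda,
      seed = as.integer(seed), mode = match.arg(mode))
}

.eliteCount <- function(config)
  as.integer(round(config@eliteFraction * config@populationSize))

# species ids 1..S in order of first appearance (block iteration order)
.speciesIds <- function(species)
  as.integer(factor(species, levels = unique(species)))

#' Initial GA population
#'
#' Draws `populationSize` scrambled pairings (plain uniform permutations in
#' global mode; within-species scrambles in paralog mode), seeding the RNG
#' from `config@seed`.
#'
#' @param pair an [AlignmentPair-class].
#' @param config a [GAConfig-class].
#' @return List of [Pairing-class] objects.
#' @export
initPopulation <- function(pair, config) {
  set.seed(config@seed)
  M <- nRows(pair)
  sp <- speciesLabels(pair)
  if (config@mode == "within_species" && is.null(sp))
    stop("within_species mode needs species labels on the alignment pair")
  lapply(seq_len(config@populationSize), function(i) {
    if (config@mode == "global") Pairing(.fyPermutation(M))
    else Pairing(.fyWithinSpecies(sp))
  })
}

#' Mutate a pairing by swapping two rows' partners
#'
#' Applies `mutationsPerOffspring` swaps; each swap exchanges the B-partners
#' of two distinct uniformly chosen A-rows. In within-species mode a species
#' with at least two members is first chosen uniformly and the swap stays
#' inside it. Draws come from the current RNG state.
#'
#' @param z a [Pairing-class].
#' @param config a [GAConfig-class].
#' @param species labels, required in within-species mode.
#' @return The mutated [Pairing-class] (a copy).
#' @export
mutatePairing <- function(z, config, species = NULL) {
  p <- perm(z)
  M <- length(p)
  if (config@mode == "within_species") {
    if (is.null(species)) stop("within_species mode needs species labels")
    elig <- unique(species)[table(factor(species, levels = unique(species))) >= 2]
    if (!length(elig)) stop("no species with at least two members")
  } else if (M < 2L) stop("need M >= 2 to mutate")
  for (m in seq_len(config@mutationsPerOffspring)) {
    if (config@mode == "global") {
      r1 <- .randInt(M)
      j0 <- .randInt(M - 1L)
      r2 <- j0 + (j0 >= r1)
    } else {
      blk <- which(species == elig[.randInt(length(elig))])
      b <- length(blk)
      i0 <- .randInt(b)
      j0 <- .randInt(b - 1L)
      r1 <- blk[i0]
      r2 <- blk[j0 + (j0 >= i0)]
    }
    tmp <- p[r1]; p[r1] <- p[r2]; p[r2] <- tmp
  }
  Pairing(p)
}

#' One generation of selection and reproduction
#'
#' Individuals are ranked by fitness (stable: earlier index wins ties); the
#' elite survives unchanged and each non-elite slot j is refilled with a
#' mutated copy of elite member `(j - 1) mod eliteCount + 1`. The returned
#' population is in rank order, elite first.
#'
#' @param population list of [Pairing-class] individuals.
#' @param fitnesses numeric vector, total interface MI per individual.
#' @param config a [GAConfig-class].
#' @param species labels for within-species mutation.
#' @return List of [Pairing-class]: the next population.
#' @export
stepGeneration <- function(population, fitnesses, config, species = NULL) {
  P <- length(population)
  stopifnot(length(fitnesses) == P)
  e <- .eliteCount(config)
  ord <- order(-fitnesses, seq_len(P), method = "radix")
  nextPop <- population[ord]
  for (s in seq(e + 1L, P)) {
    parent <- nextPop[[(s - e - 1L) %% e + 1L]]
    nextPop[[s]] <- mutatePairing(parent, config, species)
  }
  nextPop
}

#' Run one GA optimization replicate
#'
#' Maximizes the total interface MI over pairings for `config@generations`
#' generations, recording the best population fitness at every generation
#' (entry 1 of the trajectory is the initial population). The compiled
#' engine updates fitness incrementally; its values agree with full
#' recomputation via [interfaceMI()] to better than 1e-9.
#'
#' @param pair an [AlignmentPair-class].
#' @param cmap a [ContactMap-class].
#' @param config a [GAConfig-class].
#' @param nativeReference optional [MIResult-class] under the native pairing;
#'   when supplied the trajectory also carries the fitness relative to the
#'   native total.
#' @param engine `"cpp"` (default) or `"R"` (reference implementation; same
#'   primitive draw protocol, selection and mutation logic written in plain
#'   R, with the fitness evaluated from scratch every generation).
#' @param replicateId integer tag stored in the trajectory.
#' @param refreshEvery compiled engine only: every this many generations the
#'   per-contact MI is recomputed from the count tables, clearing
#'   floating-point drift of the incremental updates; 1 makes every
#'   generation's fitness bit-identical to full recomputation.
#' @return A [GATrajectory-class].
#' @export
runGA <- function(pair, cmap, config, nativeReference = NULL,
                  engine = c("cpp", "R"), replicateId = 1L,
                  refreshEvery = 512L) {
  engine <- match.arg(engine)
  sp <- speciesLabels(pair)
  if (config@mode == "within_species" && is.null(sp))
    stop("within_species mode needs species labels")
  nativeTotal <- if (is.null(nativeReference)) NA_real_ else totalMI(nativeReference)
  encA <- .encodeMSA(msaA(pair))
  encB <- .encodeMSA(msaB(pair))

  if (engine == "cpp") {
    set.seed(config@seed)
    res <- .gaCore(encA, encB, contactPairs(cmap), config@populationSize,
                   .eliteCount(config), config@mutationsPerOffspring,
                   config@generations, config@lambda,
                   config@mode == "within_species",
                   if (is.null(sp)) integer(0) else .speciesIds(sp),
                   as.integer(refreshEvery))
    best <- res$best
    final <- Pairing(res$bestPerm)
  } else {
    evalPop <- function(population)
      .gaFitness(encA, encB, contactPairs(cmap),
                 do.call(rbind, lapply(population, perm)), config@lambda)
    population <- initPopulation(pair, config)
    fitn <- evalPop(population)
    best <- numeric(config@generations + 1L)
    best[1] <- max(fitn)
    g <- 0L
    while (g < config@generations) {
      population <- stepGeneration(population, fitn, config, sp)
      fitn <- evalPop(population)
      g <- g + 1L
      best[g + 1L] <- max(fitn)
    }
    final <- population[[which.max(fitn)]]
  }
  new("GATrajectory", bestFitness = best,
      relative = if (is.na(nativeTotal)) numeric(0) else best / nativeTotal,
      finalPairing = final, replicateId = as.integer(replicateId),
      seed = config@seed, nativeTotal = nativeTotal)
}

#' Run independent GA replicates
#'
#' Runs `replicates` optimizations with root seeds `config@seed + 0:(r-1)`,
#' each an independent trajectory in the study design's sense (six
#' replicates by default).
#'
#' @inheritParams runGA
#' @param replicates number of independent trajectories (default 6).
#' @return List of [GATrajectory-class] objects.
#' @export
runReplicates <- function(pair, cmap, config, nativeReference = NULL,
                          replicates = 6L, engine = "cpp") {
  if (is.null(nativeReference))
    nativeReference <- interfaceMI(pair, cmap, nativePairing(pair), config@lambda)
  lapply(seq_len(replicates), function(r) {
    cfg <- config
    cfg@seed <- config@seed + r - 1L
    runGA(pair, cmap, cfg, nativeReference, engine = engine, replicateId = r)
  })
}

#' Windowed derivative of a trajectory and convergence call
#'
#' Computes the windowed finite difference of the relative fitness series,
#' `(relative[g] - relative[g - window]) / window`, at the end of each
#' successive window (units: change in relative MI per generation). The run
#' is called converged when the final windowed slope does not exceed
#' `threshold` per 1000 generations (default 0.001).
#'
#' @param traj a [GATrajectory-class] with a native reference.
#' @param window window length in generations (default 1000).
#' @param threshold convergence bound on the slope, per 1000 generations.
#' @return List with `generation` (window end points), `slope` (per
#'   generation), `slopePer1000`, and logical `converged`.
#' @export
trajectoryDerivative <- function(traj, window = 1000L, threshold = 0.001) {
  rel <- relativeFitness(traj)
  G <- length(rel) - 1L
  if (window < 1L || window > G) stop("window must lie in [1, generations]")
  ends <- seq(window, G, by = window)
  slope <- (rel[ends + 1L] - rel[ends + 1L - window]) / window
  list(generation = ends, slope = slope, slopePer1000 = slope * 1000,
       converged = slope[length(slope)] * 1000 <= threshold)
}

#' Write a trajectory as TSV
#'
#' Columns: generation, best total MI, and (when available) the relative
#' series.
#'
#' @param traj a [GATrajectory-class].
#' @param path output path.
#' @param thin keep every `thin`-th generation (the first and last are
#'   always kept); default 1 writes all.
#' @export
writeTrajectory <- function(traj, path, thin = 1L) {
  G <- length(traj@bestFitness) - 1L
  keep <- unique(c(seq(0L, G, by = thin), G))
  tab <- data.frame(generation = keep, best_total_mi = traj@bestFitness[keep + 1L])
  if (length(traj@relative)) tab$relative <- traj@relative[keep + 1L]
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
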