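# End-to-end orchestration: simulate (or load) -> optimize -> evaluate ->
# classify -> report, with a manifest tying every output to the run seed.

#' Assemble a pipeline run configuration
#'
#' Inputs are either a [synthSpec()] (synthetic mode) or paths to an aligned
#' FASTA pair plus a contact-map TSV (and optionally a species TSV with
#' columns `id`, `species`).
#'
#' @param synth a [synthSpec()], or `NULL` when reading files.
#' @param msaA,msaB,contacts,species input file paths (file mode).
#' @param ga a [GAConfig-class]; its seed is the run's root seed.
#' @param replicates GA replicates (default 6).
#' @param percentile Hamming discount percentile (default 20).
#' @param threshold type-(i)/(ii) boundary (default 0.30).
#' @param k KNN neighbour count (default 10).
#' @param outDir output directory.
#' @return A list of class `"RunConfig"`.
#' @export
runConfig <- function(synth = NULL, msaA = NULL, msaB = NULL, contacts = NULL,
                      species = NULL, ga = gaConfig(), replicates = 6L,
                      percentile = 20, threshold = 0.30, k = 10L,
                      outDir = "coevopair-run") {
  cfg <- list(synth = synth, msaA = msaA, msaB = msaB, contacts = contacts,
              species = species, ga = ga, replicates = as.integer(replicates),
              percentile = percentile, threshold = threshold,
              k = as.integer(k), outDir = outDir)
  if (is.null(synth) && (is.null(msaA) || is.null(msaB) || is.null(contacts)))
    stop("either a synthetic spec or msaA + msaB + contacts paths are required")
  class(cfg) <- "RunConfig"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the [runConfig()] arguments; `synth` and `ga` are
#' nested maps passed to [synthSpec()] and [gaConfig()].
#'
#' @param path YAML file path.
#' @return A `"RunConfig"` list.
#' @export
readRunConfig <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) stop("the yaml package is required")
  y <- yaml::read_yaml(path)
  if (!is.null(y$synth)) {
    # YAML 1.1 reads a bare `N` key as boolean FALSE; restore it
    names(y$synth)[names(y$synth) %in% c("FALSE", "no")] <- "N"
    y$synth <- do.call(synthSpec, y$synth)
  }
  if (!is.null(y$ga)) y$ga <- do.call(gaConfig, y$ga)
  do.call(runConfig, y)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, GA optimization (replicated), solution
#' assessment, type classification with KNN separation where both types are
#' represented, group assignment, and report writing. A `manifest.json`
#' records the configuration, seeds and an MD5 checksum per output file, so
#' identical configuration and seed reproduce identical manifests.
#'
#' @param config a [runConfig()] list.
#' @param engine GA engine, `"cpp"` (default) or `"R"`.
#' @return Invisibly, a list with the run directory, the solution table,
#'   the group label and the manifest path.
#' @export
runPipeline <- function(config, engine = "cpp") {
  stopifnot(inherits(config, "RunConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outDir, ...)

  dat <- .stage("inputs", {
    if (!is.null(config$synth)) {
      d <- generateSyntheticPair(config$synth)
      writeSyntheticPair(d, out("data"))
      d
    } else {
      for (p in c(config$msaA, config$msaB, config$contacts))
        if (!file.exists(p)) stop("missing input file: ", p)
      mA <- readAlignment(config$msaA)
      mB <- readAlignment(config$msaB)
      sp <- if (!is.null(config$species)) {
        tab <- read.delim(config$species)
        tab$species[match(names(mA), tab$id)]
      }
      list(pair = alignmentPair(mA, mB, species = sp),
           cmap = readContactMap(config$contacts))
    }
  })

  nativeMI <- .stage("native-reference",
    interfaceMI(dat$pair, dat$cmap, nativePairing(dat$pair), config$ga@lambda))

  trajs <- .stage("optimize", {
    tr <- runReplicates(dat$pair, dat$cmap, config$ga, nativeMI,
                        config$replicates, engine = engine)
    for (t in tr) {
      writeTrajectory(t, out(sprintf("trajectory_rep%d.tsv", t@replicateId)),
                      thin = max(1L, (length(t@bestFitness) - 1L) %/% 1000L))
      writePairing(dat$pair, finalPairing(t),
                   out(sprintf("pairing_rep%d.tsv", t@replicateId)))
    }
    tr
  })

  assessments <- .stage("evaluate", {
    distances <- pairwiseHamming(msaB(dat$pair))
    sp <- speciesLabels(dat$pair)
    scrMode <- if (config$ga@mode == "within_species") "within_species" else "permutation"
    scrambled <- scramblePairing(nRows(dat$pair), scrMode, species = sp,
                                 seed = config$ga@seed)
    sols <- lapply(trajs, function(t)
      assessSolution(dat$pair, dat$cmap, finalPairing(t), nativeMI,
                     config$ga@lambda, config$percentile, config$threshold,
                     "optimized", distances))
    list(solutions = sols,
         native = assessSolution(dat$pair, dat$cmap, nativePairing(dat$pair),
                                 nativeMI, config$ga@lambda, config$percentile,
                                 config$threshold, "native", distances),
         random = assessSolution(dat$pair, dat$cmap, scrambled, nativeMI,
                                 config$ga@lambda, config$percentile,
                                 config$threshold, "random", distances))
  })

  report <- .stage("classify", {
    tab <- solutionTable(c(assessments$solutions,
                           list(assessments$native, assessments$random)))
    tab$replicate <- c(seq_along(assessments$solutions), NA, NA)
    group <- assignGroup(assessments$solutions, assessments$random)
    knn <- NULL
    nTrain <- sum(tab$type %in% c("type_i", "type_ii"))
    if (length(unique(tab$type[tab$type %in% c("type_i", "type_ii")])) == 2 &&
        nTrain > config$k)
      knn <- knnSeparation(tab, config$k)
    conv <- vapply(trajs, function(t)
      trajectoryDerivative(t, min(1000L, length(t@bestFitness) - 1L))$converged,
      logical(1))
    list(table = tab, group = group, knn = knn, converged = conv)
  })

  manifestPath <- .stage("report", {
    write.table(report$table, out("solutions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeMIReport(nativeMI, dat$cmap, out("native_mi.tsv"))
    files <- sort(list.files(config$outDir, recursive = TRUE))
    files <- setdiff(files, "manifest.json")
    sums <- tools::md5sum(file.path(config$outDir, files))
    manifest <- list(
      package = as.character(utils::packageVersion("coevopair")),
      seed = config$ga@seed, replicates = config$replicates,
      generations = config$ga@generations, mode = config$ga@mode,
      percentile = config$percentile, threshold = config$threshold,
      group = report$group,
      knnTrainingAccuracy = if (!is.null(report$knn))
        report$knn$trainingAccuracy else NA,
      converged = report$converged,
      checksums = as.list(setNames(unname(sums), files)))
    jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    out("manifest.json")
  })

  invisible(list(dir = config$outDir, table = report$table,
                 group = report$group, knn = report$knn,
                 converged = report$converged, manifest = manifestPath))
}
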