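#' @importFrom stats runif
#' @importFrom jsonlite write_json read_json
NULL

#' Build an experiment configuration
#'
#' Experiment-specific defaults mirror the benchmark designs: simset1
#' (technical: depth x technology x k), simset2 (host/PhiX contamination),
#' simset3 (richness arms 5/25/50/100/500 taxa from pools of
#' 10/40/80/130/530), simset4 (taxonomic diversity: all-taxa / same-class /
#' same-family pools of 80, 50 taxa), sketch_effect and filter_effect (25
#' taxa at 5M-pair depth). `depths` and `genomeLengthBp` are full-scale
#' values divided by `scaleFactor` (default 100) before simulation, which
#' preserves per-taxon coverage; `nSamples` defaults to 30 to keep pair
#' counts desk-scale (configurable up to the full 100).
#'
#' @param experiment experiment name (see [ExperimentConfig-class]).
#' @param nSamples simulated metagenomes per arm.
#' @param poolSize,nTaxa pool size and community richness per arm.
#' @param genomeLengthBp full-scale genome length (default 5 Mb).
#' @param depths full-scale depth grid in read pairs.
#' @param technologies platform presets.
#' @param ks k-mer lengths.
#' @param sketchSizes bottom-s sizes (sketch_effect).
#' @param filterMins minimum-abundance thresholds (filter_effect); 0 means
#'   unfiltered.
#' @param contamArms named list of contamination ranges (simset2).
#' @param lengthSpread multiplicative `c(lo, hi)` range of per-genome
#'   lengths around the nominal length (log-uniform; default `c(0.3, 2)`,
#'   i.e. 1.5-10 Mb around the 5 Mb full-scale nominal, the span typical
#'   of complete bacterial genomes). Use `c(1, 1)` for fixed lengths.
#' @param spectrumFilterMin minimum k-mer abundance applied to spectra
#'   before distance computation. Defaults to 2 (the Simka-style setting
#'   of the benchmark grids) for the simset and sketching experiments and
#'   to 0 for the filtering experiment, whose baseline is unfiltered.
#' @param lognormalMu,lognormalSigma community log-normal parameters.
#' @param masterSeed master seed.
#' @param scaleFactor joint divisor on depths and genome length.
#' @return an [ExperimentConfig-class].
#' @examples
#' cfg <- experimentConfig("simset1_technical", nSamples = 4,
#'                         genomeLengthBp = 2e5, depths = c(2e4, 2e5),
#'                         ks = c(11, 21), scaleFactor = 100, masterSeed = 7)
#' @export
experimentConfig <- function(experiment = c("simset1_technical",
                                            "simset2_contamination",
                                            "simset3_richness",
                                            "simset4_taxonomy",
                                            "sketch_effect",
                                            "filter_effect"),
                             nSamples = 30, poolSize = NULL, nTaxa = NULL,
                             genomeLengthBp = 5e6, depths = NULL,
                             technologies = NULL, ks = NULL,
                             sketchSizes = NULL, filterMins = NULL,
                             contamArms = NULL, lengthSpread = c(0.3, 2),
                             spectrumFilterMin = NULL, lognormalMu = 0,
                             lognormalSigma = 1, masterSeed = 1,
                             scaleFactor = 100) {
  experiment <- match.arg(experiment)
  fullGrid <- c(5e4, 1e5, 5e5, 1e6, 5e6, 1e7, 5e7)
  armGrid <- c(5e5, 1e6, 5e6, 1e7)
  defaults <- switch(experiment,
    simset1_technical = list(poolSize = 40, nTaxa = 25, depths = fullGrid,
                             technologies = "hiseq",
                             ks = c(10, 15, 20, 25, 30)),
    simset2_contamination = list(poolSize = 40, nTaxa = 25,
                                 depths = fullGrid, technologies = "hiseq",
                                 ks = c(10, 15, 20, 25, 30),
                                 contamArms = list(host_low = c(0, 0.02),
                                                   host_high = c(0.10, 0.25),
                                                   phix_low = c(0, 0.02))),
    simset3_richness = list(poolSize = c(10, 40, 80, 130, 530),
                            nTaxa = c(5, 25, 50, 100, 500),
                            depths = armGrid, technologies = "hiseq",
                            ks = c(10, 15, 20, 25, 30)),
    simset4_taxonomy = list(poolSize = 80, nTaxa = 50, depths = armGrid,
                            technologies = "hiseq",
                            ks = c(10, 15, 20, 25, 30)),
    sketch_effect = list(poolSize = 40, nTaxa = 25, depths = 5e6,
                         technologies = "hiseq", ks = 30,
                         sketchSizes = c(100, 1e3, 1e4, 5e4)),
    filter_effect = list(poolSize = 40, nTaxa = 25, depths = 5e6,
                         technologies = "hiseq", ks = 30,
                         filterMins = c(0, 2, 5), spectrumFilterMin = 0))
  new("ExperimentConfig", experiment = experiment, nSamples = nSamples,
      poolSize = poolSize %||% defaults$poolSize,
      nTaxa = nTaxa %||% defaults$nTaxa,
      genomeLengthBp = genomeLengthBp,
      depths = depths %||% defaults$depths,
      technologies = technologies %||% defaults$technologies %||% "hiseq",
      ks = ks %||% defaults$ks,
      sketchSizes = sketchSizes %||% defaults$sketchSizes %||% numeric(),
      filterMins = filterMins %||% defaults$filterMins %||% numeric(),
      contamArms = contamArms %||% defaults$contamArms %||% list(),
      lengthSpread = lengthSpread,
      spectrumFilterMin = spectrumFilterMin %||%
        defaults$spectrumFilterMin %||% 2,
      lognormalMu = lognormalMu, lognormalSigma = lognormalSigma,
      masterSeed = masterSeed, scaleFactor = scaleFactor)
}

# fixed-order seed streams derived from the master seed; read seeds depend
# on (sample, depth, technology) but never on the contamination arm, so an
# arm with zero spiking reproduces the clean run exactly
.seedTable <- function(masterSeed, nArms, nSamples, nDepths, nTechs) {
  .withSeed(masterSeed, {
    mx <- .Machine$integer.max
    list(pool = sample.int(mx, nArms),
         profile = matrix(sample.int(mx, nSamples * nArms),
                          nrow = nSamples),
         reads = array(sample.int(mx, nSamples * nDepths * nTechs),
                       dim = c(nSamples, nDepths, nTechs)),
         extra = sample.int(mx, 256))
  })
}

# both spectrum distance matrices from one merge pass per pair
.spectrumMatrices <- function(spectra) {
  n <- length(spectra)
  labels <- vapply(spectra, sampleId, "")
  totals <- vapply(spectra, totalKmers, 0)
  BC <- J <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      st <- cpp_pair_stats(spectra[[i]]@keys, spectra[[i]]@counts,
                           spectra[[j]]@keys, spectra[[j]]@counts)
      BC[i, j] <- BC[j, i] <- 1 - 2 * st[["sum_min"]] /
        (totals[i] + totals[j])
      J[i, j] <- J[j, i] <- 1 - st[["n_shared"]] / st[["n_union"]]
    }
  }
  list(braycurtis = BC, `jaccard-pa` = J)
}

.sketchMatrices <- function(sketches) {
  n <- length(sketches)
  labels <- vapply(sketches, sampleId, "")
  BC <- J <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      a <- sketches[[i]]; b <- sketches[[j]]
      st <- cpp_sketch_pair_stats(a@hashes, a@counts, b@hashes, b@counts,
                                  min(a@s, b@s))
      BC[i, j] <- BC[j, i] <- 1 - 2 * st[["sum_min"]] /
        (st[["total_a"]] + st[["total_b"]])
      J[i, j] <- J[j, i] <- 1 - st[["n_shared"]] / st[["m"]]
    }
  }
  list(braycurtis = BC, `jaccard-pa` = J)
}

.profileMatrices <- function(profiles) {
  list(braycurtis = pairwiseMatrix(profiles, "braycurtis"),
       `jaccard-pa` = pairwiseMatrix(profiles, "jaccard-pa"))
}

.rhoOrNA <- function(D1, D2) {
  tryCatch(spearmanMatrices(D1, D2)$rho, error = function(e) NA_real_)
}

.emptyRow <- function() {
  data.frame(experiment = character(), arm = character(),
             technology = character(), depth = numeric(),
             pairs = numeric(), k = numeric(), metric = character(),
             sketchSize = numeric(), minAbundance = numeric(),
             rho = numeric(), rhoRealized = numeric(),
             meanKmerDist = numeric(), medianAbsDiff = numeric(),
             nPairsCompared = numeric())
}

.row <- function(experiment, arm, technology, depth, pairs, k, metric,
                 rho, rhoRealized = NA, meanKmerDist = NA,
                 medianAbsDiff = NA, sketchSize = NA, minAbundance = NA,
                 nPairsCompared = NA) {
  data.frame(experiment = experiment, arm = arm, technology = technology,
             depth = depth, pairs = pairs, k = k, metric = metric,
             sketchSize = sketchSize, minAbundance = minAbundance,
             rho = rho, rhoRealized = rhoRealized,
             meanKmerDist = meanKmerDist, medianAbsDiff = medianAbsDiff,
             nPairsCompared = nPairsCompared)
}

# simulate one arm (fixed pool + profiles) over the (tech x depth x k)
# grid; returns rho rows and all k-mer distance matrices
.armSweep <- function(experiment, arm, pool, profiles, contaminants,
                      config, readSeeds, matrices) {
  expectedM <- .profileMatrices(profiles)
  scaledDepths <- pmax(1, round(config@depths / config@scaleFactor))
  rows <- list()
  for (t in seq_along(config@technologies)) {
    tech <- config@technologies[t]
    for (d in seq_along(config@depths)) {
      cfgs <- lapply(seq_along(profiles), function(i)
        readSimConfig(tech, nPairs = scaledDepths[d],
                      seed = readSeeds[i, d, t]))
      plans <- lapply(seq_along(profiles), function(i)
        .simPlan(pool, profiles[[i]], cfgs[[i]], contaminants))
      realizedM <- .profileMatrices(lapply(seq_along(plans), function(i)
        .planProfile(plans[[i]], sampleId(profiles[[i]]))))
      for (ki in seq_along(config@ks)) {
        k <- config@ks[ki]
        spectra <- lapply(seq_along(plans), function(i)
          .maybeFilter(.simulateSpectrum(plans[[i]], cfgs[[i]], k,
                                         sampleId(profiles[[i]])), config))
        kmerM <- .spectrumMatrices(spectra)
        for (metric in names(kmerM)) {
          key <- paste(arm, tech, config@depths[d], k, metric, sep = "|")
          matrices$kmer[[key]] <- kmerM[[metric]]
          rows[[length(rows) + 1L]] <- .row(
            experiment, arm, tech, config@depths[d], scaledDepths[d], k,
            metric,
            rho = .rhoOrNA(expectedM[[metric]], kmerM[[metric]]),
            rhoRealized = .rhoOrNA(realizedM[[metric]], kmerM[[metric]]),
            meanKmerDist = mean(upperTriangle(kmerM[[metric]])),
            nPairsCompared = length(upperTriangle(kmerM[[metric]])))
        }
      }
    }
  }
  matrices$expected[[arm]] <- expectedM
  do.call(rbind, rows)
}

#' Run a simulated benchmarking experiment
#'
#' Generates pools, communities and reads per the configuration, computes
#' expected-taxonomic, realized-taxonomic and k-mer (exact, sketched or
#' filtered, depending on the experiment) distance matrices for every grid
#' cell, and evaluates the Spearman agreement between the k-mer and
#' ground-truth distances. All randomness derives from
#' `config@masterSeed`; rerunning an identical configuration reproduces
#' identical outputs.
#'
#' @param config an [ExperimentConfig-class].
#' @param outDir optional directory; if given, writes `results.tsv` (the
#'   tidy condition table) and `manifest.json` (configuration + seeds,
#'   sufficient to re-run the experiment via
#'   [experimentConfigFromManifest()]).
#' @return list with `results` (one row per condition: rho between
#'   expected-taxonomic and k-mer distances, rho against realized
#'   profiles, mean k-mer distance, absolute-difference summaries for
#'   sketch/filter experiments), `matrices` (named list of all distance
#'   matrices) and `manifest`.
#' @export
runExperiment <- function(config, outDir = NULL) {
  stopifnot(is(config, "ExperimentConfig"))
  validObject(config)
  scaledLen <- round(config@genomeLengthBp / config@scaleFactor)
  if (round(scaledLen * config@lengthSpread[1]) < 1000)
    stop("genomeLengthBp * lengthSpread / scaleFactor must be >= 1000 bp")
  exp <- config@experiment
  matrices <- new.env(parent = emptyenv())
  matrices$kmer <- list()
  matrices$expected <- list()

  results <- switch(exp,
    simset1_technical = .runSimset1(config, scaledLen, matrices),
    simset2_contamination = .runSimset2(config, scaledLen, matrices),
    simset3_richness = .runSimset3(config, scaledLen, matrices),
    simset4_taxonomy = .runSimset4(config, scaledLen, matrices),
    sketch_effect = .runSketchEffect(config, scaledLen, matrices),
    filter_effect = .runFilterEffect(config, scaledLen, matrices))
  rownames(results) <- NULL

  manifest <- list(package = "kmerBeta",
                   version = as.character(utils::packageVersion("kmerBeta")),
                   config = .configAsList(config))
  out <- list(results = results,
              matrices = list(kmer = matrices$kmer,
                              expected = matrices$expected),
              manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(results, file.path(outDir, "results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write_json(manifest, file.path(outDir, "manifest.json"),
               auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

.configAsList <- function(config) {
  sl <- slotNames("ExperimentConfig")
  stats::setNames(lapply(sl, function(s) slot(config, s)), sl)
}

#' Rebuild an experiment configuration from a manifest
#'
#' @param manifest path to a `manifest.json` written by [runExperiment()],
#'   or the already-parsed manifest list.
#' @return the [ExperimentConfig-class]; running it through
#'   [runExperiment()] reproduces the original outputs.
#' @export
experimentConfigFromManifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_json(manifest,
                                                    simplifyVector = TRUE)
  cfg <- manifest$config
  num <- function(x) as.numeric(unlist(x))
  experimentConfig(experiment = cfg$experiment, nSamples = cfg$nSamples,
                   poolSize = num(cfg$poolSize), nTaxa = num(cfg$nTaxa),
                   genomeLengthBp = cfg$genomeLengthBp,
                   depths = num(cfg$depths),
                   technologies = unlist(cfg$technologies),
                   ks = num(cfg$ks),
                   sketchSizes = num(cfg$sketchSizes),
                   filterMins = num(cfg$filterMins),
                   contamArms = lapply(as.list(cfg$contamArms), num),
                   lengthSpread = num(cfg$lengthSpread),
                   spectrumFilterMin = cfg$spectrumFilterMin,
                   lognormalMu = cfg$lognormalMu,
                   lognormalSigma = cfg$lognormalSigma,
                   masterSeed = cfg$masterSeed,
                   scaleFactor = cfg$scaleFactor)
}

# pool at the scaled nominal length with the configured size spread
.makePool <- function(config, scaledLen, mode, nGenomes, seed, poolId) {
  rng <- if (all(config@lengthSpread == 1)) NULL
    else round(scaledLen * config@lengthSpread)
  generateGenomePool(nGenomes, scaledLen, mode, seed = seed,
                     poolId = poolId, lengthRange = rng)
}

# the Simka-style minimum-abundance setting of the benchmark grids
.maybeFilter <- function(spectrum, config) {
  if (config@spectrumFilterMin > 0)
    filterSpectrum(spectrum, minAbundance = config@spectrumFilterMin)
  else spectrum
}

.makeProfiles <- function(pool, config, profileSeeds, seedCol = 1L,
                          taxaArm = seedCol) {
  lapply(seq_len(config@nSamples), function(i)
    drawCommunity(pool, config@nTaxa[taxaArm], config@lognormalMu,
                  config@lognormalSigma, seed = profileSeeds[i, seedCol],
                  sampleId = sprintf("s%03d", i)))
}

.runSimset1 <- function(config, scaledLen, matrices) {
  seeds <- .seedTable(config@masterSeed, 1L, config@nSamples,
                      length(config@depths), length(config@technologies))
  pool <- .makePool(config, scaledLen, "all_taxa", config@poolSize[1],
                    seeds$pool[1], "pool1")
  profiles <- .makeProfiles(pool, config, seeds$profile)
  .armSweep(config@experiment, "main", pool, profiles, list(), config,
            seeds$reads, matrices)
}

.runSimset2 <- function(config, scaledLen, matrices) {
  seeds <- .seedTable(config@masterSeed, 1L, config@nSamples,
                      length(config@depths), length(config@technologies))
  pool <- .makePool(config, scaledLen, "all_taxa", config@poolSize[1],
                    seeds$pool[1], "pool1")
  profiles <- .makeProfiles(pool, config, seeds$profile)
  host <- hostContaminant(lengthBp = 10 * scaledLen, seed = seeds$extra[2])
  phix <- phixContaminant(seed = seeds$extra[3])
  arms <- c(list(clean = c(0, 0)), config@contamArms)
  rows <- lapply(seq_along(arms), function(a) {
    armName <- names(arms)[a]
    rng <- arms[[a]]
    genome <- if (grepl("^phix", armName)) phix else host
    fractions <- .withSeed(seeds$extra[16 + a],
                           runif(config@nSamples, rng[1], rng[2]))
    spiked <- lapply(seq_along(profiles), function(i)
      spikeContamination(profiles[[i]],
                         contaminantSpec(genome, fractions[i])))
    .armSweep(config@experiment, armName, pool, spiked, list(genome),
              config, seeds$reads, matrices)
  })
  do.call(rbind, rows)
}

.runSimset3 <- function(config, scaledLen, matrices) {
  nArms <- length(config@poolSize)
  seeds <- .seedTable(config@masterSeed, nArms, config@nSamples,
                      length(config@depths), length(config@technologies))
  rows <- lapply(seq_len(nArms), function(a) {
    pool <- .makePool(config, scaledLen, "all_taxa", config@poolSize[a],
                      seeds$pool[a], sprintf("pool%d", a))
    profiles <- .makeProfiles(pool, config, seeds$profile, a)
    .armSweep(config@experiment, sprintf("taxa%d", config@nTaxa[a]), pool,
              profiles, list(), config, seeds$reads, matrices)
  })
  do.call(rbind, rows)
}

.runSimset4 <- function(config, scaledLen, matrices) {
  modes <- c("all_taxa", "same_class", "same_family")
  seeds <- .seedTable(config@masterSeed, length(modes), config@nSamples,
                      length(config@depths), length(config@technologies))
  rows <- lapply(seq_along(modes), function(a) {
    pool <- .makePool(config, scaledLen, modes[a], config@poolSize[1],
                      seeds$pool[a], sprintf("pool_%s", modes[a]))
    profiles <- .makeProfiles(pool, config, seeds$profile, seedCol = a,
                              taxaArm = 1L)
    .armSweep(config@experiment, modes[a], pool, profiles, list(), config,
              seeds$reads, matrices)
  })
  do.call(rbind, rows)
}

# shared scaffold for the sketch and filter experiments: one arm at one
# depth/technology, exact spectra per k plus a derived (sketched or
# filtered) variant per grid value
.runVariantExperiment <- function(config, scaledLen, matrices, variantFun) {
  seeds <- .seedTable(config@masterSeed, 1L, config@nSamples,
                      length(config@depths), length(config@technologies))
  pool <- .makePool(config, scaledLen, "all_taxa", config@poolSize[1],
                    seeds$pool[1], "pool1")
  profiles <- .makeProfiles(pool, config, seeds$profile)
  expectedM <- .profileMatrices(profiles)
  matrices$expected[["main"]] <- expectedM
  scaledDepth <- max(1, round(config@depths[1] / config@scaleFactor))
  tech <- config@technologies[1]
  rows <- list()
  cfgs <- lapply(seq_along(profiles), function(i)
    readSimConfig(tech, nPairs = scaledDepth, seed = seeds$reads[i, 1, 1]))
  plans <- lapply(seq_along(profiles), function(i)
    .simPlan(pool, profiles[[i]], cfgs[[i]]))
  for (k in config@ks) {
    spectra <- lapply(seq_along(plans), function(i)
      .maybeFilter(.simulateSpectrum(plans[[i]], cfgs[[i]], k,
                                     sampleId(profiles[[i]])), config))
    exactM <- .spectrumMatrices(spectra)
    for (metric in names(exactM)) {
      matrices$kmer[[paste("main", tech, config@depths[1], k, metric,
                           "exact", sep = "|")]] <- exactM[[metric]]
      rows[[length(rows) + 1L]] <- .row(
        config@experiment, "main", tech, config@depths[1], scaledDepth, k,
        metric, rho = .rhoOrNA(expectedM[[metric]], exactM[[metric]]),
        meanKmerDist = mean(upperTriangle(exactM[[metric]])),
        medianAbsDiff = 0,
        nPairsCompared = length(upperTriangle(exactM[[metric]])))
    }
    rows <- variantFun(rows, spectra, exactM, expectedM, k, seeds,
                       scaledDepth, tech)
  }
  do.call(rbind, rows)
}

.runSketchEffect <- function(config, scaledLen, matrices) {
  hashSeed <- NULL
  .runVariantExperiment(config, scaledLen, matrices,
    function(rows, spectra, exactM, expectedM, k, seeds, scaledDepth,
             tech) {
      for (s in config@sketchSizes) {
        sketches <- lapply(spectra, sketchSpectrum, s = s,
                           hashSeed = seeds$extra[1])
        sketchM <- .sketchMatrices(sketches)
        for (metric in names(sketchM)) {
          matrices$kmer[[paste("main", tech, config@depths[1], k, metric,
                               paste0("s", s), sep = "|")]] <-
            sketchM[[metric]]
          rows[[length(rows) + 1L]] <- .row(
            config@experiment, "main", tech, config@depths[1], scaledDepth,
            k, metric, sketchSize = s,
            rho = .rhoOrNA(expectedM[[metric]], sketchM[[metric]]),
            meanKmerDist = mean(upperTriangle(sketchM[[metric]])),
            medianAbsDiff = absDifferenceSummary(exactM[[metric]],
                                                 sketchM[[metric]])["median"],
            nPairsCompared = length(upperTriangle(sketchM[[metric]])))
        }
      }
      rows
    })
}

.runFilterEffect <- function(config, scaledLen, matrices) {
  .runVariantExperiment(config, scaledLen, matrices,
    function(rows, spectra, exactM, expectedM, k, seeds, scaledDepth,
             tech) {
      for (m in setdiff(config@filterMins, 0)) {
        filtered <- lapply(spectra, filterSpectrum, minAbundance = m)
        filtM <- .spectrumMatrices(filtered)
        for (metric in names(filtM)) {
          matrices$kmer[[paste("main", tech, config@depths[1], k, metric,
                               paste0("min", m), sep = "|")]] <-
            filtM[[metric]]
          rows[[length(rows) + 1L]] <- .row(
            config@experiment, "main", tech, config@depths[1], scaledDepth,
            k, metric, minAbundance = m,
            rho = .rhoOrNA(expectedM[[metric]], filtM[[metric]]),
            meanKmerDist = mean(upperTriangle(filtM[[metric]])),
            medianAbsDiff = absDifferenceSummary(exactM[[metric]],
                                                 filtM[[metric]])["median"],
            nPairsCompared = length(upperTriangle(filtM[[metric]])))
        }
      }
      rows
    })
}
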