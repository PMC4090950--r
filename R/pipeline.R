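#' Read a flat key-value run configuration
#'
#' YAML-style flat document of `key: value` pairs; values supplied in
#' `overrides` (e.g. from command-line flags) win over file values.
#'
#' @param file path to the config file (optional).
#' @param overrides named list of overriding values.
#' @return Named list of parameters.
#' @export
readRunConfig <- function(file = NULL, overrides = list()) {
  cfg <- if (!is.null(file)) {
    if (!file.exists(file)) stop("config file not found: ", file)
    yaml::read_yaml(file)
  } else list()
  for (k in names(overrides)) cfg[[k]] <- overrides[[k]]
  cfg
}

cfgGet <- function(config, key, default = NULL, required = FALSE) {
  v <- config[[key]]
  if (is.null(v)) {
    if (required) stop("missing required config parameter: ", key)
    return(default)
  }
  v
}

cfgPath <- function(config, key) {
  p <- cfgGet(config, key, required = TRUE)
  if (!file.exists(p)) stop("input path for '", key, "' not found: ", p)
  p
}

writeSummary <- function(outDir, stage, seed, params, stats) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  path <- file.path(outDir, paste0(stage, ".summary.json"))
  jsonlite::write_json(list(stage = stage, seed = seed, params = params,
                            stats = stats),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  path
}

#' Run one pipeline stage from a file-based configuration
#'
#' Stages: `simulate` (write a synthetic dataset), `classify` (label
#' repeats against enhancers and report observed vs expected counts
#' with one-cell chi-square statistics), `profile` (metaprofile of a
#' signal track around features), `motifscan` (empirical motif
#' enrichment), `expression` (density-vs-expression binned regression),
#' `geneset` (hypergeometric gene-set enrichment of linked genes) and
#' `reproduce-synthetic` (seeded end-to-end run on synthetic data).
#' Each stage writes its outputs plus a machine-readable
#' `<stage>.summary.json` (parameter echo, seed, counts, statistics)
#' under the `out` directory.
#'
#' @param stage stage name (see above).
#' @param config named list of parameters and input paths, e.g. from
#'   [readRunConfig()]. Common keys: `out` (output directory, required)
#'   and `seed`. Stage keys follow the input formats: `genome`
#'   (chrom.sizes), `enhancers`, `repeats`, `features`, `genes` (BED),
#'   `track` (bedGraph/tag BED), `targets`, `pool` (FASTA), `pwm`
#'   (JASPAR), `regex`, `expr` (TSV), `gmt`.
#' @return Invisibly, the stage's statistics list (also written to the
#'   summary JSON).
#' @export
runStage <- function(stage, config = list()) {
  outDir <- cfgGet(config, "out", required = TRUE)
  seed <- cfgGet(config, "seed", default = 1L)
  stats <- switch(stage,
    "simulate" = stageSimulate(config, seed, outDir),
    "classify" = stageClassify(config, seed, outDir),
    "profile" = stageProfile(config, seed, outDir),
    "motifscan" = stageMotifscan(config, seed, outDir),
    "expression" = stageExpression(config, seed, outDir),
    "geneset" = stageGeneset(config, seed, outDir),
    "reproduce-synthetic" = reproduceSynthetic(seed = seed, outDir = outDir),
    stop("unknown stage: '", stage, "'. Available: simulate, classify, ",
         "profile, motifscan, expression, geneset, reproduce-synthetic")
  )
  writeSummary(outDir, stage, seed,
               config[setdiff(names(config), "out")], stats)
  invisible(stats)
}

stageSimulate <- function(config, seed, outDir) {
  cfg <- syntheticConfig(seed = seed)
  for (k in intersect(names(config), names(cfg)))
    cfg[[k]] <- config[[k]]
  cfg <- do.call(syntheticConfig, cfg[setdiff(names(cfg), character(0))])
  paths <- writeSyntheticData(cfg, outDir)
  list(written = unlist(paths))
}

stageClassify <- function(config, seed, outDir) {
  layout <- readChromSizes(cfgPath(config, "genome"))
  enh <- readEnhancerAnchors(cfgPath(config, "enhancers"), layout)
  rep <- readBed(cfgPath(config, "repeats"), layout)
  fam <- cfgGet(config, "family")
  if (!is.null(fam) && !is.null(mcols(rep)$name)) {
    famCol <- mcols(rep)$family
    if (is.null(famCol)) famCol <- sub("[0-9]+$", "", mcols(rep)$name)
    rep <- rep[famCol == fam]
  }
  if (is.null(names(rep)) && !is.null(mcols(rep)$name))
    names(rep) <- mcols(rep)$name
  cls <- classifyRepeats(enh, rep)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  out <- cls
  mcols(out)$name <- paste0(mcols(cls)$id, "|", mcols(cls)$label)
  writeBed(out, file.path(outDir, "classified_repeats.bed"))
  tab <- table(mcols(cls)$label)
  obsCore <- unname(tab[["MIR_ENHANCER"]])
  expCore <- expectedCoreCount(enh, rep, layout)
  repCore <- oneCellChiSq(obsCore, expCore, method = "analytic")
  obsEnh <- enhancersWithRepeats(enh, rep)
  expEnh <- expectedEnhancersWithRepeats(
    enh, rep, layout, nReps = cfgGet(config, "reps", 100L),
    seed = childSeed(seed, 2L))
  repEnh <- oneCellChiSq(obsEnh, as.numeric(expEnh), method = "simulated")
  stats <- list(
    nRepeats = length(cls), counts = as.list(tab),
    coreObserved = obsCore, coreExpected = expCore,
    coreChiSq = chiSquare(repCore), coreP = pValue(repCore),
    enhancersWithRepeatsObserved = obsEnh,
    enhancersWithRepeatsExpected = as.numeric(expEnh),
    enhancersChiSq = chiSquare(repEnh), enhancersP = pValue(repEnh))
  write.table(data.frame(metric = names(unlist(stats)),
                         value = unlist(stats)),
              file.path(outDir, "classify_summary.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stats
}

stageProfile <- function(config, seed, outDir) {
  layout <- readChromSizes(cfgPath(config, "genome"))
  feats <- readBed(cfgPath(config, "features"), layout)
  track <- readSignalTrack(cfgPath(config, "track"), layout)
  prof <- metaprofile(feats, track,
                      span = cfgGet(config, "span", 20000L),
                      window = cfgGet(config, "window", 500L),
                      mark = cfgGet(config, "mark", "signal"))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(offset = windowOffsets(prof),
                         fold = foldEnrichment(prof)),
              file.path(outDir, "metaprofile.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(mark = prof@mark, nWindows = length(foldEnrichment(prof)),
       centralFold = foldEnrichment(prof)[length(foldEnrichment(prof)) %/% 2L])
}

stageMotifscan <- function(config, seed, outDir) {
  targets <- readDNAStringSet(cfgPath(config, "targets"))
  pool <- readDNAStringSet(cfgPath(config, "pool"))
  motifs <- if (!is.null(config$pwm)) readJaspar(cfgPath(config, "pwm"))
            else if (!is.null(config$regex))
              list(RegexMotif(config$regex, config$regex))
            else stop("motifscan needs a 'pwm' file or a 'regex' pattern")
  rows <- lapply(motifs, function(m) {
    res <- empiricalMotifTest(targets, pool, m,
                              nReps = cfgGet(config, "reps", 1000L),
                              seed = childSeed(seed, 3L),
                              thresholdFrac = cfgGet(config, "threshold", 0.8))
    data.frame(motif = res@motifId, observed = res@observed,
               nullMedian = res@nullMedian, nullSD = res@nullSD,
               z = res@zScore, p = res@pValue)
  })
  tab <- do.call(rbind, rows)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.table(tab, file.path(outDir, "motif_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  as.list(tab[1L, ])
}

stageExpression <- function(config, seed, outDir) {
  layout <- readChromSizes(cfgPath(config, "genome"))
  genes <- readBed(cfgPath(config, "genes"), layout)
  if (is.null(names(genes)) && !is.null(mcols(genes)$name))
    names(genes) <- mcols(genes)$name
  feats <- readBed(cfgPath(config, "features"), layout)
  expr <- readExpressionMatrix(cfgPath(config, "expr"))
  mode <- cfgGet(config, "mode", "ts")
  dens <- geneFeatureDensity(genes, feats,
                             flank = cfgGet(config, "flank", 10000L))
  common <- intersect(repeatIds(genes), rownames(expr))
  if (!length(common)) stop("no shared gene ids between genes and expression")
  d <- mcols(dens)$density[match(common, repeatIds(genes))]
  e <- expr[common, , drop = FALSE]
  resp <- switch(mode,
                 ts = tsIndex(e),
                 entropy = entropySpecificity(e),
                 level = rowMeans(e),
                 stop("mode must be ts, entropy or level"))
  br <- binnedRegression(d, resp, nBins = cfgGet(config, "bins", 100L))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.table(data.frame(binDensity = br@binDensity,
                         binResponse = br@binResponse),
              file.path(outDir, "bins.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(mode = mode, nGenes = length(common), r = br@r, p = pValue(br))
}

stageGeneset <- function(config, seed, outDir) {
  layout <- readChromSizes(cfgPath(config, "genome"))
  genes <- readBed(cfgPath(config, "genes"), layout)
  if (is.null(names(genes)) && !is.null(mcols(genes)$name))
    names(genes) <- mcols(genes)$name
  feats <- readBed(cfgPath(config, "features"), layout)
  if (!is.null(config$exclude)) {
    feats <- cellSpecificFeatures(feats, readBed(cfgPath(config, "exclude"),
                                                 layout))
  }
  sets <- readGmt(cfgPath(config, "gmt"))
  linked <- linkGenes(feats, genes,
                      maxDistance = cfgGet(config, "maxDistance", 100000L),
                      anchor = cfgGet(config, "anchor", "body"))
  tab <- genesetEnrichment(linked, sets, universe = repeatIds(genes))
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  write.table(tab, file.path(outDir, "geneset_enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  list(nLinked = length(linked), nSets = nrow(tab), topSet = tab$set[1L],
       topP = tab$p[1L])
}

#' End-to-end seeded run on synthetic data
#'
#' Generates a synthetic dataset and runs every analysis stage on it:
#' repeat classification with observed vs expected counts and one-cell
#' chi-square statistics; metaprofiles of the active and repressive
#' marks around canonical enhancers and repeat-derived enhancers, with
#' mark ranking by slope-weighted congruence; empirical motif
#' enrichment of enhancer-associated repeat sequences against
#' non-enhancer repeat sequences; the density-vs-tissue-specificity
#' binned regression; and gene-set enrichment of feature-linked genes
#' against a planted gene set.
#'
#' @param seed integer seed driving the whole run.
#' @param outDir optional directory for a JSON summary.
#' @param config optional [syntheticConfig()] (defaults to
#'   `syntheticConfig(seed = seed)`).
#' @param motifTargets number of target sequences subsampled for the
#'   motif test (keeps the null resampling fast).
#' @param nReps null replicates for the motif test.
#' @return Named list of the headline statistics.
#' @export
reproduceSynthetic <- function(seed = 1L, outDir = NULL, config = NULL,
                               motifTargets = 200L, nReps = 200L) {
  if (is.null(config)) config <- syntheticConfig(seed = seed)
  ann <- generateAnnotations(config)
  cls <- classifyRepeats(ann$enhancers, ann$repeats)
  lab <- mcols(cls)$label

  # 1. repeat enrichment in enhancers: per-repeat core counts, plus the
  # better-powered count of enhancer-associated repeats vs its uniform
  # placement expectation
  obsCore <- sum(lab == "MIR_ENHANCER")
  expCore <- expectedCoreCount(ann$enhancers, ann$repeats, ann$layout)
  coreReport <- oneCellChiSq(obsCore, expCore, method = "analytic")
  obsLinked <- sum(lab != "NON_ENHANCER_MIR")
  expLinked <- expectedLinkedRepeats(ann$enhancers, ann$repeats, ann$layout)
  linkedReport <- oneCellChiSq(obsLinked, expLinked, method = "analytic")
  spans <- suppressMessages(enhancerSpans(ann$enhancers))
  foldRecovered <- featureDensityFold(spans, ann$repeats, ann$layout)

  # 2. chromatin congruence between canonical and repeat-derived enhancers
  tracks <- generateTracks(config, ann$enhancers, ann$layout)
  mirEnh <- cls[lab == "MIR_ENHANCER"]
  canonical <- lapply(tracks, function(t)
    suppressMessages(metaprofile(anchors(ann$enhancers), t)))
  test <- lapply(tracks, function(t)
    suppressMessages(metaprofile(mirEnh, t)))
  ranking <- rankMarks(canonical, test)

  # 3. motif enrichment in enhancer-associated repeat sequences
  seqs <- generateSequences(config, ann$repeats, lab)
  isTarget <- lab %in% c("MIR_ENHANCER", "ENHANCER_MIR")
  targets <- seqs[isTarget]
  pool <- seqs[!isTarget]
  # subsample targets no longer than the pool's median length, so every
  # null replicate can draw a length-matched sample without replacement
  eligible <- which(width(targets) <=
                      quantile(width(pool), 0.5, names = FALSE))
  nT <- min(motifTargets, length(eligible))
  motifRes <- withSeed(childSeed(config$seed, 50L), {
    empiricalMotifTest(targets[sample(eligible, nT)], pool,
                       RegexMotif("planted", config$motif),
                       nReps = nReps, seed = childSeed(config$seed, 51L))
  })

  # 4. density vs tissue-specificity
  dens <- geneFeatureDensity(ann$genes, cls[isTarget])
  expr <- generateExpression(config, ann$genes, mcols(dens)$density)
  reg <- binnedRegression(mcols(dens)$density, tsIndex(expr), nBins = 100L)

  # 5. gene-set enrichment of genes linked to repeat-provided enhancer
  # cores; the 10 kb linking distance is the 100 kb convention rescaled
  # to the toy genome so linkage stays selective
  linked <- linkGenes(mirEnh, ann$genes, maxDistance = 10000L)
  planted <- withSeed(childSeed(config$seed, 60L), {
    k <- min(50L, length(linked))
    unique(c(sample(linked, k),
             sample(repeatIds(ann$genes), 20L)))
  })
  gsTab <- genesetEnrichment(linked, list(planted = planted),
                             universe = repeatIds(ann$genes))

  stats <- list(
    seed = seed,
    nRepeats = length(cls),
    mirEnhancers = obsCore,
    mirEnhancersExpected = expCore,
    coreChiSq = chiSquare(coreReport),
    coreP = pValue(coreReport),
    linkedRepeats = obsLinked,
    linkedRepeatsExpected = expLinked,
    linkedChiSq = chiSquare(linkedReport),
    linkedP = pValue(linkedReport),
    plantedFoldRecovered = foldRecovered,
    centralActiveFold = foldEnrichment(canonical$H3K27ac)[20L],
    centralRepressiveFold = foldEnrichment(canonical$H3K27me3)[20L],
    markRanking = ranking$mark,
    topMarkScore = ranking$score[1L],
    repressiveMarkScore = ranking$score[nrow(ranking)],
    motifZ = zScore(motifRes),
    motifP = pValue(motifRes),
    densityTsR = reg@r,
    densityTsP = pValue(reg),
    nLinkedGenes = length(linked),
    genesetP = gsTab$p[1L])
  if (!is.null(outDir))
    writeSummary(outDir, "reproduce-synthetic", seed, list(), stats)
  stats
}
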