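# Configuration and end-to-end orchestration of the three inference
# stages: node finding, edge finding, network finding.

#' Pipeline configuration
#'
#' Hyperparameters of all three stages; the defaults mirror the
#' synthetic-benchmark settings (edge fitting: MSE loss, 10 basin-hopping
#' iterations, temperature 1, step size 0.5, adaptation interval 10;
#' network finding: pld threshold 0.98, 40 user-specified candidate
#' edges, 2-10 operations, 0% noise, move probabilities (0.1, 0.9, 0, 0),
#' 2000 sampled networks, 3000-region cap; synthetic top-network rule:
#' oscillation score 100% and pattern match score at least 50%).
#'
#' @param nodeFinding list: \code{skip}, \code{nR}, \code{periods},
#'   \code{phases}, \code{topK}.  Periods have no hidden default: they
#'   must be supplied whenever node finding runs.
#' @param edgeFinding list: \code{loss}, \code{iterations},
#'   \code{temperature}, \code{stepSize}, \code{interval}, \code{nSub},
#'   \code{localMaxit}.
#' @param networkFinding list: \code{pldThreshold}, \code{userLemEdges},
#'   \code{opRange}, \code{noiseLevel}, \code{moveProbs},
#'   \code{sampleSize}, \code{regionCap}, \code{maxAttemptsFactor}.
#' @param topNetworks list: \code{oscillationWindow},
#'   \code{patternMatchMin}, \code{replicateRule}.
#' @param seed RNG seed used by \code{\link{runPipeline}}.
#' @return a validated configuration object (class
#'   \code{PipelineConfig}).
#' @export
pipelineConfig <- function(nodeFinding = list(), edgeFinding = list(),
                           topNetworks = list(), networkFinding = list(),
                           seed = 1L) {
  cfg <- list(
    nodeFinding = utils::modifyList(list(
      skip = FALSE, nR = 1000, periods = NULL, phases = NULL,
      topK = NULL), nodeFinding),
    edgeFinding = utils::modifyList(list(
      loss = "MSE", iterations = 10, temperature = 1, stepSize = 0.5,
      interval = 10, nSub = 4L, localMaxit = 60L), edgeFinding),
    networkFinding = utils::modifyList(list(
      pldThreshold = 0.98, userLemEdges = 40, opRange = c(2L, 10L),
      noiseLevel = 0, moveProbs = c(addNode = 0.1, addEdge = 0.9,
                                    dropNode = 0, dropEdge = 0),
      sampleSize = 2000L, regionCap = 3000L,
      maxAttemptsFactor = 50L), networkFinding),
    topNetworks = utils::modifyList(list(
      oscillationWindow = c(1, 1), patternMatchMin = 0.5,
      replicateRule = "any"), topNetworks),
    seed = as.integer(seed))
  nf <- cfg$networkFinding
  if (any(nf$moveProbs < 0 | nf$moveProbs > 1) ||
      abs(sum(nf$moveProbs) - 1) > 1e-9)
    stop("move probabilities must lie in [0,1] and sum to 1")
  if (length(nf$opRange) != 2 || nf$opRange[1] > nf$opRange[2] ||
      any(nf$opRange < 1))
    stop("operation range must be a nonempty positive integer interval")
  if (nf$regionCap <= 0 || nf$sampleSize < 0)
    stop("caps must be positive")
  if (cfg$edgeFinding$loss != "MSE")
    stop("only the MSE loss is implemented")
  tn <- cfg$topNetworks
  if (tn$oscillationWindow[1] > tn$oscillationWindow[2])
    stop("malformed oscillation window")
  class(cfg) <- "PipelineConfig"
  cfg
}

#' Read/write a pipeline configuration as JSON
#'
#' @param path JSON file path.
#' @return \code{readPipelineConfig}: a \code{PipelineConfig}.
#' @export
readPipelineConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipelineConfig, raw[intersect(names(raw),
    c("nodeFinding", "edgeFinding", "networkFinding", "topNetworks",
      "seed"))])
}

#' @rdname readPipelineConfig
#' @param config a \code{PipelineConfig}.
#' @export
writePipelineConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Run the full inference pipeline
#'
#' Node finding (optional), edge finding, and network finding, producing
#' the node ranking, local edge ranking, local node ranking, sampled
#' network scores, top networks, edge prevalence, global edge ranking,
#' global node ranking and the local-versus-global comparison.  All
#' stochastic steps are governed by \code{config$seed}; rerunning with
#' the same seed reproduces every table.
#'
#' @param config a \code{PipelineConfig}.
#' @param datasets one \linkS4class{TimeSeriesSet} or a list of replicate
#'   sets sharing a gene set.
#' @param annotations optional annotation data.frame
#'   (\code{\link{readAnnotations}}).
#' @param outDir optional directory; when given, every table is written
#'   as TSV.
#' @return list of stage outputs (rankings as
#'   \linkS4class{RankingTable}s, tables as data.frames).
#' @export
runPipeline <- function(config, datasets, annotations = NULL,
                        outDir = NULL) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (is(datasets, "TimeSeriesSet")) datasets <- list(datasets)
  if (!length(datasets)) stop("at least one replicate dataset is required")
  if (config$networkFinding$sampleSize == 0)
    stop("configuration requests zero sampled networks; ",
         "the network stage cannot run")
  set.seed(config$seed)
  out <- list(config = config)

  # --- node finding ---------------------------------------------------
  genes <- Reduce(intersect, lapply(datasets, geneNames))
  if (!isTRUE(config$nodeFinding$skip)) {
    if (is.null(config$nodeFinding$periods))
      stop("node finding requires a period list in the configuration ",
           "(there is no hidden default)")
    sc <- nodeScores(datasets[[1]], config$nodeFinding$nR,
                     config$nodeFinding$periods, config$nodeFinding$phases)
    out$nodeRanking <- rankNodes(sc, config$nodeFinding$topK)
    genes <- rankedItems(out$nodeRanking)$item
    if (!length(genes))
      stop("node finding selected no genes; edge finding cannot run")
  }

  # --- edge finding ---------------------------------------------------
  ef <- config$edgeFinding
  fits <- fitAllEdges(lapply(datasets, function(d) {
    v <- exprValues(d)[genes, , drop = FALSE]
    TimeSeriesSet(v, sampleTimes(d), replicateId(d))
  }), annotations = annotations,
    iterations = ef$iterations, temperature = ef$temperature,
    stepSize = ef$stepSize, interval = ef$interval, nSub = ef$nSub,
    localMaxit = ef$localMaxit)
  out$edgeFits <- fits
  out$localEdgeRanking <- localEdgeRanking(fits)

  # --- network finding ------------------------------------------------
  nf <- config$networkFinding
  seed <- seedNetwork(out$localEdgeRanking, nf$pldThreshold)
  out$seedNetwork <- seed
  cand <- topLemEdges(out$localEdgeRanking, seed, nf$userLemEdges)
  if (!nrow(cand))
    stop("empty candidate edge set after thresholding; ",
         "network sampling cannot run")
  out$candidateEdges <- cand
  out$localParticipation <- nodeParticipation(out$localEdgeRanking,
                                              restrictTo = cand$item)
  sam <- sampleNetworks(seed, cand, m = nf$sampleSize,
                        moveProbs = nf$moveProbs,
                        opRange = nf$opRange[1]:nf$opRange[2],
                        regionCap = nf$regionCap,
                        maxAttempts = nf$maxAttemptsFactor * nf$sampleSize)
  out$sampleManifest <- sam$manifest
  dataGraphs <- lapply(datasets, periodDataGraph,
                       epsilon = nf$noiseLevel)
  out$dataGraphs <- dataGraphs
  scores <- scoreNetworks(sam$networks, dataGraphs,
                          regionCap = nf$regionCap)
  out$networkScores <- scores

  tn <- config$topNetworks
  top <- selectTopNetworks(scores, tn$oscillationWindow,
                           tn$patternMatchMin, tn$replicateRule)
  out$topNetworks <- top
  prev <- edgePrevalence(sam$networks[top$network_id], cand)
  out$edgePrevalence <- prev
  out$globalEdgeRanking <- globalEdgeRanking(prev)
  out$globalParticipation <- nodeParticipation(out$globalEdgeRanking)
  out$nodeComparison <- compareRankings(out$localParticipation,
                                        out$globalParticipation)

  if (!is.null(outDir)) .writePipelineOutputs(out, outDir)
  out
}

.writePipelineOutputs <- function(out, outDir) {
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, f) {
    p <- file.path(outDir, f)
    if (is(x, "RankingTable")) writeRankingTable(x, p)
    else write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(out$nodeRanking)) w(out$nodeRanking, "node_ranking.tsv")
  w(out$localEdgeRanking, "local_edge_ranking.tsv")
  w(out$localParticipation, "local_node_ranking.tsv")
  w(out$sampleManifest, "sample_manifest.tsv")
  w(out$networkScores, "network_scores.tsv")
  w(out$topNetworks, "top_networks.tsv")
  w(out$edgePrevalence, "edge_prevalence.tsv")
  w(out$globalEdgeRanking, "global_edge_ranking.tsv")
  w(out$globalParticipation, "global_node_ranking.tsv")
  w(out$nodeComparison, "node_comparison.tsv")
  writeLines(serializeNetwork(out$seedNetwork),
             file.path(outDir, "seed_network.txt"))
  invisible(outDir)
}
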