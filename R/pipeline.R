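#' Run the full biomarker-discovery pipeline
#'
#' Executes every stage in order: RVM moderated-t screening of miRNAs and
#' mRNAs; intersection of the two target-prediction tables; the
#' anti-correlation co-expression network; the median-score-filtered
#' gene-gene interaction network with centralities, hub calls, Markov
#' clustering, edge-betweenness ranking and (when gene sets are supplied)
#' module enrichment; biomarker panel assembly; and repeated stratified
#' k-fold cross-validation of the RBF-SVM on the panel features.  When a
#' validation miRNA matrix is supplied the model trained on the full
#' discovery cohort is additionally evaluated on it (independent dataset
#' test).  A stage failure aborts with the stage name; when `outDir` is
#' given, outputs of completed stages are already on disk together with a
#' machine-readable manifest.
#'
#' @param mirna,mrna discovery [ExpressionMatrix-class]es with group
#'   labels, sharing the sample set.
#' @param pairsA,pairsB the two target-prediction tables.
#' @param interactions gene-gene interaction table (`gene_a`, `gene_b`,
#'   `combined_score`).
#' @param geneSets optional named list of gene sets for module enrichment.
#' @param validationMirna optional independent [ExpressionMatrix-class]
#'   (miRNA, with group labels) for the independent dataset test.
#' @param config a [RunConfig-class].
#' @param outDir optional run directory for stage outputs and the manifest.
#' @return list of stage results: `de` (per-kind DE tables and screens),
#'   `pairs`, `coexp`, `mirnaRanking`, `topology` (`graph`, `report`,
#'   `hubs`, `partition`, `edgeRank`, `enrichment`), `panel`, `features`,
#'   `cv`, `validation` (or NULL), `manifest` (or NULL).
#' @seealso [runDemo()] for a one-call synthetic demonstration.
#' @export
runPipeline <- function(mirna, mrna, pairsA, pairsB, interactions,
                        geneSets = NULL, validationMirna = NULL,
                        config = runConfig(), outDir = NULL) {
  validObject(config)
  out <- list()
  paths <- character()
  emit <- function(name, writer) {
    if (is.null(outDir)) return(invisible(NULL))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    p <- file.path(outDir, name)
    writer(p)
    paths[[name]] <<- p
    invisible(p)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  out$de <- stage("differential_expression", {
    runDE <- function(x) {
      prior <- fitRVMPrior(pooledVariances(x),
                           df = ncol(x) - 2L)
      res <- rvmTTest(x, prior)
      scr <- screenDE(res, log2fcMin = config@log2fcMin, pMax = config@pMax,
                      fdrMode = config@fdrMode, fdrMax = config@fdrMax)
      list(prior = prior, results = scr$results, up = scr$up,
           down = scr$down, significant = rbind(scr$up, scr$down))
    }
    de <- list(mirna = runDE(mirna), mrna = runDE(mrna))
    if (nrow(de$mirna$significant) == 0L)
      stop("no miRNA passed the differential expression screen")
    if (nrow(de$mrna$significant) == 0L)
      stop("no mRNA passed the differential expression screen")
    emit("de_mirna.tsv", function(p) utils::write.table(
      de$mirna$results, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("de_mrna.tsv", function(p) utils::write.table(
      de$mrna$results, p, sep = "\t", quote = FALSE, row.names = FALSE))
    de
  })

  out$pairs <- stage("target_intersection", {
    pr <- intersectPredictions(pairsA, pairsB)
    if (nrow(pr) == 0L) stop("prediction tables share no pair")
    emit("common_pairs.tsv", function(p) utils::write.table(
      pr, p, sep = "\t", quote = FALSE, row.names = FALSE))
    pr
  })

  out$coexp <- stage("coexpression_network", {
    g <- buildCoexpressionNetwork(out$pairs, out$de$mirna$significant,
                                  out$de$mrna$significant, mirna, mrna,
                                  requireNegative = config@corrRequireNegative,
                                  corrPMax = config@corrPMax,
                                  requireOpposite = config@corrRequireOpposite)
    if (igraph::ecount(g) == 0L)
      stop("co-expression network has no edge under the anti-correlation rule")
    emit("coexpression.graphml", function(p) writeNetwork(g, p, "graphml"))
    emit("coexpression_edges.tsv", function(p) utils::write.table(
      coexpressionEdges(g), p, sep = "\t", quote = FALSE, row.names = FALSE))
    g
  })
  out$mirnaRanking <- keyMirna(out$coexp)

  out$topology <- stage("interaction_topology", {
    deGenes <- out$de$mrna$significant$feature_id
    g <- filterByMedianScore(interactions, deGenes)
    if (igraph::vcount(g) < 3L)
      stop("filtered interaction network has fewer than 3 nodes")
    report <- topologyReport(g)
    partition <- mclCluster(g, inflation = config@mclInflation,
                            expansion = config@mclExpansion,
                            pruneMin = config@mclPruneMin,
                            maxIter = config@mclMaxIter, tol = config@mclTol)
    edgeRank <- edgeBetweennessRanking(g)
    enrichment <- if (!is.null(geneSets))
      enrichModules(partition, geneSets,
                    universe = unique(c(deGenes,
                                        names(moduleMembership(partition)))))
    emit("topology_report.tsv", function(p) utils::write.table(
      report, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("edge_betweenness.tsv", function(p) utils::write.table(
      edgeRank, p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("modules.tsv", function(p) utils::write.table(
      data.frame(gene_id = names(moduleMembership(partition)),
                 module = moduleMembership(partition)),
      p, sep = "\t", quote = FALSE, row.names = FALSE))
    emit("interaction_network.graphml",
         function(p) writeNetwork(g, p, "graphml"))
    list(graph = g, report = report, hubs = selectHubs(report),
         partition = partition, edgeRank = edgeRank,
         enrichment = enrichment)
  })

  out$panel <- stage("biomarker_selection", {
    anchors <- keyInteractionGenes(out$topology$edgeRank,
                                   topK = config@topKEdges)
    panel <- selectUpstreamMirnas(anchors, out$coexp,
                                  out$de$mirna$results)
    emit("panel.tsv", function(p) utils::write.table(
      panelTable(panel), p, sep = "\t", quote = FALSE, row.names = FALSE))
    panel
  })
  out$features <- panelFeatureMatrix(out$panel, mirna)

  out$cv <- stage("cross_validation", {
    cv <- kfoldCV(out$features, sampleGroups(mirna),
                  k = config@cvFolds, repeats = config@cvRepeats,
                  cost = config@svmCost,
                  gamma = if (is.na(config@svmGamma)) NULL
                          else config@svmGamma,
                  scaleMode = config@scaleMode, seed = config@seed)
    emit("cv_repeats.tsv", function(p) utils::write.table(
      cvRepeats(cv), p, sep = "\t", quote = FALSE, row.names = FALSE))
    cv
  })

  out$validation <- if (!is.null(validationMirna)) {
    stage("independent_test", {
      model <- trainSVMRBF(out$features, sampleGroups(mirna),
                           cost = config@svmCost,
                           gamma = if (is.na(config@svmGamma)) NULL
                                   else config@svmGamma,
                           scaleMode = config@scaleMode)
      vx <- panelFeatureMatrix(out$panel, validationMirna)
      pr <- predict(model, vx)
      truth <- sampleGroups(validationMirna)
      cc <- confusionCounts(pr$label, truth)
      list(model = model, counts = cc,
           metrics = classifierMetrics(cc),
           roc = rocAUC(pr$decision, truth))
    })
  }

  out$manifest <- if (!is.null(outDir)) {
    manifest <- list(
      package = "miRResponse",
      version = as.character(utils::packageVersion("miRResponse")),
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = config@seed,
      config = configAsList(config),
      outputs = lapply(paths, function(p)
        list(path = p, md5 = unname(tools::md5sum(p)))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    manifest
  }
  out
}

#' One-command synthetic demonstration of the pipeline
#'
#' Simulates a cohort with [simulateCohort()] and runs [runPipeline()] on
#' it; all randomness (generation, folds) flows from `seed`.
#'
#' @param seed master seed.
#' @param spec optional [SyntheticSpec-class] (default:
#'   `syntheticSpec(seed = seed)`).
#' @param config optional [RunConfig-class] (default:
#'   `runConfig(seed = seed)`).
#' @param outDir optional run directory.
#' @param validation generate and score an independent synthetic validation
#'   cohort of this many responders/non-responders (length-2 vector); NULL
#'   to skip.
#' @return list with `sim` (the synthetic data and ground truth) and
#'   `result` (the [runPipeline()] output).
#' @examples
#' \donttest{
#' demo <- runDemo(seed = 1)
#' panelMirnas(demo$result$panel)
#' }
#' @export
runDemo <- function(seed = 1, spec = NULL, config = NULL, outDir = NULL,
                    validation = NULL) {
  if (is.null(spec)) spec <- syntheticSpec(seed = seed)
  if (is.null(config)) config <- runConfig(seed = seed)
  sim <- simulateCohort(spec, dir = if (is.null(outDir)) NULL
                                    else file.path(outDir, "input"))
  validationMirna <- NULL
  if (!is.null(validation)) {
    # same feature population (baselines, noise scales), new samples
    vspec <- spec
    vspec@nResponders <- validation[1L]
    vspec@nNonResponders <- validation[2L]
    vspec@populationSeed <- if (is.na(spec@populationSeed)) spec@seed
                            else spec@populationSeed
    vspec@seed <- spec@seed + 10000L
    validationMirna <- generateCohort(vspec)$mirna
  }
  result <- runPipeline(sim$mirna, sim$mrna, sim$pairsA, sim$pairsB,
                        sim$interactions, validationMirna = validationMirna,
                        config = config, outDir = outDir)
  list(sim = sim, result = result)
}
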