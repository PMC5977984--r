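#' SyntheticSpec: parameters of the synthetic two-group cohort generator
#'
#' The generator emulates the discovery setting of a small clinical
#' microarray cohort: two arms (responders / non-responders) of log2
#' expression values with additive Gaussian noise, a small set of planted
#' miRNAs carrying a group-level log2 fold change of alternating sign, true
#' target genes anti-correlated with their miRNA, decoy target predictions
#' split across the two prediction sources, and a gene-gene interaction
#' graph with two clique communities joined by a single high-betweenness
#' bridge interaction.
#'
#' Module `j` of the interaction graph is composed of the true targets of
#' planted miRNA `j`, so the bridge endpoints anchor distinct planted
#' miRNAs and the full pipeline can recover the planted set end-to-end.
#'
#' @slot nResponders,nNonResponders arm sizes (default 6/6).
#' @slot nMirnas,nGenes feature counts.
#' @slot plantedMirnas number of planted miRNAs; must equal
#'   `length(moduleSizes)` so each interaction-graph module maps to one
#'   planted miRNA.
#' @slot delta planted |log2 fold change| in responders; signs alternate
#'   +/- across planted miRNAs.  `delta = 0` yields a null cohort (no group
#'   effect anywhere), useful for calibration studies.
#' @slot beta coupling strength: a true target equals its baseline minus
#'   `beta` times its miRNA's centered value, plus noise.
#' @slot noiseSd typical additive Gaussian noise SD on the log2 scale;
#'   per-feature noise variances are heterogeneous, drawn as
#'   `1/sigma_i^2 ~ Gamma(varShape, rate = varShape * noiseSd^2)` (so
#'   `E[1/sigma_i^2] = 1/noiseSd^2`), the inverse-gamma heteroscedasticity
#'   microarray data shows and the random variance model assumes.
#' @slot varShape shape of the variance heterogeneity (larger = more
#'   homogeneous noise).
#' @slot decoyFraction decoy pairs per true pair (floor), each decoy present
#'   in exactly one prediction source.
#' @slot moduleSizes sizes of the two (or more) interaction-graph cliques;
#'   their genes are the true targets.
#' @slot seed RNG seed; generation is a pure function of (spec, seed).
#' @slot populationSeed seed for the feature-level population parameters
#'   (per-feature baselines and noise SDs).  `NA` (default) ties it to
#'   `seed`.  Give two specs the same `populationSeed` but different
#'   `seed`s to draw independent cohorts of the same features, e.g. a
#'   discovery and a validation cohort.
#' @export
setClass("SyntheticSpec", slots = c(
  nResponders = "numeric", nNonResponders = "numeric",
  nMirnas = "numeric", nGenes = "numeric", plantedMirnas = "numeric",
  delta = "numeric", beta = "numeric", noiseSd = "numeric",
  varShape = "numeric", decoyFraction = "numeric",
  moduleSizes = "numeric", seed = "numeric",
  populationSeed = "numeric"))

setValidity("SyntheticSpec", function(object) {
  msg <- character()
  chk <- function(ok, m) if (!ok) msg <<- c(msg, m)
  chk(object@nResponders >= 2 && object@nNonResponders >= 2,
      "both arms need >= 2 samples")
  chk(object@plantedMirnas <= object@nMirnas,
      "plantedMirnas must be <= nMirnas")
  chk(object@plantedMirnas >= 1, "need >= 1 planted miRNA")
  chk(is.finite(object@delta), "delta must be finite")
  chk(object@noiseSd > 0, "noiseSd must be > 0")
  chk(object@varShape > 2, "varShape must be > 2 (finite variance of sigma^2)")
  chk(object@decoyFraction >= 0, "decoyFraction must be >= 0")
  chk(length(object@moduleSizes) >= 2 && all(object@moduleSizes >= 2),
      "need >= 2 modules of size >= 2")
  chk(sum(object@moduleSizes) <= object@nGenes,
      "module sizes exceed nGenes")
  chk(object@plantedMirnas == length(object@moduleSizes),
      "plantedMirnas must equal the number of modules")
  chk(object@seed >= 0 && object@seed == floor(object@seed),
      "seed must be a non-negative integer")
  chk(is.na(object@populationSeed) ||
        (object@populationSeed >= 0 &&
           object@populationSeed == floor(object@populationSeed)),
      "populationSeed must be NA or a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Build a SyntheticSpec
#'
#' Defaults match the study conditions the generator emulates: 6 responders
#' vs 6 non-responders, planted |log2FC| = 1.5, unit miRNA-target coupling,
#' noise SD 0.3 log2 units, two target modules of sizes 4 and 3, and half
#' as many decoy as true target pairs.
#'
#' @param ... named slot overrides.
#' @return a validated [SyntheticSpec-class].
#' @examples
#' syntheticSpec(seed = 7)
#' @export
syntheticSpec <- function(...) {
  defaults <- list(nResponders = 6, nNonResponders = 6,
                   nMirnas = 30, nGenes = 60, plantedMirnas = 2,
                   delta = 1.5, beta = 1, noiseSd = 0.3, varShape = 4,
                   decoyFraction = 0.5, moduleSizes = c(4, 3), seed = 1,
                   populationSeed = NA_real_)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown SyntheticSpec fields: ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  do.call(new, c(list(Class = "SyntheticSpec"), defaults))
}

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf(paste0("SyntheticSpec: %d+%d samples, %d miRNAs (%d planted, ",
                     "delta %.3g), %d genes, beta %.3g, sd %.3g, seed %s\n"),
              object@nResponders, object@nNonResponders, object@nMirnas,
              object@plantedMirnas, object@delta, object@nGenes,
              object@beta, object@noiseSd, format(object@seed)))
})

withSeed <- function(seed, expr) {
  # Mersenne-Twister + inversion, pinned so generation is reproducible
  # across platforms and R sessions regardless of the caller's RNG state.
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  expr
}

truthFromSpec <- function(spec) {
  nPlanted <- spec@plantedMirnas
  mirnaIds <- sprintf("miR-%03d", seq_len(spec@nMirnas))
  geneIds <- sprintf("GENE%03d", seq_len(spec@nGenes))
  signs <- rep_len(c(1, -1), nPlanted)
  planted <- data.frame(mirna_id = mirnaIds[seq_len(nPlanted)],
                        delta = signs * spec@delta,
                        stringsAsFactors = FALSE)
  sizes <- spec@moduleSizes
  moduleOf <- rep(seq_along(sizes), sizes)
  targetGenes <- geneIds[seq_len(sum(sizes))]
  modules <- data.frame(gene_id = targetGenes, module = moduleOf,
                        stringsAsFactors = FALSE)
  truePairs <- data.frame(mirna_id = planted$mirna_id[moduleOf],
                          gene_id = targetGenes, stringsAsFactors = FALSE)
  hubs <- vapply(seq_along(sizes),
                 function(j) targetGenes[which(moduleOf == j)[1L]], "")
  list(planted = planted, truePairs = truePairs,
       bridge = hubs[1:2], modules = modules,
       mirnaIds = mirnaIds, geneIds = geneIds)
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Background features are `baseline + N(0, noiseSd)` identically in both
#' arms.  Planted miRNA `k` additionally receives a `+/- delta` mean shift
#' in responders.  Each true target gene is
#' `baseline - beta * (miRNA value - pooled miRNA mean) + N(0, noiseSd)`,
#' which produces both negative sample-level correlation with its miRNA and
#' an opposite group-level fold change.
#'
#' @param spec a [SyntheticSpec-class].
#' @return list with elements `mirna` and `mrna`
#'   ([ExpressionMatrix-class]es), `annotation` (data.frame) and `truth`
#'   (list: `planted`, `truePairs`, `bridge`, `modules`).
#' @examples
#' cohort <- generateCohort(syntheticSpec(seed = 7))
#' cohort$mirna
#' @export
generateCohort <- function(spec) {
  validObject(spec)
  tr <- truthFromSpec(spec)
  n1 <- spec@nResponders; n2 <- spec@nNonResponders
  n <- n1 + n2
  sampleIds <- c(sprintf("R%02d", seq_len(n1)), sprintf("N%02d", seq_len(n2)))
  groups <- rep(c("responder", "non_responder"), c(n1, n2))
  featureSd <- function(nf)
    1 / sqrt(stats::rgamma(nf, shape = spec@varShape,
                           rate = spec@varShape * spec@noiseSd^2))
  popSeed <- if (is.na(spec@populationSeed)) spec@seed
             else spec@populationSeed
  withSeed(popSeed, {
    baseM <- stats::runif(spec@nMirnas, 6, 12)
    sdM <- featureSd(spec@nMirnas)
    baseG <- stats::runif(spec@nGenes, 6, 12)
    sdG <- featureSd(spec@nGenes)
  })
  withSeed(spec@seed + 3L, {
    mirna <- matrix(baseM, spec@nMirnas, n) +
      matrix(stats::rnorm(spec@nMirnas * n, 0, rep(sdM, n)),
             spec@nMirnas, n)
    for (k in seq_len(nrow(tr$planted)))
      mirna[k, seq_len(n1)] <- mirna[k, seq_len(n1)] + tr$planted$delta[k]
    dimnames(mirna) <- list(tr$mirnaIds, sampleIds)

    mrna <- matrix(baseG, spec@nGenes, n) +
      matrix(stats::rnorm(spec@nGenes * n, 0, rep(sdG, n)),
             spec@nGenes, n)
    dimnames(mrna) <- list(tr$geneIds, sampleIds)
    for (i in seq_len(nrow(tr$truePairs))) {
      m <- mirna[tr$truePairs$mirna_id[i], ]
      g <- tr$truePairs$gene_id[i]
      gi <- match(g, tr$geneIds)
      mrna[g, ] <- baseG[gi] - spec@beta * (m - mean(m)) +
        stats::rnorm(n, 0, sdG[gi])
    }
  })
  annotation <- data.frame(sample_id = sampleIds, group = groups,
                           stringsAsFactors = FALSE)
  list(mirna = ExpressionMatrix(mirna, "miRNA", annotation),
       mrna = ExpressionMatrix(mrna, "mRNA", annotation),
       annotation = annotation,
       truth = tr[c("planted", "truePairs", "bridge", "modules")])
}

#' Generate the two target-prediction tables
#'
#' Every true pair appears in BOTH tables (so the intersection step keeps
#' it); decoy pairs appear in exactly one table (so the intersection step
#' removes them).  The decoy count is
#' `floor(decoyFraction * n_true_pairs)`.
#'
#' @param truth the `truth` element of [generateCohort()].
#' @param spec the [SyntheticSpec-class] used to generate it.
#' @return list with data.frames `A` and `B` (columns `mirna_id`,
#'   `gene_id`, `source`).
#' @export
generatePairTables <- function(truth, spec) {
  validObject(spec)
  true <- truth$truePairs
  nDecoy <- floor(spec@decoyFraction * nrow(true))
  mirnaIds <- sprintf("miR-%03d", seq_len(spec@nMirnas))
  geneIds <- sprintf("GENE%03d", seq_len(spec@nGenes))
  decoys <- withSeed(spec@seed + 1L, {
    trueKey <- paste(true$mirna_id, true$gene_id)
    out <- data.frame(mirna_id = character(), gene_id = character())
    guard <- 0L
    while (nrow(out) < nDecoy && guard < 1000L) {
      cand <- data.frame(
        mirna_id = sample(mirnaIds, nDecoy, replace = TRUE),
        gene_id = sample(geneIds, nDecoy, replace = TRUE),
        stringsAsFactors = FALSE)
      cand <- cand[!paste(cand$mirna_id, cand$gene_id) %in% trueKey, ]
      out <- unique(rbind(out, cand))
      guard <- guard + 1L
    }
    out[seq_len(nDecoy), , drop = FALSE]
  })
  inA <- seq_len(nrow(decoys)) %% 2L == 1L
  tabA <- rbind(true, decoys[inA, , drop = FALSE])
  tabB <- rbind(true, decoys[!inA, , drop = FALSE])
  tabA$source <- "A"; tabB$source <- "B"
  rownames(tabA) <- rownames(tabB) <- NULL
  list(A = tabA, B = tabB)
}

#' Generate the gene-gene interaction table with planted topology
#'
#' The true target genes form clique communities (one per module), joined
#' by a single bridge edge between the first gene of module 1 and the first
#' gene of module 2.  Community and bridge edges receive combined scores
#' drawn above the global score median; an equal number of random
#' background edges among non-target genes receive scores below it, so the
#' strict above-median filter keeps exactly the community + bridge edges
#' and the bridge has the unique maximum edge betweenness in the filtered
#' graph.
#'
#' @inheritParams generatePairTables
#' @return data.frame with columns `gene_a`, `gene_b`, `combined_score`.
#' @export
generateInteractionGraph <- function(truth, spec) {
  validObject(spec)
  mods <- truth$modules
  cliqueEdges <- do.call(rbind, lapply(split(mods$gene_id, mods$module),
    function(g) {
      if (length(g) < 2L) return(NULL)
      t(utils::combn(g, 2L))
    }))
  signal <- rbind(cliqueEdges, truth$bridge)
  nSignal <- nrow(signal)
  background <- withSeed(spec@seed + 2L, {
    bgGenes <- setdiff(sprintf("GENE%03d", seq_len(spec@nGenes)),
                       mods$gene_id)
    if (length(bgGenes) < 2L)
      stop("not enough background genes for background edges")
    allBg <- t(utils::combn(bgGenes, 2L))
    nBg <- min(nSignal, nrow(allBg))
    bg <- allBg[sample.int(nrow(allBg), nBg), , drop = FALSE]
    list(edges = bg,
         scoresSignal = stats::runif(nSignal, 0.55, 0.9),
         scoresBg = stats::runif(nBg, 0.2, 0.45))
  })
  out <- data.frame(
    gene_a = c(signal[, 1L], background$edges[, 1L]),
    gene_b = c(signal[, 2L], background$edges[, 2L]),
    combined_score = c(background$scoresSignal, background$scoresBg),
    stringsAsFactors = FALSE)
  normalizeInteractions(out)
}

#' Generate a full synthetic data set
#'
#' Runs [generateCohort()], [generatePairTables()] and
#' [generateInteractionGraph()] under the spec's seed and optionally writes
#' everything (plus the ground truth as JSON) to a directory in the
#' package's file formats.
#'
#' @param spec a [SyntheticSpec-class].
#' @param dir optional output directory.
#' @return list with `mirna`, `mrna`, `annotation`, `truth`, `pairsA`,
#'   `pairsB`, `interactions`.
#' @examples
#' sim <- simulateCohort(syntheticSpec(seed = 7))
#' names(sim)
#' @export
simulateCohort <- function(spec, dir = NULL) {
  cohort <- generateCohort(spec)
  tabs <- generatePairTables(cohort$truth, spec)
  inter <- generateInteractionGraph(cohort$truth, spec)
  out <- c(cohort, list(pairsA = tabs$A, pairsB = tabs$B,
                        interactions = inter))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    writeExpression(out$mirna, file.path(dir, "mirna.tsv"))
    writeExpression(out$mrna, file.path(dir, "mrna.tsv"))
    writeSampleAnnotation(out$annotation, file.path(dir, "annotation.tsv"))
    writeTargetPairs(out$pairsA, file.path(dir, "target_pairs_A.tsv"))
    writeTargetPairs(out$pairsB, file.path(dir, "target_pairs_B.tsv"))
    writeInteractions(out$interactions, file.path(dir, "interactions.tsv"))
    jsonlite::write_json(out$truth, file.path(dir, "ground_truth.json"),
                         dataframe = "columns", auto_unbox = FALSE,
                         digits = NA)
  }
  out
}
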