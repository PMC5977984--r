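#' RunConfig: pipeline thresholds and parameters
#'
#' One object holding every tunable of the pipeline: the differential
#' expression gates, the anti-correlation rule for co-expression edges, the
#' Markov clustering parameters, the SVM and cross-validation settings, the
#' number of top edge-betweenness interactions used for panel anchoring, and
#' the master RNG seed.
#'
#' @slot log2fcMin minimum |log2 fold change| (strict) for significance.
#' @slot pMax maximum p-value (strict) for significance.
#' @slot fdrMode `"report"` (compute BH q-values, gate on raw p only) or
#'   `"gate"` (additionally require `fdr_q < fdrMax`).
#' @slot fdrMax q-value gate used when `fdrMode = "gate"`.
#' @slot corrRequireNegative require Pearson r < 0 for a co-expression edge.
#' @slot corrPMax correlation-test p-value gate (strict) for an edge.
#' @slot corrRequireOpposite require opposite DE direction of miRNA and gene.
#' @slot mclInflation,mclExpansion,mclPruneMin,mclMaxIter,mclTol Markov
#'   clustering parameters.
#' @slot svmCost soft-margin cost C.
#' @slot svmGamma RBF kernel width; `NA` means 1 / (p * var(training values)).
#' @slot scaleMode feature scaling inside each CV fold: `"zscore"`,
#'   `"minmax"` or `"none"`.
#' @slot cvFolds,cvRepeats cross-validation shape.
#' @slot topKEdges number of top edge-betweenness interactions anchoring the
#'   biomarker panel (ties at the cutoff are all kept).
#' @slot seed master seed; all pipeline randomness derives from it.
#' @export
setClass("RunConfig", slots = c(
  log2fcMin = "numeric", pMax = "numeric", fdrMode = "character",
  fdrMax = "numeric",
  corrRequireNegative = "logical", corrPMax = "numeric",
  corrRequireOpposite = "logical",
  mclInflation = "numeric", mclExpansion = "numeric",
  mclPruneMin = "numeric", mclMaxIter = "numeric", mclTol = "numeric",
  svmCost = "numeric", svmGamma = "numeric", scaleMode = "character",
  cvFolds = "numeric", cvRepeats = "numeric",
  topKEdges = "numeric", seed = "numeric"))

setValidity("RunConfig", function(object) {
  msg <- character()
  chk <- function(ok, m) if (!ok) msg <<- c(msg, m)
  chk(object@log2fcMin > 0, "log2fcMin must be > 0")
  chk(object@pMax > 0 && object@pMax <= 1, "pMax must be in (0, 1]")
  chk(object@fdrMode %in% c("report", "gate"), "fdrMode: 'report' or 'gate'")
  chk(object@fdrMax > 0 && object@fdrMax <= 1, "fdrMax must be in (0, 1]")
  chk(object@corrPMax > 0 && object@corrPMax <= 1, "corrPMax in (0, 1]")
  chk(object@mclInflation > 1, "mclInflation must be > 1")
  chk(object@mclExpansion >= 2, "mclExpansion must be >= 2")
  chk(object@mclPruneMin >= 0, "mclPruneMin must be >= 0")
  chk(object@mclMaxIter >= 1, "mclMaxIter must be >= 1")
  chk(object@mclTol > 0, "mclTol must be > 0")
  chk(object@svmCost > 0, "svmCost must be > 0")
  chk(is.na(object@svmGamma) || object@svmGamma > 0,
      "svmGamma must be > 0 or NA")
  chk(object@scaleMode %in% c("zscore", "minmax", "none"),
      "scaleMode: zscore/minmax/none")
  chk(object@cvFolds >= 2, "cvFolds must be >= 2")
  chk(object@cvRepeats >= 1, "cvRepeats must be >= 1")
  chk(object@topKEdges >= 1, "topKEdges must be >= 1")
  chk(object@seed >= 0 && object@seed == floor(object@seed),
      "seed must be a non-negative integer")
  if (length(msg)) msg else TRUE
})

#' Build a RunConfig
#'
#' @param ... named slot overrides, e.g. `runConfig(log2fcMin = 1, seed = 7)`.
#' @return a validated [RunConfig-class].
#' @examples
#' runConfig(seed = 42)
#' @export
runConfig <- function(...) {
  defaults <- list(
    log2fcMin = 0.5, pMax = 0.05, fdrMode = "report", fdrMax = 0.05,
    corrRequireNegative = TRUE, corrPMax = 0.05, corrRequireOpposite = TRUE,
    mclInflation = 2, mclExpansion = 2, mclPruneMin = 1e-5,
    mclMaxIter = 100, mclTol = 1e-8,
    svmCost = 1, svmGamma = NA_real_, scaleMode = "zscore",
    cvFolds = 5, cvRepeats = 5, topKEdges = 2, seed = 1)
  override <- list(...)
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown))
    stop("unknown RunConfig fields: ", paste(unknown, collapse = ", "))
  defaults[names(override)] <- override
  do.call(new, c(list(Class = "RunConfig"), defaults))
}

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig:\n")
  utils::str(configAsList(object), no.list = TRUE, give.head = FALSE)
})

configAsList <- function(config) {
  nm <- slotNames("RunConfig")
  stats::setNames(lapply(nm, function(s) slot(config, s)), nm)
}

#' Read / write a RunConfig as YAML
#'
#' The YAML round trip is lossless: every slot is written and restored
#' exactly (numerics at full precision).
#'
#' @param path file path.
#' @param config a [RunConfig-class].
#' @return `readRunConfig` returns a validated [RunConfig-class];
#'   `writeRunConfig` invisibly returns `path`.
#' @export
readRunConfig <- function(path) {
  lst <- yaml::read_yaml(path)
  lst <- lapply(lst, function(x) if (identical(x, "NA")) NA_real_ else x)
  do.call(runConfig, lst)
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  lst <- configAsList(config)
  yaml::write_yaml(lst, path, precision = 17)
  invisible(path)
}
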