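#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' ExpressionMatrix: a log2 expression matrix with sample group labels
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] holding a
#' single `log2` assay of finite values, a `featureKind` tag (`"miRNA"` or
#' `"mRNA"`), and optionally a `group` column in `colData` assigning each
#' sample to the responder or non-responder arm plus any clinical covariates
#' (age, gender, ESR, CRP, RF, anti-CCP status).
#'
#' @slot featureKind single string, `"miRNA"` or `"mRNA"`.
#' @export
setClass("ExpressionMatrix",
  contains = "SummarizedExperiment",
  slots = c(featureKind = "character")
)

setValidity("ExpressionMatrix", function(object) {
  msg <- character()
  if (length(object@featureKind) != 1L ||
      !object@featureKind %in% c("miRNA", "mRNA"))
    msg <- c(msg, "featureKind must be 'miRNA' or 'mRNA'")
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  else {
    v <- SummarizedExperiment::assay(object, "log2")
    if (!is.numeric(v) || any(!is.finite(v)))
      msg <- c(msg, "log2 values must be finite numerics")
    if (nrow(v) == 0L || ncol(v) == 0L)
      msg <- c(msg, "expression matrix must be non-empty")
    if (is.null(rownames(v)) || anyDuplicated(rownames(v)))
      msg <- c(msg, "feature IDs must be present and unique")
    if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
      msg <- c(msg, "sample IDs must be present and unique")
  }
  if ("group" %in% colnames(SummarizedExperiment::colData(object))) {
    g <- SummarizedExperiment::colData(object)$group
    if (!all(g %in% c("responder", "non_responder")))
      msg <- c(msg, "group labels must be 'responder' or 'non_responder'")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix of log2 intensities, features x samples, with
#'   unique row (feature) and column (sample) names.
#' @param featureKind `"miRNA"` or `"mRNA"`.
#' @param annotation optional data.frame with columns `sample_id`, `group`
#'   (values `"responder"`/`"non_responder"`) and any covariate columns; one
#'   row per sample of `values`.
#' @return An [ExpressionMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(12), 3, 4,
#'   dimnames = list(paste0("miR-", 1:3), paste0("S", 1:4)))
#' ExpressionMatrix(m, "miRNA")
#' @export
ExpressionMatrix <- function(values, featureKind = c("miRNA", "mRNA"),
                             annotation = NULL) {
  featureKind <- match.arg(featureKind)
  if (!is.matrix(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(annotation)) {
    annotation <- as.data.frame(annotation)
    if (!all(c("sample_id", "group") %in% colnames(annotation)))
      stop("annotation needs 'sample_id' and 'group' columns")
    if (anyDuplicated(annotation$sample_id))
      stop("duplicate sample_id in annotation")
    missing <- setdiff(colnames(values), annotation$sample_id)
    if (length(missing))
      stop("samples without annotation: ", paste(missing, collapse = ", "))
    annotation <- annotation[match(colnames(values), annotation$sample_id), ,
                             drop = FALSE]
    cd <- S4Vectors::DataFrame(annotation[setdiff(colnames(annotation),
                                                  "sample_id")],
                               row.names = colnames(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2 = values), colData = cd)
  new("ExpressionMatrix", se, featureKind = featureKind)
}

#' @describeIn ExpressionMatrix feature kind accessor.
#' @param x an `ExpressionMatrix`.
#' @export
featureKind <- function(x) x@featureKind

#' @describeIn ExpressionMatrix the log2 value matrix.
#' @export
exprValues <- function(x) SummarizedExperiment::assay(x, "log2")

#' @describeIn ExpressionMatrix sample group labels (or NULL when absent).
#' @export
sampleGroups <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"group" %in% colnames(cd)) return(NULL)
  stats::setNames(as.character(cd$group), rownames(cd))
}

setMethod("show", "ExpressionMatrix", function(object) {
  g <- sampleGroups(object)
  cat(sprintf("ExpressionMatrix (%s): %d features x %d samples\n",
              object@featureKind, nrow(object), ncol(object)))
  if (!is.null(g))
    cat(sprintf("  groups: %d responder / %d non_responder\n",
                sum(g == "responder"), sum(g == "non_responder")))
})

#' RVMPrior: fitted random-variance-model prior
#'
#' Inverse-gamma prior on per-feature variances, parameterised so that
#' `s2 * a * b` follows an F(df, 2a) distribution for observed pooled
#' variances `s2` with `df` residual degrees of freedom.
#'
#' @slot a shape parameter (> 0).
#' @slot b scale parameter (> 0).
#' @slot logLik maximised marginal log-likelihood.
#' @slot nFeatures number of variances used in the fit.
#' @slot df residual degrees of freedom of the variances.
#' @export
setClass("RVMPrior", slots = c(a = "numeric", b = "numeric",
                               logLik = "numeric", nFeatures = "integer",
                               df = "numeric"))

setValidity("RVMPrior", function(object) {
  if (object@a <= 0 || object@b <= 0) "a and b must be positive" else TRUE
})

setMethod("show", "RVMPrior", function(object) {
  cat(sprintf(paste0("RVMPrior: a = %.4g, b = %.4g ",
                     "(df %.3g + 2a = %.4g effective df; %d features)\n"),
              object@a, object@b, object@df, object@df + 2 * object@a,
              object@nFeatures))
})

#' ModulePartition: Markov clustering result
#'
#' @slot membership named integer vector, node -> module id (1-based, ordered
#'   by decreasing module size then smallest member id).
#' @slot iterations number of expansion/inflation iterations performed.
#' @slot converged whether the iteration reached the tolerance.
#' @export
setClass("ModulePartition", slots = c(membership = "integer",
                                      iterations = "integer",
                                      converged = "logical"))

setValidity("ModulePartition", function(object) {
  m <- object@membership
  if (length(m) && (is.null(names(m)) || anyDuplicated(names(m))))
    return("membership must be named with unique node ids")
  if (length(m) && any(is.na(m))) return("every node needs a module")
  TRUE
})

#' @describeIn ModulePartition module sizes, largest first.
#' @param x a `ModulePartition`.
#' @export
moduleSizes <- function(x) {
  tab <- table(x@membership)
  as.integer(tab[order(as.integer(names(tab)))])
}

#' @describeIn ModulePartition named membership vector.
#' @export
moduleMembership <- function(x) x@membership

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition: %d nodes in %d modules (sizes %s); %s\n",
              length(object@membership),
              length(unique(object@membership)),
              paste(moduleSizes(object), collapse = "/"),
              if (object@converged)
                sprintf("converged in %d iterations", object@iterations)
              else "NOT converged"))
})

#' BiomarkerPanel: the candidate circulating miRNA panel
#'
#' @slot panel data.frame with columns `mirna_id`, `anchor_gene`, `log2fc`,
#'   `p_value`, ordered by the edge rank of the anchor genes.
#' @slot provenance list recording the key interactions used and the
#'   selection rule.
#' @export
setClass("BiomarkerPanel", slots = c(panel = "data.frame",
                                     provenance = "list"))

setValidity("BiomarkerPanel", function(object) {
  need <- c("mirna_id", "anchor_gene", "log2fc", "p_value")
  if (!all(need %in% colnames(object@panel)))
    return("panel needs mirna_id/anchor_gene/log2fc/p_value columns")
  if (anyDuplicated(object@panel$mirna_id))
    return("panel miRNA ids must be unique")
  TRUE
})

#' @describeIn BiomarkerPanel the panel miRNA identifiers, in panel order.
#' @param x a `BiomarkerPanel`.
#' @export
panelMirnas <- function(x) x@panel$mirna_id

#' @describeIn BiomarkerPanel the panel as a data.frame.
#' @export
panelTable <- function(x) x@panel

setMethod("show", "BiomarkerPanel", function(object) {
  cat(sprintf("BiomarkerPanel: %d miRNA(s)\n", nrow(object@panel)))
  print(object@panel, row.names = FALSE)
})

#' CVReport: repeated stratified k-fold cross-validation report
#'
#' @slot folds data.frame, one row per repeat x fold, with confusion counts
#'   (`TP`, `TN`, `FP`, `FN`) and per-fold metrics.
#' @slot repeats data.frame, one row per repeat, with metrics pooled over the
#'   repeat's folds (accuracy, sensitivity, specificity, AUC).
#' @slot summary named numeric vector of across-repeat means and SDs.
#' @slot assignments integer matrix samples x repeats of fold labels.
#' @slot seed the RNG seed that generated the folds.
#' @export
setClass("CVReport", slots = c(folds = "data.frame", repeats = "data.frame",
                               summary = "numeric", assignments = "matrix",
                               seed = "numeric"))

setMethod("show", "CVReport", function(object) {
  s <- object@summary
  cat(sprintf("CVReport: %d repeats x %d folds (seed %s)\n",
              nrow(object@repeats),
              max(object@folds$fold), format(object@seed)))
  cat(sprintf("  accuracy %.3f +/- %.3f, sensitivity %.3f, specificity %.3f, AUC %.3f\n",
              s[["mean_accuracy"]], s[["sd_accuracy"]],
              s[["mean_sensitivity"]], s[["mean_specificity"]],
              s[["mean_auc"]]))
})

#' @describeIn CVReport per-repeat pooled metrics.
#' @param x a `CVReport`.
#' @export
cvRepeats <- function(x) x@repeats

#' @describeIn CVReport per-fold confusion counts and metrics.
#' @export
cvFolds <- function(x) x@folds

#' @describeIn CVReport across-repeat summary (means and SDs).
#' @export
cvSummary <- function(x) x@summary
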