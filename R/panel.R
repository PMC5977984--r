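#' Genes of the top edge-betweenness interactions
#'
#' Union of the endpoint genes of the `topK` highest-scoring interactions;
#' edges tied with the score at the cutoff are all included.
#'
#' @param edgeReport data.frame from [edgeBetweennessRanking()].
#' @param topK number of key interactions to keep (>= 1).
#' @return character vector of anchor genes, in edge-rank order.
#' @export
keyInteractionGenes <- function(edgeReport, topK = 2) {
  if (topK < 1) stop("topK must be >= 1")
  if (nrow(edgeReport) == 0L) stop("edge report is empty")
  ord <- order(-edgeReport$edge_betweenness)
  sorted <- edgeReport[ord, ]
  cutoff <- sorted$edge_betweenness[min(topK, nrow(sorted))]
  kept <- sorted[sorted$edge_betweenness >= cutoff, , drop = FALSE]
  unique(as.vector(t(as.matrix(kept[, c("gene_a", "gene_b")]))))
}

#' Select the most significantly dysregulated upstream miRNA per gene
#'
#' For each anchor gene, among its incident miRNAs in the co-expression
#' network the one with the smallest DE p-value is chosen (ties: larger
#' |log2fc|, then id).  Genes without any upstream miRNA are reported and
#' skipped.  The panel is de-duplicated across genes (first anchor wins)
#' and ordered by anchor-gene edge rank.
#'
#' @param genes anchor genes from [keyInteractionGenes()], in rank order.
#' @param coexp co-expression graph from [buildCoexpressionNetwork()].
#' @param deResults DE data.frame (all features) from [rvmTTest()],
#'   supplying log2fc and p for the chosen miRNAs.
#' @return a [BiomarkerPanel-class].
#' @export
selectUpstreamMirnas <- function(genes, coexp, deResults) {
  vs <- igraph::V(coexp)$name
  picks <- list()
  skippedGenes <- character()
  for (g in genes) {
    if (!g %in% vs) { skippedGenes <- c(skippedGenes, g); next }
    nb <- igraph::neighbors(coexp, g)
    nb <- nb[nb$kind == "miRNA"]
    if (length(nb) == 0L) { skippedGenes <- c(skippedGenes, g); next }
    cand <- data.frame(mirna_id = nb$name, log2fc = nb$log2fc,
                       p_value = nb$p_value, stringsAsFactors = FALSE)
    cand <- cand[order(cand$p_value, -abs(cand$log2fc), cand$mirna_id), ]
    picks[[length(picks) + 1L]] <- data.frame(
      mirna_id = cand$mirna_id[1L], anchor_gene = g,
      stringsAsFactors = FALSE)
  }
  if (length(skippedGenes))
    message("anchor gene(s) without upstream miRNA skipped: ",
            paste(skippedGenes, collapse = ", "))
  if (length(picks) == 0L)
    stop("no anchor gene has an upstream miRNA in the co-expression network")
  panel <- do.call(rbind, picks)
  panel <- panel[!duplicated(panel$mirna_id), , drop = FALSE]
  i <- match(panel$mirna_id, deResults$feature_id)
  panel$log2fc <- deResults$log2fc[i]
  panel$p_value <- deResults$p_value[i]
  rownames(panel) <- NULL
  new("BiomarkerPanel", panel = panel,
      provenance = list(anchor_genes = genes,
                        skipped_genes = skippedGenes,
                        rule = "min DE p, tie |log2fc| desc then id; dedup by first anchor"))
}

#' Samples-by-panel feature matrix for the classifier
#'
#' Columns follow panel order; values are copied unchanged (scaling happens
#' inside the classifier, per training fold).
#'
#' @param panel a [BiomarkerPanel-class] (or character vector of miRNA ids).
#' @param mirnaX the miRNA [ExpressionMatrix-class].
#' @return numeric matrix, samples x panel miRNAs.
#' @export
panelFeatureMatrix <- function(panel, mirnaX) {
  ids <- if (is(panel, "BiomarkerPanel")) panelMirnas(panel)
         else as.character(panel)
  v <- exprValues(mirnaX)
  missing <- setdiff(ids, rownames(v))
  if (length(missing))
    stop("panel miRNA(s) missing from the matrix: ",
         paste(missing, collapse = ", "))
  t(v[ids, , drop = FALSE])
}
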