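#' Intersect two target-prediction tables
#'
#' Only miRNA-target pairs predicted by BOTH sources are retained (the
#' high-accuracy intersection rule).  The result is order-independent.
#'
#' @param tableA,tableB data.frames with columns `mirna_id`, `gene_id`
#'   (e.g. from [readTargetPairs()] or [generatePairTables()]).
#' @return data.frame of the common pairs, sorted by miRNA then gene id.
#' @export
intersectPredictions <- function(tableA, tableB) {
  if (nrow(tableA) == 0L || nrow(tableB) == 0L)
    stop("both prediction tables must be non-empty")
  keyA <- unique(paste(tableA$mirna_id, tableA$gene_id, sep = "\r"))
  keyB <- unique(paste(tableB$mirna_id, tableB$gene_id, sep = "\r"))
  common <- sort(intersect(keyA, keyB))
  parts <- strsplit(common, "\r", fixed = TRUE)
  data.frame(mirna_id = vapply(parts, `[`, "", 1L),
             gene_id = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

#' Build the miRNA-target co-expression network
#'
#' A bipartite undirected graph whose edges are predicted miRNA-target
#' pairs restricted to differentially expressed endpoints and passing the
#' anti-correlation rule.  Under the default rule an edge `(m, g)` requires
#' Pearson `r < 0` across all samples (both groups pooled), a correlation
#' test p-value `< corrPMax`, and opposite DE directions of miRNA and gene;
#' each clause can be toggled.  Pairs referencing a feature absent from its
#' matrix are skipped and counted, not fatal.
#'
#' @param pairs data.frame of predicted pairs (`mirna_id`, `gene_id`),
#'   typically from [intersectPredictions()].
#' @param deMirnas,deGenes significant DE rows (data.frames with
#'   `feature_id`, `direction`, `log2fc`, `p_value`) from [screenDE()].
#' @param mirnaX,mrnaX the [ExpressionMatrix-class]es, sharing the sample
#'   set.
#' @param requireNegative,corrPMax,requireOpposite the anti-correlation
#'   rule.
#' @return an [igraph::igraph]; vertices carry `kind`
#'   (`"miRNA"`/`"gene"`), `direction`, `log2fc`, `p_value` and `type`
#'   (logical bipartite mapping, TRUE for genes); edges carry `pearson_r`
#'   and `corr_p`.  Graph attribute `skipped` counts pairs whose features
#'   were missing from a matrix.
#' @export
buildCoexpressionNetwork <- function(pairs, deMirnas, deGenes,
                                     mirnaX, mrnaX,
                                     requireNegative = TRUE,
                                     corrPMax = 0.05,
                                     requireOpposite = TRUE) {
  mv <- exprValues(mirnaX); gv <- exprValues(mrnaX)
  if (!identical(colnames(mv), colnames(gv)))
    stop("miRNA and mRNA matrices must share the same samples in order")
  keep <- pairs$mirna_id %in% deMirnas$feature_id &
    pairs$gene_id %in% deGenes$feature_id
  cand <- pairs[keep, , drop = FALSE]
  present <- cand$mirna_id %in% rownames(mv) & cand$gene_id %in% rownames(gv)
  skipped <- sum(!present)
  if (skipped)
    message(skipped, " pair(s) referenced features missing from a matrix; skipped")
  cand <- cand[present, , drop = FALSE]
  edges <- lapply(seq_len(nrow(cand)), function(i) {
    m <- cand$mirna_id[i]; g <- cand$gene_id[i]
    ct <- stats::cor.test(mv[m, ], gv[g, ], method = "pearson")
    r <- unname(ct$estimate); pc <- ct$p.value
    ok <- TRUE
    if (requireNegative) ok <- ok && r < 0
    ok <- ok && pc < corrPMax
    if (requireOpposite) {
      dm <- deMirnas$direction[match(m, deMirnas$feature_id)]
      dg <- deGenes$direction[match(g, deGenes$feature_id)]
      ok <- ok && dm != dg
    }
    if (!ok) return(NULL)
    data.frame(mirna_id = m, gene_id = g, pearson_r = r, corr_p = pc,
               stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, edges)
  if (is.null(edges))
    edges <- data.frame(mirna_id = character(), gene_id = character(),
                        pearson_r = numeric(), corr_p = numeric())
  mNodes <- sort(unique(edges$mirna_id)); gNodes <- sort(unique(edges$gene_id))
  deAttr <- function(ids, de) {
    i <- match(ids, de$feature_id)
    list(direction = de$direction[i], log2fc = de$log2fc[i],
         p_value = de$p_value[i])
  }
  am <- deAttr(mNodes, deMirnas); ag <- deAttr(gNodes, deGenes)
  vertices <- data.frame(
    name = c(mNodes, gNodes),
    kind = rep(c("miRNA", "gene"), c(length(mNodes), length(gNodes))),
    direction = c(am$direction, ag$direction),
    log2fc = c(am$log2fc, ag$log2fc),
    p_value = c(am$p_value, ag$p_value),
    type = rep(c(FALSE, TRUE), c(length(mNodes), length(gNodes))),
    stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = vertices)
  g <- igraph::set_graph_attr(g, "skipped", skipped)
  g
}

#' Rank miRNAs of a co-expression network by degree
#'
#' The key miRNA is the one with the biggest degree, i.e. the largest
#' contribution to the target genes around it.  Ties are broken by larger
#' |log2fc|, then by id.
#'
#' @param network the co-expression graph from
#'   [buildCoexpressionNetwork()].
#' @return data.frame (`mirna_id`, `degree`, `log2fc`, `p_value`), ranked;
#'   the first row is the key miRNA.
#' @export
keyMirna <- function(network) {
  isM <- igraph::V(network)$kind == "miRNA"
  if (!any(isM)) stop("network has no miRNA nodes")
  v <- igraph::V(network)[isM]
  df <- data.frame(mirna_id = v$name,
                   degree = igraph::degree(network, v),
                   log2fc = v$log2fc,
                   p_value = v$p_value,
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, -abs(df$log2fc), df$mirna_id), ]
  rownames(df) <- NULL
  df
}

#' Co-expression network edges as a data.frame
#'
#' @param network graph from [buildCoexpressionNetwork()].
#' @return data.frame (`mirna_id`, `gene_id`, `pearson_r`, `corr_p`).
#' @export
coexpressionEdges <- function(network) {
  el <- igraph::as_edgelist(network)
  kind <- igraph::V(network)$kind[match(as.vector(el),
                                        igraph::V(network)$name)]
  dim(kind) <- dim(el)
  swap <- kind[, 1L] != "miRNA"
  mirna <- ifelse(swap, el[, 2L], el[, 1L])
  gene <- ifelse(swap, el[, 1L], el[, 2L])
  data.frame(mirna_id = mirna, gene_id = gene,
             pearson_r = igraph::E(network)$pearson_r,
             corr_p = igraph::E(network)$corr_p,
             stringsAsFactors = FALSE)
}
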