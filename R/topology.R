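#' Build the gene signal-transduction network by median score filtering
#'
#' The combined-score median is computed over ALL interactions in the input
#' table (before any restriction to differentially expressed genes).  An
#' edge is kept iff its score is strictly greater than that median AND both
#' endpoints are in `deGenes`.  Isolated nodes are dropped.
#'
#' @param interactions data.frame (`gene_a`, `gene_b`, `combined_score`),
#'   e.g. from [readInteractions()].
#' @param deGenes character vector of differentially expressed gene ids.
#' @param medianAfterRestriction compute the median over interactions among
#'   `deGenes` only (default FALSE: median over the full table).
#' @return simple undirected [igraph::igraph] (no loops, no multi-edges).
#'   An empty result is returned with a warning rather than an error.
#' @export
filterByMedianScore <- function(interactions, deGenes,
                                medianAfterRestriction = FALSE) {
  interactions <- normalizeInteractions(interactions)
  if (nrow(interactions) == 0L) stop("interaction table is empty")
  inDE <- interactions$gene_a %in% deGenes & interactions$gene_b %in% deGenes
  med <- if (medianAfterRestriction)
    stats::median(interactions$combined_score[inDE])
  else stats::median(interactions$combined_score)
  keep <- interactions$combined_score > med & inDE
  if (!any(keep)) {
    warning("median-score filter kept no interactions; returning an empty network")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  el <- as.matrix(interactions[keep, c("gene_a", "gene_b")])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::E(g)$combined_score <- interactions$combined_score[keep]
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Relative betweenness centrality
#'
#' For each vertex `v` of a graph with `n` vertices,
#' `C'B(v) = 2/(n^2 - 3n + 2) * sum_{s != v != t} sigma_st(v) / sigma_st`,
#' where `sigma_st` counts shortest s-t paths and `sigma_st(v)` those
#' passing through `v`.  Pairs in different components contribute 0.  The
#' value lies in \[0, 1\] for connected graphs.
#'
#' @param graph undirected [igraph::igraph] with >= 3 vertices.
#' @return named numeric vector of centralities.
#' @export
betweennessCentrality <- function(graph) {
  if (igraph::vcount(graph) < 3L)
    stop("relative betweenness needs >= 3 vertices")
  igraph::betweenness(graph, directed = FALSE, normalized = TRUE)
}

#' Closeness centrality
#'
#' `C(i) = 1 / sum_y d(y, i)`, the inverse of the farness.  On a
#' disconnected graph the sum runs over the vertices reachable from `i`
#' (its component); a fully isolated vertex gets closeness 0.
#'
#' @param graph undirected [igraph::igraph].
#' @return named numeric vector of closeness values.
#' @export
closenessCentrality <- function(graph) {
  if (igraph::vcount(graph) == 0L) stop("graph is empty")
  cl <- suppressWarnings(igraph::closeness(graph, mode = "all",
                                           normalized = FALSE))
  cl[!is.finite(cl)] <- 0
  cl
}

#' Per-node topological feature report
#'
#' Degree, relative betweenness and closeness for every node, their
#' medians, and the hub flag: a hub has all three features strictly greater
#' than the corresponding median.
#'
#' @param graph undirected [igraph::igraph] with >= 3 vertices.
#' @return data.frame (`gene_id`, `degree`, `betweenness`, `closeness`,
#'   `hub`) sorted by degree descending then id, with attribute `medians`.
#' @export
topologyReport <- function(graph) {
  deg <- igraph::degree(graph)
  btw <- betweennessCentrality(graph)
  cls <- closenessCentrality(graph)
  med <- c(degree = stats::median(deg), betweenness = stats::median(btw),
           closeness = stats::median(cls))
  df <- data.frame(gene_id = igraph::V(graph)$name,
                   degree = unname(deg), betweenness = unname(btw),
                   closeness = unname(cls),
                   hub = unname(deg > med["degree"] &
                                btw > med["betweenness"] &
                                cls > med["closeness"]),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$degree, df$gene_id), ]
  rownames(df) <- NULL
  attr(df, "medians") <- med
  df
}

#' Select hub genes
#'
#' @param report data.frame from [topologyReport()].
#' @return character vector of hub gene ids, highest degree first.
#' @export
selectHubs <- function(report) {
  report$gene_id[report$hub]
}

#' Markov clustering of a network into functional modules
#'
#' The column-stochastic transition matrix (self-loops of weight 1 added)
#' is iterated through expansion (matrix power), inflation (elementwise
#' power followed by column renormalisation) and pruning (entries below
#' `pruneMin` zeroed, columns renormalised) until the maximum column change
#' falls below `tol` or `maxIter` is reached.  Modules are read from the
#' limit matrix: attractors are vertices with positive diagonal mass,
#' attractors sharing support form one module, and every vertex joins the
#' module holding the largest share of its column mass (ties go to the
#' module with the smallest id).
#'
#' @param graph undirected [igraph::igraph].
#' @param inflation inflation exponent (> 1).
#' @param expansion expansion power (integer >= 2).
#' @param pruneMin pruning threshold.
#' @param maxIter,tol iteration control.
#' @return a [ModulePartition-class]; non-convergence yields a warning and
#'   `converged = FALSE`, never an error.
#' @export
mclCluster <- function(graph, inflation = 2, expansion = 2,
                       pruneMin = 1e-5, maxIter = 100, tol = 1e-8) {
  if (igraph::vcount(graph) == 0L) stop("graph is empty")
  if (inflation <= 1) stop("inflation must be > 1")
  if (expansion < 2) stop("expansion must be >= 2")
  n <- igraph::vcount(graph)
  ids <- igraph::V(graph)$name
  if (is.null(ids)) ids <- as.character(seq_len(n))
  A <- igraph::as_adjacency_matrix(graph, sparse = FALSE)
  M <- A + diag(n)
  M <- sweep(M, 2L, colSums(M), "/")
  converged <- FALSE
  it <- 0L
  while (it < maxIter) {
    it <- it + 1L
    Mn <- M
    for (e in seq_len(expansion - 1L)) Mn <- Mn %*% M
    Mn <- Mn^inflation
    Mn <- sweep(Mn, 2L, colSums(Mn), "/")
    Mn[Mn < pruneMin] <- 0
    cs <- colSums(Mn)
    if (any(cs == 0)) stop("pruning removed an entire column; lower pruneMin")
    Mn <- sweep(Mn, 2L, cs, "/")
    delta <- max(abs(Mn - M))
    M <- Mn
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("MCL did not converge within ", maxIter, " iterations")
  eps <- 1e-9
  attractors <- which(diag(M) > eps)
  if (length(attractors) == 0L) attractors <- seq_len(n)  # degenerate guard
  # attractors sharing row/column support belong to one module
  supp <- (M[attractors, , drop = FALSE] > eps)
  overlap <- supp %*% t(supp) > 0
  ag <- igraph::graph_from_adjacency_matrix(overlap, mode = "undirected",
                                            diag = FALSE)
  attrModule <- igraph::components(ag)$membership
  nMod <- max(attrModule)
  mass <- matrix(0, nMod, n)
  for (k in seq_len(nMod))
    mass[k, ] <- colSums(M[attractors[attrModule == k], , drop = FALSE])
  membership <- apply(mass, 2L, which.max)  # ties -> smallest module id
  uncovered <- colSums(mass) == 0
  if (any(uncovered)) {
    # no attractor mass (can happen pre-convergence): fall back to components
    comp <- igraph::components(graph)$membership
    membership[uncovered] <- nMod + comp[uncovered]
  }
  # relabel 1..K by decreasing size, ties by smallest member index
  sizes <- table(membership)
  first <- vapply(names(sizes),
                  function(k) min(which(membership == as.integer(k))), 1L)
  ord <- order(-as.integer(sizes), first)
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  membership <- unname(relabel[as.character(membership)])
  new("ModulePartition",
      membership = stats::setNames(as.integer(membership), ids),
      iterations = it, converged = converged)
}

#' Edge betweenness ranking of interactions
#'
#' For each edge, the sum over unordered vertex pairs of the fraction of
#' shortest paths between the pair that traverse the edge (unnormalised
#' path-count units).  Edges are ranked descending; the top-ranked edges
#' are the key signal-transfer interactions, with ties at the maximum all
#' kept.
#'
#' @param graph undirected [igraph::igraph].
#' @return data.frame (`gene_a`, `gene_b`, `edge_betweenness`) sorted
#'   descending, with attribute `key` giving the row indices tied at the
#'   maximum.
#' @export
edgeBetweennessRanking <- function(graph) {
  if (igraph::ecount(graph) == 0L) stop("graph has no edges")
  eb <- igraph::edge_betweenness(graph, directed = FALSE)
  el <- igraph::as_edgelist(graph)
  df <- data.frame(gene_a = el[, 1L], gene_b = el[, 2L],
                   edge_betweenness = eb, stringsAsFactors = FALSE)
  df <- df[order(-df$edge_betweenness, df$gene_a, df$gene_b), ]
  rownames(df) <- NULL
  attr(df, "key") <- which(df$edge_betweenness == max(df$edge_betweenness))
  df
}

#' Hypergeometric enrichment of modules against gene sets
#'
#' For a module of size `m` overlapping a gene set of size `K` (within the
#' universe, size `N`) in `k` genes, the one-sided tail `P(X >= k)` of the
#' hypergeometric distribution is reported, with Benjamini-Hochberg
#' adjustment across all (module, set) pairs.  Gene sets disjoint from the
#' universe are skipped with a warning.
#'
#' @param partition a [ModulePartition-class].
#' @param geneSets named list of character vectors (e.g. from
#'   [readGMT()]).
#' @param universe character vector containing at least all module genes.
#' @return data.frame (`module`, `gene_set`, `overlap`, `module_size`,
#'   `set_size`, `universe_size`, `p_value`, `fdr_q`).
#' @export
enrichModules <- function(partition, geneSets, universe) {
  member <- moduleMembership(partition)
  if (!all(names(member) %in% universe))
    stop("universe must contain every module gene")
  N <- length(unique(universe))
  rows <- list()
  for (mod in sort(unique(member))) {
    genes <- names(member)[member == mod]
    for (setName in names(geneSets)) {
      set <- intersect(unique(geneSets[[setName]]), universe)
      if (length(set) == 0L) {
        warning("gene set '", setName, "' is disjoint from the universe; skipped")
        next
      }
      k <- length(intersect(genes, set))
      p <- stats::phyper(k - 1, length(set), N - length(set),
                         length(genes), lower.tail = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, gene_set = setName, overlap = k,
        module_size = length(genes), set_size = length(set),
        universe_size = N, p_value = p, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no (module, gene set) pair to test")
  out <- do.call(rbind, rows)
  out$fdr_q <- bhFDR(out$p_value)
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path GMT file.
#' @return named list of character vectors.
#' @export
readGMT <- function(path) {
  parts <- strsplit(readLines(path), "\t", fixed = TRUE)
  parts <- parts[lengths(parts) >= 3L]
  stats::setNames(lapply(parts, function(p) unique(p[-(1:2)])),
                  vapply(parts, `[`, "", 1L))
}
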