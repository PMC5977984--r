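# Brute-force shortest-path oracles, independent of any graph library:
# exhaustive simple-path enumeration, practical for n <= 8.

allShortestPaths <- function(adj, s, t) {
  paths <- list()
  rec <- function(path) {
    v <- path[length(path)]
    if (v == t) {
      paths[[length(paths) + 1L]] <<- path
      return(invisible(NULL))
    }
    for (w in which(adj[v, ] > 0)) if (!w %in% path) rec(c(path, w))
  }
  rec(s)
  if (length(paths) == 0L) return(list())
  len <- vapply(paths, length, 1L)
  paths[len == min(len)]
}

bruteNodeBetweenness <- function(adj) {
  n <- nrow(adj)
  cb <- numeric(n)
  for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
    sp <- allShortestPaths(adj, s, t)
    if (length(sp) == 0L) next
    inner <- setdiff(seq_len(n), c(s, t))
    for (v in inner)
      cb[v] <- cb[v] + sum(vapply(sp, function(p) v %in% p, TRUE)) /
        length(sp)
  }
  cb * 2 / (n^2 - 3 * n + 2)
}

bruteEdgeBetweenness <- function(adj, edges) {
  # edges: 2-column matrix of vertex indices
  n <- nrow(adj)
  eb <- numeric(nrow(edges))
  usesEdge <- function(path, a, b) {
    any((path[-length(path)] == a & path[-1L] == b) |
          (path[-length(path)] == b & path[-1L] == a))
  }
  for (s in seq_len(n - 1L)) for (t in seq((s + 1L), n)) {
    sp <- allShortestPaths(adj, s, t)
    if (length(sp) == 0L) next
    for (e in seq_len(nrow(edges)))
      eb[e] <- eb[e] + sum(vapply(sp, usesEdge, TRUE,
                                  edges[e, 1L], edges[e, 2L])) / length(sp)
  }
  eb
}

bruteAUC <- function(scores, labels) {
  pos <- scores[labels == 1 | labels == "responder"]
  neg <- scores[labels == -1 | labels == "non_responder"]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

randomConnectedGraph <- function(n, p = 0.45) {
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g)) {
      igraph::V(g)$name <- paste0("v", seq_len(n))
      return(g)
    }
  }
}

# twin k-cliques joined by one bridge, nodes named g1..g(2k)
bridgedCliques <- function(k) {
  e <- rbind(t(utils::combn(seq_len(k), 2L)),
             t(utils::combn(k + seq_len(k), 2L)),
             c(1L, k + 1L))
  g <- igraph::graph_from_edgelist(e, directed = FALSE)
  igraph::V(g)$name <- paste0("g", seq_len(2L * k))
  g
}

# tiny two-group ExpressionMatrix built from an explicit value matrix
exprFixture <- function(values, kind = "miRNA",
                        groups = NULL) {
  if (is.null(groups))
    groups <- rep(c("responder", "non_responder"), length.out = ncol(values))
  ann <- data.frame(sample_id = colnames(values), group = groups,
                    stringsAsFactors = FALSE)
  ExpressionMatrix(values, kind, ann)
}

flatPrior <- function(df = 10) {
  # negligible shrinkage: moderated test collapses to the pooled t-test
  new("RVMPrior", a = 1e-9, b = 1e9, logLik = 0, nFeatures = 20L, df = df)
}
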