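#' Fit the random-variance-model prior
#'
#' The random variance model places an inverse-gamma prior on per-feature
#' variances, under which the observed pooled variance `s2` of a feature
#' with `df` residual degrees of freedom satisfies `s2 * a * b ~ F(df, 2a)`.
#' `(a, b)` are estimated by maximising the marginal likelihood with a
#' deterministic Nelder-Mead search on the log scale (fixed start at
#' `a = b = 1`, relative tolerance 1e-12).
#'
#' Sharing the prior across features adds `2a` degrees of freedom to every
#' moderated test, which is what rescues power at very small sample sizes.
#'
#' @param sampleVariances per-feature pooled variances (length >= 20, not
#'   all equal).
#' @param df residual degrees of freedom of each variance (n1 + n2 - 2).
#' @return an [RVMPrior-class].
#' @references Wright, G.W. and Simon, R.M. (2003) A random variance model
#'   for detection of differential gene expression in small microarray
#'   experiments. Bioinformatics 19, 2448-2455.
#' @export
fitRVMPrior <- function(sampleVariances, df) {
  s2 <- as.numeric(sampleVariances)
  if (length(s2) < 20L)
    stop("need >= 20 features to fit the variance prior")
  if (df < 1) stop("df must be >= 1")
  if (any(!is.finite(s2)) || any(s2 < 0)) stop("variances must be finite, >= 0")
  if (all(s2 == 0)) stop("all variances are zero; prior cannot be fit")
  if (stats::var(s2) == 0)
    stop("constant variances: prior is degenerate (a -> Inf)")
  s2 <- s2[s2 > 0]
  nll <- function(par) {
    a <- exp(par[1L]); b <- exp(par[2L])
    if (!is.finite(a) || !is.finite(b) || a > 1e8) return(1e10)
    ll <- sum(stats::df(s2 * a * b, df1 = df, df2 = 2 * a, log = TRUE) +
                log(a * b))
    if (!is.finite(ll)) return(1e10)
    -ll
  }
  fit <- stats::optim(c(0, 0), nll, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 5000))
  if (fit$convergence != 0L)
    stop("RVM prior fit did not converge (code ", fit$convergence,
         ", value ", format(fit$value), ")")
  a <- exp(fit$par[1L]); b <- exp(fit$par[2L])
  if (a > 1e6)
    stop("RVM prior fit degenerate: a -> Inf (variances nearly constant)")
  new("RVMPrior", a = a, b = b, logLik = -fit$value,
      nFeatures = length(s2), df = df)
}

groupsFrom <- function(x, annotation) {
  g <- if (is.null(annotation)) sampleGroups(x)
       else stats::setNames(annotation$group, annotation$sample_id)[
         colnames(x)]
  if (is.null(g) || any(is.na(g)))
    stop("every sample needs a responder/non_responder label")
  g
}

pooledStats <- function(values, groups) {
  i1 <- which(groups == "responder"); i2 <- which(groups == "non_responder")
  n1 <- length(i1); n2 <- length(i2)
  if (n1 < 2L || n2 < 2L) stop("both groups need >= 2 samples")
  m1 <- rowMeans(values[, i1, drop = FALSE])
  m2 <- rowMeans(values[, i2, drop = FALSE])
  v1 <- apply(values[, i1, drop = FALSE], 1L, stats::var)
  v2 <- apply(values[, i2, drop = FALSE], 1L, stats::var)
  s2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  list(n1 = n1, n2 = n2, m1 = m1, m2 = m2, s2 = s2, d = n1 + n2 - 2)
}

#' Per-feature pooled variances (for fitting the RVM prior)
#'
#' @param x an [ExpressionMatrix-class].
#' @param annotation optional annotation data.frame overriding embedded
#'   group labels.
#' @return named numeric vector of pooled two-group variances.
#' @export
pooledVariances <- function(x, annotation = NULL) {
  st <- pooledStats(exprValues(x), groupsFrom(x, annotation))
  st$s2
}

#' Moderated two-sample t-test under the random variance model
#'
#' For each feature the pooled variance is shrunk towards the prior,
#' `var_mod = (d * s2 + 2/b) / (d + 2a)` with `d = n1 + n2 - 2`, the t
#' statistic is `(mean_responder - mean_nonresponder) /
#' sqrt(var_mod * (1/n1 + 1/n2))`, and the two-sided p-value is taken from
#' a t distribution with `d + 2a` degrees of freedom.  As `a -> 0` and
#' `2/b -> 0` this reduces to the ordinary pooled two-sample t-test.
#'
#' @param x an [ExpressionMatrix-class] with group labels (or `annotation`).
#' @param prior an [RVMPrior-class] fitted on the same matrix's pooled
#'   variances.
#' @param annotation optional annotation data.frame.
#' @return data.frame with one row per feature: `feature_id`,
#'   `mean_responder`, `mean_nonresponder`, `log2fc` (responder minus
#'   non-responder), `fold_change` (2^log2fc), `t_stat`, `df_effective`,
#'   `p_value`, `fdr_q` (Benjamini-Hochberg), `direction` (`up`/`down`),
#'   `significant` (NA until [screenDE()] is applied).
#' @export
rvmTTest <- function(x, prior, annotation = NULL) {
  st <- pooledStats(exprValues(x), groupsFrom(x, annotation))
  a <- prior@a; b <- prior@b
  varMod <- (st$d * st$s2 + 2 / b) / (st$d + 2 * a)
  dfEff <- st$d + 2 * a
  tStat <- (st$m1 - st$m2) / sqrt(varMod * (1 / st$n1 + 1 / st$n2))
  p <- 2 * stats::pt(-abs(tStat), df = dfEff)
  log2fc <- st$m1 - st$m2
  data.frame(feature_id = rownames(x),
             mean_responder = unname(st$m1),
             mean_nonresponder = unname(st$m2),
             log2fc = unname(log2fc),
             fold_change = unname(2^log2fc),
             t_stat = unname(tStat),
             df_effective = dfEff,
             p_value = unname(p),
             fdr_q = unname(bhFDR(p)),
             direction = ifelse(log2fc >= 0, "up", "down"),
             significant = NA,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up adjusted values `q_(i) = min_{j >= i}(p_(j) * m / j)`, capped at
#' 1 and returned in input order.
#'
#' @param pValues numeric vector of p-values in \[0, 1\].
#' @return numeric vector of q-values, same order as the input.
#' @export
bhFDR <- function(pValues) {
  p <- as.numeric(pValues)
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Screen differentially expressed features
#'
#' A feature is significant iff `|log2fc| > log2fcMin` AND
#' `p_value < pMax` (both strict); with `fdrMode = "gate"` additionally
#' `fdr_q < fdrMax`.  Output lists are ordered by decreasing |t|, ties by
#' feature id.
#'
#' @param results data.frame from [rvmTTest()].
#' @param log2fcMin,pMax strict significance thresholds (> 0).
#' @param fdrMode,fdrMax optional additional q-value gate.
#' @return list with `up`, `down` (significant rows, partitioned by the
#'   sign of log2fc) and `results` (all rows with the `significant` flag
#'   filled in).
#' @export
screenDE <- function(results, log2fcMin = 0.5, pMax = 0.05,
                     fdrMode = c("report", "gate"), fdrMax = 0.05) {
  fdrMode <- match.arg(fdrMode)
  if (log2fcMin <= 0 || pMax <= 0) stop("thresholds must be > 0")
  sig <- abs(results$log2fc) > log2fcMin & results$p_value < pMax
  if (fdrMode == "gate") sig <- sig & results$fdr_q < fdrMax
  results$significant <- sig
  ord <- order(-abs(results$t_stat), results$feature_id)
  sigRows <- results[ord, ][results$significant[ord], ]
  list(up = sigRows[sigRows$log2fc > 0, ],
       down = sigRows[sigRows$log2fc <= 0, ],
       results = results)
}

#' Agglomerative hierarchical clustering of features
#'
#' Features are repeatedly merged closest-pair-first under the chosen
#' linkage; the branch length of each merge is the merge distance.
#' Distances: euclidean on the expression rows, or `1 - Pearson r` between
#' rows (an error for constant features, whose correlation is undefined).
#'
#' @param x an [ExpressionMatrix-class] (or plain numeric matrix),
#'   features as rows.
#' @param distance `"one_minus_pearson"` (expression-profile similarity,
#'   the heat-map convention) or `"euclidean"`.
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return an object of class `hclust` (fields `merge`, `height`, `order`,
#'   `labels`).
#' @seealso [dendrogramNewick()]
#' @export
hierarchicalCluster <- function(x,
                                distance = c("one_minus_pearson",
                                             "euclidean"),
                                linkage = c("average", "single",
                                            "complete")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  values <- if (is(x, "ExpressionMatrix")) exprValues(x) else as.matrix(x)
  if (nrow(values) < 2L) stop("need >= 2 features to cluster")
  d <- if (distance == "euclidean") {
    stats::dist(values)
  } else {
    sds <- apply(values, 1L, stats::sd)
    if (any(sds == 0))
      stop("constant feature(s): correlation distance undefined for ",
           paste(rownames(values)[sds == 0], collapse = ", "))
    stats::as.dist(1 - stats::cor(t(values)))
  }
  stats::hclust(d, method = linkage)
}

#' Export a dendrogram as Newick text
#'
#' @param h an `hclust` object from [hierarchicalCluster()].
#' @param path optional file to write to.
#' @return the Newick string, invisibly when `path` is given.
#' @export
dendrogramNewick <- function(h, path = NULL) {
  tree <- ape::as.phylo(h)
  txt <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
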