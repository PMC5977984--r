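#' Read a log2 expression matrix
#'
#' Supports a plain TSV dialect (header row of sample IDs, first column of
#' feature IDs) and the GEO series-matrix text dialect, in which only the
#' table block between the `!series_matrix_table_begin` /
#' `!series_matrix_table_end` sentinels is parsed and quoted identifiers are
#' unquoted.  Samples are never reordered relative to the input header, and
#' any non-numeric cell (including `NA`) is an error rather than a silent
#' drop.
#'
#' @param path input file.
#' @param dialect `"tsv"` or `"geo_series_matrix"`.
#' @param featureKind `"miRNA"` or `"mRNA"`.
#' @param annotation optional sample annotation data.frame (see
#'   [ExpressionMatrix()]).
#' @return an [ExpressionMatrix-class].
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path, dialect = c("tsv", "geo_series_matrix"),
                           featureKind = c("miRNA", "mRNA"),
                           annotation = NULL) {
  dialect <- match.arg(dialect)
  featureKind <- match.arg(featureKind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (dialect == "geo_series_matrix") {
    beg <- grep("^!series_matrix_table_begin", lines)
    end <- grep("^!series_matrix_table_end", lines)
    if (length(beg) != 1L || length(end) != 1L || end <= beg + 1L)
      stop("series-matrix sentinels not found or table empty")
    lines <- lines[(beg + 1L):(end - 1L)]
  }
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("empty expression table")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  widths <- lengths(cells)
  if (length(unique(widths)) != 1L)
    stop("ragged rows in expression table")
  unq <- function(x) gsub('^"|"$', "", x)
  header <- unq(cells[[1L]])
  sampleIds <- header[-1L]
  if (length(sampleIds) == 0L) stop("no sample columns")
  body <- cells[-1L]
  featureIds <- unq(vapply(body, `[`, "", 1L))
  if (anyDuplicated(featureIds))
    stop("duplicate feature ID(s): ",
         paste(unique(featureIds[duplicated(featureIds)]), collapse = ", "))
  vals <- vapply(body, function(r) {
    x <- suppressWarnings(as.numeric(r[-1L]))
    if (any(is.na(x)))
      stop("non-numeric cell in row '", unq(r[1L]), "'")
    x
  }, numeric(length(sampleIds)))
  values <- t(matrix(vals, nrow = length(sampleIds),
                     dimnames = list(sampleIds, featureIds)))
  ExpressionMatrix(values, featureKind, annotation)
}

#' Write an ExpressionMatrix as TSV
#'
#' Values are written at full double precision so that
#' `readExpression(writeExpression(x))` round-trips IDs exactly and values
#' within 1e-12.
#'
#' @param x an [ExpressionMatrix-class].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
writeExpression <- function(x, path) {
  v <- exprValues(x)
  header <- paste(c("feature_id", colnames(v)), collapse = "\t")
  rows <- vapply(seq_len(nrow(v)), function(i)
    paste(c(rownames(v)[i], formatC(v[i, ], format = "g", digits = 17)),
          collapse = "\t"), "")
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read / write sample annotations
#'
#' TSV with columns `sample_id`, `group` (`responder` / `non_responder`) and
#' optional covariate columns.
#'
#' @param path file path.
#' @param annotation data.frame to write.
#' @return `readSampleAnnotation` returns a data.frame.
#' @export
readSampleAnnotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% colnames(df)))
    stop("annotation needs 'sample_id' and 'group' columns")
  bad <- setdiff(unique(df$group), c("responder", "non_responder"))
  if (length(bad)) stop("unknown group label(s): ", paste(bad, collapse = ", "))
  df
}

#' @rdname readSampleAnnotation
#' @export
writeSampleAnnotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a miRNA target-prediction table
#'
#' TSV with columns `mirna_id` and `gene_id`.  Exact duplicate rows are
#' collapsed.  The `source` tag distinguishes the two prediction programs
#' whose outputs are later intersected.
#'
#' @param path file path.
#' @param source source tag, `"A"` or `"B"`.
#' @return data.frame with columns `mirna_id`, `gene_id`, `source`.
#' @export
readTargetPairs <- function(path, source = c("A", "B")) {
  source <- match.arg(source)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% colnames(df)))
    stop("target table needs 'mirna_id' and 'gene_id' columns")
  df <- unique(df[, c("mirna_id", "gene_id")])
  df$source <- source
  rownames(df) <- NULL
  df
}

#' @rdname readTargetPairs
#' @param pairs data.frame with `mirna_id`, `gene_id` columns.
#' @export
writeTargetPairs <- function(pairs, path) {
  utils::write.table(pairs[, c("mirna_id", "gene_id")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-gene interaction table
#'
#' TSV with columns `gene_a`, `gene_b`, `combined_score`.  Self-interactions
#' and negative scores are format errors.  Duplicate unordered pairs are
#' collapsed keeping the maximum combined score (the strongest evidence).
#'
#' @param path file path.
#' @return data.frame with columns `gene_a`, `gene_b`, `combined_score`,
#'   one row per unordered pair.
#' @export
readInteractions <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "combined_score")
  if (!all(need %in% colnames(df)))
    stop("interaction table needs columns ", paste(need, collapse = ", "))
  normalizeInteractions(df[, need])
}

#' @rdname readInteractions
#' @param interactions data.frame with the three interaction columns; the
#'   same dedup/validity rules are applied, so in-memory tables can be
#'   normalized without a file round trip.
#' @export
normalizeInteractions <- function(interactions) {
  df <- as.data.frame(interactions)
  if (!is.numeric(df$combined_score) || any(!is.finite(df$combined_score)))
    stop("combined_score must be finite numeric")
  if (any(df$combined_score < 0)) stop("negative combined_score")
  if (any(df$gene_a == df$gene_b)) stop("self-interaction row(s) present")
  a <- pmin(df$gene_a, df$gene_b)
  b <- pmax(df$gene_a, df$gene_b)
  key <- paste(a, b, sep = "\r")
  score <- tapply(df$combined_score, key, max)
  keys <- strsplit(names(score), "\r", fixed = TRUE)
  out <- data.frame(gene_a = vapply(keys, `[`, "", 1L),
                    gene_b = vapply(keys, `[`, "", 2L),
                    combined_score = as.numeric(score),
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene_a, out$gene_b), ]
  rownames(out) <- NULL
  out
}

#' @rdname readInteractions
#' @export
writeInteractions <- function(interactions, path) {
  utils::write.table(interactions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read a network
#'
#' GraphML (via igraph; node and edge attributes preserved at full double
#' precision) or SIF (one `a interacts b` line per edge).
#'
#' @param network an [igraph::igraph] object with at least one edge.
#' @param path output file.
#' @param format `"graphml"` or `"sif"`.
#' @return invisibly, `path`.
#' @export
writeNetwork <- function(network, path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (igraph::ecount(network) == 0L)
    stop("refusing to write an empty network")
  if (format == "graphml") {
    igraph::write_graph(network, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(network)
    writeLines(paste(el[, 1L], "interacts", el[, 2L]), path)
  }
  invisible(path)
}

#' @rdname writeNetwork
#' @export
readNetwork <- function(path, format = c("graphml", "sif")) {
  format <- match.arg(format)
  if (format == "graphml")
    return(igraph::read_graph(path, format = "graphml"))
  parts <- strsplit(readLines(path), " ", fixed = TRUE)
  el <- do.call(rbind, lapply(parts, function(p) p[c(1L, 3L)]))
  igraph::graph_from_edgelist(el, directed = FALSE)
}
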