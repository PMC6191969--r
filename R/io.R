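#' Read an edge-list CSV
#'
#' Parses a `from,to[,weight]` CSV (header required) into an edge table.
#' Vertex labels may be arbitrary strings or integers; they are mapped to
#' contiguous internal ids in order of first appearance (scanning each row
#' left to right), and the label dictionary is kept on the result, so
#' outputs can always be expressed in the original labels. A missing
#' weight column defaults every weight to 1.
#'
#' @param path CSV file path.
#' @return an edge table ([edgeTable()]) whose `labels` attribute is the
#'   index-to-label dictionary.
#' @export
readEdgeCsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE)
  if (nrow(raw) == 0L) stop("empty edge list: ", path)
  if (ncol(raw) < 2L) stop("edge CSV needs at least 2 columns: ", path)
  fromLab <- trimws(raw[[1L]])
  toLab <- trimws(raw[[2L]])
  bad <- which(fromLab == "" | toLab == "")
  if (length(bad))
    stop("malformed row at line ", bad[1L] + 1L, " of ", path)
  if (ncol(raw) >= 3L) {
    weight <- suppressWarnings(as.numeric(raw[[3L]]))
    bad <- which(is.na(weight))
    if (length(bad))
      stop("malformed weight at line ", bad[1L] + 1L, " of ", path)
  } else {
    weight <- rep(1, nrow(raw))
  }
  labels <- unique(as.vector(rbind(fromLab, toLab)))
  edgeTable(match(fromLab, labels), match(toLab, labels),
            weight = weight, nVertices = length(labels), labels = labels)
}

#' Write an edge table as CSV
#'
#' Emits a `from,to,weight` CSV using the table's vertex labels; the exact
#' inverse of [readEdgeCsv()] whenever every vertex occurs in some record
#' (isolated vertices have no row to live in).
#'
#' @param edges an edge table.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeEdgeCsv <- function(edges, path) {
  edges <- validateEdges(edges)
  labels <- attr(edges, "labels")
  out <- data.frame(
    from = labels[edges$from],
    to = labels[edges$to],
    weight = formatNum(edges$weight)
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## Locale-independent numeric formatting: up to 15 significant digits,
## no scientific notation surprises across re-runs.
formatNum <- function(x) {
  out <- formatC(x, digits = 15, format = "g", flag = "")
  out[is.infinite(x) & x > 0] <- "inf"
  out[is.infinite(x) & x < 0] <- "-inf"
  out[is.na(x)] <- ""
  trimws(out)
}

#' Write a labelled matrix as TSV
#'
#' One header line of column labels (prefixed by a corner field naming the
#' row dimension), then one line per row: row label followed by values.
#' Unreachable distances (`Inf`) serialize as `"inf"`; absent predecessors
#' (`NA`) serialize as empty fields. [readMatrixTsv()] is the exact
#' inverse.
#'
#' @param mat numeric or integer matrix.
#' @param path output file path.
#' @param rowLabels,colLabels labels; default to `dimnames(mat)`.
#' @param corner name of the row dimension (first header field).
#' @return `path`, invisibly.
#' @export
writeMatrixTsv <- function(mat, path, rowLabels = rownames(mat),
                           colLabels = colnames(mat), corner = "source") {
  if (is.null(rowLabels)) rowLabels <- as.character(seq_len(nrow(mat)))
  if (is.null(colLabels)) colLabels <- as.character(seq_len(ncol(mat)))
  stopifnot(length(rowLabels) == nrow(mat),
            length(colLabels) == ncol(mat))
  lines <- c(
    paste(c(corner, colLabels), collapse = "\t"),
    vapply(seq_len(nrow(mat)), function(i) {
      vals <- if (is.character(mat)) {
        x <- mat[i, ]
        x[is.na(x)] <- ""
        x
      } else formatNum(mat[i, ])
      paste(c(rowLabels[i], vals), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a matrix TSV written by [writeMatrixTsv()]
#'
#' @param path TSV file path.
#' @return a numeric matrix with row and column names; `"inf"` fields
#'   become `Inf`, empty fields become `NA`.
#' @export
readMatrixTsv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty matrix file: ", path)
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  body <- strsplit(lines[-1L], "\t", fixed = TRUE)
  vals <- lapply(body, function(f) {
    x <- f[-1L]
    out <- suppressWarnings(as.numeric(x))
    out[x == "inf"] <- Inf
    out[x == "-inf"] <- -Inf
    out
  })
  mat <- do.call(rbind, vals)
  if (is.null(mat)) mat <- matrix(numeric(0), 0L, length(header) - 1L)
  dimnames(mat) <- list(vapply(body, `[[`, character(1), 1L),
                        header[-1L])
  mat
}

#' Read an expression matrix TSV
#'
#' First column: gene label; remaining columns: one per sample, with a
#' header row of sample labels.
#'
#' @param path TSV file path.
#' @return a genes x samples numeric matrix with dimnames.
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character"))
  if (ncol(df) < 2L) stop("expression TSV needs gene + sample columns")
  mat <- vapply(df[-1L], as.numeric, numeric(nrow(df)))
  mat <- matrix(as.numeric(mat), nrow = nrow(df),
                dimnames = list(df[[1L]], names(df)[-1L]))
  mat
}

#' Write an expression matrix TSV (inverse of [readExpressionTsv()])
#'
#' @param expr genes x samples numeric matrix with dimnames.
#' @param path output file path.
#' @param geneColumn header for the gene-label column.
#' @return `path`, invisibly.
#' @export
writeExpressionTsv <- function(expr, path, geneColumn = "gene") {
  lines <- c(
    paste(c(geneColumn, colnames(expr)), collapse = "\t"),
    vapply(seq_len(nrow(expr)), function(i) {
      paste(c(rownames(expr)[i], formatNum(expr[i, ])), collapse = "\t")
    }, character(1))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Select traversal sources
#'
#' Three selection modes, mirroring how benchmark sources are usually
#' specified: an explicit list (labels or ids, passed through in order),
#' the first `k` vertices, or a random fraction of the vertex set sampled
#' without replacement under an explicit seed (e.g. `fraction = 0.2` for
#' 20% of vertices). Exactly one mode must be given.
#'
#' @param g a [CSRGraph-class]
#' @param sources explicit vertex ids (integer) or labels (character).
#' @param firstK integer: take vertices `1..firstK`.
#' @param fraction numeric in (0, 1]: sample `ceiling(fraction * |V|)`
#'   distinct vertices.
#' @param seed integer seed for `fraction` sampling.
#' @return integer vector of source vertex ids.
#' @export
selectSources <- function(g, sources = NULL, firstK = NULL,
                          fraction = NULL, seed = 1L) {
  stopifnot(is(g, "CSRGraph"))
  n <- numVertices(g)
  given <- !vapply(list(sources, firstK, fraction), is.null, logical(1))
  if (sum(given) != 1L)
    stop("give exactly one of 'sources', 'firstK', 'fraction'")
  if (!is.null(sources)) {
    if (is.character(sources)) {
      ids <- match(sources, vertexLabels(g))
      if (anyNA(ids)) stop("invalid vertex id: unknown source label(s)")
      return(ids)
    }
    ids <- as.integer(sources)
    if (anyNA(ids) || length(ids) && (min(ids) < 1L || max(ids) > n))
      stop("invalid vertex id in sources")
    return(ids)
  }
  if (!is.null(firstK)) {
    firstK <- as.integer(firstK)
    if (is.na(firstK) || firstK < 1L || firstK > n)
      stop("firstK must lie in 1..", n)
    return(seq_len(firstK))
  }
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  k <- as.integer(ceiling(fraction * n))
  withSeed(seed, sort.int(sample.int(n, k), method = "radix"))
}
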