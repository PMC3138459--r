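# Tab-separated file formats: expression matrices, MI matrices, edge
# lists, adjacency matrices and metric reports. All writers round-trip
# through their readers at double precision.

fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- "NA"
  gsub(" ", "", out)
}

#' Read a tab-separated expression matrix
#'
#' First column holds gene identifiers; remaining columns are numeric
#' measurements. A header row of experiment labels is auto-detected (the
#' file has one when the second cell of the first line does not parse as
#' a number). Blank cells and the token `NA` become missing values.
#' Ragged rows, duplicate gene ids and non-numeric cells raise a parse
#' error naming the offending line.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix with gene ids as row names (and experiment
#'   labels as column names when a header is present).
#' @export
read_expression_tsv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop_io(sprintf("%s: too few rows", path))
  cells <- strsplit(lines, "\t", fixed = TRUE)

  first <- cells[[1L]]
  has_header <- length(first) >= 2L &&
    is.na(suppressWarnings(as.numeric(first[2L]))) &&
    !(trimws(first[2L]) %in% c("", "NA"))
  col_labels <- NULL
  if (has_header) {
    col_labels <- first[-1L]
    cells <- cells[-1L]
    lines <- lines[-1L]
    line_off <- 1L
  } else line_off <- 0L
  if (length(cells) < 2L) stop_io(sprintf("%s: too few data rows", path))

  ncol_expect <- length(cells[[1L]])
  vals <- lapply(seq_along(cells), function(i) {
    row <- cells[[i]]
    if (length(row) != ncol_expect)
      stop_io(sprintf("%s: line %d has %d fields, expected %d",
                      path, i + line_off, length(row), ncol_expect))
    raw <- trimws(row[-1L])
    raw[raw == ""] <- "NA"
    v <- suppressWarnings(as.numeric(raw))
    bad <- is.na(v) & raw != "NA"
    if (any(bad))
      stop_io(sprintf("%s: line %d: non-numeric cell '%s'",
                      path, i + line_off, raw[which(bad)[1L]]))
    v
  })
  ids <- vapply(cells, `[[`, character(1L), 1L)
  if (anyDuplicated(ids))
    stop_io(sprintf("%s: duplicate gene identifier '%s'",
                    path, ids[duplicated(ids)][1L]))
  m <- do.call(rbind, vals)
  rownames(m) <- ids
  if (!is.null(col_labels)) colnames(m) <- col_labels
  as_expression_matrix(m)
}

#' Write an expression matrix as TSV
#' @param data Expression matrix (genes x measurements).
#' @param path Output path.
#' @param header Write a header row of experiment labels (default TRUE).
#' @export
write_expression_tsv <- function(data, path, header = TRUE) {
  data <- as_expression_matrix(data)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    labs <- colnames(data) %||% sprintf("E%d", seq_len(ncol(data)))
    writeLines(paste(c("gene", labs), collapse = "\t"), con)
  }
  for (i in seq_len(nrow(data)))
    writeLines(paste(c(rownames(data)[i], fmt_num(data[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' Write / read an MI matrix as TSV
#'
#' Square matrix with gene ids as both row and column labels, at full
#' double precision.
#'
#' @param mi Symmetric MI matrix with gene-id dimnames.
#' @param path File path.
#' @return `read_mi_tsv` returns the matrix.
#' @export
write_mi_tsv <- function(mi, path) {
  stopifnot(is.matrix(mi), !is.null(rownames(mi)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", rownames(mi)), collapse = "\t"), con)
  for (i in seq_len(nrow(mi)))
    writeLines(paste(c(rownames(mi)[i], fmt_num(mi[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_mi_tsv
#' @export
read_mi_tsv <- function(path) {
  m <- read_expression_tsv(path)
  colnames(m) <- rownames(m)
  m
}

#' Write / read a network edge list as TSV
#'
#' Three columns `gene_i`, `gene_j`, `mi`, with `gene_i < gene_j`
#' lexicographically; rows sorted by `gene_i`, `gene_j` and then
#' descending MI.
#'
#' @param net A [grn()].
#' @param path File path.
#' @param gene_ids For the reader: the full gene universe (edge files do
#'   not mention isolated genes). Defaults to the ids seen in the file.
#' @return `read_edge_list_tsv` returns a [grn()].
#' @export
write_edge_list_tsv <- function(net, path) {
  stopifnot(inherits(net, "grn"))
  e <- net$edges
  e <- e[order(e$from, e$to, -xtfrm(e$weight)), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("gene_i\tgene_j\tmi", con)
  if (nrow(e))
    writeLines(paste(e$from, e$to, fmt_num(e$weight), sep = "\t"), con)
  invisible(path)
}

#' @rdname write_edge_list_tsv
#' @export
read_edge_list_tsv <- function(path, gene_ids = NULL) {
  if (!file.exists(path)) stop_io(sprintf("file not found: %s", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && grepl("^gene_i\t", lines[1L])) lines <- lines[-1L]
  if (!length(lines)) {
    if (is.null(gene_ids)) stop_io("empty edge list and no gene_ids supplied")
    return(grn(gene_ids))
  }
  cells <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(cells)
  if (any(nfield < 2L))
    stop_io(sprintf("%s: line %d has fewer than 2 fields",
                    path, which(nfield < 2L)[1L]))
  from <- vapply(cells, `[[`, character(1L), 1L)
  to <- vapply(cells, `[[`, character(1L), 2L)
  w <- vapply(cells, function(r)
    if (length(r) >= 3L) suppressWarnings(as.numeric(r[3L])) else NA_real_,
    numeric(1L))
  ids <- gene_ids %||% sort(unique(c(from, to)))
  grn(ids, data.frame(from = from, to = to, weight = w,
                      stringsAsFactors = FALSE))
}

#' Write / read a 0/1 adjacency matrix as TSV
#'
#' Square matrix with gene-id headers; entry 1 marks an edge.
#'
#' @param net A [grn()].
#' @param path File path.
#' @return `read_adjacency_tsv` returns a [grn()] (weights are lost; an
#'   adjacency file stores presence only).
#' @export
write_adjacency_tsv <- function(net, path) {
  stopifnot(inherits(net, "grn"))
  ids <- net$gene_ids
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  if (nrow(net$edges)) {
    i <- match(net$edges$from, ids)
    j <- match(net$edges$to, ids)
    A[cbind(i, j)] <- 1L
    A[cbind(j, i)] <- 1L
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("gene", ids), collapse = "\t"), con)
  for (r in seq_along(ids))
    writeLines(paste(c(ids[r], A[r, ]), collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_adjacency_tsv
#' @export
read_adjacency_tsv <- function(path) {
  m <- read_expression_tsv(path)
  ids <- rownames(m)
  colnames(m) <- ids
  hit <- which(upper.tri(m) & m != 0, arr.ind = TRUE)
  grn(ids, data.frame(from = ids[hit[, 1L]], to = ids[hit[, 2L]],
                      weight = NA_real_, stringsAsFactors = FALSE))
}

#' Write a one-row metrics report as TSV
#'
#' Columns: method, time (seconds), specificity, sensitivity, precision,
#' TP, TN, FP, FN.
#'
#' @param method Method label.
#' @param counts A [confusion_counts()] object.
#' @param time Elapsed seconds (optional).
#' @param path File path.
#' @export
write_metrics_tsv <- function(method, counts, path, time = NA_real_) {
  m <- classification_metrics(counts)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("method\ttime\tspecificity\tsensitivity\tprecision\tTP\tTN\tFP\tFN", con)
  writeLines(paste(method, fmt_num(time), fmt_num(m[["specificity"]]),
                   fmt_num(m[["sensitivity"]]), fmt_num(m[["precision"]]),
                   counts$tp, counts$tn, counts$fp, counts$fn, sep = "\t"), con)
  invisible(path)
}
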