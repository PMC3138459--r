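# ARACNE-style network inference: permutation null, MI significance
# threshold, thresholded adjacency, data-processing-inequality pruning.

#' Construct a network object
#'
#' Undirected graph over gene identifiers with MI edge weights. Each
#' unordered pair is stored once, with the lexicographically smaller id
#' first; self-loops are disallowed.
#'
#' @param gene_ids Character vector of gene identifiers.
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `weight`; directed or duplicate pairs are collapsed.
#' @return An object of class `"grn"`.
#' @export
grn <- function(gene_ids, edges = NULL) {
  gene_ids <- as.character(gene_ids)
  if (anyDuplicated(gene_ids)) stop_config("gene_ids must be unique")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  } else {
    if (!all(c("from", "to") %in% names(edges)))
      stop_config("edges need `from` and `to` columns")
    from <- as.character(edges$from)
    to <- as.character(edges$to)
    if (!all(c(from, to) %in% gene_ids))
      stop_config("edge endpoints must be in gene_ids")
    if (any(from == to)) stop_config("self-loops are not allowed")
    w <- if ("weight" %in% names(edges)) as.numeric(edges$weight)
         else rep(NA_real_, length(from))
    a <- pmin(from, to)
    b <- pmax(from, to)
    key <- paste(a, b, sep = "\r")
    keep <- !duplicated(key)
    edges <- data.frame(from = a[keep], to = b[keep], weight = w[keep],
                        stringsAsFactors = FALSE)
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    rownames(edges) <- NULL
  }
  structure(list(gene_ids = gene_ids, edges = edges), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("Gene network: %d genes, %d undirected edges\n",
              length(x$gene_ids), nrow(x$edges)))
  invisible(x)
}

#' Number of edges in a network
#' @param net A [grn()] object.
#' @return Integer edge count.
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "grn"))
  nrow(net$edges)
}

#' Null distribution of MI under independence
#'
#' Builds the permutation null that backs the MI significance threshold:
#' each sample is the MI of a randomly chosen gene pair after permuting
#' the measurement order of one of the two genes, which destroys any
#' dependence while preserving both marginal distributions. Weighting
#' matrices are computed once and their rows permuted, since domain
#' normalization is order-invariant.
#'
#' @param data Expression matrix.
#' @param config A [spline_config()].
#' @param n_permutations Number of null samples `B` (at least 1000).
#' @param seed Integer seed; the same seed reproduces the sample vector.
#' @return An object of class `"null_mi"` (see [null_distribution()]).
#' @export
null_mi_distribution <- function(data, config = spline_config(),
                                 n_permutations = 10000L, seed = 1L) {
  data <- as_expression_matrix(data)
  n <- nrow(data)
  if (n < 2L) stop_config("need at least 2 genes for a permutation null")
  n_permutations <- as.integer(n_permutations)
  if (n_permutations < 1000L)
    stop_config("n_permutations must be at least 1000")
  m <- ncol(data)
  wms <- lapply(seq_len(n), function(i)
    weighting_matrix(data[i, ], config, gene_id = rownames(data)[i]))

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  samples <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    pair <- sample.int(n, 2L)
    perm <- sample.int(m)
    wy <- wms[[pair[2L]]]
    wy_perm <- structure(list(W = wy$W[perm, , drop = FALSE],
                              valid = wy$valid[perm],
                              gene_id = wy$gene_id),
                         class = "weighting_matrix")
    samples[b] <- mi_from_wms(wms[[pair[1L]]], wy_perm, config$log_base)
  }
  null_distribution(samples, seed)
}

#' Wrap MI null samples
#'
#' Container for a vector of null MI samples, as produced by
#' [null_mi_distribution()] or supplied directly (e.g. for calibration
#' tests of the tail extrapolation).
#'
#' @param samples Nonnegative numeric vector of at least 1000 null MI
#'   values.
#' @param seed The seed that generated them (bookkeeping only).
#' @return An object of class `"null_mi"`.
#' @export
null_distribution <- function(samples, seed = NA_integer_) {
  samples <- as.numeric(samples)
  if (length(samples) < 1000L)
    stop_config("a null distribution needs at least 1000 samples")
  if (any(samples < 0)) stop_config("null MI samples must be nonnegative")
  structure(list(samples = samples, generator_seed = seed,
                 n_permutations = length(samples)),
            class = "null_mi")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
}

#' MI threshold at a target P-value
#'
#' For `p_value >= 1/B` the threshold is the empirical `1 - p` quantile of
#' the null samples. Below the empirical resolution (the usual case: the
#' default P-value of 1e-5 with B = 10,000 samples) the upper tail is
#' extrapolated with a log-linear fit of the survival function,
#' `ln P(MI >= s) ~ a + b s`, on the top 5% of samples -- the classic
#' large-deviation tail form.
#'
#' @param null A `"null_mi"` object.
#' @param p_value Target P-value in (0, 1].
#' @return The MI threshold (a single number).
#' @export
mi_threshold <- function(null, p_value) {
  stopifnot(inherits(null, "null_mi"))
  if (!is.numeric(p_value) || length(p_value) != 1L ||
      p_value <= 0 || p_value > 1)
    stop_config("p_value must be in (0, 1]")
  s <- sort(null$samples, decreasing = TRUE)
  B <- length(s)
  if (p_value >= 1 / B)
    return(unname(stats::quantile(s, 1 - p_value, type = 7)))
  ntail <- max(ceiling(0.05 * B), 20L)
  top <- s[seq_len(ntail)]
  if (max(top) - min(top) < .Machine$double.eps)
    stop_config(paste("degenerate null tail: top samples are all equal;",
                      "increase n_permutations"))
  surv <- log(seq_len(ntail) / B)
  fit <- stats::lm.fit(cbind(1, top), surv)
  a <- fit$coefficients[1L]
  b <- fit$coefficients[2L]
  if (!is.finite(b) || b >= 0)
    stop_config("null tail is not decreasing; cannot extrapolate threshold")
  unname((log(p_value) - a) / b)
}

#' Threshold an MI matrix into a network
#'
#' Keeps every unordered gene pair whose MI is at least the threshold.
#'
#' @param mi Symmetric MI matrix with gene ids as dimnames (diagonal
#'   ignored).
#' @param threshold MI cutoff.
#' @return A [grn()] with MI edge weights.
#' @export
threshold_network <- function(mi, threshold) {
  stopifnot(is.matrix(mi), !is.null(rownames(mi)))
  ids <- rownames(mi)
  ut <- upper.tri(mi)
  hit <- which(ut & mi >= threshold, arr.ind = TRUE)
  edges <- data.frame(from = ids[hit[, 1L]], to = ids[hit[, 2L]],
                      weight = mi[hit], stringsAsFactors = FALSE)
  grn(ids, edges)
}

#' Data-processing-inequality pruning
#'
#' ARACNE's pruning rule: in every fully connected triangle, the edge
#' `(i, j)` is marked for removal when
#' `MI(i, j) < (1 - tolerance) * min(MI(i, k), MI(j, k))`, i.e. it is the
#' clearly weakest of the three and therefore presumed indirect. All marks
#' are computed against the original network and all marked edges are
#' removed simultaneously, so the result does not depend on edge order.
#' With `tolerance = 0` the rule removes the strictly weakest edge of
#' every triangle; a positive tolerance spares edges within a relative
#' margin of the minimum.
#'
#' @param net A [grn()] whose edge weights agree with `mi`.
#' @param mi The symmetric MI matrix the network was thresholded from.
#' @param tolerance Nonnegative relative tolerance (default 0.01).
#' @return The pruned [grn()].
#' @export
apply_dpi <- function(net, mi, tolerance = 0.01) {
  stopifnot(inherits(net, "grn"), is.matrix(mi))
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance < 0)
    stop_config("tolerance must be a nonnegative real")
  ne <- nrow(net$edges)
  if (ne == 0L) return(net)
  ids <- net$gene_ids
  if (!all(ids %in% rownames(mi)))
    stop_config("MI matrix does not cover the network's genes")
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  ei <- match(net$edges$from, ids)
  ej <- match(net$edges$to, ids)
  A[cbind(ei, ej)] <- TRUE
  A[cbind(ej, ei)] <- TRUE
  W <- mi[ids, ids]

  drop <- logical(ne)
  for (e in seq_len(ne)) {
    i <- ei[e]; j <- ej[e]
    common <- which(A[i, ] & A[j, ])
    if (!length(common)) next
    lim <- (1 - tolerance) * pmin(W[i, common], W[j, common])
    drop[e] <- any(W[i, j] < lim)
  }
  grn(ids, net$edges[!drop, , drop = FALSE])
}

#' Infer a gene regulatory network
#'
#' The full inference pipeline: pairwise B-spline MI, permutation-null
#' threshold at the target P-value, adjacency construction, and DPI
#' pruning, in that order. Defaults follow the standard settings for this
#' estimator: `R = 10` bins, spline order `k = 3`, P-value `1e-5` and DPI
#' tolerance `0.01`. Deterministic given `seed`.
#'
#' @param data Expression matrix (genes x measurements).
#' @param config A [spline_config()].
#' @param p_value Significance level for the MI threshold.
#' @param tolerance DPI tolerance.
#' @param n_permutations Null sample count `B`.
#' @param seed Integer seed for the permutation null.
#' @param plan A [partition_plan()] for the pairwise-MI stage.
#' @return A [grn()]; attributes `threshold` (the MI cutoff used) and
#'   `mi` (the full MI matrix) are attached for downstream inspection.
#' @export
infer_grn <- function(data, config = spline_config(), p_value = 1e-5,
                      tolerance = 0.01, n_permutations = 10000L, seed = 1L,
                      plan = partition_plan()) {
  data <- as_expression_matrix(data)
  mi <- pairwise_mi(data, config, plan)
  null <- null_mi_distribution(data, config, n_permutations, seed)
  thr <- mi_threshold(null, p_value)
  net <- threshold_network(mi, thr)
  net <- apply_dpi(net, mi, tolerance)
  attr(net, "threshold") <- thr
  attr(net, "mi") <- mi
  net
}
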