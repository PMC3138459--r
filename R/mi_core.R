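# Entropy and mutual-information estimation: single pairs, the full
# pairwise matrix with memory-bounded blocked execution, integrity scan.

#' Validate an expression matrix
#'
#' An expression matrix is a plain numeric matrix of N genes (rows) by M
#' measurements (columns) with unique gene identifiers as row names;
#' missing measurements are `NA`. This helper checks those invariants and
#' attaches default identifiers if none are present.
#'
#' @param data Numeric matrix, genes in rows.
#' @return The validated matrix (with row names guaranteed).
#' @export
as_expression_matrix <- function(data) {
  if (!is.matrix(data) || !is.numeric(data))
    stop_config("expression data must be a numeric matrix (genes x measurements)")
  if (nrow(data) < 2L || ncol(data) < 2L)
    stop_config("expression matrix needs at least 2 genes and 2 measurements")
  if (is.null(rownames(data)))
    rownames(data) <- sprintf("G%d", seq_len(nrow(data)))
  if (anyDuplicated(rownames(data)))
    stop_config("gene identifiers (row names) must be unique")
  data
}

#' Integrity scan of an expression matrix
#'
#' Reports, without modifying the data, every missing cell and every
#' degenerate gene (a gene whose observed values are all identical, for
#' which domain normalization is undefined).
#'
#' @param data Expression matrix (see [as_expression_matrix()]).
#' @return A list with `missing` (data frame of `gene`, `experiment`
#'   coordinates), `missing_per_gene` (named integer vector) and
#'   `degenerate` (character vector of degenerate gene ids).
#' @export
scan_integrity <- function(data) {
  data <- as_expression_matrix(data)
  idx <- which(is.na(data), arr.ind = TRUE)
  missing <- data.frame(
    gene = rownames(data)[idx[, 1L]],
    experiment = unname(idx[, 2L]),
    stringsAsFactors = FALSE)
  missing <- missing[order(match(missing$gene, rownames(data)),
                           missing$experiment), , drop = FALSE]
  rownames(missing) <- NULL
  per_gene <- rowSums(is.na(data))
  degen <- vapply(seq_len(nrow(data)), function(i) {
    v <- data[i, ]
    v <- v[is.finite(v)]
    length(v) < 2L || max(v) == min(v)
  }, logical(1L))
  list(missing = missing,
       missing_per_gene = per_gene,
       degenerate = rownames(data)[degen])
}

#' Marginal bin probabilities of a weighting matrix
#'
#' The probability of bin `j` is the mean of column `j` over the valid
#' rows: each measurement contributes its fractional bin memberships, so
#' the probabilities sum to exactly 1.
#'
#' @param wm A [weighting_matrix()].
#' @return Numeric vector of `R` probabilities.
#' @export
marginal_probabilities <- function(wm) {
  stopifnot(inherits(wm, "weighting_matrix"))
  if (!any(wm$valid)) stop_degenerate("weighting matrix has no valid rows")
  colMeans(wm$W[wm$valid, , drop = FALSE])
}

#' Shannon entropy of a discrete distribution
#'
#' `-sum(p * log(p))` with the `0 * log(0) = 0` convention; accepts a
#' marginal vector or a joint matrix.
#'
#' @param p Numeric vector or matrix of probabilities (sums to 1).
#' @param log_base Logarithm base; 2 gives bits.
#' @return Entropy (nonnegative real).
#' @examples
#' shannon_entropy(rep(0.1, 10))  # log2(10) bits
#' @export
shannon_entropy <- function(p, log_base = 2) {
  p <- as.numeric(p)
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(log_base)
}

#' Joint bin probabilities of two weighting matrices
#'
#' The joint probability of bins `(j, l)` is the average over jointly
#' valid measurements of the product of the two genes' bin weights --
#' the cross-product of the two weighting matrices divided by the number
#' of jointly observed measurements.
#'
#' @param wx,wy [weighting_matrix()] objects over the same experiment set.
#' @return An `R x R` matrix of probabilities summing to 1.
#' @export
joint_probabilities <- function(wx, wy) {
  stopifnot(inherits(wx, "weighting_matrix"), inherits(wy, "weighting_matrix"))
  if (nrow(wx$W) != nrow(wy$W))
    stop_config("weighting matrices cover different numbers of measurements")
  rows <- wx$valid & wy$valid
  m <- sum(rows)
  if (m == 0L)
    stop_degenerate("no jointly observed measurements for this gene pair")
  crossprod(wx$W[rows, , drop = FALSE], wy$W[rows, , drop = FALSE]) / m
}

# MI from two weighting matrices, pairwise complete-case: joint AND the
# marginals entering the entropies are computed on the intersection of
# valid measurements, so the marginals are exact marginals of the joint
# and the estimate is a true KL divergence (hence >= 0 up to roundoff).
mi_from_wms <- function(wx, wy, log_base = 2) {
  J <- joint_probabilities(wx, wy)
  px <- rowSums(J)
  py <- colSums(J)
  mi <- shannon_entropy(px, log_base) + shannon_entropy(py, log_base) -
    shannon_entropy(J, log_base)
  clamp_mi(mi)
}

clamp_mi <- function(mi) {
  if (mi < -1e-9)
    stop(errorCondition(
      sprintf("internal consistency failure: MI = %.3g is more negative than roundoff allows", mi),
      class = c("splineMI_internal_error", "error", "condition")))
  max(mi, 0)
}

#' Mutual information of one gene pair
#'
#' Estimates `MI(X, Y) = H(X) + H(Y) - H(X, Y)` with the B-spline binning
#' estimator. Weighting matrices are built per gene over that gene's own
#' observed values; the joint distribution and both marginals entering the
#' entropies are then computed over the measurements observed in *both*
#' genes (pairwise complete-case), which guarantees a nonnegative
#' estimate. Tiny negative values from floating-point cancellation are
#' clamped to 0.
#'
#' @param x,y Numeric measurement vectors of equal length (may contain
#'   `NA`).
#' @param config A [spline_config()].
#' @return The estimated mutual information (in `log_base` units).
#' @examples
#' p <- dependent_pair(1000, rho = 0.9, seed = 1)
#' mi_pair(p$x, p$y, spline_config())
#' @export
mi_pair <- function(x, y, config = spline_config()) {
  if (length(x) != length(y))
    stop_config("x and y must have the same number of measurements")
  wx <- weighting_matrix(x, config)
  wy <- weighting_matrix(y, config)
  mi_from_wms(wx, wy, config$log_base)
}

#' Per-gene self-entropies
#'
#' The entropy of each gene's own marginal bin distribution, computed
#' from its observed measurements. These populate the diagonal of the
#' pairwise MI matrix.
#'
#' @param data Expression matrix.
#' @param config A [spline_config()].
#' @return Named numeric vector of entropies.
#' @export
self_entropies <- function(data, config = spline_config()) {
  data <- as_expression_matrix(data)
  h <- vapply(seq_len(nrow(data)), function(i) {
    wm <- weighting_matrix(data[i, ], config, gene_id = rownames(data)[i])
    shannon_entropy(marginal_probabilities(wm), config$log_base)
  }, numeric(1L))
  names(h) <- rownames(data)
  h
}

#' Partition plan for blocked execution
#'
#' Describes how the pairwise-MI computation is split into groups so that
#' peak working memory stays bounded: genes are partitioned into `P`
#' groups for weighting-matrix construction and the weighting matrices
#' into `Q` groups for the pairwise stage. Alternatively a memory budget
#' in bytes can be given, from which group sizes are derived using the
#' `8 * n * M * R` bytes footprint of `n` double-precision weighting
#' matrices; the budget must accommodate at least two weighting matrices
#' (one pair) or the plan is infeasible.
#'
#' @param gene_groups Positive integer `P` (weighting-matrix stage).
#' @param wm_groups Positive integer `Q` (pairwise stage).
#' @param memory_budget Optional budget in bytes; when supplied it
#'   overrides `wm_groups` at [pairwise_mi()] time.
#' @return An object of class `"partition_plan"`.
#' @export
partition_plan <- function(gene_groups = 1L, wm_groups = 1L,
                           memory_budget = NULL) {
  gene_groups <- as.integer(gene_groups)
  wm_groups <- as.integer(wm_groups)
  if (is.na(gene_groups) || gene_groups < 1L || is.na(wm_groups) || wm_groups < 1L)
    stop_plan("group counts must be positive integers")
  if (!is.null(memory_budget) &&
      (!is.numeric(memory_budget) || memory_budget <= 0))
    stop_plan("memory_budget must be a positive number of bytes")
  structure(list(gene_group_count = gene_groups,
                 wm_group_count = wm_groups,
                 memory_budget = memory_budget),
            class = "partition_plan")
}

# resolve Q (number of WM groups) for N genes given a plan
resolve_wm_groups <- function(plan, n_genes, n_meas, bins) {
  if (!is.null(plan$memory_budget)) {
    per_wm <- 8 * n_meas * bins
    group_size <- floor(plan$memory_budget / per_wm / 2)  # two groups resident
    if (group_size < 1L)
      stop_plan(sprintf(
        "memory budget of %g bytes cannot hold one pair of weighting matrices (%g bytes)",
        plan$memory_budget, 2 * per_wm))
    max(1L, ceiling(n_genes / group_size))
  } else {
    min(plan$wm_group_count, n_genes)
  }
}

split_groups <- function(n, q) {
  q <- max(1L, min(q, n))
  size <- ceiling(n / q)
  unname(split(seq_len(n), rep(seq_len(q), each = size, length.out = n)))
}

#' Pairwise mutual-information matrix
#'
#' Computes MI for all `N(N-1)/2` unordered gene pairs. Weighting matrices
#' are built once per gene and reused; the pairwise stage proceeds block
#' by block over groups of weighting matrices so that peak working memory
#' is bounded by the partition plan, and the result is identical (to
#' floating-point roundoff) for every valid plan. For fully observed data
#' the joint distributions of a whole block of pairs are obtained with one
#' stacked cross-product (a dense matrix multiplication); with missing
#' data each pair falls back to its own jointly observed measurement set.
#'
#' The diagonal of the returned matrix holds each gene's self-entropy
#' `H(X_i)`, not `MI(X_i, X_i)`.
#'
#' @param data Expression matrix (genes x measurements, `NA` = missing).
#' @param config A [spline_config()].
#' @param plan A [partition_plan()]; the default computes in one block.
#' @param on_degenerate `"error"` (default) to fail on degenerate genes,
#'   `"drop"` to remove them with a warning.
#' @return Symmetric `N x N` matrix with gene ids as dimnames; diagonal =
#'   self-entropies.
#' @export
pairwise_mi <- function(data, config = spline_config(),
                        plan = partition_plan(),
                        on_degenerate = c("error", "drop")) {
  data <- as_expression_matrix(data)
  on_degenerate <- match.arg(on_degenerate)
  stopifnot(inherits(plan, "partition_plan"))

  rep_ <- scan_integrity(data)
  if (length(rep_$degenerate)) {
    if (on_degenerate == "error")
      stop_degenerate(sprintf("degenerate genes present: %s",
                              paste(rep_$degenerate, collapse = ", ")))
    warning(sprintf("dropping %d degenerate gene(s): %s",
                    length(rep_$degenerate),
                    paste(rep_$degenerate, collapse = ", ")))
    data <- data[!rownames(data) %in% rep_$degenerate, , drop = FALSE]
    if (nrow(data) < 2L)
      stop_degenerate("fewer than 2 genes remain after dropping degenerate genes")
  }

  n <- nrow(data)
  m <- ncol(data)
  R <- config$bins
  ids <- rownames(data)

  # stage 1: weighting matrices, gene group by gene group
  wms <- vector("list", n)
  for (grp in split_groups(n, min(plan$gene_group_count, n))) {
    for (i in grp)
      wms[[i]] <- weighting_matrix(data[i, ], config, gene_id = ids[i])
  }

  mi <- matrix(0, n, n, dimnames = list(ids, ids))
  diag(mi) <- vapply(wms, function(w)
    shannon_entropy(marginal_probabilities(w), config$log_base), numeric(1L))

  q <- resolve_wm_groups(plan, n, m, R)
  groups <- split_groups(n, q)
  complete <- !anyNA(data)

  for (a in seq_along(groups)) {
    for (b in a:length(groups)) {
      ga <- groups[[a]]
      gb <- groups[[b]]
      if (complete) {
        blk <- block_mi_complete(wms, ga, gb, diag(mi), config)
        mi[ga, gb] <- blk
        mi[gb, ga] <- t(blk)
      } else {
        for (i in ga) for (j in gb) {
          if (j <= i) next
          v <- mi_from_wms(wms[[i]], wms[[j]], config$log_base)
          mi[i, j] <- v
          mi[j, i] <- v
        }
      }
    }
  }
  if (complete) diag(mi) <- vapply(wms, function(w)
    shannon_entropy(marginal_probabilities(w), config$log_base), numeric(1L))
  # enforce exact symmetry: within-group blocks can differ from their
  # transpose by summation order at the last ulp
  mi[lower.tri(mi)] <- t(mi)[lower.tri(mi)]
  mi
}

# MI for all pairs between two gene groups at once (fully observed data).
# Stacks the groups' WMs into M x (g*R) matrices; one crossprod yields all
# joint count matrices, and the R x R block sums needed for the joint
# entropies are obtained with indicator-matrix products.
block_mi_complete <- function(wms, ga, gb, self_h, config) {
  R <- config$bins
  m <- nrow(wms[[ga[1L]]]$W)
  Ua <- do.call(cbind, lapply(wms[ga], `[[`, "W"))
  Ub <- if (identical(ga, gb)) Ua else do.call(cbind, lapply(wms[gb], `[[`, "W"))
  J <- crossprod(Ua, Ub) / m            # (|ga|R) x (|gb|R), joint probs per block
  P <- J
  nz <- P > 0
  P[nz] <- P[nz] * log(P[nz])
  P[!nz] <- 0
  Ka <- kronecker(diag(length(ga)), matrix(1, R, 1L))
  Kb <- if (identical(ga, gb)) Ka else kronecker(diag(length(gb)), matrix(1, R, 1L))
  Hxy <- -crossprod(Ka, P %*% Kb) / log(config$log_base)  # |ga| x |gb|
  blk <- outer(self_h[ga], self_h[gb], `+`) - Hxy
  # clamp roundoff negatives; diagonal blocks' i==j cells revert to self-entropy
  if (identical(ga, gb)) {
    off <- blk[row(blk) != col(blk)]
    if (any(off < -1e-9)) stop_internal_mi(min(off))
    blk[row(blk) != col(blk) & blk < 0] <- 0
    diag(blk) <- self_h[ga]
  } else {
    if (any(blk < -1e-9)) stop_internal_mi(min(blk))
    blk[blk < 0] <- 0
  }
  blk
}

stop_internal_mi <- function(v)
  stop(errorCondition(
    sprintf("internal consistency failure: MI = %.3g is more negative than roundoff allows", v),
    class = c("splineMI_internal_error", "error", "condition")))
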