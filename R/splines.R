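# B-spline basis machinery: knot vectors, domain normalization, basis
# evaluation and per-gene weighting matrices.

#' Spline estimator configuration
#'
#' Bundles the parameters of the B-spline binning estimator: the number of
#' bins `R`, the spline order `k` (polynomial degree `k - 1`) and the
#' logarithm base used for entropies. With `order = 1` the estimator
#' degenerates to plain histogram binning; larger orders spread each
#' measurement smoothly over up to `k` adjacent bins, which stabilises the
#' mutual-information estimate against bin-edge fluctuations.
#'
#' @param bins Number of bins `R` (integer, at least 2). Default 10.
#' @param order Spline order `k`, which must satisfy `1 <= k <= bins - 1`.
#'   Default 3.
#' @param log_base Base of the logarithm used for entropies; 2 (the
#'   default) reports entropies and mutual information in bits.
#' @return An object of class `"spline_config"`.
#' @examples
#' cfg <- spline_config(bins = 10, order = 3)
#' @export
spline_config <- function(bins = 10, order = 3, log_base = 2) {
  bins <- as.integer(bins)
  order <- as.integer(order)
  if (length(bins) != 1L || is.na(bins) || bins < 2L)
    stop_config("`bins` must be a single integer >= 2")
  if (length(order) != 1L || is.na(order) || order < 1L || order > bins - 1L)
    stop_config(sprintf(
      "`order` must satisfy 1 <= k <= bins - 1; got k = %d with R = %d",
      order, bins))
  if (!is.numeric(log_base) || length(log_base) != 1L || log_base <= 1)
    stop_config("`log_base` must be a single real > 1")
  structure(list(bins = bins, order = order, log_base = log_base),
            class = "spline_config")
}

#' @export
print.spline_config <- function(x, ...) {
  cat(sprintf("B-spline estimator config: R = %d bins, order k = %d, log base %g\n",
              x$bins, x$order, x$log_base))
  invisible(x)
}

#' Clamped uniform knot vector
#'
#' Builds the knot vector of the B-spline basis: `k` repeated zeros, the
#' interior integers `1, ..., R - k`, and `k` repeated copies of the domain
#' endpoint `R - k + 1`. The `R + k` knots induce exactly `R` basis
#' functions of order `k` on the interval `[0, R - k + 1]`, and the
#' endpoint repetition clamps the basis so that it sums to one over the
#' whole closed domain.
#'
#' @param config A [spline_config()].
#' @return Numeric vector of `R + k` nondecreasing knots.
#' @examples
#' knot_vector(spline_config(bins = 5, order = 1))  # 0 1 2 3 4 5
#' @export
knot_vector <- function(config) {
  stopifnot(inherits(config, "spline_config"))
  R <- config$bins
  k <- config$order
  dmax <- R - k + 1
  c(rep(0, k), seq_len(R - k), rep(dmax, k))
}

#' Normalize measurements onto the spline domain
#'
#' Affinely maps measurements onto the basis domain `[0, R - k + 1]`:
#' the minimum observed value maps to 0 and the maximum to `R - k + 1`.
#' Missing values (`NA`) propagate. Because the map is affine, any strictly
#' increasing affine transform of the input leaves the normalized values --
#' and hence every downstream entropy -- unchanged.
#'
#' @param values Numeric vector of measurements, possibly with `NA`.
#' @param config A [spline_config()].
#' @return Numeric vector of the same length, values in `[0, R - k + 1]`.
#' @examples
#' normalize_to_domain(c(1, 2, 3), spline_config(bins = 10, order = 3))
#' @export
normalize_to_domain <- function(values, config) {
  stopifnot(inherits(config, "spline_config"))
  ok <- is.finite(values)
  if (sum(ok) < 2L)
    stop_degenerate("need at least two finite values to normalize")
  xmin <- min(values[ok])
  xmax <- max(values[ok])
  if (xmax == xmin)
    stop_degenerate("degenerate gene: all observed values identical (x_max == x_min)")
  (values - xmin) / (xmax - xmin) * (config$bins - config$order + 1)
}

#' Evaluate all B-spline basis functions at once
#'
#' Vectorised Cox--de Boor recursion: returns the matrix of all `R` basis
#' values for each point of `z`. The order-1 base case is the indicator of
#' the half-open knot interval `[t_i, t_{i+1})`; the right endpoint of the
#' domain, which the half-open convention would leave uncovered, is
#' assigned to the last basis function so that the partition of unity holds
#' on the closed domain.
#'
#' @param z Numeric vector of points in `[0, R - k + 1]`.
#' @param config A [spline_config()].
#' @return A `length(z) x R` matrix; each row is nonnegative and sums to 1.
#' @export
bspline_basis <- function(z, config) {
  stopifnot(inherits(config, "spline_config"))
  R <- config$bins
  k <- config$order
  dmax <- R - k + 1
  if (anyNA(z) || any(z < -1e-9) || any(z > dmax + 1e-9))
    stop_domain(sprintf("z outside the spline domain [0, %d]", dmax))
  z <- pmin(pmax(z, 0), dmax)
  kn <- knot_vector(config)
  n <- length(z)

  # order-1: indicator of [t_i, t_{i+1}); R + k - 1 functions, the ones on
  # zero-length (repeated-knot) intervals are identically zero
  nb <- R + k - 1L
  B <- matrix(0, n, nb)
  for (i in seq_len(nb)) {
    if (kn[i] < kn[i + 1L])
      B[, i] <- as.numeric(z >= kn[i] & z < kn[i + 1L])
  }
  at_end <- z >= dmax
  if (any(at_end)) {
    last_pos <- max(which(diff(kn) > 0))
    B[at_end, ] <- 0
    B[at_end, last_pos] <- 1
  }

  if (k > 1L) {
    for (m in 2:k) {
      nbm <- R + k - m
      Bm <- matrix(0, n, nbm)
      for (i in seq_len(nbm)) {
        d1 <- kn[i + m - 1L] - kn[i]
        d2 <- kn[i + m] - kn[i + 1L]
        acc <- 0
        if (d1 > 0) acc <- (z - kn[i]) / d1 * B[, i]
        if (d2 > 0) acc <- acc + (kn[i + m] - z) / d2 * B[, i + 1L]
        Bm[, i] <- acc
      }
      B <- Bm
    }
  }
  B
}

#' Evaluate a single B-spline basis function
#'
#' Scalar interface to the Cox--de Boor recursion: the value of basis
#' function `bin_index` (order `k`) at point `z`.
#'
#' @param bin_index Integer in `1..R`.
#' @param z A single point in `[0, R - k + 1]`.
#' @param config A [spline_config()].
#' @return The basis value, a real in `[0, 1]`.
#' @export
eval_basis <- function(bin_index, z, config) {
  stopifnot(inherits(config, "spline_config"),
            length(bin_index) == 1L, length(z) == 1L)
  bin_index <- as.integer(bin_index)
  if (bin_index < 1L || bin_index > config$bins)
    stop_config(sprintf("bin_index must be in 1..%d", config$bins))
  bspline_basis(z, config)[1L, bin_index]
}

#' Weighting matrix of a gene
#'
#' The `M x R` matrix whose row `i` gives measurement `i`'s fractional
#' membership in each of the `R` bins: entry `(i, j)` is the order-`k`
#' B-spline basis function `j` evaluated at the domain-normalized value of
#' measurement `i`. Rows of missing measurements are zero and flagged
#' invalid; every valid row sums to 1.
#'
#' @param values Numeric vector of `M` measurements (may contain `NA`).
#' @param config A [spline_config()].
#' @param gene_id Optional identifier carried along with the matrix.
#' @return An object of class `"weighting_matrix"`: a list with `W`
#'   (`M x R` numeric matrix), `valid` (length-`M` logical) and `gene_id`.
#' @examples
#' wm <- weighting_matrix(rnorm(20), spline_config())
#' rowSums(wm$W[wm$valid, ])  # all 1
#' @export
weighting_matrix <- function(values, config, gene_id = NULL) {
  stopifnot(inherits(config, "spline_config"))
  valid <- is.finite(values)
  if (sum(valid) < 2L)
    stop_degenerate(sprintf("gene %s: fewer than two observed measurements",
                            gene_id %||% "<unnamed>"))
  z <- normalize_to_domain(values[valid], config)
  W <- matrix(0, length(values), config$bins)
  W[valid, ] <- bspline_basis(z, config)
  structure(list(W = W, valid = valid, gene_id = gene_id),
            class = "weighting_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# condition constructors: distinguishable error classes for callers
stop_config <- function(msg)
  stop(errorCondition(msg, class = c("splineMI_config_error", "error", "condition")))
stop_degenerate <- function(msg)
  stop(errorCondition(msg, class = c("splineMI_degenerate_gene", "error", "condition")))
stop_domain <- function(msg)
  stop(errorCondition(msg, class = c("splineMI_domain_error", "error", "condition")))
stop_plan <- function(msg)
  stop(errorCondition(msg, class = c("splineMI_plan_error", "error", "condition")))
stop_io <- function(msg)
  stop(errorCondition(msg, class = c("splineMI_io_error", "error", "condition")))
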