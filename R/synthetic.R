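# Synthetic data generators: random expression matrices for scalability
# checks, correlated Gaussian pairs for calibrating the MI estimator, and
# nonlinear regulatory networks with a known gold standard.

#' Random expression matrix
#'
#' Independent standard-normal values per cell, with gene identifiers.
#' Useful for scalability testing and for checking that the MI of
#' independent genes concentrates near zero.
#'
#' @param n_genes,n_experiments Matrix dimensions (each at least 2).
#' @param seed Integer seed; the same seed reproduces the matrix.
#' @return Numeric matrix with gene ids as row names.
#' @export
random_expression <- function(n_genes, n_experiments, seed = 1L) {
  if (n_genes < 2L || n_experiments < 2L)
    stop_config("need at least 2 genes and 2 experiments")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * n_experiments), n_genes, n_experiments)
  rownames(m) <- gene_labels(n_genes)
  m
}

gene_labels <- function(n) sprintf("G%0*d", nchar(as.character(n)), seq_len(n))

#' Correlated Gaussian pair with known mutual information
#'
#' Draws `n` samples of a bivariate normal with correlation `rho`, whose
#' exact mutual information is `-0.5 * log2(1 - rho^2)` bits -- the
#' closed-form benchmark used to calibrate the estimator.
#'
#' @param n Sample count (at least 10).
#' @param rho Correlation in (-1, 1).
#' @param seed Integer seed.
#' @return List with `x`, `y` (length-`n` vectors) and `analytic_mi`
#'   (bits).
#' @export
dependent_pair <- function(n, rho, seed = 1L) {
  if (n < 10L) stop_config("n must be at least 10")
  if (!is.numeric(rho) || abs(rho) >= 1)
    stop_config("rho must lie strictly inside (-1, 1)")
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  x <- stats::rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n)
  list(x = x, y = y, analytic_mi = -0.5 * log2(1 - rho^2))
}

#' Simulate expression from a known regulatory network
#'
#' Emulates the statistical shape of SynTReN-style benchmark data: a
#' directed acyclic regulatory topology over `n_genes` genes is sampled
#' (scale-free via preferential attachment, or uniformly random), each
#' regulator--target interaction is assigned a Hill-type activation or
#' repression response, and `n_experiments` independent steady-state
#' conditions are simulated by drawing root-gene inputs uniformly and
#' propagating them through the network in topological order with
#' additive Gaussian noise. The defaults -- 250 genes, 500 experiments and
#' 385 interactions -- mirror the scale at which MI-based inference is
#' commonly benchmarked on such data.
#'
#' @param n_genes Number of genes (default 250).
#' @param n_experiments Number of steady-state conditions (default 500).
#' @param n_edges Number of regulatory interactions in the gold network
#'   (default 385).
#' @param topology `"scale_free"` (preferential attachment, default) or
#'   `"random"`.
#' @param noise_sd Standard deviation of the additive Gaussian measurement
#'   noise on each regulated gene (default 0.1, on the unit scale of the
#'   Hill responses).
#' @param missing_rate Fraction of cells set missing (`NA`), default 0.
#' @param seed Integer seed; identical arguments and seed reproduce both
#'   outputs exactly.
#' @return List with `expression` (matrix, genes x experiments) and
#'   `network` (the gold-standard [grn()], directed edges collapsed to
#'   unordered pairs).
#' @export
simulate_network_expression <- function(n_genes = 250L, n_experiments = 500L,
                                        n_edges = 385L,
                                        topology = c("scale_free", "random"),
                                        noise_sd = 0.1, missing_rate = 0,
                                        seed = 1L) {
  topology <- match.arg(topology)
  n_genes <- as.integer(n_genes)
  n_experiments <- as.integer(n_experiments)
  n_edges <- as.integer(n_edges)
  if (n_genes < 3L || n_experiments < 2L)
    stop_config("need at least 3 genes and 2 experiments")
  if (n_edges < 1L || n_edges > n_genes * (n_genes - 1) / 2)
    stop_config("n_edges must be between 1 and choose(n_genes, 2)")
  if (!is.numeric(noise_sd) || noise_sd < 0)
    stop_config("noise_sd must be nonnegative")
  if (!is.numeric(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    stop_config("missing_rate must lie in [0, 1)")

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  ids <- gene_labels(n_genes)
  # sample a DAG on the gene order 1..N: each edge points from an earlier
  # gene (regulator) to a later one (target)
  src <- integer(n_edges)
  tgt <- integer(n_edges)
  outdeg <- rep(0L, n_genes)
  seen <- new.env(hash = TRUE)
  e <- 0L
  guard <- 0L
  while (e < n_edges) {
    guard <- guard + 1L
    if (guard > 50L * n_edges)
      stop_config("could not place the requested number of edges; topology infeasible")
    t <- sample(2:n_genes, 1L)
    cand <- seq_len(t - 1L)
    w <- if (topology == "scale_free") outdeg[cand] + 1 else rep(1, t - 1L)
    s <- if (t == 2L) 1L else sample(cand, 1L, prob = w)
    key <- paste0(s, ".", t)
    if (!is.null(seen[[key]])) next
    seen[[key]] <- TRUE
    e <- e + 1L
    src[e] <- s
    tgt[e] <- t
    outdeg[s] <- outdeg[s] + 1L
  }

  # Hill kinetics per edge: random sign, coefficient and half-saturation
  sign_act <- stats::runif(n_edges) < 0.7
  hill_n <- sample(c(1, 2, 4), n_edges, replace = TRUE)
  hill_k <- stats::runif(n_edges, 0.3, 0.7)

  regulators <- split(seq_len(n_edges), tgt)
  expr <- matrix(NA_real_, n_genes, n_experiments, dimnames = list(ids, NULL))
  for (g in seq_len(n_genes)) {
    regs <- regulators[[as.character(g)]]
    if (is.null(regs)) {
      expr[g, ] <- stats::runif(n_experiments)        # root gene input
    } else {
      resp <- matrix(0, length(regs), n_experiments)
      for (r in seq_along(regs)) {
        ed <- regs[r]
        x <- pmin(pmax(expr[src[ed], ], 0), 1)   # kinetics operate on [0, 1]
        h <- x^hill_n[ed] / (hill_k[ed]^hill_n[ed] + x^hill_n[ed])
        resp[r, ] <- if (sign_act[ed]) h else 1 - h
      }
      expr[g, ] <- colMeans(resp) +
        stats::rnorm(n_experiments, sd = noise_sd)
    }
  }

  if (missing_rate > 0) {
    holes <- which(stats::runif(length(expr)) < missing_rate)
    expr[holes] <- NA_real_
  }

  truth <- grn(ids, data.frame(from = ids[src], to = ids[tgt], weight = 1,
                               stringsAsFactors = FALSE))
  list(expression = expr, network = truth)
}
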