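cfg10 <- spline_config(10, 3)

test_that("integrity scan reports missing cells and degenerate genes", {
  d <- random_expression(5, 8, seed = 1)
  expect_equal(nrow(scan_integrity(d)$missing), 0L)
  expect_length(scan_integrity(d)$degenerate, 0L)

  d[3, 7] <- NA
  rep_ <- scan_integrity(d)
  expect_equal(rep_$missing,
               data.frame(gene = rownames(d)[3], experiment = 7L,
                          stringsAsFactors = FALSE))
  expect_equal(unname(rep_$missing_per_gene[3]), 1)

  d[2, ] <- 4.2
  expect_equal(scan_integrity(d)$degenerate, rownames(d)[2])
})

test_that("marginal probabilities are valid-row column means", {
  set.seed(2)
  # 10 values occupying 5 bins twice each under hard binning
  v <- c(0.05, 0.15, 0.25, 0.35, 0.45, 0.55, 0.65, 0.75, 0.85, 0.95) * 5
  p <- marginal_probabilities(weighting_matrix(v, spline_config(5, 1)))
  expect_equal(p, rep(0.2, 5))

  wm <- weighting_matrix(rnorm(30), cfg10)
  expect_equal(sum(marginal_probabilities(wm)), 1, tolerance = 1e-12)
})

test_that("Shannon entropy matches closed forms", {
  expect_equal(shannon_entropy(c(1, rep(0, 9))), 0)
  expect_equal(shannon_entropy(rep(0.1, 10)), log2(10))
  expect_equal(shannon_entropy(matrix(1 / 100, 10, 10)), 2 * log2(10))
  expect_equal(shannon_entropy(rep(0.1, 10), log_base = exp(1)), log(10))
})

test_that("joint probabilities sum to 1 with consistent margins", {
  set.seed(3)
  wx <- weighting_matrix(rnorm(40), cfg10)
  wy <- weighting_matrix(rnorm(40), cfg10)
  J <- joint_probabilities(wx, wy)
  expect_equal(dim(J), c(10L, 10L))
  expect_equal(sum(J), 1, tolerance = 1e-9)
  expect_equal(rowSums(J), unname(marginal_probabilities(wx)), tolerance = 1e-12)
  expect_equal(colSums(J), unname(marginal_probabilities(wy)), tolerance = 1e-12)
})

test_that("k = 1 joint of a gene with itself is diagonal", {
  set.seed(4)
  w <- weighting_matrix(rnorm(50), spline_config(10, 1))
  J <- joint_probabilities(w, w)
  expect_equal(diag(J), unname(marginal_probabilities(w)))
  expect_equal(sum(J) - sum(diag(J)), 0)
})

test_that("k = 1 uniform contingency gives the uniform joint", {
  R <- 4
  grid <- expand.grid(x = seq_len(R), y = seq_len(R))  # each combination once
  wx <- weighting_matrix(grid$x, spline_config(R, 1))
  wy <- weighting_matrix(grid$y, spline_config(R, 1))
  expect_equal(joint_probabilities(wx, wy),
               matrix(1 / R^2, R, R), tolerance = 1e-12)
})

test_that("MI is symmetric and self-MI at k = 1 equals the entropy", {
  set.seed(5)
  x <- rnorm(50)
  y <- rnorm(50)
  expect_identical(mi_pair(x, y, cfg10), mi_pair(y, x, cfg10))
  cfg1 <- spline_config(10, 1)
  h <- shannon_entropy(marginal_probabilities(weighting_matrix(x, cfg1)))
  expect_equal(mi_pair(x, x, cfg1), h, tolerance = 1e-12)
})

test_that("independent-pair MI shrinks as M grows (estimator bias)", {
  err <- vapply(c(200, 2000, 20000), function(m) {
    mean(vapply(1:10, function(s) {
      set.seed(s)
      mi_pair(rnorm(m), rnorm(m), cfg10)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(err) < 0))
  expect_gt(err[1], 0)     # finite-sample MI is positively biased
})

test_that("dependent-pair estimates settle toward a large-M value from above", {
  est <- vapply(c(500, 5000, 50000), function(m) {
    mean(vapply(1:5, function(s)
      with(dependent_pair(m, 0.6, seed = s), mi_pair(x, y, cfg10)),
      numeric(1)))
  }, numeric(1))
  expect_true(all(diff(est) < 0))          # positive bias shrinks with M
  expect_lt(diff(est)[2], diff(est)[1] / 2)  # and the decrements contract
})

test_that("self-entropies are affine-invariant and compose correctly", {
  set.seed(6)
  d <- random_expression(4, 30, seed = 6)
  h <- self_entropies(d, cfg10)
  expect_named(h, rownames(d))
  expect_equal(unname(h[2]),
               shannon_entropy(marginal_probabilities(
                 weighting_matrix(d[2, ], cfg10))))
  d2 <- d * 10 - 3
  expect_equal(self_entropies(d2, cfg10), h, tolerance = 1e-12)
  # uniform bin occupancy at k = 1 attains log2(R)
  v <- (seq_len(10) - 0.5)  # one value per bin
  hu <- shannon_entropy(marginal_probabilities(
    weighting_matrix(v, spline_config(10, 1))))
  expect_equal(hu, log2(10))
})

test_that("pairwise_mi equals a brute-force loop and honours plans", {
  d <- random_expression(20, 50, seed = 7)
  mi <- pairwise_mi(d, cfg10)
  expect_identical(mi, t(mi))
  expect_true(all(mi[upper.tri(mi)] >= 0))
  expect_lt(max(abs(mi - naive_pairwise(d, cfg10))), 1e-12)
  for (pl in list(c(2, 2), c(3, 5), c(20, 20)))
    expect_lt(max(abs(mi - pairwise_mi(d, cfg10, partition_plan(pl[1], pl[2])))),
              1e-12)
})

test_that("pairwise_mi populates exactly the off-diagonal pairs", {
  d <- random_expression(4, 25, seed = 8)
  mi <- pairwise_mi(d, cfg10)
  expect_equal(dim(mi), c(4L, 4L))
  expect_equal(diag(mi), self_entropies(d, cfg10))
  expect_equal(sum(upper.tri(mi)), 6L)   # N(N-1)/2 values computed
})

test_that("missing data uses pairwise complete-case and stays nonnegative", {
  d <- random_expression(8, 40, seed = 9)
  d[2, c(3, 8)] <- NA
  d[5, 40] <- NA
  mi <- pairwise_mi(d, cfg10)
  expect_identical(mi, t(mi))
  expect_true(all(mi[upper.tri(mi)] >= 0))
  # pair (2, 5): only jointly observed measurements enter
  keep <- !is.na(d[2, ]) & !is.na(d[5, ])
  wx <- weighting_matrix(d[2, ], cfg10)
  wy <- weighting_matrix(d[5, ], cfg10)
  J <- joint_probabilities(wx, wy)
  expect_equal(sum(J), 1, tolerance = 1e-12)
  manual <- shannon_entropy(rowSums(J)) + shannon_entropy(colSums(J)) -
    shannon_entropy(J)
  expect_equal(mi[2, 5], max(manual, 0), tolerance = 1e-12)
  expect_equal(sum(keep), 37L)
})

test_that("degenerate genes error by default and can be dropped", {
  d <- random_expression(5, 20, seed = 10)
  d[3, ] <- 1
  expect_error(pairwise_mi(d, cfg10), class = "splineMI_degenerate_gene")
  expect_warning(mi <- pairwise_mi(d, cfg10, on_degenerate = "drop"),
                 "degenerate")
  expect_equal(nrow(mi), 4L)
  expect_false(rownames(d)[3] %in% rownames(mi))
})

test_that("partition plans validate and derive group counts from a budget", {
  expect_error(partition_plan(0, 1), class = "splineMI_plan_error")
  expect_error(partition_plan(memory_budget = -5), class = "splineMI_plan_error")
  d <- random_expression(10, 30, seed = 11)
  expect_error(
    pairwise_mi(d, cfg10, partition_plan(memory_budget = 100)),
    class = "splineMI_plan_error")  # cannot hold one WM pair
  mi_budget <- pairwise_mi(d, cfg10,
                           partition_plan(memory_budget = 8 * 30 * 10 * 6))
  expect_lt(max(abs(mi_budget - pairwise_mi(d, cfg10))), 1e-12)
})
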