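test_that("PCA handles rank-1 data and satisfies its invariants", {
  set.seed(20)
  t <- rnorm(12)
  res <- pca(cbind(a = 3 * t, b = -2 * t))
  expect_equal(res$variance_fraction[1], 1, tolerance = 1e-12)
  expect_equal(num_pcs_for(0.99, res), 1L)

  x <- matrix(rnorm(80), 16, 5)
  for (std in c(FALSE, TRUE)) {
    res <- pca(x, standardize = std)
    expect_equal(sum(res$variance_fraction), 1, tolerance = 1e-9)
    expect_equal_tol(colSums(res$contributions), rep(100, 5), 1e-6)
    # sign convention: largest-|loading| entry positive
    for (k in 1:5) {
      l <- res$loadings[, k]
      expect_gt(l[which.max(abs(l))], 0)
    }
    # reconstruction of the centered (scaled) data
    target <- scale(x, center = TRUE, scale = if (std) res$scale else FALSE)
    expect_equal_tol(res$scores %*% t(res$loadings), unclass(target), 1e-8)
  }
  expect_error(pca(cbind(rep(1, 5), rnorm(5)), standardize = TRUE), "constant")
})

test_that("PCA matches a covariance-eigendecomposition oracle", {
  set.seed(21)
  x <- matrix(rnorm(24), 6, 4)
  res <- pca(x)
  eg <- eigen(stats::cov(x), symmetric = TRUE)
  vec <- eg$vectors
  for (k in 1:4) vec[, k] <- vec[, k] * sign(vec[which.max(abs(vec[, k])), k])
  expect_equal_tol(res$loadings, vec, 1e-8)
  expect_equal_tol(res$variance_fraction, eg$values / sum(eg$values), 1e-8)
  expect_equal_tol(res$scores, scale(x, scale = FALSE) %*% vec, 1e-8)
})

test_that("PCA reconstruction holds on larger random tables", {
  set.seed(22)
  for (dims in list(c(20, 6), c(50, 10))) {
    x <- matrix(rnorm(prod(dims)), dims[1], dims[2])
    res <- pca(x)
    expect_equal_tol(res$scores %*% t(res$loadings),
                     scale(x, scale = FALSE), 1e-8)
  }
})

test_that("num_pcs_for counts cumulative variance correctly", {
  # four exactly equal-variance uncorrelated variables: 3 PCs reach 75%
  x <- rbind(diag(4), -diag(4))
  res <- pca(x)
  expect_equal_tol(res$variance_fraction, rep(0.25, 4), 1e-12)
  expect_equal(num_pcs_for(0.75, res), 3L)
  expect_equal(num_pcs_for(0.76, res), 4L)
  expect_error(num_pcs_for(0, res), "fraction")
})

test_that("correlation report reproduces exact identities", {
  set.seed(23)
  v <- rnorm(20)
  rep_ <- correlation_report(cbind(a = v, b = v, c = -v, d = rnorm(20)))
  expect_equal(rep_$r["a", "b"], 1, tolerance = 1e-12)
  expect_lt(rep_$p["a", "b"], 1e-12)
  expect_equal(rep_$r["a", "c"], -1, tolerance = 1e-12)
  expect_true(all(diag(rep_$r) == 1))
  expect_equal(rep_$r, t(rep_$r))
  expect_true(all(rep_$p >= 0 & rep_$p <= 1))
  expect_true(all(rep_$ci_low <= rep_$r + 1e-12 & rep_$r <= rep_$ci_high + 1e-12))
})

test_that("correlation r matches a naive two-pass covariance oracle", {
  set.seed(24)
  x <- matrix(rnorm(36), 12, 3)
  rep_ <- correlation_report(x)
  for (i in 1:2) for (j in (i + 1):3) {
    a <- x[, i] - mean(x[, i]); b <- x[, j] - mean(x[, j])
    expect_equal(rep_$r[i, j], sum(a * b) / sqrt(sum(a^2) * sum(b^2)),
                 tolerance = 1e-12)
  }
})

test_that("correlation p-values agree with a permutation oracle near r = 0", {
  # two orthogonal-by-construction vectors, n = 12
  a <- rep(c(1, -1), 6)
  set.seed(25)
  b <- rnorm(12); b <- b - mean(b)
  b <- b - a * sum(a * b) / sum(a^2)  # exactly uncorrelated with a
  noise <- rnorm(12, sd = 0.3)
  x <- cbind(p = a + noise, q = b)
  rep_ <- correlation_report(x)
  robs <- abs(stats::cor(x[, 1], x[, 2]))
  perm <- mean(replicate(10000, abs(stats::cor(x[, 1], sample(x[, 2]))) >= robs))
  expect_lt(abs(rep_$p["p", "q"] - perm), 0.02)
})

test_that("zero-variance columns are flagged pairwise, not fatally", {
  x <- cbind(a = rnorm(10), b = rep(2, 10), c = rnorm(10))
  rep_ <- correlation_report(x)
  expect_true(is.na(rep_$r["a", "b"]))
  expect_false(is.na(rep_$r["a", "c"]))
  long <- correlation_long(rep_)
  expect_equal(nrow(long), 3)
})

test_that("equal-width binning follows the heatmap rule", {
  expect_identical(bin_scores(0:9, 10), 1:10)
  expect_identical(bin_scores(rep(3.5, 7), 10), rep(1L, 7))
  expect_identical(bin_scores(c(0, 0.15, 0.95), 10), c(1L, 2L, 10L))
  expect_error(bin_scores(numeric(0), 10), "empty")
  # order preservation on random data
  set.seed(26)
  v <- rnorm(100)
  lab <- bin_scores(v, 10)
  expect_true(all(tapply(v, lab, min)[-1] >=
                  head(tapply(v, lab, max), -1) - 1e-12))
})

test_that("metric-shape alignment correlates metrics with retained PCs", {
  set.seed(27)
  flat <- matrix(rnorm(30 * 8), 30, 8)
  rownames(flat) <- sprintf("s%02d", 1:30)
  sp <- pca(flat)
  keep <- which(sp$variance_fraction > 0.05)
  scores <- data.frame(specimen_id = rownames(flat),
                       si = sp$scores[, keep[1]],     # metric equal to a PC
                       psd = rnorm(30))
  al <- metric_shape_alignment(scores, sp, top_fraction = 0.05)
  expect_equal(nrow(al), 2 * length(keep))
  r_match <- al$r[al$metric == "si" & al$pc == paste0("PC", keep[1])]
  expect_equal(r_match, 1, tolerance = 1e-9)
  shuffled <- scores[c(2:30, 1), ]
  expect_error(metric_shape_alignment(shuffled, sp), "mismatch")
})
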