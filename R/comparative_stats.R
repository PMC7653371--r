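# Comparison machinery: PCA of shapes or of complexity scores, Pearson
# correlation reports with significance and confidence intervals, equal-width
# binning for heatmaps, and metric-vs-shape-PC alignment.

#' Principal component analysis with loadings and contributions
#'
#' Wraps an eigen-decomposition of the covariance (or, with
#' `standardize = TRUE`, the correlation) matrix. PCs are ordered by
#' decreasing variance, and each loading vector is flipped so its
#' largest-magnitude entry is positive — eigenvector signs are arbitrary and
#' this fixes a reproducible convention. Variable contributions are the
#' squared-loading shares of each component, in percent.
#'
#' Shape data (flattened superimposed coordinates) should be analysed
#' unstandardized since all coordinates share units; complexity scores live
#' on incommensurable scales and are usually standardized.
#'
#' @param data Numeric matrix or data frame, specimens in rows.
#' @param standardize Analyse the correlation rather than covariance matrix.
#' @return Object of class `pca_result`: `scores`, `loadings`,
#'   `variance_fraction`, `contributions` (variables x PCs, percent),
#'   `center`, `scale`, `sdev`.
#' @export
pca <- function(data, standardize = FALSE) {
  x <- as.matrix(data)
  if (!is.numeric(x)) stop("pca needs a numeric table")
  if (nrow(x) < 2 || ncol(x) < 2) stop("pca needs >= 2 rows and >= 2 columns")
  if (anyNA(x)) stop("pca input contains missing values")
  if (standardize && any(apply(x, 2, stats::sd) == 0))
    stop("constant column cannot be standardized")
  fit <- stats::prcomp(x, center = TRUE, scale. = standardize)
  # sign convention: largest-|loading| entry of each PC positive
  flip <- apply(fit$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  scores <- sweep(fit$x, 2, flip, `*`)
  varfrac <- fit$sdev^2 / sum(fit$sdev^2)
  contrib <- sweep(loadings^2, 2, colSums(loadings^2), `/`) * 100
  structure(
    list(scores = scores, loadings = loadings,
         variance_fraction = varfrac, contributions = contrib,
         center = fit$center,
         scale = if (standardize) fit$scale else rep(1, ncol(x)),
         sdev = fit$sdev),
    class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  k <- min(5, length(x$variance_fraction))
  cat("<pca_result> ", nrow(x$scores), " specimens x ", nrow(x$loadings),
      " variables\n  variance fractions: ",
      paste(sprintf("PC%d %.1f%%", 1:k, 100 * x$variance_fraction[1:k]),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Number of PCs needed to reach a cumulative variance fraction
#'
#' @param fraction Target cumulative fraction in (0, 1].
#' @param result A [pca()] result.
#' @return Smallest k with cumulative variance fraction >= `fraction`.
#' @export
num_pcs_for <- function(fraction, result) {
  if (!(fraction > 0 && fraction <= 1)) stop("fraction must be in (0, 1]")
  which(cumsum(result$variance_fraction) >= fraction - 1e-12)[1]
}

#' Pairwise Pearson correlation report
#'
#' Pearson r for every pair of columns, with two-sided p-values from the
#' t-test on n - 2 degrees of freedom and 95% confidence intervals from the
#' Fisher z-transform (both as computed by [stats::cor.test()]). No
#' multiple-testing correction is applied. Zero-variance columns yield `NA`
#' entries for their pairs rather than a global failure.
#'
#' @param table Numeric matrix or data frame with >= 3 rows.
#' @return Object of class `correlation_report`: square matrices `r`, `p`,
#'   `ci_low`, `ci_high` and the sample size `n`.
#' @export
correlation_report <- function(table) {
  x <- as.matrix(table)
  if (nrow(x) < 3) stop("correlation report needs >= 3 rows")
  k <- ncol(x)
  nm <- colnames(x)
  r <- p <- lo <- hi <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  diag(r) <- 1; diag(p) <- 0; diag(lo) <- 1; diag(hi) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    if (stats::sd(x[, i]) == 0 || stats::sd(x[, j]) == 0) next
    ct <- stats::cor.test(x[, i], x[, j], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
    lo[i, j] <- lo[j, i] <- ct$conf.int[1]
    hi[i, j] <- hi[j, i] <- ct$conf.int[2]
  }
  structure(list(r = r, p = p, ci_low = lo, ci_high = hi, n = nrow(x)),
            class = "correlation_report")
}

#' @export
print.correlation_report <- function(x, ...) {
  cat("<correlation_report> ", nrow(x$r), " variables, n = ", x$n, "\n", sep = "")
  print(round(x$r, 3))
  invisible(x)
}

#' Long-format view of a correlation report
#' @param report A [correlation_report()].
#' @return Data frame with one row per unordered variable pair.
#' @export
correlation_long <- function(report) {
  nm <- colnames(report$r)
  k <- length(nm)
  pairs <- which(upper.tri(report$r), arr.ind = TRUE)
  data.frame(
    var1 = nm[pairs[, 1]], var2 = nm[pairs[, 2]],
    r = report$r[pairs], p = report$p[pairs],
    ci_low = report$ci_low[pairs], ci_high = report$ci_high[pairs],
    n = report$n, row.names = NULL)
}

#' Assign values to equal-width bins
#'
#' Subdivides the observed range `[min, max]` into `k` equal-width bins for
#' heatmap colour associations. The maximum value falls in bin `k`; a
#' constant vector falls entirely in bin 1.
#'
#' @param values Numeric vector.
#' @param k Number of bins (>= 1).
#' @return Integer vector of bin labels in `1..k`.
#' @export
bin_scores <- function(values, k = 10) {
  if (!length(values)) stop("empty vector cannot be binned")
  if (k < 1) stop("k must be >= 1")
  rng <- range(values)
  if (rng[1] == rng[2]) return(rep(1L, length(values)))
  edges <- seq(rng[1], rng[2], length.out = k + 1)
  findInterval(values, edges, all.inside = TRUE)
}

#' Correlate complexity metrics with retained shape PCs
#'
#' Extracts the PC scores whose axes each explain more than `top_fraction`
#' of the overall shape variation, and correlates every metric column against
#' every retained PC score with the same machinery as
#' [correlation_report()]. Specimens must be in the same order in both
#' inputs.
#'
#' @param scores Data frame of complexity scores with a `specimen_id` column.
#' @param shape_pca A [pca()] result on the shape data, with specimen ids as
#'   score rownames.
#' @param top_fraction Retention threshold on the per-PC variance fraction.
#' @return Data frame with one row per metric x retained-PC pair: `metric`,
#'   `pc`, `r`, `p`, `ci_low`, `ci_high`.
#' @export
metric_shape_alignment <- function(scores, shape_pca, top_fraction = 0.05) {
  ids <- rownames(shape_pca$scores)
  if (!is.null(ids) && !identical(as.character(scores$specimen_id), ids))
    stop("specimen mismatch between score table and shape PCA")
  keep <- which(shape_pca$variance_fraction > top_fraction)
  if (!length(keep)) stop("no PC exceeds the retention threshold")
  metric_cols <- names(scores)[vapply(scores, is.numeric, logical(1))]
  metric_cols <- setdiff(metric_cols, c("major_lobes", "minor_lobes", "hurst"))
  out <- do.call(rbind, lapply(metric_cols, function(mcol) {
    do.call(rbind, lapply(keep, function(pc) {
      ct <- stats::cor.test(scores[[mcol]], shape_pca$scores[, pc])
      data.frame(metric = mcol, pc = paste0("PC", pc),
                 r = unname(ct$estimate), p = ct$p.value,
                 ci_low = ct$conf.int[1], ci_high = ct$conf.int[2],
                 row.names = NULL)
    }))
  }))
  out
}
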