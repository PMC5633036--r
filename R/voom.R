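LOG2_1E6 <- log2(1e6)

#' log2 counts-per-million
#'
#' `z_gi = log2((x_gi + 0.5) / (X_.i + 1) * 1e6)`. The 0.5 and 1 offsets keep
#' the ratio strictly inside (0, 1) before the million scaling, so the result
#' is always finite, including for zero counts.
#'
#' @param counts gene x sample matrix (or per-gene vector for one sample) of
#'   non-negative values; may be normalized and fractional
#' @param lib_sizes per-sample library sizes (column sums of the matrix being
#'   transformed, or normalized effective sizes)
#' @return matrix (or vector) of log2 cpm values, same shape as `counts`
#' @export
log_cpm <- function(counts, lib_sizes) {
  vec <- is.null(dim(counts))
  if (vec) counts <- matrix(counts, ncol = 1, dimnames = list(names(counts), NULL))
  stopifnot(length(lib_sizes) == ncol(counts), all(lib_sizes >= 0))
  z <- log2(sweep(counts + 0.5, 2, lib_sizes + 1, "/") * 1e6)
  if (vec) z[, 1] else z
}

#' Per-gene linear models on the class design
#'
#' Fits, gene by gene, the ordinary-least-squares model `E(z_g) = D beta_g`
#' with D the class-indicator design matrix; the fitted values are the class
#' means of the log-cpm values and the residual standard deviation is
#' `s_g = sqrt(RSS_g / (n - K))`. With no labels (or one class) the model
#' reduces to the intercept: fitted values are the overall mean and `s_g` is
#' the ordinary standard deviation with divisor n - 1.
#'
#' @param z p x n log-cpm matrix
#' @param labels factor of classes (or `NULL` for intercept-only)
#' @return list with `beta` (p x K matrix of class means), `fitted` (p x n),
#'   `resid_sd` (length p) and `df_residual`
#' @export
fit_gene_models <- function(z, labels = NULL) {
  n <- ncol(z)
  if (is.null(labels)) labels <- factor(rep("all", n))
  labels <- droplevels(as_class_factor(labels))
  K <- nlevels(labels)
  if (n <= K) stop("zero residual degrees of freedom: need n > K")
  beta <- vapply(levels(labels), function(k) {
    rowMeans(z[, labels == k, drop = FALSE])
  }, numeric(nrow(z)))
  beta <- matrix(beta, nrow = nrow(z),
                 dimnames = list(rownames(z), levels(labels)))
  fitted <- beta[, as.integer(labels), drop = FALSE]
  dimnames(fitted) <- dimnames(z)
  resid_sd <- sqrt(rowSums((z - fitted)^2) / (n - K))
  list(beta = beta, fitted = fitted, resid_sd = resid_sd, df_residual = n - K)
}

#' Mean log-counts from mean fitted log-cpm
#'
#' Delta-rule conversion of per-gene mean fitted log-cpm back to the
#' log-count scale: `x~_g = zbar_g + log2(geomean(X_.i + 1)) - log2(1e6)`.
#'
#' @param z_bar per-gene mean of the fitted log-cpm values
#' @param lib_sizes per-sample library sizes
#' @return per-gene mean log2 counts
#' @export
mean_log_counts <- function(z_bar, lib_sizes) {
  stopifnot(all(lib_sizes > 0))
  z_bar + mean(log2(lib_sizes + 1)) - LOG2_1E6
}

#' Fit the lowess mean-variance trend
#'
#' Smooths the square root of the per-gene residual standard deviations
#' (i.e. variance to the 1/4 power) against the mean log-counts with
#' [stats::lowess()], and stores the result as a piecewise-linear function:
#' sorted unique knots with their smoothed values.
#'
#' @param x_tilde per-gene mean log-counts
#' @param resid_sd per-gene residual standard deviations
#' @param span lowess span (default 0.5)
#' @return object of class `voom_trend`: list with knot abscissae `x` and
#'   values `y`
#' @export
fit_trend <- function(x_tilde, resid_sd, span = 0.5) {
  ok <- is.finite(x_tilde) & is.finite(resid_sd)
  if (sum(ok) < 10) stop("need at least 10 genes with finite statistics to fit the trend")
  if (all(resid_sd[ok] == 0)) stop("all residual standard deviations are zero; degenerate variance structure")
  l <- stats::lowess(x_tilde[ok], sqrt(resid_sd[ok]), f = span)
  keep <- !duplicated(l$x)
  structure(list(x = l$x[keep], y = l$y[keep], span = span), class = "voom_trend")
}

#' Evaluate a fitted mean-variance trend
#'
#' Linear interpolation between knots; constant (nearest-knot) extension
#' outside the knot range. Values are floored at 1e-6 so the fourth-power
#' reciprocal weights stay finite.
#'
#' @param trend a `voom_trend`
#' @param x abscissae (mean log-counts) at which to evaluate
#' @return trend values, same shape as `x`
#' @export
trend_eval <- function(trend, x) {
  y <- if (length(trend$x) == 1) {
    rep(trend$y, length(x))
  } else {
    stats::approx(trend$x, trend$y, xout = as.vector(x), rule = 2)$y
  }
  y <- pmax(y, 1e-6)
  if (!is.null(dim(x))) dim(y) <- dim(x)
  y
}

#' Precision weights from fitted log-counts
#'
#' `w_gi = lo(mu^_gi)^(-4)`: the predicted standard deviation from the trend
#' (on the quarter-root-variance scale) raised to the minus fourth power,
#' i.e. the inverse predicted variance of the log-cpm observation.
#'
#' @param mu_hat matrix of fitted log2 counts
#' @param trend a `voom_trend`
#' @return matrix of strictly positive weights, same shape as `mu_hat`
#' @export
precision_weights <- function(mu_hat, trend) {
  w <- trend_eval(trend, mu_hat)^(-4)
  dimnames(w) <- dimnames(mu_hat)
  w
}

#' Voom transformation: log-cpm values and precision weights
#'
#' Composition of [log_cpm()], [fit_gene_models()], [mean_log_counts()],
#' [fit_trend()] and [precision_weights()]: transforms a (optionally
#' normalized) count matrix into log-cpm values `z` with per-observation
#' precision weights `w`, and freezes the mean-variance trend and library
#' statistics needed to transform unseen test observations with the same
#' parameters.
#'
#' @param m a `count_matrix` (filtered; normalized if desired)
#' @param labels class labels; defaults to `m$labels`
#' @param lib_sizes effective library sizes; defaults to column sums
#' @param span lowess span for the trend
#' @return object of class `voom_fit` with elements `z`, `w` (p x n), `beta`,
#'   `resid_sd`, `mean_log_count`, `trend`, `lib_sizes`, `geo_mean_lib`,
#'   `labels`, `genes`
#' @export
voom_transform <- function(m, labels = NULL, lib_sizes = NULL, span = 0.5) {
  counts <- m$counts
  if (is.null(labels)) labels <- m$labels
  if (is.null(labels)) stop("class labels are required")
  labels <- as_class_factor(labels)
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  z <- log_cpm(counts, lib_sizes)
  fg <- fit_gene_models(z, labels)
  z_bar <- rowMeans(fg$fitted)
  x_tilde <- mean_log_counts(z_bar, lib_sizes)
  trend <- fit_trend(x_tilde, fg$resid_sd, span = span)
  mu_hat <- sweep(fg$fitted, 2, log2(lib_sizes + 1) - LOG2_1E6, "+")
  w <- precision_weights(mu_hat, trend)
  structure(list(z = z, w = w, beta = fg$beta, resid_sd = fg$resid_sd,
                 mean_log_count = x_tilde, trend = trend,
                 lib_sizes = lib_sizes,
                 geo_mean_lib = exp(mean(log(lib_sizes + 1))),
                 labels = labels, genes = rownames(counts)),
            class = "voom_fit")
}

#' @export
print.voom_fit <- function(x, ...) {
  cat(sprintf("voom_fit: %d genes x %d samples, %d classes, %d trend knots\n",
              nrow(x$z), ncol(x$z), nlevels(x$labels), length(x$trend$x)))
  invisible(x)
}

#' Transform a test observation with frozen training parameters
#'
#' Normalizes one test count vector with the frozen training
#' `norm_model` (test size factor for DESeq, effective library size for
#' TMM), computes its log-cpm values, and evaluates precision weights from
#' the FROZEN training trend at the test observation's fitted log-counts.
#' The mean-variance relationship is never re-estimated.
#'
#' @param x_star named per-gene test counts covering both the normalization
#'   gene universe and the classifier genes
#' @param norm the training `norm_model`
#' @param fit the training `voom_fit`
#' @return list with `z` (per-gene log-cpm), `w` (per-gene weights),
#'   `lib_size` (effective library size) and `size_factor`
#' @export
transform_test <- function(x_star, norm, fit) {
  xs <- match_genes(x_star, fit$genes)
  sf <- 1
  if (norm$method == "deseq") {
    sf <- deseq_test_size_factor(x_star, norm)
    xs <- xs / sf
    lib <- sum(xs)
  } else if (norm$method == "tmm") {
    f <- tmm_test_factor(x_star, norm)
    sf <- 2^f
    lib <- sum(xs) * sf
  } else {
    lib <- sum(xs)
  }
  z_star <- log_cpm(xs, lib)
  mu_star <- z_star + log2(lib + 1) - LOG2_1E6
  w_star <- trend_eval(fit$trend, mu_star)^(-4)
  list(z = z_star, w = w_star, lib_size = lib, size_factor = sf)
}
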