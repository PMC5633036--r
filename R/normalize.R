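#' Normalization factor models
#'
#' A `norm_model` freezes everything needed to place an unseen test
#' observation on the training scale without revisiting the training counts:
#' per-sample size factors (DESeq median-ratio), log2 TMM factors against a
#' stored reference sample, per-gene geometric means, and library sizes.
#'
#' @param m a `count_matrix` of training counts
#' @param method one of `"deseq"`, `"tmm"`, `"none"`
#' @param ... passed on to the method-specific estimator
#' @return an object of class `norm_model`
#' @seealso [deseq_size_factors()], [tmm_factors()], [apply_normalization()]
#' @export
norm_factors <- function(m, method = c("deseq", "tmm", "none"), ...) {
  method <- match.arg(method)
  switch(method,
    deseq = deseq_size_factors(m, ...),
    tmm = tmm_factors(m, ...),
    none = {
      counts <- m$counts
      structure(list(method = "none",
                     size_factors = stats::setNames(rep(1, ncol(counts)), colnames(counts)),
                     lib_sizes = colSums(counts),
                     genes = rownames(counts)),
                class = "norm_model")
    })
}

#' @export
print.norm_model <- function(x, ...) {
  cat(sprintf("norm_model: method=%s, %d training samples, %d genes\n",
              x$method, length(x$size_factors), length(x$genes)))
  if (x$method == "tmm") cat("reference sample:", x$reference, "\n")
  invisible(x)
}

#' DESeq median-ratio size factors
#'
#' The size factor of sample i is the median over genes of
#' `x_gi / geomean_g`, where `geomean_g` is the geometric mean of gene g
#' across training samples and the median runs over genes with strictly
#' positive counts in every sample. The per-gene geometric means are stored
#' so that a test observation can be normalized against the frozen training
#' reference ([deseq_test_size_factor()]).
#'
#' @param m a `count_matrix`
#' @return a `norm_model` with `method = "deseq"`
#' @export
deseq_size_factors <- function(m) {
  counts <- m$counts
  log_geo <- rowMeans(log(counts))      # -Inf for genes with any zero
  pos <- is.finite(log_geo)
  if (!any(pos)) {
    stop("no gene has positive counts in every sample; filter low-count genes first")
  }
  geo <- ifelse(pos, exp(log_geo), NA_real_)
  sf <- apply(counts[pos, , drop = FALSE], 2, function(x) {
    stats::median(x / geo[pos])
  })
  structure(list(method = "deseq",
                 size_factors = sf,
                 gene_geo_means = stats::setNames(geo, rownames(counts)),
                 lib_sizes = colSums(counts),
                 genes = rownames(counts)),
            class = "norm_model")
}

#' Size factor of a single test observation (median-ratio transfer)
#'
#' Computes `m_* = median_g { x_g* / geomean_g }` against the per-gene
#' geometric means stored in the training model, so the test sample lands on
#' the training scale. When a training sample is passed back in, its
#' training factor is recovered exactly.
#'
#' @param x_star named per-gene counts of one test observation, covering the
#'   training gene universe
#' @param model a `norm_model` with `method = "deseq"`
#' @param rescale if `TRUE`, additionally renormalizes the n+1 factors
#'   (training factors plus `m_*`) to geometric mean one and returns the
#'   rescaled test factor. Default `FALSE`: `m_*` itself already places the
#'   observation on the training scale.
#' @return positive scalar size factor
#' @export
deseq_test_size_factor <- function(x_star, model, rescale = FALSE) {
  if (model$method != "deseq") stop("model is not a DESeq median-ratio model")
  x_star <- match_genes(x_star, model$genes)
  geo <- model$gene_geo_means
  use <- !is.na(geo)
  if (!any(use)) stop("no usable genes: all stored geometric means are zero")
  m_star <- stats::median(x_star[use] / geo[use])
  if (!is.finite(m_star) || m_star <= 0) {
    stop("test size factor is not positive; too many zero counts in the test sample")
  }
  if (rescale) {
    all_f <- c(model$size_factors, m_star)
    m_star <- m_star / exp(mean(log(all_f)))
  }
  m_star
}

#' Trimmed mean of M-values (TMM) factors against a training reference
#'
#' Selects as reference the training sample whose upper-quartile/library-size
#' ratio is closest to the mean of those ratios, then computes each sample's
#' log2 scaling factor against the reference as a weighted mean of per-gene
#' log count-per-million ratios (M values), after trimming the most extreme
#' `trim_m` fraction of M values and `trim_a` fraction of average-intensity
#' (A) values. Genes with a zero count in either sample are excluded. The
#' weight of gene g is `(X_.i - x_gi)/(X_.i x_gi) + (X_.r - x_gr)/(X_.r x_gr)`.
#' The reference's own factor is exactly 0.
#'
#' @param m a `count_matrix` with at least two samples
#' @param trim_m two-sided trim fraction on M values (default 0.30); set both
#'   trims to 0 for the untrimmed weighted mean
#' @param trim_a two-sided trim fraction on A values (default 0.05)
#' @return a `norm_model` with `method = "tmm"`, holding per-sample
#'   `log2_tmm` factors and the reference sample's counts
#' @export
tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05) {
  counts <- m$counts
  if (ncol(counts) < 2) stop("TMM needs at least two samples")
  lib <- colSums(counts)
  f75 <- vapply(seq_len(ncol(counts)), function(i) {
    stats::quantile(counts[, i], probs = 0.75, names = FALSE) / lib[i]
  }, numeric(1))
  ref <- which.min(abs(f75 - mean(f75)))
  log2_tmm <- vapply(seq_len(ncol(counts)), function(i) {
    tmm_pair(counts[, i], counts[, ref], lib[i], lib[ref], trim_m, trim_a)
  }, numeric(1))
  names(log2_tmm) <- colnames(counts)
  structure(list(method = "tmm",
                 size_factors = 2^log2_tmm,
                 log2_tmm = log2_tmm,
                 reference = colnames(counts)[ref],
                 ref_counts = counts[, ref],
                 ref_lib_size = lib[ref],
                 lib_sizes = lib,
                 trim_m = trim_m, trim_a = trim_a,
                 genes = rownames(counts)),
            class = "norm_model")
}

# Weighted trimmed mean of M values for one sample against the reference.
# M is the log2 ratio of count proportions; weights are the delta-method
# binomial variance expression evaluated at both samples.
tmm_pair <- function(x, xr, lib_x, lib_r, trim_m, trim_a) {
  ok <- x > 0 & xr > 0
  if (sum(ok) < 2) stop("fewer than 2 genes with positive counts in both sample and reference")
  px <- x[ok] / lib_x
  pr <- xr[ok] / lib_r
  M <- log2(px / pr)
  A <- 0.5 * log2(px * pr)
  w <- (lib_x - x[ok]) / (lib_x * x[ok]) + (lib_r - xr[ok]) / (lib_r * xr[ok])
  if (max(abs(M)) < 1e-6) return(0)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rM <- rank(M)
  rA <- rank(A)
  keep <- rM >= lo_m & rM <= hi_m & rA >= lo_a & rA <= hi_a
  if (!any(keep)) stop("trimming removed all genes; lower the trim fractions")
  sum(w[keep] * M[keep]) / sum(w[keep])
}

#' log2 TMM factor of a single test observation
#'
#' Applies the same weighted trimmed mean of M values as [tmm_factors()],
#' against the frozen training reference sample, over genes with positive
#' counts in both the test observation and the reference.
#'
#' @param x_star named per-gene counts of one test observation
#' @param model a `norm_model` with `method = "tmm"`
#' @return scalar log2 TMM factor
#' @export
tmm_test_factor <- function(x_star, model) {
  if (model$method != "tmm") stop("model is not a TMM model")
  x_star <- match_genes(x_star, model$genes)
  tmm_pair(x_star, model$ref_counts, sum(x_star), model$ref_lib_size,
           model$trim_m, model$trim_a)
}

#' Apply a frozen normalization model to a count matrix
#'
#' DESeq: each sample's counts are divided by its size factor. TMM: counts
#' are returned unchanged (the factor scales the effective library size used
#' downstream, see [effective_lib_sizes()]). `none`: identity.
#'
#' @param m a `count_matrix` whose samples all appear in the model
#' @param model a `norm_model`
#' @return a `count_matrix`
#' @export
apply_normalization <- function(m, model) {
  if (model$method %in% c("none", "tmm")) return(m)
  sf <- model$size_factors
  missing <- setdiff(colnames(m$counts), names(sf))
  if (length(missing)) {
    stop(sprintf("no size factor for sample(s): %s", paste(missing, collapse = ", ")))
  }
  out <- m
  out$counts <- sweep(m$counts, 2, sf[colnames(m$counts)], "/")
  out
}

#' Effective library sizes under a normalization model
#'
#' For DESeq (after [apply_normalization()]) and `none` these are the column
#' sums of `m`; for TMM the raw column sums scaled by `2^log2_tmm`.
#'
#' @param m a `count_matrix` (normalized for DESeq)
#' @param model a `norm_model`
#' @return named per-sample library sizes
#' @export
effective_lib_sizes <- function(m, model) {
  lib <- colSums(m$counts)
  if (model$method == "tmm") {
    f <- model$log2_tmm[colnames(m$counts)]
    if (anyNA(f)) stop("no TMM factor for some samples")
    lib <- lib * 2^f
  }
  lib
}

# Align a named test vector with a gene universe; unnamed vectors must
# already be in universe order.
match_genes <- function(x, genes) {
  if (is.null(names(x))) {
    if (length(x) != length(genes)) {
      stop(sprintf("test observation has %d genes; expected %d", length(x), length(genes)))
    }
    return(x)
  }
  missing <- setdiff(genes, names(x))
  if (length(missing)) {
    stop(sprintf("test observation lacks gene(s): %s",
                 paste(utils::head(missing, 5), collapse = ", ")))
  }
  x[genes]
}
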