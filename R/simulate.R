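#' Define a negative binomial simulation scenario
#'
#' Collects the parameters of the count generator: counts are drawn as
#' `x_gi | y_i = k ~ NB(mu_gi e_gk, phi_g)` with mean `mu_gi e_gk` and
#' variance `mu_gi e_gk + (mu_gi e_gk)^2 phi`, where `mu_gi = g_g s_i`,
#' the per-sample size factors are `s_i ~ Unif(0.2, 2.2)`, the per-gene
#' abundances are `g_g ~ Exp(mean 25)`, and for differentially expressed
#' genes (a `de_prob` Bernoulli draw per gene) the per-class fold change is
#' `e_gk = exp(z_gk)` with `z_gk ~ N(0, sigma^2)` drawn independently for
#' every class. A constant `epsilon` is added to every count so downstream
#' logarithms never see a zero.
#'
#' @param p total number of genes simulated
#' @param n number of samples
#' @param K number of classes (samples are assigned in balanced blocks,
#'   shuffled by the seed)
#' @param de_prob probability that a gene is differentially expressed
#' @param sigma standard deviation of the per-class log fold changes
#' @param phi negative binomial dispersion (0.01 very slight, 0.1
#'   substantial, 1 very high overdispersion)
#' @param epsilon constant added to every count (default 1)
#' @param p_keep number of top-variance genes retained by the evaluation
#'   protocol ([run_scenario()])
#' @param train_frac fraction of samples assigned to the training split
#' @param seed integer seed
#' @return object of class `sim_scenario`
#' @export
sim_scenario <- function(p = 2000, n = 100, K = 2, de_prob = 0.10,
                         sigma = 0.2, phi = 0.01, epsilon = 1,
                         p_keep = min(500, p), train_frac = 0.70, seed = 1) {
  stopifnot(p >= 2, n >= 2 * K, K >= 2,
            de_prob > 0 || de_prob == 0, de_prob < 1,
            sigma > 0, phi > 0, epsilon >= 0,
            p_keep <= p, train_frac > 0, train_frac < 1)
  structure(list(p = p, n = n, K = K, de_prob = de_prob, sigma = sigma,
                 phi = phi, epsilon = epsilon, p_keep = p_keep,
                 train_frac = train_frac, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Negative binomial draws parameterized by mean and dispersion
#'
#' Thin wrapper over [stats::rnbinom()] with `size = 1/phi`, so draws have
#' mean `mu` and variance `mu + mu^2 phi`.
#'
#' @param n number of draws
#' @param mu mean (scalar or vector)
#' @param phi dispersion, `phi > 0`
#' @return integer-valued numeric vector
#' @export
rnb_mean_disp <- function(n, mu, phi) {
  stopifnot(phi > 0)
  stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a labelled RNA-seq count dataset
#'
#' Draws a `count_matrix` with class labels under a [sim_scenario()], plus a
#' truth table flagging the differentially expressed genes and their
#' per-class fold changes.
#'
#' @param sc a `sim_scenario` (or parameters passed to [sim_scenario()])
#' @param ... used to build a scenario when `sc` is not one already
#' @return list with `data` (a `count_matrix` with labels) and `truth`
#'   (data frame: `gene`, `is_de`, `e_1..e_K`)
#' @export
simulate_counts <- function(sc = sim_scenario(), ...) {
  if (!inherits(sc, "sim_scenario")) sc <- sim_scenario(sc, ...)
  set.seed(sc$seed)
  p <- sc$p; n <- sc$n; K <- sc$K
  s_i <- stats::runif(n, 0.2, 2.2)
  g_g <- stats::rexp(p, rate = 1 / 25)
  de <- stats::runif(p) < sc$de_prob
  e <- matrix(1, p, K)
  if (any(de)) {
    e[de, ] <- exp(matrix(stats::rnorm(sum(de) * K, 0, sc$sigma), ncol = K))
  }
  sizes <- rep(n %/% K, K)
  if (n %% K) sizes[seq_len(n %% K)] <- sizes[seq_len(n %% K)] + 1
  cls <- sample(rep(seq_len(K), sizes))
  mu <- outer(g_g, s_i) * e[, cls, drop = FALSE]
  x <- matrix(rnb_mean_disp(p * n, as.vector(mu), sc$phi), p, n)
  counts <- x + sc$epsilon
  genes <- sprintf("g%0*d", nchar(p), seq_len(p))
  samples <- sprintf("s%0*d", nchar(n), seq_len(n))
  dimnames(counts) <- list(genes, samples)
  labels <- paste0("class", cls)
  truth <- data.frame(gene = genes, is_de = de,
                      stats::setNames(as.data.frame(e), paste0("e_", seq_len(K))),
                      stringsAsFactors = FALSE)
  list(data = count_matrix(counts, labels), truth = truth, scenario = sc)
}

# Stratified train/test split indices; round(train_frac * n_k) per class.
split_train_test <- function(labels, train_frac, seed) {
  labels <- as_class_factor(labels)
  set.seed(seed)
  train <- logical(length(labels))
  for (k in levels(labels)) {
    idx <- which(labels == k)
    n_tr <- max(2, round(train_frac * length(idx)))
    train[sample(idx, n_tr)] <- TRUE
  }
  train
}

#' Run the full evaluation protocol on a simulated scenario
#'
#' Per repetition: simulate counts, split 70/30 (stratified), remove
#' near-zero-variance genes on the training set, keep the `p_keep` genes
#' with the largest variance of the stabilized training counts, estimate
#' normalization factors from the unfiltered raw training set, fit the
#' classifier (with cross-validated threshold for voomNSC), predict the
#' held-out test samples, and record misclassification error, balanced
#' error and (for voomNSC) sparsity. Repetition r uses seed `sc$seed + r - 1`.
#'
#' @param sc a [sim_scenario()]
#' @param method `"voomNSC"`, `"voomDLDA"` or `"voomDQDA"`
#' @param reps number of repetitions
#' @param normalization `"deseq"`, `"tmm"` or `"none"`
#' @param cv_folds,n_lambda voomNSC cross-validation settings
#' @return list with `per_rep` (data frame of per-repetition results) and
#'   `summary` (means with 95 percent confidence intervals)
#' @export
run_scenario <- function(sc, method = c("voomNSC", "voomDLDA", "voomDQDA"),
                         reps = 1, normalization = c("deseq", "tmm", "none"),
                         cv_folds = 5, n_lambda = 30) {
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    sc_r <- sc
    sc_r$seed <- sc$seed + r - 1L
    sim <- simulate_counts(sc_r)
    train <- split_train_test(sim$data$labels, sc$train_frac, sc_r$seed)
    m_tr <- sim$data[, train]
    m_ts <- sim$data[, !train]

    nz <- near_zero_filter(m_tr)
    keep_genes <- rownames(nz$kept$counts)

    rank_sf <- if (normalization == "deseq") {
      deseq_size_factors(nz$kept)$size_factors
    }
    m_tr_f <- variance_filter(nz$kept, min(sc$p_keep, length(keep_genes)), rank_sf)

    norm_model <- norm_factors(m_tr, normalization)

    if (method == "voomNSC") {
      fit <- fit_nsc(m_tr_f, m_tr$labels, normalization = normalization,
                     cv_folds = cv_folds, n_lambda = n_lambda,
                     seed = sc_r$seed, norm_model = norm_model)
      n_feat <- length(fit$survivors)
    } else {
      fit <- fit_dda(m_tr_f, m_tr$labels,
                     flavor = if (method == "voomDLDA") "voomDLDA" else "voomDQDA",
                     normalization = normalization, norm_model = norm_model)
      n_feat <- length(fit$genes)
    }
    pred <- stats::predict(fit, m_ts)
    ev <- evaluate_predictions(m_ts$labels, pred, n_feat, nrow(m_tr_f$counts))
    truth_f <- sim$truth[match(rownames(m_tr_f$counts), sim$truth$gene), ]
    enr_p <- if (method == "voomNSC" && n_feat > 0) {
      enrichment_test(fit$survivors, truth_f$gene[truth_f$is_de], truth_f$gene)
    } else NA_real_
    rows[[r]] <- data.frame(rep = r, seed = sc_r$seed, error = ev$error,
                            balanced_error = ev$balanced_error,
                            sparsity = n_feat,
                            relative_sparsity = n_feat / nrow(m_tr_f$counts),
                            enrichment_p = enr_p)
  }
  per_rep <- do.call(rbind, rows)
  ci <- function(x) {
    x <- x[is.finite(x)]
    m <- mean(x)
    half <- if (length(x) > 1) stats::qt(0.975, length(x) - 1) * stats::sd(x) / sqrt(length(x)) else 0
    c(mean = m, lo = m - half, hi = m + half)
  }
  list(per_rep = per_rep,
       summary = rbind(error = ci(per_rep$error),
                       balanced_error = ci(per_rep$balanced_error),
                       sparsity = ci(per_rep$sparsity)),
       method = method, scenario = sc)
}

#' Hypergeometric enrichment of a gene selection for a truth set
#'
#' Upper-tail hypergeometric probability of observing at least the realized
#' overlap between `selected` and `truth` within `universe`.
#'
#' @param selected selected gene identifiers
#' @param truth true positive gene identifiers
#' @param universe all candidate gene identifiers
#' @return p-value
#' @export
enrichment_test <- function(selected, truth, universe) {
  selected <- intersect(selected, universe)
  truth <- intersect(truth, universe)
  q <- length(intersect(selected, truth))
  stats::phyper(q - 1, length(truth), length(universe) - length(truth),
                length(selected), lower.tail = FALSE)
}
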