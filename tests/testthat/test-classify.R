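# small fitted model on easy simulated data, reused across blocks
fit_toy_models <- function(seed = 301) {
  sim <- simulate_counts(sim_scenario(p = 300, n = 40, K = 2, de_prob = 0.1,
                                      sigma = 0.3, phi = 0.01, p_keep = 150,
                                      seed = seed))
  nz <- near_zero_filter(sim$data)
  mf <- variance_filter(nz$kept, 150, deseq_size_factors(nz$kept)$size_factors)
  list(sim = sim, mf = mf)
}

test_that("soft thresholding follows the sign-max table", {
  expect_equal(soft_threshold(2.5, 1), 1.5)
  expect_equal(soft_threshold(-0.3, 0.5), 0)
  expect_equal(soft_threshold(-2, 0.5), -1.5)
  d <- matrix(rnorm(20), 4, 5)
  expect_equal(soft_threshold(d, 0), d)
  for (seed in 1:100) {
    set.seed(seed)
    d <- rnorm(10, sd = 2)
    lam <- runif(1, 0, 2)
    expect_equal(soft_threshold(d, lam),
                 sapply(d, function(x) sign(x) * max(abs(x) - lam, 0)))
  }
  expect_error(soft_threshold(d, -0.1), "lambda")
})

test_that("difference scores satisfy the algebraic inversion identity", {
  toy <- fit_toy_models()
  fit <- voom_transform(toy$mf)
  mom <- weighted_moments(fit$z, fit$w, toy$mf$labels)
  ds <- difference_scores(mom)
  # hand case: contrast 1, m_k = 0.5, s + s0 = 2 -> d = 1
  expect_equal(1 / (0.5 * 2), 1)
  # algebraic inversion: the class centroids reconstruct from d exactly
  recon <- mom$overall_mean + outer(ds$s_wg + ds$s0, ds$m_k) * ds$d
  expect_equal(recon, mom$class_means, tolerance = 1e-12, ignore_attr = TRUE)
  # centroid equal to the overall mean gives a zero score
  mom0 <- mom
  mom0$class_means[1, ] <- mom0$overall_mean[1]
  expect_equal(unname(difference_scores(mom0)$d[1, ]), c(0, 0))
  # s0 is the median pooled sd by default
  expect_equal(ds$s0, median(sqrt(mom$pooled_vars)))
})

test_that("lambda grid spans 0 to max|d| with even spacing", {
  d <- matrix(c(-3, 1, 0.5, 2), 2)
  expect_equal(lambda_grid(d, 2), c(0, 3))
  g <- lambda_grid(d, 30)
  expect_length(g, 30)
  expect_true(all(diff(g) > 0))
  expect_equal(max(g), 3)
  expect_equal(diff(g), rep(3 / 29, 29))
  expect_warning(lambda_grid(matrix(0, 2, 2), 5), "degenerate")
})

test_that("threshold selection takes the sparsest (largest) error minimizer", {
  # the published worked example: minimum error attained on a plateau of
  # thresholds up to 1.775 -> select 1.775
  plateau <- c(0.561, 0.654, 0.748, 1.028, 1.121, 1.215, 1.308, 1.402,
               1.495, 1.588, 1.682, 1.775)
  lam <- c(0.1, 0.25, plateau, 1.9, 2.1)
  err <- c(0.10, 0.08, rep(0.035, length(plateau)), 0.08, 0.20)
  expect_equal(select_lambda(lam, err), 1.775)
  # all-equal errors select the grid maximum
  expect_equal(select_lambda(c(0, 0.5, 1), rep(0.2, 3)), 1)
})

test_that("diagonal discriminant scores match the brute-force sum", {
  toy <- fit_toy_models()
  model <- fit_dda(toy$mf, flavor = "voomDQDA", normalization = "none")
  model_l <- fit_dda(toy$mf, flavor = "voomDLDA", normalization = "none")
  set.seed(77)
  for (r in 1:5) {
    z_star <- rnorm(150, mean = 8, sd = 3)
    expect_equal(unname(dda_discriminant(z_star, model)),
                 bf_dda_scores(z_star, model$moments$class_means,
                               model$moments$class_vars, model$priors),
                 tolerance = 1e-9)
    expect_equal(unname(dda_discriminant(z_star, model_l)),
                 bf_dda_scores(z_star, model$moments$class_means, NULL,
                               model$priors, dlda_pooled = model$moments$pooled_vars),
                 tolerance = 1e-9)
  }
  # observation at a class centroid with equal priors goes to that class
  model_eq <- fit_dda(toy$mf, flavor = "voomDLDA", normalization = "none",
                      priors = c(0.5, 0.5))
  sc <- dda_discriminant(model_eq$moments$class_means[, 1], model_eq)
  expect_equal(names(which.max(sc)), model_eq$classes[1])
  # equal distances: the prior term decides
  model_pr <- fit_dda(toy$mf, flavor = "voomDLDA", normalization = "none",
                      priors = c(0.9, 0.1))
  mid <- rowMeans(model_pr$moments$class_means)
  sc2 <- dda_discriminant(mid, model_pr)
  expect_equal(names(which.max(sc2)), model_pr$classes[1])
})

test_that("voomNSC at lambda 0 keeps everything and matches unshrunken centroids", {
  toy <- fit_toy_models()
  model <- fit_nsc(toy$mf, lambda = 0, normalization = "none")
  expect_identical(model$survivors, model$genes)
  expect_equal(model$shrunk_centroids, model$moments$class_means,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(model$d_shrunk, model$d)
})

test_that("total shrinkage predicts the prior-argmax class for every input", {
  toy <- fit_toy_models()
  model <- fit_nsc(toy$mf, lambda = max(abs(fit_nsc(toy$mf, lambda = 0,
                                                    normalization = "none")$d)) + 1,
                   normalization = "none", priors = c(0.7, 0.3))
  expect_length(model$survivors, 0)
  test_m <- simulate_counts(sim_scenario(p = 300, n = 20, K = 2, phi = 0.1,
                                         de_prob = 0.1, sigma = 0.3, p_keep = 150,
                                         seed = 999))$data
  pred <- predict(model, test_m[model$genes, ])
  expect_true(all(pred == model$classes[which.max(model$priors)]))
})

test_that("with unit weights voomNSC reduces to the classical NSC recipe", {
  toy <- fit_toy_models()
  fit <- voom_transform(toy$mf)
  z <- fit$z
  labels <- toy$mf$labels
  lambda <- 0.8
  ref <- bf_classical_nsc(z, labels, lambda)
  mom <- weighted_moments(z, matrix(1, nrow(z), ncol(z)), labels)
  ds <- difference_scores(mom)
  expect_equal(unname(ds$d), unname(ref$d), tolerance = 1e-10)
  expect_equal(ds$s0, ref$s0, tolerance = 1e-10)
  d_shr <- soft_threshold(ds$d, lambda)
  expect_equal(unname(d_shr), unname(ref$d_shrunk), tolerance = 1e-10)
  cent <- mom$overall_mean + outer(ds$s_wg + ds$s0, ds$m_k) * d_shr
  expect_equal(unname(cent), unname(ref$shrunk_centroids), tolerance = 1e-10)
  # and the discriminant of a random observation agrees with the loop oracle
  set.seed(12)
  z_star <- rnorm(nrow(z), 8, 2)
  model <- list(shrunk_centroids = cent, s_wg = ds$s_wg, s0 = ds$s0,
                priors = mom$priors, classes = mom$classes)
  got <- nsc_discriminant(z_star, model)
  expect_equal(unname(got$scores), bf_nsc_score(z_star, ref), tolerance = 1e-9)
  expect_equal(sum(got$posterior), 1, tolerance = 1e-12)
})

test_that("posteriors follow the stated exponential form in both sign conventions", {
  model <- list(shrunk_centroids = matrix(c(0, 0, 1, 1), 2), s_wg = c(1, 1),
                s0 = 0.5, priors = c(A = 0.5, B = 0.5), classes = c("A", "B"))
  sc <- nsc_discriminant(c(0.5, 0.5), model)
  # equidistant observation with equal priors: all posteriors 1/K
  expect_equal(unname(sc$posterior), c(0.5, 0.5))
  sc2 <- nsc_discriminant(c(0, 0), model)
  delta <- sc2$scores
  expect_equal(unname(sc2$posterior),
               unname(exp(-delta) / sum(exp(-delta))), tolerance = 1e-12)
  sc3 <- nsc_discriminant(c(0, 0), model, posterior_sign = "softmax")
  expect_equal(unname(sc3$posterior),
               unname(exp(delta) / sum(exp(delta))), tolerance = 1e-12)
  # the printed convention anti-ranks the scores; softmax ranks with them
  expect_equal(order(sc2$posterior), order(-sc2$scores))
  expect_equal(order(sc3$posterior), order(sc3$scores))
})

test_that("cross-validation picks sparse thresholds deterministically", {
  toy <- fit_toy_models()
  cv1 <- cross_validate_nsc(toy$mf, normalization = "none", seed = 11, n_lambda = 12)
  cv2 <- cross_validate_nsc(toy$mf, normalization = "none", seed = 11, n_lambda = 12)
  expect_identical(cv1$fold_id, cv2$fold_id)
  expect_identical(cv1$cv_error, cv2$cv_error)
  expect_identical(cv1$best_lambda, cv2$best_lambda)
  # survivors are monotonically non-increasing across the grid
  expect_true(all(diff(cv1$n_survivors) <= 0))
  # the chosen lambda is the largest error minimizer
  expect_equal(cv1$best_lambda,
               max(cv1$lambda[cv1$cv_error == min(cv1$cv_error)]))
  # folds are stratified: every fold sees both classes
  expect_true(all(table(cv1$fold_id, toy$mf$labels) > 0))
})

test_that("shrunken survivors are enriched for truly differential genes", {
  toy <- toy_split(seed = 310)
  model <- fit_nsc(toy$train, normalization = "deseq", seed = 17)
  expect_gt(length(model$survivors), 0)
  de_genes <- toy$sim$truth$gene[toy$sim$truth$is_de]
  p <- enrichment_test(model$survivors, de_genes, model$genes)
  expect_lt(p, 0.01)
})

test_that("classification metrics match a confusion-matrix oracle", {
  truth <- c("A", "A", "A", "B", "B", "B", "B", "B")
  pred <- c("A", "A", "B", "B", "B", "B", "A", "B")
  ev <- evaluate_predictions(truth, pred, n_features = 4, n_total = 20)
  ref <- bf_metrics(truth, pred)
  expect_equal(ev$error, ref$error)
  expect_equal(ev$balanced_error, ref$balanced_error)
  expect_equal(ev$sparsity, 4)
  expect_equal(ev$relative_sparsity, 0.2)
  # perfect prediction
  expect_equal(evaluate_predictions(truth, truth)$error, 0)
  expect_equal(evaluate_predictions(truth, truth)$balanced_error, 0)
  # sens 1, spec 0.5 -> balanced error 0.25
  t2 <- c(rep("P", 4), rep("N", 4))
  p2 <- c(rep("P", 4), "P", "P", "N", "N")
  expect_equal(evaluate_predictions(t2, p2)$balanced_error, 0.25)
  # random tables against the oracle
  for (seed in 1:30) {
    set.seed(seed)
    t3 <- sample(c("A", "B", "C"), 30, replace = TRUE)
    p3 <- sample(c("A", "B", "C"), 30, replace = TRUE)
    ev3 <- evaluate_predictions(t3, p3)
    ref3 <- bf_metrics(t3, p3)
    expect_equal(ev3$error, ref3$error)
    expect_equal(ev3$balanced_error, ref3$balanced_error)
  }
  expect_error(evaluate_predictions(c("A", "B"), c("A", "Z")), "absent")
})

test_that("voomDLDA and lambda-0 voomNSC rank test samples consistently", {
  agree <- sapply(c(301, 305), function(seed) {
    toy <- toy_split(seed)
    dlda <- fit_dda(toy$train, flavor = "voomDLDA", normalization = "none")
    nsc0 <- fit_nsc(toy$train, lambda = 0, normalization = "none")
    mean(predict(dlda, toy$test) == predict(nsc0, toy$test))
  })
  expect_gte(mean(agree), 0.95)
})
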