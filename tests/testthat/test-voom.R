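test_that("log-cpm matches hand arithmetic and the brute-force formula", {
  # x = 0 with X = 999,999: (0.5/1e6)*1e6 = 0.5 -> z = -1
  expect_equal(log_cpm(matrix(0), 999999)[1], -1)
  # x = 2 with X = 999: (2.5/1000)*1e6 = 2500
  expect_equal(log_cpm(matrix(2), 999)[1], log2(2500))
  # ratio exactly 1e-6 -> z = 0
  expect_equal(log_cpm(matrix(0.5), 999999)[1], 0)
  for (seed in 1:100) {
    set.seed(seed)
    x <- matrix(rpois(5 * 3, 20), 5, 3)
    lib <- colSums(x)
    expect_equal(log_cpm(x, lib), bf_log_cpm(x, lib), tolerance = 1e-12)
  }
  # zero counts stay finite thanks to the offsets
  expect_true(all(is.finite(log_cpm(matrix(0, 3, 2), c(10, 10)))))
})

test_that("per-gene OLS on the class design returns class means and residual sd", {
  set.seed(8)
  z <- matrix(rnorm(20 * 8), 20, 8)
  labels <- factor(rep(c("A", "B"), each = 4))
  fg <- fit_gene_models(z, labels)
  for (g in c(1, 7, 20)) {
    mA <- mean(z[g, 1:4]); mB <- mean(z[g, 5:8])
    expect_equal(unname(fg$beta[g, ]), c(mA, mB))
    expect_equal(unname(fg$fitted[g, ]), rep(c(mA, mB), each = 4))
    rss <- sum((z[g, 1:4] - mA)^2) + sum((z[g, 5:8] - mB)^2)
    expect_equal(fg$resid_sd[g], sqrt(rss / 6))
  }
  # single class reduces to intercept: overall mean and sd with divisor n-1
  fg1 <- fit_gene_models(z, NULL)
  expect_equal(unname(fg1$beta[, 1]), rowMeans(z))
  expect_equal(fg1$resid_sd, apply(z, 1, sd))
  # constant within class -> zero residual sd
  zc <- matrix(rep(c(1, 5), each = 4), 1, 8, byrow = TRUE)
  expect_equal(fit_gene_models(zc, labels)$resid_sd, 0)
  expect_error(fit_gene_models(z[, 1:2], factor(c("A", "B"))), "residual degrees")
})

test_that("mean log-count conversion obeys the delta rule", {
  # all libraries 1e6 - 1 so X + 1 = 1e6 and the offsets cancel
  expect_equal(mean_log_counts(0, rep(1e6 - 1, 4)), 0)
  # geometric mean 2e6 adds exactly 1 relative to the 1e6 reference
  expect_equal(mean_log_counts(3, rep(2e6 - 1, 3)), 4)
  # doubling every library size adds ~1 to every mean log-count
  lib <- c(2e5, 5e5, 9e5)
  expect_equal(mean_log_counts(1.3, 2 * lib) - mean_log_counts(1.3, lib), 1,
               tolerance = 1e-5)
})

test_that("lowess trend stores monotone knots and interpolates linearly", {
  x <- seq(1, 10, length.out = 50)
  # flat relation: constant trend everywhere, including out of range
  flat <- fit_trend(x, rep(4, 50))
  expect_equal(trend_eval(flat, c(-5, 3.3, 40)), rep(2, 3))
  # noiseless line is reproduced at and between the knots
  sd_line <- (0.5 + 0.2 * x)^2
  tr <- fit_trend(x, sd_line)
  expect_true(all(diff(tr$x) > 0))
  expect_equal(trend_eval(tr, tr$x), tr$y)
  mid <- (tr$x[1] + tr$x[2]) / 2
  expect_equal(trend_eval(tr, mid), 0.5 + 0.2 * mid, tolerance = 1e-6)
  # constant extension beyond the knot range
  expect_equal(trend_eval(tr, 1e6), tr$y[length(tr$y)])
  expect_error(fit_trend(x, rep(0, 50)), "zero")
})

test_that("precision weights are the inverse fourth power of the trend", {
  tr <- structure(list(x = c(0, 10), y = c(1, 1)), class = "voom_trend")
  expect_equal(precision_weights(matrix(5, 2, 2), tr), matrix(1, 2, 2))
  tr2 <- structure(list(x = c(0, 10), y = c(2, 2)), class = "voom_trend")
  expect_equal(precision_weights(matrix(5), tr2)[1], 1 / 16)
  # monotone: larger trend value means strictly smaller weight
  tr3 <- structure(list(x = c(0, 10), y = c(0.5, 3)), class = "voom_trend")
  xs <- sort(runif(50, 0, 10))
  w <- precision_weights(matrix(xs, ncol = 1), tr3)
  expect_true(all(diff(w[, 1]) < 0))
})

test_that("voom transform matches the independent limma implementation", {
  set.seed(42)
  m <- rand_counts(400, 12, mu = 60, labels = two_class_labels(12))
  fit <- voom_transform(m)
  design <- stats::model.matrix(~0 + m$labels)
  v <- limma::voom(m$counts, design, lib.size = colSums(m$counts), span = 0.5)
  expect_identical(fit$z, v$E)
  expect_equal(fit$w, v$weights, tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("voom transform is equivariant and symmetric", {
  m <- rand_counts(60, 10, labels = two_class_labels(10), seed = 13)
  fit <- voom_transform(m)
  perm <- c(3, 1, 2, 6, 4, 5, 9, 7, 10, 8)
  mp <- m[, perm]
  fitp <- voom_transform(mp, m$labels[perm])
  expect_equal(fitp$z, fit$z[, perm])
  expect_equal(fitp$w, fit$w[, perm])
  # relabeling classes permutes nothing in the weights
  swapped <- factor(ifelse(m$labels == "A", "B", "A"), levels = c("B", "A"))
  expect_equal(voom_transform(m, swapped)$w, fit$w)
  # fully symmetric data gives identical weights everywhere
  mc <- count_matrix(matrix(7, 20, 6, dimnames = list(paste0("g", 1:20), paste0("s", 1:6))))
  expect_error(voom_transform(mc, two_class_labels(6)), "zero")
})

test_that("test transformation reproduces training columns bit-for-bit", {
  m <- rand_counts(80, 9, labels = factor(rep(c("A", "B", "C"), each = 3)), seed = 4)
  nm <- norm_factors(m, "none")
  fit <- voom_transform(m)
  for (i in c(1, 5, 9)) {
    tt <- transform_test(m$counts[, i], nm, fit)
    expect_identical(unname(tt$z), unname(fit$z[, i]))
  }
  # all-zero test sample stays finite
  tt0 <- transform_test(setNames(rep(0, 80), rownames(m$counts)), nm, fit)
  expect_true(all(is.finite(tt0$z)) && all(is.finite(tt0$w)))
  # hand formula spot-check on 5 genes of a random test vector
  set.seed(99)
  x <- setNames(rpois(80, 30), rownames(m$counts))
  tt <- transform_test(x, nm, fit)
  lib <- sum(x)
  for (g in sample(80, 5)) {
    expect_equal(unname(tt$z[g]), log2((x[[g]] + 0.5) / (lib + 1) * 1e6), tolerance = 1e-12)
  }
  expect_error(transform_test(x[-1], nm, fit), "lacks gene")
})
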