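random_counts <- function(nr, nc, seed = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(nr * nc, mu = exp(rnorm(nr, 4, 1)), size = 5), nr, nc)
  dimnames(m) <- list(sprintf("f%03d", seq_len(nr)), sprintf("s%02d", seq_len(nc)))
  m
}

test_that("compute_cpm scales by full-matrix library size", {
  m <- matrix(c(10, 999990, 5, 15), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- compute_cpm(m)
  expect_equal(cpm["a", "s1"], 10)  # count 10 over library 1e6
  expect_true(all(abs(colSums(cpm) - 1e6) < 1e-6))

  m2 <- rbind(m, z = c(0, 0))
  expect_equal(unname(compute_cpm(m2)["z", ]), c(0, 0))

  m3 <- cbind(m, s3 = c(0, 0))
  expect_error(compute_cpm(m3), "s3")
})

test_that("filter_features applies the low/prevalence/extreme-high rules", {
  n <- 100
  lib <- 1e6
  base <- matrix(10, 4, n, dimnames = list(c("low", "kept", "high", "ref"), NULL))
  base["low", ] <- 0.1            # CPM 0.1 everywhere -> mean below 0.2
  base["kept", ] <- c(rep(0.6, 60), rep(0, 40))  # CPM .6 in 60 samples, mean .36
  base["high", ] <- c(rep(60000, 3), rep(10, 97))
  base["ref", ] <- lib - colSums(base[c("low", "kept", "high"), , drop = FALSE])
  colnames(base) <- sprintf("s%03d", 1:n)
  kept <- filter_features(base, min_samples = 50)
  expect_false("low" %in% kept)
  expect_true("kept" %in% kept)
  expect_false("high" %in% kept)  # CPM > 50,000 in 1..49 samples
  # idempotence
  expect_identical(filter_features(base[kept, ], min_samples = 50), kept)
  expect_warning(filter_features(random_counts(5, 3), min_samples = 50),
                 "exceeds the number of samples")
})

test_that("TMM factors satisfy their invariants and hand cases", {
  m <- random_counts(200, 4, seed = 2)
  same <- m[, c(1, 1, 1)]
  colnames(same) <- c("a", "b", "c")
  expect_equal(unname(tmm_factors(same)), rep(1, 3))

  # doubling a column is pure library-size scaling: all M-values are 0
  two <- cbind(a = m[, 1], b = 2 * m[, 1])
  expect_equal(unname(tmm_factors(two)), c(1, 1))

  f <- tmm_factors(m)
  expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
  # scaling one sample is pure depth: factors move only via the
  # depth-dependent precision weights, i.e. negligibly
  m2 <- m
  m2[, 2] <- m2[, 2] * 5
  expect_equal(unname(tmm_factors(m2)), unname(f), tolerance = 0.02)

  expect_error(tmm_factors(m[, 1, drop = FALSE]), "2 samples")
})

test_that("TMM matches the reference implementation", {
  for (seed in 1:5) {
    m <- random_counts(300, 4, seed = seed)
    expect_equal(unname(tmm_factors(m)),
                 unname(edgeR::calcNormFactors(m, method = "TMM")),
                 tolerance = 1e-10)
  }
})

test_that("log2_cpm uses offset 0.5 and effective library sizes", {
  m <- matrix(c(0, 1e6 - 0), 2, 1, dimnames = list(c("a", "b"), "s1"))
  v <- log2_cpm(m, factors = 1)
  expect_equal(v["a", 1], log2(0.5 / (1e6 + 1) * 1e6))

  # doubling counts and library leaves high-count values nearly unchanged
  # (the prior-count perturbation scales as 1/count)
  m2 <- random_counts(50, 3, seed = 3) + 500
  d <- abs(log2_cpm(2 * m2) - log2_cpm(m2))
  expect_true(all(d < 1e-3))

  # monotone in the count for a fixed sample
  m3 <- matrix(c(1, 10, 100, 889), 4, 1, dimnames = list(letters[1:4], "s"))
  expect_true(all(diff(log2_cpm(m3)[, 1]) > 0))

  expect_error(log2_cpm(m, factors = -1), "positive")
})

test_that("quantile normalization equalizes sorted columns with mean-tie rule", {
  x <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(x)
  expect_equal(unname(qn), cbind(c(2.5, 3.5, 4.5), c(2.5, 3.5, 4.5)))

  same <- cbind(a = c(1, 5, 9), b = c(1, 5, 9))
  expect_equal(quantile_normalize(same), same)

  # ties at ranks 1-2 receive the mean of reference values 0.5 and 1.5
  tied <- cbind(a = c(1, 1, 2), b = c(0, 2, 4))
  expect_equal(unname(quantile_normalize(tied)),
               cbind(c(1, 1, 3), c(0.5, 1.5, 3)))

  # idempotence and identical sorted columns
  y <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  q1 <- quantile_normalize(y)
  expect_equal(quantile_normalize(q1), q1, tolerance = 1e-12)
  expect_equal(apply(q1, 2, sort), replicate(3, sort(q1[, 1])),
               ignore_attr = TRUE)
})

test_that("adjust_covariates removes covariate effects and keeps the class effect", {
  set.seed(5)
  n <- 40
  samples <- data.frame(sample_id = sprintf("s%02d", 1:n),
                        label = rep(0:1, n / 2),
                        age = rnorm(n, 60, 8),
                        sex = factor(sample(c("F", "M"), n, TRUE)))
  # expression exactly 2*age -> adjusted row constant (up to label term ~ 0)
  e_age <- matrix(2 * samples$age, 1, n,
                  dimnames = list("f1", samples$sample_id))
  adj <- adjust_covariates(e_age, samples, "age")
  expect_lt(diff(range(adj[1, samples$label == 0])), 1e-9)

  # expression exactly 3*label -> unchanged (class effect retained)
  e_lab <- matrix(3 * samples$label, 1, n,
                  dimnames = list("f1", samples$sample_id))
  expect_equal(adjust_covariates(e_lab, samples, c("age", "sex")), e_lab,
               tolerance = 1e-10)

  # matches a per-feature OLS oracle: subtract covariate terms only
  expr <- matrix(rnorm(5 * n), 5, n,
                 dimnames = list(paste0("f", 1:5), samples$sample_id))
  adj2 <- adjust_covariates(expr, samples, c("age", "sex"))
  X <- model.matrix(~ label + age + sex, samples)
  oracle <- t(apply(expr, 1, function(yy) {
    b <- solve(crossprod(X), crossprod(X, yy))
    yy - X[, c("age", "sexM")] %*% b[c("age", "sexM"), ]
  }))
  dimnames(oracle) <- dimnames(expr)
  expect_equal(adj2, oracle, tolerance = 1e-9)

  # projection: adjusting twice equals adjusting once
  expect_equal(adjust_covariates(adj2, samples, c("age", "sex")), adj2,
               tolerance = 1e-10)

  samples$age2 <- samples$age  # collinear duplicate
  expect_error(adjust_covariates(expr, samples, c("age", "age2")),
               "rank deficient")
})

test_that("split_dataset yields exact stratified sizes and folds", {
  set.seed(11)
  samples <- data.frame(sample_id = sprintf("s%04d", 1:2557),
                        label = rbinom(2557, 1, 0.354))
  sp <- split_dataset(samples, c(1637, 407, 513), seed = 1)
  expect_equal(sum(sp$split == "train"), 1637)
  expect_equal(sum(sp$split == "validation"), 407)
  expect_equal(sum(sp$split == "test"), 513)
  # stratification: per-split positive count within 1 of proportional share
  p_global <- mean(samples$label)
  for (s in c("train", "validation", "test")) {
    idx <- sp$split == s
    expect_lte(abs(sum(samples$label[idx]) - p_global * sum(idx)), 1)
  }
  # folds: 5 near-equal label-stratified folds on training samples only
  tr <- sp$split == "train"
  expect_true(all(is.na(sp$fold[!tr])))
  expect_true(all(!is.na(sp$fold[tr])))
  expect_lte(diff(range(table(sp$fold[tr]))), 1)

  # reproducible given seed, different otherwise
  expect_identical(split_dataset(samples, c(1637, 407, 513), seed = 1), sp)
  sp2 <- split_dataset(samples, c(1637, 407, 513), seed = 2)
  expect_false(identical(sp2$split, sp$split))
  expect_equal(sum(sp2$split == "train"), 1637)

  small <- data.frame(sample_id = letters[1:10],
                      label = rep(0:1, 5))
  s3 <- split_dataset(small, c(6, 2, 2), n_folds = 5, seed = 3)
  expect_equal(as.vector(table(s3$split)[c("train", "validation", "test")]),
               c(6L, 2L, 2L))
  expect_error(split_dataset(small, c(6, 2, 3)), "sum")
})

test_that("restrict_to_panel keeps features of panel genes in order", {
  m <- random_counts(4, 2)
  map <- c(f001 = "G1", f002 = "G1", f003 = "G2", f004 = "G3")
  expect_equal(rownames(restrict_to_panel(m, "G1", map)), c("f001", "f002"))
  expect_identical(restrict_to_panel(m, c("G1", "G2", "G3"), map), m)
  expect_warning(out <- restrict_to_panel(m, character(0), map), "no features")
  expect_equal(nrow(out), 0)
  expect_error(restrict_to_panel(m, "G1", map[-2]), "missing from")
})
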