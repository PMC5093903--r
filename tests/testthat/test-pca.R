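as_log2 <- function(m) { attr(m, "scale_tag") <- "log2cpm"; m }

test_that("PCA explained fractions conserve variance and scores are orthogonal", {
  # rank-1: a single varying gene puts all variance on PC1
  m <- matrix(5, 20, 12, dimnames = list(sprintf("g%d", 1:20),
                                         sprintf("s%d", 1:12)))
  m[1, ] <- seq_len(12)
  pc <- run_pca(as_log2(m))
  expect_equal(pc$explained_fraction[1], 1)

  set.seed(7)
  r <- matrix(rnorm(50 * 12), 50, 12,
              dimnames = list(sprintf("g%d", 1:50), sprintf("s%d", 1:12)))
  pc <- run_pca(as_log2(r))
  expect_equal(sum(pc$explained_fraction), 1)
  cc <- cov(pc$scores)
  expect_lt(max(abs(cc[upper.tri(cc)])), 1e-10)
  # deterministic sign convention: dominant loading entry positive
  for (j in seq_len(ncol(pc$loadings))) {
    v <- pc$loadings[, j]
    expect_gte(v[which.max(abs(v))], 0)
  }
  expect_error(run_pca(as_log2(r[, 1, drop = FALSE])), "2 samples")
})

test_that("correlation outlier detection flags the constructed outlier only", {
  set.seed(8)
  base <- rnorm(200, 8, 2)
  m <- sapply(1:11, function(i) base + rnorm(200, 0, 0.05))
  dimnames(m) <- list(sprintf("g%d", 1:200), sprintf("s%d", 1:11))
  m[, 11] <- sample(m[, 11])  # permuted sample decorrelates
  out <- detect_outliers(m, threshold = 0.8)
  expect_equal(out$sample, "s11")
  expect_equal(out$reason, "low_correlation")

  # identical samples: perfectly correlated, none flagged
  ident <- matrix(rep(base, 5), 200, 5,
                  dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:5)))
  expect_equal(nrow(detect_outliers(ident, threshold = 0.8)), 0)

  # vacuous threshold flags nothing on positively correlated data
  expect_equal(nrow(detect_outliers(m[, 1:10], threshold = 0)), 0)

  # constant-expression sample is degenerate
  m[, 3] <- 7
  out <- detect_outliers(m, threshold = 0)
  expect_true("degenerate" %in% out$reason[out$sample == "s3"])
})

test_that("covariate association finds separation, is calibrated and relabel-invariant", {
  # covariate splitting PC1 into well-separated clusters
  scores <- cbind(PC1 = c(rnorm(10, -50, 0.5), rnorm(10, 50, 0.5)),
                  PC2 = rnorm(20))
  fake_pca <- structure(list(scores = scores), class = "st_pca")
  meta <- data.frame(sample = sprintf("s%d", 1:20),
                     group = rep(c("a", "b"), each = 10))
  pv <- associate_covariates(fake_pca, meta, "group", 2)
  expect_lt(pv["group", 1], 1e-6)

  # equal groups with identical values: F = 0, p = 1
  fake2 <- structure(list(scores = cbind(PC1 = c(1, 2, 3, 1, 2, 3))),
                     class = "st_pca")
  meta2 <- data.frame(sample = sprintf("s%d", 1:6),
                      group = rep(c("a", "b"), each = 3))
  expect_equal(associate_covariates(fake2, meta2, "group", 1)[1, 1], 1)

  # relabel invariance
  meta3 <- meta
  meta3$group <- c(a = "zz", b = "aa")[meta$group]
  expect_equal(associate_covariates(fake_pca, meta3, "group", 2), pv,
               ignore_attr = TRUE)

  # single-level covariate is not testable
  meta4 <- meta
  meta4$group <- "a"
  expect_warning(pv4 <- associate_covariates(fake_pca, meta4, "group", 2),
                 "single level")
  expect_true(all(is.na(pv4)))

  # permutation-null p-values are uniform (KS at alpha = 0.01)
  set.seed(9)
  sc <- rnorm(40)
  fake5 <- structure(list(scores = cbind(PC1 = sc)), class = "st_pca")
  labs <- rep(c("a", "b"), each = 20)
  ps <- replicate(1000, {
    md <- data.frame(sample = sprintf("s%d", 1:40), group = sample(labs))
    associate_covariates(fake5, md, "group", 1)[1, 1]
  })
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("an injected batch effect is detected on a leading component", {
  b <- simulate_dataset(sim_config(batch_log2_effect = 2, seed = 6))
  pc <- run_pca(log_transform(cpm_normalize(b$counts)))
  pv <- associate_covariates(pc, b$metadata, c("batch", "population"), 10)
  expect_lt(min(pv["batch", 1:3]), 0.01)
  # population (the dominant biological factor) loads a leading component
  expect_lt(min(pv["population", 1:3]), 1e-10)

  # without an injected effect the batch covariate stays quiet up front
  b0 <- simulate_dataset(sim_config(seed = 6))
  pc0 <- run_pca(log_transform(cpm_normalize(b0$counts)))
  pv0 <- associate_covariates(pc0, b0$metadata, "batch", 10)
  expect_gt(min(pv0["batch", 1:3]), 0.01)
})
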