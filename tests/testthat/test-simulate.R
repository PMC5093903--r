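test_that("default design yields 47 samples, 16 conditions, L10 exception", {
  b <- simulate_dataset(sim_config(n_genes = 50, seed = 1))
  expect_equal(ncol(b$counts), 47)
  meta <- b$metadata
  tab <- table(meta$population, meta$time_point)
  expect_equal(nrow(unique(meta[, c("population", "time_point")])), 16)
  expect_equal(unname(tab["basal", "L10"]), 2)
  expect_true(all(tab[cbind(rep(c("luminal", "basal"), each = 7),
                            rep(setdiff(time_points(), "L10"), 2))] == 3))
  expect_equal(unname(tab["luminal", "L10"]), 3)
  # truth has one record per gene
  expect_equal(nrow(b$truth), 50)
  # counts are non-negative integers
  expect_true(all(b$counts >= 0))
  expect_equal(b$counts, round(b$counts))
})

test_that("simulation is deterministic given the seed and restores RNG state", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  b1 <- simulate_dataset(sim_config(n_genes = 100, seed = 5))
  after <- runif(1)
  expect_equal(after, before)  # caller RNG untouched by the simulation

  b2 <- simulate_dataset(sim_config(n_genes = 100, seed = 5))
  expect_identical(b1$counts, b2$counts)
  expect_identical(b1$truth, b2$truth)
  b3 <- simulate_dataset(sim_config(n_genes = 100, seed = 6))
  expect_false(identical(b1$counts, b3$counts))
})

test_that("config validation rejects bad mixtures and sizes", {
  expect_error(sim_config(mixture = c(null = 0.5, population_specific = 0.1,
                                      timepoint_specific = 0.1,
                                      stage_specific = 0.1,
                                      switching = 0.1)), "sum to 1")
  expect_error(sim_config(dispersion = 0), "dispersion")
  expect_error(sim_config(n_genes = 0), "n_genes")
  all_null <- c(null = 1, population_specific = 0, timepoint_specific = 0,
                stage_specific = 0, switching = 0)
  b <- simulate_dataset(sim_config(n_genes = 30, mixture = all_null,
                                   seed = 2))
  expect_true(all(b$truth$archetype == "null"))
})

test_that("fixture files round-trip through the readers", {
  b <- simulate_dataset(sim_config(n_genes = 40, seed = 1))
  dir <- withr::local_tempdir()
  paths <- write_fixture(b, dir)
  expect_identical(read_counts(paths[["counts"]]), b$counts)
  meta <- read_metadata(paths[["metadata"]], b$counts)
  expect_equal(meta$sample, b$metadata$sample)
  expect_equal(meta$time_point, b$metadata$time_point)
  truth <- read.delim(paths[["truth"]])
  expect_equal(nrow(truth), 40)
  expect_error(write_fixture(list(counts = NULL), dir), "no genes")
})

test_that("empirical mean CPM converges to the planted truth", {
  # 200 replicates per condition; sampling allowance: the NB noise still
  # leaves a few percent of entries outside a 5% band at this depth
  b <- simulate_dataset(sim_config(n_genes = 300, replicates = 200,
                                   l10_basal_replicates = 200, seed = 9))
  cpm <- cpm_normalize(b$counts)
  cond <- paste(b$metadata$population, b$metadata$time_point, sep = ".")
  emp <- sapply(colnames(b$true_cpm),
                function(cn) rowMeans(cpm[, cond == cn, drop = FALSE]))
  sel <- b$true_cpm >= 10
  rel <- abs(emp - b$true_cpm)[sel] / b$true_cpm[sel]
  expect_lt(stats::median(rel), 0.02)
  expect_gt(mean(rel <= 0.05), 0.95)
})

test_that("population-specific recovery is monotone in the planted effect", {
  rates <- vapply(c(1, 2, 4), function(eff) {
    b <- simulate_dataset(sim_config(n_genes = 600, log2_effect = eff,
                                     seed = 21))
    sp <- spatial_de_calls(cpm_normalize(b$counts), b$metadata)
    cls <- classify_specificity(sp)
    ps <- b$truth[b$truth$archetype == "population_specific", ]
    mean(cls$specificity[match(ps$gene, cls$gene)] == ps$population)
  }, 0)
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], 0.9)
})
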