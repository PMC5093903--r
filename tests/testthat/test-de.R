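test_that("BH adjustment matches the step-up oracle and hand examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(11)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # elementwise >= p, permutation equivariance
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("fold change is exact, antisymmetric and guards inputs", {
  expect_equal(compute_fold_change(100, 25, 1), log2(101 / 26))
  expect_equal(compute_fold_change(100, 25, 1), 1.958, tolerance = 1e-3)
  expect_equal(compute_fold_change(42, 42, 1), 0)
  a <- runif(20, 0, 1000); b <- runif(20, 0, 1000)
  expect_equal(compute_fold_change(a, b), -compute_fold_change(b, a))
  expect_error(compute_fold_change(-1, 5), "negative")
  expect_error(compute_fold_change(1, 5, 0), "pseudocount")
})

test_that("per-gene tests match stats-package oracles on random inputs", {
  set.seed(12)
  meta <- full_design_meta(3, l10_basal = 2)
  ng <- 40
  cpm <- design_cpm(meta, n_genes = ng, baseline = 200, noise_sd = 0.5,
                    seed = 12)
  lg <- log2(cpm + 1)

  # Welch and pooled p-values vs t.test, 1e-10
  sp_w <- spatial_de_calls(cpm, meta, test = "welch")
  sp_p <- spatial_de_calls(cpm, meta, test = "pooled")
  for (tp in c("W10", "L10", "M4")) {
    lum <- meta$population == "luminal" & meta$time_point == tp
    bas <- meta$population == "basal" & meta$time_point == tp
    for (g in sample(ng, 8)) {
      expect_equal(sp_w$p[g, tp],
                   stats::t.test(lg[g, bas], lg[g, lum])$p.value,
                   tolerance = 1e-10)
      expect_equal(sp_p$p[g, tp],
                   stats::t.test(lg[g, bas], lg[g, lum],
                                 var.equal = TRUE)$p.value,
                   tolerance = 1e-10)
    }
  }

  # condition-model contrast test vs an aov-residual-MSE oracle
  sp_a <- spatial_de_calls(cpm, meta, test = "anova")
  cond <- factor(paste(meta$population, meta$time_point))
  for (g in sample(ng, 8)) {
    fit <- stats::aov(lg[g, ] ~ cond)
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    tp <- "P14.5"
    lum <- meta$population == "luminal" & meta$time_point == tp
    bas <- meta$population == "basal" & meta$time_point == tp
    tt <- (mean(lg[g, bas]) - mean(lg[g, lum])) /
      sqrt(mse * (1 / sum(bas) + 1 / sum(lum)))
    p_or <- 2 * stats::pt(abs(tt), fit$df.residual, lower.tail = FALSE)
    expect_equal(sp_a$p[g, tp], p_or, tolerance = 1e-10)
  }

  # omnibus ANOVA p vs anova(lm) oracle
  an <- anova_filter(cpm, meta)
  for (g in sample(ng, 8)) {
    p_or <- stats::anova(stats::lm(lg[g, ] ~ cond))$`Pr(>F)`[1]
    expect_equal(an$anova_p[g], p_or, tolerance = 1e-10)
  }
})

test_that("degenerate and threshold edge cases behave as documented", {
  meta <- full_design_meta(3)
  # constant gene: p = 1, never flagged, no temporal calls
  cpm <- design_cpm(meta, n_genes = 3, baseline = 50)
  an <- anova_filter(cpm, meta)
  expect_equal(an$anova_p, rep(1, 3))
  expect_false(any(an$anova_de))
  tmp <- temporal_de_calls(cpm, meta)
  expect_false(any(tmp$call))

  # constructed strong single-condition spike is flagged
  shift <- list(list(gene = 1, population = "basal", time_point = "L3",
                     log2 = 5))
  cpm2 <- design_cpm(meta, n_genes = 200, baseline = 100, shift = shift,
                     noise_sd = 0.1, seed = 13)
  an2 <- anova_filter(cpm2, meta)
  expect_lt(an2$anova_fdr[1], 0.01)
  expect_true(an2$anova_de[1])

  # fold-change gate: |log2FC| = 0.9 with minuscule noise is not called
  shift3 <- list(list(gene = 1, population = "basal",
                      time_point = time_points(), log2 = 0.9))
  cpm3 <- design_cpm(meta, n_genes = 50, baseline = 1000, shift = shift3,
                     noise_sd = 0.01, seed = 14)
  sp3 <- spatial_de_calls(cpm3, meta)
  expect_lt(min(sp3$fdr[1, ]), 0.01)      # overwhelmingly significant
  expect_true(all(sp3$call[1, ] == 0L))   # but below the fold-change gate
  expect_true(all(abs(sp3$lfc[1, ]) < 1))

  # a single-replicate condition is dropped with a warning
  meta1 <- meta[!(meta$population == "basal" & meta$time_point == "L10" &
                    meta$replicate > 1), ]
  cpm4 <- design_cpm(meta1, n_genes = 5, baseline = 100, noise_sd = 0.2,
                     seed = 15)
  expect_warning(anova_filter(cpm4, meta1), "< 2 replicates")
  expect_warning(spatial_de_calls(cpm4, meta1, test = "welch"),
                 "< 2 replicates")
})

test_that("specificity classification follows its definitions", {
  mk <- function(calls) {
    structure(list(call = calls), class = "st_spatial")
  }
  tps <- time_points()
  cl <- matrix(0L, 4, 8, dimnames = list(c("a", "b", "c", "d"), tps))
  cl["a", "P3.5"] <- -1L                     # luminal-up once
  cl["b", "W10"] <- -1L; cl["b", "L3"] <- 1L # both directions
  cl["c", ] <- 1L                            # basal-up everywhere
  out <- classify_specificity(mk(cl))
  expect_equal(out$specificity, c("luminal", "switching", "basal", "none"))
  expect_equal(out$always_specific, c(FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$spatial_de, c(TRUE, TRUE, TRUE, FALSE))
})

test_that("time-point/stage-specific calling distinguishes targets", {
  meta <- full_design_meta(3, l10_basal = 2)
  shift <- list(
    list(gene = 1, population = "basal", time_point = "L3", log2 = 4),
    list(gene = 2, population = "basal",
         time_point = c("P14.5", "L3", "L10"), log2 = 4))
  cpm <- design_cpm(meta, n_genes = 100, baseline = 100, shift = shift,
                    noise_sd = 0.3, seed = 16)
  g <- rownames(cpm)
  s_l3 <- specific_genes(cpm, meta, "basal", "L3")
  s_lact <- specific_genes(cpm, meta, "basal", "lactogenesis")
  s_l10 <- specific_genes(cpm, meta, "basal", "L10")
  expect_true(g[1] %in% s_l3$gene)
  expect_false(g[2] %in% s_l3$gene)     # fails L3 vs P14.5
  expect_true(g[2] %in% s_lact$gene)
  expect_false(g[1] %in% s_l10$gene)
  expect_equal(s_l3$direction[s_l3$gene == g[1]], 1L)
  # pooled-complement mode also recovers the stage gene
  s_pool <- specific_genes(cpm, meta, "basal", "lactogenesis",
                           stage_mode = "pooled_complement")
  expect_true(g[2] %in% s_pool$gene)
  expect_error(specific_genes(cpm, meta, "basal", "everything",
                              stages = list(everything = time_points())),
               "complement")
  expect_error(specific_genes(cpm, meta, "basal", "NOPE"), "unknown target")
})

test_that("call sets respect threshold monotonicity and set algebra", {
  b <- simulate_dataset(sim_config(n_genes = 500, seed = 17))
  cpm <- cpm_normalize(b$counts)
  meta <- b$metadata
  sp <- spatial_de_calls(cpm, meta, fc_min = 2, alpha_fdr = 0.01)
  sp_strict_fc <- spatial_de_calls(cpm, meta, fc_min = 4, alpha_fdr = 0.01)
  sp_strict_a <- spatial_de_calls(cpm, meta, fc_min = 2, alpha_fdr = 0.001)
  expect_true(all((sp_strict_fc$call != 0) <= (sp$call != 0)))
  expect_true(all((sp_strict_a$call != 0) <= (sp$call != 0)))

  f <- st_fit(b$counts, meta, specific_targets = "none")
  cl <- f$classification
  de <- cl[cl$anova_de, ]
  n_s <- sum(de$spatial_de); n_t <- sum(de$temporal_de)
  n_b <- sum(de$spatial_de & de$temporal_de)
  expect_equal(sum(de$spatial_de | de$temporal_de), n_s + n_t - n_b)
  # specificity classes partition the spatial set
  expect_equal(sum(de$specificity %in% c("luminal", "basal", "switching")),
               n_s)
  expect_true(all(cl$specificity[!cl$spatial_de] == "none"))
  # accounting is consistent with the classification
  expect_equal(f$accounting$n_spatial, n_s)
  expect_equal(f$accounting$n_union, n_s + n_t - n_b)
})
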