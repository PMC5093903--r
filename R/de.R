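# Per-gene residual mean square of the one-way condition model: the variance
# estimate shared by every contrast of that gene's condition means
# (df = n - k). Conditions with a single sample contribute nothing to the
# residual but keep their mean available for contrasts.
row_condition_mse <- function(x, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  n <- ncol(x)
  if (n - k < 1) stop("condition model has no residual degrees of freedom")
  ssw <- numeric(nrow(x))
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    mg <- rowMeans(x[, idx, drop = FALSE])
    ssw <- ssw + rowSums((x[, idx, drop = FALSE] - mg)^2)
  }
  list(mse = ssw / (n - k), df = n - k)
}

# Contrast t test between two sample groups using a shared per-gene residual
# variance (from row_condition_mse). Degenerate rows (zero variance) get
# p = 1 when the means agree and p = 0 otherwise.
row_contrast_ttest <- function(x1, x2, mse, df) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  se2 <- mse$mse * (1 / n1 + 1 / n2)
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), mse$df, lower.tail = FALSE)
  deg <- se2 == 0
  if (any(deg)) p[deg] <- ifelse(m1[deg] == m2[deg], 1, 0)
  list(t = tt, df = rep(mse$df, length(m1)), p = p, mean1 = m1, mean2 = m2)
}

# Vectorised two-sample t test across the rows of two matrices.
# Welch by default; pooled-variance optional. Degenerate rows (zero standard
# error) get p = 1 when the means agree and p = 0 otherwise.
row_ttest <- function(x1, x2, pooled = FALSE) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  if (n1 < 2 || n2 < 2) stop("both groups need at least 2 replicates")
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, length(m1))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  }
  tt <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  deg <- se2 == 0
  if (any(deg)) p[deg] <- ifelse(m1[deg] == m2[deg], 1, 0)
  list(t = tt, df = df, p = p, mean1 = m1, mean2 = m2)
}

# Vectorised one-way ANOVA across rows. `groups` is a factor over columns;
# levels with fewer than 2 observations must be removed by the caller.
# Constant rows (zero total sum of squares) get p = 1; rows with zero
# within-group variance but non-zero between-group variance get p = 0.
row_anova <- function(x, groups) {
  groups <- droplevels(factor(groups))
  k <- nlevels(groups)
  if (k < 2) stop("ANOVA requires at least 2 groups")
  n <- ncol(x)
  gm <- rowMeans(x)
  ssb <- numeric(nrow(x))
  ssw <- numeric(nrow(x))
  for (lev in levels(groups)) {
    idx <- which(groups == lev)
    mg <- rowMeans(x[, idx, drop = FALSE])
    ssb <- ssb + length(idx) * (mg - gm)^2
    ssw <- ssw + rowSums((x[, idx, drop = FALSE] - mg)^2)
  }
  df1 <- k - 1
  df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  sst <- ssb + ssw
  p[sst <= 0] <- 1
  p[ssw == 0 & ssb > 0] <- 0
  list(f = f, p = p, df1 = df1, df2 = df2)
}

#' Log2 fold change between two group means
#'
#' `log2((mean_a + pseudocount) / (mean_b + pseudocount))` on the CPM scale;
#' antisymmetric under swapping the groups.
#'
#' @param mean_a,mean_b Non-negative group mean CPM (vectorised).
#' @param pseudocount Positive offset (default 1).
#' @return Numeric log2 fold change(s).
#' @export
compute_fold_change <- function(mean_a, mean_b, pseudocount = 1) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(mean_a < 0) || any(mean_b < 0)) stop("negative group mean")
  log2((mean_a + pseudocount) / (mean_b + pseudocount))
}

# Resolve a CPM matrix and its log2 companion from a user-supplied matrix.
de_scales <- function(expr, pseudocount) {
  sc <- expr_scale(expr)
  if (sc == "cpm") {
    list(cpm = expr, log = log_transform(expr, pseudocount))
  } else if (sc == "log2cpm") {
    pc <- attr(expr, "pseudocount")
    if (is.null(pc)) pc <- pseudocount
    cpm <- 2^expr - pc
    cpm[cpm < 0] <- 0
    attr(cpm, "scale_tag") <- "cpm"
    list(cpm = cpm, log = expr)
  } else stop("expression matrix must be cpm or log2cpm")
}

#' Omnibus ANOVA expression filter
#'
#' Per gene, a one-way ANOVA of log2 CPM across the population x time-point
#' condition groups, with Benjamini-Hochberg adjustment across genes. A gene
#' passes the filter when its FDR is below `alpha_fdr` — i.e. it is
#' differentially expressed in at least one population at at least one time
#' point. Conditions with fewer than 2 replicates are dropped from the test
#' with a warning.
#'
#' @param expr Expression matrix (cpm or log2cpm scale).
#' @param meta Sample metadata aligned with `expr` columns.
#' @param alpha_fdr FDR threshold (default 0.01).
#' @param pseudocount Pseudocount for the log scale when `expr` is CPM.
#' @return Data frame (one row per gene): `gene`, `anova_p`, `anova_fdr`,
#'   `anova_de`.
#' @export
anova_filter <- function(expr, meta, alpha_fdr = 0.01, pseudocount = 1) {
  meta <- validate_metadata(meta, NULL)
  if (!identical(meta$sample, colnames(expr)))
    meta <- meta[match(colnames(expr), meta$sample), , drop = FALSE]
  sc <- de_scales(expr, pseudocount)
  cond <- factor(paste(meta$population, meta$time_point, sep = "."))
  tab <- table(cond)
  small <- names(tab)[tab < 2]
  keep <- !(cond %in% small)
  if (length(small) > 0)
    warning("dropping condition(s) with < 2 replicates: ",
            paste(small, collapse = ", "))
  res <- row_anova(sc$log[, keep, drop = FALSE], cond[keep])
  fdr <- bh_adjust(res$p)
  data.frame(gene = rownames(expr), anova_p = res$p, anova_fdr = fdr,
             anova_de = fdr < alpha_fdr,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spatial differential-expression calls (luminal vs basal per time point)
#'
#' At each time point, a two-sample test of basal vs luminal log2 CPM per
#' gene, with one Benjamini-Hochberg family across all gene x time-point
#' tests. A call requires FDR < `alpha_fdr` and |log2FC| >= log2(`fc_min`);
#' the fold change is basal minus luminal on pseudocounted mean CPM, so a
#' direction of +1 means basal-up and -1 means luminal-up.
#'
#' @inheritParams anova_filter
#' @param fc_min Minimum fold change (default 2; applied as
#'   |log2FC| >= log2(fc_min)).
#' @param test Per-comparison test. `"anova"` (default): contrast t test on
#'   the group means with the per-gene residual variance of the one-way
#'   condition model (df = n - k, no cross-gene information sharing);
#'   `"welch"` / `"pooled"`: two-sample t tests on the two groups alone.
#' @return List of class `"st_spatial"` with genes x time-point matrices
#'   `lfc`, `p`, `fdr` and integer `call` (0 none, +1 basal-up, -1
#'   luminal-up), plus the thresholds used.
#' @export
spatial_de_calls <- function(expr, meta, fc_min = 2, alpha_fdr = 0.01,
                             pseudocount = 1,
                             test = c("anova", "welch", "pooled")) {
  test <- match.arg(test)
  meta <- validate_metadata(meta, NULL)
  if (!identical(meta$sample, colnames(expr)))
    meta <- meta[match(colnames(expr), meta$sample), , drop = FALSE]
  sc <- de_scales(expr, pseudocount)
  tps <- intersect(time_points(), unique(meta$time_point))
  ng <- nrow(expr)
  mse <- if (test == "anova")
    row_condition_mse(sc$log, paste(meta$population, meta$time_point,
                                    sep = "."))
  lfc <- p <- matrix(NA_real_, ng, length(tps),
                     dimnames = list(rownames(expr), tps))
  for (tp in tps) {
    lum <- which(meta$time_point == tp & meta$population == "luminal")
    bas <- which(meta$time_point == tp & meta$population == "basal")
    if (length(lum) < 2 || length(bas) < 2) {
      warning("skipping time point ", tp, ": a population has < 2 replicates")
      next
    }
    tt <- if (test == "anova")
      row_contrast_ttest(sc$log[, bas, drop = FALSE],
                         sc$log[, lum, drop = FALSE], mse, mse$df)
    else row_ttest(sc$log[, bas, drop = FALSE], sc$log[, lum, drop = FALSE],
                   pooled = test == "pooled")
    p[, tp] <- tt$p
    lfc[, tp] <- compute_fold_change(
      rowMeans(sc$cpm[, bas, drop = FALSE]),
      rowMeans(sc$cpm[, lum, drop = FALSE]), pseudocount)
  }
  fdr <- matrix(bh_adjust(as.vector(p)), ng, length(tps),
                dimnames = dimnames(p))
  call <- matrix(0L, ng, length(tps), dimnames = dimnames(p))
  hit <- !is.na(fdr) & fdr < alpha_fdr & abs(lfc) >= log2(fc_min)
  call[hit] <- ifelse(lfc[hit] > 0, 1L, -1L)
  structure(list(lfc = lfc, p = p, fdr = fdr, call = call,
                 fc_min = fc_min, alpha_fdr = alpha_fdr),
            class = "st_spatial")
}

#' Temporal differential-expression calls (time-point pairs per population)
#'
#' Within each population, a two-sample test per gene for every unordered
#' pair of time points (28 pairs for the full design), with one
#' Benjamini-Hochberg family across all gene x pair x population tests.
#' The fold change is the later time point minus the earlier (canonical
#' developmental order) on pseudocounted mean CPM.
#'
#' @inheritParams spatial_de_calls
#' @return List of class `"st_temporal"` with genes x (population.pair)
#'   matrices `lfc`, `p`, `fdr`, logical `call`, plus a `comparisons` data
#'   frame (population, tp1, tp2).
#' @export
temporal_de_calls <- function(expr, meta, fc_min = 2, alpha_fdr = 0.01,
                              pseudocount = 1,
                              test = c("anova", "welch", "pooled")) {
  test <- match.arg(test)
  meta <- validate_metadata(meta, NULL)
  if (!identical(meta$sample, colnames(expr)))
    meta <- meta[match(colnames(expr), meta$sample), , drop = FALSE]
  sc <- de_scales(expr, pseudocount)
  tps <- intersect(time_points(), unique(meta$time_point))
  pairs <- utils::combn(tps, 2)
  comps <- expand.grid(pair = seq_len(ncol(pairs)),
                       population = populations(),
                       stringsAsFactors = FALSE)
  comps$tp1 <- pairs[1, comps$pair]
  comps$tp2 <- pairs[2, comps$pair]
  comps$name <- paste(comps$population, comps$tp1, comps$tp2, sep = ".")
  ng <- nrow(expr)
  mse <- if (test == "anova")
    row_condition_mse(sc$log, paste(meta$population, meta$time_point,
                                    sep = "."))
  lfc <- p <- matrix(NA_real_, ng, nrow(comps),
                     dimnames = list(rownames(expr), comps$name))
  skipped <- character(0)
  for (i in seq_len(nrow(comps))) {
    g1 <- which(meta$population == comps$population[i] &
                  meta$time_point == comps$tp1[i])
    g2 <- which(meta$population == comps$population[i] &
                  meta$time_point == comps$tp2[i])
    if (length(g1) < 2 || length(g2) < 2) {
      skipped <- c(skipped, comps$name[i])
      next
    }
    tt <- if (test == "anova")
      row_contrast_ttest(sc$log[, g2, drop = FALSE],
                         sc$log[, g1, drop = FALSE], mse, mse$df)
    else row_ttest(sc$log[, g2, drop = FALSE], sc$log[, g1, drop = FALSE],
                   pooled = test == "pooled")
    p[, i] <- tt$p
    lfc[, i] <- compute_fold_change(
      rowMeans(sc$cpm[, g2, drop = FALSE]),
      rowMeans(sc$cpm[, g1, drop = FALSE]), pseudocount)
  }
  if (length(skipped) > 0)
    warning("skipping comparison(s) with < 2 replicates: ",
            paste(skipped, collapse = ", "))
  fdr <- matrix(bh_adjust(as.vector(p)), ng, nrow(comps),
                dimnames = dimnames(p))
  call <- !is.na(fdr) & fdr < alpha_fdr & abs(lfc) >= log2(fc_min)
  structure(list(lfc = lfc, p = p, fdr = fdr, call = call,
                 comparisons = comps[, c("population", "tp1", "tp2", "name")],
                 fc_min = fc_min, alpha_fdr = alpha_fdr),
            class = "st_temporal")
}

#' Classify spatial specificity per gene
#'
#' A gene is luminal-specific when it has a luminal-up call at one or more
#' time points and no basal-up call anywhere (basal symmetric); switching
#' when both directions occur; none when it has no spatial call. A gene is
#' always-specific when its direction is called at every tested time point.
#'
#' @param spatial Result of [spatial_de_calls()].
#' @return Data frame: `gene`, `spatial_de`, `specificity`
#'   (luminal/basal/switching/none), `always_specific`.
#' @export
classify_specificity <- function(spatial) {
  cl <- spatial$call
  n_lum <- rowSums(cl == -1L)
  n_bas <- rowSums(cl == 1L)
  spec <- rep("none", nrow(cl))
  spec[n_lum > 0 & n_bas == 0] <- "luminal"
  spec[n_bas > 0 & n_lum == 0] <- "basal"
  spec[n_lum > 0 & n_bas > 0] <- "switching"
  always <- (n_lum == ncol(cl) & n_bas == 0) |
    (n_bas == ncol(cl) & n_lum == 0)
  data.frame(gene = rownames(cl), spatial_de = spec != "none",
             specificity = spec, always_specific = always,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Time-point- or stage-specific genes in one population
#'
#' For a time-point target t, each gene is compared (within the population)
#' between t and every other time point; for a stage target, the stage's
#' member time points are pooled into one group and compared against each
#' time point outside the stage (default), or against the pooled complement
#' when `stage_mode = "pooled_complement"`. A gene is target-specific when
#' every comparison is called (FDR < `alpha_fdr`, |log2FC| >= log2(`fc_min`),
#' one BH family per target across genes x comparisons) with a consistent
#' direction.
#'
#' @inheritParams spatial_de_calls
#' @param population `"luminal"` or `"basal"`.
#' @param target A canonical time-point label or a name in `stages`.
#' @param stages Stage table (see [default_stages()]).
#' @param stage_mode `"per_timepoint"` (default) or `"pooled_complement"`.
#' @return Data frame of selected genes: `gene`, `direction` (+1 up in the
#'   target, -1 down), `min_abs_lfc` (smallest |log2FC| over the
#'   comparisons), `max_fdr` (largest FDR over the comparisons).
#' @export
specific_genes <- function(expr, meta, population, target,
                           fc_min = 2, alpha_fdr = 0.01, pseudocount = 1,
                           test = c("anova", "welch", "pooled"),
                           stages = default_stages(),
                           stage_mode = c("per_timepoint",
                                          "pooled_complement")) {
  test <- match.arg(test)
  stage_mode <- match.arg(stage_mode)
  population <- match.arg(population, populations())
  meta <- validate_metadata(meta, NULL)
  if (!identical(meta$sample, colnames(expr)))
    meta <- meta[match(colnames(expr), meta$sample), , drop = FALSE]
  sc <- de_scales(expr, pseudocount)
  check_stages(stages)
  if (target %in% time_points()) {
    members <- target
  } else if (target %in% names(stages)) {
    members <- stages[[target]]
  } else stop("unknown target: ", target)
  others <- setdiff(time_points(), members)
  if (length(others) == 0) stop("target covers all time points; no complement")
  pop_idx <- which(meta$population == population)
  in_target <- pop_idx[meta$time_point[pop_idx] %in% members]
  if (length(in_target) < 2)
    stop("target has < 2 replicates in population ", population)
  comp_groups <- if (stage_mode == "pooled_complement" &&
                       !(target %in% time_points())) {
    list(complement = pop_idx[meta$time_point[pop_idx] %in% others])
  } else {
    setNames(lapply(others, function(tp)
      pop_idx[meta$time_point[pop_idx] == tp]), others)
  }
  ng <- nrow(expr)
  mse <- if (test == "anova")
    row_condition_mse(sc$log, paste(meta$population, meta$time_point,
                                    sep = "."))
  lfc <- p <- matrix(NA_real_, ng, length(comp_groups),
                     dimnames = list(rownames(expr), names(comp_groups)))
  for (j in seq_along(comp_groups)) {
    idx <- comp_groups[[j]]
    if (length(idx) < 2) {
      warning("skipping comparison vs ", names(comp_groups)[j],
              ": < 2 replicates")
      next
    }
    tt <- if (test == "anova")
      row_contrast_ttest(sc$log[, in_target, drop = FALSE],
                         sc$log[, idx, drop = FALSE], mse, mse$df)
    else row_ttest(sc$log[, in_target, drop = FALSE],
                   sc$log[, idx, drop = FALSE], pooled = test == "pooled")
    p[, j] <- tt$p
    lfc[, j] <- compute_fold_change(
      rowMeans(sc$cpm[, in_target, drop = FALSE]),
      rowMeans(sc$cpm[, idx, drop = FALSE]), pseudocount)
  }
  fdr <- matrix(bh_adjust(as.vector(p)), ng, ncol(p), dimnames = dimnames(p))
  called <- !is.na(fdr) & fdr < alpha_fdr & abs(lfc) >= log2(fc_min)
  all_called <- rowSums(called) == ncol(called)
  same_dir <- abs(rowSums(sign(lfc))) == ncol(lfc)
  sel <- which(all_called & same_dir)
  data.frame(gene = rownames(expr)[sel],
             direction = as.integer(sign(rowSums(sign(lfc))[sel])),
             min_abs_lfc = apply(abs(lfc), 1, min)[sel],
             max_fdr = apply(fdr, 1, max)[sel],
             row.names = NULL, stringsAsFactors = FALSE)
}

pct1 <- function(num, den) {
  if (is.na(den) || den <= 0) return(NA_real_)
  round(100 * num / den, 1)
}

#' Accounting identities over headline counts
#'
#' Pure arithmetic over the classification counts: every percentage is
#' reported at one-decimal rounding against its reference denominator, and
#' the spatial/temporal union is derived by inclusion-exclusion.
#'
#' @param n_universe Genes surviving the expression filter.
#' @param n_anova_de Genes passing the omnibus ANOVA FDR filter.
#' @param n_spatial,n_temporal,n_both Spatially DE, temporally DE, and
#'   both-spatially-and-temporally DE gene counts (within the ANOVA set).
#' @param n_luminal,n_basal,n_switching Specificity partition of the spatial
#'   set.
#' @param n_always_luminal,n_always_basal Genes specific to one population at
#'   every time point.
#' @param unique_timepoint_stage_de Optional named vector (per population) of
#'   unique DE genes across that population's time-point- and stage-specific
#'   sets.
#' @return List of class `"st_accounting"` with all counts and percentages.
#' @export
accounting_identities <- function(n_universe, n_anova_de,
                                  n_spatial, n_temporal, n_both,
                                  n_luminal = NA, n_basal = NA,
                                  n_switching = NA,
                                  n_always_luminal = NA, n_always_basal = NA,
                                  unique_timepoint_stage_de = NULL) {
  if (!is.na(n_both) && n_both > min(n_spatial, n_temporal))
    stop("n_both exceeds min(n_spatial, n_temporal)")
  n_union <- n_spatial + n_temporal - n_both
  out <- list(
    n_universe = n_universe,
    n_anova_de = n_anova_de,
    pct_anova_de = pct1(n_anova_de, n_universe),
    n_spatial = n_spatial,
    pct_spatial = pct1(n_spatial, n_anova_de),
    n_temporal = n_temporal,
    pct_temporal = pct1(n_temporal, n_anova_de),
    n_both = n_both,
    pct_both = pct1(n_both, n_anova_de),
    pct_spatial_also_temporal = pct1(n_both, n_spatial),
    n_union = n_union,
    pct_union = pct1(n_union, n_anova_de),
    n_luminal = n_luminal,
    pct_luminal = pct1(n_luminal, n_spatial),
    n_basal = n_basal,
    pct_basal = pct1(n_basal, n_spatial),
    n_switching = n_switching,
    pct_switching = pct1(n_switching, n_spatial),
    n_always_luminal = n_always_luminal,
    pct_always_luminal = pct1(n_always_luminal, n_luminal),
    n_always_basal = n_always_basal,
    pct_always_basal = pct1(n_always_basal, n_basal),
    unique_timepoint_stage_de = unique_timepoint_stage_de
  )
  structure(out, class = "st_accounting")
}

#' Accounting report from a gene classification
#'
#' @param classification Data frame as assembled by [st_fit()] (columns
#'   `anova_de`, `spatial_de`, `temporal_de`, `specificity`,
#'   `always_specific`).
#' @param specific_sets Optional nested list `specific_sets[[population]]`
#'   of per-target gene vectors/data frames, used for the per-population
#'   unique DE gene counts.
#' @param n_universe Universe size (default: rows of `classification`).
#' @return An `"st_accounting"` list; see [accounting_identities()].
#' @export
accounting_report <- function(classification, specific_sets = NULL,
                              n_universe = nrow(classification)) {
  cl <- classification
  de <- cl[cl$anova_de, , drop = FALSE]
  uniq <- NULL
  if (!is.null(specific_sets)) {
    uniq <- vapply(specific_sets, function(targets) {
      genes <- unlist(lapply(targets, function(t)
        if (is.data.frame(t)) t$gene else t), use.names = FALSE)
      length(unique(genes))
    }, 0L)
  }
  accounting_identities(
    n_universe = n_universe,
    n_anova_de = sum(cl$anova_de),
    n_spatial = sum(de$spatial_de),
    n_temporal = sum(de$temporal_de),
    n_both = sum(de$spatial_de & de$temporal_de),
    n_luminal = sum(de$specificity == "luminal"),
    n_basal = sum(de$specificity == "basal"),
    n_switching = sum(de$specificity == "switching"),
    n_always_luminal = sum(de$specificity == "luminal" & de$always_specific),
    n_always_basal = sum(de$specificity == "basal" & de$always_specific),
    unique_timepoint_stage_de = uniq
  )
}

#' @export
print.st_accounting <- function(x, ...) {
  cat("Spatio-temporal DE accounting\n")
  cat(sprintf("  universe: %d genes\n", x$n_universe))
  cat(sprintf("  ANOVA DE: %d (%.1f%% of universe)\n",
              x$n_anova_de, x$pct_anova_de))
  cat(sprintf("  spatial DE: %d (%.1f%%)   temporal DE: %d (%.1f%%)\n",
              x$n_spatial, x$pct_spatial, x$n_temporal, x$pct_temporal))
  cat(sprintf("  both: %d (%.1f%% of ANOVA DE; %.1f%% of spatial)\n",
              x$n_both, x$pct_both, x$pct_spatial_also_temporal))
  cat(sprintf("  union: %d (%.1f%%)\n", x$n_union, x$pct_union))
  if (!is.na(x$n_luminal))
    cat(sprintf(
      "  specificity: luminal %d (%.1f%%), basal %d (%.1f%%), switching %d (%.1f%%)\n",
      x$n_luminal, x$pct_luminal, x$n_basal, x$pct_basal,
      x$n_switching, x$pct_switching))
  if (!is.na(x$n_always_luminal))
    cat(sprintf(
      "  always-specific: luminal %d (%.1f%% of luminal), basal %d (%.1f%% of basal)\n",
      x$n_always_luminal, x$pct_always_luminal,
      x$n_always_basal, x$pct_always_basal))
  if (!is.null(x$unique_timepoint_stage_de))
    cat("  unique time-point/stage DE genes:",
        paste(names(x$unique_timepoint_stage_de),
              x$unique_timepoint_stage_de, sep = " = ", collapse = ", "),
        "\n")
  invisible(x)
}
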