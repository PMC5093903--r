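#' Per-condition expression trajectories
#'
#' For each requested gene and each (population, time point) condition:
#' mean CPM across biological replicates, standard error (sample sd /
#' sqrt(n); `NA` when n = 1) and replicate count — the numbers behind
#' trajectory plots.
#'
#' @param expr CPM matrix.
#' @param meta Sample metadata aligned with `expr` columns.
#' @param genes Gene ids to tabulate; unknown ids are an error.
#' @return Data frame: `gene`, `population`, `time_point`, `mean_cpm`, `se`,
#'   `n`.
#' @export
trajectory_table <- function(expr, meta, genes) {
  if (expr_scale(expr) != "cpm") stop("trajectory_table expects a CPM matrix")
  meta <- validate_metadata(meta, NULL)
  if (!identical(meta$sample, colnames(expr)))
    meta <- meta[match(colnames(expr), meta$sample), , drop = FALSE]
  unknown <- setdiff(genes, rownames(expr))
  if (length(unknown) > 0)
    stop("unknown gene id(s): ", paste(unknown, collapse = ", "))
  conds <- unique(meta[, c("population", "time_point")])
  rows <- lapply(seq_len(nrow(conds)), function(i) {
    idx <- which(meta$population == conds$population[i] &
                   meta$time_point == conds$time_point[i])
    vals <- expr[genes, idx, drop = FALSE]
    n <- length(idx)
    data.frame(gene = genes,
               population = conds$population[i],
               time_point = conds$time_point[i],
               mean_cpm = rowMeans(vals),
               se = if (n > 1) apply(vals, 1, stats::sd) / sqrt(n)
                    else NA_real_,
               n = n, row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$gene, out$population,
            match(out$time_point, time_points())), , drop = FALSE]
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  has_input <- !is.null(config$input)
  has_sim <- !is.null(config$simulate)
  if (has_input == has_sim)
    stop("config must contain exactly one of 'input' and 'simulate'")
  if (has_input) {
    for (f in c("counts", "metadata")) {
      if (is.null(config$input[[f]]))
        stop("config input block missing '", f, "'")
      if (!file.exists(config$input[[f]]))
        stop("input file not found: ", config$input[[f]])
    }
  }
  config
}

#' Run the full analysis pipeline from a single configuration
#'
#' Executes simulate/read, preprocessing, PCA QC with covariate association
#' (and optional outlier removal), the spatio-temporal DE fit, optional GMT
#' enrichment of the specificity classes, and writes all result tables plus
#' a machine-readable manifest to `out_dir`. Reruns with the same config
#' (including the seed) are byte-identical.
#'
#' Config (list or YAML path): exactly one of
#' \describe{
#'   \item{input}{`counts`, `metadata` (TSV paths), optional `gene_sets`
#'     (GMT path)}
#'   \item{simulate}{arguments for [sim_config()]}
#' }
#' plus optional blocks `preprocess` (`min_cpm`, `min_samples`,
#' `pseudocount`), `qc` (`n_components`, `outlier_threshold`,
#' `remove_outliers`), `de` (`alpha_fdr`, `fc_min`, `test`, `stage_mode`,
#' `specific_targets`), `enrichment` (`alpha`), and a top-level `seed`
#' (overrides the simulate block's).
#'
#' @param config List or YAML file path.
#' @param out_dir Output directory (created if needed).
#' @return The `"st_fit"` object, invisibly, with the manifest attached as
#'   attribute `"manifest"`.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  gp <- function(block, key, default) {
    v <- config[[block]][[key]]
    if (is.null(v)) default else v
  }

  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (!is.null(config$seed)) sim_args$seed <- config$seed
    bundle <- simulate_dataset(do.call(sim_config, sim_args))
    counts <- bundle$counts
    meta <- bundle$metadata
    utils::write.table(bundle$truth, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    counts <- read_counts(config$input$counts)
    meta <- read_metadata(config$input$metadata, counts)
  }

  pseudocount <- gp("preprocess", "pseudocount", 1)
  fit <- st_fit(
    counts, meta,
    min_cpm = gp("preprocess", "min_cpm", 1),
    min_samples = gp("preprocess", "min_samples", 2),
    pseudocount = pseudocount,
    alpha_fdr = gp("de", "alpha_fdr", 0.01),
    fc_min = gp("de", "fc_min", 2),
    test = gp("de", "test", "welch"),
    stage_mode = gp("de", "stage_mode", "per_timepoint"),
    specific_targets = gp("de", "specific_targets", "all"),
    remove_outliers = gp("qc", "remove_outliers", FALSE),
    outlier_threshold = gp("qc", "outlier_threshold", 0.8))

  logcpm <- log_transform(fit$cpm, pseudocount)
  pca <- run_pca(logcpm)
  n_comp <- gp("qc", "n_components", 10)
  assoc <- associate_covariates(pca, fit$metadata, n_components = n_comp)

  enr <- NULL
  if (!is.null(config$input$gene_sets)) {
    refs <- read_gmt(config$input$gene_sets)
    cls <- fit$classification
    queries <- list(
      luminal_specific = cls$gene[cls$specificity == "luminal"],
      basal_specific = cls$gene[cls$specificity == "basal"],
      switching = cls$gene[cls$specificity == "switching"])
    queries <- queries[lengths(queries) > 0]
    if (length(queries) > 0)
      enr <- enrichment_matrix(queries, refs, fit$universe,
                               alpha = gp("enrichment", "alpha", 0.01))
  }

  wt <- function(x, file) utils::write.table(
    x, file.path(out_dir, file), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(fit$anova, "de_stats.tsv")
  wt(fit$classification, "classification.tsv")
  wt(data.frame(sample = rownames(pca$scores),
                round(pca$scores[, seq_len(min(10, ncol(pca$scores))),
                                 drop = FALSE], 6)), "pca_scores.tsv")
  wt(data.frame(component = seq_along(pca$explained_fraction),
                explained_fraction = round(pca$explained_fraction, 8)),
     "scree.tsv")
  wt(data.frame(covariate = rownames(assoc),
                kind = attr(assoc, "covariate_kind"),
                signif(assoc, 6), check.names = FALSE),
     "covariate_pvalues.tsv")
  writeLines(fit$outliers$sample, file.path(out_dir, "outliers.txt"))
  if (!is.null(enr)) wt(enr, "enrichment.tsv")
  if (!is.null(fit$specific_sets)) {
    dir.create(file.path(out_dir, "specific_sets"), showWarnings = FALSE)
    for (pop in names(fit$specific_sets))
      for (tg in names(fit$specific_sets[[pop]]))
        writeLines(fit$specific_sets[[pop]][[tg]]$gene,
                   file.path(out_dir, "specific_sets",
                             paste0(pop, "_", tg, ".txt")))
  }
  traj_genes <- utils::head(fit$classification$gene[
    fit$classification$spatial_de], 20)
  if (length(traj_genes) > 0)
    wt(trajectory_table(fit$cpm, fit$metadata, traj_genes),
       "trajectories.tsv")

  acc <- fit$accounting
  acc_json <- acc[!vapply(acc, is.null, TRUE)]
  class(acc_json) <- NULL
  jsonlite::write_json(acc_json, file.path(out_dir, "accounting.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package = "spatempo",
    version = as.character(utils::packageVersion("spatempo")),
    seed = config$seed,
    config_hash = digest_config(config),
    n_samples = nrow(fit$metadata),
    n_genes_input = nrow(counts),
    n_universe = length(fit$universe),
    n_anova_de = acc$n_anova_de,
    n_spatial = acc$n_spatial,
    n_temporal = acc$n_temporal,
    outliers = fit$outliers$sample)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(fit, "manifest") <- manifest
  invisible(fit)
}

# Stable fingerprint of the (serialised) config for the manifest; a plain
# sum over the serialised bytes is enough to detect config drift.
digest_config <- function(config) {
  raw <- serialize(config, NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw)) %% .Machine$integer.max,
          length(raw))
}
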