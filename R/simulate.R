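#' Simulation configuration
#'
#' Builds the configuration for [simulate_dataset()]. Defaults reproduce the
#' study design this package models: 2 populations x 8 time points x 3
#' biological replicates, except a single missing replicate at lactation day
#' 10 (basal), for 47 samples in 16 conditions. Counts are negative-binomial
#' with a constant dispersion; baseline expression is log-normal on the CPM
#' scale; library sizes are log-uniform; technical covariates are assigned
#' round-robin by sample index.
#'
#' Archetypes planted per gene:
#' \describe{
#'   \item{null}{no condition effect}
#'   \item{population_specific}{up in one population at every time point}
#'   \item{timepoint_specific}{up in one population at one time point}
#'   \item{stage_specific}{up in one population across one stage's time points}
#'   \item{switching}{up in luminal at one time point and up in basal at a
#'     different time point}
#' }
#'
#' @param n_genes Number of genes to simulate.
#' @param mixture Named numeric vector of archetype proportions over
#'   `c("null","population_specific","timepoint_specific","stage_specific",
#'   "switching")`; must sum to 1. The default plants 10 percent effect
#'   genes in total, keeping the planted mass a small fraction of each
#'   library so that null genes stay flat after CPM renormalisation.
#' @param log2_effect Log2 shift applied to the mean of targeted conditions.
#' @param baseline_log2_mean,baseline_log2_sd Normal parameters of baseline
#'   log2 CPM expression.
#' @param dispersion Negative-binomial dispersion (alpha; variance =
#'   mu + alpha mu^2), constant across genes.
#' @param lib_size_range Range of per-sample library sizes (log-uniform draw).
#' @param replicates Replicates per condition; the `l10_basal_replicates`
#'   exception is applied on top.
#' @param l10_basal_replicates Replicates for the basal population at L10
#'   (default 2, giving the 47-sample design).
#' @param batch_log2_effect Additive log2 batch effect applied to a subset of
#'   genes for samples in odd-numbered batches (default 0 = none).
#' @param batch_gene_fraction Fraction of genes carrying the batch effect.
#' @param n_batches,n_lanes,n_amp_batches,n_sorting_times Numbers of levels of
#'   the round-robin technical covariates.
#' @param stages Stage table used to draw stage-specific targets.
#' @param seed Integer seed; simulation is deterministic given the config.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(n_genes = 2000,
                       mixture = c(null = 0.9,
                                   population_specific = 0.025,
                                   timepoint_specific = 0.025,
                                   stage_specific = 0.025, switching = 0.025),
                       log2_effect = 4,
                       baseline_log2_mean = 5, baseline_log2_sd = 2,
                       dispersion = 0.1,
                       lib_size_range = c(0.5e6, 2e6),
                       replicates = 3, l10_basal_replicates = 2,
                       batch_log2_effect = 0, batch_gene_fraction = 0.2,
                       n_batches = 4, n_lanes = 8, n_amp_batches = 5,
                       n_sorting_times = 16,
                       stages = default_stages()[c("lactogenesis",
                                                   "lact-invo", "lacto-invo")],
                       seed = 1) {
  arch <- c("null", "population_specific", "timepoint_specific",
            "stage_specific", "switching")
  if (!setequal(names(mixture), arch))
    stop("mixture must be named over the five archetypes")
  mixture <- mixture[arch]
  if (abs(sum(mixture) - 1) > 1e-8)
    stop("archetype mixture proportions must sum to 1")
  if (dispersion <= 0) stop("dispersion must be > 0")
  if (n_genes < 1) stop("n_genes must be positive")
  check_stages(stages)
  structure(list(
    n_genes = n_genes, mixture = mixture, log2_effect = log2_effect,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    dispersion = dispersion, lib_size_range = lib_size_range,
    replicates = replicates, l10_basal_replicates = l10_basal_replicates,
    batch_log2_effect = batch_log2_effect,
    batch_gene_fraction = batch_gene_fraction,
    n_batches = n_batches, n_lanes = n_lanes,
    n_amp_batches = n_amp_batches, n_sorting_times = n_sorting_times,
    stages = stages, seed = seed
  ), class = "sim_config")
}

# Metadata of the simulated design: one row per sample with round-robin
# technical covariates.
sim_design <- function(config) {
  rows <- list()
  for (pop in populations()) {
    for (tp in time_points()) {
      n <- if (pop == "basal" && tp == "L10")
        config$l10_basal_replicates else config$replicates
      if (n < 1) next
      rows[[length(rows) + 1L]] <- data.frame(
        sample = paste(pop, tp, seq_len(n), sep = "_"),
        population = pop, time_point = tp, replicate = seq_len(n),
        stringsAsFactors = FALSE)
    }
  }
  meta <- do.call(rbind, rows)
  i <- seq_len(nrow(meta)) - 1L
  meta$batch <- paste0("b", (i %% config$n_batches) + 1L)
  meta$lane <- paste0("lane", (i %% config$n_lanes) + 1L)
  meta$rna_amp_batch <- paste0("amp", (i %% config$n_amp_batches) + 1L)
  meta$sorting_time <- paste0("sort", (i %% config$n_sorting_times) + 1L)
  rownames(meta) <- NULL
  meta
}

#' Simulate a count matrix with planted ground truth
#'
#' Draws per-gene baseline expression, plants archetype effects on the
#' condition-mean matrix, renormalises each condition's true means to CPM
#' scale (sum 1e6), and samples negative-binomial counts with per-sample
#' library sizes. Deterministic given the config (including its seed); the
#' caller's RNG state is restored on exit.
#'
#' @param config A [sim_config()].
#' @return List with elements `counts` (genes x samples integer matrix),
#'   `metadata` (data frame), `truth` (per-gene archetype, target population,
#'   target time points, log2 effect) and `true_cpm` (genes x conditions true
#'   mean CPM matrix, condition names `population.time_point`).
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  ng <- config$n_genes
  genes <- sprintf("gene_%05d", seq_len(ng))
  meta <- sim_design(config)
  conds <- expand.grid(population = populations(),
                       time_point = time_points(),
                       stringsAsFactors = FALSE)
  cond_names <- paste(conds$population, conds$time_point, sep = ".")

  # archetype assignment: largest-remainder apportionment, then shuffled
  n_arch <- floor(config$mixture * ng)
  rem <- ng - sum(n_arch)
  if (rem > 0) {
    frac <- config$mixture * ng - floor(config$mixture * ng)
    top <- order(frac, decreasing = TRUE)[seq_len(rem)]
    n_arch[top] <- n_arch[top] + 1L
  }
  archetype <- sample(rep(names(n_arch), times = n_arch))

  base_log2 <- stats::rnorm(ng, config$baseline_log2_mean,
                            config$baseline_log2_sd)
  log2_mu <- matrix(base_log2, nrow = ng, ncol = nrow(conds),
                    dimnames = list(genes, cond_names))

  eff <- config$log2_effect
  truth <- data.frame(gene = genes, archetype = archetype,
                      population = NA_character_, targets = NA_character_,
                      log2_effect = 0, stringsAsFactors = FALSE)
  cond_cols <- function(pop, tps) which(conds$population == pop &
                                          conds$time_point %in% tps)
  tp_cycle <- 0L; st_cycle <- 0L; sw_cycle <- 0L; pop_cycle <- 0L
  tps <- time_points()
  # Effects are planted by suppressing the complement: the gene keeps its
  # baseline in the target conditions and sits log2_effect lower everywhere
  # else. The target-vs-rest contrast is the same as an up-shift, but each
  # gene's contribution to any library is bounded by its baseline, so null
  # genes stay flat after the per-condition CPM renormalisation even when an
  # abundant gene draws an effect.
  for (g in which(archetype != "null")) {
    a <- archetype[g]
    if (a == "population_specific") {
      pop <- populations()[(pop_cycle %% 2L) + 1L]; pop_cycle <- pop_cycle + 1L
      target <- cond_cols(pop, tps)
      truth$population[g] <- pop
      truth$targets[g] <- paste(tps, collapse = ",")
    } else if (a == "timepoint_specific") {
      pop <- populations()[(tp_cycle %% 2L) + 1L]
      tp <- tps[((tp_cycle %/% 2L) %% 8L) + 1L]; tp_cycle <- tp_cycle + 1L
      target <- cond_cols(pop, tp)
      truth$population[g] <- pop
      truth$targets[g] <- tp
    } else if (a == "stage_specific") {
      pop <- populations()[(st_cycle %% 2L) + 1L]
      st <- ((st_cycle %/% 2L) %% length(config$stages)) + 1L
      st_cycle <- st_cycle + 1L
      target <- cond_cols(pop, config$stages[[st]])
      truth$population[g] <- pop
      truth$targets[g] <- names(config$stages)[st]
    } else if (a == "switching") {
      tp_a <- tps[(sw_cycle %% 8L) + 1L]
      tp_b <- tps[((sw_cycle + 3L) %% 8L) + 1L]  # offset keeps them disjoint
      sw_cycle <- sw_cycle + 1L
      target <- c(cond_cols("luminal", tp_a), cond_cols("basal", tp_b))
      truth$population[g] <- "luminal|basal"
      truth$targets[g] <- paste0("luminal:", tp_a, "|basal:", tp_b)
    }
    log2_mu[g, -target] <- log2_mu[g, -target] - eff
    truth$log2_effect[g] <- eff
  }

  # renormalise each condition's true means to the CPM scale so empirical
  # CPM converges to the planted truth
  mu_cpm <- 2^log2_mu
  mu_cpm <- sweep(mu_cpm, 2, colSums(mu_cpm), "/") * 1e6

  lib <- exp(stats::runif(nrow(meta), log(config$lib_size_range[1]),
                          log(config$lib_size_range[2])))
  cond_of_sample <- match(paste(meta$population, meta$time_point, sep = "."),
                          cond_names)

  batch_genes <- rep(FALSE, ng)
  if (config$batch_log2_effect != 0) {
    nb <- max(1L, round(config$batch_gene_fraction * ng))
    batch_genes[sample.int(ng, nb)] <- TRUE
  }
  batch_hit <- as.integer(sub("^b", "", meta$batch)) %% 2L == 1L

  counts <- matrix(0L, nrow = ng, ncol = nrow(meta),
                   dimnames = list(genes, meta$sample))
  size <- 1 / config$dispersion
  for (j in seq_len(nrow(meta))) {
    mu <- mu_cpm[, cond_of_sample[j]] * lib[j] / 1e6
    if (config$batch_log2_effect != 0 && batch_hit[j])
      mu[batch_genes] <- mu[batch_genes] * 2^config$batch_log2_effect
    counts[, j] <- stats::rnbinom(ng, mu = mu, size = size)
  }

  list(counts = counts, metadata = meta, truth = truth, true_cpm = mu_cpm)
}

#' Write a simulated bundle as plain-text fixture files
#'
#' @param bundle Result of [simulate_dataset()].
#' @param out_dir Output directory (created if absent). Writes `counts.tsv`,
#'   `metadata.tsv` and `truth.tsv`, readable by [read_counts()] and
#'   [read_metadata()].
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture <- function(bundle, out_dir) {
  if (is.null(bundle$counts) || nrow(bundle$counts) == 0)
    stop("bundle has no genes")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(counts = file.path(out_dir, "counts.tsv"),
             metadata = file.path(out_dir, "metadata.tsv"),
             truth = file.path(out_dir, "truth.tsv"))
  write_counts(bundle$counts, paths["counts"])
  write_metadata(bundle$metadata, paths["metadata"])
  utils::write.table(bundle$truth, paths["truth"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
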