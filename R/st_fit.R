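#' Fit the spatio-temporal differential-expression model
#'
#' The package's main entry point. Runs the full inference on a raw count
#' matrix from a two-population developmental time course:
#' \enumerate{
#'   \item CPM normalisation and low-expression filtering (the "normalized
#'     genes" universe);
#'   \item optionally, correlation-based outlier removal;
#'   \item omnibus one-way ANOVA across the population x time-point
#'     conditions with BH-FDR, retaining genes DE in at least one condition;
#'   \item per-time-point spatial (basal vs luminal) and per-time-point-pair
#'     temporal calls on the ANOVA-passing genes, each requiring
#'     FDR < `alpha_fdr` and a fold change of at least `fc_min`;
#'   \item classification into luminal-specific, basal-specific and
#'     switching genes, with always-specific flags;
#'   \item all-pairwise time-point- and stage-specific gene calling per
#'     population;
#'   \item the accounting report of all headline counts and percentages.
#' }
#'
#' @param counts Raw count matrix (genes x samples) or path readable by
#'   [read_counts()].
#' @param metadata Sample metadata data frame or TSV path (see
#'   [read_metadata()]).
#' @param min_cpm,min_samples Expression filter (see
#'   [filter_low_expression()]).
#' @param pseudocount Pseudocount for log2 CPM and fold changes.
#' @param alpha_fdr BH-FDR threshold for every call family (default 0.01).
#' @param fc_min Minimum fold change for spatial/temporal/specific calls
#'   (default 2).
#' @param test Per-comparison test for the spatial/temporal/specific calls:
#'   `"anova"` (default; condition-model contrast t), `"welch"` or
#'   `"pooled"` (see [spatial_de_calls()]).
#' @param stages Stage table for stage-specific calling (see
#'   [default_stages()]).
#' @param stage_mode Stage comparison mode (see [specific_genes()]).
#' @param specific_targets Targets for specificity calling: `"all"` (eight
#'   time points plus all stages), `"timepoints"`, `"none"`, or a character
#'   vector of targets.
#' @param remove_outliers Drop correlation outliers before testing.
#' @param outlier_threshold Median-correlation threshold (see
#'   [detect_outliers()]).
#' @return An object of class `"st_fit"`: list with `universe`, `dropped`,
#'   `cpm`, `anova`, `spatial`, `temporal`, `classification`,
#'   `specific_sets` (nested population -> target), `accounting`,
#'   `outliers`, `metadata` and the call parameters.
#' @seealso [summary.st_fit()], [plot.st_fit()], [simulate_dataset()]
#' @export
st_fit <- function(counts, metadata,
                   min_cpm = 1, min_samples = 2, pseudocount = 1,
                   alpha_fdr = 0.01, fc_min = 2,
                   test = c("anova", "welch", "pooled"),
                   stages = default_stages(),
                   stage_mode = c("per_timepoint", "pooled_complement"),
                   specific_targets = "all",
                   remove_outliers = FALSE, outlier_threshold = 0.8) {
  test <- match.arg(test)
  stage_mode <- match.arg(stage_mode)
  if (is.character(counts) && length(counts) == 1) counts <- read_counts(counts)
  if (is.character(metadata) && length(metadata) == 1)
    metadata <- read_metadata(metadata)
  validate_counts(counts)
  meta <- validate_metadata(metadata, counts)
  check_stages(stages)

  cpm_all <- cpm_normalize(counts)
  outliers <- detect_outliers(log_transform(cpm_all, pseudocount),
                              threshold = outlier_threshold)
  if (remove_outliers && nrow(outliers) > 0) {
    keep <- !(colnames(counts) %in% outliers$sample)
    counts <- counts[, keep, drop = FALSE]
    meta <- meta[keep, , drop = FALSE]
    cpm_all <- cpm_normalize(counts)
  }

  filt <- filter_low_expression(cpm_all, min_cpm, min_samples)
  cpm <- filt$expr
  universe <- rownames(cpm)

  an <- anova_filter(cpm, meta, alpha_fdr, pseudocount)
  de_genes <- an$gene[an$anova_de]

  cpm_de <- cpm[de_genes, , drop = FALSE]
  attr(cpm_de, "scale_tag") <- "cpm"
  spatial <- spatial_de_calls(cpm_de, meta, fc_min, alpha_fdr,
                              pseudocount, test)
  temporal <- temporal_de_calls(cpm_de, meta, fc_min, alpha_fdr,
                                pseudocount, test)

  spec <- classify_specificity(spatial)
  temporal_de <- rowSums(temporal$call, na.rm = TRUE) > 0

  classification <- data.frame(
    gene = universe,
    anova_de = an$anova_de,
    spatial_de = FALSE, temporal_de = FALSE,
    specificity = "none", always_specific = FALSE,
    stringsAsFactors = FALSE)
  i <- match(de_genes, classification$gene)
  classification$spatial_de[i] <- spec$spatial_de
  classification$temporal_de[i] <- temporal_de
  classification$specificity[i] <- spec$specificity
  classification$always_specific[i] <- spec$always_specific

  targets <- if (identical(specific_targets, "all")) {
    c(time_points(), names(stages))
  } else if (identical(specific_targets, "timepoints")) {
    time_points()
  } else if (identical(specific_targets, "none")) {
    character(0)
  } else specific_targets
  specific_sets <- NULL
  if (length(targets) > 0) {
    specific_sets <- lapply(setNames(populations(), populations()),
                            function(pop) {
      lapply(setNames(targets, targets), function(tg)
        specific_genes(cpm_de, meta, pop, tg, fc_min, alpha_fdr,
                       pseudocount, test, stages, stage_mode))
    })
  }

  accounting <- accounting_report(classification, specific_sets)

  structure(list(
    universe = universe, dropped = filt$dropped,
    cpm = cpm, anova = an, spatial = spatial, temporal = temporal,
    classification = classification, specific_sets = specific_sets,
    accounting = accounting, outliers = outliers, metadata = meta,
    params = list(min_cpm = min_cpm, min_samples = min_samples,
                  pseudocount = pseudocount, alpha_fdr = alpha_fdr,
                  fc_min = fc_min, test = test, stages = stages,
                  stage_mode = stage_mode,
                  remove_outliers = remove_outliers,
                  outlier_threshold = outlier_threshold)
  ), class = "st_fit")
}

#' @export
print.st_fit <- function(x, ...) {
  a <- x$accounting
  cat("Spatio-temporal DE fit:", length(x$universe), "genes x",
      nrow(x$metadata), "samples (", length(x$dropped), "genes filtered )\n")
  cat(sprintf("  ANOVA DE (FDR < %g): %d (%.1f%%)\n",
              x$params$alpha_fdr, a$n_anova_de, a$pct_anova_de))
  cat(sprintf("  spatial %d, temporal %d, both %d, union %d\n",
              a$n_spatial, a$n_temporal, a$n_both, a$n_union))
  if (nrow(x$outliers) > 0) {
    shown <- utils::head(x$outliers$sample, 5)
    more <- nrow(x$outliers) - length(shown)
    cat("  flagged outliers (", nrow(x$outliers), "): ",
        paste(shown, collapse = ", "),
        if (more > 0) paste0(" ... +", more), " ",
        if (x$params$remove_outliers) "(removed)\n" else "(kept)\n",
        sep = "")
  }
  invisible(x)
}

#' Summary of a spatio-temporal DE fit
#'
#' @param object An `"st_fit"`.
#' @param ... Unused.
#' @return The fit's `"st_accounting"` report, printed and returned
#'   invisibly.
#' @export
summary.st_fit <- function(object, ...) {
  print(object$accounting)
  invisible(object$accounting)
}

#' Expression trajectories of selected genes
#'
#' Plots the mean CPM per condition with standard-error bars, one panel per
#' gene, luminal and basal traces overlaid across the developmental time
#' points — the standard trajectory display for this design.
#'
#' @param x An `"st_fit"`.
#' @param genes Character vector of gene ids to plot (default: first gene).
#' @param ... Passed to [graphics::plot()].
#' @return The trajectory table used, invisibly.
#' @export
plot.st_fit <- function(x, genes = x$universe[1], ...) {
  tab <- trajectory_table(x$cpm, x$metadata, genes)
  tps <- time_points()
  old <- graphics::par(mfrow = c(1, length(genes)))
  on.exit(graphics::par(old))
  cols <- c(luminal = "#1b9e77", basal = "#d95f02")
  for (g in genes) {
    sub <- tab[tab$gene == g, ]
    ylim <- range(0, sub$mean_cpm + ifelse(is.na(sub$se), 0, sub$se))
    graphics::plot(NA, xlim = c(1, length(tps)), ylim = ylim, xaxt = "n",
                   xlab = "time point", ylab = "mean CPM", main = g, ...)
    graphics::axis(1, at = seq_along(tps), labels = tps, las = 2)
    for (pop in populations()) {
      d <- sub[sub$population == pop, ]
      d <- d[match(tps, d$time_point), ]
      graphics::lines(seq_along(tps), d$mean_cpm, col = cols[pop], type = "b",
                      pch = 16)
      se <- ifelse(is.na(d$se), 0, d$se)
      graphics::arrows(seq_along(tps), d$mean_cpm - se,
                       seq_along(tps), d$mean_cpm + se,
                       angle = 90, code = 3, length = 0.03, col = cols[pop])
    }
  }
  graphics::legend("topleft", legend = populations(), col = cols, lty = 1,
                   pch = 16, bty = "n")
  invisible(tab)
}
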