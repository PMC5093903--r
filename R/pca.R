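#' Principal component analysis of an expression matrix
#'
#' PCA with samples as observations and genes as features, on the log2 CPM
#' matrix (centred; unscaled by default, the convention for log expression).
#' Component signs are fixed deterministically: each loading vector is
#' flipped so that its largest-magnitude entry is positive.
#'
#' @param expr log2 CPM matrix (genes x samples).
#' @param center,scale Passed to [stats::prcomp()].
#' @return List of class `"st_pca"` with `scores` (samples x components),
#'   `loadings` (genes x components) and `explained_fraction` (per component,
#'   sums to 1 over all non-degenerate components).
#' @export
run_pca <- function(expr, center = TRUE, scale = FALSE) {
  if (expr_scale(expr) != "log2cpm") stop("run_pca expects a log2cpm matrix")
  if (ncol(expr) < 2) stop("PCA requires at least 2 samples")
  if (scale) {
    sds <- apply(expr, 1, stats::sd)
    if (any(sds == 0)) expr <- expr[sds > 0, , drop = FALSE]
  }
  pc <- stats::prcomp(t(expr), center = center, scale. = scale)
  flip <- apply(pc$rotation, 2, function(v) {
    if (v[which.max(abs(v))] < 0) -1 else 1
  })
  scores <- sweep(pc$x, 2, flip, "*")
  loadings <- sweep(pc$rotation, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(scores = scores, loadings = loadings,
                 explained_fraction = ev / sum(ev)),
            class = "st_pca")
}

#' Flag outlier samples by pairwise Pearson correlation
#'
#' A sample is flagged when the median of its Pearson correlations with all
#' other samples falls below `threshold`. Samples with zero expression
#' variance (correlation undefined) are flagged with reason `"degenerate"`.
#'
#' @param expr Expression matrix (genes x samples; any scale).
#' @param method Only `"pearson_median"` is implemented.
#' @param threshold Minimum acceptable median correlation (default 0.8).
#' @return Data frame with columns `sample`, `median_correlation`, `reason`;
#'   zero rows when nothing is flagged.
#' @export
detect_outliers <- function(expr, method = "pearson_median", threshold = 0.8) {
  method <- match.arg(method, "pearson_median")
  if (ncol(expr) < 3) stop("outlier detection requires at least 3 samples")
  sds <- apply(expr, 2, stats::sd)
  degenerate <- sds == 0
  med <- rep(NA_real_, ncol(expr))
  ok <- which(!degenerate)
  if (length(ok) >= 2) {
    cc <- suppressWarnings(stats::cor(expr[, ok, drop = FALSE]))
    diag(cc) <- NA
    med[ok] <- apply(cc, 2, stats::median, na.rm = TRUE)
  }
  flag_low <- !degenerate & !is.na(med) & med < threshold
  out <- data.frame(
    sample = colnames(expr)[degenerate | flag_low],
    median_correlation = med[degenerate | flag_low],
    reason = ifelse(degenerate[degenerate | flag_low], "degenerate",
                    "low_correlation"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Associate covariates with principal components
#'
#' For each covariate and each of the leading principal components, tests the
#' association of the component scores with the covariate: one-way ANOVA
#' (F-test) for categorical covariates, simple linear-regression F-test for
#' numeric ones. Covariates with a single level among the retained samples
#' are recorded as `NA` (not testable) with a warning.
#'
#' @param pca Result of [run_pca()].
#' @param meta Sample metadata (rows aligned with the PCA's samples).
#' @param covariates Character vector of metadata column names to test;
#'   defaults to every metadata column except `sample`. Missing columns are
#'   skipped.
#' @param n_components Number of leading components to test (default 10,
#'   capped at the number available).
#' @return Matrix of p-values, covariates x components, with a
#'   `"covariate_kind"` attribute tagging rows `biological` (population,
#'   time_point, condition, stage) or `technical`.
#' @export
associate_covariates <- function(pca, meta, covariates = NULL,
                                 n_components = 10) {
  scores <- pca$scores
  if (nrow(scores) != nrow(meta))
    stop("metadata rows do not match PCA samples")
  if (is.null(covariates))
    covariates <- setdiff(names(meta), c("sample", "replicate"))
  covariates <- intersect(covariates, names(meta))
  if (length(covariates) == 0) stop("no covariates to test")
  k <- min(n_components, ncol(scores))
  pmat <- matrix(NA_real_, nrow = length(covariates), ncol = k,
                 dimnames = list(covariates, colnames(scores)[seq_len(k)]))
  for (cv in covariates) {
    x <- meta[[cv]]
    if (!is.numeric(x)) x <- factor(x)
    nlev <- if (is.factor(x)) nlevels(droplevels(x)) else
      length(unique(x))
    if (nlev < 2) {
      warning("covariate '", cv, "' has a single level; not testable")
      next
    }
    for (j in seq_len(k)) {
      fit <- stats::lm(scores[, j] ~ x)
      an <- stats::anova(fit)
      pmat[cv, j] <- an$`Pr(>F)`[1]
    }
  }
  biological <- c("population", "time_point", "condition", "stage",
                  "cell_type")
  attr(pmat, "covariate_kind") <- ifelse(rownames(pmat) %in% biological,
                                         "biological", "technical")
  pmat
}

#' @export
print.st_pca <- function(x, ...) {
  k <- min(5, length(x$explained_fraction))
  cat("PCA of", nrow(x$scores), "samples x", nrow(x$loadings), "genes\n")
  cat("Variance explained (first", k, "components):",
      paste0(sprintf("%.1f%%", 100 * x$explained_fraction[seq_len(k)]),
             collapse = ", "), "\n")
  invisible(x)
}
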