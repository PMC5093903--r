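expr_scale <- function(expr) {
  sc <- attr(expr, "scale_tag")
  if (is.null(sc)) stop("expression matrix lacks a scale_tag attribute")
  sc
}

#' Counts-per-million normalisation
#'
#' Scales each sample to counts per million: `cpm(g,s) = counts(g,s) /
#' library_size(s) * 1e6`, with library size the raw column total over all
#' genes (so CPM does not depend on any later gene filtering).
#'
#' @param counts Count matrix (genes x samples).
#' @return Numeric matrix with `scale_tag` attribute `"cpm"`; every column
#'   sums to 1e6.
#' @export
cpm_normalize <- function(counts) {
  validate_counts(counts)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  out <- sweep(counts, 2, lib, "/") * 1e6
  attr(out, "scale_tag") <- "cpm"
  attr(out, "library_sizes") <- lib
  out
}

#' Log2 transform of a CPM matrix
#'
#' @param expr CPM matrix from [cpm_normalize()].
#' @param pseudocount Positive offset added before the log (default 1, so a
#'   CPM of zero maps to zero).
#' @return Matrix of `log2(cpm + pseudocount)` with `scale_tag` `"log2cpm"`.
#' @export
log_transform <- function(expr, pseudocount = 1) {
  if (expr_scale(expr) != "cpm") stop("log_transform expects a CPM matrix")
  if (!is.numeric(pseudocount) || pseudocount <= 0)
    stop("pseudocount must be > 0")
  out <- log2(expr + pseudocount)
  attr(out, "scale_tag") <- "log2cpm"
  attr(out, "pseudocount") <- pseudocount
  out
}

#' Drop genes below an expression floor
#'
#' Keeps genes with CPM >= `min_cpm` in at least `min_samples` samples,
#' preserving gene order; the dropped ids are returned alongside.
#'
#' @param expr CPM matrix.
#' @param min_cpm Minimum CPM (default 1).
#' @param min_samples Minimum number of samples meeting `min_cpm` (default 2).
#' @return List with `expr` (filtered matrix, CPM scale) and `dropped`
#'   (character vector of removed gene ids).
#' @export
filter_low_expression <- function(expr, min_cpm = 1, min_samples = 2) {
  if (expr_scale(expr) != "cpm") stop("filter expects a CPM matrix")
  if (min_samples > ncol(expr))
    stop("min_samples exceeds the number of samples")
  keep <- rowSums(expr >= min_cpm) >= min_samples
  out <- expr[keep, , drop = FALSE]
  attr(out, "scale_tag") <- "cpm"
  attr(out, "library_sizes") <- attr(expr, "library_sizes")
  list(expr = out, dropped = rownames(expr)[!keep])
}
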