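#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (clipped at 1, order-preserving), delegating to
#' [stats::p.adjust()]. `NA` entries are passed through untouched so that
#' matrix-shaped families with skipped cells keep their layout.
#'
#' @param p Numeric vector of p-values in [0, 1] (NAs allowed).
#' @return Adjusted values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  out <- p
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Hypergeometric over-representation test
#'
#' Upper-tail (inclusive) hypergeometric test of the overlap between a query
#' gene set and a reference set within a universe: with N the universe size,
#' K the reference genes in the universe, n the query size and k the overlap,
#' p = P(X >= k) for X ~ Hypergeometric(N, K, n). Query and reference genes
#' outside the universe are dropped (and counted) before testing.
#'
#' @param query,reference Character vectors of gene ids.
#' @param universe Character vector of gene ids defining the background
#'   (typically the post-filter expression universe).
#' @return One-row data frame: `N`, `K`, `n`, `k`, `p_value`,
#'   `query_outside` and `reference_outside` (genes dropped at
#'   intersection).
#' @export
hypergeom_test <- function(query, reference, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) stop("empty universe")
  query <- unique(query); reference <- unique(reference)
  q_in <- intersect(query, universe)
  r_in <- intersect(reference, universe)
  N <- length(universe); K <- length(r_in); n <- length(q_in)
  k <- length(intersect(q_in, r_in))
  if (n == 0) {
    warning("query empty after intersection with universe; p set to 1")
    p <- 1
  } else {
    # P(X >= k), inclusive upper tail
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  }
  data.frame(N = N, K = K, n = n, k = k, p_value = p,
             query_outside = length(query) - n,
             reference_outside = length(reference) - K)
}

#' All-pairwise enrichment of query sets against reference sets
#'
#' Runs [hypergeom_test()] for every query x reference pair, adjusts the
#' whole grid as one Benjamini-Hochberg family, and flags significance at
#' raw p < `alpha` (mirroring significance display conventions for such
#' grids; use the `fdr` column for a principled cutoff).
#'
#' @param queries,references Named lists of gene-id vectors (see
#'   [read_gmt()]).
#' @param universe Background gene ids.
#' @param alpha Raw-p significance threshold for the `significant` flag
#'   (default 0.01).
#' @return Data frame with one row per pair: `query`, `reference`, `N`, `K`,
#'   `n`, `k`, `p_value`, `fdr`, `significant`.
#' @export
enrichment_matrix <- function(queries, references, universe, alpha = 0.01) {
  if (length(queries) == 0 || length(references) == 0)
    stop("empty gene-set collection")
  grid <- expand.grid(query = names(queries), reference = names(references),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i)
    hypergeom_test(queries[[grid$query[i]]],
                   references[[grid$reference[i]]], universe))
  out <- cbind(grid, do.call(rbind, rows))
  out$fdr <- bh_adjust(out$p_value)
  out$significant <- out$p_value < alpha
  out
}

#' Map gene ids through an ortholog table
#'
#' Two-column mapping (from, to), e.g. mouse-to-human symbols, for
#' cross-species enrichment; unmapped ids are dropped.
#'
#' @param genes Character vector of ids in the `from` namespace.
#' @param map Data frame or two-column TSV path with columns `from`, `to`.
#' @return Character vector of mapped ids (unique, order of first
#'   occurrence).
#' @export
map_orthologs <- function(genes, map) {
  if (is.character(map) && length(map) == 1)
    map <- utils::read.delim(map, header = TRUE, sep = "\t",
                             colClasses = "character")
  if (!all(c("from", "to") %in% names(map)))
    stop("ortholog map needs columns 'from' and 'to'")
  unique(map$to[map$from %in% genes & !is.na(map$to)])
}
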