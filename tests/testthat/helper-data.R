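# Small in-code fixtures shared across test files.

# Minimal valid count matrix.
tiny_counts <- function(values = matrix(c(1, 3, 2, 4), 2, 2),
                        genes = c("g1", "g2"), samples = c("s1", "s2")) {
  dimnames(values) <- list(genes, samples)
  storage.mode(values) <- "double"
  values
}

# Full two-population x eight-time-point metadata (n replicates each,
# optionally one fewer for basal L10 to mirror the 47-sample design).
full_design_meta <- function(n = 3, l10_basal = n) {
  rows <- do.call(rbind, lapply(populations(), function(pop) {
    do.call(rbind, lapply(time_points(), function(tp) {
      k <- if (pop == "basal" && tp == "L10") l10_basal else n
      data.frame(sample = paste(pop, tp, seq_len(k), sep = "_"),
                 population = pop, time_point = tp, replicate = seq_len(k),
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(rows) <- NULL
  rows
}

# Deterministic CPM-scale matrix for a given design: constant baseline plus
# optional per-gene condition shifts supplied on the log2 scale.
design_cpm <- function(meta, n_genes = 10, baseline = 100,
                       shift = NULL, noise_sd = 0, seed = 1) {
  set.seed(seed)
  genes <- sprintf("g%03d", seq_len(n_genes))
  m <- matrix(baseline, n_genes, nrow(meta),
              dimnames = list(genes, meta$sample))
  if (!is.null(shift)) {
    for (i in seq_along(shift)) {
      s <- shift[[i]]
      idx <- which(meta$population %in% s$population &
                     meta$time_point %in% s$time_point)
      m[s$gene, idx] <- m[s$gene, idx] * 2^s$log2
    }
  }
  if (noise_sd > 0)
    m <- m * 2^matrix(stats::rnorm(length(m), 0, noise_sd), nrow(m))
  attr(m, "scale_tag") <- "cpm"
  m
}

# Independent step-up BH oracle: sort, p*m/i, right cummin, clip at 1.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Exhaustive hypergeometric upper tail by enumerating all C(N, n) draws.
hyper_oracle <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # items 1..K are the reference
  mean(hits >= k)
}
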