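# Fixtures are built in code; nothing is read from disk except round-trip
# temp files created by the tests themselves.

# Independent brute-force co-occurrence oracle: per-pair hand-computed
# Spearman rho (Pearson product-moment formula on average ranks) and
# t-approximation p-value, Bonferroni by direct multiplication. Returns a
# sorted character vector of "a|b" edge keys.
oracleEdges <- function(counts, rhoThreshold = 0.8, alpha = 0.05) {
  X <- sweep(counts, 2, colSums(counts), "/")
  taxa <- rownames(X)
  n <- ncol(X)
  keep <- apply(X, 1, function(v) any(v != v[1]))
  idx <- which(keep)
  pairs <- t(combn(idx, 2))
  m <- nrow(pairs)
  edges <- character(0)
  for (k in seq_len(m)) {
    a <- rank(X[pairs[k, 1], ]); b <- rank(X[pairs[k, 2], ])
    rho <- sum((a - mean(a)) * (b - mean(b))) /
      sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
    if (abs(rho) >= 1) p <- 0
    else {
      tt <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tt), df = n - 2)
    }
    if (abs(rho) > rhoThreshold && p * m < alpha) {
      e <- sort(taxa[pairs[k, ]])
      edges <- c(edges, paste(e[1], e[2], sep = "|"))
    }
  }
  sort(edges)
}

edgeKeys <- function(net) {
  e <- networkEdges(net)
  if (nrow(e) == 0) return(character(0))
  sort(paste(e$source, e$target, sep = "|"))
}

# small labelled count matrix
toyCounts <- function(values, nTaxa, nSamples) {
  matrix(values, nTaxa, nSamples,
         dimnames = list(sprintf("t%02d", seq_len(nTaxa)),
                         sprintf("s%02d", seq_len(nSamples))))
}

# wrap a bare igraph in the network class used by topology helpers
asNetwork <- function(g, group = "toy") {
  if (igraph::ecount(g) > 0 && is.null(igraph::E(g)$rho)) {
    igraph::E(g)$rho <- 0.9
    igraph::E(g)$sign <- "+"
  }
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- paste0("n", seq_len(igraph::vcount(g)))
  methods::new("CoOccurrenceNetwork", graph = g, group = group,
               rhoThreshold = 0.8, alpha = 0.05)
}
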