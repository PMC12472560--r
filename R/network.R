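#' Prevalence / abundance pre-filter for network construction
#'
#' Keeps taxa detected (count > 0) in at least `minPrevalence` of the
#' samples and whose mean relative abundance is at least `minMeanRelabund`.
#'
#' @param asv [AsvExperiment-class] or count matrix.
#' @param minPrevalence Fraction of samples in \[0, 1\].
#' @param minMeanRelabund Mean relative abundance threshold.
#' @return The filtered table (same class as input for `AsvExperiment`).
#' @export
filterTaxa <- function(asv, minPrevalence = 0.5, minMeanRelabund = 1e-4) {
  stopifnot(minPrevalence >= 0, minPrevalence <= 1, minMeanRelabund >= 0)
  m <- asvCounts(asv)
  prev <- rowMeans(m > 0)
  rel <- rowMeans(.relabund(m))
  keep <- prev >= minPrevalence & rel >= minMeanRelabund
  if (!any(keep))
    stop("filter removed all ", nrow(m), " taxa (prevalence >= ",
         minPrevalence, ", mean relative abundance >= ", minMeanRelabund, ")")
  if (is(asv, "SummarizedExperiment")) asv[keep, ] else m[keep, , drop = FALSE]
}

#' All-pairs Spearman correlation with Bonferroni correction
#'
#' Ranks each taxon's relative abundances across samples (average ranks for
#' ties) and computes Pearson correlation on the ranks. Two-sided p-values
#' use the t approximation for n >= 10 samples and per-pair
#' [stats::cor.test()] (exact where tie-free) for smaller n. Constant taxa
#' yield undefined correlations: those pairs are excluded from the
#' Bonferroni denominator `m` and reported as `NA`.
#'
#' @param asv [AsvExperiment-class] or count matrix (>= 2 taxa,
#'   >= 4 samples).
#' @param method p-value method: `"auto"` (default rule above), `"approx"`
#'   or `"exact"`.
#' @return A [CorrelationResult-class].
#' @export
spearmanMatrix <- function(asv, method = c("auto", "approx", "exact")) {
  method <- match.arg(method)
  m <- asvCounts(asv)
  if (nrow(m) < 2) stop("need >= 2 taxa")
  n <- ncol(m)
  if (n < 4) stop("need >= 4 samples")
  X <- .relabund(m)
  constant <- apply(X, 1, function(v) all(v == v[1]))
  if (any(constant))
    message(sum(constant), " constant taxa excluded from testable pairs: ",
            paste(utils::head(rownames(X)[constant], 5), collapse = ", "))
  rho <- suppressWarnings(cor(t(X), method = "spearman"))
  rho[constant, ] <- NA
  rho[, constant] <- NA
  diag(rho) <- 1
  useExact <- method == "exact" || (method == "auto" && n < 10)
  p <- matrix(NA_real_, nrow(m), nrow(m), dimnames = dimnames(rho))
  if (!useExact) {
    r <- rho
    diag(r) <- NA
    tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
    p[] <- 2 * pt(-abs(tstat), df = n - 2)
    p[!is.na(r) & abs(r) >= 1] <- 0
  } else {
    ok <- which(!constant)
    for (a in seq_along(ok)) for (b in seq_along(ok)) {
      if (b <= a) next
      ct <- suppressWarnings(
        cor.test(X[ok[a], ], X[ok[b], ], method = "spearman"))
      p[ok[a], ok[b]] <- p[ok[b], ok[a]] <- ct$p.value
    }
  }
  diag(p) <- NA
  mTest <- sum(!is.na(p[upper.tri(p)]))
  padj <- p * mTest
  padj[!is.na(padj) & padj > 1] <- 1
  new("CorrelationResult", rho = rho, p = p, pAdjusted = padj,
      m = as.integer(mTest), nSamples = as.integer(n))
}

#' Build a co-occurrence network from gated correlations
#'
#' An edge joins two taxa iff `|rho| > rhoThreshold` and the
#' Bonferroni-adjusted p-value is `< alpha` (both strict). Taxa left
#' without any edge are excluded from the node set, so the node count is
#' the number of connected taxa. The result is invariant to taxon input
#' order (edges are stored with lexicographically ordered endpoints).
#'
#' @param corr A [CorrelationResult-class] from [spearmanMatrix()].
#' @param rhoThreshold Absolute correlation gate (default 0.8).
#' @param alpha Adjusted-p gate (default 0.05).
#' @param group Group label to attach.
#' @return A [CoOccurrenceNetwork-class].
#' @export
buildNetwork <- function(corr, rhoThreshold = 0.8, alpha = 0.05,
                         group = "NA") {
  stopifnot(is(corr, "CorrelationResult"))
  rho <- corr@rho
  padj <- corr@pAdjusted
  taxa <- rownames(rho)
  sel <- which(upper.tri(rho) & !is.na(rho) & abs(rho) > rhoThreshold &
                 !is.na(padj) & padj < alpha, arr.ind = TRUE)
  if (nrow(sel)) {
    a <- taxa[sel[, 1]]; b <- taxa[sel[, 2]]
    swap <- a > b
    tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
    r <- rho[sel]
    o <- order(a, b)
    edges <- data.frame(source = a[o], target = b[o], rho = r[o],
                        sign = ifelse(r[o] > 0, "+", "-"),
                        stringsAsFactors = FALSE)
    g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  } else {
    g <- igraph::make_empty_graph(0, directed = FALSE)
  }
  new("CoOccurrenceNetwork", graph = g, group = group,
      rhoThreshold = rhoThreshold, alpha = alpha)
}

#' One-call network construction for a treatment group
#'
#' Subsets the samples of `group`, applies the prevalence filter, computes
#' the Spearman matrix and gates edges.
#'
#' @param asv [AsvExperiment-class] with treatment metadata.
#' @param group Treatment label.
#' @param rhoThreshold,alpha Edge gate; see [buildNetwork()].
#' @param minPrevalence,minMeanRelabund Pre-filter; see [filterTaxa()].
#' @return A [CoOccurrenceNetwork-class].
#' @export
groupNetwork <- function(asv, group, rhoThreshold = 0.8, alpha = 0.05,
                         minPrevalence = 0.5, minMeanRelabund = 1e-4) {
  tr <- treatments(asv)
  if (is.null(tr)) stop("asv must carry treatment metadata")
  if (!group %in% tr) stop("unknown group: ", group)
  sub <- asv[, tr == group]
  sub <- filterTaxa(sub, minPrevalence, minMeanRelabund)
  buildNetwork(spearmanMatrix(sub), rhoThreshold, alpha, group = group)
}
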