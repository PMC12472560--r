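#' Null-model community cohesion
#'
#' Implements the taxon-shuffle cohesion index. Observed pairwise
#' correlations `r_jk` between taxa (across samples, on relative
#' abundances) are corrected by their null expectation `E0[r_jk]`, the mean
#' correlation over `nullIterations` randomisations in which each taxon's
#' abundance vector is independently permuted across samples. For each
#' taxon, positive connectedness is the mean of its positive corrected
#' correlations (negative connectedness likewise over the negative ones).
#' Per-sample cohesion weights connectedness by relative abundance:
#' `cohesion_pos(i) = sum_j a_ij * connectedness_pos(j)` (and the negative
#' analogue), so positive cohesion is always >= 0 and negative cohesion
#' <= 0.
#'
#' @param asv [AsvExperiment-class] or count matrix (>= 4 samples).
#' @param nullIterations Number of taxon-shuffle randomisations.
#' @param method Correlation inside the index: `"pearson"` (default, the
#'   index's conventional choice) or `"spearman"`.
#' @param seed Seed for the null shuffles.
#' @return A [CohesionProfile-class].
#' @export
communityCohesion <- function(asv, nullIterations = 200L,
                              method = c("pearson", "spearman"), seed = 1L) {
  method <- match.arg(method)
  m <- asvCounts(asv)
  if (ncol(m) < 4) stop("need >= 4 samples")
  X <- .relabund(m)
  obs <- suppressWarnings(cor(t(X), method = method))
  nullMean <- withr::with_seed(.stageSeed(seed, "cohesion"), {
    acc <- matrix(0, nrow(X), nrow(X))
    for (b in seq_len(nullIterations)) {
      Xp <- t(apply(X, 1, sample))
      acc <- acc + suppressWarnings(cor(t(X), t(Xp), method = method))
    }
    acc / nullIterations
  })
  nullMean <- (nullMean + t(nullMean)) / 2
  rprime <- obs - nullMean
  diag(rprime) <- NA
  rprime[is.na(obs)] <- NA  # constant taxa: undefined pairs
  connPos <- apply(rprime, 1, function(v) {
    v <- v[!is.na(v) & v > 0]
    if (length(v)) mean(v) else 0
  })
  connNeg <- apply(rprime, 1, function(v) {
    v <- v[!is.na(v) & v < 0]
    if (length(v)) mean(v) else 0
  })
  cohPos <- as.numeric(crossprod(X, connPos))
  cohNeg <- as.numeric(crossprod(X, connNeg))
  names(cohPos) <- names(cohNeg) <- colnames(X)
  names(connPos) <- names(connNeg) <- rownames(X)
  new("CohesionProfile", connectednessPos = connPos,
      connectednessNeg = connNeg, cohesionPos = cohPos, cohesionNeg = cohNeg,
      nullIterations = as.integer(nullIterations), method = method,
      seed = as.integer(seed))
}

#' Network robustness under simulated node removal
#'
#' Random mode removes `floor(removalFraction * N)` nodes uniformly without
#' replacement, independently per replicate; targeted mode removes nodes in
#' descending degree order (ties broken by node id) and is deterministic
#' (one replicate). The connectivity metric is the size of the largest
#' connected component divided by the number of surviving nodes, or the
#' post/pre ratio of natural connectivity.
#'
#' @param net [CoOccurrenceNetwork-class] or igraph (nonempty).
#' @param mode `"random"` or `"targeted"`.
#' @param removalFraction Fraction of nodes to remove, in \[0, 1).
#' @param replicates Replicates for random mode.
#' @param metric `"giant_component_fraction"` or `"natural_connectivity"`.
#' @param seed Seed for random removals.
#' @return A [RobustnessResult-class].
#' @export
robustness <- function(net, mode = c("random", "targeted"),
                       removalFraction = 0.5, replicates = 100L,
                       metric = c("giant_component_fraction",
                                  "natural_connectivity"),
                       seed = 1L) {
  mode <- match.arg(mode)
  metric <- match.arg(metric)
  g <- if (is(net, "CoOccurrenceNetwork")) net@graph else net
  N <- igraph::vcount(g)
  if (N == 0) stop("network is empty")
  if (removalFraction < 0 || removalFraction >= 1)
    stop("removalFraction must lie in [0, 1)")
  k <- floor(removalFraction * N)
  measure <- function(sub, nSurv) {
    if (nSurv == 0) return(0)
    if (metric == "giant_component_fraction") {
      max(igraph::components(sub)$csize) / nSurv
    } else {
      .naturalConnectivity(sub) / .naturalConnectivity(g)
    }
  }
  if (mode == "targeted") {
    deg <- igraph::degree(g)
    nm <- igraph::V(g)$name
    if (is.null(nm)) nm <- as.character(seq_len(N))
    ord <- order(-deg, nm)
    remove <- ord[seq_len(k)]
    sub <- igraph::delete_vertices(g, remove)
    vals <- measure(sub, N - k)
    replicates <- 1L
  } else {
    vals <- withr::with_seed(.stageSeed(seed, "robustness"), {
      vapply(seq_len(replicates), function(r) {
        remove <- sample.int(N, k)
        measure(igraph::delete_vertices(g, remove), N - k)
      }, numeric(1))
    })
  }
  new("RobustnessResult", mode = mode, removalFraction = removalFraction,
      replicates = as.integer(replicates), metric = metric,
      values = as.numeric(vals))
}

# natural connectivity: log mean exponential of adjacency eigenvalues
.naturalConnectivity <- function(g) {
  n <- igraph::vcount(g)
  if (n == 0) return(0)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  ev <- eigen(a, symmetric = TRUE, only.values = TRUE)$values
  log(mean(exp(ev)))
}

#' Compare stability measures between treatment groups
#'
#' Pairwise two-sided Wilcoxon rank-sum tests on per-sample stability
#' ratios (or any per-replicate stability values such as robustness
#' distributions), with significance stars.
#'
#' @param values Named list: group label -> numeric vector (each length
#'   >= 2).
#' @return `data.frame(group1, group2, median1, median2, W, p, stars)`.
#' @export
compareStability <- function(values) {
  if (length(values) < 2) stop("need >= 2 groups")
  if (any(vapply(values, length, 1L) < 2)) stop("every group needs n >= 2")
  prs <- combn(names(values), 2)
  res <- apply(prs, 2, function(pr) {
    x <- values[[pr[1]]]; y <- values[[pr[2]]]
    if (all(x == x[1]) && all(y == y[1]) && x[1] == y[1]) {
      w <- list(statistic = length(x) * length(y) / 2, p.value = 1)
    } else {
      w <- suppressWarnings(wilcox.test(x, y))
    }
    data.frame(group1 = pr[1], group2 = pr[2],
               median1 = median(x), median2 = median(y),
               W = unname(w$statistic), p = w$p.value,
               stars = significanceStars(w$p.value),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}
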