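#' Rarefy an ASV table to even depth
#'
#' Subsamples every sample's reads without replacement to a common depth.
#' Samples whose total is below the requested depth are dropped with a
#' warning (never silently).
#'
#' @param asv [AsvExperiment-class] or count matrix (taxa x samples).
#' @param depth Target depth, or `"auto"` for the minimum column sum.
#' @param seed Seed controlling the subsampling.
#' @return A rarefied [AsvExperiment-class] whose column sums all equal
#'   `depth`.
#' @export
#' @examples
#' m <- matrix(c(10, 0, 0, 6, 3, 1), ncol = 2,
#'             dimnames = list(paste0("t", 1:3), c("a", "b")))
#' colSums(asvCounts(rarefy(m, depth = 5, seed = 1)))
rarefy <- function(asv, depth = "auto", seed = 1L) {
  counts <- asvCounts(asv)
  cs <- colSums(counts)
  if (identical(depth, "auto")) depth <- min(cs)
  depth <- as.integer(depth)
  if (depth <= 0) stop("rarefaction depth must be positive")
  drop <- cs < depth
  if (any(drop)) {
    warning("dropping ", sum(drop), " sample(s) below depth ", depth, ": ",
            paste(colnames(counts)[drop], collapse = ", "))
    counts <- counts[, !drop, drop = FALSE]
    cs <- cs[!drop]
    if (ncol(counts) == 0) stop("no samples at or above depth ", depth)
  }
  out <- withr::with_seed(.stageSeed(seed, "rarefy"), {
    res <- counts
    for (j in seq_len(ncol(counts))) {
      if (cs[j] == depth) next
      reads <- rep.int(seq_len(nrow(counts)), counts[, j])
      keep <- sample(reads, depth)
      res[, j] <- tabulate(keep, nbins = nrow(counts))
    }
    res
  })
  if (is(asv, "SummarizedExperiment")) {
    res <- asv[, colnames(out)]
    assay(res, "counts") <- out
    res
  } else AsvExperiment(out)
}

#' Bias-corrected Chao1 richness
#'
#' `S_obs + F1 * (F1 - 1) / (2 * (F2 + 1))`, where `F1`/`F2` are singleton
#' and doubleton counts. The bias-corrected form is defined for
#' doubleton-free samples. An all-zero sample has richness 0.
#'
#' @param column Non-negative integer count vector for one sample.
#' @return Chao1 estimate (>= observed richness).
#' @export
#' @examples
#' chao1(c(1, 1, 2, 0))  # 3 + 2*1/(2*2) = 3.5
chao1 <- function(column) {
  if (any(column < 0) || any(column != round(column)))
    stop("counts must be non-negative integers")
  sobs <- sum(column > 0)
  if (sobs == 0) return(0)
  f1 <- sum(column == 1)
  f2 <- sum(column == 2)
  sobs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * ln(p_i))` over nonzero proportions.
#'
#' @param column Non-negative count (or proportion) vector with positive sum.
#' @return Shannon index in nats.
#' @export
#' @examples
#' shannon(c(5, 5))  # log(2)
shannon <- function(column) {
  if (any(column < 0)) stop("counts must be non-negative")
  tot <- sum(column)
  if (tot <= 0) stop("zero-sum sample: Shannon index undefined")
  p <- column[column > 0] / tot
  -sum(p * log(p))
}

#' Per-sample alpha diversity table
#'
#' @param asv [AsvExperiment-class] or count matrix.
#' @return `data.frame(sample_id, chao1, shannon, richness)`.
#' @export
alphaDiversity <- function(asv) {
  m <- asvCounts(asv)
  data.frame(sample_id = colnames(m),
             chao1 = apply(m, 2, chao1),
             shannon = apply(m, 2, shannon),
             richness = colSums(m > 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Bray-Curtis distance matrix between samples
#'
#' `BC_jk = sum|x_ij - x_ik| / sum(x_ij + x_ik)`, computed with
#' [vegan::vegdist()]. A pair of all-zero samples is assigned distance 0
#' with a warning.
#'
#' @param asv [AsvExperiment-class] or count matrix (taxa x samples).
#' @return Symmetric matrix with zero diagonal, entries in \[0, 1\], sample
#'   ids as dimnames.
#' @export
brayCurtis <- function(asv) {
  m <- asvCounts(asv)
  if (ncol(m) < 2) stop("need >= 2 samples")
  d <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  if (anyNA(d)) {
    warning("all-zero sample pair(s): Bray-Curtis distance set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal Coordinates Analysis (classical scaling)
#'
#' Double-centres `-0.5 * D^2` and eigen-decomposes it via
#' [stats::cmdscale()]. Axes are ordered by descending eigenvalue, the
#' proportion explained is taken over positive eigenvalues only, and each
#' axis is oriented so its first nonzero loading is positive.
#'
#' @param d Symmetric distance matrix (e.g. from [brayCurtis()]).
#' @param k Number of axes, `k <= n - 1`.
#' @return List with `coordinates` (n x k, rownames = sample ids),
#'   `eigenvalues` and `proportionExplained` (over positive eigenvalues).
#' @export
pcoa <- function(d, k = 2) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
    stop("distance matrix must be symmetric")
  n <- nrow(d)
  if (k > n - 1) stop("k must be <= n - 1")
  fit <- cmdscale(as.dist(d), k = k, eig = TRUE)
  coords <- fit$points
  for (j in seq_len(ncol(coords))) {
    nz <- which(abs(coords[, j]) > 1e-12)
    if (length(nz) && coords[nz[1], j] < 0) coords[, j] <- -coords[, j]
  }
  pos <- fit$eig[fit$eig > 1e-12]
  prop <- if (length(pos)) pos / sum(pos) else numeric(0)
  list(coordinates = coords,
       eigenvalues = fit$eig,
       proportionExplained = prop[seq_len(min(k, length(prop)))])
}

#' PERMANOVA on a distance matrix
#'
#' Permutational multivariate ANOVA (pseudo-F from the Gower-centred
#' partition of the distance matrix) via [vegan::adonis2()], with
#' unrestricted label permutations and
#' `p = (1 + #\{F_perm >= F_obs\}) / (1 + nPerm)`.
#'
#' @param d Symmetric distance matrix with sample ids as dimnames.
#' @param metadata `data.frame(sample_id, treatment)`; >= 2 groups with
#'   >= 2 samples each.
#' @param nPerm Number of permutations.
#' @param seed Seed for the permutation stream.
#' @return List with `pseudoF`, `p`, `R2`, `df`.
#' @export
permanova <- function(d, metadata, nPerm = 999, seed = 1L) {
  d <- as.matrix(d)
  idx <- match(rownames(d), metadata$sample_id)
  if (anyNA(idx)) stop("metadata is missing samples: ",
                       paste(rownames(d)[is.na(idx)], collapse = ", "))
  grp <- metadata$treatment[idx]
  tab <- table(grp)
  if (length(tab) < 2) stop("need >= 2 groups")
  if (any(tab < 2)) stop("every group needs >= 2 samples; offending: ",
                         paste(names(tab)[tab < 2], collapse = ", "))
  df <- data.frame(treatment = factor(grp))
  fit <- withr::with_seed(.stageSeed(seed, "permanova"),
    vegan::adonis2(as.dist(d) ~ treatment, data = df, permutations = nPerm))
  list(pseudoF = fit$F[1], p = fit$`Pr(>F)`[1], R2 = fit$R2[1],
       df = fit$Df[1])
}
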