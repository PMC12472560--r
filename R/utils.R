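# Derive a reproducible sub-seed for a named pipeline stage. Keeps the
# result well below .Machine$integer.max so set.seed() is safe.
.stageSeed <- function(seed, stage) {
  offsets <- c(baseline = 11L, factors = 23L, noise = 37L, sampling = 53L,
               rarefy = 67L, permanova = 79L, cohesion = 97L,
               robustness = 113L, effect = 131L)
  off <- offsets[[stage]]
  (as.integer(seed) %% 1000000L) * 1000L + off
}

.relabund <- function(counts) {
  cs <- colSums(counts)
  if (any(cs == 0)) stop("sample(s) with zero total counts: ",
                         paste(colnames(counts)[cs == 0], collapse = ", "))
  sweep(counts, 2, cs, "/")
}

#' Significance stars for a p-value
#'
#' Standard convention: `*` p < 0.05, `**` p < 0.01, `***` p < 0.001,
#' `****` p < 0.0001, `ns` otherwise (strict inequalities, so p = 0.05 is
#' `ns`).
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Character vector of labels.
#' @export
#' @examples
#' significanceStars(c(0.03, 0.5, 5e-5))
significanceStars <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  vapply(p, function(pi) {
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}

# Piepho-style insert-and-absorb compact letter display.
# sig: logical matrix (groups x groups), TRUE where the pair differs.
.letterDisplay <- function(sig) {
  groups <- rownames(sig)
  cols <- list(groups)  # start: one letter containing everyone
  for (i in seq_along(groups)) {
    for (j in seq_along(groups)) {
      if (j <= i || !sig[i, j]) next
      newcols <- list()
      for (col in cols) {
        if (all(c(groups[i], groups[j]) %in% col)) {
          newcols <- c(newcols, list(setdiff(col, groups[i])),
                       list(setdiff(col, groups[j])))
        } else newcols <- c(newcols, list(col))
      }
      # absorb: drop columns that are subsets of another
      keep <- rep(TRUE, length(newcols))
      for (a in seq_along(newcols)) for (b in seq_along(newcols)) {
        if (a != b && keep[a] && keep[b] &&
            all(newcols[[a]] %in% newcols[[b]]) &&
            !(a < b && identical(newcols[[a]], newcols[[b]])))
          keep[a] <- FALSE
      }
      cols <- newcols[keep]
    }
  }
  letters_out <- setNames(rep("", length(groups)), groups)
  for (ci in seq_along(cols)) {
    for (g in cols[[ci]])
      letters_out[g] <- paste0(letters_out[g], letters[ci])
  }
  letters_out
}

#' Kruskal-Wallis test with rank-based post hoc letters
#'
#' Kruskal-Wallis H (tie-corrected) across three or more groups, followed by
#' pairwise Conover-style t-tests on mean ranks (the post hoc behind the
#' common agronomy-package letter displays), Holm-adjusted, and a compact
#' letter display at `alpha`.
#'
#' @param values Numeric vector of observations.
#' @param groups Factor or character vector of group labels, same length.
#' @param alpha Significance level for the letter display.
#' @param p.adjust.method Adjustment for the pairwise p-values
#'   (default `"holm"`).
#' @return List with `H`, `df`, `p`, `pairwise` (data.frame of pairwise
#'   comparisons) and `letters` (named character vector; groups sharing a
#'   letter do not differ at `alpha`).
#' @export
#' @examples
#' kruskalPosthoc(c(1:4, 11:14, 21:24), rep(c("CK", "CF", "BF"), each = 4))
kruskalPosthoc <- function(values, groups, alpha = 0.05,
                           p.adjust.method = "holm") {
  groups <- as.character(groups)
  glev <- unique(groups)
  if (length(glev) < 3)
    stop("need >= 3 groups; use a two-group rank-sum test instead")
  if (any(table(groups) < 2)) stop("every group needs n >= 2")
  kw <- kruskal.test(values, factor(groups, levels = glev))
  N <- length(values)
  k <- length(glev)
  r <- rank(values)
  meanR <- tapply(r, groups, mean)[glev]
  n <- tapply(r, groups, length)[glev]
  H <- unname(kw$statistic)
  # Conover: t-tests on mean ranks with pooled variance S2*(N-1-H)/(N-k)
  ties <- table(r)
  S2 <- (sum(r^2) - N * (N + 1)^2 / 4) / (N - 1)
  mse <- S2 * (N - 1 - H) / (N - k)
  pairs <- combn(glev, 2)
  pw <- apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    diffR <- meanR[[i]] - meanR[[j]]
    if (mse <= .Machine$double.eps^0.5)  # complete separation of ranks
      return(if (abs(diffR) < 1e-12) 1 else 0)
    se <- sqrt(mse * (1 / n[[i]] + 1 / n[[j]]))
    2 * pt(-abs(diffR / se), df = N - k)
  })
  pw <- p.adjust(pw, method = p.adjust.method)
  sig <- matrix(FALSE, k, k, dimnames = list(glev, glev))
  for (c2 in seq_len(ncol(pairs)))
    sig[pairs[1, c2], pairs[2, c2]] <- sig[pairs[2, c2], pairs[1, c2]] <-
      pw[c2] < alpha
  list(H = H, df = unname(kw$parameter), p = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             p = pw, stars = significanceStars(pw)),
       letters = .letterDisplay(sig))
}
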