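test_that("cohesion sign constraints hold and shuffles are reproducible", {
  d <- simulationDesign(nGroups = 1, replicatesPerGroup = 10, nTaxa = 25,
                        nModules = 2, moduleSize = 6, moduleStrength = 0.8,
                        seed = 6)
  counts <- asvCounts(generateDataset(d)$asv)
  p1 <- communityCohesion(counts, nullIterations = 50, seed = 4)
  expect_true(all(p1@cohesionPos >= 0))
  expect_true(all(p1@cohesionNeg <= 0))
  expect_true(all(p1@connectednessPos >= 0))
  expect_true(all(p1@connectednessNeg <= 0))
  p2 <- communityCohesion(counts, nullIterations = 50, seed = 4)
  expect_identical(p1@cohesionPos, p2@cohesionPos)
  expect_error(communityCohesion(counts[, 1:3]), ">= 4 samples")
})

test_that("anti-correlated abundant taxa drive negative cohesion", {
  # two dominant, perfectly anti-correlated taxa
  X2 <- rbind(t1 = c(40, 10, 30, 20, 35, 15),
              t2 = c(10, 40, 20, 30, 15, 35))
  colnames(X2) <- paste0("s", 1:6)
  p2 <- communityCohesion(X2, nullIterations = 100, seed = 1)
  expect_true(all(p2@cohesionNeg < 0))
  # same pair plus two weakly co-varying rare taxa: the positive side is
  # small but nonzero, so the stability ratio is defined and exceeds 1
  X4 <- rbind(X2, t3 = c(2, 3, 2, 4, 3, 2), t4 = c(2, 4, 2, 4, 4, 2))
  p4 <- communityCohesion(X4, nullIterations = 200, seed = 1)
  r <- stabilityRatio(p4)
  expect_true(all(is.finite(r)))
  expect_true(all(r > 1))
})

test_that("stability ratio is |negative| / positive, with undefined flagged", {
  prof <- methods::new("CohesionProfile",
                       connectednessPos = c(a = 0.2),
                       connectednessNeg = c(a = -0.1),
                       cohesionPos = c(s1 = 0.2, s2 = 0.4, s3 = 0),
                       cohesionNeg = c(s1 = -0.1, s2 = 0, s3 = -0.2),
                       nullIterations = 1L, method = "pearson", seed = 1L)
  expect_warning(r <- stabilityRatio(prof), "undefined")
  expect_equal(unname(r[1:2]), c(0.5, 0))
  expect_true(is.na(r[3]))
})

test_that("duplicating every sample leaves connectedness nearly unchanged", {
  d <- simulationDesign(nGroups = 1, replicatesPerGroup = 12, nTaxa = 15,
                        nModules = 1, moduleSize = 5, moduleStrength = 0.9,
                        seed = 2)
  counts <- asvCounts(generateDataset(d)$asv)
  dup <- cbind(counts, counts)
  colnames(dup) <- paste0("s", seq_len(ncol(dup)))
  pa <- communityCohesion(counts, nullIterations = 400, seed = 1)
  pb <- communityCohesion(dup, nullIterations = 400, seed = 1)
  # observed correlations are identical; only the null estimate moves
  expect_lt(max(abs(pa@connectednessPos - pb@connectednessPos)), 0.06)
  expect_lt(max(abs(pa@connectednessNeg - pb@connectednessNeg)), 0.06)
})

test_that("corrected correlations converge as null iterations double", {
  d <- simulationDesign(nGroups = 1, replicatesPerGroup = 15, nTaxa = 40,
                        nModules = 2, moduleSize = 8, moduleStrength = 0.8,
                        seed = 3)
  sim <- generateDataset(d)
  X <- filterTaxa(rarefy(sim$asv, "auto", seed = 3))
  pA <- communityCohesion(X, nullIterations = 200, seed = 5)
  pB <- communityCohesion(X, nullIterations = 400, seed = 5)
  rms <- sqrt(mean(c((pA@connectednessPos - pB@connectednessPos)^2,
                     (pA@connectednessNeg - pB@connectednessNeg)^2)))
  expect_lt(rms, 0.02)
})

test_that("independent communities give balanced cohesion, ratio near 1", {
  res <- vapply(1:10, function(s) {
    d <- simulationDesign(nGroups = 1, replicatesPerGroup = 15, nTaxa = 30,
                          nModules = 0, moduleSize = 0, moduleStrength = 0,
                          seed = s)
    p <- communityCohesion(asvCounts(generateDataset(d)$asv),
                           nullIterations = 100, seed = s)
    c(total = mean(p@cohesionPos + p@cohesionNeg),
      ratio = mean(suppressWarnings(stabilityRatio(p))))
  }, numeric(2))
  expect_lt(abs(mean(res["total", ])), 0.05)
  expect_gt(median(res["ratio", ]), 0.8)
  expect_lt(median(res["ratio", ]), 1.25)
})

test_that("robustness closed-form cases: complete and star graphs", {
  k10 <- igraph::make_full_graph(10)
  r <- robustness(k10, "random", removalFraction = 0.5, replicates = 5,
                  seed = 1)
  expect_true(all(r@values == 1))   # complete graphs stay connected
  star <- igraph::make_star(10, mode = "undirected")
  rt <- robustness(star, "targeted", removalFraction = 0.1)
  expect_equal(rt@values, 1 / 9)    # hub removed, nine isolated leaves
  expect_equal(rt@replicates, 1L)
  # determinism of random mode under a fixed seed
  r1 <- robustness(k10, "random", 0.5, replicates = 2, seed = 7)
  r2 <- robustness(k10, "random", 0.5, replicates = 2, seed = 7)
  expect_identical(r1@values, r2@values)
  expect_error(robustness(k10, "random", removalFraction = 1), "removalFraction")
})

test_that("giant component declines monotonically with removal fraction", {
  fracs <- c(0.1, 0.3, 0.5, 0.7)
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_gnp(60, 0.06)
    means <- vapply(fracs, function(f)
      mean(robustness(g, "random", f, replicates = 60, seed = s)@values),
      numeric(1))
    expect_true(all(diff(means) <= 0.02))
  }
})

test_that("targeted attack is at most as survivable as random attack", {
  for (s in 1:5) {
    set.seed(s)
    g <- igraph::sample_pa(80, m = 2, directed = FALSE)
    tv <- robustness(g, "targeted", 0.5)@values
    rv <- mean(robustness(g, "random", 0.5, replicates = 40, seed = s)@values)
    expect_lte(tv, rv)
  }
})

test_that("natural connectivity variant stays within sane bounds", {
  g <- igraph::make_full_graph(12)
  r <- robustness(g, "random", 0.5, replicates = 3,
                  metric = "natural_connectivity", seed = 2)
  expect_true(all(is.finite(r@values)))
  expect_true(all(r@values <= 1 + 1e-9))
})

test_that("group stability comparisons: identity and separation", {
  same <- list(A = c(1, 1, 1), B = c(1, 1, 1))
  res <- compareStability(same)
  expect_equal(res$stars, "ns")
  sep <- list(A = c(0.1, 0.12, 0.11, 0.13), B = c(0.9, 0.92, 0.91, 0.93))
  res2 <- compareStability(sep)
  expect_lt(res2$p, 0.05)
  expect_error(compareStability(list(A = 1:3)), ">= 2 groups")
  expect_error(compareStability(list(A = 1:3, B = 2)), "n >= 2")
})
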