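test_that("taxon filter keeps prevalent, abundant taxa", {
  # rows: t01 everywhere-abundant, t02 in 2/4 samples, t03 in 1/4
  m <- rbind(t01 = c(10, 12, 11, 10),
             t02 = c(1, 0, 0, 2),
             t03 = c(0, 0, 0, 1))
  colnames(m) <- paste0("s", 1:4)
  # identity at zero thresholds
  expect_identical(filterTaxa(m, 0, 0), m)
  # taxon present in 1 of 4 samples dropped at prevalence 0.5
  f <- filterTaxa(m, minPrevalence = 0.5, minMeanRelabund = 0)
  expect_false("t03" %in% rownames(f))
  expect_true(all(c("t01", "t02") %in% rownames(f)))
  expect_error(filterTaxa(m, 1, 0.99), "removed all")
})

test_that("spearman matrix reproduces closed-form correlations", {
  # equal column sums so the per-sample relative-abundance transform is
  # rank-preserving
  m <- rbind(a = c(1, 2, 3, 4), b = c(10, 20, 30, 40),
             c = c(4, 3, 2, 1), d = c(40, 30, 20, 10))
  colnames(m) <- paste0("s", 1:4)
  expect_equal(unique(colSums(m)), 55)
  cr <- spearmanMatrix(m, method = "approx")
  expect_equal(cr@rho["a", "a"], 1)
  expect_equal(cr@rho["a", "b"], 1)   # perfectly monotone pair
  expect_equal(cr@rho["a", "c"], -1)
  expect_equal(cr@m, 6L)
  expect_equal(cr@rho, t(cr@rho))
  expect_error(spearmanMatrix(m[1, , drop = FALSE]), ">= 2 taxa")
  expect_error(spearmanMatrix(m[, 1:3]), ">= 4 samples")
})

test_that("constant taxa are excluded from the Bonferroni denominator", {
  # equal column sums keep 'flat' constant after normalisation
  m <- rbind(a = 1:10, b = 10:1, flat = rep(5, 10))
  colnames(m) <- paste0("s", 1:10)
  expect_message(cr <- spearmanMatrix(m), "constant")
  expect_true(is.na(cr@rho["flat", "a"]))
  expect_equal(cr@m, 1L)  # only (a, b) testable
  expect_equal(cr@rho["a", "b"], -1)
  expect_equal(cr@pAdjusted["a", "b"], 0)
})

test_that("network edges satisfy the gate and drop isolated nodes", {
  taxa <- paste0("t", 1:4)
  rho <- diag(4); dimnames(rho) <- list(taxa, taxa)
  rho[1, 2] <- rho[2, 1] <- 0.95    # passes both gates
  rho[1, 3] <- rho[3, 1] <- 0.85    # fails p gate below
  rho[3, 4] <- rho[4, 3] <- -0.9    # negative edge
  p <- matrix(NA_real_, 4, 4, dimnames = list(taxa, taxa))
  p[1, 2] <- p[2, 1] <- 1e-6
  p[1, 3] <- p[3, 1] <- 0.03        # 0.03 * m > 0.05
  p[3, 4] <- p[4, 3] <- 1e-6
  p[1, 4] <- p[4, 1] <- 0.9; p[2, 3] <- p[3, 2] <- 0.9
  p[2, 4] <- p[4, 2] <- 0.9
  cr <- methods::new("CorrelationResult", rho = rho, p = p,
                     pAdjusted = pmin(matrix(1, 4, 4,
                                             dimnames = list(taxa, taxa)),
                                      p * 6), m = 6L, nSamples = 12L)
  net <- buildNetwork(cr, rhoThreshold = 0.8, alpha = 0.05)
  e <- networkEdges(net)
  expect_equal(e$source, c("t1", "t3"))
  expect_equal(e$target, c("t2", "t4"))
  expect_equal(e$sign, c("+", "-"))
  # every node in the network has at least one edge
  expect_true(all(igraph::degree(networkGraph(net)) >= 1))
})

test_that("all-zero correlations yield an empty network", {
  taxa <- c("a", "b")
  rho <- diag(2); dimnames(rho) <- list(taxa, taxa)
  p <- matrix(c(NA, 1, 1, NA), 2, dimnames = list(taxa, taxa))
  cr <- methods::new("CorrelationResult", rho = rho, p = p, pAdjusted = p,
                     m = 1L, nSamples = 8L)
  expect_equal(igraph::ecount(networkGraph(buildNetwork(cr))), 0)
})

test_that("network construction matches the brute-force oracle", {
  for (s in 1:5) {
    d <- simulationDesign(nGroups = 1, replicatesPerGroup = 15, nTaxa = 10,
                          nModules = 1, moduleSize = 5, moduleStrength = 0.9,
                          seed = s)
    counts <- asvCounts(generateDataset(d)$asv)
    counts <- counts[rowSums(counts > 0) > 1, ]
    net <- buildNetwork(spearmanMatrix(counts), 0.8, 0.05)
    expect_identical(edgeKeys(net), oracleEdges(counts, 0.8, 0.05))
  }
})

test_that("network is invariant to taxon input order", {
  d <- simulationDesign(nGroups = 1, replicatesPerGroup = 15, nTaxa = 12,
                        nModules = 2, moduleSize = 4, moduleStrength = 0.9,
                        seed = 8)
  counts <- asvCounts(generateDataset(d)$asv)
  net1 <- buildNetwork(spearmanMatrix(counts))
  set.seed(1)
  perm <- sample(nrow(counts))
  net2 <- buildNetwork(spearmanMatrix(counts[perm, ]))
  expect_identical(edgeKeys(net1), edgeKeys(net2))
})

test_that("null tables stay below the Bonferroni edge budget", {
  edges <- vapply(1:10, function(s) {
    d <- simulationDesign(nGroups = 1, replicatesPerGroup = 10, nTaxa = 25,
                          nModules = 0, moduleSize = 0, moduleStrength = 0,
                          seed = 100 + s)
    counts <- asvCounts(generateDataset(d)$asv)
    cr <- suppressMessages(spearmanMatrix(counts))
    c(igraph::ecount(networkGraph(buildNetwork(cr))), cr@m)
  }, numeric(2))
  expect_lte(mean(edges[1, ]), 0.05 * mean(edges[2, ]))
})
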