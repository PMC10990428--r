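test_that("Spearman correlation matches the rank-then-Pearson oracle", {
  expect_equal(spearmanRho(1:10, (1:10)^2), 1)
  expect_equal(spearmanRho(1:10, rev(1:10)), -1)
  for (seed in 1:5) {
    set.seed(seed)
    # integer-valued vectors with plenty of ties
    x <- sample(1:4, 30, replace = TRUE)
    y <- x + sample(0:3, 30, replace = TRUE)
    expect_equal(spearmanRho(x, y), spearmanOracle(x, y),
                 tolerance = 1e-12)
    # pairwise deletion
    x[c(3, 7)] <- NA; y[5] <- NA
    expect_equal(spearmanRho(x, y), spearmanOracle(x, y),
                 tolerance = 1e-12)
  }
  expect_message(r <- spearmanRho(c(1, 2, NA), c(1, NA, 2)), "fewer than 3")
  expect_true(is.na(r))
})

makeLandscapes <- function(tree, nWindows, seed) {
  set.seed(seed)
  g <- windowGrid(nWindows * 1e4, 1e4, "c")
  lapply(allDescriptors(tree), function(d)
    methods::new("Landscape", stat = d, grid = g,
                 values = runif(nWindows, 0, 0.01),
                 callableFrac = rep(1, nWindows)))
}

test_that("all pairwise correlations enumerate and annotate records", {
  tr <- toyTree()
  ls <- makeLandscapes(tr, 20, seed = 2)     # 3 pi + 3 dxy
  recs <- allPairwiseCorrelations(ls, tr)
  expect_equal(nrow(recs), choose(6, 2))
  expect_setequal(unique(recs$type), c("pi_pi", "pi_dxy", "dxy_dxy"))
  # records match one-at-a-time spearman calls
  for (i in c(1, 5, 11)) {
    expect_equal(recs$rho[i],
                 spearmanRho(ls[[recs$statA[i]]], ls[[recs$statB[i]]]))
    expect_equal(recs$dT[i],
                 phyloDistance(tr, ls[[recs$statA[i]]]@stat,
                               ls[[recs$statB[i]]]@stat))
  }
  expect_error(allPairwiseCorrelations(c(ls, ls[1]), tr), "duplicate")
})

test_that("the shared-branch filter drops exactly the overlapping pairs", {
  qt <- quartetTree()
  ls <- makeLandscapes(qt, 15, seed = 3)
  all <- allPairwiseCorrelations(ls, qt)
  kept <- allPairwiseCorrelations(ls, qt, excludeSharedBranches = TRUE)
  expect_equal(nrow(all) - nrow(kept), sum(all$sharesBranches))
  key <- function(d) paste(d$statA, d$statB)
  expect_false(key(data.frame(statA = "dxy_V_X", statB = "dxy_X_Y")) %in%
               key(kept))
  expect_true(any(kept$statA == "dxy_V_W" & kept$statB == "dxy_X_Y"))
})

test_that("low-Ne flags follow the species threshold", {
  tr <- toyTree(neA = 5e3)   # A below the 8e3 default
  ls <- makeLandscapes(tr, 10, seed = 4)
  recs <- allPairwiseCorrelations(ls, tr)
  involvesA <- vapply(seq_len(nrow(recs)), function(i) {
    taxa <- c(ls[[recs$statA[i]]]@stat@taxa, ls[[recs$statB[i]]]@stat@taxa)
    "A" %in% taxa
  }, TRUE)
  expect_equal(recs$lowNe, involvesA)
  # configurable override
  recs2 <- allPairwiseCorrelations(ls, tr, lowNeThreshold = 100)
  expect_false(any(recs2$lowNe))
})

test_that("covariance series recovers Cov(R, X) exactly for exact inputs", {
  set.seed(6)
  nW <- 50
  g <- windowGrid(nW * 1e4, 1e4, "c")
  X <- runif(nW)
  R <- 1e-9 + 1e-9 * X + rnorm(nW, 0, 2e-10)
  ts <- c(1e4, 5e4, 2e5)
  divs <- lapply(seq_along(ts), function(i)
    methods::new("Landscape", stat = dxyStat("a", paste0("b", i)),
                 grid = g, values = pmin(R * ts[i], 1),
                 callableFrac = rep(1, nW)))
  cs <- covarianceSeries(divs, ts, X)
  expect_equal(cs$slope, cov(R, X), tolerance = 1e-10)
  expect_equal(cs$intercept, 0, tolerance = 1e-10)
  # constant divergence: all covariances and the slope are zero
  divs0 <- lapply(seq_along(ts), function(i)
    methods::new("Landscape", stat = dxyStat("a", paste0("b", i)),
                 grid = g, values = rep(1e-3, nW),
                 callableFrac = rep(1, nW)))
  cs0 <- covarianceSeries(divs0, ts, X)
  expect_equal(cs0$series$cov, rep(0, 3))
  expect_equal(cs0$slope, 0, tolerance = 1e-15)
  expect_error(covarianceSeries(divs, c(1, 1, 1), X), "distinct")
})

test_that("middle-half restriction uses the interior 50% of windows", {
  nW <- 40
  g <- windowGrid(nW * 1e4, 1e4, "c")
  X <- c(rep(10, 10), rep(0, 20), rep(10, 10))   # feature only in the tails
  v <- c(rep(0.01, 10), seq(0, 0.001, length.out = 20), rep(0.01, 10))
  divs <- lapply(c(1e4, 2e4), function(t)
    methods::new("Landscape", stat = dxyStat("a", paste0("b", t)),
                 grid = g, values = v, callableFrac = rep(1, nW)))
  full <- covarianceSeries(divs, c(1e4, 2e4), X)
  mid <- covarianceSeries(divs, c(1e4, 2e4), X, middleHalf = TRUE)
  expect_gt(abs(full$series$cov[1]), 0)
  expect_equal(mid$series$cov, rep(0, 2))   # X constant in the middle half
})

test_that("PCA embedding reconstructs rank-2 structure and flags exclusions", {
  set.seed(8)
  u1 <- rnorm(20); u2 <- rnorm(20)
  scores <- matrix(rnorm(24), 12, 2)
  mat <- scores %*% rbind(u1, u2)
  rownames(mat) <- c(paste0("sim", 1:11), "data")
  emb <- pcaEmbedding(mat, dataRow = "data")
  # two components carry all the variance
  expect_lt(sum(emb$sdev[-(1:2)]^2) / sum(emb$sdev^2), 1e-20)
  # duplicated data row has distance zero
  mat2 <- rbind(mat, dup = mat["data", ])
  emb2 <- pcaEmbedding(mat2, dataRow = "data")
  expect_equal(unname(emb2$distances["dup"]), 0)
  expect_gt(min(emb2$distances[paste0("sim", 1:11)]), 0)
  # strong-positive-selection filter by beneficial mutation rate
  muP <- c(rep(1e-12, 5), rep(1e-9, 6), NA)
  emb3 <- pcaEmbedding(mat, dataRow = "data", muP = muP,
                       excludeStrongPositive = TRUE)
  expect_setequal(emb3$excluded, paste0("sim", 6:11))
  expect_equal(nrow(emb3$coords), 6)
  expect_error(pcaEmbedding(mat[, 1, drop = FALSE]), "two correlation")
})

test_that("missing correlations are imputed by column means", {
  set.seed(9)
  mat <- matrix(rnorm(40), 8, 5,
                dimnames = list(paste0("r", 1:8), paste0("c", 1:5)))
  mat[2, 3] <- NA
  expect_message(emb <- pcaEmbedding(mat, dataRow = "r8"), "imputing")
  expect_false(anyNA(emb$coords))
})
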