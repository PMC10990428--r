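neutralRun <- function(seed, N = 100, T = 200, L = 5e4, mu = 1e-6,
                       r = 1e-5, windowSize = 5e3, dfe = dfeConfig(),
                       exons = NULL, samples = 5L) {
  tr <- pairTree(T, N, N, samples = samples)
  cfg <- simulationConfig(tr, chromLength = L, mu = mu, dfe = dfe,
                          exons = exons, recomb = uniformRecombMap(L, r),
                          windowSize = windowSize, seed = seed)
  simulateForward(cfg)
}

test_that("Q-rescaling preserves the governing compound parameters", {
  tr <- pairTree(1000, 10000, 10000)
  cfg <- simulationConfig(tr, chromLength = 1e5, mu = 2e-8, seed = 1)
  expect_identical(rescaleConfig(cfg, 1), cfg)
  c50 <- rescaleConfig(cfg, 50)
  expect_equal(unname(branchNe(c50@tree)["A"]), 200)
  expect_equal(c50@mu, 1e-6)
  expect_equal(4 * branchNe(c50@tree)["A"] * c50@mu,
               4 * branchNe(cfg@tree)["A"] * cfg@mu, ignore_attr = TRUE)
  expect_equal(c50@recomb$rate, cfg@recomb$rate * 50)
  expect_equal(unname(branchLengths(c50@tree)["A"]), 20)
  expect_equal(c50@rescaleQ, 50)
  expect_error(rescaleConfig(cfg, 1e4), "below 2")
})

test_that("neutral forward runs hit the coalescent expectation 4*N*mu", {
  vals <- unlist(lapply(1:3, function(s)
    landscapeValues(simLandscapes(neutralRun(s))$pi_A)))
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals) - 4 * 100 * 1e-6), 3 * se)
})

test_that("background selection depresses diversity below the neutral run", {
  piOf <- function(res) mean(landscapeValues(simLandscapes(res)$pi_A))
  exAll <- data.frame(start = 0, end = 2e4)
  neu <- vapply(1:3, function(s)
    piOf(neutralRun(s, L = 2e4, T = 400, r = 0, windowSize = 2e4)), 0)
  bgs <- vapply(1:3, function(s)
    piOf(neutralRun(s, L = 2e4, T = 400, r = 0, windowSize = 2e4,
                    dfe = dfeConfig(fracDeleterious = 1, meanSDel = -0.05),
                    exons = exAll)), 0)
  expect_lt(mean(bgs), mean(neu))
})

test_that("small-N fixation counts match the diffusion oracle", {
  dfe <- dfeConfig(fracBeneficial = 0.05, meanSBen = 0.05)
  res <- neutralRun(42, N = 100, T = 2000, L = 3e4, mu = 1e-6, r = 1e-3,
                    windowSize = 3e4, dfe = dfe,
                    exons = data.frame(start = 0, end = 3e4), samples = 2L)
  fx <- simFixations(res)
  fx <- fx[fx$branch == "A", ]
  er <- expectedSubstitutionRates(dfe, 1e-6, 100)
  horizon <- 2000 * 3e4
  for (cl in c("neutral", "beneficial")) {
    lam <- er[[cl]] * horizon
    obs <- sum(fx$class == cl)
    expect_lt(abs(obs - lam), 3.5 * sqrt(lam))
  }
})

test_that("identical config and seed give bit-identical results", {
  r1 <- neutralRun(7, L = 2e4, T = 100, windowSize = 2e4)
  r2 <- neutralRun(7, L = 2e4, T = 100, windowSize = 2e4)
  expect_identical(landscapeValues(simLandscapes(r1)$pi_A),
                   landscapeValues(simLandscapes(r2)$pi_A))
  expect_identical(simFixations(r1), simFixations(r2))
  r3 <- neutralRun(8, L = 2e4, T = 100, windowSize = 2e4)
  expect_false(identical(landscapeValues(simLandscapes(r1)$pi_A),
                         landscapeValues(simLandscapes(r3)$pi_A)))
})

test_that("neutral-mode within-population TMRCA matches 2*Ne", {
  tr <- pairTree(1, 500, 500, samples = 4L)
  g <- windowGrid(300 * 1e4, 1e4, "c")
  s <- simulateNeutralWindows(tr, g, uniformRecombMap(300 * 1e4, 0),
                              seed = 3)
  ct <- simCoalTimes(s)
  v <- ct$meanT[ct$stat == "pi_A"]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - 2 * 500), 3 * se)
})

test_that("cross-population coalescence approximates T + 2*Ne_anc", {
  tr <- pairTree(5000, 10, 100, samples = 3L)
  g <- windowGrid(250 * 1e4, 1e4, "c")
  s <- simulateNeutralWindows(tr, g, uniformRecombMap(250 * 1e4, 0),
                              seed = 5)
  ct <- simCoalTimes(s)
  v <- ct$meanT[ct$stat == "dxy_A_B"]
  se <- sd(v) / sqrt(length(v))
  expect_lt(abs(mean(v) - (5000 + 2 * 100)), 3 * se)
})

test_that("averaging more loci per window reduces between-window variance", {
  tr <- pairTree(1, 400, 400, samples = 3L)
  g <- windowGrid(60 * 1e4, 1e4, "c")
  v <- lapply(c(1e-8, 2e-6), function(r) {
    s <- simulateNeutralWindows(tr, g, uniformRecombMap(60 * 1e4, r),
                                seed = 11)
    ct <- simCoalTimes(s)
    list(k = unique(ct$nLoci), v = ct$meanT[ct$stat == "pi_A"])
  })
  expect_equal(v[[1]]$k, 1L)
  expect_gte(min(v[[2]]$k), 20L)
  expect_gt(var(v[[1]]$v), var(v[[2]]$v))
})

test_that("overlaid divergence matches pi_anc + 2*mu*T in expectation", {
  T <- 2e4; Ne <- 1e4; mu <- 2e-8
  tr <- pairTree(T, Ne, Ne, samples = 3L)
  g <- windowGrid(200 * 1e5, 1e5, "c")
  s <- simulateNeutralWindows(tr, g, uniformRecombMap(200 * 1e5, 0),
                              seed = 9)
  ls <- overlayMutations(s, buildMutationMap(g, mu, 0, seed = 1), seed = 2)
  d <- landscapeValues(ls$dxy_A_B)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - (4 * Ne * mu + 2 * mu * T)), 3 * se)
})

test_that("shared ancestry correlates sister landscapes more than distant ones", {
  phy <- ape::read.tree(text = "((A:100,B:100)AB:99900,C:100000)root;")
  tr <- speciesTree(phy, ne = c(A = 1e4, B = 1e4, C = 1e4, AB = 1e4,
                                root = 1e4),
                    samples = c(A = 3, B = 3, C = 3))
  g <- windowGrid(80 * 1e5, 1e5, "c")
  s <- simulateNeutralWindows(tr, g, uniformRecombMap(80 * 1e5, 0),
                              seed = 13)
  ls <- overlayMutations(s, buildMutationMap(g, 2e-8, 0, seed = 1),
                         seed = 3)
  rAB <- spearmanRho(ls$pi_A, ls$pi_B)
  rAC <- spearmanRho(ls$pi_A, ls$pi_C)
  # T/(2Ne) = 0.005 for the sisters: almost all variation is ancestral
  expect_gt(rAB, rAC)
  expect_gt(rAB, 0.3)
})
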