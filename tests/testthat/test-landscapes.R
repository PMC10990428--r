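test_that("windowed diversity matches forced examples", {
  g <- windowGrid(100, 100, "c")
  mask <- fullMask(100, "c")
  # 2 haploid samples differing at 3 of 100 callable sites -> 0.03
  at <- alleleTable(c(10, 20, 30),
                    ac = matrix(1L, 3, 1, dimnames = list(NULL, "p")),
                    an = matrix(2L, 3, 1, dimnames = list(NULL, "p")))
  expect_equal(landscapeValues(windowedDiversity(at, mask, g, "p")), 0.03)
  # all samples identical -> 0 everywhere (no segregating sites)
  at0 <- alleleTable(integer(0),
                     ac = matrix(integer(0), 0, 1, dimnames = list(NULL, "p")),
                     an = matrix(integer(0), 0, 1, dimnames = list(NULL, "p")))
  expect_equal(landscapeValues(windowedDiversity(at0, mask, g, "p")), 0)
  expect_error(windowedDiversity(at, mask, g, "nope"), "unknown population")
})

test_that("windowed divergence matches forced examples and is symmetric", {
  g <- windowGrid(200, 200, "c")
  mask <- fullMask(200, "c")
  # popA fixed REF, popB fixed ALT at k = 4 of L = 200 callable sites
  ac <- cbind(a = c(0L, 0L, 0L, 0L), b = c(2L, 2L, 2L, 2L))
  an <- cbind(a = rep(2L, 4), b = rep(2L, 4))
  at <- alleleTable(c(5, 50, 120, 180), ac, an)
  expect_equal(landscapeValues(windowedDivergence(at, mask, g, "a", "b")),
               4 / 200)
  expect_equal(landscapeValues(windowedDivergence(at, mask, g, "b", "a")),
               4 / 200)
  # identical single-sample populations -> 0
  ac2 <- cbind(a = c(1L, 1L), b = c(1L, 1L))
  an2 <- cbind(a = c(1L, 1L), b = c(1L, 1L))
  at2 <- alleleTable(c(10, 20), ac2, an2)
  expect_equal(landscapeValues(windowedDivergence(at2, mask, g, "a", "b")),
               0)
  expect_error(windowedDivergence(at, mask, g, "a", "a"), "differ")
})

test_that("windowed statistics equal the brute-force pairwise oracle", {
  for (seed in 1:6) {
    L <- sample(100:500, 1)
    fx <- randomHapFixture(c(a = sample(2:4, 1), b = sample(2:4, 1)),
                           L, seed = seed)
    at <- fixtureAlleles(fx)
    # random mask: a handful of callable intervals
    set.seed(seed + 100)
    cut <- sort(sample.int(L - 1, 4))
    iv <- data.frame(start = c(0, cut[2], cut[4] - 1),
                     end = c(cut[1], cut[3], L))
    masks <- callableMask(list(a = iv, b = iv), chrom = "c")
    cm <- intersectMasks(masks)
    g <- windowGrid(L, ceiling(L / 2), "c")
    sites01 <- rep(FALSE, L)
    for (r in seq_len(nrow(iv))) sites01[(iv$start[r] + 1):iv$end[r]] <- TRUE
    for (w in 1:2) {
      wIdx <- (GenomicRanges::start(g)[w]):(GenomicRanges::end(g)[w])
      inW <- rep(FALSE, L); inW[wIdx] <- TRUE
      pi1 <- landscapeValues(windowedDiversity(at, masks, g, "a"))[w]
      expect_equal(pi1, brutePi(fx, "a", sites01 & inW), tolerance = 1e-12)
      d1 <- landscapeValues(windowedDivergence(at, masks, g, "a", "b"))[w]
      expect_equal(d1, bruteDxy(fx, "a", "b", sites01 & inW),
                   tolerance = 1e-12)
    }
  }
})

test_that("dXY between random halves of one population averages to its pi", {
  # exact identity when all half-splits are enumerated: each allele pair is
  # a cross-pair in the same fraction of splits
  fx <- randomHapFixture(c(p = 2L), 200, seed = 9)   # 4 haplotypes
  mask <- fullMask(200, "c")
  g <- windowGrid(200, 200, "c")
  at <- fixtureAlleles(fx)
  piP <- landscapeValues(windowedDiversity(at, mask, g, "p"))
  splits <- list(c(1, 2), c(1, 3), c(1, 4))
  dvals <- vapply(splits, function(half) {
    fx2 <- fx
    fx2$pops <- ifelse(seq_len(4) %in% half, "h1", "h2")
    at2 <- fixtureAlleles(fx2)
    landscapeValues(windowedDivergence(at2, mask, g, "h1", "h2"))
  }, 0)
  expect_equal(mean(dvals), piP, tolerance = 1e-12)
})

test_that("window filter drops strictly-below-threshold windows only", {
  g <- windowGrid(300, 100, "c")
  l <- methods::new("Landscape", stat = piStat("p"), grid = g,
                    values = c(0.01, 0.02, 0.03),
                    callableFrac = c(0.39, 0.40, 0.41))
  f <- applyWindowFilter(l, 0.40)
  expect_equal(is.na(landscapeValues(f)), c(TRUE, FALSE, FALSE))
  # recount on a synthetic mask fixture with known per-window fractions
  set.seed(4)
  fr <- runif(20)
  l2 <- methods::new("Landscape", stat = piStat("p"),
                     grid = windowGrid(2000, 100, "c"),
                     values = rep(0, 20), callableFrac = fr)
  f2 <- applyWindowFilter(l2, 0.40)
  expect_equal(sum(is.na(landscapeValues(f2))), sum(fr < 0.40))
})

test_that("site classification agrees with the exhaustive |S| oracle", {
  nuc <- c("A", "C", "G", "T")
  confs <- as.matrix(expand.grid(nuc, nuc, nuc, nuc,
                                 stringsAsFactors = FALSE))
  expect_equal(nrow(confs), 256)
  got <- classifySiteType(confs)
  want <- apply(confs, 1, classifyOracle)
  expect_equal(got, unname(want))
  # printed examples
  expect_equal(classifySiteType(c("A", "A", "T", "T")), "WW_SS")
  expect_equal(classifySiteType(c("A", "G", "A", "A")), "WS")
  expect_equal(classifySiteType(c("A", "G", "G", "C")), "multi_excluded")
  expect_equal(classifySiteType(c("G", "G", "C", "C")), "WW_SS")
  # missing state excludes the site; bad symbols are errors
  expect_true(is.na(classifySiteType(c("A", NA, "T", "T"))))
  expect_error(classifySiteType(c("A", "N", "T", "T")), "non-nucleotide")
})

test_that("outgroup polarization maps weak/strong/missing correctly", {
  expect_equal(polarizeByOutgroup(c("A", "T", "G", "C", NA)),
               c("ancestrally_weak", "ancestrally_weak",
                 "ancestrally_strong", "ancestrally_strong", "excluded"))
  expect_error(polarizeByOutgroup("X"), "non-nucleotide")
})

test_that("partitioned divergence restricts to the requested site class", {
  g <- windowGrid(1000, 1000, "c")
  mask <- fullMask(1000, "c")
  mk <- function(pos, ref, alt, acRow) {
    n <- length(pos)
    alleleTable(pos,
                ac = matrix(rep(acRow, each = n), n, 4,
                            dimnames = list(NULL, c("a", "b", "x", "y"))),
                an = matrix(2L, n, 4,
                            dimnames = list(NULL, c("a", "b", "x", "y"))),
                ref = rep(ref, n), alt = rep(alt, n))
  }
  # only W-W sites present: the WS partition has all-zero numerators
  atWW <- mk(c(100, 200, 300), "A", "T", c(0L, 0L, 2L, 2L))
  res <- partitionedDivergence(atWW, mask, g, c("a", "b"), c("x", "y"), "WS")
  expect_equal(landscapeValues(res[[1]]), 0)
  expect_equal(landscapeValues(res[[2]]), 0)
  # one W-S site differing within pairA only
  atWS <- mk(500, "A", "G", c(0L, 2L, 0L, 0L))
  res2 <- partitionedDivergence(atWS, mask, g, c("a", "b"), c("x", "y"),
                                "WS")
  expect_equal(landscapeValues(res2[[1]]), 1 / 1000)
  expect_equal(landscapeValues(res2[[2]]), 0)
  expect_error(partitionedDivergence(atWS, mask, g, c("a", "b"),
                                     c("b", "y"), "WS"), "distinct")
})

test_that("per-class site counts match brute-force reclassification", {
  set.seed(21)
  L <- 400
  nuc <- c("A", "C", "G", "T")
  fx <- randomHapFixture(c(a = 2L, b = 2L, x = 2L, y = 2L), L, seed = 31)
  ref <- sample(nuc, L, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nuc, r), 1), "")
  at <- fixtureAlleles(fx, ref = ref, alt = alt)
  pops <- c("a", "b", "x", "y")
  # brute force: per site majority state per pop, then the |S| rule
  states <- vapply(seq_len(nSites(at)), function(i) {
    st <- vapply(pops, function(p) {
      acp <- at@ac[i, p]; anp <- at@an[i, p]
      if (2 * acp > anp) at@alt[i]
      else if (2 * acp < anp) at@ref[i] else NA_character_
    }, "")
    classifyOracle(st)
  }, "")
  for (cl in c("WW_SS", "WS")) {
    want <- sum(states == cl, na.rm = TRUE)
    cls <- classifySiteType(apescapes:::representativeStates(at, pops))
    expect_equal(sum(cls == cl, na.rm = TRUE), want)
  }
  # classes partition the classified biallelic sites: restricted difference
  # counts sum to the unrestricted count over classified sites
  mask <- fullMask(L, "c"); g <- windowGrid(L, L, "c")
  cls <- classifySiteType(apescapes:::representativeStates(at, pops))
  keepAll <- !is.na(cls) & cls %in% c("WW_SS", "WS", "invariant")
  sub <- function(keep) {
    alleleTable(at@pos[keep], at@ac[keep, , drop = FALSE],
                at@an[keep, , drop = FALSE], ref = at@ref[keep],
                alt = at@alt[keep])
  }
  base <- landscapeValues(windowedDivergence(sub(keepAll), mask, g,
                                             "a", "x"))
  parts <- vapply(c("WW_SS", "WS", "invariant"), function(cl)
    landscapeValues(windowedDivergence(sub(!is.na(cls) & cls == cl), mask,
                                       g, "a", "x")), 0)
  expect_equal(sum(parts), base, tolerance = 1e-12)
})

test_that("allele tables validate their invariants", {
  expect_error(alleleTable(c(5, 5),
                           ac = matrix(0L, 2, 1, dimnames = list(NULL, "p")),
                           an = matrix(2L, 2, 1, dimnames = list(NULL, "p"))),
               "strictly increasing")
  expect_error(alleleTable(1,
                           ac = matrix(3L, 1, 1, dimnames = list(NULL, "p")),
                           an = matrix(2L, 1, 1, dimnames = list(NULL, "p"))),
               "exceed")
})
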