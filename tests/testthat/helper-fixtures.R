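# Shared fixtures and independent brute-force oracles.

# ((A:100,B:100)AB:900,C:1000): A,B split 100 generations ago, C 1000
toyTree <- function(neA = 1e4, samples = c(A = 2, B = 2, C = 2)) {
  speciesTree(ape::read.tree(text = "((A:100,B:100)AB:900,C:1000)root;"),
              ne = c(A = neA, B = 1e4, C = 1e4, AB = 2e4, root = 5e4),
              samples = samples)
}

# balanced quartet ((V,W),(X,Y))
quartetTree <- function() {
  speciesTree(
    ape::read.tree(text = "((V:100,W:100)VW:900,(X:500,Y:500)XY:500)root;"),
    ne = c(V = 1e4, W = 1e4, X = 1e4, Y = 1e4, VW = 2e4, XY = 2e4,
           root = 5e4),
    samples = c(V = 2, W = 2, X = 2, Y = 2))
}

# random ultrametric tree with generations-scale depth and random sizes
randomTree <- function(ntips, seed) {
  set.seed(seed)
  phy <- ape::rcoal(ntips, tip.label = paste0("t", seq_len(ntips)))
  phy$edge.length <- phy$edge.length * 1e4
  phy$node.label <- paste0("n", seq_len(phy$Nnode))
  ne <- setNames(round(runif(ntips + phy$Nnode, 1e3, 5e4)),
                 c(phy$tip.label, phy$node.label))
  speciesTree(phy, ne, setNames(rep(2L, ntips), phy$tip.label))
}

# oracle: MRCA by intersecting root-to-tip node paths
mrcaOracle <- function(tree, pops) {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  parent <- integer(max(phy$edge)); parent[phy$edge[, 2]] <- phy$edge[, 1]
  chain <- function(tip) {
    n <- match(tip, phy$tip.label)
    out <- n
    while (parent[n] != 0L) { n <- parent[n]; out <- c(out, n) }
    out
  }
  common <- Reduce(intersect, lapply(pops, chain))
  labs[common[1]]  # chains are ordered tipward-first
}

# random haplotype fixture: list(haps = 0/1 matrix (2*sum(n) x L), pops)
randomHapFixture <- function(nPerPop, L, seed, pVariant = 0.15) {
  set.seed(seed)
  H <- 2L * sum(nPerPop)
  haps <- matrix(0L, H, L)
  nv <- rbinom(1, L, pVariant)
  sites <- sort(sample.int(L, nv))
  for (s in sites) haps[sample.int(H, sample.int(H - 1L, 1)), s] <- 1L
  list(haps = haps, pops = rep(names(nPerPop), 2L * nPerPop), sites = sites)
}

# fixture -> AlleleTable (all sites, including invariant columns dropped)
fixtureAlleles <- function(fx, ref = NULL, alt = NULL) {
  seg <- which(colSums(fx$haps) > 0 & colSums(fx$haps) < nrow(fx$haps))
  pops <- unique(fx$pops)
  ac <- vapply(pops, function(p)
    colSums(fx$haps[fx$pops == p, seg, drop = FALSE]), numeric(length(seg)))
  an <- vapply(pops, function(p)
    rep(sum(fx$pops == p), length(seg)), numeric(length(seg)))
  if (length(seg) == 1L) { ac <- t(ac); an <- t(an) }
  alleleTable(seg, ac, an,
              ref = if (is.null(ref)) NULL else ref[seg],
              alt = if (is.null(alt)) NULL else alt[seg])
}

# O(n^2 L) brute-force windowed pi over callable sites `sites01` (logical L)
brutePi <- function(fx, pop, sites01) {
  h <- fx$haps[fx$pops == pop, sites01, drop = FALSE]
  n <- nrow(h)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(h[i, ] != h[j, ])
  tot / choose(n, 2) / sum(sites01)
}

bruteDxy <- function(fx, popA, popB, sites01) {
  ha <- fx$haps[fx$pops == popA, sites01, drop = FALSE]
  hb <- fx$haps[fx$pops == popB, sites01, drop = FALSE]
  tot <- 0
  for (i in seq_len(nrow(ha))) for (j in seq_len(nrow(hb)))
    tot <- tot + sum(ha[i, ] != hb[j, ])
  tot / (nrow(ha) * nrow(hb)) / sum(sites01)
}

# oracle: site class from the |distinct states| rule
classifyOracle <- function(states) {
  if (anyNA(states)) return(NA_character_)
  S <- unique(states)
  if (length(S) == 1) return("invariant")
  if (length(S) >= 3) return("multi_excluded")
  w <- S %in% c("A", "T")
  if (sum(w) == 1) "WS" else "WW_SS"
}

# oracle: Spearman as Pearson on average ranks
spearmanOracle <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  cor(rank(x[ok]), rank(y[ok]))
}

# full-chromosome mask
fullMask <- function(L, chrom = "chr12")
  GenomicRanges::GRanges(chrom, IRanges::IRanges(1, L))

# two-tip tree helper for simulator calibrations
pairTree <- function(T, neTip, neAnc = neTip, samples = 5L) {
  speciesTree(
    ape::read.tree(text = sprintf("(A:%d,B:%d)root;", T, T)),
    ne = c(A = neTip, B = neTip, root = neAnc),
    samples = c(A = samples, B = samples))
}

# synthetic SimResult carrying given per-window mean coalescence times
fakeNeutralResult <- function(tree, grid, meanT) {
  desc <- allDescriptors(tree)
  ct <- do.call(rbind, lapply(seq_along(meanT[[1]]), function(w)
    data.frame(window = w, stat = names(desc),
               meanT = vapply(names(desc), function(s) meanT[[s]][w], 0),
               nLoci = 1L)))
  methods::new("SimResult", landscapes = list(), fixations = data.frame(),
               coalTimes = ct, genealogies = list(), alleles = NULL,
               config = list(tree = tree, grid = grid), seed = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
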