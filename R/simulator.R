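## Forward Wright-Fisher simulation of the species tree (Rcpp core) and a
## fast neutral multispecies-coalescent mode with per-window genealogies.

#' Build a recombination map
#'
#' @param start,end 0-based half-open interval bounds tiling the chromosome.
#' @param rate crossover rate per bp per generation.
#' @return data.frame recombination map.
#' @export
recombinationMap <- function(start, end, rate) {
  stopifnot(length(start) == length(end), length(end) == length(rate),
            all(rate >= 0), all(end > start))
  o <- order(start)
  df <- data.frame(start = start[o], end = end[o], rate = rate[o])
  if (any(df$start[-1] != df$end[-nrow(df)]))
    stop("recombination intervals must tile the chromosome")
  df
}

#' Uniform recombination map over a chromosome
#' @param chromLength chromosome length in bp.
#' @param rate per-bp per-generation crossover rate.
#' @export
uniformRecombMap <- function(chromLength, rate = 1e-8)
  recombinationMap(0, chromLength, rate)

#' Configure a forward simulation
#'
#' @param tree a [SpeciesTree-class].
#' @param chromLength chromosome length in bp.
#' @param mu total per-site per-generation mutation rate (default `2e-8`).
#' @param dfe a [DFEConfig-class] for exonic mutations.
#' @param exons data.frame with 0-based half-open `start`, `end` columns, or
#'   an [IRanges::IRanges]; default none.
#' @param recomb recombination map data.frame (see [recombinationMap()]);
#'   default uniform `1e-8`.
#' @param windowSize window size for output landscapes.
#' @param burninMult burn-in length in units of the (rescaled) root Ne.
#' @param seed integer seed.
#' @return a [SimulationConfig-class] (unrescaled; see [rescaleConfig()]).
#' @export
simulationConfig <- function(tree, chromLength, mu = 2e-8,
                             dfe = dfeConfig(), exons = NULL, recomb = NULL,
                             windowSize = chromLength, burninMult = 10,
                             seed = 1L) {
  if (is.null(recomb)) recomb <- uniformRecombMap(chromLength)
  ex <- if (is.null(exons)) IRanges::IRanges()
        else if (is.data.frame(exons))
          IRanges::IRanges(exons$start + 1L, exons$end)
        else exons
  grid <- windowGrid(chromLength, windowSize)
  methods::new("SimulationConfig", tree = tree, mu = mu, dfe = dfe,
               exons = ex, recomb = recomb, grid = grid,
               chromLength = chromLength, rescaleQ = 1,
               burninMult = burninMult, seed = as.integer(seed))
}

#' Rescale a simulation configuration by a factor Q
#'
#' Standard population-genetic rescaling: effective sizes and branch lengths
#' are divided by `Q` (sizes rounded), while the mutation rate, the
#' recombination rates and -- at draw time -- the selection coefficients are
#' multiplied by `Q`, preserving the products `4 Ne mu`, `4 Ne r` and
#' `4 Ne s` that govern the dynamics (up to rounding).  `Q = 1` is the
#' identity.
#'
#' @param config a [SimulationConfig-class].
#' @param Q rescaling factor `>= 1`.
#' @return the rescaled [SimulationConfig-class] (with `rescaleQ` recording
#'   the cumulative factor used to scale selection coefficients).
#' @export
rescaleConfig <- function(config, Q) {
  if (Q < 1) stop("Q must be >= 1")
  if (Q == 1) return(config)
  tree <- config@tree
  newNe <- round(tree@ne / Q)
  if (any(newNe < 2))
    stop("Q too large: a rescaled Ne falls below 2 diploids")
  phy <- tree@phylo
  phy$edge.length <- phy$edge.length / Q
  tree2 <- methods::new("SpeciesTree", phylo = phy, ne = newNe,
                        samples = tree@samples)
  rc <- config@recomb
  rc$rate <- rc$rate * Q
  methods::initialize(config, tree = tree2, mu = config@mu * Q, recomb = rc,
                      rescaleQ = config@rescaleQ * Q)
}

## pre-order branch table for the C++ core
branchTable <- function(tree) {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  root <- setdiff(phy$edge[, 1], phy$edge[, 2])
  ord <- root
  repeat {
    kids <- phy$edge[phy$edge[, 1] %in% ord & !phy$edge[, 2] %in% ord, 2]
    if (!length(kids)) break
    ord <- c(ord, kids)
  }
  parent <- integer(max(phy$edge)); parent[phy$edge[, 2]] <- phy$edge[, 1]
  blen <- numeric(max(phy$edge)); blen[phy$edge[, 2]] <- phy$edge.length
  ntip <- length(phy$tip.label)
  list(name = labs[ord],
       parent = match(ifelse(ord == root, NA_integer_, parent[ord]), ord) - 1L,
       gens = as.integer(round(blen[ord])),
       N = as.integer(round(tree@ne[labs[ord]])),
       isTip = ord <= ntip,
       nSamples = as.integer(ifelse(ord <= ntip,
                                    tree@samples[labs[ord]], 0L)))
}

#' Forward Wright--Fisher simulation of a species tree
#'
#' Runs a burn-in of `burninMult` times the (rescaled) root Ne generations
#' in the ancestral population, then traverses the tree: at each split both
#' daughter populations start as replicas of the parent, and each branch
#' evolves for its length at its constant diploid size.  Mutation classes
#' are drawn from the [DFEConfig-class] within exons (neutral elsewhere and
#' for the residual exonic fraction); fitness is multiplicative across sites
#' and additive within a site (h = 0.5: genotype fitnesses 1, 1+s, 1+2s, so
#' `s` is the per-allele-copy effect, the convention under which a new
#' beneficial mutation fixes with probability about `2s` as in
#' [fixationProbability()]).  Every mutation reaching frequency
#' 1 within a branch is recorded as a fixation; fixed neutral (and selected)
#' mutations contribute fixed differences to the tip allele table, so
#' between-species divergence includes the substitution process.
#'
#' @param config a [SimulationConfig-class] (apply [rescaleConfig()] first
#'   for desk-scale runs; branch lengths/sizes are used as-is).
#' @param sweepEvery generations between fixation sweeps (granularity of
#'   recorded fixation times).
#' @return a [SimResult-class] with landscapes (pi per tip, dXY per pair on
#'   the config grid), fixation records, and the tip-sample
#'   [AlleleTable-class].
#' @export
simulateForward <- function(config, sweepEvery = 10L) {
  tree <- config@tree
  bt <- branchTable(tree)
  dfe <- config@dfe
  params <- list(
    L = config@chromLength,
    exonStart = as.numeric(IRanges::start(config@exons) - 1L),
    exonEnd = as.numeric(IRanges::end(config@exons)),
    muNeutralNonExon = config@mu,
    muNeutralExon = config@mu * (1 - dfe@fracDeleterious - dfe@fracBeneficial),
    muDel = config@mu * dfe@fracDeleterious,
    muBen = config@mu * dfe@fracBeneficial,
    gammaShape = dfe@gammaShape,
    gammaScale = abs(dfe@meanSDel) / dfe@gammaShape,
    expMean = dfe@meanSBen,
    sFactor = config@rescaleQ,
    recombStart = config@recomb$start, recombEnd = config@recomb$end,
    recombRate = config@recomb$rate)
  rootN <- bt$N[1]
  burnin <- as.integer(round(config@burninMult * rootN))
  raw <- .forwardWF(bt, params, burnin, as.integer(sweepEvery),
                    as.numeric(config@seed))
  fix <- data.frame(branch = bt$name[raw$fixBranch],
                    pos = floor(raw$fixPos) + 1,
                    class = c("neutral", "deleterious", "beneficial")[raw$fixClass + 1L],
                    s = raw$fixS, generation = raw$fixGen,
                    stringsAsFactors = FALSE)
  at <- assembleForwardAlleles(raw, bt, tree, fix)
  mask <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(config@grid)[1]),
    IRanges::IRanges(1, config@chromLength))
  tips <- tipNames(tree)
  ls <- lapply(allDescriptors(tree), function(d) {
    tx <- statTaxa(d)
    if (statKind(d) == "diversity") windowedDiversity(at, mask, config@grid, tx)
    else windowedDivergence(at, mask, config@grid, tx[1], tx[2])
  })
  methods::new("SimResult", landscapes = ls, fixations = fix,
               coalTimes = data.frame(), genealogies = list(), alleles = at,
               config = config, seed = config@seed)
}

## build the tip-sample AlleleTable from raw C++ output: segregating sites
## in the samples plus fixed differences from post-root fixation records
assembleForwardAlleles <- function(raw, bt, tree, fix) {
  tips <- bt$name[bt$isTip]
  rootName <- bt$name[1]
  segIds <- sort(unique(unlist(lapply(which(bt$isTip), function(i)
    unlist(raw$tipHaps[[i]])))))
  fixRec <- fix[fix$branch != rootName, , drop = FALSE]
  # branches on the root-to-tip path of each tip
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  pathOf <- lapply(tips, function(tp)
    labs[ancestorChain(phy, nodeNumber(tree, tp))])
  names(pathOf) <- tips
  # fixed mutation ids and which tips carry them
  fixIds <- integer(0)
  if (nrow(fixRec)) {
    # recover registry ids of fixed records by matching position is fragile;
    # instead the C++ side reports class/s/pos: treat each fixed record as
    # its own site (ids beyond the registry are synthesized)
    fixIds <- seq_len(nrow(fixRec))
  }
  segPos <- floor(raw$mutPos[segIds + 1L]) + 1L
  allPos <- c(segPos, if (length(fixIds)) as.integer(fixRec$pos) else integer(0))
  isFix <- c(rep(FALSE, length(segIds)), rep(TRUE, length(fixIds)))
  srcId <- c(segIds, fixIds)
  o <- order(allPos, isFix, srcId)
  allPos <- allPos[o]; isFix <- isFix[o]; srcId <- srcId[o]
  # drop duplicate positions (finite-sites collisions are rare; keep first)
  dup <- duplicated(allPos)
  allPos <- allPos[!dup]; isFix <- isFix[!dup]; srcId <- srcId[!dup]
  n <- length(allPos)
  ac <- matrix(0L, n, length(tips), dimnames = list(NULL, tips))
  an <- matrix(0L, n, length(tips), dimnames = list(NULL, tips))
  segRowOf <- match(segIds, replace(srcId, isFix, NA_integer_))
  for (k in seq_along(tips)) {
    i <- which(bt$isTip)[k]
    haps <- raw$tipHaps[[i]]
    an[, k] <- length(haps)
    cnt <- as.integer(table(factor(unlist(haps), levels = segIds)))
    ok <- !is.na(segRowOf)
    ac[segRowOf[ok], k] <- ac[segRowOf[ok], k] + cnt[ok]
  }
  if (any(isFix)) {
    for (r in which(isFix)) {
      br <- fixRec$branch[srcId[r]]
      carrier <- vapply(tips, function(tp) br %in% pathOf[[tp]], TRUE)
      ac[r, carrier] <- an[r, carrier]
    }
  }
  alleleTable(allPos, ac, an)
}

## -- neutral multispecies-coalescent mode ----------------------------------

## one multispecies-coalescent genealogy; lineagesPerTip: named int vector of
## haploid sample sizes.  Returns pairwise coalescence-time matrix over
## haplotypes (grouped by tip, in tip order) and a node-table genealogy.
simulateMSC <- function(tree, lineagesPerTip) {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  tims <- nodeTimes(tree)
  H <- sum(lineagesPerTip)
  hapTip <- rep(names(lineagesPerTip), lineagesPerTip)
  Tmat <- matrix(0, H, H)
  # genealogy arrays: nodes 1..H are haplotypes; internal appended
  parent <- integer(2L * H); ntime <- numeric(2L * H); nnodes <- H
  # clade membership per active lineage; lineage node id in genealogy
  offs <- c(0, cumsum(lineagesPerTip))
  names(offs) <- NULL
  active <- list()  # per species-tree node label: list of lineages
  coalesceIn <- function(lins, Ne, t0, t1) {
    t <- t0
    while (length(lins$members) > 1L) {
      k <- length(lins$members)
      t <- t + rexp(1, rate = k * (k - 1) / 2 / (2 * Ne))
      if (t >= t1) return(lins)
      ij <- sample.int(k, 2L)
      a <- lins$members[[ij[1]]]; b <- lins$members[[ij[2]]]
      Tmat[a, b] <<- t; Tmat[b, a] <<- t
      nnodes <<- nnodes + 1L
      ntime[nnodes] <<- t
      parent[lins$nodes[ij[1]]] <<- nnodes
      parent[lins$nodes[ij[2]]] <<- nnodes
      lins$members[[ij[1]]] <- c(a, b)
      lins$nodes[ij[1]] <- nnodes
      lins$members <- lins$members[-ij[2]]
      lins$nodes <- lins$nodes[-ij[2]]
    }
    lins
  }
  # process species nodes in time order (tips first)
  procOrder <- order(tims[labs])
  surv <- list()
  parentLab <- function(lab) {
    e <- phy$edge
    i <- match(nodeNumber(tree, lab), e[, 2])
    if (is.na(i)) NA_character_ else labs[e[i, 1]]
  }
  for (lab in labs[procOrder]) {
    num <- nodeNumber(tree, lab)
    if (num <= length(phy$tip.label)) {
      k <- match(lab, names(lineagesPerTip))
      ids <- (offs[k] + 1L):(offs[k] + lineagesPerTip[k])
      lins <- list(members = as.list(ids), nodes = as.integer(ids))
    } else {
      kids <- labs[phy$edge[phy$edge[, 1] == num, 2]]
      lins <- list(members = list(), nodes = integer(0))
      for (kd in kids) {
        lins$members <- c(lins$members, surv[[kd]]$members)
        lins$nodes <- c(lins$nodes, surv[[kd]]$nodes)
      }
    }
    pl <- parentLab(lab)
    t1 <- if (is.na(pl)) Inf else tims[pl]
    surv[[lab]] <- coalesceIn(lins, tree@ne[lab], tims[lab], t1)
  }
  list(Tmat = Tmat, hapTip = hapTip,
       parent = parent[seq_len(nnodes)], time = ntime[seq_len(nnodes)],
       nTips = H)
}

## mean pairwise coalescence times for every descriptor, from one Tmat
mscMeanTimes <- function(Tmat, hapTip, descriptors) {
  vapply(descriptors, function(d) {
    tx <- statTaxa(d)
    if (statKind(d) == "diversity") {
      i <- which(hapTip == tx)
      if (length(i) < 2L) return(NA_real_)
      m <- Tmat[i, i]
      mean(m[upper.tri(m)])
    } else {
      i <- which(hapTip == tx[1]); j <- which(hapTip == tx[2])
      mean(Tmat[i, j, drop = FALSE])
    }
  }, 0)
}

#' Neutral multispecies-coalescent simulation in windows
#'
#' Per window, simulates `k` independent recombination-free genealogies
#' under the multispecies coalescent with the tree's branch sizes, where
#' `k = max(1, round(lociPerCM * window map length in cM))` so averaging
#' within a window scales with its genetic length (a 1 cM window gives 10
#' loci at the default).  Stores the realized mean pairwise coalescence time
#' per window for every diversity and divergence descriptor; landscapes are
#' obtained afterwards by overlaying mutations ([overlayMutations()]), so
#' the same genealogies can be reused across mutation-rate maps.
#'
#' @param tree a [SpeciesTree-class] with tip sample counts.
#' @param grid window [GenomicRanges::GRanges].
#' @param recomb recombination map data.frame (0-based half-open
#'   `start`,`end`,`rate`), or `NULL` for a uniform `1e-8` map.
#' @param seed integer seed.
#' @param lociPerCM genealogies per centimorgan of window map length.
#' @param keepGenealogies keep per-locus genealogies (needed for
#'   genotype-level mutation dropping by the synthetic-data generator).
#' @return a [SimResult-class] with `coalTimes` filled in (and
#'   `genealogies` if requested).
#' @export
simulateNeutralWindows <- function(tree, grid, recomb = NULL, seed = 1L,
                                   lociPerCM = 10, keepGenealogies = FALSE) {
  if (any(tipSamples(tree) < 1L)) stop("every tip needs at least one sample")
  set.seed(seed)
  chromLength <- max(GenomicRanges::end(grid))
  if (is.null(recomb)) recomb <- uniformRecombMap(chromLength)
  lin <- 2L * tipSamples(tree)[tipNames(tree)]
  desc <- allDescriptors(tree)
  nw <- length(grid)
  # map length (Morgans) per window
  rcg <- GenomicRanges::GRanges(
    as.character(GenomicRanges::seqnames(grid)[1]),
    IRanges::IRanges(recomb$start + 1L, recomb$end))
  ov <- GenomicRanges::findOverlaps(grid, rcg)
  wbp <- IRanges::width(IRanges::pintersect(grid[S4Vectors::queryHits(ov)],
                                            rcg[S4Vectors::subjectHits(ov)]))
  morg <- numeric(nw)
  mm <- tapply(wbp * recomb$rate[S4Vectors::subjectHits(ov)],
               S4Vectors::queryHits(ov), sum)
  morg[as.integer(names(mm))] <- mm
  k <- pmax(1L, as.integer(round(lociPerCM * morg * 100)))
  coal <- vector("list", nw)
  gen <- if (keepGenealogies) vector("list", nw) else list()
  for (w in seq_len(nw)) {
    acc <- matrix(0, length(desc), k[w])
    loci <- if (keepGenealogies) vector("list", k[w]) else NULL
    for (l in seq_len(k[w])) {
      msc <- simulateMSC(tree, lin)
      acc[, l] <- mscMeanTimes(msc$Tmat, msc$hapTip, desc)
      if (keepGenealogies) loci[[l]] <- msc[c("parent", "time", "nTips", "hapTip")]
    }
    coal[[w]] <- data.frame(window = w, stat = names(desc),
                            meanT = rowMeans(acc), nLoci = k[w])
    if (keepGenealogies) gen[[w]] <- loci
  }
  methods::new("SimResult", landscapes = list(),
               fixations = data.frame(),
               coalTimes = do.call(rbind, coal),
               genealogies = gen, alleles = NULL,
               config = list(tree = tree, grid = grid, recomb = recomb,
                             lociPerCM = lociPerCM),
               seed = as.integer(seed))
}

#' @describeIn simulateForward landscapes of a result, named by [statLabel()].
#' @param x a [SimResult-class].
#' @export
simLandscapes <- function(x) x@landscapes

#' @describeIn simulateForward fixation records of a result.
#' @export
simFixations <- function(x) x@fixations

#' @describeIn simulateForward realized mean pairwise coalescence times
#'   (neutral mode).
#' @export
simCoalTimes <- function(x) x@coalTimes

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d landscapes, %d fixation records, %s coalescence summaries (seed %d)\n",
              length(object@landscapes), nrow(object@fixations),
              if (nrow(object@coalTimes)) "with" else "no", object@seed))
})
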