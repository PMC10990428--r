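## Seeded synthetic dataset generator: a self-contained stand-in with the
## statistical structure of a ten-population great-apes panel (VCF + masks +
## exons + recombination map + truth record).

#' Specify a synthetic dataset
#'
#' Defaults emulate the empirical panel: the ten populations of
#' [greatApesTree()] with their printed sample counts, nucleotide states,
#' per-population callable masks with a controllable fraction of windows
#' below the 40% threshold, an outgroup allele at a fraction of sites, and
#' heterogeneous exon-density and recombination-rate profiles.  The
#' chromosome is desk-scale (1 Mb of 50 kb windows by default); window size
#' and length are free parameters.
#'
#' @param tree a [SpeciesTree-class] with tip sample counts.
#' @param chromLength,windowSize chromosome and window lengths in bp.
#' @param chrom chromosome name used in output files.
#' @param mu neutral per-site per-generation mutation rate.
#' @param lowCallableFrac fraction of windows drawn below 40% callable.
#' @param exonDensity optional per-window exon densities in `[0,1]`
#'   (recycled); default: an internally drawn profile.
#' @param recombRates optional per-window recombination rates; default: a
#'   log-normal profile around `1e-8` including a near-zero window.
#' @param outgroupFrac fraction of variant sites carrying an outgroup
#'   (ancestral) allele.
#' @param lociPerWindow lower bound on independent genealogies per window.
#' @return a [SyntheticDatasetSpec-class].
#' @export
syntheticDatasetSpec <- function(tree = greatApesTree(), chromLength = 1e6,
                                 windowSize = 5e4, chrom = "chr12",
                                 mu = 2e-8, lowCallableFrac = 0.15,
                                 exonDensity = numeric(0),
                                 recombRates = numeric(0),
                                 outgroupFrac = 0.7, lociPerWindow = 2) {
  methods::new("SyntheticDatasetSpec", tree = tree,
               chromLength = chromLength, windowSize = windowSize,
               chrom = chrom, mu = mu, lowCallableFrac = lowCallableFrac,
               exonDensity = exonDensity, recombRates = recombRates,
               outgroupFrac = outgroupFrac, lociPerWindow = lociPerWindow)
}

setMethod("show", "SyntheticDatasetSpec", function(object) {
  cat(sprintf("SyntheticDatasetSpec: %d pops, %.0f bp in %.0f bp windows, mu=%.3g\n",
              length(tipNames(object@tree)), object@chromLength,
              object@windowSize, object@mu))
})

## descendant tip sets per genealogy node (parent-pointer representation)
descendantTips <- function(parent, nTips) {
  n <- length(parent)
  sets <- vector("list", n)
  for (i in seq_len(nTips)) sets[[i]] <- i
  # internal nodes appear after tips in creation (time) order
  kids <- split(seq_len(n)[parent > 0], parent[parent > 0])
  for (i in (nTips + 1L):n) {
    ch <- kids[[as.character(i)]]
    sets[[i]] <- unlist(sets[ch], use.names = FALSE)
  }
  sets
}

## drop mutations on one genealogy: returns list(posFrac, carriers) where
## posFrac is in [0,1) within the locus span
dropMutations <- function(gen, mu, bpSpan) {
  parent <- gen$parent; tm <- gen$time; nT <- gen$nTips
  sets <- descendantTips(parent, nT)
  hasPar <- which(parent > 0)
  elen <- tm[parent[hasPar]] - tm[hasPar]
  nm <- rpois(length(hasPar), mu * elen * bpSpan)
  tot <- sum(nm)
  if (tot == 0) return(list(posFrac = numeric(0), carriers = list()))
  node <- rep(hasPar, nm)
  list(posFrac = runif(tot), carriers = sets[node])
}

#' Generate a synthetic dataset
#'
#' Runs the neutral multispecies-coalescent simulator on the spec's tree and
#' window grid, drops mutations onto the genealogies, assigns
#' ancestral/derived nucleotides uniformly over ordered pairs, plants the
#' outgroup allele (equal to the simulated ancestral state) at a fraction of
#' sites, and writes standards-compliant files: a VCF 4.2 with per-sample
#' phased GT, one callable-mask BED per population, an exon BED, a
#' recombination-map TSV, the species tree (Newick + branch-parameter TSV),
#' and a truth JSON recording seeds, per-window design values and the
#' internally computed landscapes for recovery tests.  Output is
#' byte-identical for a fixed seed.
#'
#' @param spec a [SyntheticDatasetSpec-class].
#' @param seed integer seed.
#' @param outdir output directory (created if needed).
#' @return invisibly, a named list of the file paths plus the in-memory
#'   [AlleleTable-class] and masks.
#' @export
generateDataset <- function(spec, seed = 1L, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  tree <- spec@tree
  grid <- windowGrid(spec@chromLength, spec@windowSize, spec@chrom)
  nw <- length(grid)
  wlen <- IRanges::width(grid)

  ## design profiles
  exDen <- if (length(spec@exonDensity)) rep_len(spec@exonDensity, nw)
           else pmin(0.35, stats::rgamma(nw, shape = 2, scale = 0.03))
  rcRate <- if (length(spec@recombRates)) rep_len(spec@recombRates, nw)
            else { r <- stats::rlnorm(nw, log(1e-8), 0.7); r[1] <- 1e-10; r }
  recomb <- recombinationMap(GenomicRanges::start(grid) - 1L,
                             GenomicRanges::end(grid), rcRate)

  ## exon intervals: tile each window's exonic bp as 2 kb blocks spread out
  exList <- lapply(seq_len(nw), function(w) {
    bp <- round(exDen[w] * wlen[w])
    if (bp < 1) return(NULL)
    nEx <- max(1L, ceiling(bp / 2000))
    sz <- rep(floor(bp / nEx), nEx); sz[1] <- sz[1] + bp - sum(sz)
    gap <- floor((wlen[w] - bp) / (nEx + 1))
    st <- GenomicRanges::start(grid)[w] - 1L +
      cumsum(c(gap, head(sz, -1) + gap))
    data.frame(start = st, end = st + sz)
  })
  exons <- do.call(rbind, exList)

  ## callable masks: a designed joint interval per window plus disjoint
  ## population-specific extras (so the intersection equals the design)
  nLow <- floor(spec@lowCallableFrac * nw)
  lowWin <- if (nLow > 0) sort(sample.int(nw, nLow)) else integer(0)
  jointFrac <- runif(nw, 0.55, 0.95)
  jointFrac[lowWin] <- runif(nLow, 0.05, 0.35)
  jointLen <- round(jointFrac * wlen)
  pops <- tipNames(tree)
  ws <- GenomicRanges::start(grid) - 1L
  masks <- lapply(seq_along(pops), function(k) {
    ext <- pmax(0, floor((wlen - jointLen) / (length(pops) + 1)) - 2L)
    st2 <- ws + jointLen + (k - 1L) * (ext + 2L)
    keep <- ext > 0 & st2 + ext <= ws + wlen
    df <- rbind(data.frame(start = ws, end = ws + jointLen),
                data.frame(start = st2[keep], end = (st2 + ext)[keep]))
    df[df$end > df$start, ]
  })
  names(masks) <- pops
  maskList <- callableMask(masks, chrom = spec@chrom)
  joint <- intersectMasks(maskList)

  ## neutral genealogies
  sim <- simulateNeutralWindows(tree, grid, recomb,
                                seed = seed + 1000L,
                                keepGenealogies = TRUE)
  ## ensure the lower bound on loci was respected is not needed: drop
  ## mutations per realized locus
  hapTipOrder <- rep(pops, 2L * tipSamples(tree)[pops])

  ## drop mutations
  siteRows <- list()
  for (w in seq_len(nw)) {
    loci <- sim@genealogies[[w]]
    k <- length(loci)
    span <- wlen[w] / k
    for (l in seq_len(k)) {
      mut <- dropMutations(loci[[l]], spec@mu, span)
      if (!length(mut$posFrac)) next
      pos0 <- ws[w] + (l - 1) * span + mut$posFrac * span
      siteRows[[length(siteRows) + 1L]] <-
        list(pos = as.integer(floor(pos0)) + 1L, carriers = mut$carriers)
    }
  }
  pos <- unlist(lapply(siteRows, `[[`, "pos"))
  carriers <- do.call(c, lapply(siteRows, `[[`, "carriers"))
  o <- order(pos)
  pos <- pos[o]; carriers <- carriers[o]
  dup <- duplicated(pos)               # finite-sites collisions: keep first
  pos <- pos[!dup]; carriers <- carriers[!dup]
  nSite <- length(pos)

  ## per-population counts, honouring per-population masks
  H <- length(hapTipOrder)
  nPerPop <- 2L * tipSamples(tree)[pops]
  ac <- matrix(0L, nSite, length(pops), dimnames = list(NULL, pops))
  an <- matrix(rep(nPerPop, each = nSite), nSite, length(pops),
               dimnames = list(NULL, pops))
  for (i in seq_len(nSite)) {
    tb <- table(factor(hapTipOrder[carriers[[i]]], levels = pops))
    ac[i, ] <- as.integer(tb)
  }
  for (p in pops) {
    inP <- IRanges::overlapsAny(
      GenomicRanges::GRanges(spec@chrom, IRanges::IRanges(pos, pos)),
      maskList[[p]])
    an[!inP, p] <- 0L
    ac[!inP, p] <- 0L
  }

  ## nucleotide assignment: ordered (ancestral, derived) pair uniform
  nuc <- c("A", "C", "G", "T")
  prs <- expand.grid(anc = nuc, der = nuc, stringsAsFactors = FALSE)
  prs <- prs[prs$anc != prs$der, ]
  pick <- sample.int(nrow(prs), nSite, replace = TRUE)
  anc <- prs$anc[pick]; der <- prs$der[pick]
  og <- ifelse(runif(nSite) < spec@outgroupFrac, anc, NA_character_)

  at <- alleleTable(pos, ac, an, ref = anc, alt = der, outgroup = og)

  ## write files
  paths <- list(
    vcf = file.path(outdir, "synthetic.vcf"),
    exons = file.path(outdir, "exons.bed"),
    recomb = file.path(outdir, "recomb_map.tsv"),
    newick = file.path(outdir, "tree.nwk"),
    treeParams = file.path(outdir, "tree_params.tsv"),
    truth = file.path(outdir, "truth.json"))
  for (p in pops)
    paths[[paste0("mask_", p)]] <- file.path(outdir, sprintf("mask_%s.bed", p))
  writeBed(exons, paths$exons, chrom = spec@chrom)
  writeRecombMap(recomb, paths$recomb)
  writeSpeciesTree(tree, paths$newick, paths$treeParams)
  for (p in pops) {
    m <- masks[[p]]
    writeBed(m[order(m$start), ], paths[[paste0("mask_", p)]],
             chrom = spec@chrom)
  }
  writeSyntheticVcf(paths$vcf, spec, at, carriers, hapTipOrder, maskList)

  ## internal landscapes and truth record
  desc <- allDescriptors(tree)
  internal <- lapply(desc, function(d) {
    tx <- statTaxa(d)
    l <- if (statKind(d) == "diversity")
      windowedDiversity(at, joint, grid, tx)
    else windowedDivergence(at, joint, grid, tx[1], tx[2])
    l@values
  })
  ct <- sim@coalTimes
  expected <- lapply(names(desc), function(lab) {
    rows <- ct[ct$stat == lab, ]
    v <- rep(NA_real_, nw); v[rows$window] <- 2 * spec@mu * rows$meanT
    v
  })
  names(expected) <- names(desc)
  truth <- list(seed = seed, chrom = spec@chrom,
                chromLength = spec@chromLength, windowSize = spec@windowSize,
                mu = spec@mu, populations = as.list(tipSamples(tree)),
                lowWindows = lowWin, jointCallableFrac = jointFrac,
                exonDensity = exDen, recombRates = rcRate,
                nSites = nSite,
                internalLandscapes = internal,
                expectedLandscapes = expected)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(alleles = at, masks = maskList, grid = grid)))
}

## VCF 4.2 writer with phased GT and AA INFO tag
writeSyntheticVcf <- function(file, spec, at, carriers, hapTipOrder,
                              maskList) {
  pops <- unique(hapTipOrder)
  nInd <- table(factor(hapTipOrder, levels = pops)) / 2L
  sampleNames <- unlist(lapply(pops, function(p)
    sprintf("%s_%d", p, seq_len(nInd[[p]]))))
  H <- length(hapTipOrder)
  nSite <- nSites(at)
  ## haplotype carrier matrix
  gtm <- matrix(0L, nSite, H)
  for (i in seq_len(nSite)) gtm[i, carriers[[i]]] <- 1L
  ## per-pop callability per site
  calledPop <- vapply(pops, function(p) IRanges::overlapsAny(
    GenomicRanges::GRanges(spec@chrom, IRanges::IRanges(at@pos, at@pos)),
    maskList[[p]]), logical(nSite))
  hapPop <- match(hapTipOrder, pops)
  gtStr <- matrix("", nSite, H / 2L)
  for (j in seq_len(H / 2L)) {
    p <- hapPop[2L * j - 1L]
    g <- paste0(gtm[, 2L * j - 1L], "|", gtm[, 2L * j])
    g[!calledPop[, p]] <- ".|."
    gtStr[, j] <- g
  }
  info <- ifelse(is.na(at@outgroup), ".", paste0("AA=", at@outgroup))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", spec@chrom,
                   as.integer(spec@chromLength)),
           "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral (outgroup) allele\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", sampleNames), collapse = "\t"))
  body <- do.call(paste, c(list(spec@chrom, at@pos, ".", at@ref, at@alt, ".",
                                "PASS", info, "GT"),
                           lapply(seq_len(ncol(gtStr)),
                                  function(j) gtStr[, j]),
                           sep = "\t"))
  writeLines(c(hdr, body), file)
  invisible(file)
}

#' Population map for a synthetic dataset's VCF
#'
#' Sample names in generated VCFs are `<population>_<i>`; this rebuilds the
#' sample-to-population map expected by [readVcfAlleles()].
#'
#' @param tree the [SpeciesTree-class] used for generation.
#' @return named character vector (sample -> population).
#' @export
syntheticPopmap <- function(tree) {
  pops <- tipNames(tree)
  smp <- tipSamples(tree)
  unlist(lapply(pops, function(p)
    setNames(rep(p, smp[p]), sprintf("%s_%d", p, seq_len(smp[p])))))
}
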