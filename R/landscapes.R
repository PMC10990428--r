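## Windowed nucleotide diversity and divergence from allele tables with
## callable-site masks; window filters; weak/strong site partitioning.

#' Build a non-overlapping window grid
#'
#' Contiguous, sorted, non-overlapping windows covering `[1, chromLength]`;
#' the last window may be short.
#'
#' @param chromLength chromosome length in bp.
#' @param windowSize window length in bp.
#' @param chrom chromosome name.
#' @return a [GenomicRanges::GRanges] of windows.
#' @export
windowGrid <- function(chromLength, windowSize, chrom = "chr12") {
  starts <- seq(1L, chromLength, by = windowSize)
  ends <- pmin(starts + windowSize - 1L, chromLength)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

#' Construct an allele table
#'
#' @param pos integer 1-based positions, strictly increasing.
#' @param ac,an integer matrices (sites x populations) of alternate-allele
#'   counts and called-allele numbers, with population column names.
#' @param ref,alt optional nucleotide states per site.
#' @param outgroup optional outgroup allele per site (`NA` = missing).
#' @return an [AlleleTable-class].
#' @export
alleleTable <- function(pos, ac, an, ref = NULL, alt = NULL, outgroup = NULL) {
  n <- length(pos)
  ac <- as.matrix(ac); an <- as.matrix(an)
  storage.mode(ac) <- "integer"; storage.mode(an) <- "integer"
  blank <- rep(NA_character_, n)
  methods::new("AlleleTable", pos = as.integer(pos),
               ref = if (is.null(ref)) blank else as.character(ref),
               alt = if (is.null(alt)) blank else as.character(alt),
               ac = ac, an = an,
               outgroup = if (is.null(outgroup)) blank else as.character(outgroup))
}

#' @describeIn alleleTable population names of the table.
#' @param x an [AlleleTable-class].
#' @export
populations <- function(x) colnames(x@ac)

#' @describeIn alleleTable number of sites.
#' @export
nSites <- function(x) length(x@pos)

setMethod("show", "AlleleTable", function(object) {
  cat(sprintf("AlleleTable: %d sites, %d populations (%s)\n",
              nSites(object), ncol(object@ac),
              paste(head(populations(object), 4), collapse = ", ")))
  cat(sprintf("  nucleotide states: %s; outgroup present at %d sites\n",
              if (all(is.na(object@ref))) "unassigned" else "assigned",
              sum(!is.na(object@outgroup))))
})

#' Per-population callable masks
#'
#' A callable mask is a named list of [GenomicRanges::GRanges] (one per
#' population) of callable intervals; intervals within a population must be
#' non-overlapping.  `intersectMasks` reduces the list to the sites callable
#' in all populations, the only sites the statistics use.
#'
#' @param masks named list of `GRanges` (or of data.frames with 0-based
#'   half-open `start`, `end` columns, converted on the fly).
#' @param chrom chromosome name for data.frame input.
#' @return `callableMask`: the validated list; `intersectMasks`: one
#'   `GRanges` of jointly callable intervals.
#' @export
callableMask <- function(masks, chrom = "chr12") {
  out <- lapply(masks, function(m) {
    if (is.data.frame(m))
      m <- GenomicRanges::GRanges(chrom, IRanges::IRanges(m$start + 1L, m$end))
    m <- GenomicRanges::sort(m)
    if (!GenomicRanges::isDisjoint(m))
      stop("mask intervals must be non-overlapping within a population")
    m
  })
  if (is.null(names(out)) || any(names(out) == ""))
    stop("masks must be named by population")
  out
}

#' @rdname callableMask
#' @export
intersectMasks <- function(masks) {
  Reduce(GenomicRanges::intersect, masks)
}

## callable bp of `mask` (a GRanges) in each window of `grid`
windowCallableLength <- function(mask, grid) {
  ov <- GenomicRanges::findOverlaps(grid, mask)
  w <- IRanges::width(IRanges::pintersect(
    grid[S4Vectors::queryHits(ov)], mask[S4Vectors::subjectHits(ov)]))
  out <- numeric(length(grid))
  if (length(ov)) {
    agg <- tapply(w, S4Vectors::queryHits(ov), sum)
    out[as.integer(names(agg))] <- agg
  }
  out
}

## logical: which table positions fall inside a GRanges mask
sitesInMask <- function(at, mask) {
  if (!length(at@pos)) return(logical(0))
  gr <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(mask)[1]),
                               IRanges::IRanges(at@pos, at@pos))
  IRanges::overlapsAny(gr, mask)
}

## window index (or NA) of each table position
siteWindow <- function(at, grid) {
  if (!length(at@pos)) return(integer(0))
  gr <- GenomicRanges::GRanges(as.character(GenomicRanges::seqnames(grid)[1]),
                               IRanges::IRanges(at@pos, at@pos))
  GenomicRanges::findOverlaps(gr, grid, select = "first")
}

## assemble a Landscape from per-site numerators (already per-site rates)
assembleLandscape <- function(stat, grid, siteRate, win, callable) {
  vals <- numeric(length(grid))
  keep <- !is.na(win)
  if (any(keep)) {
    agg <- tapply(siteRate[keep], win[keep], sum)
    vals[as.integer(names(agg))] <- agg
  }
  vals <- ifelse(callable > 0, vals / callable, NA_real_)
  methods::new("Landscape", stat = stat, grid = grid, values = vals,
               callableFrac = callable / IRanges::width(grid))
}

#' Windowed nucleotide diversity
#'
#' Per window, the mean number of pairwise differences among the
#' population's sampled alleles divided by the number of jointly callable
#' sites.  At each site with `an` called alleles of which `ac` carry the
#' alternate state, the mean pairwise difference is
#' `ac (an - ac) / choose(an, 2)`; all ordered sample-allele pairs are
#' counted, including the two alleles of one diploid (the standard unbiased
#' estimator).  Monomorphic callable sites contribute to denominators only.
#' Masks are intersected across all populations first; windows with zero
#' jointly callable sites are `NA`.
#'
#' @param alleles an [AlleleTable-class].
#' @param masks per-population [callableMask()] list (or a single `GRanges`
#'   already intersected).
#' @param grid window [GenomicRanges::GRanges] from [windowGrid()].
#' @param pop population name.
#' @return a [Landscape-class].
#' @export
windowedDiversity <- function(alleles, masks, grid, pop) {
  if (!pop %in% populations(alleles)) stop("unknown population: ", pop)
  cm <- if (inherits(masks, "GRanges")) masks else intersectMasks(masks)
  callable <- windowCallableLength(cm, grid)
  inMask <- sitesInMask(alleles, cm)
  ac <- alleles@ac[, pop]; an <- alleles@an[, pop]
  if (length(an) && all(an == 0L))
    stop("population has no called alleles: ", pop)
  pairs <- an * (an - 1) / 2
  rate <- ifelse(an >= 2L, ac * (an - ac) / pmax(pairs, 1), 0)
  rate[!inMask] <- 0
  win <- siteWindow(alleles, grid)
  win[!inMask] <- NA
  assembleLandscape(piStat(pop), grid, rate, win, callable)
}

#' Windowed absolute divergence (dXY)
#'
#' Per window, the mean number of pairwise differences between
#' cross-population allele pairs divided by the number of jointly callable
#' sites: at each site the cross-pair difference rate is
#' `(acA (anB - acB) + (anA - acA) acB) / (anA anB)`.  Symmetric in the two
#' populations.
#'
#' @inheritParams windowedDiversity
#' @param popA,popB distinct population names.
#' @return a [Landscape-class].
#' @export
windowedDivergence <- function(alleles, masks, grid, popA, popB) {
  if (popA == popB) stop("popA and popB must differ")
  for (p in c(popA, popB))
    if (!p %in% populations(alleles)) stop("unknown population: ", p)
  cm <- if (inherits(masks, "GRanges")) masks else intersectMasks(masks)
  callable <- windowCallableLength(cm, grid)
  inMask <- sitesInMask(alleles, cm)
  acA <- alleles@ac[, popA]; anA <- alleles@an[, popA]
  acB <- alleles@ac[, popB]; anB <- alleles@an[, popB]
  ok <- anA >= 1L & anB >= 1L
  rate <- ifelse(ok, (acA * (anB - acB) + (anA - acA) * acB) /
                   pmax(anA * anB, 1), 0)
  rate[!inMask] <- 0
  win <- siteWindow(alleles, grid)
  win[!inMask] <- NA
  assembleLandscape(dxyStat(popA, popB), grid, rate, win, callable)
}

#' Mask windows below a callable-fraction threshold
#'
#' Windows with callable fraction strictly below `threshold` are set to
#' `NA`; a fraction exactly equal to the threshold is kept.  The main
#' analyses use 0.40; the weak/strong partitioned analyses use 0.05.
#'
#' @param landscape a [Landscape-class].
#' @param threshold callable fraction in `[0, 1]`.
#' @return the filtered [Landscape-class].
#' @export
applyWindowFilter <- function(landscape, threshold = 0.40) {
  stopifnot(threshold >= 0, threshold <= 1)
  v <- landscape@values
  v[landscape@callableFrac < threshold] <- NA_real_
  methods::initialize(landscape, values = v)
}

#' @describeIn applyWindowFilter per-window values of a landscape.
#' @export
landscapeValues <- function(landscape) landscape@values

#' @describeIn applyWindowFilter per-window callable fractions.
#' @export
callableFraction <- function(landscape) landscape@callableFrac

#' @describeIn applyWindowFilter the landscape's [StatDescriptor-class].
#' @export
statDescriptor <- function(landscape) landscape@stat

setMethod("show", "Landscape", function(object) {
  v <- object@values
  cat(sprintf("Landscape %s: %d windows (%d missing), mean %.3g\n",
              statLabel(object@stat), length(v), sum(is.na(v)),
              mean(v, na.rm = TRUE)))
})

#' Classify a site by weak/strong mutation type across four species
#'
#' Given one representative nucleotide per species at a site, the set `S` of
#' distinct states determines the class: one state is `invariant`; two
#' states that are both weak (A/T) or both strong (G/C) imply a single
#' weak-to-weak or strong-to-strong change (`WW_SS`, unaffected by GC-biased
#' gene conversion); one weak plus one strong state implies a weak/strong
#' change (`WS`, potentially affected); three or more states imply multiple
#' mutations and the site is removed (`multi_excluded`).  A missing state
#' (`NA`) excludes the site (`NA` returned).
#'
#' @param states character vector of 4 nucleotides, or an `n x 4` matrix for
#'   vectorized use.
#' @return class label(s) in `{"invariant", "WW_SS", "WS",
#'   "multi_excluded"}`, `NA` for sites with missing states.
#' @export
classifySiteType <- function(states) {
  m <- if (is.matrix(states)) states else matrix(states, nrow = 1L)
  if (ncol(m) != 4L) stop("exactly 4 species states are required")
  bad <- !is.na(m) & !m %in% c("A", "C", "G", "T")
  if (any(bad)) stop("non-nucleotide symbol: ", paste(unique(m[bad]), collapse = ", "))
  out <- rep(NA_character_, nrow(m))
  complete <- rowSums(is.na(m)) == 0L
  weak <- matrix(m %in% c("A", "T"), nrow = nrow(m))
  for (i in which(complete)) {
    S <- unique(m[i, ])
    out[i] <- if (length(S) == 1L) "invariant"
      else if (length(S) >= 3L) "multi_excluded"
      else if (xor(S[1] %in% c("A", "T"), S[2] %in% c("A", "T"))) "WS"
      else "WW_SS"
  }
  out
}

#' Polarize a site by its outgroup allele
#'
#' The ancestral state is taken to be the outgroup allele; sites whose
#' outgroup allele is missing are excluded.
#'
#' @param outgroup character vector of outgroup alleles (`NA` = missing).
#' @return `"ancestrally_weak"` (A/T), `"ancestrally_strong"` (G/C) or
#'   `"excluded"` per site.
#' @export
polarizeByOutgroup <- function(outgroup) {
  bad <- !is.na(outgroup) & !outgroup %in% c("A", "C", "G", "T")
  if (any(bad)) stop("non-nucleotide outgroup symbol: ",
                     paste(unique(outgroup[bad]), collapse = ", "))
  ifelse(is.na(outgroup), "excluded",
         ifelse(outgroup %in% c("A", "T"), "ancestrally_weak",
                "ancestrally_strong"))
}

## representative (majority) allele per species at each site; ties and
## uncalled sites -> NA
representativeStates <- function(alleles, pops) {
  if (all(is.na(alleles@ref)))
    stop("allele table has no nucleotide states; cannot classify sites")
  out <- matrix(NA_character_, nSites(alleles), length(pops),
                dimnames = list(NULL, pops))
  for (p in pops) {
    ac <- alleles@ac[, p]; an <- alleles@an[, p]
    maj <- ifelse(an == 0L, NA_character_,
            ifelse(2L * ac > an, alleles@alt,
             ifelse(2L * ac < an, alleles@ref, NA_character_)))
    out[, p] <- maj
  }
  out
}

#' Divergence landscapes partitioned by weak/strong site class
#'
#' For two divergence comparisons spanning four distinct species, classifies
#' every site by [classifySiteType()] applied to the per-species majority
#' alleles and computes both dXY landscapes using only sites of the
#' requested class; the 5% callable-fraction filter is applied.
#'
#' @inheritParams windowedDiversity
#' @param pairA,pairB character vectors of 2 population names each; all four
#'   must be distinct.
#' @param class `"WW_SS"` or `"WS"`.
#' @param threshold callable-fraction filter (default 0.05).
#' @return list of two [Landscape-class] objects (`pairA`, `pairB`).
#' @export
partitionedDivergence <- function(alleles, masks, grid, pairA, pairB,
                                  class = c("WW_SS", "WS"), threshold = 0.05) {
  class <- match.arg(class)
  pops <- c(pairA, pairB)
  if (length(pops) != 4L || anyDuplicated(pops))
    stop("pairA and pairB must name 4 distinct populations")
  cls <- classifySiteType(representativeStates(alleles, pops))
  keep <- !is.na(cls) & cls == class
  sub <- methods::initialize(alleles,
    pos = alleles@pos[keep], ref = alleles@ref[keep], alt = alleles@alt[keep],
    ac = alleles@ac[keep, , drop = FALSE], an = alleles@an[keep, , drop = FALSE],
    outgroup = alleles@outgroup[keep])
  lapply(list(pairA, pairB), function(pr)
    applyWindowFilter(windowedDivergence(sub, masks, grid, pr[1], pr[2]),
                      threshold))
}
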