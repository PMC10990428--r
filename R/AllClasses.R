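#' @import methods
#' @importFrom stats cor cov cumsum dexp dgamma integrate lm prcomp rbinom
#'   rexp rnorm rpois runif setNames var sd coef quantile
NULL

setOldClass("phylo")

#' Dated species tree with per-branch effective sizes
#'
#' An S4 container for a rooted, time-calibrated species tree whose branch
#' lengths are in generations.  Every node (tips, internal nodes, and the
#' root) is associated with a diploid effective population size: the size of
#' the Wright--Fisher population living along the branch *above* that node.
#' The root's entry is the size of the ancestral population predating the
#' first split.  Tips additionally carry diploid sample counts.
#'
#' @slot phylo an [ape::phylo] object, rooted, with branch lengths in
#'   generations and unique tip and node labels.
#' @slot ne named numeric vector of diploid effective sizes, one entry per
#'   node label (tips, internal nodes and root).
#' @slot samples named integer vector of diploid sample counts per tip.
#' @seealso [speciesTree()], [greatApesTree()], [phyloDistance()],
#'   [mrcaNode()]
#' @exportClass SpeciesTree
setClass("SpeciesTree",
  representation(phylo = "phylo", ne = "numeric", samples = "integer"))

setValidity("SpeciesTree", function(object) {
  tr <- object@phylo
  msg <- character()
  if (!ape::is.rooted(tr)) msg <- c(msg, "tree must be rooted")
  if (is.null(tr$edge.length)) msg <- c(msg, "tree must have branch lengths")
  else if (any(tr$edge.length < 0)) msg <- c(msg, "edge lengths must be >= 0")
  labs <- c(tr$tip.label, tr$node.label)
  if (anyDuplicated(labs)) msg <- c(msg, "node labels must be unique")
  if (!setequal(names(object@ne), labs) || anyNA(object@ne))
    msg <- c(msg, "ne must be named by every node label")
  else if (any(object@ne <= 0)) msg <- c(msg, "all Ne must be > 0")
  if (!all(names(object@samples) %in% tr$tip.label))
    msg <- c(msg, "sample counts must be named by tips")
  if (any(object@samples < 1L)) msg <- c(msg, "sample counts must be >= 1")
  # ultrametric in time: all tips at (numerically) the same depth
  if (length(msg) == 0L) {
    dep <- ape::node.depth.edgelength(tr)[seq_along(tr$tip.label)]
    if (diff(range(dep)) > 1e-6 * max(dep, 1))
      msg <- c(msg, "tree must be ultrametric (tips at time 0)")
  }
  if (length(msg)) msg else TRUE
})

#' Descriptor of a windowed landscape statistic
#'
#' Identifies one landscape: either the nucleotide diversity (pi) of a single
#' population, or the absolute divergence (dXY) of an unordered pair of
#' populations.
#'
#' @slot kind `"diversity"` or `"divergence"`.
#' @slot taxa character vector of one population name (diversity) or two
#'   distinct names (divergence), stored sorted.
#' @seealso [piStat()], [dxyStat()], [statLabel()]
#' @exportClass StatDescriptor
setClass("StatDescriptor",
  representation(kind = "character", taxa = "character"))

setValidity("StatDescriptor", function(object) {
  if (!object@kind %in% c("diversity", "divergence"))
    return("kind must be 'diversity' or 'divergence'")
  n <- length(object@taxa)
  if (object@kind == "diversity" && n != 1L)
    return("diversity takes exactly one population")
  if (object@kind == "divergence" &&
      (n != 2L || object@taxa[1] == object@taxa[2]))
    return("divergence takes two distinct populations")
  TRUE
})

#' Table of biallelic variant sites across populations
#'
#' The bridge between VCF input (or simulator output) and the windowed
#' statistics.  Each row is one site; per-population columns give the number
#' of sampled alleles that carry the alternate state (`ac`) and the total
#' number of called alleles (`an`).  Reference/alternate nucleotide states
#' and an outgroup allele are optional (simulator output is assigned
#' nucleotides only by the synthetic-data generator).
#'
#' @slot pos integer vector of 1-based positions, strictly increasing.
#' @slot ref,alt character vectors of nucleotide states (`A`/`C`/`G`/`T`), or
#'   `NA` when states have not been assigned.
#' @slot ac,an integer matrices (sites x populations) of alternate-allele
#'   counts and called-allele numbers; `colnames` are population names.
#' @slot outgroup character vector of outgroup alleles (`NA` when absent).
#' @seealso [alleleTable()], [readVcfAlleles()], [windowedDiversity()]
#' @exportClass AlleleTable
setClass("AlleleTable",
  representation(pos = "integer", ref = "character", alt = "character",
                 ac = "matrix", an = "matrix", outgroup = "character"))

setValidity("AlleleTable", function(object) {
  n <- length(object@pos)
  msg <- character()
  if (n > 1L && any(diff(object@pos) <= 0L))
    msg <- c(msg, "positions must be strictly increasing")
  for (s in c("ref", "alt", "outgroup")) {
    v <- slot(object, s)
    if (length(v) != n) msg <- c(msg, sprintf("%s must have one entry per site", s))
    bad <- !is.na(v) & !v %in% c("A", "C", "G", "T")
    if (any(bad)) msg <- c(msg, sprintf("%s contains non-nucleotide symbols", s))
  }
  if (nrow(object@ac) != n || nrow(object@an) != n)
    msg <- c(msg, "ac/an must have one row per site")
  if (is.null(colnames(object@ac)) ||
      !identical(colnames(object@ac), colnames(object@an)))
    msg <- c(msg, "ac and an must share population column names")
  if (any(object@ac > object@an, na.rm = TRUE))
    msg <- c(msg, "allele count cannot exceed called-allele number")
  if (any(object@an < 0L, na.rm = TRUE) || any(object@ac < 0L, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (length(msg)) msg else TRUE
})

#' A windowed landscape of diversity or divergence
#'
#' Per-window values of one statistic on a window grid, together with the
#' fraction of each window that is callable.  Values are per-site rates in
#' `[0, 1]`; filtered windows are `NA`.
#'
#' @slot stat the [StatDescriptor-class] the landscape measures.
#' @slot grid a [GenomicRanges::GRanges] of non-overlapping windows.
#' @slot values numeric per-window values (`NA` = filtered/missing).
#' @slot callableFrac numeric per-window callable fraction in `[0, 1]`.
#' @seealso [windowedDiversity()], [applyWindowFilter()]
#' @exportClass Landscape
setClass("Landscape",
  representation(stat = "StatDescriptor", grid = "GRanges",
                 values = "numeric", callableFrac = "numeric"))

setValidity("Landscape", function(object) {
  nw <- length(object@grid)
  msg <- character()
  if (length(object@values) != nw || length(object@callableFrac) != nw)
    msg <- c(msg, "values and callableFrac must match the grid length")
  v <- object@values
  if (any(v < -1e-12 | v > 1 + 1e-12, na.rm = TRUE))
    msg <- c(msg, "values must lie in [0, 1]")
  cf <- object@callableFrac
  if (any(cf < 0 | cf > 1 + 1e-9, na.rm = TRUE))
    msg <- c(msg, "callable fractions must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Distribution of fitness effects for exonic mutations
#'
#' Within exons a fraction of new mutations is deleterious with gamma
#' distributed selection coefficients (shape `alpha`, mean `meanSDel` < 0;
#' the mean equals shape/rate), a fraction is beneficial with exponentially
#' distributed coefficients (mean `meanSBen` > 0), and the residual fraction
#' is neutral.
#'
#' @slot fracDeleterious,fracBeneficial fractions of exonic mutations in each
#'   selected class; non-negative, summing to at most 1.
#' @slot gammaShape gamma shape parameter alpha of the deleterious DFE.
#' @slot meanSDel mean (negative) deleterious selection coefficient.
#' @slot meanSBen mean (positive) beneficial selection coefficient.
#' @seealso [dfeConfig()], [expectedSubstitutionRates()]
#' @exportClass DFEConfig
setClass("DFEConfig",
  representation(fracDeleterious = "numeric", fracBeneficial = "numeric",
                 gammaShape = "numeric", meanSDel = "numeric",
                 meanSBen = "numeric"))

setValidity("DFEConfig", function(object) {
  msg <- character()
  fd <- object@fracDeleterious; fb <- object@fracBeneficial
  if (fd < 0 || fb < 0 || fd + fb > 1 + 1e-12)
    msg <- c(msg, "class fractions must be >= 0 and sum to <= 1")
  if (object@gammaShape <= 0) msg <- c(msg, "gamma shape must be > 0")
  if (object@meanSDel >= 0) msg <- c(msg, "mean deleterious s must be < 0")
  if (object@meanSBen <= 0) msg <- c(msg, "mean beneficial s must be > 0")
  if (length(msg)) msg else TRUE
})

#' Configuration of a forward Wright--Fisher simulation
#'
#' @slot tree a [SpeciesTree-class].
#' @slot mu total per-site per-generation mutation rate.
#' @slot dfe a [DFEConfig-class] applying within exons.
#' @slot exons [IRanges::IRanges] of exon intervals (0-based half-open
#'   converted on construction; stored 1-based as IRanges convention).
#' @slot recomb data.frame `start`, `end`, `rate` (crossovers per bp per
#'   generation; 0-based half-open, tiling the chromosome).
#' @slot grid window [GenomicRanges::GRanges].
#' @slot chromLength chromosome length in bp.
#' @slot rescaleQ rescaling factor Q >= 1 (see [rescaleConfig()]).
#' @slot burninMult burn-in length in units of the (rescaled) root Ne.
#' @slot seed integer random seed.
#' @seealso [simulationConfig()], [simulateForward()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
  representation(tree = "SpeciesTree", mu = "numeric", dfe = "DFEConfig",
                 exons = "IRanges", recomb = "data.frame", grid = "GRanges",
                 chromLength = "numeric", rescaleQ = "numeric",
                 burninMult = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
  if (object@rescaleQ < 1) msg <- c(msg, "Q must be >= 1")
  if (object@chromLength < 1) msg <- c(msg, "chromosome length must be >= 1")
  if (length(object@exons) &&
      max(IRanges::end(object@exons)) > object@chromLength)
    msg <- c(msg, "exons must lie within the chromosome")
  rc <- object@recomb
  if (!all(c("start", "end", "rate") %in% names(rc)))
    msg <- c(msg, "recomb map needs start/end/rate columns")
  else if (any(rc$rate < 0)) msg <- c(msg, "recombination rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Heterogeneous neutral mutation-rate map
#'
#' Per-window neutral mutation rates drawn around a global mean, with
#' exon-overlapping sub-intervals carrying the window rate minus the
#' non-neutral exonic rate (floored at zero).
#'
#' @slot grid window [GenomicRanges::GRanges].
#' @slot windowRate numeric per-window drawn neutral rate.
#' @slot intervals data.frame `start`, `end` (0-based half-open), `window`,
#'   `rate`: the fine partition after exon subtraction.
#' @slot meanRate global mean rate.
#' @slot sigmaRel relative standard deviation of the window draws.
#' @seealso [buildMutationMap()], [overlayMutations()]
#' @exportClass MutationRateMap
setClass("MutationRateMap",
  representation(grid = "GRanges", windowRate = "numeric",
                 intervals = "data.frame", meanRate = "numeric",
                 sigmaRel = "numeric"))

setValidity("MutationRateMap", function(object) {
  msg <- character()
  if (length(object@windowRate) != length(object@grid))
    msg <- c(msg, "one rate per window required")
  if (any(object@windowRate < 0)) msg <- c(msg, "rates must be >= 0")
  if (any(object@intervals$rate < 0)) msg <- c(msg, "interval rates must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Result of a simulation run
#'
#' @slot landscapes list of [Landscape-class] objects (pi per tip, dXY per
#'   tip pair), named by [statLabel()].
#' @slot fixations data.frame of fixation records: `branch`, `pos` (1-based
#'   bp), `class` (`neutral`/`deleterious`/`beneficial`), `s`, `generation`.
#' @slot coalTimes data.frame of realized per-window mean pairwise
#'   coalescence times (neutral mode only): `window`, `stat`, `meanT`.
#' @slot genealogies list of per-window genealogies (neutral mode only; used
#'   for mutation overlay at genotype level), possibly empty.
#' @slot alleles the tip-sample [AlleleTable-class] (forward mode) or `NULL`.
#' @slot config the generating [SimulationConfig-class] (or a config echo
#'   list for neutral mode).
#' @slot seed the seed used.
#' @exportClass SimResult
setClass("SimResult",
  representation(landscapes = "list", fixations = "data.frame",
                 coalTimes = "data.frame", genealogies = "list",
                 alleles = "ANY", config = "ANY", seed = "integer"))

#' Specification of a synthetic multi-population dataset
#'
#' Describes the shape of a generated dataset emulating a ten-population
#' great-apes panel: the species tree with sample counts, the window grid,
#' per-population callable-mask structure with a controllable fraction of
#' windows below the 40% callable threshold, exon-density and
#' recombination-rate profiles, and the fraction of sites carrying an
#' outgroup allele.
#'
#' @slot tree a [SpeciesTree-class] with tip sample counts.
#' @slot chromLength chromosome length in bp.
#' @slot windowSize window size in bp.
#' @slot chrom chromosome name used in output files.
#' @slot mu neutral per-site mutation rate used to generate variation.
#' @slot lowCallableFrac fraction of windows whose callable fraction is drawn
#'   below 0.40 (exercises the window filter).
#' @slot exonDensity numeric per-window exon density profile in `[0, 1]`
#'   (recycled), or length-0 for an internally generated profile.
#' @slot recombRates numeric per-window recombination rate profile (per bp
#'   per generation), or length-0 for an internal profile.
#' @slot outgroupFrac fraction of variant sites with an outgroup allele.
#' @slot lociPerWindow number of independent genealogies per window.
#' @seealso [syntheticDatasetSpec()], [generateDataset()]
#' @exportClass SyntheticDatasetSpec
setClass("SyntheticDatasetSpec",
  representation(tree = "SpeciesTree", chromLength = "numeric",
                 windowSize = "numeric", chrom = "character", mu = "numeric",
                 lowCallableFrac = "numeric", exonDensity = "numeric",
                 recombRates = "numeric", outgroupFrac = "numeric",
                 lociPerWindow = "numeric"))

setValidity("SyntheticDatasetSpec", function(object) {
  msg <- character()
  if (object@lowCallableFrac < 0 || object@lowCallableFrac > 1)
    msg <- c(msg, "lowCallableFrac must be in [0, 1]")
  if (object@outgroupFrac < 0 || object@outgroupFrac > 1)
    msg <- c(msg, "outgroupFrac must be in [0, 1]")
  if (object@windowSize <= 0 || object@chromLength < object@windowSize)
    msg <- c(msg, "need chromLength >= windowSize > 0")
  if (length(msg)) msg else TRUE
})
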