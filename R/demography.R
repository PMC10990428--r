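## Species-tree demography: construction, node times, MRCA-based phylogenetic
## distances and branch-sharing relations between landscape statistics.

#' Construct a species tree with per-branch effective sizes
#'
#' @param phylo an [ape::phylo], rooted, branch lengths in generations,
#'   ultrametric in time.  Internal nodes without labels are auto-labelled
#'   `n<number>`.
#' @param ne named numeric vector of diploid effective sizes.  Names are node
#'   labels; the entry for a node is the size of the population along the
#'   branch above it, and the root entry is the ancestral population size.
#' @param samples named integer-like vector of diploid sample counts per tip.
#'   Tips absent from `samples` default to 1.
#' @param generationTime if the input branch lengths are in years, supply the
#'   generation time in years and lengths are divided by it; default `NULL`
#'   (lengths already in generations).
#' @return a [SpeciesTree-class].
#' @examples
#' tr <- ape::read.tree(text = "((A:100,B:100)AB:900,C:1000)root;")
#' st <- speciesTree(tr, ne = c(A = 1e4, B = 1e4, C = 1e4, AB = 2e4, root = 5e4),
#'                   samples = c(A = 4, B = 4, C = 2))
#' phyloDistance(st, piStat("A"), piStat("B"))
#' @export
speciesTree <- function(phylo, ne, samples = NULL, generationTime = NULL) {
  if (!inherits(phylo, "phylo")) stop("phylo must be an ape 'phylo' object")
  if (!is.null(generationTime)) {
    stopifnot(generationTime > 0)
    phylo$edge.length <- phylo$edge.length / generationTime
  }
  nint <- phylo$Nnode
  if (is.null(phylo$node.label) || any(phylo$node.label == "")) {
    lab <- phylo$node.label
    if (is.null(lab)) lab <- rep("", nint)
    auto <- paste0("n", seq_len(nint) + length(phylo$tip.label))
    lab[lab == ""] <- auto[lab == ""]
    phylo$node.label <- lab
  }
  if (is.null(samples)) samples <- setNames(rep(1L, length(phylo$tip.label)),
                                            phylo$tip.label)
  smp <- setNames(rep(1L, length(phylo$tip.label)), phylo$tip.label)
  smp[names(samples)] <- as.integer(samples)
  methods::new("SpeciesTree", phylo = phylo, ne = ne[c(phylo$tip.label, phylo$node.label)],
               samples = smp)
}

#' Read a species tree from Newick plus a branch-parameter table
#'
#' Newick carries topology and branch lengths (in generations); a sidecar
#' tab-delimited table with header `branch  ne  samples` carries per-branch
#' diploid effective sizes and per-tip sample counts (sample count `NA` or
#' empty for internal branches).
#'
#' @param newickFile path to a Newick file with labelled internal nodes.
#' @param paramsFile path to the branch-parameter TSV.
#' @inheritParams speciesTree
#' @return a [SpeciesTree-class].
#' @export
readSpeciesTree <- function(newickFile, paramsFile, generationTime = NULL) {
  tr <- ape::read.tree(newickFile)
  par <- read.table(paramsFile, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
  if (!all(c("branch", "ne") %in% names(par)))
    stop("branch-parameter table needs columns 'branch' and 'ne'")
  ne <- setNames(par$ne, par$branch)
  smp <- NULL
  if ("samples" %in% names(par)) {
    keep <- !is.na(par$samples) & par$branch %in% tr$tip.label
    smp <- setNames(as.integer(par$samples[keep]), par$branch[keep])
  }
  speciesTree(tr, ne, smp, generationTime = generationTime)
}

#' Write a species tree as Newick plus a branch-parameter table
#'
#' @param tree a [SpeciesTree-class].
#' @param newickFile,paramsFile output paths.
#' @return invisibly, the two paths.
#' @export
writeSpeciesTree <- function(tree, newickFile, paramsFile) {
  ape::write.tree(tree@phylo, file = newickFile)
  labs <- names(tree@ne)
  smp <- rep(NA_integer_, length(labs))
  smp[match(names(tree@samples), labs)] <- tree@samples
  write.table(data.frame(branch = labs, ne = tree@ne, samples = smp),
              paramsFile, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(newickFile, paramsFile))
}

#' @describeIn speciesTree tip labels of the tree.
#' @param tree a [SpeciesTree-class].
#' @export
tipNames <- function(tree) tree@phylo$tip.label

#' @describeIn speciesTree named diploid sample counts per tip.
#' @export
tipSamples <- function(tree) tree@samples

#' @describeIn speciesTree named diploid effective sizes per branch (keyed by
#'   the branch's child node; the root entry is the ancestral population).
#' @export
branchNe <- function(tree) tree@ne

#' @describeIn speciesTree named vector of node times in generations before
#'   present (tips at 0).
#' @export
nodeTimes <- function(tree) {
  tr <- tree@phylo
  dep <- ape::node.depth.edgelength(tr)
  t <- max(dep) - dep
  setNames(t, c(tr$tip.label, tr$node.label))
}

#' @describeIn speciesTree named vector of branch lengths in generations
#'   (length of the branch above each non-root node).
#' @export
branchLengths <- function(tree) {
  tr <- tree@phylo
  labs <- c(tr$tip.label, tr$node.label)
  out <- setNames(rep(NA_real_, length(labs)), labs)
  out[labs[tr$edge[, 2]]] <- tr$edge.length
  out
}

setMethod("show", "SpeciesTree", function(object) {
  tr <- object@phylo
  cat(sprintf("SpeciesTree: %d tips, %d internal nodes, depth %.0f generations\n",
              length(tr$tip.label), tr$Nnode, max(nodeTimes(object))))
  cat("  tips:", paste(sprintf("%s(n=%d)", tr$tip.label,
                               object@samples[tr$tip.label]), collapse = " "), "\n")
  cat(sprintf("  Ne range: %.0f - %.0f (root %s = %.0f)\n",
              min(object@ne), max(object@ne), rootLabel(object),
              object@ne[rootLabel(object)]))
})

## label of the root node
rootLabel <- function(tree) {
  tr <- tree@phylo
  root <- setdiff(tr$edge[, 1], tr$edge[, 2])
  c(tr$tip.label, tr$node.label)[root]
}

## node label -> ape node number
nodeNumber <- function(tree, label) {
  labs <- c(tree@phylo$tip.label, tree@phylo$node.label)
  i <- match(label, labs)
  if (anyNA(i)) stop("unknown node label(s): ",
                     paste(label[is.na(i)], collapse = ", "))
  i
}

## ancestor chain (node numbers, self first, root last)
ancestorChain <- function(phylo, node) {
  parent <- integer(max(phylo$edge))
  parent[phylo$edge[, 2]] <- phylo$edge[, 1]
  chain <- node
  while (parent[node] != 0L) {
    node <- parent[node]
    chain <- c(chain, node)
  }
  chain
}

#' Most recent common ancestor of a set of tips
#'
#' The MRCA of a single tip is defined as the tip itself, so that the
#' self-distance of a diversity statistic is zero.
#'
#' @param tree a [SpeciesTree-class].
#' @param pops character vector of tip (population) names.
#' @return the label of the MRCA node.
#' @export
mrcaNode <- function(tree, pops) {
  pops <- unique(pops)
  bad <- setdiff(pops, tipNames(tree))
  if (length(bad)) stop("unknown population(s): ", paste(bad, collapse = ", "))
  labs <- c(tree@phylo$tip.label, tree@phylo$node.label)
  if (length(pops) == 1L) return(pops)
  labs[ape::getMRCA(tree@phylo, pops)]
}

#' Create landscape-statistic descriptors
#'
#' `piStat(pop)` describes the nucleotide-diversity landscape of one
#' population; `dxyStat(a, b)` the absolute-divergence landscape of an
#' unordered pair.
#'
#' @param pop,a,b population (tip) names.
#' @return a [StatDescriptor-class].
#' @export
piStat <- function(pop)
  methods::new("StatDescriptor", kind = "diversity", taxa = pop)

#' @rdname piStat
#' @export
dxyStat <- function(a, b)
  methods::new("StatDescriptor", kind = "divergence", taxa = sort(c(a, b)))

#' @rdname piStat
#' @param x a [StatDescriptor-class].
#' @export
statKind <- function(x) x@kind

#' @rdname piStat
#' @export
statTaxa <- function(x) x@taxa

#' @rdname piStat
#' @export
statLabel <- function(x)
  paste(c(if (x@kind == "diversity") "pi" else "dxy", x@taxa), collapse = "_")

setMethod("show", "StatDescriptor", function(object)
  cat(sprintf("<%s: %s>\n",
              if (object@kind == "diversity") "pi" else "dXY",
              paste(object@taxa, collapse = " - "))))

## defining node of a descriptor: MRCA of its taxa (a tip for diversity)
descriptorNode <- function(tree, x) mrcaNode(tree, x@taxa)

#' Phylogenetic distance (dT) between two landscape statistics
#'
#' Each statistic is mapped to the MRCA node of its taxa (the tip itself for
#' a diversity); `phyloDistance` returns the path length in generations
#' between the two nodes.  For a diversity of tip W against the divergence of
#' sister tips X, Y below W's sister clade, this reduces to
#' `2 * T_VWXY - T_XY`, twice the deeper split time minus the shallower one.
#'
#' @param tree a [SpeciesTree-class].
#' @param a,b [StatDescriptor-class] objects.
#' @return distance in generations (0 when both map to the same node).
#' @export
phyloDistance <- function(tree, a, b) {
  na <- nodeNumber(tree, descriptorNode(tree, a))
  nb <- nodeNumber(tree, descriptorNode(tree, b))
  if (na == nb) return(0)
  t <- nodeTimes(tree)
  labs <- c(tree@phylo$tip.label, tree@phylo$node.label)
  chA <- ancestorChain(tree@phylo, na)
  chB <- ancestorChain(tree@phylo, nb)
  common <- intersect(chA, chB)
  m <- common[which.min(t[labs[common]])]  # lowest common ancestor
  unname((t[labs[m]] - t[labs[na]]) + (t[labs[m]] - t[labs[nb]]))
}

## edge set defining a descriptor: branches (keyed by child node) on the
## tip-to-tip path through the MRCA for a divergence; the terminal branch
## for a diversity.
definingEdges <- function(tree, x) {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  if (x@kind == "diversity") return(x@taxa)
  m <- nodeNumber(tree, mrcaNode(tree, x@taxa))
  edges <- character()
  for (tip in x@taxa) {
    ch <- ancestorChain(phy, nodeNumber(tree, tip))
    ch <- ch[seq_len(which(ch == m) - 1L)]  # nodes below the MRCA
    edges <- c(edges, labs[ch])
  }
  unique(edges)
}

#' Do two landscape statistics share tree branches by definition?
#'
#' A divergence is defined by the branches on the tip-to-tip path through its
#' MRCA; a diversity by the terminal branch of its tip.  Two statistics share
#' branches when the two edge sets intersect, irrespective of split times.
#' Such pairs are excluded from the main distance-vs-correlation plots
#' because dT is not a good proxy for their expected correlation.
#'
#' @inheritParams phyloDistance
#' @return logical flag.
#' @export
sharesBranches <- function(tree, a, b)
  length(intersect(definingEdges(tree, a), definingEdges(tree, b))) > 0L

#' Probability that two lineages coalesce before a species split
#'
#' For two samples from a population of diploid size `Ne`, the probability of
#' coalescing within `T` generations (before the split with a sister species)
#' is `1 - exp(-T / (2 Ne))`.
#'
#' @param T time in generations (>= 0).
#' @param Ne diploid effective population size (> 0).
#' @return probability in `[0, 1)`.
#' @export
coalesceBeforeSplit <- function(T, Ne) {
  if (any(Ne <= 0)) stop("Ne must be > 0")
  if (any(T < 0)) stop("T must be >= 0")
  -expm1(-T / (2 * Ne))
}

#' Default great-apes species tree
#'
#' A ten-population dated tree emulating the great-apes panel: human (n=9),
#' bonobo (n=13), Nigeria-Cameroon chimpanzee (n=10), eastern chimpanzee
#' (n=6), central chimpanzee (n=4), western chimpanzee (n=4), eastern gorilla
#' (n=3), western gorilla (n=27), Sumatran orangutan (n=5), Bornean orangutan
#' (n=5).  Split times use literature-standard dates (root 12 Mya, gorilla 8
#' Mya, human-chimp 6 Mya, chimp-bonobo 2 Mya; generation time 25 y).  The
#' great-apes ancestral size is 125,089 and the human branch 7,672; sizes on
#' the remaining human-lineage branches are geometrically interpolated
#' between the two, and other branch sizes are plausible defaults satisfying
#' the low-Ne (< 8e3) status of bonobos, western chimpanzees and eastern
#' gorillas.  All values are configurable by building a tree directly with
#' [speciesTree()].
#'
#' @return a [SpeciesTree-class].
#' @examples
#' tr <- greatApesTree()
#' phyloDistance(tr, piStat("human"), piStat("bonobo"))
#' @export
greatApesTree <- function() {
  newick <- paste0(
    "(((human:240000,",
    "(bonobo:80000,",
    "(western_chimp:20000,",
    "((central_chimp:10000,eastern_chimp:10000)chimp_ce:6000,",
    "nigeria_chimp:16000)chimp_cen:4000)chimp:60000)pan:160000)homo_pan:80000,",
    "(eastern_gorilla:10000,western_gorilla:10000)gorilla:310000)african:160000,",
    "(sumatran_orang:40000,bornean_orang:40000)orang:440000)great_apes;")
  tr <- ape::read.tree(text = newick)
  # interpolated human-lineage internal sizes: 125089 * r^k, r = (7672/125089)^(1/3)
  r <- (7672 / 125089)^(1 / 3)
  ne <- c(
    human = 7672, bonobo = 5000, western_chimp = 5500,
    central_chimp = 30000, eastern_chimp = 15000, nigeria_chimp = 17000,
    eastern_gorilla = 2500, western_gorilla = 25000,
    sumatran_orang = 25000, bornean_orang = 15000,
    chimp_ce = 45000, chimp_cen = 50000, chimp = 60000, pan = 30000,
    gorilla = 40000, orang = 40000,
    homo_pan = 125089 * r^2, african = 125089 * r, great_apes = 125089)
  samples <- c(human = 9, bonobo = 13, nigeria_chimp = 10, eastern_chimp = 6,
               central_chimp = 4, western_chimp = 4, eastern_gorilla = 3,
               western_gorilla = 27, sumatran_orang = 5, bornean_orang = 5)
  speciesTree(tr, ne, samples)
}

#' All landscape statistic descriptors on a tree
#'
#' One diversity per tip plus one divergence per unordered tip pair.
#'
#' @param tree a [SpeciesTree-class].
#' @return list of [StatDescriptor-class] named by [statLabel()].
#' @export
allDescriptors <- function(tree) {
  tips <- tipNames(tree)
  out <- lapply(tips, piStat)
  if (length(tips) > 1L) {
    prs <- combn(tips, 2L)
    out <- c(out, lapply(seq_len(ncol(prs)),
                         function(i) dxyStat(prs[1, i], prs[2, i])))
  }
  setNames(out, vapply(out, statLabel, ""))
}
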