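## Diffusion-approximation substitution rates by mutation class, and
## empirical fixation accounting from forward simulations.

#' Diffusion-approximation fixation probability of a new mutation
#'
#' For a new semidominant mutation with homozygote advantage `s` in a
#' Wright--Fisher population of `N` diploids, the fixation probability is
#' `u(s) = (1 - exp(-2 s)) / (1 - exp(-4 N s))`, with the continuous neutral
#' limit `u(0) = 1 / (2 N)`.  Evaluation is numerically stable for large
#' `|4 N s|`: strongly deleterious mutations return `exp((4 N - 2) s)`
#' (underflowing to 0) instead of overflowing.
#'
#' @param s selection coefficient(s) (may be negative).
#' @param N diploid population size (>= 2).
#' @return fixation probability, vectorized over `s`.
#' @examples
#' fixationProbability(0, 1000)       # 1 / 2000
#' fixationProbability(0.001, 1000)   # ~ 2.035e-3
#' @export
fixationProbability <- function(s, N) {
  if (N < 2) stop("N must be >= 2")
  s <- as.numeric(s)
  out <- numeric(length(s))
  x <- 4 * N * s
  neutral <- abs(x) < 1e-12
  out[neutral] <- 1 / (2 * N)
  deep <- !neutral & -x > 500          # strongly deleterious: avoid overflow
  if (any(deep)) {
    sd <- s[deep]
    out[deep] <- ifelse(-2 * sd > 500, exp((4 * N - 2) * sd),
                        expm1(-2 * sd) * exp(4 * N * sd))
  }
  reg <- !neutral & !deep
  out[reg] <- expm1(-2 * s[reg]) / expm1(-4 * N * s[reg])
  out
}

#' DFE configuration
#'
#' @param fracDeleterious,fracBeneficial fractions of exonic mutations that
#'   are deleterious/beneficial (the residual fraction is neutral).
#' @param gammaShape gamma shape alpha of the deleterious DFE.
#' @param meanSDel mean (negative) deleterious selection coefficient; the
#'   gamma scale is `|meanSDel| / gammaShape`.
#' @param meanSBen mean (positive) beneficial coefficient of the exponential
#'   beneficial DFE.
#' @return a [DFEConfig-class].
#' @examples
#' # best-fit exonic DFE: 60% deleterious, beneficial rate 1e-12 of 2e-8
#' dfeConfig(0.6, 1e-12 / 2e-8, gammaShape = 0.16,
#'           meanSDel = -0.03, meanSBen = 0.01)
#' @export
dfeConfig <- function(fracDeleterious = 0, fracBeneficial = 0,
                      gammaShape = 0.16, meanSDel = -0.03, meanSBen = 0.01) {
  methods::new("DFEConfig", fracDeleterious = fracDeleterious,
               fracBeneficial = fracBeneficial, gammaShape = gammaShape,
               meanSDel = meanSDel, meanSBen = meanSBen)
}

## E[2N u(sign * s)] over a density on s > 0, integrated in log space so the
## gamma's mass concentrated near 0 (shape < 1) is captured.
expectedScaledFixation <- function(N, dens, sign) {
  g <- function(y) {
    s <- exp(y)
    dens(s) * 2 * N * fixationProbability(sign * s, N) * s
  }
  r <- try(integrate(g, -80, 10, rel.tol = 1e-10, subdivisions = 5000L),
           silent = TRUE)
  if (inherits(r, "try-error") || r$message != "OK")
    stop("DFE integration failed: ",
         if (inherits(r, "try-error")) as.character(r) else r$message)
  r$value
}

#' Expected substitution rates by mutation class
#'
#' Per-site per-generation substitution rates within exons for the neutral,
#' deleterious and beneficial classes, obtained by integrating the diffusion
#' fixation probability over the DFE: the class rate is the class mutation
#' rate times `2 N E[u(s)]` (so the neutral class substitutes at its
#' mutation rate).  For a lineage whose population size changes through
#' time, supply a schedule of `(N, duration)` segments; rates are
#' duration-weighted averages across segments.  Also reports the beneficial
#' share of exonic substitutions and the ratio of the exonic substitution
#' rate to the neutral rate.
#'
#' @param dfe a [DFEConfig-class].
#' @param totalRate total per-site mutation rate within exons.
#' @param N a single diploid size, or a data.frame with columns `N` and
#'   `duration` (generations) for a lineage schedule.
#' @return list with per-class rates (`neutral`, `deleterious`,
#'   `beneficial`), `total`, `beneficialFraction`, `exonNeutralRatio`, and
#'   the inputs echoed.
#' @seealso [fixationProbability()], [humanLineageSchedule()]
#' @export
expectedSubstitutionRates <- function(dfe, totalRate, N) {
  sched <- if (is.data.frame(N)) N else data.frame(N = N, duration = 1)
  stopifnot(all(sched$N >= 2), all(sched$duration > 0))
  muD <- totalRate * dfe@fracDeleterious
  muB <- totalRate * dfe@fracBeneficial
  muN <- totalRate - muD - muB
  scaleD <- abs(dfe@meanSDel) / dfe@gammaShape
  perSeg <- vapply(seq_len(nrow(sched)), function(i) {
    Ni <- sched$N[i]
    c(del = if (muD > 0) muD * expectedScaledFixation(Ni,
        function(s) dgamma(s, shape = dfe@gammaShape, scale = scaleD), -1)
      else 0,
      ben = if (muB > 0) muB * expectedScaledFixation(Ni,
        function(s) dexp(s, rate = 1 / dfe@meanSBen), +1)
      else 0)
  }, c(del = 0, ben = 0))
  w <- sched$duration / sum(sched$duration)
  del <- sum(perSeg["del", ] * w)
  ben <- sum(perSeg["ben", ] * w)
  total <- muN + del + ben
  list(neutral = muN, deleterious = del, beneficial = ben, total = total,
       beneficialFraction = if (total > 0) ben / total else 0,
       exonNeutralRatio = total / totalRate,
       dfe = dfe, totalRate = totalRate, schedule = sched)
}

#' Population-size schedule along the human lineage
#'
#' Extracts the root-to-tip path for one tip of a species tree as a
#' `(N, duration)` schedule usable by [expectedSubstitutionRates()]: one
#' segment per branch on the path, oldest first.  With the default
#' [greatApesTree()] this yields the African-ape ancestor, the Homo-Pan
#' ancestor and the human branch, whose sizes interpolate geometrically
#' between the great-apes ancestral size (125,089) and the human branch size
#' (7,672).
#'
#' @param tree a [SpeciesTree-class].
#' @param tip tip name (default `"human"`).
#' @return data.frame with columns `branch`, `N`, `duration`.
#' @export
humanLineageSchedule <- function(tree = greatApesTree(), tip = "human") {
  phy <- tree@phylo
  labs <- c(phy$tip.label, phy$node.label)
  chain <- ancestorChain(phy, nodeNumber(tree, tip))
  path <- rev(labs[chain[-length(chain)]])   # root-ward first, drop root
  bl <- branchLengths(tree)
  data.frame(branch = path, N = unname(tree@ne[path]),
             duration = unname(bl[path]))
}

#' Empirical fixation accounting from forward-simulation records
#'
#' Counts fixations by class along a root-to-tip branch path and converts
#' them to per-site per-generation rates over the path's total duration,
#' field-for-field comparable with [expectedSubstitutionRates()].
#'
#' @param records data.frame of fixation records (`branch`, `pos`, `class`,
#'   `s`, `generation`), e.g. from [simulateForward()].
#' @param path character vector of branch names from root to tip.
#' @param exonLength total exon length in bp (denominator for rates).
#' @param generations total generations spanned by the path.
#' @return list with per-class `counts` and `rates`, `total` rate and
#'   `beneficialFraction`.
#' @export
fixationFractions <- function(records, path, exonLength, generations) {
  if (length(path) == 0L) stop("empty branch path")
  stopifnot(exonLength > 0, generations > 0)
  rec <- records[records$branch %in% path, , drop = FALSE]
  counts <- vapply(c("neutral", "deleterious", "beneficial"),
                   function(cl) sum(rec$class == cl), 0)
  rates <- counts / (exonLength * generations)
  tot <- sum(counts)
  list(counts = counts, rates = rates, total = sum(rates),
       beneficialFraction = if (tot > 0) unname(counts["beneficial"] / tot) else 0)
}
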