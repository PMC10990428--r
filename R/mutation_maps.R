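## Heterogeneous neutral mutation-rate maps and overlay of mutations onto
## stored genealogical summaries.

#' Build a heterogeneous neutral mutation-rate map
#'
#' Per-window neutral rates are drawn i.i.d. from
#' `Normal(meanRate, sigmaRel * meanRate)`, truncated below at 0 (at the
#' relative-SD values of interest, 0.005--0.150, truncation is essentially
#' never triggered).  Sub-intervals overlapping exons carry the window rate
#' minus the non-neutral exonic rate, floored at 0 with a warning, so the
#' total (neutral plus non-neutral) rate stays constant along the genome.
#' The map is shared identically by all branches of the tree.
#'
#' @param grid window [GenomicRanges::GRanges].
#' @param meanRate global mean neutral rate (default `2e-8`).
#' @param sigmaRel relative standard deviation of window draws (e.g. one of
#'   0.005, 0.007, 0.011, 0.016, 0.023, 0.033, 0.048, 0.070, 0.103, 0.150).
#' @param exons data.frame with 0-based half-open `start`,`end`, or `NULL`.
#' @param nonneutralRate per-site non-neutral mutation rate within exons
#'   subtracted from exon-overlapping intervals.
#' @param seed integer seed.
#' @return a [MutationRateMap-class].
#' @export
buildMutationMap <- function(grid, meanRate = 2e-8, sigmaRel = 0,
                             exons = NULL, nonneutralRate = 0, seed = 1L) {
  stopifnot(meanRate > 0, sigmaRel >= 0)
  set.seed(seed)
  nw <- length(grid)
  rates <- rnorm(nw, meanRate, sigmaRel * meanRate)
  rates <- pmax(rates, 0)
  ws <- GenomicRanges::start(grid) - 1L     # 0-based half-open
  we <- GenomicRanges::end(grid)
  pieces <- vector("list", nw)
  floored <- FALSE
  for (w in seq_len(nw)) {
    segs <- data.frame(start = ws[w], end = we[w], window = w,
                       rate = rates[w])
    if (!is.null(exons) && nrow(exons)) {
      ex <- exons[exons$end > ws[w] & exons$start < we[w], , drop = FALSE]
      if (nrow(ex)) {
        ex$start <- pmax(ex$start, ws[w]); ex$end <- pmin(ex$end, we[w])
        bounds <- sort(unique(c(ws[w], we[w], ex$start, ex$end)))
        segs <- data.frame(start = bounds[-length(bounds)],
                           end = bounds[-1], window = w, rate = rates[w])
        inEx <- vapply(segs$start, function(s)
          any(ex$start <= s & ex$end > s), TRUE)
        adj <- rates[w] - nonneutralRate
        if (any(inEx) && adj < 0) floored <- TRUE
        segs$rate[inEx] <- max(adj, 0)
      }
    }
    pieces[[w]] <- segs
  }
  if (floored)
    warning("non-neutral rate exceeds a window rate; exonic neutral rate floored at 0")
  methods::new("MutationRateMap", grid = grid, windowRate = rates,
               intervals = do.call(rbind, pieces), meanRate = meanRate,
               sigmaRel = sigmaRel)
}

#' @describeIn buildMutationMap length-weighted mean neutral rate per window
#'   (after exon subtraction); the effective rate used by the overlay.
#' @param map a [MutationRateMap-class].
#' @export
windowEffectiveRate <- function(map) {
  iv <- map@intervals
  w <- iv$end - iv$start
  as.numeric(tapply(iv$rate * w, iv$window, sum) /
             tapply(w, iv$window, sum))
}

setMethod("show", "MutationRateMap", function(object) {
  cat(sprintf("MutationRateMap: %d windows, mean %.3g, relative SD %.3g\n",
              length(object@grid), object@meanRate, object@sigmaRel))
})

#' Overlay mutations onto stored genealogical summaries
#'
#' Converts realized per-window mean pairwise coalescence times (from
#' [simulateNeutralWindows()]) into diversity and divergence landscapes
#' under a mutation-rate map: the expected per-site value in window `w` for
#' a statistic with mean time `T` is `2 * rate_w * T`; the realized value is
#' Poisson-sampled over the window's callable length and divided by it.
#' Because the genealogies are fixed, the same simulation can be re-overlaid
#' under different maps, mirroring the add-mutations-after-the-fact design.
#'
#' @param sim a [SimResult-class] from [simulateNeutralWindows()].
#' @param map a [MutationRateMap-class] on the same grid.
#' @param callableLength numeric per-window callable bp (default: full
#'   window widths).
#' @param seed integer seed for the Poisson sampling.
#' @return named list of [Landscape-class] objects, one per descriptor.
#' @export
overlayMutations <- function(sim, map, callableLength = NULL, seed = 1L) {
  ct <- sim@coalTimes
  if (!nrow(ct)) stop("sim has no coalescence summaries; run simulateNeutralWindows")
  grid <- sim@config$grid
  if (length(map@grid) != length(grid))
    stop("map grid does not match the simulation grid")
  set.seed(seed)
  rate <- windowEffectiveRate(map)
  if (is.null(callableLength)) callableLength <- IRanges::width(grid)
  tree <- sim@config$tree
  desc <- allDescriptors(tree)
  nw <- length(grid)
  lapply(desc, function(d) {
    lab <- statLabel(d)
    rows <- ct[ct$stat == lab, ]
    vals <- rep(NA_real_, nw)
    meanT <- rep(NA_real_, nw)
    meanT[rows$window] <- rows$meanT
    lam <- 2 * rate * meanT * callableLength
    ok <- !is.na(lam) & callableLength > 0
    vals[ok] <- rpois(sum(ok), lam[ok]) / callableLength[ok]
    methods::new("Landscape", stat = d, grid = grid,
                 values = pmin(vals, 1),
                 callableFrac = callableLength / IRanges::width(grid))
  })
}
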