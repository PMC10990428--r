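## Pairwise Spearman correlations between landscapes organized by
## phylogenetic distance; covariance decomposition against genomic
## features; PCA embedding of simulations and data.

#' Spearman correlation between two landscapes
#'
#' Rank correlation with average ranks for ties; windows missing in either
#' vector are dropped pairwise.  Fewer than 3 complete pairs (or a constant
#' vector) yields `NA` with a message.
#'
#' @param x,y numeric per-window values (or [Landscape-class] objects).
#' @return Spearman rho, or `NA` when undefined.
#' @export
spearmanRho <- function(x, y) {
  if (methods::is(x, "Landscape")) x <- x@values
  if (methods::is(y, "Landscape")) y <- y@values
  if (length(x) != length(y)) stop("landscapes must share a grid")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3L) {
    message("fewer than 3 complete window pairs; correlation undefined")
    return(NA_real_)
  }
  suppressWarnings(cor(x[ok], y[ok], method = "spearman"))
}

#' All pairwise correlations between landscapes
#'
#' One record per unordered pair of landscapes, annotated with the
#' phylogenetic distance dT between the statistics' MRCA nodes, the
#' comparison type (`pi_pi`, `pi_dxy`, `dxy_dxy`), whether the two
#' statistics share tree branches by definition, and whether any involved
#' tip belongs to a low-Ne species (species Ne below `lowNeThreshold`,
#' default 8e3).  Optionally drops shared-branch pairs, the main-figure
#' convention, since dT is not a good correlation proxy for them.
#'
#' @param landscapes named list of [Landscape-class] objects on one grid.
#' @param tree the [SpeciesTree-class] the statistics live on.
#' @param excludeSharedBranches drop pairs whose statistics share branches.
#' @param lowNeThreshold Ne below which a species is flagged low-Ne.
#' @return data.frame with columns `statA`, `statB`, `type`, `dT`, `rho`,
#'   `sharesBranches`, `lowNe`.
#' @export
allPairwiseCorrelations <- function(landscapes, tree,
                                    excludeSharedBranches = FALSE,
                                    lowNeThreshold = 8e3) {
  labs <- vapply(landscapes, function(l) statLabel(l@stat), "")
  if (anyDuplicated(labs)) stop("duplicate landscape descriptors")
  n <- length(landscapes)
  if (n < 2L) stop("need at least two landscapes")
  ne <- branchNe(tree)
  prs <- combn(n, 2L)
  recs <- lapply(seq_len(ncol(prs)), function(i) {
    a <- landscapes[[prs[1, i]]]; b <- landscapes[[prs[2, i]]]
    da <- a@stat; db <- b@stat
    kinds <- sort(c(da@kind, db@kind))
    type <- if (all(kinds == "diversity")) "pi_pi"
            else if (all(kinds == "divergence")) "dxy_dxy" else "pi_dxy"
    sb <- sharesBranches(tree, da, db)
    tips <- unique(c(da@taxa, db@taxa))
    data.frame(statA = statLabel(da), statB = statLabel(db), type = type,
               dT = phyloDistance(tree, da, db),
               rho = spearmanRho(a, b),
               sharesBranches = sb,
               lowNe = any(ne[tips] < lowNeThreshold),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (excludeSharedBranches) out <- out[!out$sharesBranches, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Covariance of divergence landscapes with a genomic feature over time
#'
#' For each divergence landscape `D(t)` (with split time `t`), computes the
#' sample covariance and correlation across windows with a per-window
#' feature `X` (exon density or mean recombination rate), then fits
#' `Cov(D(t), X) ~ t` by ordinary least squares.  Under the decomposition
#' `D_i(t) = pi_i(t) + R_i t + eps_i` the covariance is
#' `Cov(pi(t), X) + t Cov(R, X) + Cov(eps, X)`, so the fitted slope
#' estimates `Cov(R, X)`, the covariance between per-window substitution
#' rates and the feature.  Optionally restricts to the interior 50% of
#' windows by index ("middle half"), which removes chromosome-end effects
#' such as GC-biased gene conversion hotspots.
#'
#' @param divergences list of [Landscape-class] divergence objects.
#' @param splitTimes numeric split times `t` (generations), one per
#'   landscape; at least two distinct values.
#' @param feature numeric per-window feature vector on the same grid.
#' @param middleHalf restrict to the interior 50% of windows.
#' @return list with `series` (data.frame `pair`, `t`, `cov`, `cor`),
#'   `slope`, `intercept` (the OLS fit of cov on t).
#' @export
covarianceSeries <- function(divergences, splitTimes, feature,
                             middleHalf = FALSE) {
  stopifnot(length(divergences) == length(splitTimes))
  if (length(unique(splitTimes)) < 2L)
    stop("need at least two distinct split times to fit a slope")
  nw <- length(divergences[[1]]@values)
  idx <- seq_len(nw)
  if (middleHalf) idx <- idx[idx > nw / 4 & idx <= 3 * nw / 4]
  rows <- lapply(seq_along(divergences), function(i) {
    v <- divergences[[i]]@values[idx]
    f <- feature[idx]
    ok <- !is.na(v) & !is.na(f)
    data.frame(pair = statLabel(divergences[[i]]@stat),
               t = splitTimes[i],
               cov = if (sum(ok) >= 2) cov(v[ok], f[ok]) else NA_real_,
               cor = if (sum(ok) >= 3 && sd(v[ok]) > 0 && sd(f[ok]) > 0)
                       cor(v[ok], f[ok]) else NA_real_,
               stringsAsFactors = FALSE)
  })
  series <- do.call(rbind, rows)
  series <- series[order(series$t), ]
  rownames(series) <- NULL
  fit <- lm(cov ~ t, data = series)
  list(series = series, slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]))
}

#' PCA embedding of simulations and data by their correlation vectors
#'
#' Rows are simulation runs plus the (empirical or held-out) data row;
#' columns are pairwise Spearman correlations between landscapes.  Columns
#' are mean-centered but not variance-scaled (correlations already share a
#' scale); missing entries are imputed by the column mean (with a message).
#' Returns the top-`k` coordinates and the Euclidean distance in the full
#' centered space from the data row to every other row.  Runs with a
#' beneficial mutation rate at or above `muPMax` can be excluded, since
#' strong positive selection induces negative correlations that dominate
#' low-order components.
#'
#' @param mat numeric matrix, rows = runs (+ data), columns = correlations;
#'   rownames identify runs.
#' @param dataRow name or index of the data row (default: last row).
#' @param muP optional numeric per-row beneficial mutation rate used by the
#'   exclusion filter (`NA` for the data row).
#' @param muPMax threshold for exclusion (default `1e-10`).
#' @param excludeStrongPositive apply the `muP >= muPMax` filter.
#' @param k number of components returned (default 2).
#' @return list with `coords` (rows x k), `sdev`, `distances` (named, from
#'   the data row), `excluded` (row names dropped by the filter).
#' @export
pcaEmbedding <- function(mat, dataRow = nrow(mat), muP = NULL,
                         muPMax = 1e-10, excludeStrongPositive = FALSE,
                         k = 2L) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2L) stop("need at least two correlation columns")
  if (nrow(mat) < 2L) stop("need at least two rows")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("run", seq_len(nrow(mat)))
  dataName <- if (is.character(dataRow)) dataRow else rownames(mat)[dataRow]
  excluded <- character(0)
  if (excludeStrongPositive && !is.null(muP)) {
    drop <- !is.na(muP) & muP >= muPMax & rownames(mat) != dataName
    excluded <- rownames(mat)[drop]
    mat <- mat[!drop, , drop = FALSE]
  }
  if (anyNA(mat)) {
    message("imputing ", sum(is.na(mat)), " missing correlations by column mean")
    for (j in seq_len(ncol(mat))) {
      nas <- is.na(mat[, j])
      if (any(nas)) mat[nas, j] <- mean(mat[, j], na.rm = TRUE)
    }
  }
  ctr <- scale(mat, center = TRUE, scale = FALSE)
  pc <- prcomp(ctr, center = FALSE, scale. = FALSE)
  k <- min(k, ncol(pc$x))
  di <- which(rownames(mat) == dataName)
  if (!length(di)) stop("data row not found: ", dataName)
  dists <- sqrt(rowSums((ctr - matrix(ctr[di, ], nrow(ctr), ncol(ctr),
                                      byrow = TRUE))^2))
  list(coords = pc$x[, seq_len(k), drop = FALSE], sdev = pc$sdev,
       distances = dists[-di], excluded = excluded)
}
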