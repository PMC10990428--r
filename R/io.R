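## Readers and writers for the standard interchange formats: VCF allele
## tables, BED masks/exons, recombination-map and landscape TSVs.

#' Read an allele table from a VCF
#'
#' Reads biallelic SNP records with per-sample GT fields and collapses them
#' to per-population alternate-allele counts (`ac`) and called-allele
#' numbers (`an`).  An `AA=` INFO tag, when present, is taken as the
#' outgroup (ancestral) allele.
#'
#' @param vcfFile path to a VCF (optionally gzipped).
#' @param popmap named character vector mapping sample name to population.
#' @return an [AlleleTable-class].
#' @export
readVcfAlleles <- function(vcfFile, popmap) {
  v <- vcfR::read.vcfR(vcfFile, verbose = FALSE)
  fixed <- vcfR::getFIX(v, getINFO = TRUE)
  keep <- !is.na(fixed[, "ALT"]) & !grepl(",", fixed[, "ALT"]) &
          fixed[, "REF"] %in% c("A", "C", "G", "T") &
          fixed[, "ALT"] %in% c("A", "C", "G", "T")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  pos <- as.integer(fixed[keep, "POS"])
  info <- fixed[keep, "INFO"]
  aa <- ifelse(grepl("AA=", info), sub(".*AA=([ACGT]).*", "\\1", info),
               NA_character_)
  aa[!aa %in% c("A", "C", "G", "T")] <- NA_character_
  samples <- colnames(gt)
  miss <- setdiff(samples, names(popmap))
  if (length(miss)) stop("samples missing from popmap: ",
                         paste(head(miss, 5), collapse = ", "))
  pops <- unique(popmap[samples])
  n <- length(pos)
  ac <- matrix(0L, n, length(pops), dimnames = list(NULL, pops))
  an <- matrix(0L, n, length(pops), dimnames = list(NULL, pops))
  for (p in pops) {
    cols <- samples[popmap[samples] == p]
    sub <- gt[, cols, drop = FALSE]
    a1 <- substr(sub, 1, 1); a2 <- substr(sub, 3, 3)
    called <- matrix(a1 %in% c("0", "1"), n) + matrix(a2 %in% c("0", "1"), n)
    alt <- matrix(a1 == "1", n) + matrix(a2 == "1", n)
    an[, p] <- as.integer(rowSums(called))
    ac[, p] <- as.integer(rowSums(alt))
  }
  o <- order(pos)
  alleleTable(pos[o], ac[o, , drop = FALSE], an[o, , drop = FALSE],
              ref = fixed[keep, "REF"][o], alt = fixed[keep, "ALT"][o],
              outgroup = aa[o])
}

#' Read per-population callable masks from BED files
#'
#' @param files named character vector (population -> BED path); BED is
#'   0-based half-open.
#' @param chrom chromosome to keep.
#' @return a [callableMask()] list of `GRanges`.
#' @export
readMaskBeds <- function(files, chrom = "chr12") {
  masks <- lapply(files, function(f) {
    b <- data.table::fread(f, header = FALSE, sep = "\t",
                           col.names = c("chrom", "start", "end")[1:3])
    b <- b[b$chrom == chrom, ]
    data.frame(start = b$start, end = b$end)
  })
  callableMask(masks, chrom = chrom)
}

#' Read exon intervals from a BED file
#'
#' @param file BED path (0-based half-open).
#' @param chrom chromosome to keep.
#' @return data.frame with `start`, `end` (0-based half-open).
#' @export
readExonBed <- function(file, chrom = "chr12") {
  b <- data.table::fread(file, header = FALSE, sep = "\t")
  names(b)[1:3] <- c("chrom", "start", "end")
  b <- b[b$chrom == chrom, ]
  data.frame(start = b$start, end = b$end)
}

#' Write intervals to a BED file
#' @param df data.frame with `start`, `end` (0-based half-open).
#' @param file output path.
#' @param chrom chromosome name.
#' @export
writeBed <- function(df, file, chrom = "chr12") {
  data.table::fwrite(data.frame(chrom = chrom, start = df$start, end = df$end),
                     file, sep = "\t", col.names = FALSE)
  invisible(file)
}

#' Read/write a recombination map TSV (`start  end  rate_per_bp`)
#' @param file path.
#' @return data.frame `start`, `end`, `rate`.
#' @export
readRecombMap <- function(file) {
  m <- data.table::fread(file, header = TRUE, sep = "\t")
  recombinationMap(m$start, m$end, m[[3]])
}

#' @rdname readRecombMap
#' @param map recombination map data.frame.
#' @export
writeRecombMap <- function(map, file) {
  data.table::fwrite(data.frame(start = map$start, end = map$end,
                                rate_per_bp = map$rate),
                     file, sep = "\t")
  invisible(file)
}

#' Write landscapes to TSV
#'
#' Columns `chrom start end stat taxa value callable_frac`; one row per
#' window per landscape.  `start`/`end` are 0-based half-open.
#'
#' @param landscapes list of [Landscape-class] objects.
#' @param file output path.
#' @param header optional named character vector written as `# key=value`
#'   comment lines (e.g. seed and config hash).
#' @export
writeLandscapeTSV <- function(landscapes, file, header = NULL) {
  rows <- lapply(landscapes, function(l) {
    g <- l@grid
    data.frame(chrom = as.character(GenomicRanges::seqnames(g)),
               start = GenomicRanges::start(g) - 1L,
               end = GenomicRanges::end(g),
               stat = l@stat@kind,
               taxa = paste(l@stat@taxa, collapse = ","),
               value = l@values,
               callable_frac = l@callableFrac)
  })
  df <- do.call(rbind, rows)
  con <- file(file, "w")
  on.exit(close(con))
  if (!is.null(header))
    writeLines(sprintf("# %s=%s", names(header), header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeLandscapeTSV
#' @return `readLandscapeTSV`: named list of [Landscape-class] objects.
#' @export
readLandscapeTSV <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  key <- paste(df$stat, df$taxa)
  out <- lapply(split(df, key), function(d) {
    d <- d[order(d$start), ]
    taxa <- strsplit(d$taxa[1], ",")[[1]]
    stat <- if (d$stat[1] == "diversity") piStat(taxa)
            else dxyStat(taxa[1], taxa[2])
    methods::new("Landscape", stat = stat,
                 grid = GenomicRanges::GRanges(d$chrom[1],
                        IRanges::IRanges(d$start + 1L, d$end)),
                 values = d$value, callableFrac = d$callable_frac)
  })
  setNames(out, vapply(out, function(l) statLabel(l@stat), ""))
}

#' Per-window exon density as a feature vector
#'
#' The percentage (as a fraction) of callable nucleotides in each window
#' that fall within an exon.
#'
#' @param exons data.frame with 0-based half-open `start`, `end`.
#' @param masks [callableMask()] list (or single `GRanges`); `NULL` treats
#'   every base as callable.
#' @param grid window [GenomicRanges::GRanges].
#' @return numeric per-window exon density (NA where nothing is callable).
#' @export
exonDensityFeature <- function(exons, masks, grid) {
  chrom <- as.character(GenomicRanges::seqnames(grid)[1])
  cm <- if (is.null(masks)) GenomicRanges::GRanges(chrom,
          IRanges::IRanges(1, max(GenomicRanges::end(grid))))
        else if (inherits(masks, "GRanges")) masks else intersectMasks(masks)
  exg <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(exons$start + 1L, exons$end))
  callEx <- GenomicRanges::intersect(cm, exg)
  tot <- windowCallableLength(cm, grid)
  inEx <- windowCallableLength(callEx, grid)
  ifelse(tot > 0, inEx / tot, NA_real_)
}

#' Per-window mean recombination rate as a feature vector
#'
#' @param recomb recombination map data.frame.
#' @param grid window [GenomicRanges::GRanges].
#' @return numeric per-window mean rate (per bp per generation).
#' @export
recombRateFeature <- function(recomb, grid) {
  chrom <- as.character(GenomicRanges::seqnames(grid)[1])
  rcg <- GenomicRanges::GRanges(chrom,
          IRanges::IRanges(recomb$start + 1L, recomb$end))
  ov <- GenomicRanges::findOverlaps(grid, rcg)
  w <- IRanges::width(IRanges::pintersect(grid[S4Vectors::queryHits(ov)],
                                          rcg[S4Vectors::subjectHits(ov)]))
  num <- tapply(w * recomb$rate[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov), sum)
  den <- tapply(w, S4Vectors::queryHits(ov), sum)
  out <- rep(NA_real_, length(grid))
  out[as.integer(names(num))] <- num / den
  out
}
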