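smallTree <- function() {
  speciesTree(
    ape::read.tree(text = "((A:2000,B:2000)AB:8000,C:10000)root;"),
    ne = c(A = 2000, B = 1000, C = 1500, AB = 2000, root = 2000),
    samples = c(A = 3, B = 2, C = 2))
}

test_that("generation is byte-identical under a fixed seed", {
  sp <- syntheticDatasetSpec(tree = smallTree(), chromLength = 2e5,
                             windowSize = 2e4)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generateDataset(sp, seed = 11, outdir = d1)
  generateDataset(sp, seed = 11, outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("checksum of", f))
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  generateDataset(sp, seed = 12, outdir = d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "synthetic.vcf"))),
    unname(tools::md5sum(file.path(d3, "synthetic.vcf")))))
})

test_that("the default panel writes the printed per-population sample counts", {
  sp <- syntheticDatasetSpec(chromLength = 1e5, windowSize = 2e4)
  d <- withr::local_tempdir()
  generateDataset(sp, seed = 21, outdir = d)
  hdr <- grep("^#CHROM", readLines(file.path(d, "synthetic.vcf"), n = 10),
              value = TRUE)
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  pops <- sub("_\\d+$", "", samples)
  counts <- table(pops)
  want <- c(human = 9, bonobo = 13, nigeria_chimp = 10, eastern_chimp = 6,
            central_chimp = 4, western_chimp = 4, eastern_gorilla = 3,
            western_gorilla = 27, sumatran_orang = 5, bornean_orang = 5)
  expect_equal(as.integer(counts[names(want)]), unname(want),
               ignore_attr = TRUE)
})

test_that("designed low-callable windows are exactly the filtered ones", {
  sp <- syntheticDatasetSpec(tree = smallTree(), chromLength = 4e5,
                             windowSize = 2e4, lowCallableFrac = 0.25)
  d <- withr::local_tempdir()
  out <- generateDataset(sp, seed = 31, outdir = d)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(length(truth$lowWindows), 5)   # floor(0.25 * 20)
  l <- windowedDiversity(out$alleles, out$masks, out$grid, "A")
  f <- applyWindowFilter(l, 0.40)
  expect_equal(which(is.na(landscapeValues(f))), truth$lowWindows)
})

test_that("landscapes from the written VCF equal the internal computation", {
  tr <- smallTree()
  sp <- syntheticDatasetSpec(tree = tr, chromLength = 2e5,
                             windowSize = 2e4)
  d <- withr::local_tempdir()
  out <- generateDataset(sp, seed = 41, outdir = d)
  truth <- jsonlite::read_json(file.path(d, "truth.json"),
                               simplifyVector = TRUE)
  at <- readVcfAlleles(file.path(d, "synthetic.vcf"), syntheticPopmap(tr))
  masks <- readMaskBeds(setNames(
    file.path(d, sprintf("mask_%s.bed", tipNames(tr))), tipNames(tr)))
  for (lab in c("pi_A", "dxy_A_C")) {
    tx <- strsplit(sub("^(pi|dxy)_", "", lab), "_")[[1]]
    l <- if (startsWith(lab, "pi"))
      windowedDiversity(at, masks, out$grid, tx)
    else windowedDivergence(at, masks, out$grid, tx[1], tx[2])
    expect_equal(landscapeValues(l), truth$internalLandscapes[[lab]],
                 tolerance = 1e-9)
    # and both sit within sampling noise of the genealogical expectation
    expected <- truth$expectedLandscapes[[lab]]
    expect_equal(mean(landscapeValues(l), na.rm = TRUE),
                 mean(expected, na.rm = TRUE), tolerance = 0.35)
  }
})

test_that("outgroup planting and nucleotide assignment follow the model", {
  tr <- smallTree()
  sp <- syntheticDatasetSpec(tree = tr, chromLength = 4e5,
                             windowSize = 4e4, outgroupFrac = 0.7)
  d <- withr::local_tempdir()
  out <- generateDataset(sp, seed = 51, outdir = d)
  at <- out$alleles
  n <- nSites(at)
  # outgroup present at ~ the configured fraction, equal to REF (ancestral)
  hasOg <- !is.na(at@outgroup)
  expect_equal(mean(hasOg), 0.7, tolerance = 3 * sqrt(0.21 / n) / 0.7 + 0.02)
  expect_true(all(at@outgroup[hasOg] == at@ref[hasOg]))
  # classify the polarization split of present outgroup alleles
  pol <- polarizeByOutgroup(at@outgroup)
  expect_equal(sum(pol == "excluded"), sum(!hasOg))
  # uniform ordered-pair model: among biallelic (anc, der) assignments the
  # weak/strong change probability is 2/3
  cls <- ifelse(xor(at@ref %in% c("A", "T"), at@alt %in% c("A", "T")),
                "WS", "WW_SS")
  p <- mean(cls == "WS")
  expect_lt(abs(p - 2 / 3), 3 * sqrt(2 / 9 / n))
})

test_that("site class frequencies across four species match the model", {
  tr <- smallTree()
  sp <- syntheticDatasetSpec(tree = tr, chromLength = 4e5,
                             windowSize = 4e4)
  d <- withr::local_tempdir()
  out <- generateDataset(sp, seed = 61, outdir = d)
  at <- out$alleles
  # representative states over three species (plus outgroup column is not a
  # species); use A, B, C plus the ancestral allele as a fourth lineage
  st <- apescapes:::representativeStates(at, c("A", "B", "C"))
  st4 <- cbind(st, at@ref)
  cls <- classifySiteType(st4)
  tab <- table(cls)
  # with one mutation per site only biallelic classes appear
  expect_false("multi_excluded" %in% names(tab))
  frac <- tab[["WS"]] / (tab[["WS"]] + tab[["WW_SS"]])
  nn <- tab[["WS"]] + tab[["WW_SS"]]
  expect_lt(abs(frac - 2 / 3), 3 * sqrt(2 / 9 / nn))
})
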