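test_that("the generator is deterministic under a fixed seed", {
  cfg <- tinyConfig(seed = 77)
  g1 <- generateReference(cfg)
  g2 <- generateReference(cfg)
  expect_equal(as.character(g1), as.character(g2))
  p1 <- plantSorfs(cfg, g1)
  p2 <- plantSorfs(cfg, g2)
  expect_equal(as.character(p1$genome), as.character(p2$genome))
  expect_equal(sorfIds(p1$sorfs), sorfIds(p2$sorfs))
  s1 <- simulateSorfStudy(cfg)
  s2 <- simulateSorfStudy(cfg)
  expect_equal(s1$variants, s2$variants)
  expect_equal(s1$oeuf, s2$oeuf)
})

test_that("reference composition follows the configured GC", {
  cfg <- simulationConfig(seed = 5, genomeLength = 1e5, gc = 0.5,
                          cpgDepletion = 1)  # no depletion
  g <- generateReference(cfg)
  counts <- Biostrings::alphabetFrequency(g[[1]])[c("A", "C", "G", "T")]
  gcObs <- sum(counts[c("C", "G")]) / sum(counts)
  expect_lt(abs(gcObs - 0.5), 0.02)
  # depletion removes most CpG dinucleotides
  cfgDep <- simulationConfig(seed = 5, genomeLength = 1e5, gc = 0.5,
                             cpgDepletion = 0.2)
  gDep <- generateReference(cfgDep)
  nCpG <- function(x) length(Biostrings::matchPattern("CG", x[[1]]))
  expect_lt(nCpG(gDep), 0.35 * nCpG(g))
  expect_error(simulationConfig(genomeLength = 0), "genomeLength")
})

test_that("planted sORFs have the requested classes and clean reading frames", {
  cfg <- tinyConfig(seed = 31)
  pl <- plantSorfs(cfg, generateReference(cfg))
  expect_equal(length(pl$sorfs), sum(cfg$nPerClass))
  tab <- table(sorfClass(pl$sorfs))
  expect_equal(as.integer(tab[names(cfg$nPerClass)]),
               as.integer(cfg$nPerClass))
  cdsList <- extractCodingSequence(pl$genome, pl$sorfs)
  for (cds in cdsList) {
    s <- codingBases(cds)
    expect_equal(nchar(s) %% 3, 0)
    expect_equal(substr(s, 1, 3), "ATG")
    aa <- suppressWarnings(as.character(
      Biostrings::translate(Biostrings::DNAString(s))))
    # a single stop, at the end
    expect_equal(substr(aa, nchar(aa), nchar(aa)), "*")
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1)))
  }
  # overlap classes are embedded in their planted gene interval
  ov <- sorfClass(pl$sorfs) %in% c("intORF", "uoORF", "doORF")
  sp <- sorfSpans(pl$sorfs)
  genes <- pl$genes[match(sorfIds(pl$sorfs), pl$genes$sorf_id)]
  expect_true(all(GenomicRanges::start(sp[ov]) <=
                    GenomicRanges::end(genes[ov]) &
                  GenomicRanges::end(sp[ov]) >=
                    GenomicRanges::start(genes[ov])))
})

test_that("a zero cohort scale produces zero variants", {
  cfg <- tinyConfig(seed = 13, cohortScale = 0)
  ref <- generateReference(cfg)
  pl <- plantSorfs(cfg, ref)
  cds <- extractCodingSequence(pl$genome, pl$sorfs)
  sim <- simulateVariants(cfg, cds, toyRateTable(), NULL)
  expect_equal(nrow(sim$variants), 0L)
  expect_gt(nrow(sim$coverage), 0L)
})

test_that("track generation matches the configured shape", {
  cfg <- tinyConfig(seed = 19, nMethylomes = 5L, scoreWindow = 500L,
                    scoreSlide = 100L)
  tr <- generateTracks(cfg, generateReference(cfg))
  expect_length(tr$methylation, 5L)
  expect_true(all(vapply(tr$methylation, function(t)
    all(t$fraction >= 0 & t$fraction <= 1), logical(1))))
  # window starts advance by the slide
  st <- GenomicRanges::start(tr$score)
  expect_true(all(diff(st) == 100L))
  expect_true(all(GenomicRanges::width(tr$score) == 500L))
  cfgC <- tinyConfig(seed = 19, constantScore = 2.5)
  trC <- generateTracks(cfgC, generateReference(cfgC))
  expect_true(all(trC$score$score == 2.5))
})

test_that("a too-small genome is rejected with advice", {
  cfg <- simulationConfig(seed = 1, genomeLength = 2e3)
  expect_error(plantSorfs(cfg, generateReference(cfg)), "genomeLength")
})

test_that("a tiny end-to-end study produces a coherent constraint table", {
  st <- simulateSorfStudy(tinyConfig(seed = 47))
  oe <- st$oeuf
  expect_equal(nrow(oe), 3L * length(st$sorfs))
  expect_true(all(oe$observed >= 0))
  expect_true(all(oe[!is.na(upper), upper >= lower]))
  expect_true(all(oe[!is.na(upper), upper <= 2]))
  expect_true(all(oe$powered == (oe$expected >= 10)))
  expect_gt(st$calibrationK, 0)
  # written inputs round-trip through the io layer
  dir <- tempfile()
  writeSimulatedInputs(st, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  back <- readBed12(file.path(dir, "sorfs.bed"))
  expect_equal(sort(sorfIds(back)),
               sort(paste0(sorfIds(st$sorfs), "|",
                           sorfClass(st$sorfs))))
  expect_equal(unname(sorfClass(back)[paste0(sorfIds(st$sorfs), "|",
                                             sorfClass(st$sorfs))]),
               unname(sorfClass(st$sorfs)))
  v <- readVariantSites(file.path(dir, "variants.tsv"))
  expect_equal(nrow(v), nrow(st$variants))
})
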