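test_that("methylation fractions bin into the 16 stated intervals", {
  expect_equal(methylationBin(0), 0L)
  expect_equal(methylationBin(1), 15L)   # last bin closed
  expect_equal(methylationBin(0.5), 8L)  # [0.5, 0.5625)
  expect_equal(methylationBin(0.4375), 7L)
  expect_equal(methylationBin(0.0624), 0L)
  expect_equal(methylationBin(0.0625), 1L)
  expect_error(methylationBin(1.2), "\\[0, 1\\]")
})

test_that("methylation maps average across epigenomes before binning", {
  t1 <- data.table(chrom = "chr1", pos = c(5L, 9L), fraction = c(0, 0.4))
  t2 <- data.table(chrom = "chr1", pos = c(5L, 9L), fraction = c(0, 0.6))
  m <- buildMethylationMap(list(t1, t2))
  p <- m@positions
  expect_equal(p[pos == 5, bin], 0L)
  expect_equal(p[pos == 9, fraction], 0.5)
  expect_equal(p[pos == 9, bin], 8L)
  expect_error(buildMethylationMap(list(data.table(chrom = "c", pos = 1L,
                                                   fraction = 1.5))),
               "\\[0, 1\\]")
})

test_that("enumeration yields 9 possible variants per codon", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  poss <- enumeratePossible(classifyAll(cds), toyRateTable())
  expect_equal(nrow(poss), 27L)  # 3 codons x 9
  expect_equal(nrow(poss[codon_index == 2L]), 9L)
  expect_true(all(poss$mu > 0))
  # per-codon conservation before exclusions
  expect_equal(as.integer(table(poss$codon_index)), rep(9L, 3L))
})

test_that("rate lookups canonicalise to the reverse-complement strand", {
  rt <- toyRateTable()
  # keep only contexts whose middle base is a pyrimidine: purine-centred
  # queries must resolve via reverse complement
  half <- rt@rates[substr(context, 2, 2) %in% c("C", "T")]
  rtHalf <- new("MutationRateTable", rates = half)
  expect_equal(rateLookup(rtHalf, "ACG", "T", 3),
               rateLookup(rt, "ACG", "T", 3))
  expect_equal(rateLookup(rtHalf, "CGT", "A", 3),  # revcomp of ACG, alt A->T
               rateLookup(rt, "ACG", "T", 3))
  expect_error(rateLookup(rtHalf, "NNA", "G", 0), "not found")
})

test_that("CpG-restricted methylation bins only apply at CpG contexts", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  cm <- classifyAll(cds)
  # methylated everywhere; fig8 sORF has no CpG context, so bins forced to 0
  mm <- buildMethylationMap(data.table(chrom = "chr1", pos = 1:11,
                                       fraction = 1))
  possCpG <- enumeratePossible(cm, toyRateTable(), mm,
                               cpgOnlyMethylation = TRUE)
  expect_true(all(possCpG$meth_bin == 0L))
  possAll <- enumeratePossible(cm, toyRateTable(), mm,
                               cpgOnlyMethylation = FALSE)
  expect_true(all(possAll$meth_bin == 15L))
})

test_that("expected counts rise with methylation under a CpG-sensitive table", {
  # sORF with CpG contexts: ATG CGA CGA TAA
  g <- makeGenome(chr1 = paste0("T", "ATGCGACGATAA", "T"))
  sorf <- makeSorf("chr1", list(c(2, 13)), "+", "cpg")
  cm <- classifyAll(extractCodingSequence(g, sorf, "cpg"))
  mkMap <- function(f) buildMethylationMap(
    data.table(chrom = "chr1", pos = 1:14, fraction = f))
  eLow <- expectedCounts(enumeratePossible(cm, toyRateTable(), mkMap(0)),
                         calibrationK = 1, quiet = TRUE)
  eHigh <- expectedCounts(enumeratePossible(cm, toyRateTable(), mkMap(1)),
                          calibrationK = 1, quiet = TRUE)
  expect_true(sum(eHigh$expected) > sum(eLow$expected))
  # and per class never decreases
  expect_true(all(eHigh$expected >= eLow$expected - 1e-15))
})

test_that("possible variants are excluded for high AF, low quality and low coverage", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  poss <- enumeratePossible(classifyAll(cds), toyRateTable())
  variants <- data.table(chrom = "chr1", pos = c(4L, 5L),
                         alt = c("A", "T"), af = c(0.002, 0.0001),
                         low_quality = c(FALSE, TRUE))
  coverage <- data.table(chrom = "chr1", pos = 2:10,
                         depth = c(30, 0.5, rep(30, 7)),
                         low_quality = FALSE)
  f <- filterPossible(poss, variants, coverage)
  expect_equal(f[gpos == 4 & galt == "A", reason], "high_af")
  expect_true(all(f[gpos == 5, reason] == "low_quality_site"))  # whole site
  expect_true(all(f[gpos == 3, reason] == "low_coverage"))
  expect_false(any(f[gpos == 6, excluded]))
  # retained set excludes exactly the flagged rows
  expect_equal(sum(f$excluded), 3L + 3L + 1L)
})

test_that("expected counts are linear in rates and additive across classes", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  cm <- classifyAll(cds)
  p1 <- enumeratePossible(cm, flatRateTable(1e-8))
  p2 <- enumeratePossible(cm, flatRateTable(2e-8))
  e1 <- expectedCounts(p1, calibrationK = 1, quiet = TRUE)
  e2 <- expectedCounts(p2, calibrationK = 1, quiet = TRUE)
  expect_equal(e2$expected, 2 * e1$expected)
  ek <- expectedCounts(p1, calibrationK = 3)
  expect_equal(ek$expected, 3 * e1$expected)
  # rate decomposition: class rate sums add to the SNV total
  expect_equal(sum(e1$rate_sum), sum(p1$mu))
  expect_error(expectedCounts(p1, calibrationK = 0), "positive")
})

test_that("calibration recovers exact and noisy proportionality", {
  expect_equal(fitCalibration(c(10, 20), c(5, 10)), 2)
  expect_equal(fitCalibration(8, 4, allowSingle = TRUE), 2)
  expect_error(fitCalibration(8, 4), "at least two")
  expect_error(fitCalibration(c(1, 2), c(0, 0)), "zero")
  set.seed(99)
  rs <- runif(300, 2, 40)
  obs <- rpois(300, 3 * rs)
  expect_lt(abs(fitCalibration(obs, rs) - 3) / 3, 0.05)
})

test_that("proportion calibration reproduces per-rate observation fractions", {
  set.seed(5)
  n <- 6000
  mus <- sample(c(1e-9, 3e-9, 3e-8), n, replace = TRUE)
  poss <- data.table(
    sorf_id = sample(sprintf("s%02d", 1:20), n, replace = TRUE),
    chrom = "chr1", gpos = seq_len(n), gref = "A", galt = "G",
    consequence = sample(c("synonymous", "missense"), n, replace = TRUE),
    mu = mus, excluded = FALSE)
  pTrue <- 1 - exp(-2e7 * poss$mu)
  seen <- runif(n) < pTrue
  obs <- poss[seen, .(chrom, pos = gpos, ref = gref, alt = galt)]
  cal <- fitProportionCalibration(poss, obs)
  expect_equal(nrow(cal$curve), 3L)
  # each group's fitted fraction is near its true probability
  cmp <- merge(cal$curve, data.table(mu_group = signif(unique(mus), 3),
                                     p = 1 - exp(-2e7 * unique(mus))),
               by = "mu_group")
  expect_true(all(abs(cmp$p_hat - cmp$p) < 0.05))
  ec <- expectedCountsProportion(poss, cal)
  agg <- merge(ec[, .(e = sum(expected)), by = consequence],
               poss[seen, .(o = .N), by = consequence], by = "consequence")
  expect_true(all(abs(agg$o / agg$e - 1) < 0.1))
})
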