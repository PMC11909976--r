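test_that("the toy five-record table leaves exactly one unique variant", {
  v <- data.table(
    chrom = "chr1",
    pos = c(10L, 11L, 12L, 13L, 10L),
    ref = c("A", "C", "G", "T", "A"),
    alt = c("G", "T", "A", "C", "G"),
    af = c(5e-4, 5e-4, 2e-3, 5e-4, 5e-4),
    passed_filters = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    depth = c(5, 30, 30, 0.5, 5))
  kept <- filterObserved(v)
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$pos, 10L)
})

test_that("filter boundaries: af == 0.001 dropped, depth == 1 kept", {
  v <- data.table(chrom = "chr1", pos = 1:2, ref = "A", alt = "G",
                  af = c(0.001, 5e-4), passed_filters = TRUE,
                  depth = c(30, 1))
  kept <- filterObserved(v)
  expect_equal(kept$pos, 2L)
})

test_that("observed filtering is idempotent", {
  set.seed(3)
  v <- data.table(chrom = "chr1", pos = sample(1:50, 80, replace = TRUE),
                  ref = sample(c("A", "C"), 80, TRUE),
                  alt = sample(c("G", "T"), 80, TRUE),
                  af = 10^runif(80, -5, -2),
                  passed_filters = runif(80) < 0.8,
                  depth = runif(80, 0, 40))
  once <- filterObserved(v)
  twice <- filterObserved(once)
  expect_equal(twice, once)
})

test_that("per-class counts are unique-variant counts restricted to the map", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  cm <- classifyAll(cds)
  # two synonymous (CTG->CTA at pos 7, TAA->TAG at pos 10) and one missense
  # (CTG->CAG at pos 6); a duplicate; one outside the blocks; one with a
  # mismatching ref allele at a coding position
  v <- data.table(
    chrom = "chr1",
    pos = c(7L, 10L, 6L, 7L, 200L, 5L),
    ref = c("G", "A", "T", "G", "A", "T"),
    alt = c("A", "G", "A", "A", "G", "A"),
    af = 1e-4, passed_filters = TRUE, depth = 30)
  counts <- countObserved(filterObserved(v), cm)
  expect_equal(counts[consequence == "synonymous", observed], 2L)
  expect_equal(counts[consequence == "missense", observed], 1L)
  expect_equal(counts[consequence == "SNV", observed], 3L)
  expect_equal(attr(counts, "n_ignored"), 1L)
})

test_that("a variant inside two overlapping elements counts once in each", {
  g <- makeGenome(chr1 = "AATGCTGTAAG")
  two <- SorfSet(GenomicRanges::GRangesList(
    a = GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 10), "+"),
    b = GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 10), "+")),
    c("uORF", "intORF"))
  cm <- classifyAll(extractCodingSequence(g, two))
  v <- data.table(chrom = "chr1", pos = 7L, ref = "G", alt = "A",
                  af = 1e-4, passed_filters = TRUE, depth = 30)
  counts <- countObserved(filterObserved(v), cm)
  expect_equal(counts[consequence == "SNV", observed], c(1L, 1L))
})

test_that("counting is monotone in added passing variants", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  cm <- classifyAll(cds)
  base <- data.table(chrom = "chr1", pos = 7L, ref = "G", alt = "A",
                     af = 1e-4, passed_filters = TRUE, depth = 30)
  more <- rbind(base, data.table(chrom = "chr1", pos = 6L, ref = "T",
                                 alt = "A", af = 1e-4,
                                 passed_filters = TRUE, depth = 30))
  c1 <- countObserved(filterObserved(base), cm)
  c2 <- countObserved(filterObserved(more), cm)
  m <- merge(c1, c2, by = c("sorf_id", "consequence"))
  expect_true(all(m$observed.y >= m$observed.x))
})

test_that("the retained-site restriction drops variants at excluded sites", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  cm <- classifyAll(cds)
  v <- data.table(chrom = "chr1", pos = c(7L, 6L), ref = c("G", "T"),
                  alt = c("A", "A"), af = 1e-4, passed_filters = TRUE,
                  depth = 30)
  retained <- data.table(chrom = "chr1", gpos = 7L, galt = "A")
  counts <- countObserved(filterObserved(v), cm, retained = retained)
  expect_equal(counts[consequence == "SNV", observed], 1L)
})

test_that("loss-of-function counts are the start/stop class union", {
  counts <- data.table(
    consequence = c("start_loss", "stop_loss", "stop_gain", "missense"),
    observed = c(1L, 0L, 2L, 7L))
  expect_equal(loeufClassCounts(counts), 3)
  expect_equal(loeufClassCounts(counts[4]), 0)
  counts$observed <- 0L
  expect_equal(loeufClassCounts(counts), 0)
})
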