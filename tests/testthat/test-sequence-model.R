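test_that("plus-strand extraction gives spliced bases and flank contexts", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  expect_equal(codingBases(cds), "ATGCTGTAA")
  # context of the first A uses the genomic left neighbour
  expect_equal(cds@context[1], "AAT")
  expect_equal(cds@context[9], "AAG")
  expect_true(cds@startIsATG)
  expect_equal(codonCount(cds), 3L)
})

test_that("minus-strand extraction reverse-complements into translation order", {
  # plus strand of the block reads TTACAGCAT -> coding ATGCTGTAA
  g <- makeGenome(chr1 = "GTTACAGCATC")
  sorf <- makeSorf("chr1", list(c(2, 10)), "-", "neg")
  cds <- extractCodingSequence(g, sorf, "neg")
  expect_equal(codingBases(cds), "ATGCTGTAA")
  expect_equal(cds@genomicPos, 10:2)
  # context of the first coding base: genomic triplet at pos 9-11 is ATC;
  # oriented to the coding strand it reads GAT (middle = coding base A)
  expect_equal(cds@context[1], "GAT")
})

test_that("contexts at splice junctions use the genomic neighbour, not the next block", {
  # block1 ATGCT | intron GGG | block2 GTAA: the genomic right neighbour of
  # block1's last base (T) is G (intron); block2 starts with G too, so make
  # the intron distinct: use intron CCC
  g <- makeGenome(chr1 = paste0("A", "ATGCT", "CCC", "GTAA", "G"))
  sorf <- makeSorf("chr1", list(c(2, 6), c(10, 13)), "+", "j1")
  cds <- extractCodingSequence(g, sorf, "j1")
  expect_equal(codingBases(cds), "ATGCTGTAA")
  # last base of block 1 is T at genomic pos 6; its context is C T C
  expect_equal(cds@context[5], "CTC")
  # first base of block 2 (G at pos 10): left genomic neighbour is intronic C
  expect_equal(cds@context[6], "CGT")
})

test_that("extraction is strand-symmetric under reverse complement", {
  set.seed(42)
  for (rep in 1:5) {
    L <- 60L
    seq <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                 collapse = "")
    gPlus <- makeGenome(chr1 = seq)
    gMinus <- makeGenome(chr1 = as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq))))
    # a 9-base block away from the edges
    s <- sample(5:(L - 15), 1)
    e <- s + 8L
    sorfPlus <- makeSorf("chr1", list(c(s, e)), "+", "p")
    sorfMinus <- makeSorf("chr1", list(c(L + 1 - e, L + 1 - s)), "-", "p")
    cdsP <- extractCodingSequence(gPlus, sorfPlus, "p")
    cdsM <- extractCodingSequence(gMinus, sorfMinus, "p")
    expect_equal(cdsP@bases, cdsM@bases)
    expect_equal(cdsP@context, cdsM@context)
  }
})

test_that("context middle base equals the coding base by construction", {
  set.seed(1)
  seq <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
               collapse = "")
  g <- makeGenome(chr1 = seq)
  sorf <- makeSorf("chr1", list(c(10, 21), c(50, 58)), "-", "m")
  cds <- extractCodingSequence(g, sorf, "m")
  expect_equal(substr(cds@context, 2, 2), cds@bases)
})

test_that("blocks touching the reference edge are a range error", {
  g <- makeGenome(chr1 = "ATGCTGTAA")  # no flank on either side
  sorf <- makeSorf("chr1", list(c(1, 9)), "+", "edge")
  expect_error(extractCodingSequence(g, sorf, "edge"), "flanking")
  sorf2 <- makeSorf("chr2", list(c(2, 7)), "+", "nochrom")
  expect_error(extractCodingSequence(g, sorf2, "nochrom"), "absent")
})

test_that("codons() yields ordered codons with start/stop flags", {
  cds <- extractCodingSequence(fig8Genome(), fig8Sorf(), "fig8")
  cc <- codons(cds)
  expect_equal(cc$codon, c("ATG", "CTG", "TAA"))
  expect_equal(cc$is_start, c(TRUE, FALSE, FALSE))
  expect_equal(cc$is_stop, c(FALSE, FALSE, TRUE))
  # 6-base sequence -> 2 codons
  g <- makeGenome(chr1 = "TATGTAAT")
  cds2 <- extractCodingSequence(g, makeSorf("chr1", list(c(2, 7)), "+", "s2"),
                                "s2")
  expect_equal(nrow(codons(cds2)), 2L)
})

test_that("codons touching reference Ns are flagged excluded", {
  g <- makeGenome(chr1 = "AATGCNGTAATAAG")
  sorf <- makeSorf("chr1", list(c(2, 13)), "+", "nfix")
  cds <- extractCodingSequence(g, sorf, "nfix")
  cc <- codons(cds)
  expect_equal(cc$excluded, c(FALSE, TRUE, FALSE, FALSE))
  # the N also poisons the neighbouring base's context in codon 1? no:
  # codon 1 is ATG at pos 2..4, its contexts stay N-free
  expect_false(any(grepl("N", cc$ctx1[1])))
})
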