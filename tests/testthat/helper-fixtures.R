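# Shared fixture builders: tiny genomes and sORFs constructed in code.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(Biostrings)
  library(data.table)
})

makeGenome <- function(...) {
  DNAStringSet(c(...))
}

# blocks: list of c(start, end) in 1-based closed coordinates
makeSorf <- function(chrom, blocks, strand = "+", id = "s1",
                     class = "unknown") {
  gr <- GRanges(chrom,
                IRanges(vapply(blocks, `[`, numeric(1), 1),
                        vapply(blocks, `[`, numeric(1), 2)),
                strand)
  bl <- GRangesList(gr)
  names(bl) <- id
  SorfSet(bl, class)
}

# the worked single-exon example: ...A[ATGCTGTAA]G... on the plus strand
fig8Genome <- function() makeGenome(chr1 = "AATGCTGTAAG")
fig8Sorf <- function() makeSorf("chr1", list(c(2, 10)), "+", "fig8", "uORF")

# uniform rate table (every context/alt/bin the same rate) for tests that
# must not depend on rate structure
flatRateTable <- function(mu = 1e-8) {
  tr <- toyRateTable()
  r <- tr@rates
  r$mu <- mu
  new("MutationRateTable", rates = r)
}

tinyConfig <- function(seed = 7, ...) {
  simulationConfig(
    seed = seed, genomeLength = 6e4,
    nPerClass = c(uORF = 4L, dORF = 3L, intORF = 3L, uoORF = 2L,
                  doORF = 2L, `lncRNA-ORF` = 3L),
    ...)
}

# independent translate-and-compare oracle for consequence classification,
# written against Biostrings::translate rather than the package's rules
oracleClassify <- function(codon, pos, alt, isStart = FALSE, isStop = FALSE) {
  mut <- codon
  substr(mut, pos, pos) <- alt
  tr <- function(x) suppressWarnings(
    as.character(Biostrings::translate(Biostrings::DNAString(x),
                                       no.init.codon = TRUE)))
  aaR <- tr(codon); aaM <- tr(mut)
  if (isStart && aaM != aaR) return("start_loss")
  if (isStop && aaR == "*") return(if (aaM == "*") "synonymous" else "stop_loss")
  if (aaM == "*") return("stop_gain")
  if (aaM == aaR) "synonymous" else "missense"
}
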