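#' @import methods
#' @importFrom utils head globalVariables
#' @importFrom stats setNames median rnorm runif rbeta rgamma rpois
#' @importFrom GenomicRanges GRanges GRangesList start end width strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<- elementNROWS
#' @importFrom data.table data.table as.data.table := setkeyv rbindlist setorderv .N .SD
NULL

# data.table non-standard evaluation columns
utils::globalVariables(c(
  ".", "af", "alt", "base", "bin", "chrom", "class", "codon", "codon_index",
  "coding_alt", "coding_index", "coding_ref", "consequence", "context",
  "context_genomic", "decile", "depth", "element_id", "excluded", "expected",
  "fraction", "galt", "gpos", "gref", "group", "is_start", "is_stop",
  "low_quality", "meth_bin", "mu", "n_possible", "observed", "pair_id",
  "passed_filters", "pos", "pos_in_codon", "powered", "rate_sum", "ratio",
  "reason", "ref", "score", "sorf_class", "sorf_id", "strand", "upper",
  "lower", "value", "va", "vb", "x.af", "x.bin", "x.depth", "x.low_quality",
  "x.mu", "x.p_hat", "mu_group", "p_hat", "W", "U", "mRank1", "mRank2",
  "n1", "n2", "n_dropped_pairs",
  "ks_D", "p_ks", "p_ks_label", "p_mwu", "p_mwu_label", "p_wilcoxon",
  "p_wilcoxon_label", "p_kendall", "p_kendall_label", "tau", "vda",
  "constrained", ".I", "n", "filter"
))

#' sORF interval set
#'
#' A set of short open reading frames (sORFs), each a strand-aware list of
#' genomic blocks (exons) plus a class label. Blocks are stored as a
#' [GenomicRanges::GRangesList] in standard Bioconductor coordinates
#' (1-based, closed); conversion from/to BED12 happens only at the format
#' boundary.
#'
#' @slot blocks `GRangesList`, one element per sORF, names are sORF ids;
#'   within an element, blocks are sorted by start, non-overlapping, and on a
#'   single strand.
#' @slot sorfClass character vector parallel to `blocks`; one of `uORF`,
#'   `dORF`, `intORF`, `uoORF`, `doORF`, `lncRNA-ORF`, `unknown`.
#'
#' @seealso [readBed12()], [writeBed12()], [writeSorfGtf()]
#' @exportClass SorfSet
setClass("SorfSet",
  representation(blocks = "GRangesList", sorfClass = "character"))

.SORF_CLASSES <- c("uORF", "dORF", "intORF", "uoORF", "doORF", "lncRNA-ORF",
                   "unknown")

setValidity("SorfSet", function(object) {
  msgs <- character()
  if (length(object@blocks) != length(object@sorfClass))
    msgs <- c(msgs, "sorfClass must be parallel to blocks")
  if (is.null(names(object@blocks)) && length(object@blocks) > 0)
    msgs <- c(msgs, "blocks must be named by sORF id")
  if (!all(object@sorfClass %in% .SORF_CLASSES))
    msgs <- c(msgs, sprintf("unknown sORF class label(s): %s",
      paste(setdiff(object@sorfClass, .SORF_CLASSES), collapse = ", ")))
  w <- sum(GenomicRanges::width(object@blocks))
  if (any(w %% 3L != 0L))
    msgs <- c(msgs, "total block length must be divisible by 3")
  if (any(w < 6L))
    msgs <- c(msgs, "total block length must be >= 6 (start + stop codon)")
  for (i in seq_along(object@blocks)) {
    b <- object@blocks[[i]]
    if (length(unique(as.character(GenomicRanges::strand(b)))) != 1L ||
        any(as.character(GenomicRanges::strand(b)) == "*")) {
      msgs <- c(msgs, "each sORF must lie on a single explicit strand")
      break
    }
    st <- GenomicRanges::start(b)
    if (is.unsorted(st, strictly = TRUE) ||
        any(GenomicRanges::start(b)[-1] <= GenomicRanges::end(b)[-length(b)])) {
      msgs <- c(msgs, "blocks must be sorted by start and non-overlapping")
      break
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SorfSet
#'
#' @param blocks `GRangesList` of per-sORF blocks, named by sORF id.
#' @param sorfClass class label per sORF; recycled if length 1. Defaults to
#'   `"unknown"`.
#' @return A [SorfSet-class] object.
#' @examples
#' bl <- GenomicRanges::GRangesList(
#'   s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 109), "+"))
#' SorfSet(bl, "uORF")
#' @export
SorfSet <- function(blocks, sorfClass = "unknown") {
  if (length(sorfClass) == 1L) sorfClass <- rep(sorfClass, length(blocks))
  new("SorfSet", blocks = blocks, sorfClass = unname(sorfClass))
}

#' Spliced, strand-oriented coding sequence with per-base genomic context
#'
#' Bases are stored in translation order (reverse-complemented for minus
#' strand); each base carries its genomic position and its genomic context
#' triplet (the base with its two immediate genomic neighbours, oriented to
#' the coding strand). Context triplets come from the genomic reference, not
#' across splice junctions; codons are read off the spliced sequence.
#'
#' @slot sorfId sORF identifier.
#' @slot chrom chromosome name.
#' @slot strand `"+"` or `"-"`.
#' @slot bases per-base coding-strand nucleotides, translation order.
#' @slot genomicPos per-base genomic position (1-based).
#' @slot context per-base coding-strand-oriented genomic context triplet.
#' @slot contextGenomic per-base plus-strand genomic context triplet.
#' @slot excluded per-base flag: TRUE when the base's codon touches an
#'   ambiguous (N) reference base and is excluded from enumeration.
#' @slot startIsATG whether the first codon is the canonical ATG.
#' @exportClass CodingSequence
setClass("CodingSequence",
  representation(sorfId = "character", chrom = "character",
                 strand = "character", bases = "character",
                 genomicPos = "integer", context = "character",
                 contextGenomic = "character", excluded = "logical",
                 startIsATG = "logical"))

setValidity("CodingSequence", function(object) {
  n <- length(object@bases)
  msgs <- character()
  if (n %% 3L != 0L) msgs <- c(msgs, "coding length must be divisible by 3")
  if (length(object@genomicPos) != n || length(object@context) != n ||
      length(object@excluded) != n || length(object@contextGenomic) != n)
    msgs <- c(msgs, "per-base slots must have equal length")
  mid <- substr(object@context, 2L, 2L)
  ok <- mid == object@bases | object@bases == "N" | mid == "N"
  if (!all(ok))
    msgs <- c(msgs, "context middle base must equal the coding base")
  if (length(msgs)) msgs else TRUE
})

#' Context- and methylation-dependent mutation-rate table
#'
#' Maps (context triplet, alternate base, methylation bin 0..15) to a
#' per-site, per-generation mutation rate. Lookups are strand-symmetric: a
#' context absent from the table is retried as its reverse complement with
#' the complementary alternate base.
#'
#' @slot rates a `data.table` with columns `context`, `ref`, `alt`, `bin`,
#'   `mu`.
#' @seealso [toyRateTable()], [readRateTable()], [rateLookup()]
#' @exportClass MutationRateTable
setClass("MutationRateTable", representation(rates = "data.table"))

setValidity("MutationRateTable", function(object) {
  r <- object@rates
  need <- c("context", "ref", "alt", "bin", "mu")
  if (!all(need %in% names(r)))
    return(sprintf("rate table must have columns %s", paste(need, collapse = ", ")))
  if (any(r$mu < 0)) return("all rates must be >= 0")
  if (any(substr(r$context, 2L, 2L) != r$ref))
    return("context middle base must equal ref")
  TRUE
})

#' Per-position methylation map
#'
#' Mean methylation fraction per genomic position (averaged across
#' epigenomes) together with its bin index under the 16 equal-width bins on
#' \[0, 1\] (left-closed, right-open; last bin closed).
#'
#' @slot positions `data.table` with columns `chrom`, `pos`, `fraction`,
#'   `bin`.
#' @seealso [buildMethylationMap()], [methylationBin()]
#' @exportClass MethylationMap
setClass("MethylationMap", representation(positions = "data.table"))

setValidity("MethylationMap", function(object) {
  p <- object@positions
  need <- c("chrom", "pos", "fraction", "bin")
  if (!all(need %in% names(p)))
    return(sprintf("methylation map must have columns %s",
                   paste(need, collapse = ", ")))
  if (any(p$fraction < 0 | p$fraction > 1))
    return("methylation fractions must lie in [0, 1]")
  if (any(p$bin != methylationBin(p$fraction)))
    return("bin must be consistent with fraction")
  TRUE
})
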