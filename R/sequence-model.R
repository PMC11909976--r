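#' @include AllClasses.R utils.R
NULL

# Vectorised per-base coding table for a whole SorfSet.
# One row per coding base, in translation order within each sORF:
#   sorf_id, chrom, strand, gpos, base (coding strand), context
#   (coding-strand-oriented genomic triplet), context_genomic (plus strand),
#   coding_index, codon_index, pos_in_codon, excluded.
# Context triplets are taken from the genomic reference around each base
# (never across splice junctions); codons are read off the spliced sequence.
.codingBaseTable <- function(genome, sorfs) {
  bl <- sorfBlocks(sorfs)
  flat <- unlist(bl, use.names = FALSE)
  ids <- rep(names(bl), elementNROWS(bl))
  dt <- data.table(
    sorf_id = rep(ids, GenomicRanges::width(flat)),
    chrom = rep(as.character(GenomicRanges::seqnames(flat)),
                GenomicRanges::width(flat)),
    strand = rep(as.character(GenomicRanges::strand(flat)),
                 GenomicRanges::width(flat)),
    gpos = unlist(lapply(seq_along(flat), function(i)
      seq.int(GenomicRanges::start(flat)[i], GenomicRanges::end(flat)[i])))
  )
  # genomic context triplets, fetched per chromosome in one pass
  chromLen <- stats::setNames(Biostrings::width(genome), names(genome))
  missing <- setdiff(unique(dt$chrom), names(genome))
  if (length(missing))
    stop(sprintf("chromosome(s) absent from reference: %s",
                 paste(missing, collapse = ", ")))
  if (any(dt$gpos - 1L < 1L | dt$gpos + 1L > chromLen[dt$chrom]))
    stop("sORF blocks (plus one flanking base) must lie within the reference")
  dt[, context_genomic := {
    v <- Biostrings::Views(genome[[chrom[1]]], start = gpos - 1L,
                           end = gpos + 1L)
    as.character(v)
  }, by = chrom]
  # translation order: ascending genomic position on +, descending on -
  dt[, coding_index := if (strand[1] == "+") seq_len(.N) else rev(seq_len(.N)),
     by = sorf_id]
  setorderv(dt, c("sorf_id", "coding_index"))
  minus <- dt$strand == "-"
  dt[, context := context_genomic]
  if (any(minus)) dt$context[minus] <- .revcomp(dt$context_genomic[minus])
  dt[, base := substr(context, 2L, 2L)]
  dt[, codon_index := (coding_index - 1L) %/% 3L + 1L]
  dt[, pos_in_codon := (coding_index - 1L) %% 3L + 1L]
  # a reference N inside a coding triplet excludes the whole codon; an N in
  # a flanking context base excludes just that base (its rate is undefined)
  dt[, excluded := any(base == "N") | grepl("N", context, fixed = TRUE),
     by = .(sorf_id, codon_index)]
  dt[]
}

#' Extract spliced coding sequence(s) with genomic context triplets
#'
#' Bases are concatenated across blocks and reverse-complemented for
#' minus-strand sORFs; each base's context triplet is read from the genomic
#' reference around its genomic position (so at block boundaries the context
#' uses the intronic neighbour, not the next block's base) and then oriented
#' to the coding strand.
#'
#' @param genome named `DNAStringSet` (chromosomes).
#' @param sorfs a [SorfSet-class].
#' @param id optional sORF id (or index); when given, a single
#'   [CodingSequence-class] is returned, otherwise a named list of them.
#' @return [CodingSequence-class] or a named list of them.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AATGCTGTAAG"))
#' bl <- GenomicRanges::GRangesList(
#'   s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 10), "+"))
#' extractCodingSequence(g, SorfSet(bl, "uORF"), "s1")
#' @export
extractCodingSequence <- function(genome, sorfs, id = NULL) {
  if (!is.null(id)) sorfs <- sorfs[id]
  tab <- .codingBaseTable(genome, sorfs)
  build <- function(d) {
    new("CodingSequence", sorfId = d$sorf_id[1], chrom = d$chrom[1],
        strand = d$strand[1], bases = d$base,
        genomicPos = as.integer(d$gpos), context = d$context,
        contextGenomic = d$context_genomic, excluded = d$excluded,
        startIsATG = paste(d$base[1:3], collapse = "") == "ATG")
  }
  out <- lapply(split(tab, tab$sorf_id, drop = TRUE), build)
  out <- out[intersect(sorfIds(sorfs), names(out))]
  if (!is.null(id) && length(out) == 1L) out[[1]] else out
}

#' Iterate over the codons of a coding sequence
#'
#' Yields the spliced codons in translation order, flagging the first
#' (start) and last (stop) codon and propagating the N-exclusion flag.
#'
#' @param cds a [CodingSequence-class].
#' @return `data.table` with columns `codon_index`, `codon`, `is_start`,
#'   `is_stop`, `excluded`, and the three per-base context triplets
#'   `ctx1`..`ctx3` (coding-strand-oriented).
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "AATGCTGTAAG"))
#' bl <- GenomicRanges::GRangesList(
#'   s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(2, 10), "+"))
#' codons(extractCodingSequence(g, SorfSet(bl, "uORF"), "s1"))
#' @export
codons <- function(cds) {
  stopifnot(is(cds, "CodingSequence"))
  n <- length(cds@bases) %/% 3L
  i1 <- (seq_len(n) - 1L) * 3L + 1L
  data.table(
    codon_index = seq_len(n),
    codon = paste0(cds@bases[i1], cds@bases[i1 + 1L], cds@bases[i1 + 2L]),
    is_start = seq_len(n) == 1L,
    is_stop = seq_len(n) == n,
    excluded = cds@excluded[i1] | cds@excluded[i1 + 1L] | cds@excluded[i1 + 2L],
    ctx1 = cds@context[i1], ctx2 = cds@context[i1 + 1L],
    ctx3 = cds@context[i1 + 2L])
}
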