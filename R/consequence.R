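#' @include AllClasses.R utils.R sequence-model.R
NULL

.GC <- Biostrings::GENETIC_CODE  # standard nuclear code, codon -> AA ("*" = stop)

#' Classify the consequence of a single-base codon change
#'
#' Frame-aware classification by the standard genetic code, with priority
#' `start_loss > stop_loss > stop_gain > (synonymous | missense)`:
#' any amino-acid-changing substitution in the start codon is `start_loss`
#' (a synonymous change in a non-ATG start stays synonymous); a change in
#' the stop codon producing a non-stop codon is `stop_loss`, producing
#' another stop codon is `synonymous`; elsewhere, a change creating a stop
#' codon is `stop_gain`, otherwise `synonymous`/`missense` by amino-acid
#' identity. All arguments are vectorised.
#'
#' @param codon reference codon(s), 3 uppercase bases, no N.
#' @param posInCodon position of the substituted base, 1..3.
#' @param alt alternate base (coding strand), different from the reference
#'   base at that position.
#' @param isStart,isStop whether the codon is the first/last codon of the
#'   reading frame.
#' @return character vector over
#'   `c("synonymous","missense","stop_gain","stop_loss","start_loss")`.
#' @examples
#' classifyChange("CTG", 3, "A")              # synonymous (Leu -> Leu)
#' classifyChange("ATG", 1, "C", isStart = TRUE)  # start_loss
#' classifyChange("TGG", 3, "A")              # stop_gain (TGG -> TGA)
#' classifyChange("TAA", 3, "G", isStop = TRUE)   # stop -> stop: synonymous
#' @export
classifyChange <- function(codon, posInCodon, alt, isStart = FALSE,
                           isStop = FALSE) {
  n <- max(length(codon), length(posInCodon), length(alt))
  codon <- rep_len(toupper(codon), n)
  posInCodon <- rep_len(as.integer(posInCodon), n)
  alt <- rep_len(toupper(alt), n)
  isStart <- rep_len(isStart, n)
  isStop <- rep_len(isStop, n)
  .stopifnotBases(alt, "alt base")
  .stopifnotBases(unlist(strsplit(codon, "")), "codon base")
  stopifnot(all(posInCodon %in% 1:3))
  ref <- substr(codon, posInCodon, posInCodon)
  if (any(ref == alt))
    stop("alt must differ from the codon base at posInCodon")
  mut <- codon
  substr(mut, posInCodon, posInCodon) <- alt
  aaRef <- unname(.GC[codon])
  aaAlt <- unname(.GC[mut])
  out <- ifelse(aaAlt == "*", "stop_gain",
         ifelse(aaAlt == aaRef, "synonymous", "missense"))
  stopCase <- isStop & aaRef == "*"
  out[stopCase] <- ifelse(aaAlt[stopCase] == "*", "synonymous", "stop_loss")
  startCase <- isStart & aaAlt != aaRef
  out[startCase] <- "start_loss"
  out
}

#' Classify all possible SNVs of a coding sequence
#'
#' One entry for each of the 3 possible alternate alleles at each coding
#' base whose codon is not N-excluded. Alleles are reported on both the
#' coding strand and the genomic plus strand (complemented for minus-strand
#' sORFs).
#'
#' @param cds a [CodingSequence-class], a list of them (results are
#'   concatenated), or a per-base coding table as produced internally for a
#'   whole [SorfSet-class].
#' @return `data.table` with columns `sorf_id`, `chrom`, `strand`, `gpos`,
#'   `gref`, `galt` (genomic strand), `coding_ref`, `coding_alt`,
#'   `codon_index`, `pos_in_codon`, `context` (coding-strand),
#'   `context_genomic`, `consequence`.
#' @export
classifyAll <- function(cds) {
  if (is(cds, "CodingSequence")) {
    tab <- data.table(
      sorf_id = cds@sorfId, chrom = cds@chrom, strand = cds@strand,
      gpos = cds@genomicPos, base = cds@bases, context = cds@context,
      context_genomic = cds@contextGenomic,
      coding_index = seq_along(cds@bases),
      codon_index = (seq_along(cds@bases) - 1L) %/% 3L + 1L,
      pos_in_codon = (seq_along(cds@bases) - 1L) %% 3L + 1L,
      excluded = cds@excluded)
    return(.classifyTable(tab))
  }
  if (is.data.frame(cds)) return(.classifyTable(as.data.table(cds)))
  if (is.list(cds)) return(rbindlist(lapply(cds, classifyAll)))
  stop("cds must be a CodingSequence, a list of them, or a coding table")
}

# vectorised classification of all 3 alts per non-excluded base of a pooled
# per-base coding table (columns as produced by .codingBaseTable)
.classifyTable <- function(tab) {
  tab <- data.table::copy(tab)
  setorderv(tab, c("sorf_id", "coding_index"))
  tab[, codon := {
    i1 <- (codon_index - 1L) * 3L + 1L
    paste0(base[i1], base[i1 + 1L], base[i1 + 2L])
  }, by = sorf_id]
  tab[, `:=`(is_start = codon_index == 1L,
             is_stop = codon_index == max(codon_index)), by = sorf_id]
  keep <- tab[excluded == FALSE]
  if (!nrow(keep)) {
    return(data.table(sorf_id = character(), chrom = character(),
      strand = character(), gpos = integer(), gref = character(),
      galt = character(), coding_ref = character(), coding_alt = character(),
      codon_index = integer(), pos_in_codon = integer(), context = character(),
      context_genomic = character(), consequence = character()))
  }
  idx <- rep(seq_len(nrow(keep)), each = 3L)
  dt <- keep[idx]
  # the 3 alternates of base b are .BASES[-match(b, .BASES)]
  altPool <- matrix(c("C","G","T", "A","G","T", "A","C","T", "A","C","G"),
                    nrow = 3, dimnames = list(NULL, .BASES))
  dt[, coding_alt := altPool[cbind(rep(1:3, times = nrow(keep)),
                                   match(base, .BASES))]]
  dt[, consequence := classifyChange(codon, pos_in_codon, coding_alt,
                                     isStart = is_start, isStop = is_stop)]
  dt[, coding_ref := base]
  dt[, gref := ifelse(strand == "-", .complement(coding_ref), coding_ref)]
  dt[, galt := ifelse(strand == "-", .complement(coding_alt), coding_alt)]
  dt[, .(sorf_id, chrom, strand, gpos, gref, galt, coding_ref, coding_alt,
         codon_index, pos_in_codon, context, context_genomic, consequence)]
}
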