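#' @include AllClasses.R utils.R
NULL

#' Read a mutation-rate table
#'
#' Tab-separated columns `context`, `ref`, `alt`, `methylation_level` (bin
#' index 0..15), `mu`.
#'
#' @param path TSV path.
#' @return A [MutationRateTable-class].
#' @export
readRateTable <- function(path) {
  r <- data.table::fread(path, sep = "\t", header = TRUE)
  names(r) <- sub("^methylation_level$", "bin", names(r))
  new("MutationRateTable",
      rates = r[, .(context, ref, alt, bin = as.integer(bin),
                    mu = as.numeric(mu))])
}

#' Write a mutation-rate table
#' @param rates a [MutationRateTable-class].
#' @param path TSV output path.
#' @return `path`, invisibly.
#' @export
writeRateTable <- function(rates, path) {
  out <- data.table::copy(rates@rates)
  data.table::setnames(out, "bin", "methylation_level")
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

#' Read an interval score track
#'
#' Accepts either a BED4-like table (`chrom`, `start`, `end`, `score`;
#' start 0-based half-open, as in BED) or a per-position table (`chrom`,
#' `pos`, `score`; 1-based). Column layout is detected from the header.
#'
#' @param path TSV path with header.
#' @return `GRanges` with a `score` metadata column, sorted by position.
#' @export
readScoreTrack <- function(path) {
  r <- data.table::fread(path, sep = "\t", header = TRUE)
  names(r) <- tolower(names(r))
  if (all(c("start", "end") %in% names(r))) {
    gr <- GenomicRanges::GRanges(r$chrom,
                                 IRanges::IRanges(r$start + 1L, r$end),
                                 score = as.numeric(r$score))
  } else if ("pos" %in% names(r)) {
    gr <- GenomicRanges::GRanges(r$chrom, IRanges::IRanges(r$pos, r$pos),
                                 score = as.numeric(r$score))
  } else stop("score track needs chrom/start/end/score or chrom/pos/score")
  if (any(!is.finite(gr$score))) stop("track scores must be finite")
  GenomicRanges::sort(gr)
}

#' Write an interval score track as BED4-like TSV
#' @param track `GRanges` with `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeScoreTrack <- function(track, path) {
  data.table::fwrite(data.table(
    chrom = as.character(GenomicRanges::seqnames(track)),
    start = GenomicRanges::start(track) - 1L,
    end = GenomicRanges::end(track),
    score = track$score), path, sep = "\t")
  invisible(path)
}

#' Read one per-epigenome methylation track
#'
#' Tab-separated `chrom`, `pos` (1-based), `fraction` in \[0, 1\].
#'
#' @param path TSV path.
#' @return `data.table` with those columns.
#' @export
readMethylationTrack <- function(path) {
  r <- data.table::fread(path, sep = "\t", header = TRUE)
  names(r) <- tolower(names(r))
  if (!all(c("chrom", "pos", "fraction") %in% names(r)))
    stop("methylation track needs columns chrom, pos, fraction")
  r[, .(chrom = as.character(chrom), pos = as.integer(pos),
        fraction = as.numeric(fraction))]
}
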