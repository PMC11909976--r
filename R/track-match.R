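#' @include AllClasses.R utils.R
NULL

#' Average an interval score track over a genomic element
#'
#' In `"within"` mode (default), the mean of the scores of all track
#' intervals fully contained in the element span is returned; when no
#' interval is contained, the fallback takes the unweighted mean of the two
#' closest intervals by distance (one on each side when equidistant). In
#' `"any"` mode, any-overlap replaces containment (useful for short
#' elements against wide sliding windows); with `requireUnique = TRUE` the
#' element must overlap exactly one interval, otherwise NA (the
#' non-overlapping track variant where elements must fall into exactly one
#' interval).
#'
#' @param element a length-1 `GRanges` (the element span).
#' @param track a `GRanges` score track (sorted; see [readScoreTrack()]).
#' @param mode `"within"` or `"any"`.
#' @param requireUnique in `"any"` mode, return NA unless exactly one
#'   interval overlaps.
#' @param fallbackNearest use the two-closest-intervals fallback when no
#'   interval qualifies (default TRUE in `"within"` mode, ignored when
#'   `requireUnique`).
#' @return mean score (NA with a warning when the chromosome is absent from
#'   the track, or when uniqueness fails).
#' @export
matchElement <- function(element, track, mode = c("within", "any"),
                         requireUnique = FALSE, fallbackNearest = TRUE) {
  mode <- match.arg(mode)
  stopifnot(is(element, "GRanges"), length(element) == 1L)
  chromTrack <- track[as.character(GenomicRanges::seqnames(track)) ==
                        as.character(GenomicRanges::seqnames(element))]
  if (length(chromTrack) == 0L) {
    warning("no track intervals on the element's chromosome; returning NA",
            call. = FALSE)
    return(NA_real_)
  }
  hits <- GenomicRanges::findOverlaps(
    chromTrack, element, type = if (mode == "within") "within" else "any",
    ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  if (mode == "any" && requireUnique) {
    if (length(q) != 1L) return(NA_real_)
    return(chromTrack$score[q])
  }
  if (length(q) > 0L) return(mean(chromTrack$score[q]))
  if (!fallbackNearest) return(NA_real_)
  # fallback: the two closest intervals by distance; on a distance tie take
  # one interval from each side of the element
  d <- GenomicRanges::distance(chromTrack, element, ignore.strand = TRUE)
  side <- ifelse(GenomicRanges::end(chromTrack) <
                   GenomicRanges::start(element), "L",
          ifelse(GenomicRanges::start(chromTrack) >
                   GenomicRanges::end(element), "R", "O"))
  ord <- order(d, GenomicRanges::start(chromTrack))
  if (length(ord) == 1L) return(chromTrack$score[ord])
  pick <- ord[1:2]
  if (side[pick[1]] == side[pick[2]]) {
    other <- ord[-(1:2)]
    alt <- other[side[other] != side[pick[1]]]
    if (length(alt) && d[alt[1]] == d[pick[2]]) pick[2] <- alt[1]
  }
  mean(chromTrack$score[pick])
}

#' Average a per-position score track over coding blocks
#'
#' Simple unweighted mean of the per-position scores across all block
#' positions; positions missing from the track are skipped and the covered
#' fraction is reported as an attribute.
#'
#' @param blocks `GRanges` of coding blocks (one element), or a
#'   `GRangesList` element.
#' @param track per-position `GRanges` score track (width-1 ranges), or a
#'   fine-interval track (every overlapped position takes the interval's
#'   score).
#' @return mean score with attribute `coverage` (fraction of block
#'   positions that had a score); NA when none did.
#' @export
matchBlocks <- function(blocks, track) {
  if (is(blocks, "GRangesList")) blocks <- unlist(blocks)
  totalPos <- sum(GenomicRanges::width(blocks))
  hits <- GenomicRanges::findOverlaps(track, blocks, ignore.strand = TRUE)
  q <- S4Vectors::queryHits(hits)
  s <- S4Vectors::subjectHits(hits)
  if (!length(q)) {
    out <- NA_real_
    attr(out, "coverage") <- 0
    return(out)
  }
  # per overlapping pair, the number of block positions the interval covers
  ov <- GenomicRanges::pintersect(track[q], blocks[s], ignore.strand = TRUE)
  w <- GenomicRanges::width(ov)
  out <- sum(track$score[q] * w) / sum(w)
  attr(out, "coverage") <- sum(w) / totalPos
  out
}

#' Constraint call from a per-kilobase constraint z-score
#'
#' TRUE iff the score reaches the cut-off marking the most constrained
#' percentile of the genome (boundary inclusive).
#'
#' @param score numeric score(s).
#' @param cutoff constraint cut-off (default 4).
#' @return logical vector.
#' @examples
#' gnocchiConstrained(c(4, 1.264, -1))
#' @export
gnocchiConstrained <- function(score, cutoff = 4) {
  score >= cutoff
}
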