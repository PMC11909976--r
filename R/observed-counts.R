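#' @include AllClasses.R utils.R
NULL

#' Filter observed variant sites by the constraint-workflow rules
#'
#' Keeps a variant iff its allele frequency is strictly below `afMax`, it
#' passed all filters, and its per-site depth is at least `depthMin`
#' (boundaries: `af == afMax` is dropped, `depth == depthMin` is kept).
#' Duplicate records of the same (chrom, pos, ref, alt) collapse to one, so
#' downstream counts are counts of unique variants. Idempotent.
#'
#' @param variants `data.table`/data.frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `af`, `passed_filters`, `depth` (see
#'   [readVariantSites()]).
#' @param afMax allele-frequency threshold (default 0.001).
#' @param depthMin minimum per-site depth (default 1).
#' @return filtered, de-duplicated `data.table`.
#' @export
filterObserved <- function(variants, afMax = 0.001, depthMin = 1) {
  v <- as.data.table(variants)
  v <- v[af < afMax & passed_filters == TRUE & depth >= depthMin]
  unique(v, by = c("chrom", "pos", "ref", "alt"))
}

#' Count observed variants per consequence class per element
#'
#' Joins filtered observed variants onto a consequence map (from
#' [classifyAll()]) and counts unique variants per element and class.
#' Variants at coding positions whose allele is not in the map (e.g. a
#' reference mismatch) are ignored and counted in the `n_ignored`
#' attribute. When `retained` is supplied (e.g. the non-excluded rows of
#' [filterPossible()]), counting is further restricted to those
#' (position, allele) pairs so the observed and expected sides see the same
#' site space.
#'
#' @param variants filtered observed variants ([filterObserved()]).
#' @param consequenceMap output of [classifyAll()] for one or more elements.
#' @param retained optional table with columns `chrom`, `gpos`, `galt`
#'   restricting the countable site space.
#' @return `data.table` with columns `sorf_id`, `consequence`, `observed`
#'   (all five classes zero-filled per element), plus an `SNV` total row per
#'   element.
#' @export
countObserved <- function(variants, consequenceMap, retained = NULL) {
  v <- unique(as.data.table(variants), by = c("chrom", "pos", "ref", "alt"))
  cmap <- as.data.table(consequenceMap)
  if (!is.null(retained)) {
    r <- as.data.table(retained)[, .(chrom, gpos, galt)]
    cmap <- cmap[r, on = c("chrom", "gpos", "galt"), nomatch = NULL]
  }
  hits <- cmap[v, on = c(chrom = "chrom", gpos = "pos", galt = "alt"),
               nomatch = NULL]
  if ("ref" %in% names(hits)) hits <- hits[ref == gref]
  # a variant at a coding position whose allele/ref is absent from the map
  inCoding <- v[unique(cmap[, .(chrom, gpos)]),
                on = c(chrom = "chrom", pos = "gpos"), nomatch = NULL]
  nIgnored <- nrow(unique(inCoding, by = c("chrom", "pos", "alt"))) -
    nrow(unique(hits, by = c("chrom", "gpos", "galt")))
  counts <- hits[, .(observed = .N), by = .(sorf_id, consequence)]
  full <- data.table(expand.grid(sorf_id = unique(cmap$sorf_id),
                                 consequence = .CONSEQUENCES,
                                 stringsAsFactors = FALSE))
  out <- counts[full, on = c("sorf_id", "consequence")]
  out[is.na(observed), observed := 0L]
  snv <- out[, .(consequence = "SNV", observed = sum(observed)),
             by = sorf_id]
  out <- rbind(out, snv)
  setorderv(out, c("sorf_id", "consequence"))
  attr(out, "n_ignored") <- max(nIgnored, 0L)
  out[]
}

#' Loss-of-function count from per-class counts
#'
#' The constraint workflow's loss-of-function class for SNVs is the union of
#' start-loss, stop-loss and stop-gain variants.
#'
#' @param counts output of [countObserved()] (or any table with
#'   `consequence` and a count column) for one element.
#' @param column count column name (default `"observed"`).
#' @return total LoF count (numeric).
#' @examples
#' loeufClassCounts(data.frame(
#'   consequence = c("start_loss", "stop_loss", "stop_gain", "missense"),
#'   observed = c(1, 0, 2, 7)))
#' @export
loeufClassCounts <- function(counts, column = "observed") {
  d <- as.data.table(counts)
  sum(d[[column]][d$consequence %in% .LOF_CLASSES])
}
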