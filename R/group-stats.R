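#' @include AllClasses.R utils.R
NULL

#' Vargha--Delaney A effect size
#'
#' The probability that a value drawn from group `x` exceeds a value drawn
#' from group `y`, counting ties as one half:
#' `A = (#\{x_i > y_j\} + 0.5 #\{x_i = y_j\}) / (|x| |y|)`. Computed via
#' pooled mid-ranks, so it is exact including ties.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return A in \[0, 1\].
#' @examples
#' varghaDelaneyA(c(4, 5, 6), c(1, 2, 3))  # 1: full separation
#' varghaDelaneyA(1:3, 1:3)                # 0.5: identical groups
#' @export
varghaDelaneyA <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))  # mid-ranks for ties
  u <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u / (nx * ny)
}

#' Pooled mean ranks and rank-sum statistic of two groups
#'
#' Ranks the concatenated sample with average ranks for ties, and reports
#' the per-group mean ranks (the M_Rank summaries used alongside a
#' Mann--Whitney U test) and the U statistic of the first group from the
#' standard rank-sum relation.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `mRank1`, `mRank2`, `U`, `n1`, `n2`.
#' @examples
#' meanRanks(c(1, 2), c(3, 4))  # mRank1 = 1.5, mRank2 = 3.5
#' @export
meanRanks <- function(x, y) {
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  r1 <- sum(r[seq_len(n1)])
  list(mRank1 = r1 / n1, mRank2 = (sum(r) - r1) / n2,
       U = r1 - n1 * (n1 + 1) / 2, n1 = n1, n2 = n2)
}

# classes whose constraint values are not independent of canonical coding
# regions (they overlap them); excluded from independence-assuming tests
.OVERLAP_CLASSES <- c("intORF", "uoORF", "doORF")

#' Run a planned set of group comparisons
#'
#' Orchestrates the classical tests around the native effect-size
#' statistics: for unpaired comparisons a two-sample Kolmogorov--Smirnov
#' test, a Mann--Whitney U test with pooled mean ranks and the
#' Vargha--Delaney A; for paired comparisons a Wilcoxon signed-rank test
#' (pairs with a missing member are dropped and logged); optionally a
#' Kendall rank correlation (tau-b, tie-corrected). Rows of the
#' overlapping sORF classes (intORF, uoORF, doORF) are excluded from
#' unpaired comparisons when a `sorf_class` column is present and
#' `excludeOverlapClasses` is not turned off. p-values below 0.001 are
#' rendered as `"<0.001"` in the `p_label` columns; raw values are kept.
#'
#' @param data data.frame with columns `group`, `value`, optionally
#'   `sorf_class`, and for paired plans `pair_id`.
#' @param plan data.frame with columns `name`, `groupA`, `groupB`,
#'   `paired` (logical), optional `kendall` (logical) and
#'   `excludeOverlapClasses` (logical, default TRUE for unpaired plans).
#' @return `data.table`, one row per comparison: test statistics, raw
#'   p-values and `"<0.001>"`-floored labels, mean ranks, Vargha--Delaney A,
#'   sample sizes and the number of dropped pairs.
#' @export
runComparisons <- function(data, plan) {
  data <- as.data.table(data)
  plan <- as.data.frame(plan)
  if (is.null(plan$kendall)) plan$kendall <- FALSE
  if (is.null(plan$excludeOverlapClasses)) plan$excludeOverlapClasses <- TRUE
  one <- function(i) {
    p <- plan[i, ]
    d <- data
    if (isTRUE(p$excludeOverlapClasses) && "sorf_class" %in% names(d))
      d <- d[!(sorf_class %in% .OVERLAP_CLASSES)]
    a <- d[group == p$groupA]
    b <- d[group == p$groupB]
    out <- data.table(name = p$name, groupA = p$groupA, groupB = p$groupB,
                      paired = isTRUE(p$paired))
    if (isTRUE(p$paired)) {
      stopifnot("pair_id" %in% names(d))
      m <- merge(a[, .(pair_id, va = value)], b[, .(pair_id, vb = value)],
                 by = "pair_id")
      dropped <- (nrow(a) - nrow(m)) + (nrow(b) - nrow(m))
      if (dropped > 0)
        message(sprintf("%s: dropped %g unmatched pair member(s)",
                        p$name, dropped))
      w <- stats::wilcox.test(m$va, m$vb, paired = TRUE, exact = FALSE)
      out[, `:=`(n1 = nrow(m), n2 = nrow(m), n_dropped_pairs = dropped,
                 W = unname(w$statistic), p_wilcoxon = w$p.value,
                 p_wilcoxon_label = formatPValue(w$p.value))]
      if (isTRUE(p$kendall)) {
        kt <- suppressWarnings(
          stats::cor.test(m$va, m$vb, method = "kendall"))
        out[, `:=`(tau = unname(kt$estimate), p_kendall = kt$p.value,
                   p_kendall_label = formatPValue(kt$p.value))]
      }
    } else {
      stopifnot(nrow(a) > 0, nrow(b) > 0)
      ks <- suppressWarnings(stats::ks.test(a$value, b$value))
      mw <- stats::wilcox.test(a$value, b$value, exact = FALSE)
      mr <- meanRanks(a$value, b$value)
      out[, `:=`(n1 = nrow(a), n2 = nrow(b),
                 ks_D = unname(ks$statistic), p_ks = ks$p.value,
                 p_ks_label = formatPValue(ks$p.value),
                 U = mr$U, mRank1 = mr$mRank1, mRank2 = mr$mRank2,
                 p_mwu = mw$p.value, p_mwu_label = formatPValue(mw$p.value),
                 vda = varghaDelaneyA(a$value, b$value))]
      if (isTRUE(p$kendall)) {
        m <- min(nrow(a), nrow(b))
        kt <- suppressWarnings(stats::cor.test(a$value[seq_len(m)],
                                               b$value[seq_len(m)],
                                               method = "kendall"))
        out[, `:=`(tau = unname(kt$estimate), p_kendall = kt$p.value,
                   p_kendall_label = formatPValue(kt$p.value))]
      }
    }
    out
  }
  rbindlist(lapply(seq_len(nrow(plan)), one), fill = TRUE)
}
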