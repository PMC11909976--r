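#' @include AllClasses.R utils.R
NULL

#' Poisson-grid bounds on the observed/expected ratio
#'
#' For an observed count `k` and an expected count lambda-prime, the Poisson
#' pmf `G(X = k) = lambda^k e^(-lambda) / k!` is evaluated at
#' lambda = x * lambda-prime over the ratio grid `x = 0, step, ..., gridMax`;
#' the pmf values are cumulated and normalised to end at 1, and the bounds
#' are the smallest grid ratios whose normalised cumulative value reaches
#' 0.05 (lower) and 0.95 (upper). The upper bound is the OEUF. Both bounds
#' are capped at `gridMax` by construction.
#'
#' @param observed observed count(s) `k`, non-negative integer(s).
#' @param expected expected count(s) lambda-prime, strictly positive.
#' @param step grid step (default 0.001).
#' @param gridMax grid upper end (default 2).
#' @param probs the two cumulative cut points (default `c(0.05, 0.95)`,
#'   a 90 percent interval).
#' @return `data.table` with columns `lower` and `upper`, one row per
#'   (observed, expected) pair.
#' @examples
#' poissonBounds(0, 30)   # upper close to 0.1
#' poissonBounds(10, 10)  # brackets 1
#' @export
poissonBounds <- function(observed, expected, step = 0.001, gridMax = 2,
                          probs = c(0.05, 0.95)) {
  n <- max(length(observed), length(expected))
  observed <- rep_len(observed, n)
  expected <- rep_len(expected, n)
  if (any(observed < 0) || any(observed != floor(observed)))
    stop("observed counts must be non-negative integers")
  if (any(expected <= 0))
    stop("expected counts must be strictly positive (degenerate grid otherwise)")
  x <- seq(0, gridMax, by = step)
  one <- function(k, lam) {
    pmf <- stats::dpois(k, x * lam)
    tot <- sum(pmf)
    if (tot == 0) return(c(NA_real_, NA_real_))  # k far beyond grid reach
    cum <- cumsum(pmf) / tot
    c(x[which(cum >= probs[1])[1]], x[which(cum >= probs[2])[1]])
  }
  res <- vapply(seq_len(n), function(i) one(observed[i], expected[i]),
                numeric(2))
  data.table(lower = res[1, ], upper = res[2, ])
}

#' Compute OEUF results for elements
#'
#' Pairs observed and expected counts per element for one constraint class
#' (`SNVOEUF`, `MOEUF` or `LOEUF`), runs [poissonBounds()], and flags
#' elements as powered when the expected count reaches `poweredMin`
#' (default 10; under-powered results are retained but flagged). Elements
#' with `expected == 0` are marked not computable (NA bounds).
#'
#' @param observed named or parallel numeric vector of observed counts.
#' @param expected numeric vector of expected counts (same order).
#' @param elementId element identifiers.
#' @param class one of `"SNVOEUF"`, `"MOEUF"`, `"LOEUF"` (or any label).
#' @param poweredMin powered threshold on the expected count (default 10).
#' @param ... passed to [poissonBounds()].
#' @return `data.table` with columns `element_id`, `class`, `observed`,
#'   `expected`, `lower`, `upper`, `ratio`, `powered`.
#' @export
computeOeuf <- function(observed, expected, elementId = names(observed),
                        class = "SNVOEUF", poweredMin = 10, ...) {
  if (is.null(elementId)) elementId <- as.character(seq_along(observed))
  out <- data.table(element_id = elementId, class = class,
                    observed = as.numeric(observed),
                    expected = as.numeric(expected),
                    lower = NA_real_, upper = NA_real_)
  ok <- out$expected > 0
  if (any(ok)) {
    b <- poissonBounds(out$observed[ok], out$expected[ok], ...)
    out[ok, `:=`(lower = b$lower, upper = b$upper)]
  }
  out[, ratio := ifelse(expected > 0, observed / expected, NA_real_)]
  out[, powered := expected >= poweredMin]
  out[]
}

#' Decile cut-off for constraint
#'
#' Sorts OEUF values ascending into 10 equal-count bins and returns the
#' maximum value of the most constrained (lowest) bin as the constraint
#' cut-off, plus each value's decile index 1..10. Bin membership for sorted
#' position `j` of `n` is `ceiling(10 * j / n)` (so the lowest bin holds
#' `floor(n/10)` values when `n` is not a multiple of 10); ties at bin
#' boundaries are broken by a stable sort on (value, element id).
#'
#' @param values numeric OEUF values (>= 10 of them).
#' @param ids optional element ids used for deterministic tie-breaking.
#' @return list with `cutoff` (numeric) and `decile` (integer vector in the
#'   original order of `values`).
#' @examples
#' decileCutoff(1:100)$cutoff  # 10
#' @export
decileCutoff <- function(values, ids = NULL) {
  n <- length(values)
  if (n < 10L) stop("decile cut-off needs at least 10 values")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  ord <- order(values, ids, method = "radix")
  dec <- integer(n)
  dec[ord] <- as.integer(ceiling(10 * seq_len(n) / n))
  cutoff <- max(values[dec == 1L])
  list(cutoff = cutoff, decile = dec)
}

#' Frame-respect flag
#'
#' An sORF whose missense constraint is stronger than its all-SNV
#' constraint (MOEUF strictly below SNVOEUF) is more likely constrained in
#' its own reading frame rather than through overlapping elements. Only
#' evaluated when both results are powered; otherwise NA (excluded from
#' tallies).
#'
#' @param moeuf,snvoeuf OEUF upper bounds (numeric, vectorised).
#' @param moeufPowered,snvoeufPowered powered flags (default TRUE).
#' @return logical vector (NA where unpowered).
#' @examples
#' frameRespectFlag(0.6, 0.933)  # TRUE
#' @export
frameRespectFlag <- function(moeuf, snvoeuf, moeufPowered = TRUE,
                             snvoeufPowered = TRUE) {
  ifelse(moeufPowered & snvoeufPowered, moeuf < snvoeuf, NA)
}

#' Regional UTR constraint of a gene
#'
#' A gene is regionally UTR-constrained when it has multiple UTRs whose
#' OEUF deciles (computed over the full UTR OEUF distribution with
#' [decileCutoff()]) are separated by at least two other deciles, i.e. some
#' pair of its UTRs has decile indices differing by >= 3. UTRs shorter than
#' `minLen` or with expected counts below `poweredMin` are dropped first.
#'
#' @param deciles integer decile indices (1..10) of the gene's UTRs.
#' @param expected optional expected counts per UTR (powered filter).
#' @param lengths optional UTR lengths in bases (length filter).
#' @param minLen minimum UTR length (default 0, no filter).
#' @param poweredMin expected-count filter (default 10).
#' @return logical: TRUE iff the gene is regionally UTR-constrained.
#' @examples
#' regionalUtrConstraint(c(1, 4))     # TRUE: deciles 2 and 3 lie between
#' regionalUtrConstraint(c(1, 3))     # FALSE
#' regionalUtrConstraint(c(2, 2, 7))  # TRUE via the (2, 7) pair
#' @export
regionalUtrConstraint <- function(deciles, expected = NULL, lengths = NULL,
                                  minLen = 0, poweredMin = 10) {
  keep <- rep(TRUE, length(deciles))
  if (!is.null(expected)) keep <- keep & expected >= poweredMin
  if (minLen > 0) {
    if (is.null(lengths)) stop("lengths are required when minLen > 0")
    keep <- keep & lengths >= minLen
  }
  d <- deciles[keep]
  if (length(d) < 2L) return(FALSE)
  max(d) - min(d) >= 3L
}

#' Assemble a per-element constraint table
#'
#' Convenience join of observed counts ([countObserved()]) and expected
#' counts ([expectedCounts()]) into OEUF results for the three constraint
#' classes: `SNVOEUF` (all SNVs), `MOEUF` (missense) and `LOEUF`
#' (start-loss + stop-loss + stop-gain), with decile indices per class
#' computed over powered elements.
#'
#' @param obsCounts output of [countObserved()].
#' @param expCounts output of [expectedCounts()] (already calibrated).
#' @param classes subset of `c("SNVOEUF", "MOEUF", "LOEUF")`.
#' @param poweredMin powered threshold (default 10).
#' @param ... passed to [poissonBounds()].
#' @return `data.table` with one row per element x class: `element_id`,
#'   `class`, `observed`, `expected`, `lower`, `upper`, `ratio`, `powered`,
#'   `decile` (NA for unpowered elements).
#' @export
oeufTable <- function(obsCounts, expCounts,
                      classes = c("SNVOEUF", "MOEUF", "LOEUF"),
                      poweredMin = 10, ...) {
  obs <- as.data.table(obsCounts)
  ex <- as.data.table(expCounts)
  classDef <- list(
    SNVOEUF = .CONSEQUENCES,
    MOEUF = "missense",
    LOEUF = .LOF_CLASSES)
  res <- rbindlist(lapply(classes, function(cl) {
    oc <- obs[consequence %in% classDef[[cl]],
              .(observed = sum(observed)), by = sorf_id]
    ec <- ex[consequence %in% classDef[[cl]],
             .(expected = sum(expected)), by = sorf_id]
    m <- ec[oc, on = "sorf_id"]
    computeOeuf(m$observed, m$expected, m$sorf_id, class = cl,
                poweredMin = poweredMin, ...)
  }))
  res[, decile := NA_integer_]
  for (cl in classes) {
    p <- which(res$class == cl & res$powered & !is.na(res$upper))
    if (length(p) >= 10L)
      res$decile[p] <- decileCutoff(res$upper[p], res$element_id[p])$decile
  }
  setorderv(res, c("element_id", "class"))
  res[]
}
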