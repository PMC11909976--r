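#' @include AllClasses.R utils.R consequence.R
NULL

#' Map a methylation fraction to one of 16 bins
#'
#' Sixteen equal-width bins on \[0, 1\] (width 0.0625), left-closed and
#' right-open except the last bin, which is closed: 0.5 falls in bin 8
#' (the 0.5--0.5625 interval) and 1.0 in bin 15.
#'
#' @param fraction numeric in \[0, 1\].
#' @return integer bin index 0..15.
#' @examples
#' methylationBin(c(0, 0.5, 1))
#' @export
methylationBin <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop("methylation fractions must lie in [0, 1]")
  pmin(as.integer(floor(fraction / 0.0625)), 15L)
}

#' Average per-epigenome methylation tracks into a methylation map
#'
#' Per genomic position, the mean methylation fraction over the tracks that
#' carry a value at that position, binned into the 16 equal-width bins.
#'
#' @param tracks a list of `data.table`s with columns `chrom`, `pos`,
#'   `fraction` (one per epigenome; typically 37), or a single such table.
#' @return A [MethylationMap-class].
#' @export
buildMethylationMap <- function(tracks) {
  if (is.data.frame(tracks)) tracks <- list(tracks)
  if (!length(tracks)) stop("at least one methylation track is required")
  all <- rbindlist(lapply(tracks, function(t)
    as.data.table(t)[, .(chrom = as.character(chrom), pos = as.integer(pos),
                         fraction = as.numeric(fraction))]))
  if (any(all$fraction < 0 | all$fraction > 1))
    stop("methylation fractions must lie in [0, 1]")
  m <- all[, .(fraction = mean(fraction)), by = .(chrom, pos)]
  m[, bin := methylationBin(fraction)]
  setkeyv(m, c("chrom", "pos"))
  new("MethylationMap", positions = m[])
}

#' Built-in toy mutation-rate table
#'
#' A qualitative stand-in for published trinucleotide-context rate tables,
#' with the structure the model must be sensitive to: transitions 3x
#' transversions, and the CpG deamination transition (C>T with a 3'G
#' neighbour, or equivalently G>A with a 5'C neighbour) scaled linearly in
#' the methylation bin from 1x (bin 0, unmethylated CpGs mutate like
#' non-CpG sites) to 10x (bin 15, fully methylated). Rates for all other
#' (context, alt) pairs are bin-independent. Covers all 64 contexts x 3
#' alternate alleles x 16 bins.
#'
#' @param transversion per-site per-generation transversion rate.
#' @param transitionFactor transition/transversion rate ratio.
#' @param cpgFactorMax CpG-transition multiplier at full methylation.
#' @return A [MutationRateTable-class].
#' @export
toyRateTable <- function(transversion = 4e-9, transitionFactor = 3,
                         cpgFactorMax = 10) {
  ctx <- do.call(paste0, expand.grid(.BASES, .BASES, .BASES,
                                     stringsAsFactors = FALSE)[, c(1, 2, 3)])
  grid <- data.table(expand.grid(context = ctx, alt = .BASES, bin = 0:15,
                                 stringsAsFactors = FALSE))
  grid[, ref := substr(context, 2L, 2L)]
  grid <- grid[ref != alt]
  ti <- .isTransition(grid$ref, grid$alt)
  mu <- ifelse(ti, transversion * transitionFactor, transversion)
  cpgDeam <- (grid$ref == "C" & grid$alt == "T" &
                substr(grid$context, 3L, 3L) == "G") |
             (grid$ref == "G" & grid$alt == "A" &
                substr(grid$context, 1L, 1L) == "C")
  mult <- 1 + (cpgFactorMax - 1) * grid$bin / 15
  mu[cpgDeam] <- mu[cpgDeam] * mult[cpgDeam]
  grid[, mu := mu]
  new("MutationRateTable",
      rates = grid[, .(context, ref, alt, bin = as.integer(bin), mu)])
}

#' Look up mutation rates with strand canonicalisation
#'
#' Lookup is attempted on the given (genomic-strand) context; entries absent
#' from the table are retried as the reverse-complement context with the
#' complementary alternate allele (published rate tables are usually
#' strand-collapsed). A context still missing after canonicalisation is a
#' configuration error.
#'
#' @param rates a [MutationRateTable-class].
#' @param context context triplet(s).
#' @param alt alternate allele(s) on the same strand as `context`.
#' @param bin methylation bin(s) 0..15.
#' @return numeric rate vector.
#' @export
rateLookup <- function(rates, context, alt, bin) {
  r <- rates@rates
  q <- data.table(context = context, alt = alt, bin = as.integer(bin))
  res <- r[q, on = c("context", "alt", "bin"), x.mu]
  miss <- is.na(res)
  if (any(miss)) {
    q2 <- data.table(context = .revcomp(q$context[miss]),
                     alt = .complement(q$alt[miss]), bin = q$bin[miss])
    res[miss] <- r[q2, on = c("context", "alt", "bin"), x.mu]
  }
  if (anyNA(res)) {
    bad <- unique(paste0(q$context[is.na(res)], ">", q$alt[is.na(res)]))
    stop(sprintf("context(s) not found in rate table after canonicalisation: %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  res
}

#' Enumerate possible SNVs with context- and methylation-aware rates
#'
#' Takes the frame-aware classification of every possible SNV (from
#' [classifyAll()]) and attaches, per variant, its methylation bin and its
#' mutation rate: exactly 9 possible variants per non-excluded codon. By
#' default methylation bins are applied only where the genomic context
#' contains a CpG dinucleotide; elsewhere bin 0 is forced
#' (`cpgOnlyMethylation = FALSE` disables this).
#'
#' @param consequences output of [classifyAll()] (a `data.table`), or a
#'   [CodingSequence-class]/list thereof (then classified internally).
#' @param rates a [MutationRateTable-class].
#' @param methylation a [MethylationMap-class], or NULL (all bins 0).
#' @param cpgOnlyMethylation force bin 0 at non-CpG contexts (default TRUE).
#' @return `data.table`: the `consequences` columns plus `meth_bin`, `mu`,
#'   `excluded` (FALSE), `reason` (NA).
#' @export
enumeratePossible <- function(consequences, rates, methylation = NULL,
                              cpgOnlyMethylation = TRUE) {
  if (!is.data.frame(consequences)) consequences <- classifyAll(consequences)
  poss <- data.table::copy(as.data.table(consequences))
  if (is.null(methylation) || nrow(methylation@positions) == 0L) {
    poss[, bin := 0L]
  } else {
    mp <- methylation@positions
    poss[, bin := mp[poss, on = c(chrom = "chrom", pos = "gpos"), x.bin]]
    poss[is.na(bin), bin := 0L]
  }
  if (cpgOnlyMethylation)
    poss[!grepl("CG", context_genomic, fixed = TRUE), bin := 0L]
  # rate lookup on the genomic-strand context and allele
  poss[, mu := rateLookup(rates, context_genomic, galt, bin)]
  data.table::setnames(poss, "bin", "meth_bin")
  poss[, excluded := FALSE]
  poss[, reason := NA_character_]
  poss[]
}

#' Exclude possible variants at unusable sites
#'
#' Mirrors the observed-side site filters on the expectation side: a
#' possible variant is excluded (with a reason) when the position carries a
#' low-quality variant call, when the matching observed allele has a high
#' allele frequency (>= `afMax`), or when the site depth is below
#' `depthMin`. Reason priority: `low_quality_site` > `high_af` >
#' `low_coverage`. Non-excluded variants are retained with
#' `excluded = FALSE`.
#'
#' @param possible output of [enumeratePossible()].
#' @param variants observed variant sites (`chrom`, `pos`, `alt`, `af`, and
#'   optionally `low_quality`), used for the high-AF and low-quality checks;
#'   NULL to skip.
#' @param coverage per-position site info (`chrom`, `pos`, `depth`, and
#'   optionally `low_quality`); NULL to skip the coverage check. Positions
#'   absent from `coverage` are treated as covered.
#' @param afMax allele-frequency exclusion threshold (default 0.001,
#'   exclusion at `af >= afMax`).
#' @param depthMin minimum per-site depth (default 1; exclusion at
#'   `depth < depthMin`).
#' @return the `possible` table with `excluded`/`reason` filled in.
#' @export
filterPossible <- function(possible, variants = NULL, coverage = NULL,
                           afMax = 0.001, depthMin = 1) {
  poss <- data.table::copy(as.data.table(possible))
  poss[, `:=`(excluded = FALSE, reason = NA_character_)]
  if (!is.null(coverage)) {
    cov <- as.data.table(coverage)
    d <- cov[poss, on = c(chrom = "chrom", pos = "gpos"), x.depth]
    poss[!is.na(d) & d < depthMin,
         `:=`(excluded = TRUE, reason = "low_coverage")]
    if ("low_quality" %in% names(cov)) {
      lq <- cov[poss, on = c(chrom = "chrom", pos = "gpos"), x.low_quality]
      poss[!is.na(lq) & lq, `:=`(excluded = TRUE, reason = "low_quality_site")]
    }
  }
  if (!is.null(variants)) {
    v <- as.data.table(variants)
    a <- v[poss, on = c(chrom = "chrom", pos = "gpos", alt = "galt"), x.af]
    poss[!is.na(a) & a >= afMax & reason %in% c(NA, "low_coverage"),
         `:=`(excluded = TRUE, reason = "high_af")]
    if ("low_quality" %in% names(v)) {
      vl <- unique(v[low_quality == TRUE, .(chrom, pos)])
      if (nrow(vl)) {
        hit <- paste(poss$chrom, poss$gpos) %in% paste(vl$chrom, vl$pos)
        poss[hit, `:=`(excluded = TRUE, reason = "low_quality_site")]
      }
    }
  }
  poss[]
}

#' Expected variant counts per consequence class
#'
#' Per element and consequence class, sums the mutation rates and possible
#' variant counts over retained (non-excluded) possible variants and scales
#' the rate sum by a calibration factor: `E = calibrationK * sum(mu)`.
#' Classes with no retained variants report `E = 0`.
#'
#' @param possible output of [enumeratePossible()]/[filterPossible()].
#' @param calibrationK observed-per-rate calibration factor (> 0); see
#'   [fitCalibration()]. With the default 1 (a warning is emitted), `E` is
#'   the raw rate sum, interpretable as a relative rate.
#' @param quiet suppress the default-calibration warning.
#' @return `data.table` with columns `sorf_id`, `consequence`, `n_possible`,
#'   `rate_sum`, `expected` (all five classes present for every element,
#'   zero-filled).
#' @export
expectedCounts <- function(possible, calibrationK = 1, quiet = FALSE) {
  if (!is.numeric(calibrationK) || length(calibrationK) != 1L ||
      calibrationK <= 0)
    stop("calibrationK must be a single positive number")
  if (missing(calibrationK) && !quiet)
    warning("no calibration supplied; expected counts are relative rates (k = 1)",
            call. = FALSE)
  poss <- as.data.table(possible)[excluded == FALSE]
  agg <- poss[, .(n_possible = .N, rate_sum = sum(mu)),
              by = .(sorf_id, consequence)]
  full <- data.table(expand.grid(
    sorf_id = unique(as.data.table(possible)$sorf_id),
    consequence = .CONSEQUENCES, stringsAsFactors = FALSE))
  out <- agg[full, on = c("sorf_id", "consequence")]
  out[is.na(n_possible), `:=`(n_possible = 0L, rate_sum = 0)]
  out[, expected := calibrationK * rate_sum]
  setorderv(out, c("sorf_id", "consequence"))
  out[]
}

#' Fit the observed-per-rate calibration factor
#'
#' Zero-intercept least-squares fit of observed synonymous counts on
#' synonymous rate sums across a reference set of elements:
#' `k = sum(obs * rs) / sum(rs^2)`. The external calibration protocol used
#' with real cohorts is not restated here; this proportional fit is the
#' package's substitute and assumes the cohort is in the linear
#' (unsaturated) regime.
#'
#' @param observedSyn per-element observed synonymous counts.
#' @param rateSumSyn per-element synonymous rate sums (same order).
#' @param allowSingle allow a single reference element (default FALSE,
#'   requiring >= 2).
#' @return calibration factor `k` (> 0).
#' @examples
#' fitCalibration(c(10, 20), c(5, 10))  # exactly 2
#' @export
fitCalibration <- function(observedSyn, rateSumSyn, allowSingle = FALSE) {
  stopifnot(length(observedSyn) == length(rateSumSyn))
  keep <- is.finite(observedSyn) & is.finite(rateSumSyn)
  observedSyn <- observedSyn[keep]; rateSumSyn <- rateSumSyn[keep]
  if (length(observedSyn) < if (allowSingle) 1L else 2L)
    stop("calibration needs at least two reference elements (or allowSingle)")
  if (all(rateSumSyn == 0)) stop("all rate sums are zero; cannot calibrate")
  sum(observedSyn * rateSumSyn) / sum(rateSumSyn^2)
}

#' Fit a proportion-observed calibration curve on synonymous sites
#'
#' At large cohort sizes the number of unique segregating sites saturates
#' in the mutation rate (most strongly at methylated CpG transitions), so a
#' single proportional factor mis-calibrates classes whose rate composition
#' differs from the synonymous reference. This calibration instead
#' estimates, per distinct mutation rate, the fraction of synonymous
#' possible variants observed as segregating sites, and predicts expected
#' counts for any class by summing those fractions over its sites ---
#' a nonparametric proportion-observed curve in the spirit of the external
#' constraint-calibration protocols. Rates are grouped by `signif(mu,
#' digits)`; rate groups with fewer than `minGroup` synonymous sites fall
#' back to the linear fit `min(1, k * mu)` with `k` the global
#' observed-per-rate ratio of the synonymous reference.
#'
#' @param possible retained possible variants ([filterPossible()] rows with
#'   `excluded == FALSE`).
#' @param observed filtered observed variant sites ([filterObserved()]).
#' @param digits significant digits used to group rates (default 3).
#' @param minGroup minimum synonymous sites per rate group (default 50).
#' @return object of class `proportionCalibration`: a list with `curve`
#'   (`data.table`: `mu_group`, `p_hat`, `n`), `kFallback`, `digits`.
#' @seealso [expectedCounts()] for the plain proportional calibration.
#' @export
fitProportionCalibration <- function(possible, observed, digits = 3,
                                     minGroup = 50) {
  poss <- as.data.table(possible)[excluded == FALSE]
  syn <- poss[consequence == "synonymous"]
  if (nrow(syn) < 2L) stop("calibration needs synonymous possible variants")
  obs <- as.data.table(observed)
  hit <- !is.na(obs[syn, on = c(chrom = "chrom", pos = "gpos", alt = "galt"),
                    which = TRUE, mult = "first"])
  syn[, mu_group := signif(mu, digits)]
  curve <- syn[, .(p_hat = mean(hit[.I]), n = .N), by = mu_group]
  kFallback <- sum(hit) / sum(syn$mu)
  curve <- curve[n >= minGroup]
  structure(list(curve = curve[], kFallback = kFallback, digits = digits),
            class = "proportionCalibration")
}

#' Expected counts from a proportion-observed calibration
#'
#' Like [expectedCounts()], but the expected count of each class is the sum
#' of the calibrated per-site observation probabilities instead of a scaled
#' rate sum, which keeps classes with different rate composition comparable
#' when high-rate sites are saturated.
#'
#' @param possible output of [enumeratePossible()]/[filterPossible()].
#' @param calibration a `proportionCalibration` from
#'   [fitProportionCalibration()].
#' @return `data.table` with columns `sorf_id`, `consequence`,
#'   `n_possible`, `rate_sum`, `expected` (five classes, zero-filled).
#' @export
expectedCountsProportion <- function(possible, calibration) {
  stopifnot(inherits(calibration, "proportionCalibration"))
  poss <- as.data.table(possible)[excluded == FALSE]
  poss[, mu_group := signif(mu, calibration$digits)]
  poss[, p_hat := calibration$curve[poss, on = "mu_group", x.p_hat]]
  poss[is.na(p_hat), p_hat := pmin(1, calibration$kFallback * mu)]
  agg <- poss[, .(n_possible = .N, rate_sum = sum(mu),
                  expected = sum(p_hat)),
              by = .(sorf_id, consequence)]
  full <- data.table(expand.grid(
    sorf_id = unique(as.data.table(possible)$sorf_id),
    consequence = .CONSEQUENCES, stringsAsFactors = FALSE))
  out <- agg[full, on = c("sorf_id", "consequence")]
  out[is.na(n_possible), `:=`(n_possible = 0L, rate_sum = 0, expected = 0)]
  setorderv(out, c("sorf_id", "consequence"))
  out[]
}
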