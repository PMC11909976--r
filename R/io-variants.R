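#' @include AllClasses.R utils.R
NULL

.SNV_RE <- "^[ACGT]$"

#' Read biallelic SNV sites from a VCF or a VCF-like table
#'
#' Multi-allelic records are decomposed into one site per alternate allele;
#' non-SNV alleles (indels, MNVs, symbolic alleles) are dropped and counted.
#' `passed_filters` is TRUE iff the FILTER field is `PASS` (or `.`, treated
#' as unfiltered PASS in VCF-like tables only when `dotIsPass = TRUE`).
#'
#' For `.vcf`/`.vcf.gz` input the allele frequency and depth are pulled from
#' the INFO column; for tab-separated input, column names are configurable.
#' A `low_quality` flag column is honoured when present, otherwise derived
#' as `!passed_filters`.
#'
#' @param path path to a VCF (4.x) or a tab-separated sites table with a
#'   header line.
#' @param afField,depthField field/column names for allele frequency and
#'   per-site depth (defaults `"AF"` and `"DP"`; the table reader also
#'   accepts lower-case `af`/`depth`).
#' @param dotIsPass treat `.` FILTER as passing (default FALSE).
#' @return `data.table` with columns `chrom`, `pos`, `ref`, `alt`, `af`,
#'   `passed_filters`, `depth`, `low_quality`; the number of dropped non-SNV
#'   alleles is attached as attribute `n_dropped_non_snv`.
#' @export
readVariantSites <- function(path, afField = "AF", depthField = "DP",
                             dotIsPass = FALSE) {
  if (grepl("\\.vcf(\\.gz)?$", path)) {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    af <- vcfR::extract.info(v, afField)
    dp <- vcfR::extract.info(v, depthField, as.numeric = TRUE)
    if (all(is.na(af))) stop(sprintf("missing required INFO field %s", afField))
    dt <- data.table(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     ref = fix$REF, alt = fix$ALT,
                     af = as.character(af),
                     filter = fix$FILTER,
                     depth = as.numeric(dp))
    dt[, low_quality := NA]
  } else {
    raw <- data.table::fread(path, sep = "\t", header = TRUE,
                             colClasses = list(character = 1))
    names(raw) <- tolower(names(raw))
    lc <- function(x) tolower(x)
    pick <- function(cands) {
      hit <- cands[cands %in% names(raw)]
      if (!length(hit)) stop(sprintf("missing required field (%s)",
                                     paste(cands, collapse = "/")))
      hit[1]
    }
    dt <- data.table(
      chrom = as.character(raw[[pick(c("chrom", "#chrom", "chr"))]]),
      pos = as.integer(raw[[pick("pos")]]),
      ref = as.character(raw[[pick("ref")]]),
      alt = as.character(raw[[pick("alt")]]),
      af = as.character(raw[[pick(c(lc(afField), "af"))]]),
      filter = as.character(raw[[pick("filter")]]),
      depth = as.numeric(raw[[pick(c(lc(depthField), "depth", "dp"))]]))
    dt[, low_quality := if ("low_quality" %in% names(raw))
      as.logical(raw$low_quality) else NA]
  }
  # decompose multi-allelic records: ALT (and Number=A AF) are comma-lists
  nalt <- lengths(strsplit(dt$alt, ",", fixed = TRUE))
  idx <- rep(seq_len(nrow(dt)), nalt)
  long <- dt[idx]
  long[, alt := unlist(strsplit(dt$alt, ",", fixed = TRUE))]
  afl <- strsplit(dt$af, ",", fixed = TRUE)
  afv <- unlist(lapply(seq_along(afl), function(i) {
    a <- afl[[i]]
    if (length(a) == nalt[i]) a else rep(a[1], nalt[i])
  }))
  long[, af := as.numeric(afv)]
  snv <- grepl(.SNV_RE, long$ref) & grepl(.SNV_RE, long$alt) &
    long$ref != long$alt
  dropped <- sum(!snv)
  long <- long[snv]
  long[, passed_filters := filter == "PASS" |
         (dotIsPass & filter == ".")]
  long[, low_quality := ifelse(is.na(low_quality), !passed_filters,
                               low_quality)]
  out <- long[, .(chrom, pos, ref, alt, af, passed_filters, depth,
                  low_quality)]
  attr(out, "n_dropped_non_snv") <- dropped
  out
}

#' Read a reference sequence from FASTA
#'
#' Thin wrapper over [Biostrings::readDNAStringSet()] that keeps only the
#' first whitespace-delimited token of each header as the chromosome name.
#'
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
readReference <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}
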