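#' @include AllClasses.R
NULL

.BASES <- c("A", "C", "G", "T")

# vectorized nucleotide complement / reverse complement on plain characters
.complement <- function(x) chartr("ACGTN", "TGCAN", x)

.revcomp <- function(x) {
  if (!length(x)) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

.isTransition <- function(ref, alt) {
  (ref == "A" & alt == "G") | (ref == "G" & alt == "A") |
  (ref == "C" & alt == "T") | (ref == "T" & alt == "C")
}

.stopifnotBases <- function(x, what = "base") {
  bad <- !(x %in% .BASES)
  if (any(bad))
    stop(sprintf("invalid %s: %s", what,
                 paste(unique(x[bad]), collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# per-generation consequence classes, in reporting order
.CONSEQUENCES <- c("synonymous", "missense", "stop_gain", "stop_loss",
                   "start_loss")
.LOF_CLASSES <- c("start_loss", "stop_loss", "stop_gain")

#' Format a p-value with a reporting floor
#'
#' Values below `floor` are rendered as `"<floor"` (the machine-readable raw
#' value should be kept alongside); larger values are formatted with
#' `signif()`.
#'
#' @param p numeric p-value(s).
#' @param floor reporting floor (default 0.001).
#' @param digits significant digits for values above the floor.
#' @return character vector.
#' @examples
#' formatPValue(c(0.04, 2e-7))
#' @export
formatPValue <- function(p, floor = 0.001, digits = 3) {
  vapply(p, function(pi) {
    if (is.na(pi)) return(NA_character_)
    if (pi < floor) paste0("<", format(floor))
    else format(signif(pi, digits), scientific = FALSE)
  }, character(1))
}
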