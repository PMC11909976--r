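#' @include AllClasses.R utils.R
NULL

# extract a class label from a BED name field; the GENCODE Ribo-seq ORF
# release encodes the class in the record name, synthetic data writes
# "<id>|<class>". The mapping is configurable via a regular expression.
.classFromName <- function(name, pattern = NULL) {
  labels <- setdiff(.SORF_CLASSES, "unknown")
  if (is.null(pattern))
    pattern <- paste0("(", paste(gsub("-", "[-_]", labels), collapse = "|"), ")")
  m <- regmatches(name, regexpr(pattern, name, ignore.case = TRUE))
  out <- rep("unknown", length(name))
  hit <- vapply(regexpr(pattern, name, ignore.case = TRUE), function(z) z > 0,
                logical(1))
  if (any(hit)) {
    found <- tolower(m)
    canon <- stats::setNames(labels, tolower(gsub("-", "-", labels)))
    # normalise "lncrna_orf" style hits back to the canonical label
    found <- gsub("_", "-", found)
    out[hit] <- ifelse(found %in% names(canon), canon[found], "unknown")
  }
  out
}

#' Read sORF definitions from a BED12 file
#'
#' Blocks are reconstructed from `blockStarts`/`blockSizes` relative to
#' `chromStart` (rtracklayer does the 0-based half-open to 1-based closed
#' conversion). Records whose total block length is not divisible by 3 are
#' reported and skipped with a warning. Class labels are parsed from the BED
#' name field when present, otherwise set to `"unknown"`.
#'
#' @param path path to a BED12 file.
#' @param classPattern optional regular expression used to pull a class label
#'   out of the name field; by default the six class labels are matched
#'   anywhere in the name (case-insensitive, `-` or `_` separated).
#' @return A [SorfSet-class]. The number of skipped records is attached as
#'   attribute `n_skipped`.
#' @examples
#' bed <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t162\ts1|uORF\t0\t+\t100\t162\t0\t2\t9,12\t0,50", bed)
#' readBed12(bed)
#' @export
readBed12 <- function(path, classPattern = NULL) {
  gr <- rtracklayer::import(path, format = "bed")
  if (is.null(gr$name) || anyNA(gr$name))
    stop("BED12 input must carry a name field for every record")
  if (is.null(gr$blocks)) {
    # plain BED without blocks: treat each record as a single block
    bl <- GenomicRanges::GRangesList(lapply(seq_along(gr), function(i) gr[i]))
  } else {
    bl <- rtracklayer::blocks(gr)
  }
  names(bl) <- gr$name
  w <- sum(GenomicRanges::width(bl))
  bad <- w %% 3L != 0L | w < 6L
  if (any(bad)) {
    warning(sprintf(
      "skipped %d sORF record(s) with coding length not divisible by 3 (or < 6): %s",
      sum(bad), paste(utils::head(gr$name[bad], 5), collapse = ", ")),
      call. = FALSE)
    bl <- bl[!bad]
    gr <- gr[!bad]
  }
  out <- SorfSet(bl, .classFromName(gr$name, classPattern))
  attr(out, "n_skipped") <- sum(bad)
  out
}

#' Write a SorfSet to BED12
#'
#' The inverse of [readBed12()]: each sORF becomes one BED12 record whose
#' blocks are the sORF blocks. Names carry `<id>|<class>` when class labels
#' are known (so they round-trip through the name parser).
#'
#' @param sorfs a [SorfSet-class].
#' @param path output path.
#' @param encodeClass append `|<class>` to record names (default TRUE).
#' @return `path`, invisibly.
#' @export
writeBed12 <- function(sorfs, path, encodeClass = TRUE) {
  bl <- sorfBlocks(sorfs)
  nm <- names(bl)
  if (encodeClass) {
    cls <- sorfClass(sorfs)
    nm <- ifelse(cls == "unknown", nm, paste0(nm, "|", cls))
  }
  names(bl) <- nm
  rtracklayer::export(bl, path, format = "bed")
  invisible(path)
}

#' Write sORFs as a GTF defining their reading frames
#'
#' Emits, per sORF, one `gene` feature spanning min(start)..max(end) and one
#' `exon` feature per block, with `gene_id` set to the sORF id --- the file
#' shape used to hand a reading-frame definition to a consequence annotator.
#' GTF coordinates are 1-based inclusive.
#'
#' @param sorfs a [SorfSet-class].
#' @param path optional output path; when NULL the GTF lines are returned.
#' @return Character vector of GTF lines (invisibly when `path` is given).
#' @examples
#' bl <- GenomicRanges::GRangesList(
#'   s1 = GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 109), "+"))
#' writeSorfGtf(SorfSet(bl, "uORF"))
#' @export
writeSorfGtf <- function(sorfs, path = NULL) {
  bl <- sorfBlocks(sorfs)
  if (any(elementNROWS(bl) == 0L))
    stop("sORF with empty block list cannot be written as GTF")
  lines <- character()
  cls <- sorfClass(sorfs)
  for (i in seq_along(bl)) {
    b <- bl[[i]]
    id <- names(bl)[i]
    chrom <- as.character(GenomicRanges::seqnames(b))[1]
    strand <- as.character(GenomicRanges::strand(b))[1]
    attrs <- sprintf('gene_id "%s"; gene_biotype "sORF"; sorf_class "%s";',
                     id, cls[i])
    gene <- sprintf("%s\tsorfConstraint\tgene\t%d\t%d\t.\t%s\t.\t%s",
                    chrom, min(GenomicRanges::start(b)),
                    max(GenomicRanges::end(b)), strand, attrs)
    exons <- sprintf("%s\tsorfConstraint\texon\t%d\t%d\t.\t%s\t.\t%s",
                     chrom, GenomicRanges::start(b), GenomicRanges::end(b),
                     strand, attrs)
    lines <- c(lines, gene, exons)
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
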