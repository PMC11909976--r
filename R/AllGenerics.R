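#' @include AllClasses.R
NULL

#' Accessors for SorfSet and CodingSequence objects
#'
#' `sorfIds()` returns element identifiers; `sorfClass()` the per-sORF class
#' labels; `sorfBlocks()` the per-sORF genomic blocks as a `GRangesList`;
#' `sorfSpans()` one range per sORF covering min(start)..max(end);
#' `codingBases()` the spliced coding sequence as a single string;
#' `codonCount()` the number of codons.
#'
#' @param x a [SorfSet-class] or [CodingSequence-class] object.
#' @return See individual descriptions.
#' @name sorf-accessors
NULL

#' @rdname sorf-accessors
#' @export
setGeneric("sorfIds", function(x) standardGeneric("sorfIds"))

#' @rdname sorf-accessors
#' @export
setGeneric("sorfClass", function(x) standardGeneric("sorfClass"))

#' @rdname sorf-accessors
#' @export
setGeneric("sorfBlocks", function(x) standardGeneric("sorfBlocks"))

#' @rdname sorf-accessors
#' @export
setGeneric("sorfSpans", function(x) standardGeneric("sorfSpans"))

#' @rdname sorf-accessors
#' @export
setGeneric("codingBases", function(x) standardGeneric("codingBases"))

#' @rdname sorf-accessors
#' @export
setGeneric("codonCount", function(x) standardGeneric("codonCount"))

#' @rdname sorf-accessors
setMethod("sorfIds", "SorfSet", function(x) names(x@blocks))

#' @rdname sorf-accessors
setMethod("sorfClass", "SorfSet", function(x) {
  stats::setNames(x@sorfClass, names(x@blocks))
})

#' @rdname sorf-accessors
setMethod("sorfBlocks", "SorfSet", function(x) x@blocks)

#' @rdname sorf-accessors
setMethod("sorfSpans", "SorfSet", function(x) {
  sp <- unlist(range(x@blocks))
  S4Vectors::mcols(sp)$sorf_class <- x@sorfClass
  sp
})

#' @rdname sorf-accessors
#' @aliases length,SorfSet-method
setMethod("length", "SorfSet", function(x) length(x@blocks))

#' @rdname sorf-accessors
#' @aliases [,SorfSet,ANY-method
setMethod("[", "SorfSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, names(x@blocks))
  new("SorfSet", blocks = x@blocks[i], sorfClass = x@sorfClass[i])
})

setMethod("show", "SorfSet", function(object) {
  cat(sprintf("SorfSet with %d sORF(s)\n", length(object)))
  tab <- table(object@sorfClass)
  cat("  classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  if (length(object) > 0) {
    w <- sum(GenomicRanges::width(object@blocks))
    cat(sprintf("  coding length: %d-%d nt (median %.0f)\n",
                min(w), max(w), stats::median(w)))
  }
})

#' @rdname sorf-accessors
setMethod("sorfIds", "CodingSequence", function(x) x@sorfId)

#' @rdname sorf-accessors
setMethod("codingBases", "CodingSequence", function(x) {
  paste(x@bases, collapse = "")
})

#' @rdname sorf-accessors
setMethod("codonCount", "CodingSequence", function(x) {
  length(x@bases) %/% 3L
})

#' @rdname sorf-accessors
#' @aliases length,CodingSequence-method
setMethod("length", "CodingSequence", function(x) length(x@bases))

setMethod("show", "CodingSequence", function(object) {
  cat(sprintf("CodingSequence %s (%s%s), %d nt / %d codons%s\n",
              object@sorfId, object@chrom, object@strand,
              length(object@bases), length(object@bases) %/% 3L,
              if (object@startIsATG) "" else " [non-ATG start]"))
  s <- codingBases(object)
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" ", s, "\n")
  if (any(object@excluded))
    cat(sprintf("  %d base(s) in N-touching codons excluded\n",
                sum(object@excluded)))
})

setMethod("show", "MutationRateTable", function(object) {
  r <- object@rates
  cat(sprintf("MutationRateTable: %d entries, %d contexts, bins %d..%d\n",
              nrow(r), length(unique(r$context)), min(r$bin), max(r$bin)))
  cat(sprintf("  rate range: %.3g - %.3g per site per generation\n",
              min(r$mu), max(r$mu)))
})

setMethod("show", "MethylationMap", function(object) {
  p <- object@positions
  cat(sprintf("MethylationMap: %d position(s)", nrow(p)))
  if (nrow(p) > 0)
    cat(sprintf(", mean fraction %.3f, bins %d..%d",
                mean(p$fraction), min(p$bin), max(p$bin)))
  cat("\n")
})
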