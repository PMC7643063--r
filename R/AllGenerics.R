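#' Accessors for SeqCompTrends classes
#'
#' @param x an object of one of the package's S4 classes.
#' @return \code{genomeSeq}: the cleaned sequence string; \code{genomeLength}:
#'   its length in bases; \code{nDomains}: the number of compositional
#'   domains; \code{domains}: the domain table (0-based half-open
#'   coordinates plus per-domain composition); \code{sccValue}: the SCC value
#'   in bits; \code{profileTable}: the per-genome metric data.frame.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("genomeSeq", function(x) standardGeneric("genomeSeq"))
#' @rdname accessors
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))
#' @rdname accessors
#' @export
setGeneric("nDomains", function(x) standardGeneric("nDomains"))
#' @rdname accessors
#' @export
setGeneric("domains", function(x) standardGeneric("domains"))
#' @rdname accessors
#' @export
setGeneric("sccValue", function(x) standardGeneric("sccValue"))
#' @rdname accessors
#' @export
setGeneric("profileTable", function(x) standardGeneric("profileTable"))

#' @rdname accessors
setMethod("genomeSeq", "GenomeRecord", function(x) x@seq)
#' @rdname accessors
setMethod("genomeLength", "GenomeRecord", function(x) x@G)
#' @rdname accessors
setMethod("nDomains", "Segmentation", function(x) nrow(x@domains))
#' @rdname accessors
setMethod("nDomains", "SccResult", function(x) nrow(x@segmentation@domains))
#' @rdname accessors
setMethod("domains", "Segmentation", function(x) {
  cbind(x@domains, as.data.frame(x@freqs))
})
#' @rdname accessors
setMethod("domains", "SccResult", function(x) domains(x@segmentation))
#' @rdname accessors
setMethod("sccValue", "SccResult", function(x) x@value)
#' @rdname accessors
setMethod("profileTable", "ComplexityProfile", function(x) x@table)

setMethod("show", "GenomeRecord", function(object) {
  cat(sprintf("GenomeRecord '%s': %d bp (%d non-ACGT symbols dropped)\n",
              object@id, object@G, object@nDropped))
  s <- object@seq
  prev <- if (nchar(s) > 60) paste0(substr(s, 1, 57), "...") else s
  cat(" ", prev, "\n")
})

setMethod("show", "Segmentation", function(object) {
  cat(sprintf(
    "Segmentation: %d domain(s) over %d symbols (alphabet {%s}, s = %g)\n",
    nrow(object@domains), sum(object@domains$length),
    paste(object@alphabet, collapse = ","), object@s))
})

setMethod("show", "SccResult", function(object) {
  cat(sprintf("SCC [%s alphabet]: %.6f bits from %d domain(s)\n",
              object@scheme, object@value, nDomains(object)))
})

setMethod("show", "ComplexityProfile", function(object) {
  cat(sprintf("ComplexityProfile: %d genome(s), s = %g, min_len = %d\n",
              nrow(object@table), object@params$s, object@params$minLen))
  print(utils::head(object@table, 6))
  if (nrow(object@table) > 6) cat("  ...\n")
})
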