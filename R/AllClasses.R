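#' @import methods
NULL

DNA_ALPHABET <- c("A", "C", "G", "T")

#' GenomeRecord: a cleaned genome sequence
#'
#' Holds one DNA sequence after cleaning: lowercase bases are uppercased and
#' any symbol outside \code{A,C,G,T} is removed (the number removed is kept in
#' \code{nDropped}).
#'
#' @slot id character scalar, record identifier.
#' @slot seq character scalar over \code{A,C,G,T}.
#' @slot G integer, sequence length after cleaning.
#' @slot nDropped integer, non-ACGT symbols removed during cleaning.
#'
#' @seealso [readGenomeFasta()], [sccMetric()], [biobit()], [genomicSignature()]
#' @export
setClass("GenomeRecord",
  representation(id = "character", seq = "character",
                 G = "integer", nDropped = "integer"))

setValidity("GenomeRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || !nzchar(object@id))
    msg <- c(msg, "'id' must be a non-empty string")
  if (length(object@seq) != 1L)
    msg <- c(msg, "'seq' must be a single string")
  if (object@G < 1L)
    msg <- c(msg, "sequence is empty after cleaning")
  if (nchar(object@seq) != object@G)
    msg <- c(msg, "'G' does not match nchar(seq)")
  if (grepl("[^ACGT]", object@seq))
    msg <- c(msg, "'seq' contains symbols outside {A,C,G,T}")
  if (object@nDropped < 0L)
    msg <- c(msg, "'nDropped' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Segmentation: compositional domains of one sequence
#'
#' An ordered, gap-free tiling of \code{[0, G)} into compositional domains,
#' each with its symbol-frequency vector, produced by recursive binary
#' splitting at the maximal Jensen-Shannon divergence point subject to a
#' significance threshold \code{s}.
#'
#' Coordinates are 0-based half-open throughout.
#'
#' @slot domains data.frame with columns \code{start}, \code{end},
#'   \code{length} (one row per domain, in sequence order).
#' @slot freqs numeric matrix, one row per domain, columns named by the
#'   working alphabet; each row sums to 1.
#' @slot f numeric, whole-sequence frequency vector over the same alphabet.
#' @slot alphabet character vector of working symbols (length 4 or 2).
#' @slot s numeric in (0,1), the significance level used.
#' @slot minLen integer, minimum admissible domain length.
#'
#' @export
setClass("Segmentation",
  representation(domains = "data.frame", freqs = "matrix", f = "numeric",
                 alphabet = "character", s = "numeric", minLen = "integer"))

setValidity("Segmentation", function(object) {
  msg <- character()
  d <- object@domains
  if (!all(c("start", "end", "length") %in% names(d)))
    msg <- c(msg, "'domains' needs start/end/length columns")
  else {
    if (nrow(d) < 1L) msg <- c(msg, "at least one domain required")
    if (any(d$end <= d$start)) msg <- c(msg, "empty domain present")
    if (any(d$length != d$end - d$start))
      msg <- c(msg, "domain lengths inconsistent with coordinates")
    if (nrow(d) > 1L && any(d$start[-1L] != d$end[-nrow(d)]))
      msg <- c(msg, "domains do not tile the sequence")
    if (nrow(d) >= 1L && d$start[1L] != 0L)
      msg <- c(msg, "first domain must start at 0")
  }
  if (object@s <= 0 || object@s >= 1)
    msg <- c(msg, "'s' must lie in (0,1)")
  if (nrow(object@freqs) != nrow(d))
    msg <- c(msg, "one frequency row per domain required")
  if (any(abs(rowSums(object@freqs) - 1) > 1e-9))
    msg <- c(msg, "domain frequency rows must sum to 1")
  # length-weighted domain compositions must reproduce the global composition
  w <- d$length / sum(d$length)
  if (max(abs(colSums(object@freqs * w) - object@f)) > 1e-9)
    msg <- c(msg, "weighted domain compositions do not average to 'f'")
  if (length(msg)) msg else TRUE
})

#' SccResult: Sequence Compositional Complexity of one genome
#'
#' @slot value numeric, SCC in bits: the Shannon entropy of the whole-sequence
#'   composition minus the length-weighted sum of domain entropies.
#' @slot scheme one of \code{"ACGT"}, \code{"SW"}, \code{"RY"}, \code{"KM"}.
#' @slot segmentation the [Segmentation-class] the value was computed from.
#'
#' @export
setClass("SccResult",
  representation(value = "numeric", scheme = "character",
                 segmentation = "Segmentation"))

setValidity("SccResult", function(object) {
  msg <- character()
  if (!object@scheme %in% c("ACGT", "SW", "RY", "KM"))
    msg <- c(msg, "unknown alphabet scheme")
  k <- length(object@segmentation@alphabet)
  if (object@value < -1e-12 || object@value > log2(k) + 1e-12)
    msg <- c(msg, sprintf("SCC must lie in [0, log2(%d)]", k))
  n <- nrow(object@segmentation@domains)
  if (n == 1L && abs(object@value) > 1e-12)
    msg <- c(msg, "single-domain segmentation must give SCC = 0")
  if (length(msg)) msg else TRUE
})

#' ComplexityProfile: per-genome complexity metrics and genome parameters
#'
#' One row per genome: the four SCC variants, Biobit, Genomic Signature,
#' genome size, %GC and (optionally) gene count.
#'
#' @slot table data.frame with columns \code{id}, \code{SCC}, \code{SCC_SW},
#'   \code{SCC_RY}, \code{SCC_KM}, \code{BB}, \code{GS}, \code{genome_size},
#'   \code{pct_gc} and optionally \code{n_genes}.
#' @slot params list of the parameters the metrics were computed under
#'   (\code{s}, \code{minLen}, \code{gsKRange}).
#'
#' @export
setClass("ComplexityProfile",
  representation(table = "data.frame", params = "list"))

setValidity("ComplexityProfile", function(object) {
  msg <- character()
  need <- c("id", "SCC", "SCC_SW", "SCC_RY", "SCC_KM", "BB", "GS",
            "genome_size", "pct_gc")
  missing <- setdiff(need, names(object@table))
  if (length(missing))
    msg <- c(msg, paste("missing profile columns:",
                        paste(missing, collapse = ", ")))
  else {
    num <- object@table[setdiff(need, "id")]
    if (!all(vapply(num, function(v) all(is.finite(v)), logical(1))))
      msg <- c(msg, "metric columns must be finite")
    if (any(object@table$pct_gc < 0 | object@table$pct_gc > 100))
      msg <- c(msg, "pct_gc must lie in [0,100]")
  }
  if (length(msg)) msg else TRUE
})
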