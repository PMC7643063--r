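#' Count overlapping k-mers
#'
#' Counts every overlapping window of length \code{k} on the given strand
#' (no reverse-complement pooling), over the full \code{4^k} lexicographic
#' word table.
#'
#' @param seq character scalar over \code{A,C,G,T}, or a
#'   [GenomeRecord-class].
#' @param k word length, \code{1 <= k <= min(G, 10)} for the full table
#'   (\code{4^k} cells are allocated).
#' @return named integer vector of length \code{4^k} with attribute
#'   \code{total = G - k + 1}.
#' @examples
#' countKmers("ACGTA", 2)[c("AC", "CG", "GT", "TA")]
#' @export
countKmers <- function(seq, k) {
  if (is(seq, "GenomeRecord")) seq <- genomeSeq(seq)
  G <- nchar(seq)
  k <- as.integer(k)
  if (k < 1L || k > G) stop("'k' must lie in [1, G]")
  if (k > 10L) stop("full 4^k table too large for k > 10; ",
                    "use the sparse internal counter")
  cnt <- Biostrings::oligonucleotideFrequency(Biostrings::DNAString(seq),
                                              width = k)
  storage.mode(cnt) <- "integer"
  attr(cnt, "total") <- G - k + 1L
  cnt
}

# sparse k-mer counts for large k: only observed words, via sort + run
# lengths (the full 4^k table is unrepresentable once 4^k >> G)
.kmerCountsObserved <- function(seq, k) {
  G <- nchar(seq)
  n <- G - k + 1L
  words <- substring(seq, seq_len(n), seq_len(n) + k - 1L)
  r <- rle(sort(words))
  stats::setNames(r$lengths, r$values)
}

#' Biobit complexity of a genome
#'
#' Decomposes the genome's word entropy at length \code{k = round(2 L)},
#' \code{L = log4(G)}, into an anti-entropic component
#' \eqn{A = 2L - E_{2L}} (clamped to \code{[0, L]}) and an entropic component
#' \eqn{E = L - A}, so that \eqn{A + E = L}. A random genome has word entropy
#' near the maximum \code{2L} (hence \code{A} near 0); repetitive genomes
#' fall toward the minimum \code{L}. The Biobit score is the non-linear
#' combination
#' \deqn{BB = \sqrt{L}\,\sqrt{A/L}\,(1 - 2A/L)^3,}
#' which vanishes both for fully random sequences (\code{A = 0}) and at
#' \code{A/L = 1/2}.
#'
#' @param genome a [GenomeRecord-class] with \code{G >= 16}.
#' @return list with \code{L}, \code{kUsed}, \code{E2L} (bits), \code{A},
#'   \code{E} and \code{BB}.
#' @export
biobit <- function(genome) {
  G <- genomeLength(genome)
  if (G < 16L) stop("Biobit needs G >= 16 (word length degenerates)")
  L <- log(G) / log(4)
  kUsed <- max(1L, as.integer(round(2 * L)))
  cnt <- if (kUsed <= 10L) {
    v <- countKmers(genome, kUsed); v[v > 0L]
  } else {
    .kmerCountsObserved(genomeSeq(genome), kUsed)
  }
  f <- cnt / sum(cnt)
  E2L <- -sum(f * log2(f))
  A <- min(max(0, 2 * L - E2L), L)
  E <- L - A
  BB <- sqrt(L) * sqrt(A / L) * (1 - 2 * A / L)^3
  list(L = L, kUsed = kUsed, E2L = E2L, A = A, E = E, BB = BB)
}

#' Genomic Signature of a genome
#'
#' For each word length \code{k}, compares the observed k-mer counts against
#' the flat random expectation \eqn{EV = (G - k + 1)/4^k} and sums the
#' absolute relative deviations over the complete word table,
#' \eqn{\sum_i |P_i/EV - 1|}; the Genomic Signature is the maximum of this
#' deviation sum over the k range (smallest k on ties). Absent words each
#' contribute 1, so the sum degenerates once \code{4^k} far exceeds
#' \code{G}; the bounded default range reflects that.
#'
#' @param genome a [GenomeRecord-class].
#' @param kRange integer vector of word lengths, each \code{<= min(G, 10)}
#'   (default \code{1:8}).
#' @return list with \code{GS}, \code{kStar} and \code{perK} (a data.frame
#'   of the deviation sum for each k).
#' @export
genomicSignature <- function(genome, kRange = 1:8) {
  if (length(kRange) == 0L) stop("empty k range")
  G <- genomeLength(genome)
  kRange <- sort(unique(as.integer(kRange)))
  if (any(kRange < 1L) || any(kRange > G))
    stop("every k must lie in [1, G]")
  dev <- vapply(kRange, function(k) {
    cnt <- countKmers(genome, k)
    EV <- (G - k + 1) / 4^k
    sum(abs(cnt / EV - 1))
  }, numeric(1))
  iStar <- which.max(dev)   # first (smallest k) maximum
  list(GS = dev[iStar], kStar = kRange[iStar],
       perK = data.frame(k = kRange, deviation = dev))
}
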