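.pkgEnv <- new.env(parent = emptyenv())

#' Shannon entropy of a frequency vector
#'
#' \eqn{H = -\sum f \log_2 f} with \eqn{0 \log 0 = 0}, in bits.
#'
#' For length-4 vectors the four terms are accumulated as
#' \code{(A+T) + (C+G)} so that the result is bit-for-bit invariant under
#' complementation of the alphabet, which makes downstream SCC values exactly
#' orientation-invariant rather than invariant only up to rounding.
#'
#' @param f numeric vector of non-negative frequencies summing to 1
#'   (tolerance 1e-9).
#' @return entropy in bits, in \code{[0, log2(length(f))]}.
#' @examples
#' shannonEntropy(rep(0.25, 4))  # 2 bits
#' @export
shannonEntropy <- function(f) {
  if (any(f < 0)) stop("negative frequencies")
  if (abs(sum(f) - 1) > 1e-9) stop("frequencies must sum to 1")
  t <- ifelse(f > 0, f * log2(f), 0)
  if (length(t) == 4L) -((t[1L] + t[4L]) + (t[2L] + t[3L])) else -sum(t)
}

# ---- internal machinery ----------------------------------------------------

.knownAlphabets <- list(
  ACGT = c("A", "C", "G", "T"), SW = c("S", "W"),
  RY = c("R", "Y"), KM = c("K", "M"))

.detectAlphabet <- function(seq) {
  sym <- unique(strsplit(seq, "", fixed = TRUE)[[1L]])
  for (a in .knownAlphabets) if (all(sym %in% a)) return(a)
  stop("cannot infer a working alphabet from symbols: ",
       paste(sym, collapse = ","))
}

.encodeSeq <- function(seq, alphabet) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1L]], alphabet)
  if (anyNA(codes)) stop("sequence contains symbols outside the alphabet")
  codes
}

# cumulative counts with a leading zero row: counts of [lo, hi) (0-based
# half-open) are cum[hi + 1, ] - cum[lo + 1, ]
.cumCounts <- function(codes, k) {
  N <- length(codes)
  ind <- matrix(0L, N, k)
  ind[cbind(seq_len(N), codes)] <- 1L
  rbind(0L, apply(ind, 2L, cumsum))
}

# entropy (bits) of each row of a count matrix; complement-stable for k = 4
.rowEntropy <- function(cnt) {
  tot <- rowSums(cnt)
  f <- cnt / tot
  t <- ifelse(f > 0, f * log2(f), 0)
  if (ncol(cnt) == 4L) -((t[, 1L] + t[, 4L]) + (t[, 2L] + t[, 3L]))
  else -rowSums(t)
}

.neffTable <- function() {
  if (is.null(.pkgEnv$neff)) {
    path <- system.file("extdata", "jsd_null_neff.tsv",
                        package = "SeqCompTrends", mustWork = TRUE)
    .pkgEnv$neff <- utils::read.delim(path)
  }
  .pkgEnv$neff
}

# effective number of independent cut points for the maximal-JSD null,
# log-linear in N (Monte-Carlo calibrated table, linear extrapolation)
.neffLookup <- function(N, df) {
  tab <- .neffTable()
  tab <- tab[tab$df == if (df <= 2) 1L else 3L, ]
  lx <- log(tab$N); ly <- tab$n_eff
  x <- log(N)
  if (x <= lx[1L]) {
    sl <- (ly[2L] - ly[1L]) / (lx[2L] - lx[1L])
    y <- ly[1L] + sl * (x - lx[1L])
  } else if (x >= lx[length(lx)]) {
    m <- length(lx)
    sl <- (ly[m] - ly[m - 1L]) / (lx[m] - lx[m - 1L])
    y <- ly[m] + sl * (x - lx[m])
  } else {
    y <- stats::approx(lx, ly, xout = x)$y
  }
  max(1, y)
}

# significance of an observed maximal JSD statistic: probability that the
# maximal statistic of an i.i.d. null sequence of the same length falls below
# the observed one, P = F_chisq(stat; df)^n_eff
.jsdSignificance <- function(stat, N, df) {
  stats::pchisq(stat, df)^.neffLookup(N, df)
}

# scan all admissible cuts of [lo, hi); returns NULL if too short
.maxJsdScan <- function(cum, lo, hi, minLen) {
  N <- hi - lo
  k <- ncol(cum)
  if (N < 2L * minLen) return(NULL)
  p <- (lo + minLen):(hi - minLen)            # absolute cut positions
  left <- cum[p + 1L, , drop = FALSE] - rep(cum[lo + 1L, ], each = length(p))
  tot <- cum[hi + 1L, ] - cum[lo + 1L, ]
  right <- rep(tot, each = length(p)) - left
  Hl <- .rowEntropy(left)
  Hr <- .rowEntropy(right)
  Hp <- .rowEntropy(matrix(tot, 1L))
  n1 <- p - lo
  n2 <- hi - p
  jsd <- Hp - ((n1 / N) * Hl + (n2 / N) * Hr)
  i <- which.max(jsd)                         # leftmost maximum
  stat <- 2 * N * log(2) * jsd[i]
  list(pos = p[i], jsd = jsd[i], stat = stat,
       significance = .jsdSignificance(stat, N, k - 1L))
}

# ---- user-facing operations ------------------------------------------------

#' Best single Jensen-Shannon split of a sequence
#'
#' Scans every admissible cut point and returns the one maximizing the
#' Jensen-Shannon divergence between the two halves,
#' \eqn{D = H(f_{pool}) - (n_1/n) H(f_{left}) - (n_2/n) H(f_{right})},
#' together with the significance of the split: the probability, under the
#' calibrated i.i.d. null, that the maximal divergence of a homogeneous
#' sequence of the same length stays below the observed one. Ties are broken
#' leftmost.
#'
#' @param seq character scalar over a fixed alphabet (DNA or one of the
#'   binary recodings).
#' @param minLen minimum length of either part (default 2).
#' @param alphabet working alphabet; inferred from the symbols when NULL.
#' @return list with \code{pos} (0-based cut position; NA when the sequence
#'   is shorter than \code{2 * minLen}), \code{jsd} (bits), \code{stat}
#'   (\eqn{2 N \ln 2 \cdot JSD}) and \code{significance}.
#' @examples
#' maxJsdSplit("AATT")$jsd   # 1 bit: halves are pure, pool is 50/50
#' @export
maxJsdSplit <- function(seq, minLen = 2L, alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- .detectAlphabet(seq)
  codes <- .encodeSeq(seq, alphabet)
  cum <- .cumCounts(codes, length(alphabet))
  res <- .maxJsdScan(cum, 0L, length(codes), as.integer(minLen))
  if (is.null(res))
    return(list(pos = NA_integer_, jsd = 0, stat = 0, significance = 0))
  res
}

#' Segment a sequence into compositional domains
#'
#' Recursive binary segmentation: the maximal-JSD cut of the (sub)sequence is
#' accepted iff its significance reaches \code{s} and both parts are at least
#' \code{minLen} long; accepted parts are re-scanned in isolation, otherwise
#' the subsequence becomes one domain. No merging pass is applied afterwards.
#'
#' @inheritParams maxJsdSplit
#' @param s significance level in (0,1); the probability that a split this
#'   strong is not an i.i.d. fluctuation (default 0.95).
#' @return a [Segmentation-class]; domain coordinates are 0-based half-open.
#' @examples
#' seg <- segmentSequence(strrep("AT", 200), s = 0.95)
#' nDomains(seg)
#' @export
segmentSequence <- function(seq, s = 0.95, minLen = 2L, alphabet = NULL) {
  if (s <= 0 || s >= 1) stop("'s' must lie in (0,1)")
  if (is.null(alphabet)) alphabet <- .detectAlphabet(seq)
  minLen <- as.integer(minLen)
  codes <- .encodeSeq(seq, alphabet)
  k <- length(alphabet)
  cum <- .cumCounts(codes, k)
  N <- length(codes)

  bounds <- integer(0)                 # accepted internal breakpoints
  stack <- list(c(0L, N))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    res <- .maxJsdScan(cum, seg[1L], seg[2L], minLen)
    if (!is.null(res) && res$significance >= s) {
      bounds <- c(bounds, res$pos)
      stack <- c(stack, list(c(seg[1L], res$pos)), list(c(res$pos, seg[2L])))
    }
  }
  edges <- c(0L, sort(bounds), N)
  starts <- edges[-length(edges)]
  ends <- edges[-1L]
  freqs <- matrix(0, length(starts), k, dimnames = list(NULL, alphabet))
  for (i in seq_along(starts)) {
    cnt <- cum[ends[i] + 1L, ] - cum[starts[i] + 1L, ]
    freqs[i, ] <- cnt / sum(cnt)
  }
  new("Segmentation",
      domains = data.frame(start = starts, end = ends,
                           length = ends - starts),
      freqs = freqs, f = (cum[N + 1L, ] - cum[1L, ]) / N,
      alphabet = alphabet, s = s, minLen = minLen)
}

#' Build a Segmentation from fixed breakpoints
#'
#' Bypasses the significance machinery; useful for forced segmentations and
#' for the analytic truths of synthetic domain genomes.
#'
#' @inheritParams segmentSequence
#' @param breakpoints increasing internal cut positions (0-based, exclusive
#'   of 0 and the sequence length).
#' @return a [Segmentation-class].
#' @export
segmentationFromBreakpoints <- function(seq, breakpoints, s = 0.95,
                                        alphabet = NULL) {
  if (is.null(alphabet)) alphabet <- .detectAlphabet(seq)
  codes <- .encodeSeq(seq, alphabet)
  k <- length(alphabet)
  cum <- .cumCounts(codes, k)
  N <- length(codes)
  bp <- sort(unique(as.integer(breakpoints)))
  if (length(bp) && (min(bp) <= 0L || max(bp) >= N))
    stop("breakpoints must lie strictly inside (0, length)")
  edges <- c(0L, bp, N)
  starts <- edges[-length(edges)]
  ends <- edges[-1L]
  freqs <- matrix(0, length(starts), k, dimnames = list(NULL, alphabet))
  for (i in seq_along(starts)) {
    cnt <- cum[ends[i] + 1L, ] - cum[starts[i] + 1L, ]
    freqs[i, ] <- cnt / sum(cnt)
  }
  new("Segmentation",
      domains = data.frame(start = starts, end = ends,
                           length = ends - starts),
      freqs = freqs, f = (cum[N + 1L, ] - cum[1L, ]) / N,
      alphabet = alphabet, s = s, minLen = 1L)
}

#' SCC of a segmentation
#'
#' \eqn{SCC = H(S) - \sum_i (G_i/G) H(S_i)}: whole-sequence entropy minus the
#' length-weighted entropies of the compositional domains. The weighted terms
#' are summed in sorted order so the value is exactly invariant under
#' mirroring of the domain list.
#'
#' @param segmentation a [Segmentation-class].
#' @return SCC in bits.
#' @export
sccFromSegmentation <- function(segmentation) {
  d <- segmentation@domains
  w <- d$length / sum(d$length)
  Hs <- apply(segmentation@freqs, 1L, shannonEntropy)
  shannonEntropy(segmentation@f) - sum(sort(w * Hs))
}

#' Sequence Compositional Complexity of a genome
#'
#' Two-step metric: the genome (after optional recoding to a binary
#' alphabet) is segmented into compositionally homogeneous domains by
#' recursive Jensen-Shannon splitting at significance \code{s}, then SCC is
#' the whole-sequence Shannon entropy minus the length-weighted domain
#' entropies. It grows with the number, length and compositional contrast of
#' the domains, and is zero for a compositionally homogeneous sequence.
#'
#' @param genome a [GenomeRecord-class].
#' @param scheme alphabet scheme: \code{"ACGT"} (4-symbol) or one of the
#'   binary recodings \code{"SW"}, \code{"RY"}, \code{"KM"}.
#' @inheritParams segmentSequence
#' @return an [SccResult-class].
#' @examples
#' g <- makeIidGenome(4000, c(0.4, 0.1, 0.1, 0.4), seed = 1)
#' sccMetric(g, "ACGT")
#' @export
sccMetric <- function(genome, scheme = c("ACGT", "SW", "RY", "KM"),
                      s = 0.95, minLen = 2L) {
  scheme <- match.arg(scheme)
  seq <- genomeSeq(genome)
  alphabet <- DNA_ALPHABET
  if (scheme != "ACGT") {
    seq <- recodeSequence(seq, scheme)
    alphabet <- binaryAlphabet(scheme)
  }
  seg <- segmentSequence(seq, s = s, minLen = minLen, alphabet = alphabet)
  new("SccResult", value = sccFromSegmentation(seg), scheme = scheme,
      segmentation = seg)
}

#' Write a domain map as BED
#'
#' 0-based half-open BED: chrom = record id, name = domain index, score =
#' 1000 times the domain's GC-like fraction (C+G on DNA, the S symbol on the
#' SW alphabet, the first alphabet symbol otherwise), capped at 1000.
#'
#' @param scc an [SccResult-class].
#' @param id chromosome/record identifier for column 1.
#' @param path output BED path.
#' @return invisibly, the BED data.frame.
#' @export
writeDomainsBed <- function(scc, id, path) {
  seg <- scc@segmentation
  a <- seg@alphabet
  gcCols <- if (length(a) == 4L) c("C", "G") else
    if ("S" %in% a) "S" else a[1L]
  gc <- rowSums(seg@freqs[, gcCols, drop = FALSE])
  bed <- data.frame(chrom = id, start = seg@domains$start,
                    end = seg@domains$end,
                    name = seq_len(nrow(seg@domains)),
                    score = pmin(1000L, as.integer(round(1000 * gc))))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(bed)
}
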