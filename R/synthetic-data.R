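#' Generate a domain-structured synthetic genome
#'
#' Concatenates i.i.d. draws from per-domain base compositions, emulating a
#' genome made of homogeneous compositional domains, and returns the
#' generative ground truth alongside: the true breakpoints and the analytic
#' SCC upper bound \eqn{H(\sum w_i f_i) - \sum w_i H(f_i)} (the
#' Jensen-Shannon divergence of the generative mixture), which a perfect
#' segmentation would recover up to sampling noise.
#'
#' @param lengths integer vector of domain lengths (bases).
#' @param compositions list (or 4-column matrix, rows) of base-frequency
#'   vectors over A,C,G,T, one per domain, each summing to 1.
#' @param seed integer seed.
#' @param id record identifier.
#' @return list with \code{genome} ([GenomeRecord-class]),
#'   \code{breakpoints} (0-based internal cut positions) and
#'   \code{sccTruth} (bits).
#' @examples
#' g <- makeDomainGenome(c(500, 500),
#'                       list(c(1, 0, 0, 0), c(0, 0, 0, 1)), seed = 1)
#' g$sccTruth   # 1 bit
#' @export
makeDomainGenome <- function(lengths, compositions, seed, id = "synthetic") {
  if (is.matrix(compositions))
    compositions <- split(compositions, row(compositions))
  if (length(lengths) == 0L) stop("empty domain spec")
  if (length(lengths) != length(compositions))
    stop("one composition per domain required")
  if (any(lengths < 1L)) stop("domain lengths must be >= 1")
  comps <- lapply(compositions, function(f) {
    if (length(f) != 4L || any(f < 0) || abs(sum(f) - 1) > 1e-9)
      stop("compositions must be 4-vectors summing to 1")
    f / sum(f)
  })
  set.seed(seed)
  parts <- mapply(function(L, f) {
    paste(sample(DNA_ALPHABET, L, replace = TRUE, prob = f), collapse = "")
  }, lengths, comps)
  w <- lengths / sum(lengths)
  mix <- Reduce(`+`, mapply(`*`, comps, w, SIMPLIFY = FALSE))
  truth <- shannonEntropy(mix) -
    sum(w * vapply(comps, shannonEntropy, numeric(1)))
  list(genome = new("GenomeRecord", id = id,
                    seq = paste(parts, collapse = ""),
                    G = as.integer(sum(lengths)), nDropped = 0L),
       breakpoints = cumsum(lengths)[-length(lengths)],
       sccTruth = truth)
}

#' Generate an i.i.d. control genome
#'
#' @param length genome length in bases.
#' @param composition base frequencies over A,C,G,T (default uniform).
#' @param seed integer seed.
#' @param id record identifier.
#' @return a [GenomeRecord-class].
#' @export
makeIidGenome <- function(length, composition = rep(0.25, 4), seed,
                          id = "iid") {
  if (length < 1L) stop("length must be >= 1")
  makeDomainGenome(length, list(composition), seed = seed, id = id)$genome
}

#' Generate a pure-birth (Yule) tree
#'
#' @param nTips number of tips, \code{>= 2}.
#' @param birthRate speciation rate.
#' @param seed integer seed.
#' @return rooted binary \code{phylo} with tip labels \code{t1..tn}.
#' @export
yuleTree <- function(nTips, birthRate = 1, seed) {
  if (nTips < 2L) stop("need at least 2 tips")
  set.seed(seed)
  tr <- ape::rphylo(nTips, birth = birthRate, death = 0)
  validateTree(tr)
  tr
}

#' Simulate Brownian motion reflected at a lower wall
#'
#' The passive-trend regime: Brownian increments with reflection at
#' \code{lowerWall}, discretised per branch into 20 equal steps (step length
#' at most 1/20 of the branch). With the wall at \code{-Inf} this reduces to
#' plain Brownian motion. Started at the wall, the tip distribution becomes
#' positively skewed -- diffusion away from a minimum with no per-lineage
#' bias.
#'
#' @inheritParams simulateBM
#' @param lowerWall reflecting lower bound; \code{z0} must not be below it.
#' @param stepsPerEdge discretisation steps per branch (default 20).
#' @return list with named \code{tips} and \code{nodes} vectors.
#' @export
simulateBoundedBM <- function(tree, sigma2 = 1, z0 = 0, lowerWall = -Inf,
                              seed = NULL, stepsPerEdge = 20L) {
  validateTree(tree)
  if (sigma2 <= 0) stop("sigma2 must be > 0")
  if (z0 < lowerWall) stop("z0 must be >= lowerWall")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  tr <- stats::reorder(tree, "cladewise")
  x <- numeric(n + tree$Nnode)
  x[n + 1L] <- z0
  for (i in seq_len(nrow(tr$edge))) {
    v <- x[tr$edge[i, 1L]]
    dt <- tr$edge.length[i] / stepsPerEdge
    inc <- stats::rnorm(stepsPerEdge, 0, sqrt(sigma2 * dt))
    for (s in seq_len(stepsPerEdge)) {
      v <- v + inc[s]
      if (v < lowerWall) v <- 2 * lowerWall - v
    }
    x[tr$edge[i, 2L]] <- v
  }
  list(tips = stats::setNames(x[seq_len(n)], tree$tip.label),
       nodes = stats::setNames(x[(n + 1L):(n + tree$Nnode)],
                               as.character((n + 1L):(n + tree$Nnode))))
}

#' Write genome records to FASTA
#'
#' @param records list of [GenomeRecord-class].
#' @param path output FASTA path.
#' @export
writeGenomeFasta <- function(records, path) {
  set <- Biostrings::DNAStringSet(
    vapply(records, genomeSeq, character(1)))
  names(set) <- vapply(records, function(r) r@id, character(1))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a trait table (with optional ground truth) as TSV
#'
#' @param traits named list of named tip vectors.
#' @param path output TSV path.
#' @export
writeTraitTable <- function(traits, path) {
  ids <- names(traits[[1L]])
  df <- data.frame(id = ids)
  for (nm in names(traits)) df[[nm]] <- as.numeric(traits[[nm]][ids])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
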