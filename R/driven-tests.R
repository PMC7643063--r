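#' D'Agostino skewness test
#'
#' Sample skewness \eqn{g_1 = m_3 / m_2^{3/2}} with D'Agostino's normalising
#' z-transform; a significant positive \eqn{g_1} across the whole clade is
#' the first proof of the minimum test (evidence of a lower wall).
#'
#' @param values numeric vector, \code{n >= 8} (the transform is undefined
#'   below that).
#' @return list with \code{g1}, \code{z} and two-sided \code{P}.
#' @export
skewnessTest <- function(values) {
  x <- values[is.finite(values)]
  n <- length(x)
  if (n < 8L) stop("skewness test needs n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  if (m2 == 0) stop("zero variance")
  g1 <- m3 / m2^1.5
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))
  list(g1 = g1, z = z, P = 2 * stats::pnorm(-abs(z)))
}

#' Chi-square goodness of fit of two counts against equality
#'
#' Pearson goodness-of-fit of the observed pair \code{(a, b)} against equal
#' expectation \code{(a+b)/2} each, 1 degree of freedom, upper-tail p-value,
#' no continuity correction. Used by the minimum test on the counts of
#' clades above versus below the basal value.
#'
#' @param a,b non-negative counts, \code{a + b >= 1}.
#' @return upper-tail p-value.
#' @examples
#' chiSquareGof(139, 40)  # ~1.37e-13
#' @export
chiSquareGof <- function(a, b) {
  if (a < 0 || b < 0 || a + b < 1) stop("need non-negative counts summing >= 1")
  e <- (a + b) / 2
  stat <- (a - e)^2 / e + (b - e)^2 / e
  stats::pchisq(stat, df = 1, lower.tail = FALSE)
}

#' The minimum test (three proofs)
#'
#' Given reconstructed values at every node, takes the designated basal
#' node's value \eqn{x_b} as the putative minimum and asks whether the rest
#' of the clade has moved away from it: (1) D'Agostino skewness of the tip
#' values (a positive skew supports a lower wall); (2) chi-square test of the
#' counts of non-root, non-basal nodes above versus below \eqn{x_b} (ties
#' excluded); (3) pooled-variance Student's t-test comparing
#' \eqn{|x_d - x_b|} between the above and below groups (Welch behind the
#' \code{welch} flag).
#'
#' @param nodeValues node-value table from [ancestralStates()] (or with true
#'   simulated node states).
#' @param basalNode id of the basal node (must not be the root).
#' @param welch use Welch's t instead of pooled-variance Student's t.
#' @return list with \code{g1}, \code{skewP}, \code{nHigher}, \code{nLower},
#'   \code{nTie}, \code{meanAbsHigher}, \code{meanAbsLower}, \code{chisqP},
#'   \code{tP} and \code{xb}.
#' @export
minimumTest <- function(nodeValues, basalNode, welch = FALSE) {
  nv <- nodeValues
  root <- nv$id[is.na(nv$parent)]
  if (length(root) != 1L) stop("node table must have exactly one root")
  if (!basalNode %in% nv$id) stop("unknown basal node id: ", basalNode)
  if (basalNode == root) stop("basal node must not be the root")
  xb <- nv$value[nv$id == basalNode]
  rest <- nv[!(nv$id %in% c(root, basalNode)), ]
  hi <- rest$value > xb
  lo <- rest$value < xb
  if (!any(hi) && !any(lo)) stop("all values tied with the basal value")
  sk <- skewnessTest(nv$value[nv$isTip])
  dHi <- abs(rest$value[hi] - xb)
  dLo <- abs(rest$value[lo] - xb)
  tP <- if (length(dHi) >= 2L && length(dLo) >= 2L)
    stats::t.test(dHi, dLo, var.equal = !welch)$p.value else NA_real_
  list(g1 = sk$g1, skewP = sk$P,
       nHigher = sum(hi), nLower = sum(lo),
       nTie = nrow(rest) - sum(hi) - sum(lo),
       meanAbsHigher = if (any(hi)) mean(dHi) else NA_real_,
       meanAbsLower = if (any(lo)) mean(dLo) else NA_real_,
       chisqP = chiSquareGof(sum(hi), sum(lo)),
       tP = tP, xb = xb)
}

#' The ancestor-descendant test
#'
#' In a passive trend, increases and decreases along parent-to-child edges
#' are equally likely once the analysis is kept away from the wall; in a
#' driven trend increases dominate. Following McShea's recommendation, only
#' edges whose two endpoints both exceed the threshold (by default the mean
#' tip value) are counted. Default significance is the exact two-sided
#' binomial sign test on (up, down); the \code{"fisher"} option tests the
#' observed (up, down) split against a balanced one in a 2x2 table (a
#' non-canonical construction, provided for comparison only).
#'
#' @param tree rooted \code{phylo}.
#' @param nodeValues node-value table covering all nodes.
#' @param threshold wall-avoidance threshold; defaults to the mean of the
#'   tip values.
#' @param test \code{"binomial"} (default) or \code{"fisher"}.
#' @return list with \code{nUp}, \code{nDown}, \code{nTie}, \code{nEdges}
#'   (qualifying edges), \code{threshold} and \code{P}.
#' @export
ancestorDescendantTest <- function(tree, nodeValues, threshold = NULL,
                                   test = c("binomial", "fisher")) {
  test <- match.arg(test)
  validateTree(tree)
  nv <- nodeValues[order(nodeValues$id), ]
  if (is.null(threshold)) threshold <- mean(nv$value[nv$isTip])
  v <- nv$value
  par <- tree$edge[, 1L]
  chi <- tree$edge[, 2L]
  keep <- v[par] > threshold & v[chi] > threshold
  if (!any(keep)) stop("no edges with both endpoints above the threshold")
  dv <- v[chi[keep]] - v[par[keep]]
  up <- sum(dv > 0); down <- sum(dv < 0); tie <- sum(dv == 0)
  P <- if (up + down == 0L) 1 else if (test == "binomial") {
    stats::binom.test(up, up + down, p = 0.5)$p.value
  } else {
    half <- (up + down) / 2
    m <- matrix(c(up, down, ceiling(half), floor(half)), 2L, byrow = TRUE)
    stats::fisher.test(m)$p.value
  }
  list(nUp = up, nDown = down, nTie = tie, nEdges = sum(keep),
       threshold = threshold, P = P)
}

#' Mood's median test
#'
#' Counts values above and below the pooled median in each group and tests
#' association with Fisher's exact test (ties at the median are dropped).
#'
#' @param x,y numeric vectors.
#' @return list with the pooled \code{median}, the 2x2 \code{counts} and
#'   \code{P}.
#' @export
moodMedianTest <- function(x, y) {
  med <- stats::median(c(x, y))
  tab <- rbind(c(sum(x > med), sum(x < med)),
               c(sum(y > med), sum(y < med)))
  P <- if (any(rowSums(tab) == 0L)) 1 else stats::fisher.test(tab)$p.value
  list(median = med, counts = tab, P = P)
}

#' The sub-clade test
#'
#' For each designated monophyletic sub-clade: (1) the root-to-tip trend
#' test re-run inside the sub-tree; (2) Mood's median test of the sub-clade
#' tip values against the whole-clade tip values; (3) the skewness proof,
#' applied only when the sub-clade median significantly exceeds the
#' whole-clade median (the applicability rule for drawing a sub-clade from
#' the right tail).
#'
#' @inheritParams searchTrend
#' @param subcladeRoots internal node ids of the sub-clade roots.
#' @param alpha significance level for the applicability rule.
#' @return data.frame with one row per sub-clade: \code{node}, \code{nTips},
#'   \code{slope}, \code{trendP} (NA with \code{trendSkipped = TRUE} for
#'   sub-clades under 4 tips), \code{moodP}, \code{medianAbove},
#'   \code{skewApplicable}, \code{g1}, \code{skewP}.
#' @export
subcladeTest <- function(tree, trait, subcladeRoots, nSim = 1000L,
                         seed = NULL, alpha = 0.05) {
  validateTree(tree)
  x <- .orderTrait(tree, trait)
  names(x) <- tree$tip.label
  n <- ape::Ntip(tree)
  phylumMedian <- stats::median(x)
  out <- vector("list", length(subcladeRoots))
  for (i in seq_along(subcladeRoots)) {
    node <- subcladeRoots[i]
    if (node <= n) stop("sub-clade root must be an internal node: ", node)
    if (!is.null(seed)) seedI <- seed + i else seedI <- NULL
    sub <- ape::extract.clade(tree, node)
    xs <- x[sub$tip.label]
    skipped <- length(xs) < 4L
    if (!skipped) {
      tr <- searchTrend(sub, xs, nSim = nSim, seed = seedI)
      slope <- tr$slope; trendP <- tr$P
    } else {
      slope <- NA_real_; trendP <- NA_real_
    }
    mood <- moodMedianTest(xs, x)
    above <- stats::median(xs) > phylumMedian
    applicable <- above && mood$P < alpha
    if (applicable && length(xs) >= 8L) {
      sk <- skewnessTest(xs)
      g1 <- sk$g1; skewP <- sk$P
    } else {
      g1 <- NA_real_; skewP <- NA_real_
    }
    out[[i]] <- data.frame(
      node = node, nTips = length(xs), slope = slope, trendP = trendP,
      trendSkipped = skipped, moodP = mood$P, medianAbove = above,
      skewApplicable = applicable, g1 = g1, skewP = skewP)
  }
  do.call(rbind, out)
}

#' Mann-Whitney comparison of two trait groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a trait between two
#' tip groups, e.g. heterocyst-forming versus non-heterocyst-forming taxa.
#'
#' @param trait named numeric vector.
#' @param labels named character/factor vector over the same names with
#'   exactly two levels.
#' @return list with \code{groups}, \code{nPerGroup}, \code{U} and \code{P}.
#' @export
mannWhitneyGroups <- function(trait, labels) {
  labels <- labels[names(trait)]
  if (anyNA(labels)) stop("labels must cover every trait name")
  lev <- unique(as.character(labels))
  if (length(lev) != 2L) stop("exactly two groups required")
  g1 <- trait[labels == lev[1L]]
  g2 <- trait[labels == lev[2L]]
  if (!length(g1) || !length(g2)) stop("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(g1, g2))
  list(groups = lev,
       nPerGroup = c(length(g1), length(g2)),
       U = unname(wt$statistic), P = wt$p.value)
}

# sign-code one p-value with a direction: "+", "-" or "0"
.signCode <- function(P, positive, alpha = 0.05) {
  if (is.na(P) || P >= alpha) "0" else if (positive) "+" else "-"
}

#' Summarise all trend evidence for one metric
#'
#' Collapses the component tests into the +/-/0 grid: phylogenetic signal,
#' general trend, the three minimum-test proofs, the ancestor-descendant
#' test, and the tally of sub-clade trend signs. Coding is purely
#' deterministic from the component p-values at \code{alpha}.
#'
#' @param signal output of [blombergK()].
#' @param trend output of [searchTrend()].
#' @param minimum output of [minimumTest()].
#' @param ancDesc output of [ancestorDescendantTest()].
#' @param subclades output of [subcladeTest()] or NULL.
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame with sign columns \code{K}, \code{trend},
#'   \code{skewness}, \code{chisq}, \code{ttest}, \code{ancDesc} and the
#'   sub-clade tallies \code{sub_plus}, \code{sub_minus}, \code{sub_zero}.
#' @export
drivenTrendSummary <- function(signal, trend, minimum, ancDesc,
                               subclades = NULL, alpha = 0.05) {
  kSign <- .signCode(signal$P, TRUE, alpha)
  trendSign <- .signCode(trend$P, trend$slope > 0, alpha)
  skewSign <- .signCode(minimum$skewP, minimum$g1 > 0, alpha)
  chiSign <- .signCode(minimum$chisqP, minimum$nHigher > minimum$nLower,
                       alpha)
  tSign <- if (is.na(minimum$tP)) "0" else
    .signCode(minimum$tP, minimum$meanAbsHigher > minimum$meanAbsLower,
              alpha)
  adSign <- .signCode(ancDesc$P, ancDesc$nUp > ancDesc$nDown, alpha)
  if (!is.null(subclades)) {
    signs <- mapply(.signCode, subclades$trendP, subclades$slope > 0,
                    MoreArgs = list(alpha = alpha))
    signs[subclades$trendSkipped] <- "0"
  } else signs <- character(0)
  data.frame(K = kSign, trend = trendSign, skewness = skewSign,
             chisq = chiSign, ttest = tSign, ancDesc = adSign,
             sub_plus = sum(signs == "+"), sub_minus = sum(signs == "-"),
             sub_zero = sum(signs == "0"))
}
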