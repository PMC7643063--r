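#' Read a rooted tree with branch lengths
#'
#' @param path newick file path.
#' @return an \code{ape::phylo} object, validated rooted with complete
#'   non-negative branch lengths.
#' @export
readRootedTree <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse newick file: ", path)
  validateTree(tr)
  tr
}

validateTree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object")
  # a basal multifurcation (e.g. a star tree) is treated as rooted at the
  # basal node; what must be unique is the root itself
  nTotal <- ape::Ntip(tree) + tree$Nnode
  roots <- setdiff(seq_len(nTotal), tree$edge[, 2L])
  if (length(roots) != 1L) stop("tree must have exactly one root")
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (anyNA(tree$edge.length) || any(tree$edge.length < 0))
    stop("branch lengths must be non-negative and complete")
  if (anyDuplicated(tree$tip.label)) stop("tip labels must be unique")
  invisible(tree)
}

#' Root-to-node distances
#'
#' Summed branch lengths from the root to every tip and internal node (the
#' "evolutionary age" axis of the trend regression). The root has depth 0.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @return named numeric vector over tips (by label) then internal nodes (by
#'   ape node number).
#' @export
nodeDepths <- function(tree) {
  validateTree(tree)
  d <- ape::node.depth.edgelength(tree)
  n <- ape::Ntip(tree)
  names(d) <- c(tree$tip.label,
                as.character((n + 1L):(n + tree$Nnode)))
  d
}

#' Phylogenetic variance-covariance matrix
#'
#' \code{C[i, j]} is the shared root-to-MRCA path length of nodes i and j;
#' the diagonal holds root-to-node depths. Under Brownian motion this is the
#' trait covariance implied by the tree.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param nodes include internal nodes (default FALSE: tips only).
#' @return symmetric positive semi-definite matrix.
#' @export
phyloVcv <- function(tree, nodes = FALSE) {
  validateTree(tree)
  if (!nodes) return(ape::vcv(tree))
  d <- ape::node.depth.edgelength(tree)
  M <- ape::mrca(tree, full = TRUE)
  C <- matrix(d[M], nrow(M), ncol(M))
  n <- ape::Ntip(tree)
  ids <- c(tree$tip.label, as.character((n + 1L):(n + tree$Nnode)))
  dimnames(C) <- list(ids, ids)
  C
}

# inverse via Cholesky, retrying once with a small jitter
.safeInv <- function(C) {
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) ch <- chol(C + diag(1e-10, nrow(C)))
  chol2inv(ch)
}

.orderTrait <- function(tree, trait) {
  if (is.null(names(trait))) stop("trait vector must be named by tip label")
  missing <- setdiff(tree$tip.label, names(trait))
  if (length(missing))
    stop("trait missing for tips: ", paste(missing, collapse = ", "))
  as.numeric(trait[tree$tip.label])
}

#' Blomberg's K phylogenetic signal
#'
#' \eqn{K} compares the observed ratio of the non-phylogenetic to the
#' phylogenetic mean squared error of the trait around its GLS mean with the
#' ratio expected under Brownian motion on the same tree; \eqn{K = 1} is the
#' Brownian expectation, larger values mean relatives resemble each other
#' more than Brownian motion predicts. Significance comes from permuting
#' trait values across tips: the p-value is the one-tailed rank of the
#' observed phylogenetic MSE among the permuted ones, with the
#' \eqn{(x+1)/(n+1)} estimator so 0 is never reported.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param trait named numeric vector covering every tip.
#' @param nPerm number of tip-label permutations (default 999).
#' @param seed optional integer seed for the permutations.
#' @return list with \code{K}, \code{P} and \code{nPerm}.
#' @export
blombergK <- function(tree, trait, nPerm = 999L, seed = NULL) {
  validateTree(tree)
  x <- .orderTrait(tree, trait)
  n <- length(x)
  if (stats::sd(x) == 0) stop("constant trait: K undefined")
  if (nPerm < 99L) stop("nPerm must be >= 99")
  C <- ape::vcv(tree)
  Cinv <- .safeInv(C)
  Cinv1 <- rowSums(Cinv)
  sC <- sum(Cinv1)
  mseRatio <- function(v) {
    a <- sum(Cinv1 * v) / sC
    e <- v - a
    mse0 <- sum(e * e) / (n - 1)
    mse <- as.numeric(e %*% Cinv %*% e) / (n - 1)
    c(mse0 / mse, mse)
  }
  obs <- mseRatio(x)
  expected <- (sum(diag(C)) - n / sC) / (n - 1)
  K <- obs[1L] / expected
  if (!is.null(seed)) set.seed(seed)
  msePerm <- vapply(seq_len(nPerm),
                    function(i) mseRatio(sample(x))[2L], numeric(1))
  P <- (sum(msePerm <= obs[2L]) + 1) / (nPerm + 1)
  list(K = K, P = P, nPerm = as.integer(nPerm))
}

#' Phylogenetic Pearson correlation
#'
#' GLS-centred cross-covariance of two tip traits under the Brownian
#' covariance \code{C}, normalised to a correlation; significance against a
#' t-distribution with \code{n - 2} degrees of freedom (two-sided). On a
#' star tree with unit branches this reduces to the ordinary Pearson
#' correlation.
#'
#' @inheritParams blombergK
#' @param x,y named numeric tip vectors.
#' @return list with \code{r}, \code{t}, \code{df} and \code{P}.
#' @export
phyloCorrelation <- function(tree, x, y) {
  validateTree(tree)
  vx <- .orderTrait(tree, x)
  vy <- .orderTrait(tree, y)
  n <- length(vx)
  C <- ape::vcv(tree)
  Cinv <- .safeInv(C)
  Cinv1 <- rowSums(Cinv)
  sC <- sum(Cinv1)
  ex <- vx - sum(Cinv1 * vx) / sC
  ey <- vy - sum(Cinv1 * vy) / sC
  sxx <- as.numeric(ex %*% Cinv %*% ex)
  syy <- as.numeric(ey %*% Cinv %*% ey)
  if (sxx <= 0 || syy <= 0) stop("zero phylogenetic variance")
  r <- as.numeric(ex %*% Cinv %*% ey) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  tval <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  P <- 2 * stats::pt(-abs(tval), n - 2)
  list(r = r, t = tval, df = n - 2L, P = P)
}

#' All pairwise phylogenetic correlations with FDR control
#'
#' @inheritParams blombergK
#' @param traits data.frame or matrix of tip traits (rows named by tip, or
#'   with an \code{id} column).
#' @return list with matrices \code{r}, \code{P} and \code{Padj}
#'   (Benjamini-Hochberg across all pairs).
#' @export
phyloCorrelationMatrix <- function(tree, traits) {
  traits <- as.data.frame(traits)
  if ("id" %in% names(traits)) {
    rownames(traits) <- traits$id
    traits$id <- NULL
  }
  vars <- names(traits)
  p <- length(vars)
  r <- P <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  diag(r) <- 1
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    xi <- stats::setNames(traits[[i]], rownames(traits))
    yj <- stats::setNames(traits[[j]], rownames(traits))
    res <- phyloCorrelation(tree, xi, yj)
    r[i, j] <- r[j, i] <- res$r
    P[i, j] <- P[j, i] <- res$P
  }
  raw <- P[upper.tri(P)]
  adj <- stats::p.adjust(raw, method = "BH")
  Padj <- P
  Padj[upper.tri(Padj)] <- adj
  Padj[lower.tri(Padj)] <- t(Padj)[lower.tri(Padj)]
  list(r = r, P = P, Padj = Padj)
}

# linear operator mapping tip values to ML/BM values at every node
# (tips first, internal nodes after, in ape numbering); the root row is the
# GLS-mean weight vector
.ancOperator <- function(tree) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  Cfull <- phyloVcv(tree, nodes = TRUE)
  Ct <- Cfull[seq_len(n), seq_len(n)]
  Cint <- Cfull[n + seq_len(m), seq_len(n), drop = FALSE]
  Cinv <- .safeInv(Ct)
  Cinv1 <- rowSums(Cinv)
  g <- Cinv1 / sum(Cinv1)
  Aint <- matrix(g, m, n, byrow = TRUE) +
    Cint %*% Cinv %*% (diag(n) - matrix(g, n, n, byrow = TRUE))
  M <- rbind(diag(n), Aint)
  rownames(M) <- c(tree$tip.label, as.character(n + seq_len(m)))
  M
}

.parentOf <- function(tree) {
  n <- ape::Ntip(tree)
  parent <- rep(NA_integer_, n + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  parent
}

# assemble the per-node table: id, label, value, root distance, tip flag,
# parent id
.nodeTable <- function(tree, values) {
  n <- ape::Ntip(tree)
  total <- n + tree$Nnode
  stopifnot(length(values) == total)
  data.frame(
    id = seq_len(total),
    label = c(tree$tip.label, as.character(n + seq_len(tree$Nnode))),
    value = as.numeric(values),
    depth = as.numeric(ape::node.depth.edgelength(tree)),
    isTip = seq_len(total) <= n,
    parent = .parentOf(tree))
}

# ridge reconstruction: per-edge evolutionary rates with an L2 penalty,
# lambda picked by leave-one-tip-out cross-validation on a log grid
.ridgeAncestral <- function(tree, x, lambda = NULL) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  nE <- nrow(tree$edge)
  tr <- stats::reorder(tree, "cladewise")
  Pfull <- matrix(0, n + m, nE)
  for (i in seq_len(nE)) {
    par <- tr$edge[i, 1L]; chi <- tr$edge[i, 2L]
    Pfull[chi, ] <- Pfull[par, ]
    Pfull[chi, i] <- tr$edge.length[i]
  }
  Ct <- ape::vcv(tree)
  Cinv1 <- rowSums(.safeInv(Ct))
  ahat <- sum(Cinv1 * x) / sum(Cinv1)
  y <- x - ahat
  Ptip <- Pfull[seq_len(n), , drop = FALSE]
  PtP <- crossprod(Ptip)
  scale <- mean(diag(PtP))
  if (is.null(lambda)) {
    grid <- scale * 10^seq(-6, 3, length.out = 19)
    cv <- vapply(grid, function(l) {
      H <- Ptip %*% solve(PtP + diag(l, nE), t(Ptip))
      res <- (y - H %*% y) / pmin(1 - diag(H), 1 - 1e-10)
      mean(res^2)
    }, numeric(1))
    lambda <- grid[which.min(cv)]
  }
  beta <- solve(PtP + diag(lambda, nE), crossprod(Ptip, y))
  list(values = as.numeric(ahat + Pfull %*% beta), lambda = lambda,
       rates = as.numeric(beta), rootValue = ahat)
}

#' Ancestral state estimation for a continuous trait
#'
#' \code{method = "ml_bm"}: maximum-likelihood states under Brownian motion,
#' i.e. the GLS conditional expectation of each internal node given the tips
#' (the root estimate is the GLS mean). \code{method = "ridge"}: a
#' rate-penalised variant that fits one evolutionary rate per branch with an
#' L2 penalty (chosen by leave-one-tip-out cross-validation) and accumulates
#' rates along root-to-node paths.
#'
#' @inheritParams blombergK
#' @param method \code{"ml_bm"} (default) or \code{"ridge"}.
#' @return data.frame (node-value table) with columns \code{id},
#'   \code{label}, \code{value}, \code{depth}, \code{isTip}, \code{parent};
#'   attribute \code{rootValue} holds the root estimate.
#' @export
ancestralStates <- function(tree, trait, method = c("ml_bm", "ridge")) {
  method <- match.arg(method)
  validateTree(tree)
  x <- .orderTrait(tree, trait)
  if (method == "ml_bm") {
    M <- .ancOperator(tree)
    vals <- as.numeric(M %*% x)
  } else {
    vals <- .ridgeAncestral(tree, x)$values
  }
  out <- .nodeTable(tree, vals)
  attr(out, "rootValue") <- vals[ape::Ntip(tree) + 1L]
  out
}

#' Linear interpolation of node states along edges
#'
#' @param tree rooted \code{phylo}.
#' @param nodeValues node-value table as returned by [ancestralStates()].
#' @param nPoints number of segments per edge; \code{nPoints = 1} returns
#'   the endpoints only.
#' @return data.frame with one row per interpolation point: \code{edge},
#'   \code{parent}, \code{child}, \code{fraction}, \code{position} (absolute
#'   root distance) and \code{value}.
#' @export
interpolateEdgeStates <- function(tree, nodeValues, nPoints = 10L) {
  validateTree(tree)
  v <- nodeValues$value[order(nodeValues$id)]
  d <- ape::node.depth.edgelength(tree)
  out <- vector("list", nrow(tree$edge))
  fr <- seq(0, 1, length.out = nPoints + 1L)
  for (i in seq_len(nrow(tree$edge))) {
    par <- tree$edge[i, 1L]; chi <- tree$edge[i, 2L]
    len <- tree$edge.length[i]
    out[[i]] <- data.frame(
      edge = i, parent = par, child = chi, fraction = fr,
      position = d[par] + fr * len,
      value = v[par] + fr * (v[chi] - v[par]))
  }
  do.call(rbind, out)
}

#' Simulate Brownian trait evolution on a tree
#'
#' Each branch of length \code{t} adds an independent
#' \eqn{Normal(\mu t, \sigma^2 t)} increment; \code{mu = 0} is plain (null)
#' Brownian motion, \code{mu != 0} a directional drift (driven regime).
#'
#' @inheritParams blombergK
#' @param sigma2 Brownian rate (variance per unit branch length), \code{>= 0}.
#' @param z0 root state.
#' @param mu drift per unit branch length.
#' @param seed optional integer seed.
#' @param internal also return internal-node states.
#' @return named tip vector, or (with \code{internal = TRUE}) a list with
#'   \code{tips} and \code{nodes}.
#' @export
simulateBM <- function(tree, sigma2 = 1, z0 = 0, mu = 0, seed = NULL,
                       internal = FALSE) {
  validateTree(tree)
  if (sigma2 < 0) stop("sigma2 must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- ape::Ntip(tree)
  tr <- stats::reorder(tree, "cladewise")
  x <- numeric(n + tree$Nnode)
  x[n + 1L] <- z0
  len <- tr$edge.length
  inc <- mu * len + sqrt(sigma2 * len) * stats::rnorm(length(len))
  for (i in seq_along(len)) x[tr$edge[i, 2L]] <- x[tr$edge[i, 1L]] + inc[i]
  tips <- stats::setNames(x[seq_len(n)], tree$tip.label)
  if (!internal) return(tips)
  list(tips = tips,
       nodes = stats::setNames(x[(n + 1L):(n + tree$Nnode)],
                               as.character((n + 1L):(n + tree$Nnode))))
}

#' Root-to-tip evolutionary trend test
#'
#' Reconstructs internal-node states from the tip trait, regresses all tip
#' and node values on their root distance, and calibrates the slope against
#' \code{nSim} no-trend Brownian simulations re-analysed identically (same
#' reconstruction, same regression), with the Brownian rate estimated from
#' the observed tips by GLS. The two-sided p-value is the
#' \eqn{(x+1)/(n+1)} rank of the absolute observed slope among the absolute
#' null slopes.
#'
#' Because the reconstruction is a fixed linear operator for a given tree,
#' each null slope is a linear functional of a multivariate normal draw, so
#' the whole null distribution is computed as one matrix product.
#'
#' @inheritParams blombergK
#' @param nSim number of Brownian null simulations (default 10000).
#' @param method ancestral reconstruction passed to [ancestralStates()].
#' @return list with \code{slope}, \code{P}, \code{nSim}, \code{sigma2},
#'   \code{method} and \code{nodeValues} (the node-value table used).
#' @export
searchTrend <- function(tree, trait, nSim = 10000L, seed = NULL,
                        method = c("ml_bm", "ridge")) {
  method <- match.arg(method)
  validateTree(tree)
  if (nSim < 100L) stop("nSim must be >= 100")
  x <- .orderTrait(tree, trait)
  n <- length(x)
  if (n < 4L) stop("need at least 4 tips")

  if (method == "ml_bm") {
    M <- .ancOperator(tree)
  } else {
    rf <- .ridgeAncestral(tree, x)
    # freeze lambda at the observed fit so the null re-analysis is the same
    # linear operator applied to simulated tips
    M <- .ridgeOperator(tree, rf$lambda)
  }
  d <- as.numeric(ape::node.depth.edgelength(tree))
  u <- d - mean(d)
  w <- u / sum(u * u)
  svec <- as.numeric(crossprod(M, w))      # slope = svec . tips
  obs <- sum(svec * x)

  C <- ape::vcv(tree)
  Cinv <- .safeInv(C)
  Cinv1 <- rowSums(Cinv)
  ahat <- sum(Cinv1 * x) / sum(Cinv1)
  e <- x - ahat
  sigma2 <- max(as.numeric(e %*% Cinv %*% e) / (n - 1),
                .Machine$double.eps)

  if (!is.null(seed)) set.seed(seed)
  R <- chol(C)                              # C = t(R) R
  proj <- as.numeric(svec %*% t(R))         # slope = sqrt(s2) proj . z
  Z <- matrix(stats::rnorm(n * nSim), n, nSim)
  nullSlopes <- sqrt(sigma2) * as.numeric(proj %*% Z)
  P <- (sum(abs(nullSlopes) >= abs(obs)) + 1) / (nSim + 1)

  vals <- as.numeric(M %*% x)
  list(slope = obs, P = P, nSim = as.integer(nSim), sigma2 = sigma2,
       method = method, nodeValues = .nodeTable(tree, vals))
}

# linear operator version of the ridge reconstruction at fixed lambda
.ridgeOperator <- function(tree, lambda) {
  n <- ape::Ntip(tree)
  m <- tree$Nnode
  nE <- nrow(tree$edge)
  tr <- stats::reorder(tree, "cladewise")
  Pfull <- matrix(0, n + m, nE)
  for (i in seq_len(nE)) {
    par <- tr$edge[i, 1L]; chi <- tr$edge[i, 2L]
    Pfull[chi, ] <- Pfull[par, ]
    Pfull[chi, i] <- tr$edge.length[i]
  }
  Ptip <- Pfull[seq_len(n), , drop = FALSE]
  Cinv1 <- rowSums(.safeInv(ape::vcv(tree)))
  g <- Cinv1 / sum(Cinv1)
  B <- solve(crossprod(Ptip) + diag(lambda, nE), t(Ptip))
  center <- diag(n) - matrix(g, n, n, byrow = TRUE)
  M <- matrix(g, n + m, n, byrow = TRUE) + Pfull %*% B %*% center
  rownames(M) <- c(tree$tip.label, as.character(n + seq_len(m)))
  M
}
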