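# Independent brute-force oracles used across the suite. These deliberately
# share nothing with the package's optimized code paths: entropies from raw
# string splits, k-mer counts from a dictionary, segmentation by naive
# recursive scanning over character vectors.

oracle_entropy <- function(symbols, alphabet) {
  f <- table(factor(symbols, levels = alphabet)) / length(symbols)
  f <- f[f > 0]
  -sum(f * log2(f))
}

# naive scan of every cut point of a character vector
oracle_best_cut <- function(sym, alphabet, min_len) {
  N <- length(sym)
  if (N < 2 * min_len) return(NULL)
  best <- list(jsd = -Inf)
  for (p in min_len:(N - min_len)) {
    l <- sym[1:p]; r <- sym[(p + 1):N]
    jsd <- oracle_entropy(sym, alphabet) -
      (p / N) * oracle_entropy(l, alphabet) -
      ((N - p) / N) * oracle_entropy(r, alphabet)
    if (jsd > best$jsd) best <- list(pos = p, jsd = jsd)
  }
  best$stat <- 2 * N * log(2) * best$jsd
  best
}

# exhaustive recursive segmentation with the same acceptance rule (the
# calibrated null is a shared design constant; what this oracle checks
# independently is the scanning, tie-breaking and recursion)
oracle_segment <- function(seq, s, min_len, alphabet) {
  sym <- strsplit(seq, "", fixed = TRUE)[[1]]
  recurse <- function(lo, hi) {       # 0-based half-open
    cut <- oracle_best_cut(sym[(lo + 1):hi], alphabet, min_len)
    if (is.null(cut)) return(integer(0))
    sig <- SeqCompTrends:::.jsdSignificance(cut$stat, hi - lo,
                                            length(alphabet) - 1)
    if (sig < s) return(integer(0))
    p <- lo + cut$pos
    c(recurse(lo, p), p, recurse(p, hi))
  }
  bp <- recurse(0, length(sym))
  c(0, bp, length(sym))
}

oracle_kmer_counts <- function(seq, k) {
  n <- nchar(seq) - k + 1
  words <- substring(seq, 1:n, k:nchar(seq))
  tab <- table(words)
  out <- stats::setNames(integer(length(tab)), names(tab))
  out[] <- as.integer(tab)
  out
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mw_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  r <- rank(pooled)
  u_of <- function(i) sum(r[i]) - n * (n + 1) / 2
  u_all <- apply(idx, 2, u_of)
  u_obs <- u_of(seq_len(n))
  p <- 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs))
  min(1, p)
}

# shared-path-length VCV by explicit root-to-tip edge enumeration
oracle_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  paths <- lapply(seq_len(n), function(tip) {
    edges <- integer(0)
    node <- tip
    repeat {
      e <- which(tree$edge[, 2] == node)
      if (!length(e)) break
      edges <- c(edges, e)
      node <- tree$edge[e, 1]
    }
    edges
  })
  C <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in seq_len(n))
    C[i, j] <- sum(tree$edge.length[intersect(paths[[i]], paths[[j]])])
  C
}

# GLS quantities for Blomberg's K spelled out with solve() and explicit sums
oracle_k_gls <- function(C, x) {
  n <- length(x)
  Ci <- solve(C)
  one <- rep(1, n)
  a <- as.numeric(t(one) %*% Ci %*% x) / as.numeric(t(one) %*% Ci %*% one)
  mse0 <- sum((x - a)^2) / (n - 1)
  mse <- as.numeric(t(x - a) %*% Ci %*% (x - a)) / (n - 1)
  expct <- (sum(diag(C)) - n / as.numeric(t(one) %*% Ci %*% one)) / (n - 1)
  (mse0 / mse) / expct
}

# fixtures -------------------------------------------------------------------

fixture_tree_nonultra <- function(n = 64, seed = 77) {
  set.seed(seed)
  ape::rtree(n)
}

node_table_from_sim <- function(tree, sim) {
  SeqCompTrends:::.nodeTable(tree, c(unname(sim$tips), unname(sim$nodes)))
}

gc_composition <- function(gc) c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)

# end-to-end scenario: genomes whose GC structure drifts with the tree,
# small enough to run the full report stack quickly
make_scenario <- function(dir, nTips = 16, seed = 900) {
  tr <- yuleTree(nTips, seed = seed)
  depths <- nodeDepths(tr)[tr$tip.label]
  rel <- depths / max(depths)
  for (i in seq_len(nTips)) {
    tip <- tr$tip.label[i]
    gcA <- 0.35 + 0.1 * rel[i]
    g <- makeDomainGenome(c(1500, 1500),
                          lapply(c(gcA, gcA + 0.2), gc_composition),
                          seed = seed + i, id = tip)
    writeGenomeFasta(list(g$genome), file.path(dir, paste0(tip, ".fa")))
  }
  tr
}
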