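#' Pipeline configuration
#'
#' Collects every tunable parameter of the pipeline with its default. Each
#' stochastic stage draws its seed deterministically from the single
#' \code{seed} given here.
#'
#' @param seed integer master seed (mandatory).
#' @param s segmentation significance level.
#' @param minLen minimum domain length for segmentation.
#' @param gsKRange word-length range for the Genomic Signature.
#' @param nPerm permutations for the phylogenetic signal.
#' @param nSim Brownian simulations for the trend test.
#' @param alpha significance level for sign coding.
#' @param basalTip tip label designating the basal lineage; the basal node
#'   of the minimum test is the root child ancestral to it. Defaults to the
#'   smaller root subtree.
#' @param subcladeRoots internal node ids for the sub-clade test (optional).
#' @return a validated config list.
#' @export
pipelineConfig <- function(seed, s = 0.95, minLen = 2L, gsKRange = 1:8,
                           nPerm = 999L, nSim = 10000L, alpha = 0.05,
                           basalTip = NULL, subcladeRoots = NULL) {
  if (missing(seed) || !is.numeric(seed))
    stop("an integer master seed is mandatory")
  if (s <= 0 || s >= 1) stop("'s' must lie in (0,1)")
  list(seed = as.integer(seed), s = s, minLen = as.integer(minLen),
       gsKRange = as.integer(gsKRange), nPerm = as.integer(nPerm),
       nSim = as.integer(nSim), alpha = alpha, basalTip = basalTip,
       subcladeRoots = subcladeRoots)
}

#' Compute the complexity profile of a set of genomes
#'
#' Runs all six sequence-complexity metrics plus the standard genome
#' parameters on each genome. This stage is independent of any tree and its
#' output can be cached and fed back to [runPipeline()].
#'
#' @param genomes named list of [GenomeRecord-class] (names become ids).
#' @param s,minLen segmentation parameters (see [sccMetric()]).
#' @param gsKRange Genomic Signature word-length range.
#' @param geneCounts optional named integer vector of gene counts.
#' @param bedDir optional directory: 4-symbol domain maps are written there
#'   as one BED per genome.
#' @return a [ComplexityProfile-class].
#' @export
computeComplexityProfile <- function(genomes, s = 0.95, minLen = 2L,
                                     gsKRange = 1:8, geneCounts = NULL,
                                     bedDir = NULL) {
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g@id, character(1))
  rows <- lapply(names(genomes), function(id) {
    g <- genomes[[id]]
    sccs <- lapply(c(ACGT = "ACGT", SW = "SW", RY = "RY", KM = "KM"),
                   function(sc) sccMetric(g, sc, s = s, minLen = minLen))
    if (!is.null(bedDir))
      writeDomainsBed(sccs$ACGT, id, file.path(bedDir, paste0(id, ".bed")))
    data.frame(id = id,
               SCC = sccValue(sccs$ACGT), SCC_SW = sccValue(sccs$SW),
               SCC_RY = sccValue(sccs$RY), SCC_KM = sccValue(sccs$KM),
               BB = biobit(g)$BB,
               GS = genomicSignature(g, gsKRange)$GS,
               genome_size = genomeLength(g), pct_gc = percentGC(g))
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(geneCounts)) tab$n_genes <- as.numeric(geneCounts[tab$id])
  new("ComplexityProfile", table = tab,
      params = list(s = s, minLen = as.integer(minLen),
                    gsKRange = as.integer(gsKRange)))
}

# the root child on the designated basal lineage (or the smaller root
# subtree when no tip is designated)
.basalNode <- function(tree, basalTip = NULL) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  children <- tree$edge[tree$edge[, 1L] == root, 2L]
  if (!is.null(basalTip)) {
    if (!basalTip %in% tree$tip.label) stop("unknown basal tip: ", basalTip)
    tip <- match(basalTip, tree$tip.label)
    node <- tip
    parent <- .parentOf(tree)
    while (!is.na(parent[node]) && parent[node] != root) node <- parent[node]
    return(node)
  }
  sizes <- vapply(children, function(ch) {
    if (ch <= n) 1L else length(ape::extract.clade(tree, ch)$tip.label)
  }, integer(1))
  children[which.min(sizes)]
}

.readProfileInput <- function(profile) {
  if (is.character(profile)) profile <- utils::read.delim(profile)
  if (is(profile, "ComplexityProfile")) profile <- profileTable(profile)
  profile
}

#' Run the full complexity-trend pipeline
#'
#' Genomes to metrics table to phylogenetic tests to driven-trend report:
#' (1) complexity profile, (2) phylogenetic signal table, (3) FDR-corrected
#' phylogenetic correlation matrix, (4) trend table per metric, (5) minimum
#' and ancestor-descendant (and optionally sub-clade) reports, (6) the
#' +/-/0 summary grid, (7) a machine-readable JSON bundle, (8) a run log
#' with versions, seeds and parameters. All stages are deterministic under
#' the config seed.
#'
#' @param tree rooted \code{phylo} or newick path.
#' @param genomeDir directory of per-tip FASTA files (\code{<tip>.fa[sta]});
#'   multi-record files are concatenated in file order. Ignored when
#'   \code{profile} is given.
#' @param profile optional precomputed profile (TSV path, data.frame or
#'   [ComplexityProfile-class]); lets stages 2-6 rerun without the genomes.
#' @param config list from [pipelineConfig()].
#' @param outDir output directory (created if needed).
#' @return invisibly, the report bundle (list).
#' @export
runPipeline <- function(tree, genomeDir = NULL, profile = NULL, config,
                        outDir) {
  if (is.character(tree)) tree <- readRootedTree(tree)
  validateTree(tree)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(profile)) {
    if (is.null(genomeDir)) stop("need either 'genomeDir' or 'profile'")
    files <- list.files(genomeDir, pattern = "\\.(fa|fasta|fna)$",
                        full.names = TRUE)
    ids <- sub("\\.(fa|fasta|fna)$", "", basename(files))
    missing <- setdiff(tree$tip.label, ids)
    extra <- setdiff(ids, tree$tip.label)
    if (length(missing) || length(extra))
      stop("tip/genome mismatch; missing genomes: [",
           paste(missing, collapse = ", "), "]; unmatched files: [",
           paste(extra, collapse = ", "), "]")
    genomes <- lapply(files, function(f)
      concatGenomeRecords(readGenomeFasta(f)))
    names(genomes) <- ids
    bedDir <- file.path(outDir, "domains")
    dir.create(bedDir, showWarnings = FALSE)
    prof <- computeComplexityProfile(genomes, s = config$s,
                                     minLen = config$minLen,
                                     gsKRange = config$gsKRange,
                                     bedDir = bedDir)
    tab <- profileTable(prof)
  } else {
    tab <- .readProfileInput(profile)
    missing <- setdiff(tree$tip.label, tab$id)
    if (length(missing))
      stop("profile missing rows for tips: ",
           paste(missing, collapse = ", "))
  }
  utils::write.table(tab, file.path(outDir, "profile.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  metrics <- setdiff(names(tab), "id")
  constant <- metrics[vapply(metrics,
                             function(m) stats::sd(tab[[m]]) == 0,
                             logical(1))]
  metrics <- setdiff(metrics, constant)
  if (!length(metrics))
    stop("every metric column is constant across genomes")
  basal <- .basalNode(tree, config$basalTip)
  signal <- list(); trend <- list(); minimum <- list(); ancdesc <- list()
  subclades <- list(); grid <- list()
  for (i in seq_along(metrics)) {
    m <- metrics[i]
    v <- stats::setNames(tab[[m]], tab$id)
    signal[[m]] <- blombergK(tree, v, nPerm = config$nPerm,
                             seed = config$seed + 1000L + i)
    trend[[m]] <- searchTrend(tree, v, nSim = config$nSim,
                              seed = config$seed + 2000L + i)
    minimum[[m]] <- minimumTest(trend[[m]]$nodeValues, basal)
    ancdesc[[m]] <- ancestorDescendantTest(tree, trend[[m]]$nodeValues)
    if (!is.null(config$subcladeRoots))
      subclades[[m]] <- subcladeTest(tree, v, config$subcladeRoots,
                                     nSim = max(100L, config$nSim %/% 10L),
                                     seed = config$seed + 3000L + i,
                                     alpha = config$alpha)
    grid[[m]] <- drivenTrendSummary(signal[[m]], trend[[m]], minimum[[m]],
                                    ancdesc[[m]],
                                    if (length(subclades)) subclades[[m]],
                                    alpha = config$alpha)
  }

  signalTab <- data.frame(metric = metrics,
                          K = vapply(signal, `[[`, numeric(1), "K"),
                          P = vapply(signal, `[[`, numeric(1), "P"))
  trendTab <- data.frame(metric = metrics,
                         slope = vapply(trend, `[[`, numeric(1), "slope"),
                         P = vapply(trend, `[[`, numeric(1), "P"))
  minTab <- cbind(metric = metrics,
                  do.call(rbind, lapply(minimum, as.data.frame)))
  adTab <- cbind(metric = metrics,
                 do.call(rbind, lapply(ancdesc, as.data.frame)))
  gridTab <- cbind(metric = metrics, do.call(rbind, grid))
  rownames(signalTab) <- rownames(trendTab) <- rownames(minTab) <-
    rownames(adTab) <- rownames(gridTab) <- NULL
  corr <- phyloCorrelationMatrix(tree, tab[c("id", metrics)])

  wt <- function(x, f) utils::write.table(
    x, file.path(outDir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(signalTab, "signal.tsv")
  wt(trendTab, "trends.tsv")
  wt(minTab, "minimum_test.tsv")
  wt(adTab, "ancestor_descendant.tsv")
  wt(gridTab, "summary_grid.tsv")
  starred <- matrix(paste0(signif(corr$r, 3),
                           ifelse(is.na(corr$Padj), "",
                                  ifelse(corr$Padj < 0.001, "***",
                                  ifelse(corr$Padj < 0.01, "**",
                                  ifelse(corr$Padj < 0.05, "*", "^ns^"))))),
                    nrow(corr$r), dimnames = dimnames(corr$r))
  utils::write.table(starred, file.path(outDir, "correlations.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (length(subclades)) {
    subTab <- do.call(rbind, mapply(function(m, d) cbind(metric = m, d),
                                    names(subclades), subclades,
                                    SIMPLIFY = FALSE))
    rownames(subTab) <- NULL
    wt(subTab, "subclades.tsv")
  }

  bundle <- list(
    config = config[!vapply(config, is.null, logical(1))],
    profile = tab, signal = signalTab,
    correlations = list(r = corr$r, P = corr$P, Padj = corr$Padj),
    trends = trendTab, minimum_test = minTab,
    ancestor_descendant = adTab,
    subclades = if (length(subclades)) subclades,
    summary_grid = gridTab,
    basal_node = basal)
  jsonlite::write_json(bundle, file.path(outDir, "bundle.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  log <- c(sprintf("SeqCompTrends %s on R %s.%s",
                   as.character(utils::packageVersion("SeqCompTrends")),
                   R.version$major, R.version$minor),
           sprintf("run at %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S")),
           sprintf("seed=%d s=%g minLen=%d nPerm=%d nSim=%d alpha=%g",
                   config$seed, config$s, config$minLen, config$nPerm,
                   config$nSim, config$alpha),
           sprintf("GS k range: %s", paste(config$gsKRange, collapse = ",")),
           if (length(constant))
             sprintf("constant metric columns skipped in comparative stages: %s",
                     paste(constant, collapse = ", ")),
           sprintf("basal node: %d%s", basal,
                   if (is.null(config$basalTip))
                     " (default: smaller root subtree; designate basalTip to override)"
                   else sprintf(" (lineage of tip '%s')", config$basalTip)),
           "note: segmentation significance s and the GS k bound are mandatory reported parameters")
  writeLines(log, file.path(outDir, "run_log.txt"))
  invisible(bundle)
}
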