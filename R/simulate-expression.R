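#' Simulate a log-scale expression matrix with planted programs
#'
#' Gaussian model on the log2 scale: every gene has a baseline mean drawn
#' once (shared across samples), samples add i.i.d. Gaussian noise of
#' standard deviation `noiseSd`, and each genotype's planted program genes
#' are shifted by `effectLog2fc` in that genotype's samples. Non-planted
#' genes are exchangeable across groups. Gene identifiers are emitted
#' upper-case so that downstream set operations are case-robust.
#'
#' @param nGenes total number of genes (planted genes are drawn from these
#'   unless `plantedPrograms` names genes outside `GENE0001..`).
#' @param groups named character vector mapping sample name -> genotype; or
#'   `NULL` to build `replicatesPerGroup` samples per genotype named in
#'   `plantedPrograms`.
#' @param plantedPrograms named list genotype -> character vector of planted
#'   up-regulated genes (may be empty).
#' @param effectLog2fc log2 fold-change added to planted genes (default 2).
#' @param noiseSd per-sample Gaussian noise SD on the log2 scale
#'   (default 0.25, a typical replicate-level spread for cell-line RNA-seq).
#' @param replicatesPerGroup replicates per genotype when `groups` is NULL
#'   (must be >= 2; a t-test is undefined below that).
#' @param baselineMeanRange range of per-gene baseline log2 means.
#' @param featurePrefix prefix for generated feature identifiers (default
#'   `"GENE"`; use e.g. `"MB"` to simulate a metabolite matrix).
#' @param seed integer RNG seed.
#' @return list with `matrix` (genes x samples, log2 scale), `groups`
#'   (named vector sample -> genotype) and `truth` (list with
#'   `true_deg_genes` per genotype, effect size, seed).
#' @examples
#' sim <- simulateExpression(500, plantedPrograms = list(
#'   EGFR = c("PSPH", "PHGDH"), WT = character()), seed = 7)
#' dim(sim$matrix)
#' @export
simulateExpression <- function(nGenes,
                               groups = NULL,
                               plantedPrograms = list(),
                               effectLog2fc = 2,
                               noiseSd = 0.25,
                               replicatesPerGroup = 3L,
                               baselineMeanRange = c(4, 12),
                               featurePrefix = "GENE",
                               seed = 1L) {
  if (is.null(groups)) {
    if (replicatesPerGroup < 2L)
      stop("'replicatesPerGroup' must be >= 2 (t-test undefined otherwise)")
    genotypes <- names(plantedPrograms)
    if (is.null(genotypes) || !length(genotypes))
      stop("either 'groups' or a named 'plantedPrograms' list is required")
    groups <- setNames(
      rep(genotypes, each = replicatesPerGroup),
      paste0(rep(genotypes, each = replicatesPerGroup), "_R",
             rep(seq_len(replicatesPerGroup), length(genotypes))))
  }
  if (min(table(groups)) < 2L)
    stop("every group needs >= 2 replicates (t-test undefined otherwise)")
  plantedPrograms <- lapply(plantedPrograms, toupper)
  set.seed(as.integer(seed))
  genes <- sprintf("%s%04d", featurePrefix, seq_len(nGenes))
  extra <- setdiff(toupper(unlist(plantedPrograms)), genes)
  genes <- unique(c(genes, extra))
  baseline <- runif(length(genes), baselineMeanRange[1], baselineMeanRange[2])
  mat <- matrix(rnorm(length(genes) * length(groups), mean = baseline,
                      sd = noiseSd),
                nrow = length(genes),
                dimnames = list(genes, names(groups)))
  for (g in names(plantedPrograms)) {
    planted <- intersect(plantedPrograms[[g]], genes)
    cols <- names(groups)[groups == g]
    if (length(planted) && length(cols))
      mat[planted, cols] <- mat[planted, cols] + effectLog2fc
  }
  truth <- list(true_deg_genes = lapply(plantedPrograms, intersect, y = genes),
                effect_log2fc = effectLog2fc, noise_sd = noiseSd,
                seed = as.integer(seed))
  list(matrix = mat, groups = groups, truth = truth)
}

#' Simulate a TF -> target regulon database with planted enrichment
#'
#' Non-planted TFs draw their regulons uniformly from the gene universe;
#' planted TFs draw `plantedOverlapFraction` of their targets from the
#' supplied differential-gene set and the remainder from the rest of the
#' universe. Setting the overlap fraction to the background rate
#' `length(degGenes) / length(universe)` makes planted TFs null by
#' construction.
#'
#' @param nTfs number of background (non-planted) TFs.
#' @param targetsPerTf regulon size.
#' @param universe character vector of candidate target genes.
#' @param plantedTfs character vector of planted TF names (may be empty).
#' @param degGenes the differential gene set planted regulons should overlap.
#' @param plantedOverlapFraction fraction in \[0, 1\] of each planted regulon
#'   drawn from `degGenes`.
#' @param seed integer RNG seed.
#' @return list with `regulons` (named list TF -> target character vector,
#'   all ids upper-case) and `truth` (list with `true_enriched_tfs`, seed).
#' @export
simulateTfDatabase <- function(nTfs, targetsPerTf, universe,
                               plantedTfs = character(),
                               degGenes = character(),
                               plantedOverlapFraction = 0.8,
                               seed = 1L) {
  if (plantedOverlapFraction < 0 || plantedOverlapFraction > 1)
    stop("'plantedOverlapFraction' must lie in [0, 1]")
  universe <- unique(toupper(universe))
  degGenes <- intersect(toupper(degGenes), universe)
  if (targetsPerTf > length(universe))
    stop("'targetsPerTf' exceeds the universe size")
  set.seed(as.integer(seed))
  regulons <- list()
  for (i in seq_len(nTfs))
    regulons[[sprintf("TF%04d", i)]] <- sample(universe, targetsPerTf)
  nFromDeg <- round(plantedOverlapFraction * targetsPerTf)
  nFromDeg <- min(nFromDeg, length(degGenes))
  rest <- setdiff(universe, degGenes)
  for (tf in toupper(plantedTfs)) {
    hits <- if (nFromDeg > 0) sample(degGenes, nFromDeg) else character()
    fill <- sample(rest, targetsPerTf - length(hits))
    regulons[[tf]] <- c(hits, fill)
  }
  truth <- list(true_enriched_tfs = toupper(plantedTfs),
                planted_overlap_fraction = plantedOverlapFraction,
                seed = as.integer(seed))
  list(regulons = regulons, truth = truth)
}
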