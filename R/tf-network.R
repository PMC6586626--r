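#' Call differentially expressed genes
#'
#' Applies the fold-change/t-test filter of [differentialFeatures()] to a
#' log2-scale expression matrix (DEGs at 1.5-fold and p < 0.01 by default,
#' two-tailed Student's t test), returning up- and down-regulated gene sets
#' separately.
#'
#' @inheritParams differentialFeatures
#' @param m log2-scale expression matrix, genes x samples.
#' @return list with `records` (the full data.frame), `up`, `down` and
#'   `all` (character vectors of passing genes, upper-cased).
#' @examples
#' sim <- simulateExpression(300, plantedPrograms = list(
#'   EGFR = sprintf("GENE%04d", 1:5), WT = character()), seed = 2)
#' callDegs(sim$matrix, sim$groups, "EGFR", "WT")$up
#' @export
callDegs <- function(m, groups, case, control, fcCut = 1.5, pCut = 0.01,
                     varEqual = TRUE) {
  rec <- differentialFeatures(m, groups, case, control, fcCut = fcCut,
                              pCut = pCut, varEqual = varEqual,
                              log2Input = TRUE)
  up <- toupper(rec$feature[rec$passes & rec$direction == "up"])
  down <- toupper(rec$feature[rec$passes & rec$direction == "down"])
  list(records = rec, up = up, down = down, all = c(up, down))
}

#' Restrict a gene set to a metabolic-gene universe
#'
#' Case-insensitive intersection of a gene set with a metabolic-gene
#' annotation (e.g. the KEGG metabolic gene catalogue); symbols are
#' upper-cased so that mouse-style (`Psph`) and human-style (`PSPH`)
#' identifiers match.
#'
#' @param genes character vector of gene symbols.
#' @param metabolicUniverse character vector of metabolic gene symbols.
#' @return upper-cased intersection (empty with a warning when disjoint).
#' @examples
#' filterMetabolic(c("Psph", "TP53"), c("PSPH", "PHGDH"))
#' @export
filterMetabolic <- function(genes, metabolicUniverse) {
  if (!length(genes) || !length(metabolicUniverse))
    stop("both 'genes' and 'metabolicUniverse' must be non-empty")
  out <- intersect(toupper(genes), toupper(metabolicUniverse))
  message(sprintf("%d of %d genes are metabolic", length(out),
                  length(unique(toupper(genes)))))
  if (!length(out))
    warning("no overlap between gene set and metabolic universe")
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' order-preserving and with monotonicity enforced.
#'
#' @param p numeric vector of p-values in \[0, 1\]; NA/NaN rejected.
#' @return adjusted p-values, same order as input.
#' @examples
#' adjustBh(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
adjustBh <- function(p) {
  if (!length(p)) return(numeric())
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Enrich transcription-factor regulons against metabolic DEGs
#'
#' One-sided Fisher's exact test of each TF's regulon (intersected with the
#' universe) against the metabolic DEG set, Benjamini-Hochberg adjustment
#' across all tested TFs, and selection of TFs with adjusted p at or below
#' `alpha` (default 0.0005).
#'
#' @param metabolicDegs character vector of metabolic DEG symbols.
#' @param universe character vector of genes the enrichment is computed
#'   over (typically measured genes intersected with the metabolic
#'   annotation); must contain `metabolicDegs`.
#' @param regulons named list TF -> target gene set.
#' @param alpha adjusted-p selection threshold.
#' @return list with `selected` (character vector of TFs passing `alpha`,
#'   ordered by adjusted p) and `records` (the [oraFisher()] data.frame,
#'   one row per TF with non-zero universe overlap).
#' @examples
#' db <- simulateTfDatabase(50, 10, sprintf("GENE%03d", 1:100),
#'                          plantedTfs = "TFX", degGenes = sprintf("GENE%03d", 1:10),
#'                          seed = 1)
#' enrichTfs(sprintf("GENE%03d", 1:10), sprintf("GENE%03d", 1:100),
#'           db$regulons, alpha = 0.01)$selected
#' @export
enrichTfs <- function(metabolicDegs, universe, regulons, alpha = 5e-4) {
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  metabolicDegs <- unique(toupper(metabolicDegs))
  universe <- unique(toupper(universe))
  if (!all(metabolicDegs %in% universe))
    stop("'universe' must contain every metabolic DEG")
  regulons <- lapply(regulons, toupper)
  names(regulons) <- toupper(names(regulons))
  nAll <- length(regulons)
  rec <- oraFisher(metabolicDegs, universe, regulons)
  skipped <- nAll - nrow(rec)
  if (skipped > 0)
    message(skipped, " TF(s) with zero universe overlap skipped")
  sel <- rec$set[rec$adjusted_p <= alpha]
  list(selected = sel, records = rec)
}

#' Reconstruct a TF-target / PPI sub-network
#'
#' Builds the interaction network around a set of selected TFs: directed
#' TF -> target edges restricted to a target gene set, plus undirected
#' protein-protein interaction edges among the included targets. Edges
#' present in several sources are merged with their provenance tags
#' unioned; undirected PPI edges are stored with lexicographically sorted
#' endpoints so deduplication is orientation-independent.
#'
#' @param selectedTfs character vector of TF names (must exist in
#'   `regulons`).
#' @param regulons named list TF -> target gene set.
#' @param targetGenes character vector restricting which targets enter the
#'   network (e.g. the metabolic DEGs).
#' @param ppiSources list of data.frames with columns `a`, `b`, `source`
#'   (may be empty).
#' @return list with `edges` (data.frame: `from`, `to`, `type` in
#'   `{"tf-target", "ppi"}`, `sources`) and `nodes` (data.frame: `node`,
#'   `role` in `{"TF", "target"}`).
#' @examples
#' net <- buildSubnetwork("MYC", list(MYC = c("LDHA", "PSPH")),
#'                        c("LDHA", "PSPH"), list())
#' net$edges
#' @export
buildSubnetwork <- function(selectedTfs, regulons, targetGenes,
                            ppiSources = list()) {
  if (!length(selectedTfs)) stop("'selectedTfs' must be non-empty")
  selectedTfs <- toupper(selectedTfs)
  names(regulons) <- toupper(names(regulons))
  targetGenes <- unique(toupper(targetGenes))
  missing <- setdiff(selectedTfs, names(regulons))
  if (length(missing))
    stop("unknown TF(s) absent from regulon database: ",
         paste(missing, collapse = ", "))
  tfEdges <- do.call(rbind, lapply(selectedTfs, function(tf) {
    targets <- intersect(toupper(regulons[[tf]]), targetGenes)
    if (!length(targets)) return(NULL)
    data.frame(from = tf, to = targets, type = "tf-target",
               sources = "regulon", stringsAsFactors = FALSE)
  }))
  included <- unique(tfEdges$to)
  ppiEdges <- NULL
  if (length(ppiSources)) {
    ppi <- do.call(rbind, lapply(ppiSources, function(df) {
      stopifnot(all(c("a", "b", "source") %in% names(df)))
      data.frame(a = toupper(df$a), b = toupper(df$b),
                 source = as.character(df$source), stringsAsFactors = FALSE)
    }))
    if (!is.null(ppi) && nrow(ppi)) {
      swap <- ppi$a > ppi$b
      tmp <- ppi$a[swap]; ppi$a[swap] <- ppi$b[swap]; ppi$b[swap] <- tmp
      ppi <- ppi[ppi$a != ppi$b & ppi$a %in% included & ppi$b %in% included, ,
                 drop = FALSE]
      if (nrow(ppi)) {
        key <- paste(ppi$a, ppi$b, sep = "\r")
        srcByEdge <- tapply(ppi$source, key, function(s)
          paste(sort(unique(s)), collapse = ";"))
        parts <- strsplit(names(srcByEdge), "\r", fixed = TRUE)
        ppiEdges <- data.frame(
          from = vapply(parts, `[`, character(1), 1L),
          to = vapply(parts, `[`, character(1), 2L),
          type = "ppi", sources = as.character(srcByEdge),
          stringsAsFactors = FALSE)
      }
    }
  }
  edges <- rbind(tfEdges, ppiEdges)
  edges <- edges[order(edges$type, edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  nodes <- rbind(
    data.frame(node = selectedTfs, role = "TF", stringsAsFactors = FALSE),
    data.frame(node = setdiff(included, selectedTfs), role = "target",
               stringsAsFactors = FALSE))
  list(edges = edges, nodes = nodes)
}

#' Write a network in SIF format
#'
#' Simple interaction format (`node <tab> type <tab> node`) for import into
#' network viewers.
#'
#' @param network list as returned by [buildSubnetwork()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSif <- function(network, path) {
  e <- network$edges
  writeLines(paste(e$from, e$type, e$to, sep = "\t"), path)
  invisible(path)
}
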