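#' Default demo-pipeline configuration
#'
#' Parameters for the end-to-end synthetic EGFR-vs-FGFR study: tracer
#' labeling for five genotypes, a metabolite matrix with planted altered
#' metabolites, an expression matrix with planted metabolic programs and a
#' planted-TF regulon database, and a patient cohort with a positive
#' co-occurrence odds ratio. Filter thresholds default to the classical
#' 1.5-fold / p < 0.01 differential cutoff and adjusted p < 0.0005 for TF
#' selection.
#'
#' @param seed master integer seed; per-stage seeds are derived from it.
#' @return nested configuration list (round-trips through YAML unchanged).
#' @examples
#' str(defaultConfig(seed = 1), max.level = 2)
#' @export
defaultConfig <- function(seed = 1L) {
  list(
    scenario = "rtk_demo",
    seed = as.integer(seed),
    tracing = list(
      genotypes = c("EGFR", "FGFR", "RET", "MET", "WT"),
      tracer = "glucose_u13c6",
      replicates = 3L,
      noise_cv = 0.05,
      purity_correction = FALSE
    ),
    metabolomics = list(
      n_metabolites = 120L, n_altered = 15L,
      effect_log2fc = 2, noise_sd = 0.25, replicates = 3L,
      fc_cut = 1.5, p_cut = 0.01,
      n_pathways = 20L, pathway_size = 12L, planted_overlap = 0.8
    ),
    expression = list(
      n_genes = 2000L, n_metabolic = 500L, n_planted = 50L,
      effect_log2fc = 2, noise_sd = 0.25, replicates = 3L,
      fc_cut = 1.5, p_cut = 0.01,
      n_tfs = 200L, targets_per_tf = 15L, n_planted_tfs = 5L,
      planted_overlap = 0.8, alpha = 5e-4
    ),
    cohort = list(
      n_patients = 1000L, prev_a = 0.15, prev_b = 0.12, log_odds = 1.5
    )
  )
}

#' Validate a pipeline configuration
#'
#' Checks every threshold against its documented domain before any stage
#' runs.
#'
#' @param config configuration list (see [defaultConfig()]) or path to a
#'   YAML file.
#' @return the (possibly YAML-loaded) configuration list, invisibly; errors
#'   on the first violation.
#' @export
validateConfig <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  chk <- function(cond, msg) if (!cond) stop("invalid config: ", msg)
  chk(!is.null(config$seed) && is.finite(config$seed),
      "a numeric 'seed' is required")
  tr <- config$tracing
  chk(is.numeric(tr$noise_cv) && tr$noise_cv >= 0, "tracing$noise_cv >= 0")
  chk(all(tr$genotypes %in% c("EGFR", "FGFR", "RET", "MET", "WT")),
      "tracing$genotypes must be among EGFR, FGFR, RET, MET, WT")
  chk(tr$replicates >= 1, "tracing$replicates >= 1")
  for (blk in c("metabolomics", "expression")) {
    b <- config[[blk]]
    chk(b$fc_cut >= 1, paste0(blk, "$fc_cut >= 1"))
    chk(b$p_cut > 0 && b$p_cut < 1, paste0(blk, "$p_cut in (0, 1)"))
    chk(b$noise_sd >= 0, paste0(blk, "$noise_sd >= 0"))
    chk(b$replicates >= 2, paste0(blk, "$replicates >= 2"))
    chk(b$planted_overlap >= 0 && b$planted_overlap <= 1,
        paste0(blk, "$planted_overlap in [0, 1]"))
  }
  chk(config$expression$alpha >= 0 && config$expression$alpha <= 1,
      "expression$alpha in [0, 1]")
  co <- config$cohort
  chk(co$prev_a >= 0 && co$prev_a <= 1 && co$prev_b >= 0 && co$prev_b <= 1,
      "cohort prevalences in [0, 1]")
  chk(is.finite(co$log_odds), "cohort$log_odds finite")
  invisible(config)
}

#' Validate input files against expected formats
#'
#' Per-file format verdict without mutating inputs. Supported formats:
#' `"tsv"` (parseable TSV), `"gmt"` (well-formed gene-set file),
#' `"expression"` (matrix TSV with unique feature ids), `"spectra"`
#' (isotopologue table with non-negative intensities), `"cohort"` (long
#' call table with 0/1 status).
#'
#' @param paths character vector of file paths.
#' @param formats character vector of expected formats, recycled to
#'   `length(paths)`.
#' @return data.frame with columns `file`, `format`, `ok`, `issues`.
#' @export
validateInputs <- function(paths, formats) {
  formats <- rep_len(formats, length(paths))
  checkOne <- function(path, format) {
    if (!file.exists(path)) return("file not found")
    issues <- character()
    tryCatch({
      if (format == "gmt") {
        readGmt(path)
      } else {
        df <- readTsv(path)
        if (format == "expression") {
          ids <- df[[1]]
          dup <- ids[duplicated(ids)]
          if (length(dup))
            issues <- c(issues, paste("duplicate feature id(s):",
                                      paste(unique(dup), collapse = ", ")))
        } else if (format == "spectra") {
          need <- c("metabolite", "sample", "m0")
          miss <- setdiff(need, names(df))
          if (length(miss))
            issues <- c(issues, paste("missing column(s):",
                                      paste(miss, collapse = ", ")))
          mcols <- grep("^m[0-9]+$", names(df), value = TRUE)
          if (length(mcols)) {
            neg <- which(apply(df[mcols] < 0, 1L, any, na.rm = TRUE))
            if (length(neg))
              issues <- c(issues, paste("negative intensity in row(s):",
                                        paste(utils::head(neg, 5L),
                                              collapse = ", ")))
          }
        } else if (format == "cohort") {
          need <- c("patient_id", "event", "status")
          miss <- setdiff(need, names(df))
          if (length(miss))
            issues <- c(issues, paste("missing column(s):",
                                      paste(miss, collapse = ", ")))
          else if (!all(df$status %in% c(0L, 1L)))
            issues <- c(issues, "status values outside {0, 1}")
        }
      }
      if (length(issues)) paste(issues, collapse = "; ") else ""
    }, error = function(e) conditionMessage(e))
  }
  issues <- mapply(checkOne, paths, formats)
  data.frame(file = paths, format = formats, ok = !nzchar(issues),
             issues = issues, row.names = NULL, stringsAsFactors = FALSE)
}

#' Run the synthetic end-to-end demo pipeline
#'
#' Executes simulate -> correct -> metabolite statistics -> TF network ->
#' co-occurrence on fully synthetic data with planted truth, writing every
#' intermediate as provenance-stamped TSV/GMT/SIF/JSON under `outDir`.
#' Re-running with an identical configuration reproduces byte-identical
#' files (no timestamps are written).
#'
#' @param config configuration list or YAML path (see [defaultConfig()],
#'   [validateConfig()]).
#' @param outDir output directory (created if needed).
#' @return list with `manifest` (files, md5 sums, config hash) and `report`
#'   (planted-truth recovery metrics computed by the run itself), also
#'   written as JSON into `outDir`.
#' @examples
#' \donttest{
#' res <- runPipeline(defaultConfig(seed = 1), tempfile("demo"))
#' res$report$tf_recovery
#' }
#' @export
runPipeline <- function(config = defaultConfig(), outDir) {
  config <- validateConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  hash <- substr(rlang::hash(config), 1, 12)
  seed <- as.integer(config$seed)
  out <- function(name) file.path(outDir, name)
  files <- character()
  emit <- function(name) files[[length(files) + 1]] <<- out(name)
  report <- list(scenario = config$scenario, seed = seed, config_hash = hash)

  ## --- stage 1: tracer labeling, raw spectra, correction ----------------
  tr <- config$tracing
  tracer <- defaultTracers()[[tr$tracer]]
  if (is.null(tracer)) stop("stage tracing: unknown tracer ", tr$tracer)
  panel <- defaultFragmentPanel()
  rawAll <- list(); grouping <- character(); trueMids <- list()
  for (i in seq_along(tr$genotypes)) {
    g <- tr$genotypes[[i]]
    sim <- simulateLabeling(fluxRegime(g), tracer, panel, seed = seed)
    trueMids[[g]] <- sim$mids
    samples <- sprintf("%s_S%d", g, seq_len(tr$replicates))
    raw <- emitRawSpectra(sim$mids, panel, tracer, samples = samples,
                          noiseCv = tr$noise_cv, seed = seed + 100L + i)
    grouping[samples] <- g
    rawAll[[g]] <- raw
  }
  rawTab <- do.call(rbind, rawAll)
  writeTsv(rawTab, out("raw_spectra.tsv"), hash, seed); emit("raw_spectra.tsv")
  corr <- correctSpectraTable(rawTab, panel, tracer,
                              purityCorrection = isTRUE(tr$purity_correction))
  writeTsv(corr$corrected, out("corrected_mids.tsv"), hash, seed)
  emit("corrected_mids.tsv")
  writeTsv(corr$enrichment, out("enrichment.tsv"), hash, seed)
  emit("enrichment.tsv")
  fct <- fractionContributionTable(corr$corrected, grouping)
  writeMatrixTsv(fct, out("fraction_contribution.tsv"),
                 "metabolite_isotopologue", hash, seed)
  emit("fraction_contribution.tsv")
  # recovery: group-mean corrected MID vs planted truth
  midErr <- 0
  for (g in names(trueMids)) for (met in names(trueMids[[g]])) {
    sub <- corr$corrected[corr$corrected$metabolite == met &
                            grouping[corr$corrected$sample] == g, ]
    est <- tapply(sub$fraction, sub$isotopologue, mean)
    truth <- trueMids[[g]][[met]]
    names(truth) <- paste0("M", seq_along(truth) - 1L)
    midErr <- max(midErr, max(abs(est[names(truth)] - truth)))
  }
  report$mid_recovery <- list(max_abs_error_group_mean = midErr,
                              noise_cv = tr$noise_cv)

  ## --- stage 2: metabolite matrix statistics ----------------------------
  mb <- config$metabolomics
  altered <- sprintf("MB%04d", seq_len(mb$n_altered))
  mbPrograms <- list(EGFR = altered, WT = character())
  mbSim <- simulateExpression(mb$n_metabolites, plantedPrograms = mbPrograms,
                              effectLog2fc = mb$effect_log2fc,
                              noiseSd = mb$noise_sd,
                              replicatesPerGroup = mb$replicates,
                              featurePrefix = "MB", seed = seed + 200L)
  mbLinear <- 2^mbSim$matrix
  writeMatrixTsv(mbLinear, out("metabolite_matrix.tsv"), "metabolite",
                 hash, seed)
  emit("metabolite_matrix.tsv")
  z <- logZscore(mbLinear)
  writeMatrixTsv(z, out("metabolite_zscore.tsv"), "metabolite", hash, seed)
  emit("metabolite_zscore.tsv")
  pc <- pcaScores(z, k = min(3L, min(dim(z))))
  writeMatrixTsv(pc$scores, out("pca_scores.tsv"), "sample", hash, seed)
  emit("pca_scores.tsv")
  cl <- hierarchicalCluster(z, axis = "samples")
  writeTsv(data.frame(sample = cl$order, position = seq_along(cl$order)),
           out("cluster_order.tsv"), hash, seed)
  emit("cluster_order.tsv")
  diffRec <- differentialFeatures(mbLinear, mbSim$groups, "EGFR", "WT",
                                  fcCut = mb$fc_cut, pCut = mb$p_cut)
  writeTsv(diffRec, out("metabolite_differential.tsv"), hash, seed)
  emit("metabolite_differential.tsv")
  found <- toupper(diffRec$feature[diffRec$passes])
  planted <- toupper(altered)
  report$metabolite_recovery <- list(
    planted = length(planted),
    recovered = length(intersect(found, planted)),
    false_positives = length(setdiff(found, planted)))
  pw <- simulateTfDatabase(mb$n_pathways, mb$pathway_size,
                           rownames(mbLinear),
                           plantedTfs = "PLANTED_PATHWAY",
                           degGenes = planted,
                           plantedOverlapFraction = mb$planted_overlap,
                           seed = seed + 201L)
  writeGmt(pw$regulons, out("metabolite_pathways.gmt"))
  emit("metabolite_pathways.gmt")
  oraTab <- oraFisher(found, toupper(rownames(mbLinear)), pw$regulons)
  writeTsv(oraTab, out("metabolite_ora.tsv"), hash, seed)
  emit("metabolite_ora.tsv")
  report$pathway_recovery <- list(
    top_set = oraTab$set[1],
    planted_is_top = identical(oraTab$set[1], "PLANTED_PATHWAY"))

  ## --- stage 3: expression, TF enrichment, sub-network ------------------
  ex <- config$expression
  metabolicUniverse <- sprintf("GENE%04d", seq_len(ex$n_metabolic))
  plantedGenes <- sprintf("GENE%04d", seq_len(ex$n_planted))
  exSim <- simulateExpression(ex$n_genes,
                              plantedPrograms = list(EGFR = plantedGenes,
                                                     WT = character()),
                              effectLog2fc = ex$effect_log2fc,
                              noiseSd = ex$noise_sd,
                              replicatesPerGroup = ex$replicates,
                              seed = seed + 300L)
  writeMatrixTsv(exSim$matrix, out("expression_matrix.tsv"), "gene",
                 hash, seed)
  emit("expression_matrix.tsv")
  writeGmt(list(KEGG_METABOLIC = metabolicUniverse),
           out("metabolic_genes.gmt"))
  emit("metabolic_genes.gmt")
  degs <- callDegs(exSim$matrix, exSim$groups, "EGFR", "WT",
                   fcCut = ex$fc_cut, pCut = ex$p_cut)
  writeTsv(degs$records, out("deg_records.tsv"), hash, seed)
  emit("deg_records.tsv")
  metabolicDegs <- suppressMessages(
    filterMetabolic(degs$all, metabolicUniverse))
  plantedTfs <- sprintf("PLANTEDTF%02d", seq_len(ex$n_planted_tfs))
  db <- simulateTfDatabase(ex$n_tfs, ex$targets_per_tf,
                           metabolicUniverse, plantedTfs = plantedTfs,
                           degGenes = metabolicDegs,
                           plantedOverlapFraction = ex$planted_overlap,
                           seed = seed + 301L)
  writeGmt(db$regulons, out("regulons.gmt")); emit("regulons.gmt")
  universe <- intersect(toupper(rownames(exSim$matrix)),
                        toupper(metabolicUniverse))
  enr <- suppressMessages(
    enrichTfs(metabolicDegs, universe, db$regulons, alpha = ex$alpha))
  writeTsv(enr$records, out("tf_enrichment.tsv"), hash, seed)
  emit("tf_enrichment.tsv")
  report$tf_recovery <- list(
    planted = length(plantedTfs),
    selected = length(enr$selected),
    recovered = length(intersect(enr$selected, plantedTfs)),
    false_positives = length(setdiff(enr$selected, plantedTfs)),
    sensitivity = length(intersect(enr$selected, plantedTfs)) /
      length(plantedTfs))
  if (length(enr$selected)) {
    set.seed(seed + 302L)
    tgt <- metabolicDegs
    ppiPool <- if (length(tgt) >= 2L) {
      pairs <- t(utils::combn(sort(tgt), 2L))
      idx <- sample(nrow(pairs), min(40L, nrow(pairs)))
      pairs[idx, , drop = FALSE]
    } else matrix(character(), 0, 2)
    half <- seq_len(ceiling(nrow(ppiPool) / 2))
    ppiSources <- list(
      data.frame(a = ppiPool[half, 1], b = ppiPool[half, 2],
                 source = "dbA", stringsAsFactors = FALSE),
      data.frame(a = ppiPool[, 1], b = ppiPool[, 2],
                 source = "dbB", stringsAsFactors = FALSE))
    net <- buildSubnetwork(enr$selected, db$regulons, metabolicDegs,
                           ppiSources)
    writeTsv(net$edges, out("network_edges.tsv"), hash, seed)
    emit("network_edges.tsv")
    writeSif(net, out("network.sif")); emit("network.sif")
    report$network <- list(nodes = nrow(net$nodes), edges = nrow(net$edges))
  }

  ## --- stage 4: cohort co-occurrence ------------------------------------
  co <- config$cohort
  cohort <- simulateCohort(co$n_patients, co$prev_a, co$prev_b, co$log_odds,
                           seed = seed + 400L)
  writeTsv(cohort$calls, out("cohort_calls.tsv"), hash, seed)
  emit("cohort_calls.tsv")
  ct <- contingencyFromCalls(cohort$calls, "EGFR_MUT", "PSPH_AMP")
  ft <- fisherExact2x2(ct)
  coTab <- data.frame(event_a = "EGFR_MUT", event_b = "PSPH_AMP",
                      n_both = ct@nBoth, n_a_only = ct@nAOnly,
                      n_b_only = ct@nBOnly, n_neither = ct@nNeither,
                      odds_ratio = ft$odds_ratio, p_value = ft$p_value,
                      direction = ft$direction,
                      cooccurrence_rate = cooccurrenceRate(ct))
  writeTsv(coTab, out("cooccurrence.tsv"), hash, seed)
  emit("cooccurrence.tsv")
  report$cohort <- list(true_log_odds = co$log_odds,
                        sample_odds_ratio = ft$odds_ratio,
                        fisher_p = ft$p_value)

  ## --- truth, report, manifest ------------------------------------------
  truth <- list(true_mids = trueMids,
                true_altered_metabolites = planted,
                true_deg_genes = toupper(plantedGenes),
                true_enriched_tfs = plantedTfs,
                cohort_log_odds = co$log_odds)
  jsonlite::write_json(truth, out("truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  emit("truth.json")
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  emit("report.json")
  manifest <- list(
    scenario = config$scenario, seed = seed, config_hash = hash,
    files = data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  list(manifest = manifest, report = report, outDir = outDir)
}
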