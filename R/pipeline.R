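#' Pipeline configuration
#'
#' Bundles every stage threshold and sub-configuration of the end-to-end
#' run.  Defaults follow common ceRNA practice: adjusted p < 0.05 with fold
#' change > 2 for differential expression, raw hypergeometric p < 0.01 for
#' competing pairs, permutation p < 0.01 for prioritised lncRNAs, top-10
#' centrality lists.
#'
#' @param outDir output directory for stage files and the run report
#' @param synthetic a \code{SyntheticConfig} ([syntheticConfig()]) used by
#'   the simulate stage; ignored when \code{inputDir} is given
#' @param inputDir optional fixture directory ([writeFixture()] layout) to
#'   read instead of simulating
#' @param alphaDe adjusted-p threshold for differential expression
#' @param fcThreshold fold-change gate (linear fold units)
#' @param alphaCerna hypergeometric p threshold for competing pairs
#' @param alphaRwr permutation-p threshold for prioritised lncRNAs
#' @param k top-k length for the centrality lists
#' @param rwr an \code{RWRConfig} ([rwrConfig()]); its \code{seeds} default
#'   to the dataset's designated seed genes when empty
#' @param gmtPath optional GMT file enabling the annotation stage
#' @param universeMode miRNA universe definition, see [buildCernaNetwork()]
#' @param rngSeed global seed for the run
#' @return validated config list of class \code{PipelineConfig}
#' @export
pipelineConfig <- function(outDir, synthetic = syntheticConfig(),
                           inputDir = NULL, alphaDe = 0.05,
                           fcThreshold = 2.0, alphaCerna = 0.01,
                           alphaRwr = 0.01, k = 10,
                           rwr = rwrConfig(nPermutations = 1000L),
                           gmtPath = NULL,
                           universeMode = "interaction-union",
                           rngSeed = 1L) {
  for (a in c(alphaDe, alphaCerna, alphaRwr))
    if (a <= 0 || a > 1) stop("thresholds must lie in (0, 1]")
  cfg <- list(outDir = outDir, synthetic = synthetic, inputDir = inputDir,
              alphaDe = alphaDe, fcThreshold = fcThreshold,
              alphaCerna = alphaCerna, alphaRwr = alphaRwr, k = k,
              rwr = rwr, gmtPath = gmtPath, universeMode = universeMode,
              rngSeed = as.integer(rngSeed))
  class(cfg) <- "PipelineConfig"
  cfg
}

# FNV-1a on the deparsed config: a stable content fingerprint for the report
.configHash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 0x811c9dc5 %% 2^31
  for (b in bytes)
    h <- (bitwXor(as.integer(h), as.integer(b)) * 16777619) %% 2^31
  sprintf("%08x", as.integer(h))
}

.stageLog <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

#' Run the full ceRNA-network inference pipeline
#'
#' Executes, in order and with fail-fast semantics: simulate (or load),
#' differential expression per RNA class, ceRNA-network construction,
#' topology/hub analysis, random walk with restart with the permutation
#' null, and (when a GMT file is configured) correlation-gated
#' over-representation analysis for the top hub lncRNA.  All stage outputs
#' are written under \code{outDir} and a machine-readable JSON run report is
#' produced; a failing stage leaves a \code{FAILED} marker naming the stage.
#'
#' @param config a \code{PipelineConfig} from [pipelineConfig()]
#' @return the run report, invisibly (list; also serialized to
#'   \code{report.json})
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  report <- list(package_version = as.character(utils::packageVersion("ceRNAnet")),
                 config_hash = .configHash(config),
                 parameters = list(alpha_de = config$alphaDe,
                                   fc_threshold = config$fcThreshold,
                                   alpha_cerna = config$alphaCerna,
                                   alpha_rwr = config$alphaRwr,
                                   k = config$k,
                                   restart = config$rwr$restart,
                                   n_permutations = config$rwr$nPermutations,
                                   rng_seed = config$rngSeed),
                 stages = list())
  stage <- "simulate"
  fail <- function(e) {
    writeLines(paste0("FAILED at stage: ", stage, "\n", conditionMessage(e)),
               file.path(config$outDir, "FAILED"))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  }
  tryCatch({
    # ---- simulate / load ------------------------------------------------
    if (is.null(config$inputDir)) {
      .stageLog(stage, "generating synthetic dataset (seed ",
                config$synthetic$rngSeed, ")")
      ds <- generateDataset(config$synthetic)
      writeFixture(ds, file.path(config$outDir, "dataset"))
      expr <- ds@expression; interactions <- ds@interactions
      truth <- truthManifest(ds)
      seeds <- truth$seed_genes
    } else {
      .stageLog(stage, "loading fixture from ", config$inputDir)
      fx <- readFixture(config$inputDir)
      expr <- fx$expression; interactions <- fx$interactions
      truth <- fx$truth; seeds <- fx$seeds
    }
    report$stages$simulate <- list(
      n_patients = length(unique(sampleSheet(expr)$patient_id)),
      features = lapply(stats::setNames(nm = rnaClasses(expr)), function(cl)
        nrow(exprMatrix(expr, cl))),
      interaction_edges = nrow(interactionEdges(interactions)))

    # ---- differential expression ---------------------------------------
    stage <- "de"
    de <- lapply(stats::setNames(nm = rnaClasses(expr)), function(cl)
      pairedModeratedTest(expr, cl, alpha = config$alphaDe,
                          fcThreshold = config$fcThreshold))
    summ <- deSummary(de)
    utils::write.table(summ, file.path(config$outDir, "de_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cl in names(de))
      utils::write.table(de[[cl]],
                         file.path(config$outDir, paste0("de_", cl, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    .stageLog(stage, paste(sprintf("%s: %d DE", summ$rna_class,
                                   summ$total_significant), collapse = ", "))
    report$stages$de <- list(summary = summ)

    # ---- ceRNA network --------------------------------------------------
    stage <- "network"
    net <- buildCernaNetwork(de, interactions, alpha = config$alphaCerna,
                             universeMode = config$universeMode)
    writeNetwork(net, file.path(config$outDir, "cerna_edges.tsv"))
    writeNetwork(net, file.path(config$outDir, "cerna_network.graphml"),
                 format = "graphml")
    .stageLog(stage, nrow(networkEdges(net)), " competing pairs retained")
    report$stages$network <- list(
      retained_edges = nrow(networkEdges(net)),
      lncrnas = length(unique(networkEdges(net)$lncrna_id)),
      mrnas = length(unique(networkEdges(net)$mrna_id)),
      universe_size = networkEdges(net)$T[1])

    # ---- topology -------------------------------------------------------
    stage <- "topology"
    cent <- centralities(net)
    utils::write.table(cent, file.path(config$outDir, "centralities.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    hubs <- hubIntersection(cent, k = config$k)
    dd <- suppressWarnings(degreeDistribution(cent))  # fit NA when too few bins
    .stageLog(stage, "hubs: ", paste(hubs, collapse = ", "))
    report$stages$topology <- list(
      nodes = nrow(cent), edges_consumed = nrow(networkEdges(net)),
      hubs = hubs, degree_fit = dd$fit)

    # ---- random walk with restart --------------------------------------
    stage <- "rwr"
    rcfg <- config$rwr
    if (!length(rcfg$seeds)) rcfg$seeds <- seeds
    rcfg$alpha <- config$alphaRwr
    rwres <- rwrPermutationTest(net, rcfg)
    ranking <- rankLncrnas(rwres)
    utils::write.table(ranking, file.path(config$outDir, "rwr_lncrnas.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    .stageLog(stage, sum(ranking$significant), " significant lncRNA(s)")
    report$stages$rwr <- list(
      seeds = rcfg$seeds, n_permutations = rcfg$nPermutations,
      significant_lncrnas = ranking$lncrna[ranking$significant],
      top_lncrna = if (nrow(ranking)) ranking$lncrna[1] else NA_character_)

    # ---- annotation (optional) -----------------------------------------
    if (!is.null(config$gmtPath)) {
      stage <- "annotate"
      gmt <- readGmt(config$gmtPath)
      focal <- if (length(hubs)) hubs[1] else ranking$lncrna[1]
      partners <- unique(networkEdges(net)$mrna_id[
        networkEdges(net)$lncrna_id == focal])
      sel <- pearsonSelect(expr, focal, partners)
      enr <- ora(sel$mrna[sel$selected], gmt,
                 universe = rownames(exprMatrix(expr, "mRNA")))
      utils::write.table(sel, file.path(config$outDir, "pcc_selection.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(enr, file.path(config$outDir, "enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      report$stages$annotate <- list(
        focal_lncrna = focal, selected_targets = sum(sel$selected),
        top_set = if (nrow(enr)) enr$set[1] else NA_character_)
    }
  }, error = fail)
  report$wall_time_sec <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  jsonlite::write_json(report, file.path(config$outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}
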