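#' Synthetic-dataset generator configuration
#'
#' Defines the paired-sample study design the generator emulates: eight
#' patients each contributing one ectopic (EC) and one eutopic (EU) sample,
#' three RNA classes profiled on the same samples, planted two-fold (log2)
#' differential expression, planted lncRNA-mRNA competing pairs sharing
#' miRNAs far above chance, a planted hub lncRNA and a planted
#' disease-proximal lncRNA wired (through shared differentially expressed
#' miRNAs) to the designated disease seed genes.
#'
#' @param nPatients number of EC/EU patient pairs (default 8)
#' @param nMrna,nLncrna,nMirna feature counts per RNA class
#' @param fracDe fraction of features per class with planted differential
#'   expression, in [0, 1]
#' @param log2fcPlanted planted effect size in log2 units (default 2)
#' @param noiseSd typical per-feature Gaussian noise SD in log2 units;
#'   per-feature SDs are drawn from a scaled inverse-chi-square around this
#'   value (prior df 8) so variances genuinely differ across features
#' @param patientSd SD of the per-feature patient effect shared by a
#'   patient's EC and EU samples (removed by paired differencing)
#' @param nPlantedCernaPairs total planted lncRNA-mRNA competing pairs
#'   (includes the hub's and the disease-proximal lncRNA's pairs); 0 allowed
#'   only with no planted hubs/disease lncRNAs
#' @param sharedMirnaCount miRNAs wired to both members of each planted pair
#' @param nHubLncrna lncRNAs wired to many mRNAs (default 1)
#' @param hubPairCount planted pairs per hub lncRNA (default 12)
#' @param nDiseaseLncrna disease-proximal lncRNAs (default 1)
#' @param seedGeneCount designated disease seed genes (default 4)
#' @param bgEdgesMrna,bgEdgesLncrna background random interaction edges per
#'   miRNA to mRNAs / lncRNAs
#' @param rngSeed integer RNG seed; identical seeds give identical datasets
#' @return validated config list of class \code{SyntheticConfig}
#' @export
syntheticConfig <- function(nPatients = 8L, nMrna = 300L, nLncrna = 60L,
                            nMirna = 150L, fracDe = 0.25,
                            log2fcPlanted = 2.0, noiseSd = 0.3,
                            patientSd = 0.5, nPlantedCernaPairs = 40L,
                            sharedMirnaCount = 5L, nHubLncrna = 1L,
                            hubPairCount = 12L, nDiseaseLncrna = 1L,
                            seedGeneCount = 4L, bgEdgesMrna = 3L,
                            bgEdgesLncrna = 1L, rngSeed = 1L) {
  cfg <- list(nPatients = as.integer(nPatients), nMrna = as.integer(nMrna),
              nLncrna = as.integer(nLncrna), nMirna = as.integer(nMirna),
              fracDe = fracDe, log2fcPlanted = log2fcPlanted,
              noiseSd = noiseSd, patientSd = patientSd,
              nPlantedCernaPairs = as.integer(nPlantedCernaPairs),
              sharedMirnaCount = as.integer(sharedMirnaCount),
              nHubLncrna = as.integer(nHubLncrna),
              hubPairCount = as.integer(hubPairCount),
              nDiseaseLncrna = as.integer(nDiseaseLncrna),
              seedGeneCount = as.integer(seedGeneCount),
              bgEdgesMrna = as.integer(bgEdgesMrna),
              bgEdgesLncrna = as.integer(bgEdgesLncrna),
              rngSeed = as.integer(rngSeed))
  with(cfg, {
    stopifnot(nPatients >= 1, nMrna >= 1, nLncrna >= 1, nMirna >= 1,
              fracDe >= 0, fracDe <= 1, noiseSd > 0, patientSd >= 0,
              nPlantedCernaPairs >= 0, sharedMirnaCount >= 1,
              nHubLncrna >= 0, nDiseaseLncrna >= 0, seedGeneCount >= 0,
              bgEdgesMrna >= 0, bgEdgesLncrna >= 0)
    if (sharedMirnaCount > nMirna)
      stop("sizing error: sharedMirnaCount exceeds nMirna")
  })
  class(cfg) <- "SyntheticConfig"
  cfg
}

# checks that the planted structure fits into the DE feature budget;
# fails with a sizing error otherwise
.checkSizing <- function(cfg, deMrna, deLnc, deMir) {
  minPairs <- cfg$nHubLncrna * cfg$hubPairCount +
    cfg$nDiseaseLncrna * cfg$seedGeneCount
  if (cfg$nPlantedCernaPairs > 0 && cfg$nPlantedCernaPairs < minPairs)
    stop("sizing error: nPlantedCernaPairs (", cfg$nPlantedCernaPairs,
         ") is below the ", minPairs,
         " pairs needed by the planted hubs and disease-proximal lncRNAs")
  if (cfg$nPlantedCernaPairs == 0 &&
      (cfg$nHubLncrna > 0 || cfg$nDiseaseLncrna > 0))
    stop("sizing error: planted hubs/disease lncRNAs need nPlantedCernaPairs > 0")
  if (cfg$nPlantedCernaPairs > 0) {
    if (length(deMir) < cfg$sharedMirnaCount)
      stop("sizing error: fewer planted-DE miRNAs (", length(deMir),
           ") than sharedMirnaCount (", cfg$sharedMirnaCount, ")")
    nGeneric <- cfg$nPlantedCernaPairs - minPairs
    needMrna <- cfg$nHubLncrna * cfg$hubPairCount + cfg$seedGeneCount *
      (cfg$nDiseaseLncrna > 0) + nGeneric
    if (length(deMrna) < needMrna)
      stop("sizing error: planted pairs need ", needMrna,
           " distinct DE mRNAs but only ", length(deMrna), " are planted; ",
           "raise fracDe or nMrna")
    needLnc <- cfg$nHubLncrna + cfg$nDiseaseLncrna + ceiling(nGeneric / 2)
    if (length(deLnc) < needLnc)
      stop("sizing error: planted pairs need ", needLnc,
           " distinct DE lncRNAs but only ", length(deLnc), " are planted; ",
           "raise fracDe or nLncrna")
  }
  invisible(TRUE)
}

#' Generate a synthetic paired-expression dataset with planted ground truth
#'
#' Baseline EU expression per feature is drawn from a wide uniform range on
#' the log2 scale; each feature gets its own noise SD (scaled
#' inverse-chi-square around \code{noiseSd}) and a per-patient effect shared
#' between a patient's EC and EU samples.  Planted differentially expressed
#' features receive an EC shift of \code{log2fcPlanted} with sign chosen at
#' random per feature, so both Up and Down classes are exercised.
#' Interaction tables combine random background bipartite edges with, for
#' every planted ceRNA pair, \code{sharedMirnaCount} planted-DE miRNAs wired
#' to both members.  Hub lncRNAs participate in \code{hubPairCount} pairs;
#' disease-proximal lncRNAs are wired, through a dedicated shared miRNA set,
#' to mRNAs that include the designated seed genes (2-hop connectivity).
#'
#' @param config a \code{SyntheticConfig} from [syntheticConfig()]
#' @return a [SyntheticDataset-class]; deterministic for fixed
#'   \code{rngSeed}
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "SyntheticConfig"))
  cfg <- config
  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(cfg$rngSeed)

  patients <- sprintf("P%02d", seq_len(cfg$nPatients))
  ss <- data.frame(
    sample_id = c(paste0(patients, "_EC"), paste0(patients, "_EU")),
    patient_id = rep(patients, 2),
    condition = rep(c("EC", "EU"), each = cfg$nPatients),
    stringsAsFactors = FALSE)
  ss <- ss[order(ss$patient_id, ss$condition), ]
  rownames(ss) <- NULL

  ids <- list(mRNA = sprintf("MRNA%04d", seq_len(cfg$nMrna)),
              lncRNA = sprintf("LNC%04d", seq_len(cfg$nLncrna)),
              miRNA = sprintf("MIR%04d", seq_len(cfg$nMirna)))

  plantDe <- function(feats) {
    nDe <- round(cfg$fracDe * length(feats))
    if (nDe == 0)
      return(data.frame(feature = character(0), direction = character(0)))
    de <- sort(sample(feats, nDe))
    data.frame(feature = de,
               direction = sample(c("Up", "Down"), nDe, replace = TRUE),
               stringsAsFactors = FALSE)
  }
  plantedDe <- lapply(ids, plantDe)
  .checkSizing(cfg, plantedDe$mRNA$feature, plantedDe$lncRNA$feature,
               plantedDe$miRNA$feature)

  varPriorDf <- 8  # spread of true per-feature noise SDs
  simClass <- function(feats, de) {
    nf <- length(feats)
    baseline <- stats::runif(nf, 4, 12)
    sds <- cfg$noiseSd * sqrt((varPriorDf - 2) / stats::rchisq(nf, varPriorDf))
    patEff <- matrix(stats::rnorm(nf * cfg$nPatients, sd = cfg$patientSd),
                     nf, cfg$nPatients)
    mkHalf <- function() baseline + patEff +
      matrix(stats::rnorm(nf * cfg$nPatients, sd = sds), nf, cfg$nPatients)
    eu <- mkHalf()
    ec <- mkHalf()
    shift <- numeric(nf)
    i <- match(de$feature, feats)
    shift[i] <- ifelse(de$direction == "Up", 1, -1) * cfg$log2fcPlanted
    ec <- ec + shift
    m <- cbind(ec, eu)
    dimnames(m) <- list(feats, c(paste0(patients, "_EC"),
                                 paste0(patients, "_EU")))
    m
  }
  assays <- lapply(RNA_CLASSES, function(cl)
    simClass(ids[[cl]], plantedDe[[cl]]))
  names(assays) <- RNA_CLASSES

  # --- planted ceRNA structure -------------------------------------------
  deMrna <- plantedDe$mRNA$feature
  deLnc <- plantedDe$lncRNA$feature
  deMir <- plantedDe$miRNA$feature
  pairs <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                      stringsAsFactors = FALSE)
  pairMirnas <- list()
  hubs <- character(0); disease <- character(0); seedGenes <- character(0)

  if (cfg$nPlantedCernaPairs > 0) {
    lncPool <- sample(deLnc)            # shuffled assignment order
    mrnaPool <- sample(deMrna)
    takeM <- function(n) {
      out <- mrnaPool[seq_len(n)]; mrnaPool <<- mrnaPool[-seq_len(n)]; out
    }
    hubs <- if (cfg$nHubLncrna) lncPool[seq_len(cfg$nHubLncrna)] else character(0)
    lncPool <- setdiff(lncPool, hubs)
    disease <- if (cfg$nDiseaseLncrna)
      lncPool[seq_len(cfg$nDiseaseLncrna)] else character(0)
    lncPool <- setdiff(lncPool, disease)

    addPair <- function(l, m, mirs) {
      pairs <<- rbind(pairs, data.frame(lncrna_id = l, mrna_id = m,
                                        stringsAsFactors = FALSE))
      pairMirnas[[length(pairMirnas) + 1L]] <<- mirs
    }
    for (h in hubs) {
      hubSet <- sample(deMir, cfg$sharedMirnaCount)
      for (m in takeM(cfg$hubPairCount)) addPair(h, m, hubSet)
    }
    if (length(disease)) {
      seedGenes <- takeM(cfg$seedGeneCount)
      for (dl in disease) {
        dSet <- sample(deMir, cfg$sharedMirnaCount)
        for (m in seedGenes) addPair(dl, m, dSet)
      }
    }
    nGeneric <- cfg$nPlantedCernaPairs - nrow(pairs)
    if (nGeneric > 0) {
      gl <- rep_len(lncPool, nGeneric)  # at most ceiling(n/|pool|) pairs each
      gm <- takeM(nGeneric)
      for (i in seq_len(nGeneric))
        addPair(gl[i], gm[i], sample(deMir, cfg$sharedMirnaCount))
    }
  }

  plantedEdges <- if (nrow(pairs)) {
    do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      mirs <- pairMirnas[[i]]
      rbind(data.frame(mirna_id = mirs, target_id = pairs$mrna_id[i],
                       target_class = "mRNA", stringsAsFactors = FALSE),
            data.frame(mirna_id = mirs, target_id = pairs$lncrna_id[i],
                       target_class = "lncRNA", stringsAsFactors = FALSE))
    }))
  } else NULL

  bgEdges <- do.call(rbind, lapply(ids$miRNA, function(mi) {
    rbind(
      if (cfg$bgEdgesMrna)
        data.frame(mirna_id = mi,
                   target_id = sample(ids$mRNA, cfg$bgEdgesMrna),
                   target_class = "mRNA", stringsAsFactors = FALSE) else NULL,
      if (cfg$bgEdgesLncrna)
        data.frame(mirna_id = mi,
                   target_id = sample(ids$lncRNA, cfg$bgEdgesLncrna),
                   target_class = "lncRNA", stringsAsFactors = FALSE) else NULL)
  }))
  allEdges <- rbind(plantedEdges, bgEdges)
  if (is.null(allEdges))
    allEdges <- data.frame(mirna_id = character(0), target_id = character(0),
                           target_class = character(0))
  interactions <- suppressMessages(mirnaInteractionSet(allEdges))

  pairs$shared_mirnas <- pairMirnas
  truth <- list(planted_de = plantedDe, planted_pairs = pairs,
                hub_lncrnas = sort(hubs), seed_genes = sort(seedGenes),
                disease_lncrnas = sort(disease))
  new("SyntheticDataset",
      expression = pairedExpressionSet(assays, ss),
      interactions = interactions, truth = truth, config = unclass(cfg))
}
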