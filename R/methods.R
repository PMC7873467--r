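#' Construct a PairedExpressionSet
#'
#' @param assays named list of numeric matrices (features x samples), names
#'   among \code{"mRNA"}, \code{"lncRNA"}, \code{"miRNA"}
#' @param sampleInfo data.frame with columns \code{sample_id},
#'   \code{patient_id}, \code{condition}
#' @return a validated [PairedExpressionSet-class]
#' @examples
#' ss <- data.frame(sample_id = c("P1_EC", "P1_EU", "P2_EC", "P2_EU"),
#'                  patient_id = rep(c("P1", "P2"), each = 2),
#'                  condition  = rep(c("EC", "EU"), 2))
#' m <- matrix(rnorm(8), 2, 4,
#'             dimnames = list(c("g1", "g2"), ss$sample_id))
#' pairedExpressionSet(list(mRNA = m), ss)
#' @export
pairedExpressionSet <- function(assays, sampleInfo) {
  sampleInfo <- as.data.frame(sampleInfo, stringsAsFactors = FALSE)
  sampleInfo$sample_id <- as.character(sampleInfo$sample_id)
  sampleInfo$patient_id <- as.character(sampleInfo$patient_id)
  sampleInfo$condition <- as.character(sampleInfo$condition)
  new("PairedExpressionSet", assays = assays, sampleInfo = sampleInfo)
}

#' Construct a MirnaInteractionSet, collapsing duplicate edges
#'
#' Duplicate (miRNA, target, class) rows are collapsed; the number removed is
#' reported with a message so no information is dropped silently.
#'
#' @param edges data.frame with columns \code{mirna_id}, \code{target_id},
#'   \code{target_class}
#' @return a validated [MirnaInteractionSet-class]
#' @export
mirnaInteractionSet <- function(edges) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% colnames(edges)))
    stop("interaction table needs columns ", paste(need, collapse = ", "))
  edges <- edges[need]
  for (cc in need) edges[[cc]] <- as.character(edges[[cc]])
  bad <- setdiff(unique(edges$target_class), c("mRNA", "lncRNA"))
  if (length(bad))
    stop("unknown target_class value(s): ", paste(bad, collapse = ", "))
  dup <- duplicated(edges)
  if (any(dup)) {
    message(sum(dup), " duplicate interaction edge(s) collapsed")
    edges <- edges[!dup, , drop = FALSE]
  }
  rownames(edges) <- NULL
  new("MirnaInteractionSet", edges = edges)
}

#' Construct a GeneSetCollection
#'
#' @param sets named list of character vectors of gene IDs
#' @param description optional named character vector of descriptions
#' @return a validated [GeneSetCollection-class]
#' @export
geneSetCollection <- function(sets, description = NULL) {
  if (is.null(description)) {
    description <- rep(NA_character_, length(sets))
    names(description) <- names(sets)
  }
  new("GeneSetCollection", sets = sets, description = description)
}

#' @describeIn exprMatrix matrix for one class of a PairedExpressionSet
#' @export
setMethod("exprMatrix", "PairedExpressionSet", function(x, rnaClass) {
  rnaClass <- match.arg(rnaClass, RNA_CLASSES)
  if (!rnaClass %in% names(x@assays))
    stop("no '", rnaClass, "' assay in this PairedExpressionSet")
  x@assays[[rnaClass]]
})

#' @describeIn sampleSheet sample sheet of a PairedExpressionSet
#' @export
setMethod("sampleSheet", "PairedExpressionSet", function(x) x@sampleInfo)

#' @describeIn rnaClasses classes present in a PairedExpressionSet
#' @export
setMethod("rnaClasses", "PairedExpressionSet", function(x) names(x@assays))

#' @describeIn interactionEdges edge table of a MirnaInteractionSet
#' @export
setMethod("interactionEdges", "MirnaInteractionSet", function(x) x@edges)

#' @describeIn networkEdges edge table of a CeRNANetwork
#' @export
setMethod("networkEdges", "CeRNANetwork", function(x) x@edges)

#' @describeIn rwrScores stationary scores of an RWRResult
#' @export
setMethod("rwrScores", "RWRResult", function(x) x@scores)

#' @describeIn lncrnaPvalues permutation p-values of an RWRResult
#' @export
setMethod("lncrnaPvalues", "RWRResult", function(x) x@lncrnaP)

#' @describeIn geneSets sets of a GeneSetCollection
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @describeIn truthManifest planted truth of a SyntheticDataset
#' @export
setMethod("truthManifest", "SyntheticDataset", function(x) x@truth)

setMethod("show", "PairedExpressionSet", function(object) {
  ss <- object@sampleInfo
  cat("PairedExpressionSet\n")
  cat("  patients:", length(unique(ss$patient_id)),
      " samples:", nrow(ss), "(EC/EU paired)\n")
  for (cls in names(object@assays))
    cat(sprintf("  %-7s %d features x %d samples\n", cls,
                nrow(object@assays[[cls]]), ncol(object@assays[[cls]])))
})

setMethod("show", "MirnaInteractionSet", function(object) {
  e <- object@edges
  cat("MirnaInteractionSet with", nrow(e), "edges\n")
  if (nrow(e)) {
    tab <- table(e$target_class)
    for (cls in names(tab))
      cat(sprintf("  miRNA-%s: %d edges, %d targets\n", cls, tab[[cls]],
                  length(unique(e$target_id[e$target_class == cls]))))
    cat("  miRNAs:", length(unique(e$mirna_id)), "\n")
  }
})

setMethod("show", "CeRNANetwork", function(object) {
  e <- object@edges
  cat("CeRNANetwork:", nrow(e), "lncRNA-mRNA competing pairs",
      sprintf("(p < %g)\n", object@alpha))
  cat("  lncRNAs:", length(unique(e$lncrna_id)),
      " mRNAs:", length(unique(e$mrna_id)),
      " miRNA universe:", length(object@universe), "\n")
})

setMethod("show", "RWRResult", function(object) {
  cat("RWRResult over", length(object@scores), "nodes;",
      length(object@lncrnaP), "lncRNAs scored\n")
  cat("  seeds:", paste(object@seeds, collapse = ", "), "\n")
  cat("  permutations:", object@nPermutations,
      "; significant lncRNAs (p <", object@alpha, "):",
      sum(object@lncrnaP < object@alpha), "\n")
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets;",
      "median size", if (length(object@sets))
        stats::median(lengths(object@sets)) else 0, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset (planted ground truth attached)\n")
  show(object@expression)
  show(object@interactions)
  tr <- object@truth
  cat("  planted DE:",
      paste(vapply(RNA_CLASSES, function(cl)
        sprintf("%s=%d", cl, nrow(tr$planted_de[[cl]])), ""), collapse = " "),
      "\n")
  cat("  planted pairs:", nrow(tr$planted_pairs),
      " hubs:", length(tr$hub_lncrnas),
      " seeds:", length(tr$seed_genes),
      " disease lncRNAs:", length(tr$disease_lncrnas), "\n")
})
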