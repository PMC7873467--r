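#' @import methods
NULL

RNA_CLASSES <- c("mRNA", "lncRNA", "miRNA")
CONDITIONS <- c("EC", "EU")

#' PairedExpressionSet: paired case/control expression matrices
#'
#' Container for log2-scale expression matrices (features x samples), one per
#' RNA class, together with a sample sheet pairing ectopic (EC) and eutopic
#' (EU) samples by patient.  Every sample column must appear in the sample
#' sheet and every patient must contribute exactly one EC and one EU sample
#' to every matrix.
#'
#' @slot assays named list of numeric matrices, names among
#'   \code{"mRNA"}, \code{"lncRNA"}, \code{"miRNA"}; rownames are feature IDs,
#'   colnames are sample IDs.
#' @slot sampleInfo data.frame with columns \code{sample_id},
#'   \code{patient_id}, \code{condition} (\code{"EC"} or \code{"EU"}).
#'
#' @seealso [pairedExpressionSet()], [readExpression()]
#' @exportClass PairedExpressionSet
setClass("PairedExpressionSet",
         representation(assays = "list", sampleInfo = "data.frame"))

setValidity("PairedExpressionSet", function(object) {
  ss <- object@sampleInfo
  need <- c("sample_id", "patient_id", "condition")
  if (!all(need %in% colnames(ss)))
    return(sprintf("sample sheet must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(ss$sample_id))
    return("duplicated sample_id in sample sheet")
  if (!all(ss$condition %in% CONDITIONS))
    return("condition must be 'EC' or 'EU'")
  if (length(object@assays) == 0L) return("no assay matrices")
  if (is.null(names(object@assays)) || !all(names(object@assays) %in% RNA_CLASSES))
    return(sprintf("assay names must be among %s", paste(RNA_CLASSES, collapse = ", ")))
  for (cls in names(object@assays)) {
    m <- object@assays[[cls]]
    if (!is.matrix(m) || !is.numeric(m))
      return(sprintf("assay '%s' is not a numeric matrix", cls))
    if (anyNA(m)) return(sprintf("assay '%s' contains missing values", cls))
    if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
      return(sprintf("assay '%s' needs unique feature IDs as rownames", cls))
    if (is.null(colnames(m)) || !all(colnames(m) %in% ss$sample_id))
      return(sprintf("assay '%s' has samples absent from the sample sheet", cls))
    sub <- ss[match(colnames(m), ss$sample_id), ]
    tab <- table(sub$patient_id, factor(sub$condition, levels = CONDITIONS))
    if (any(tab != 1L)) {
      bad <- rownames(tab)[rowSums(tab != 1L) > 0][1L]
      return(sprintf("patient '%s' lacks a complete EC/EU pair in assay '%s'", bad, cls))
    }
  }
  TRUE
})

#' MirnaInteractionSet: bipartite miRNA-target interactions
#'
#' A deduplicated edge table of miRNA -> target interactions, with targets
#' typed as mRNA or lncRNA (e.g. CLIP-seq-supported pairs as distributed by
#' interaction databases such as StarBase).
#'
#' @slot edges data.frame with character columns \code{mirna_id},
#'   \code{target_id}, \code{target_class} (one of \code{"mRNA"},
#'   \code{"lncRNA"}).
#'
#' @seealso [readInteractions()], [mirnaInteractionSet()]
#' @exportClass MirnaInteractionSet
setClass("MirnaInteractionSet", representation(edges = "data.frame"))

setValidity("MirnaInteractionSet", function(object) {
  e <- object@edges
  need <- c("mirna_id", "target_id", "target_class")
  if (!all(need %in% colnames(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e) && !all(e$target_class %in% c("mRNA", "lncRNA")))
    return("target_class must be 'mRNA' or 'lncRNA'")
  if (anyDuplicated(e[c("mirna_id", "target_id", "target_class")]))
    return("duplicate edges present; use mirnaInteractionSet() to collapse them")
  TRUE
})

#' CeRNANetwork: lncRNA-mRNA competing-pair network
#'
#' Undirected bipartite network of lncRNA-mRNA pairs retained by the
#' hypergeometric shared-miRNA test.  Each edge carries its evidence: the
#' miRNA universe size T, the partner counts t (mRNA) and N (lncRNA), the
#' shared count r, the shared miRNA identities, and the upper-tail p-value.
#'
#' @slot edges data.frame with columns \code{lncrna_id}, \code{mrna_id},
#'   \code{T}, \code{t}, \code{N}, \code{r}, \code{p_value} and a list column
#'   \code{shared_mirnas}.
#' @slot alpha numeric, the p-value threshold the edges were filtered at.
#' @slot universe character vector of miRNA IDs used as the universe.
#'
#' @seealso [buildCernaNetwork()], [cernaGraph()]
#' @exportClass CeRNANetwork
setClass("CeRNANetwork",
         representation(edges = "data.frame", alpha = "numeric",
                        universe = "character"))

setValidity("CeRNANetwork", function(object) {
  e <- object@edges
  need <- c("lncrna_id", "mrna_id", "T", "t", "N", "r", "p_value", "shared_mirnas")
  if (!all(need %in% colnames(e)))
    return(sprintf("edges must have columns %s", paste(need, collapse = ", ")))
  if (nrow(e)) {
    if (any(e$r > pmin(e$t, e$N)) || any(e$t > e$T) || any(e$N > e$T))
      return("count invariants violated: need r <= min(t, N) and t, N <= T")
    if (any(e$p_value < 0 | e$p_value > 1)) return("p_value outside [0, 1]")
    if (any(lengths(e$shared_mirnas) != e$r))
      return("length of shared_mirnas must equal r")
    if (length(object@alpha) == 1L && any(e$p_value >= object@alpha))
      return("edges present with p_value >= alpha (post-filter state violated)")
  }
  TRUE
})

#' RWRResult: random-walk-with-restart scores and permutation p-values
#'
#' @slot scores named numeric vector, stationary probability per network node.
#' @slot lncrnaP named numeric vector, empirical permutation p-value per
#'   lncRNA node (M/N with M = permutations scoring strictly higher).
#' @slot nPermutations integer, number of seed-shuffled walks.
#' @slot seeds character, the real seed genes used.
#' @slot alpha numeric, significance threshold on the permutation p.
#'
#' @seealso [rwrPermutationTest()], [rankLncrnas()]
#' @exportClass RWRResult
setClass("RWRResult",
         representation(scores = "numeric", lncrnaP = "numeric",
                        nPermutations = "integer", seeds = "character",
                        alpha = "numeric"))

setValidity("RWRResult", function(object) {
  if (any(object@scores < -1e-12)) return("negative stationary scores")
  if (length(object@scores) &&
      abs(sum(object@scores) - 1) > 1e-6) return("scores do not sum to 1")
  if (length(object@lncrnaP) &&
      (any(object@lncrnaP < 0) || any(object@lncrnaP > 1)))
    return("permutation p-values outside [0, 1]")
  TRUE
})

#' GeneSetCollection: named gene sets for over-representation analysis
#'
#' @slot sets named list of character vectors (gene IDs); names unique,
#'   sets non-empty.
#' @slot description named character vector of set descriptions.
#'
#' @seealso [readGmt()], [ora()]
#' @exportClass GeneSetCollection
setClass("GeneSetCollection",
         representation(sets = "list", description = "character"))

setValidity("GeneSetCollection", function(object) {
  if (length(object@sets)) {
    if (is.null(names(object@sets)) || anyDuplicated(names(object@sets)))
      return("set names must be present and unique")
    if (any(lengths(object@sets) == 0L)) return("empty gene set")
  }
  TRUE
})

#' SyntheticDataset: generated expression, interactions and planted truth
#'
#' @slot expression a [PairedExpressionSet-class] with all three RNA classes.
#' @slot interactions a [MirnaInteractionSet-class].
#' @slot truth list of planted ground truth: per-class data.frames of planted
#'   differentially expressed features with direction, the planted ceRNA
#'   pairs, hub lncRNAs, designated seed genes and disease-proximal lncRNAs.
#' @slot config the validated generator configuration used.
#'
#' @seealso [generateDataset()], [writeFixture()]
#' @exportClass SyntheticDataset
setClass("SyntheticDataset",
         representation(expression = "PairedExpressionSet",
                        interactions = "MirnaInteractionSet",
                        truth = "list", config = "list"))
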