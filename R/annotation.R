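#' Select positively co-expressed competing mRNAs of a lncRNA
#'
#' For each competing mRNA, computes the Pearson correlation coefficient
#' (PCC) with the focal lncRNA across the shared samples and a two-sided
#' p-value from the t transform \eqn{t = PCC \sqrt{(m-2)/(1-PCC^2)}} with
#' m - 2 degrees of freedom.  An mRNA is selected when p < \code{alpha} and
#' PCC > 0.  By default all EC and EU samples are pooled; restrict with
#' \code{conditions}.  Correlation p-values are deliberately not
#' multiplicity-adjusted at this selection step.
#'
#' @param expr a [PairedExpressionSet-class] with mRNA and lncRNA assays
#' @param lncrna focal lncRNA ID
#' @param mrnas character vector of competing mRNA IDs
#' @param alpha selection threshold on the correlation p (default 0.05)
#' @param conditions which conditions' samples to use (default both)
#' @return data.frame with columns \code{mrna}, \code{pcc}, \code{p_value},
#'   \code{selected}; zero-variance mRNAs are excluded with a warning
#' @export
pearsonSelect <- function(expr, lncrna, mrnas, alpha = 0.05,
                          conditions = c("EC", "EU")) {
  stopifnot(is(expr, "PairedExpressionSet"))
  lmat <- exprMatrix(expr, "lncRNA")
  mmat <- exprMatrix(expr, "mRNA")
  if (!lncrna %in% rownames(lmat)) stop("lncRNA '", lncrna, "' not found")
  missing <- setdiff(mrnas, rownames(mmat))
  if (length(missing))
    stop("mRNA(s) not found: ", paste(missing, collapse = ", "))
  ss <- sampleSheet(expr)
  use <- intersect(intersect(colnames(lmat), colnames(mmat)),
                   ss$sample_id[ss$condition %in% conditions])
  if (length(use) < 3)
    stop("need at least 3 common samples, got ", length(use))
  x <- lmat[lncrna, use]
  if (stats::sd(x) == 0) stop("lncRNA '", lncrna, "' has zero variance")
  rows <- lapply(mrnas, function(mid) {
    y <- mmat[mid, use]
    if (stats::sd(y) == 0) {
      warning("mRNA '", mid, "' has zero variance; PCC undefined, excluded")
      return(NULL)
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    data.frame(mrna = mid, pcc = unname(ct$estimate),
               p_value = ct$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(mrna = character(0), pcc = numeric(0),
                      p_value = numeric(0))
  out$selected <- out$p_value < alpha & out$pcc > 0
  rownames(out) <- NULL
  attr(out, "lncrna") <- lncrna
  out
}

#' Over-representation analysis against a gene-set collection
#'
#' Offline hypergeometric enrichment of a query gene list: per set, the
#' upper-tail probability of the observed overlap given the universe size,
#' via the same [hypergeomP()] machinery used for the ceRNA pair test
#' (T = universe size, t = set size within the universe, N = query size,
#' r = overlap), with Benjamini-Hochberg adjustment across sets.
#'
#' @param queryGenes character vector of query gene IDs (must be a subset of
#'   \code{universe})
#' @param collection a [GeneSetCollection-class]; sets are intersected with
#'   the universe
#' @param universe character vector of background gene IDs
#' @return data.frame with columns \code{set}, \code{description},
#'   \code{overlap}, \code{set_size}, \code{universe_size}, \code{p_value},
#'   \code{p_adj}, sorted by p
#' @export
ora <- function(queryGenes, collection, universe) {
  stopifnot(is(collection, "GeneSetCollection"))
  queryGenes <- unique(queryGenes); universe <- unique(universe)
  if (!length(queryGenes)) stop("empty query gene list")
  if (!length(universe)) stop("empty universe")
  outside <- setdiff(queryGenes, universe)
  if (length(outside))
    stop("query gene(s) outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "))
  sets <- lapply(geneSets(collection), intersect, universe)
  Tn <- length(universe); Nq <- length(queryGenes)
  rows <- lapply(names(sets), function(nm) {
    s <- sets[[nm]]
    r <- length(intersect(s, queryGenes))
    data.frame(set = nm, description = collection@description[[nm]],
               overlap = r, set_size = length(s), universe_size = Tn,
               p_value = hypergeomP(Tn, length(s), Nq, r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p_value, "BH")
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out
}
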