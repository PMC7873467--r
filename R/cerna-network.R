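#' Upper-tail hypergeometric probability of shared miRNA partners
#'
#' Probability that a lncRNA and an mRNA share at least \code{r} miRNA
#' partners by chance, given their individual partner counts within a miRNA
#' universe of size \code{T}: \eqn{P(X \ge r)} for
#' \eqn{X \sim \mathrm{Hypergeometric}(T, t, N)}.  The sum is evaluated over
#' the upper tail directly (no subtraction from one, so no cancellation) in
#' log space, with the per-instance shift taken at the distribution mode so
#' large universes do not overflow.
#'
#' @param T miRNA universe size (integer, vectorised)
#' @param t number of miRNAs interacting with the mRNA
#' @param N number of miRNAs interacting with the lncRNA
#' @param r number of shared miRNAs
#' @return numeric vector of probabilities in \eqn{[0, 1]}; \code{r <= 0}
#'   gives exactly 1
#' @examples
#' hypergeomP(10, 3, 3, 3)   # 1 / choose(10, 3) = 1/120
#' hypergeomP(4, 2, 2, 1)    # 5/6
#' @export
hypergeomP <- function(T, t, N, r) {
  n <- max(length(T), length(t), length(N), length(r))
  T <- rep_len(as.numeric(T), n); t <- rep_len(as.numeric(t), n)
  N <- rep_len(as.numeric(N), n); r <- rep_len(as.numeric(r), n)
  if (any(T < 0 | t < 0 | N < 0))
    stop("counts must be nonnegative")
  if (any(t > T | N > T))
    stop("domain error: need t <= T and N <= T")
  if (any(r > pmin(t, N)))
    stop("domain error: need r <= min(t, N)")
  p <- rep(1, n)                      # r <= 0: empty lower sum, P = 1
  act <- which(r >= 1)
  if (!length(act)) return(p)
  kmax <- pmin(t, N)
  len <- kmax[act] - r[act] + 1
  idx <- rep(act, len)
  k <- sequence(len, from = r[act])
  logterm <- lchoose(t[idx], k) + lchoose(T[idx] - t[idx], N[idx] - k) -
    lchoose(T[idx], N[idx])
  # terms are unimodal in k with mode floor((t+1)(N+1)/(T+2)); shifting by the
  # clamped mode makes the grouped sum of exponentials overflow-safe
  kstar <- pmax(r[act], pmin(kmax[act],
                             floor((t[act] + 1) * (N[act] + 1) / (T[act] + 2))))
  shift <- lchoose(t[act], kstar) + lchoose(T[act] - t[act], N[act] - kstar) -
    lchoose(T[act], N[act])
  shift[!is.finite(shift)] <- 0
  sums <- rowsum(exp(logterm - shift[match(idx, act)]), idx)[, 1]
  p[act] <- pmin(1, exp(shift + log(sums)))
  p
}

#' Build the ceRNA network by the hypergeometric shared-miRNA test
#'
#' Restricts the miRNA-target interaction tables to differentially expressed
#' RNAs, then tests every candidate (lncRNA, mRNA) pair sharing at least one
#' miRNA for a significant excess of shared miRNA partners.  A pair is kept
#' when its upper-tail hypergeometric p-value is below \code{alpha}
#' (raw p, no multiplicity adjustment, matching common ceRNA practice; set
#' \code{adjust = TRUE} for Benjamini-Hochberg across candidate pairs).
#'
#' @param de named list with elements \code{mRNA}, \code{lncRNA},
#'   \code{miRNA}, each a differential-expression table as returned by
#'   [pairedModeratedTest()] (only the \code{feature} and \code{significant}
#'   columns are used)
#' @param interactions a [MirnaInteractionSet-class]
#' @param alpha edge significance threshold on the hypergeometric p
#'   (default 0.01)
#' @param universeMode how the miRNA universe size T is defined:
#'   \code{"interaction-union"} (default: all miRNAs present in either
#'   DE-filtered interaction table, keeping T, t, N, r internally consistent),
#'   \code{"de-only"} (all differentially expressed miRNAs), or
#'   \code{"all-annotated"} (a caller-supplied count via \code{universeSize}).
#'   T changes every p-value, so the choice is reported in the object.
#' @param universeSize integer, required for
#'   \code{universeMode = "all-annotated"}
#' @param requireDeTargets require lncRNA and mRNA endpoints to be
#'   differentially expressed (default TRUE)
#' @param filterDeMirna restrict interactions to differentially expressed
#'   miRNAs before computing overlaps (default TRUE)
#' @param adjust apply Benjamini-Hochberg across candidate pairs before
#'   filtering (default FALSE, i.e. raw p < alpha)
#' @return a [CeRNANetwork-class]
#' @export
buildCernaNetwork <- function(de, interactions, alpha = 0.01,
                              universeMode = c("interaction-union",
                                               "de-only", "all-annotated"),
                              universeSize = NULL,
                              requireDeTargets = TRUE,
                              filterDeMirna = TRUE,
                              adjust = FALSE) {
  universeMode <- match.arg(universeMode)
  stopifnot(is(interactions, "MirnaInteractionSet"))
  for (cls in RNA_CLASSES)
    if (is.null(de[[cls]]))
      stop("differential-expression results required for class '", cls, "'")
  edges <- interactionEdges(interactions)
  if (!nrow(edges)) stop("empty interaction set")

  sigOf <- function(cls) de[[cls]]$feature[de[[cls]]$significant]
  if (filterDeMirna)
    edges <- edges[edges$mirna_id %in% sigOf("miRNA"), , drop = FALSE]
  if (requireDeTargets) {
    keep <- (edges$target_class == "mRNA" & edges$target_id %in% sigOf("mRNA")) |
      (edges$target_class == "lncRNA" & edges$target_id %in% sigOf("lncRNA"))
    edges <- edges[keep, , drop = FALSE]
  }
  universe <- switch(universeMode,
    "interaction-union" = sort(unique(edges$mirna_id)),
    "de-only" = sort(unique(sigOf("miRNA"))),
    "all-annotated" = {
      if (is.null(universeSize))
        stop("universeSize is required for universeMode = 'all-annotated'")
      character(0)
    })
  Tn <- if (universeMode == "all-annotated") as.integer(universeSize)
        else length(universe)

  empty <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                      T = integer(0), t = integer(0), N = integer(0),
                      r = integer(0), p_value = numeric(0))
  empty$shared_mirnas <- list()
  if (!nrow(edges)) {
    warning("no interactions remain after differential-expression filtering; ",
            "returning an empty network")
    return(new("CeRNANetwork", edges = empty, alpha = alpha,
               universe = universe))
  }

  mEdges <- edges[edges$target_class == "mRNA", , drop = FALSE]
  lEdges <- edges[edges$target_class == "lncRNA", , drop = FALSE]
  mPartners <- split(mEdges$mirna_id, mEdges$target_id)
  lPartners <- split(lEdges$mirna_id, lEdges$target_id)
  if (!length(mPartners) || !length(lPartners)) {
    warning("no candidate lncRNA-mRNA pairs after filtering; ",
            "returning an empty network")
    return(new("CeRNANetwork", edges = empty, alpha = alpha,
               universe = universe))
  }

  # enumerate candidates with r >= 1 via the shared-miRNA incidence product
  mirnas <- sort(unique(edges$mirna_id))
  inc <- function(partners) {
    M <- matrix(0L, length(partners), length(mirnas),
                dimnames = list(names(partners), mirnas))
    for (i in seq_along(partners))
      M[i, match(unique(partners[[i]]), mirnas)] <- 1L
    M
  }
  Ml <- inc(lPartners)                 # lncRNA x miRNA
  Mm <- inc(mPartners)                 # mRNA  x miRNA
  shared <- Ml %*% t(Mm)               # lncRNA x mRNA shared counts
  hit <- which(shared >= 1L, arr.ind = TRUE)
  if (!nrow(hit)) {
    return(new("CeRNANetwork", edges = empty, alpha = alpha,
               universe = universe))
  }
  lnc <- rownames(Ml)[hit[, 1]]
  mrn <- rownames(Mm)[hit[, 2]]
  r <- shared[hit]
  t_ <- rowSums(Mm)[hit[, 2]]
  N_ <- rowSums(Ml)[hit[, 1]]
  p <- hypergeomP(Tn, t_, N_, r)
  padj <- if (adjust) stats::p.adjust(p, "BH") else p
  keep <- padj < alpha
  if (!any(keep))
    return(new("CeRNANetwork", edges = empty, alpha = alpha,
               universe = universe))
  sharedSets <- lapply(which(keep), function(i) {
    sort(intersect(lPartners[[lnc[i]]], mPartners[[mrn[i]]]))
  })
  out <- data.frame(lncrna_id = lnc[keep], mrna_id = mrn[keep],
                    T = as.integer(Tn), t = as.integer(t_[keep]),
                    N = as.integer(N_[keep]), r = as.integer(r[keep]),
                    p_value = padj[keep], stringsAsFactors = FALSE)
  out$shared_mirnas <- sharedSets
  out <- out[order(out$lncrna_id, out$mrna_id), , drop = FALSE]
  rownames(out) <- NULL
  new("CeRNANetwork", edges = out, alpha = alpha, universe = universe)
}

#' igraph view of a ceRNA network
#'
#' @param network a [CeRNANetwork-class]
#' @return an undirected \pkg{igraph} graph with a vertex attribute
#'   \code{class} (\code{"lncRNA"} or \code{"mRNA"})
#' @export
cernaGraph <- function(network) {
  e <- networkEdges(network)
  g <- igraph::graph_from_data_frame(
    e[c("lncrna_id", "mrna_id")], directed = FALSE,
    vertices = data.frame(
      name = c(unique(e$lncrna_id), unique(e$mrna_id)),
      class = rep(c("lncRNA", "mRNA"),
                  c(length(unique(e$lncrna_id)),
                    length(unique(e$mrna_id))))))
  igraph::set_edge_attr(g, "p_value", value = e$p_value)
}

#' Extract the lncRNA-miRNA-mRNA sub-network around one lncRNA
#'
#' Restores the shared-miRNA annotations stored on the competing edges to
#' rebuild the triple (lncRNA, miRNA, mRNA) neighbourhood of a focal lncRNA.
#'
#' @param network a [CeRNANetwork-class]
#' @param lncrna focal lncRNA ID
#' @return an undirected igraph graph whose vertices carry a \code{class}
#'   attribute in \code{lncRNA}/\code{miRNA}/\code{mRNA}; edges are
#'   lncRNA-miRNA and miRNA-mRNA links through the shared miRNAs
#' @export
extractSubnetwork <- function(network, lncrna) {
  e <- networkEdges(network)
  sel <- e$lncrna_id == lncrna
  if (!any(sel))
    stop("lncRNA '", lncrna, "' is not present in the network")
  e <- e[sel, , drop = FALSE]
  lm <- do.call(rbind, lapply(seq_len(nrow(e)), function(i)
    if (length(e$shared_mirnas[[i]]))
      data.frame(from = e$shared_mirnas[[i]], to = e$mrna_id[i]) else NULL))
  mir <- sort(unique(unlist(e$shared_mirnas)))
  el <- rbind(data.frame(from = lncrna, to = mir), lm)
  verts <- data.frame(name = c(lncrna, mir, unique(e$mrna_id)),
                      class = c("lncRNA", rep("miRNA", length(mir)),
                                rep("mRNA", length(unique(e$mrna_id)))))
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' miRNA partners of a target in an interaction set
#'
#' @param interactions a [MirnaInteractionSet-class]
#' @param target target ID (mRNA or lncRNA)
#' @return character vector of miRNA IDs interacting with the target
#' @export
mirnaPartners <- function(interactions, target) {
  e <- interactionEdges(interactions)
  sort(unique(e$mirna_id[e$target_id == target]))
}
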