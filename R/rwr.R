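#' Random-walk-with-restart configuration
#'
#' @param restart restart probability r at every step, in (0, 1]
#'   (default 0.5)
#' @param tol convergence cutoff on the L1 difference between successive
#'   probability vectors (default 1e-10)
#' @param maxIter safety bound on iterations (default 10000)
#' @param seeds character vector of seed gene IDs (must be network nodes)
#' @param nPermutations number of seed-shuffled walks for the empirical null
#'   (default 10000)
#' @param permSeed RNG seed making the permutation draw reproducible
#' @param alpha significance threshold on the permutation p (default 0.01)
#' @param pseudocount use (M+1)/(N+1) instead of M/N for the permutation p,
#'   avoiding exact zeros (default FALSE, plain M/N)
#' @return validated config list of class \code{RWRConfig}
#' @export
rwrConfig <- function(restart = 0.5, tol = 1e-10, maxIter = 10000L,
                      seeds = character(0), nPermutations = 10000L,
                      permSeed = 1L, alpha = 0.01, pseudocount = FALSE) {
  stopifnot(restart > 0, restart <= 1, tol > 0, maxIter >= 1)
  cfg <- list(restart = restart, tol = tol, maxIter = as.integer(maxIter),
              seeds = as.character(seeds),
              nPermutations = as.integer(nPermutations),
              permSeed = as.integer(permSeed), alpha = alpha,
              pseudocount = isTRUE(pseudocount))
  class(cfg) <- "RWRConfig"
  cfg
}

# column-normalized adjacency + node metadata for the walk
.rwrMatrix <- function(network) {
  g <- if (is(network, "CeRNANetwork")) cernaGraph(network) else network
  iso <- which(igraph::degree(g) == 0)
  if (length(iso)) g <- igraph::delete_vertices(g, iso)  # prune isolated nodes
  A <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  degs <- colSums(A)
  W <- sweep(A, 2, pmax(degs, 1), "/")   # zero columns cannot occur post-prune
  list(W = W, nodes = colnames(A),
       class = igraph::vertex_attr(g, "class"))
}

.propagateCore <- function(W, p0, restart, tol, maxIter) {
  p <- p0
  for (it in seq_len(maxIter)) {
    pNew <- (1 - restart) * drop(W %*% p) + restart * p0
    deficit <- 1 - sum(pNew)             # mass lost to dangling columns, if any
    if (abs(deficit) > 1e-15) pNew <- pNew + deficit * p0
    res <- sum(abs(pNew - p))
    p <- pNew
    if (res < tol) return(list(p = p, iter = it, residual = res))
  }
  stop("random walk did not converge within ", maxIter,
       " iterations (L1 residual ", format(res), ")")
}

#' Random walk with restart over the ceRNA network
#'
#' Iterates \eqn{P_{t+1} = (1 - r) W P_t + r P_0} from \eqn{P_t = P_0}, where
#' W is the column-normalised adjacency matrix and \eqn{P_0} places mass 1/n
#' on each of the n seed nodes, until the L1 difference between successive
#' vectors falls below \code{tol}.  Isolated nodes are pruned before the
#' walk; the walk runs on the bipartite lncRNA-mRNA network (miRNA nodes are
#' not part of it).
#'
#' @param network a [CeRNANetwork-class] or igraph graph
#' @param config an \code{RWRConfig} from [rwrConfig()]; its \code{seeds}
#'   must be nodes of the network
#' @return named numeric vector of stationary probabilities (sums to 1)
#' @export
rwrPropagate <- function(network, config) {
  stopifnot(inherits(config, "RWRConfig"))
  m <- .rwrMatrix(network)
  missing <- setdiff(config$seeds, m$nodes)
  if (!length(config$seeds)) stop("no seed genes supplied")
  if (length(missing))
    stop("seed gene(s) not found in the network: ",
         paste(missing, collapse = ", "))
  p0 <- stats::setNames(numeric(length(m$nodes)), m$nodes)
  p0[config$seeds] <- 1 / length(config$seeds)
  .propagateCore(m$W, p0, config$restart, config$tol, config$maxIter)$p
}

#' Seed-shuffling permutation test for lncRNA prioritisation
#'
#' Runs the restart walk with the real disease-gene seeds, then repeats it
#' \code{nPermutations} times with seed sets of the same size drawn uniformly
#' without replacement from the network's mRNA nodes.  Each lncRNA's
#' empirical p-value is M/N, where M counts the permutations in which its
#' score was strictly greater than under the real seeds and N is the number
#' of permutations.
#'
#' @param network a [CeRNANetwork-class] (node classes are needed to know
#'   which nodes are mRNAs and lncRNAs), or an igraph graph with a
#'   \code{class} vertex attribute
#' @param config an \code{RWRConfig} from [rwrConfig()]
#' @param degreeMatched draw permuted seeds degree-matched to the real seeds
#'   (within-degree-bin sampling) instead of uniformly (default FALSE)
#' @return an [RWRResult-class]
#' @export
rwrPermutationTest <- function(network, config, degreeMatched = FALSE) {
  stopifnot(inherits(config, "RWRConfig"))
  if (config$nPermutations < 1)
    stop("nPermutations must be >= 1 (the ratio M/N is undefined for N = 0)")
  m <- .rwrMatrix(network)
  if (is.null(m$class))
    stop("network nodes need a 'class' attribute (lncRNA/mRNA)")
  real <- rwrPropagate(network, config)
  mrnas <- m$nodes[m$class == "mRNA"]
  lncs <- m$nodes[m$class == "lncRNA"]
  ns <- length(config$seeds)
  if (ns > length(mrnas))
    stop("more seeds (", ns, ") than mRNA nodes (", length(mrnas), ")")

  runner <- function(seedSet) {
    p0 <- stats::setNames(numeric(length(m$nodes)), m$nodes)
    p0[seedSet] <- 1 / length(seedSet)
    .propagateCore(m$W, p0, config$restart, config$tol, config$maxIter)$p[lncs]
  }
  realLnc <- real[lncs]
  M <- stats::setNames(numeric(length(lncs)), lncs)

  oldSeed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(oldSeed))
    assign(".Random.seed", oldSeed, envir = globalenv()))
  set.seed(config$permSeed)

  degBin <- NULL
  if (degreeMatched) {
    degs <- colSums(m$W > 0)
    bins <- cut(log2(degs[mrnas] + 1), breaks = 6)
    degBin <- split(mrnas, bins)
    realBins <- as.character(bins[match(config$seeds, mrnas)])
  }
  for (b in seq_len(config$nPermutations)) {
    perm <- if (degreeMatched) {
      unlist(lapply(realBins, function(bn) {
        pool <- degBin[[bn]]
        pool[sample.int(length(pool), 1L)]
      }))
    } else sample(mrnas, ns)
    M <- M + (runner(perm) > realLnc)
  }
  N <- config$nPermutations
  pvals <- if (config$pseudocount) (M + 1) / (N + 1) else M / N
  new("RWRResult", scores = real, lncrnaP = pvals,
      nPermutations = as.integer(N), seeds = config$seeds,
      alpha = config$alpha)
}

#' Rank candidate lncRNAs by stationary probability
#'
#' @param result an [RWRResult-class]
#' @return data.frame with columns \code{lncrna}, \code{score},
#'   \code{p_value}, \code{significant}, sorted by descending score with a
#'   lexicographic tie-break
#' @export
rankLncrnas <- function(result) {
  stopifnot(is(result, "RWRResult"))
  lncs <- names(lncrnaPvalues(result))
  if (!length(lncs))
    return(data.frame(lncrna = character(0), score = numeric(0),
                      p_value = numeric(0), significant = logical(0)))
  sc <- rwrScores(result)[lncs]
  ord <- order(-sc, lncs)
  out <- data.frame(lncrna = lncs[ord], score = unname(sc[ord]),
                    p_value = unname(lncrnaPvalues(result)[lncs][ord]),
                    stringsAsFactors = FALSE)
  out$significant <- out$p_value < result@alpha
  out
}
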