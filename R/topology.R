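#' Node centralities of a ceRNA network
#'
#' Computes, for every node of the (undirected, unweighted) network:
#' degree (incident edge count); betweenness (number of shortest paths
#' passing through the node, equal-length paths split evenly, normalised by
#' \eqn{(n-1)(n-2)/2}); and closeness with Wasserman-Faust component
#' scaling, \eqn{(r/(n-1)) \cdot (r / \sum d)} where r is the number of
#' other nodes reachable from the node and the distance sum runs over them.
#' Scores lie in [0, 1]; on a connected graph this is ordinary normalised
#' closeness, while on a disconnected graph the first factor downweights
#' small components so scores stay comparable across components (isolated
#' nodes score 0).
#'
#' @param network a [CeRNANetwork-class] or an igraph graph
#' @return data.frame with columns \code{node}, \code{class} (if available),
#'   \code{degree}, \code{betweenness}, \code{closeness}, one row per node
#' @export
centralities <- function(network) {
  g <- if (is(network, "CeRNANetwork")) cernaGraph(network) else network
  n <- igraph::vcount(g)
  if (n < 2) stop("centralities need a network with at least 2 nodes")
  deg <- igraph::degree(g)
  btw <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
  btw[!is.finite(btw)] <- 0            # n = 2: no possible intermediates
  dmat <- igraph::distances(g)
  clo <- apply(dmat, 1, function(dd) {
    reach <- sum(is.finite(dd)) - 1           # others in the same component
    if (reach == 0) 0
    else (reach / (n - 1)) * (reach / sum(dd[is.finite(dd)]))
  })
  cls <- igraph::vertex_attr(g, "class")
  out <- data.frame(node = igraph::V(g)$name,
                    class = if (is.null(cls)) NA_character_ else cls,
                    degree = as.integer(deg), betweenness = unname(btw),
                    closeness = unname(clo), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Top-k nodes by a centrality metric
#'
#' Descending sort with a deterministic lexicographic tie-break on node ID.
#'
#' @param report centrality table from [centralities()]
#' @param metric one of \code{"degree"}, \code{"betweenness"},
#'   \code{"closeness"}
#' @param k list length (default 10)
#' @return character vector of node IDs, best first
#' @export
topK <- function(report, metric = c("degree", "betweenness", "closeness"),
                 k = 10) {
  metric <- match.arg(metric)
  if (k > nrow(report))
    stop("k = ", k, " exceeds the number of nodes (", nrow(report), ")")
  ord <- order(-report[[metric]], report$node)
  report$node[ord][seq_len(k)]
}

#' Hub nomination: intersection of the three top-k centrality lists
#'
#' @param report centrality table from [centralities()]
#' @param k list length per metric (default 10, following common practice of
#'   ranking the top ten nodes per topological feature)
#' @return sorted character vector of nodes present in all three top-k lists
#' @export
hubIntersection <- function(report, k = 10) {
  lists <- lapply(c("degree", "betweenness", "closeness"),
                  function(m) topK(report, m, k))
  intersectRankedLists(lists)
}

#' Intersect ranked node lists
#'
#' @param lists list of character vectors (e.g. the printed top-ten lists of
#'   degree, betweenness and closeness)
#' @return sorted character vector of the common members
#' @export
intersectRankedLists <- function(lists) {
  sort(Reduce(intersect, lists))
}

#' Degree distribution and log-log power-law fit summary
#'
#' Tabulates the empirical degree histogram (optionally per node class) and,
#' when at least 5 distinct degrees are present, fits log(frequency) against
#' log(degree) by ordinary least squares over nonzero bins; the slope and
#' R-squared give a quick power-law shape check (not a rigorous power-law
#' test).
#'
#' @param report centrality table from [centralities()]
#' @param byClass split by the \code{class} column when present
#'   (default TRUE)
#' @return list with \code{histogram} (data.frame class/degree/frequency) and
#'   \code{fit} (data.frame class/slope/r_squared, NA rows where the fit was
#'   skipped with a warning)
#' @export
degreeDistribution <- function(report, byClass = TRUE) {
  groups <- if (byClass && !all(is.na(report$class)))
    split(report, report$class) else list(all = report)
  hist <- do.call(rbind, lapply(names(groups), function(gn) {
    tab <- table(groups[[gn]]$degree)
    data.frame(class = gn, degree = as.integer(names(tab)),
               frequency = as.integer(tab), stringsAsFactors = FALSE)
  }))
  fit <- do.call(rbind, lapply(names(groups), function(gn) {
    h <- hist[hist$class == gn & hist$degree > 0 & hist$frequency > 0, ]
    if (length(unique(h$degree)) < 5) {
      warning("fewer than 5 distinct degrees for class '", gn,
              "'; power-law fit skipped")
      return(data.frame(class = gn, slope = NA_real_, r_squared = NA_real_))
    }
    m <- stats::lm(log(frequency) ~ log(degree), data = h)
    data.frame(class = gn, slope = unname(stats::coef(m)[2]),
               r_squared = summary(m)$r.squared, stringsAsFactors = FALSE)
  }))
  rownames(hist) <- rownames(fit) <- NULL
  list(histogram = hist, fit = fit)
}
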