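classedGraph <- function(edges, lncs) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  igraph::V(g)$class <- ifelse(igraph::V(g)$name %in% lncs, "lncRNA", "mRNA")
  g
}

test_that("restart probability one pins the walk at the seed distribution", {
  g <- classedGraph(data.frame(from = c("a", "b"), to = c("b", "c")), "c")
  p <- rwrPropagate(g, rwrConfig(restart = 1, seeds = "a"))
  expect_equal(unname(p[c("a", "b", "c")]), c(1, 0, 0))
})

test_that("the two-node walk matches its closed-form fixed point", {
  # p = 0.5 W p + 0.5 e_a with W = [[0,1],[1,0]] solves to (2/3, 1/3)
  g <- classedGraph(data.frame(from = "a", to = "b"), character(0))
  p <- rwrPropagate(g, rwrConfig(restart = 0.5, seeds = "a"))
  expect_equal(unname(p[c("a", "b")]), c(2 / 3, 1 / 3), tolerance = 1e-9)
})

test_that("a fully seeded triangle stays uniform", {
  g <- classedGraph(data.frame(from = c("a", "b", "c"), to = c("b", "c", "a")),
                    character(0))
  p <- rwrPropagate(g, rwrConfig(seeds = c("a", "b", "c")))
  expect_equal(unname(p), rep(1 / 3, 3), tolerance = 1e-12)
})

test_that("iterative propagation equals the dense linear solve on random graphs", {
  set.seed(123)
  worst <- 0
  for (i in 1:40) {
    n <- sample(5:30, 1)
    A <- randomAdjacency(n, runif(1, 0.1, 0.4))
    g <- graphFromAdjacency(A)
    keep <- rownames(A)[rowSums(A) > 0]
    seeds <- sample(keep, sample(seq_len(min(3, length(keep))), 1))
    p <- rwrPropagate(g, rwrConfig(restart = 0.5, tol = 1e-10, seeds = seeds))
    Asub <- A[names(p), names(p)]
    W <- sweep(Asub, 2, colSums(Asub), "/")
    p0 <- setNames(numeric(length(p)), names(p))
    p0[seeds] <- 1 / length(seeds)
    exact <- rwrSolveOracle(W, p0, 0.5)
    worst <- max(worst, max(abs(p - exact)))
  }
  expect_lt(worst, 1e-8)
})

test_that("probability mass is conserved and residuals shrink monotonically", {
  set.seed(4)
  A <- randomAdjacency(20, 0.2)
  g <- graphFromAdjacency(A)
  keep <- rownames(A)[rowSums(A) > 0]
  Asub <- A[keep, keep]
  W <- sweep(Asub, 2, colSums(Asub), "/")
  p0 <- setNames(numeric(length(keep)), keep)
  p0[keep[1]] <- 1
  p <- p0; lastRes <- Inf
  for (it in 1:200) {
    pn <- 0.5 * drop(W %*% p) + 0.5 * p0
    expect_equal(sum(pn), 1, tolerance = 1e-12)
    res <- sum(abs(pn - p))
    if (it > 1) expect_lte(res, lastRes + 1e-12)
    lastRes <- res
    p <- pn
  }
})

test_that("seed and permutation-count validation errors are specific", {
  g <- classedGraph(data.frame(from = "a", to = "l1"), "l1")
  expect_error(rwrPropagate(g, rwrConfig(seeds = c("a", "nope"))), "nope")
  expect_error(rwrPropagate(g, rwrConfig()), "no seed")
  expect_error(rwrPermutationTest(g, rwrConfig(seeds = "a", nPermutations = 0L)),
               "undefined")
  expect_error(rwrPermutationTest(g, rwrConfig(seeds = c("a", "l1"),
                                               nPermutations = 10L)),
               "more seeds")
})

test_that("permutation p-values are deterministic and robust to edge order", {
  edges <- data.frame(
    from = c("m1", "m2", "m3", "m4", "m1"),
    to = c("l1", "l1", "l2", "l3", "l2"))
  g <- classedGraph(edges, c("l1", "l2", "l3"))
  cfg <- rwrConfig(seeds = "m1", nPermutations = 50L, permSeed = 5L)
  a <- rwrPermutationTest(g, cfg)
  b <- rwrPermutationTest(g, cfg)
  expect_identical(lncrnaPvalues(a), lncrnaPvalues(b))
  g2 <- classedGraph(edges[c(3, 1, 5, 2, 4), ], c("l1", "l2", "l3"))
  c2 <- rwrPermutationTest(g2, cfg)
  expect_equal(sort(names(lncrnaPvalues(a))), sort(names(lncrnaPvalues(c2))))
})

test_that("the planted disease-proximal lncRNA earns the best permutation p", {
  ds <- generateDataset(smallConfig(rngSeed = 17L))
  de <- lapply(setNames(nm = c("mRNA", "lncRNA", "miRNA")), function(cl)
    pairedModeratedTest(ds@expression, cl))
  net <- buildCernaNetwork(de, ds@interactions)
  tr <- truthManifest(ds)
  cfg <- rwrConfig(seeds = tr$seed_genes, nPermutations = 200L, permSeed = 3L)
  res <- rwrPermutationTest(net, cfg)
  pv <- lncrnaPvalues(res)
  expect_lte(pv[tr$disease_lncrnas], min(pv))
  expect_lt(pv[tr$disease_lncrnas], 0.01)
  ranking <- rankLncrnas(res)
  expect_identical(ranking$lncrna[1], tr$disease_lncrnas)
  expect_true(all(diff(ranking$score) <= 1e-15))
})

test_that("lncRNA ranking handles ties and empty sets", {
  res <- new("RWRResult",
             scores = c(b = 0.25, a = 0.25, m = 0.5),
             lncrnaP = c(b = 0.5, a = 0.5),
             nPermutations = 10L, seeds = "m", alpha = 0.01)
  rk <- rankLncrnas(res)
  expect_identical(rk$lncrna, c("a", "b"))   # lexicographic on equal scores
  empty <- new("RWRResult", scores = c(m = 1), lncrnaP = setNames(numeric(0), character(0)),
               nPermutations = 1L, seeds = "m", alpha = 0.01)
  expect_identical(nrow(rankLncrnas(empty)), 0L)
})
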