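# minimal differential-expression stand-in: every listed feature significant
fakeDe <- function(mrna = character(0), lncrna = character(0),
                   mirna = character(0)) {
  mk <- function(f) data.frame(feature = f, significant = rep(TRUE, length(f)),
                               stringsAsFactors = FALSE)
  list(mRNA = mk(mrna), lncRNA = mk(lncrna), miRNA = mk(mirna))
}

test_that("hypergeometric tail probabilities match hand-derived values", {
  expect_identical(hypergeomP(10, 3, 3, 0), 1)         # empty lower sum
  expect_equal(hypergeomP(10, 3, 3, 3), 1 / 120, tolerance = 1e-12)
  expect_equal(hypergeomP(4, 2, 2, 1), 5 / 6, tolerance = 1e-12)
  expect_error(hypergeomP(10, 3, 3, 4), "domain")
  expect_error(hypergeomP(10, 12, 3, 1), "domain")
})

test_that("hypergeomP agrees with enumeration and phyper on random instances", {
  set.seed(20)
  for (i in 1:300) {
    T <- sample(2:500, 1)
    t <- sample.int(T, 1); N <- sample.int(T, 1)
    r <- sample.int(min(t, N), 1)
    p <- hypergeomP(T, t, N, r)
    expect_equal(p, enumHypergeomOracle(T, t, N, r),
                 tolerance = 1e-10, label = sprintf("enum T=%d t=%d N=%d r=%d", T, t, N, r))
    expect_equal(p, phyper(r - 1, t, T - t, N, lower.tail = FALSE),
                 tolerance = 1e-10, label = sprintf("phyper T=%d t=%d N=%d r=%d", T, t, N, r))
  }
})

test_that("hypergeomP is monotone nonincreasing in r and survives large counts", {
  for (seeds in list(c(60, 30, 20), c(1556, 400, 80), c(5000, 1000, 600))) {
    T <- seeds[1]; t <- seeds[2]; N <- seeds[3]
    ps <- hypergeomP(T, t, N, 0:min(t, N))
    expect_true(all(diff(ps) <= 1e-12))
    expect_true(all(ps >= 0 & ps <= 1))
  }
})

test_that("a pair sharing five differentially expressed miRNAs is retained", {
  shared <- sprintf("miR-%02d", 1:5)
  others <- sprintf("miR-%02d", 6:20)
  edges <- rbind(
    data.frame(mirna_id = shared, target_id = "MRNA1", target_class = "mRNA"),
    data.frame(mirna_id = shared, target_id = "LNC1", target_class = "lncRNA"),
    data.frame(mirna_id = others, target_id = paste0("MRNA", 2:16),
               target_class = "mRNA"),
    data.frame(mirna_id = others, target_id = paste0("LNC", 2:16),
               target_class = "lncRNA"))
  ints <- mirnaInteractionSet(edges)
  de <- fakeDe(mrna = unique(edges$target_id[edges$target_class == "mRNA"]),
               lncrna = unique(edges$target_id[edges$target_class == "lncRNA"]),
               mirna = c(shared, others))
  net <- buildCernaNetwork(de, ints, alpha = 0.01)
  e <- networkEdges(net)
  expect_identical(paste(e$lncrna_id, e$mrna_id), "LNC1 MRNA1")
  expect_identical(e$T[1], 20L)
  expect_equal(e$p_value[1], enumHypergeomOracle(20, 5, 5, 5),
               tolerance = 1e-12)
  expect_lt(e$p_value[1], 0.01)
  expect_identical(sort(e$shared_mirnas[[1]]), sort(shared))
})

test_that("pairs sharing no miRNA are never candidates", {
  edges <- rbind(
    data.frame(mirna_id = "miR-1", target_id = "MRNA1", target_class = "mRNA"),
    data.frame(mirna_id = "miR-2", target_id = "LNC1", target_class = "lncRNA"))
  net <- buildCernaNetwork(fakeDe("MRNA1", "LNC1", c("miR-1", "miR-2")),
                           mirnaInteractionSet(edges), alpha = 1)
  expect_identical(nrow(networkEdges(net)), 0L)
})

test_that("network assembly matches a brute-force recomputation and planted truth", {
  ds <- generateDataset(smallConfig(rngSeed = 13L))
  de <- lapply(setNames(nm = c("mRNA", "lncRNA", "miRNA")), function(cl)
    pairedModeratedTest(ds@expression, cl))
  net <- buildCernaNetwork(de, ds@interactions, alpha = 0.01)
  e <- networkEdges(net)
  tr <- truthManifest(ds)
  expect_true(all(paste(tr$planted_pairs$lncrna_id, tr$planted_pairs$mrna_id)
                  %in% paste(e$lncrna_id, e$mrna_id)))
  # brute force over all lncRNA x mRNA combinations with phyper
  sig <- function(cl) de[[cl]]$feature[de[[cl]]$significant]
  ie <- interactionEdges(ds@interactions)
  ie <- ie[ie$mirna_id %in% sig("miRNA"), ]
  ie <- ie[(ie$target_class == "mRNA" & ie$target_id %in% sig("mRNA")) |
             (ie$target_class == "lncRNA" & ie$target_id %in% sig("lncRNA")), ]
  Tn <- length(unique(ie$mirna_id))
  parts <- split(ie$mirna_id, ie$target_id)
  lncs <- unique(ie$target_id[ie$target_class == "lncRNA"])
  mrnas <- unique(ie$target_id[ie$target_class == "mRNA"])
  kept <- character(0)
  for (l in lncs) for (m in mrnas) {
    r <- length(intersect(parts[[l]], parts[[m]]))
    if (r >= 1) {
      p <- phyper(r - 1, length(unique(parts[[m]])), Tn - length(unique(parts[[m]])),
                  length(unique(parts[[l]])), lower.tail = FALSE)
      if (p < 0.01) kept <- c(kept, paste(l, m))
    }
  }
  expect_setequal(paste(e$lncrna_id, e$mrna_id), kept)
})

test_that("edge sets are invariant to input row order", {
  ds <- generateDataset(smallConfig(rngSeed = 14L))
  de <- lapply(setNames(nm = c("mRNA", "lncRNA", "miRNA")), function(cl)
    pairedModeratedTest(ds@expression, cl))
  ie <- interactionEdges(ds@interactions)
  set.seed(1)
  shuffled <- mirnaInteractionSet(ie[sample(nrow(ie)), ])
  a <- networkEdges(buildCernaNetwork(de, ds@interactions))
  b <- networkEdges(buildCernaNetwork(de, shuffled))
  expect_identical(a[c("lncrna_id", "mrna_id", "r", "p_value")],
                   b[c("lncrna_id", "mrna_id", "r", "p_value")])
})

test_that("sub-network extraction restores the shared miRNA layer", {
  edges <- rbind(
    data.frame(mirna_id = "miR-a", target_id = "MRNA1", target_class = "mRNA"),
    data.frame(mirna_id = "miR-a", target_id = "LNC1", target_class = "lncRNA"),
    data.frame(mirna_id = "miR-b", target_id = "MRNA2", target_class = "mRNA"))
  net <- buildCernaNetwork(fakeDe(c("MRNA1", "MRNA2"), "LNC1",
                                  c("miR-a", "miR-b")),
                           mirnaInteractionSet(edges), alpha = 1)
  g <- extractSubnetwork(net, "LNC1")
  expect_equal(igraph::vcount(g), 3)             # lncRNA - miRNA - mRNA path
  expect_identical(sum(igraph::V(g)$class == "miRNA"), 1L)
  expect_equal(igraph::ecount(g), 2)
  expect_error(extractSubnetwork(net, "LNC999"), "not present")
})

test_that("an empty post-filter interaction set warns and yields an empty network", {
  edges <- data.frame(mirna_id = "miR-1", target_id = "MRNA1",
                      target_class = "mRNA")
  expect_warning(
    net <- buildCernaNetwork(fakeDe(character(0), character(0), character(0)),
                             mirnaInteractionSet(edges)),
    "empty network")
  expect_identical(nrow(networkEdges(net)), 0L)
})
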