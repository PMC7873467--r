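test_that("identical seeds produce identical datasets", {
  cfg <- smallConfig(rngSeed = 7L)
  a <- generateDataset(cfg)
  b <- generateDataset(cfg)
  for (cl in rnaClasses(a@expression))
    expect_identical(exprMatrix(a@expression, cl), exprMatrix(b@expression, cl))
  expect_identical(interactionEdges(a@interactions),
                   interactionEdges(b@interactions))
  expect_identical(truthManifest(a), truthManifest(b))
  c <- generateDataset(smallConfig(rngSeed = 8L))
  expect_false(identical(exprMatrix(a@expression, "mRNA"),
                         exprMatrix(c@expression, "mRNA")))
})

test_that("every planted entity names an existing feature and lists are consistent", {
  ds <- generateDataset(smallConfig(rngSeed = 3L))
  tr <- truthManifest(ds)
  for (cl in c("mRNA", "lncRNA", "miRNA")) {
    feats <- rownames(exprMatrix(ds@expression, cl))
    expect_true(all(tr$planted_de[[cl]]$feature %in% feats))
    expect_false(anyDuplicated(tr$planted_de[[cl]]$feature) > 0)
  }
  expect_true(all(tr$planted_pairs$lncrna_id %in%
                    tr$planted_de$lncRNA$feature))
  expect_true(all(tr$planted_pairs$mrna_id %in% tr$planted_de$mRNA$feature))
  expect_true(all(unlist(tr$planted_pairs$shared_mirnas) %in%
                    tr$planted_de$miRNA$feature))
  expect_true(all(tr$seed_genes %in% tr$planted_pairs$mrna_id))
  expect_true(all(tr$hub_lncrnas %in% tr$planted_pairs$lncrna_id))
  # disease lncRNA wired to every seed gene through shared planted miRNAs
  for (dl in tr$disease_lncrnas) {
    dp <- tr$planted_pairs[tr$planted_pairs$lncrna_id == dl, ]
    expect_true(all(tr$seed_genes %in% dp$mrna_id))
  }
})

test_that("null configuration plants nothing and keeps the raw-p rate near alpha", {
  nullCfg <- function(seed) syntheticConfig(
    nMrna = 200L, nLncrna = 10L, nMirna = 10L, fracDe = 0,
    nPlantedCernaPairs = 0L, nHubLncrna = 0L, nDiseaseLncrna = 0L,
    seedGeneCount = 0L, rngSeed = seed)
  ds <- generateDataset(nullCfg(1L))
  tr <- truthManifest(ds)
  expect_identical(nrow(tr$planted_de$mRNA), 0L)
  expect_identical(nrow(tr$planted_pairs), 0L)
  fpr <- vapply(1:10, function(s) {
    de <- pairedModeratedTest(generateDataset(nullCfg(s))@expression, "mRNA")
    mean(de$p_raw < 0.05)
  }, 0)
  expect_gt(mean(fpr), 0.02)
  expect_lt(mean(fpr), 0.09)
})

test_that("the planted hub attains the maximum lncRNA degree in the built network", {
  ds <- generateDataset(smallConfig(rngSeed = 11L))
  de <- lapply(setNames(nm = c("mRNA", "lncRNA", "miRNA")), function(cl)
    pairedModeratedTest(ds@expression, cl))
  net <- buildCernaNetwork(de, ds@interactions)
  degs <- table(networkEdges(net)$lncrna_id)
  hub <- truthManifest(ds)$hub_lncrnas
  expect_identical(names(which.max(degs)), hub)
  expect_true(all(degs[setdiff(names(degs), hub)] < max(degs)))
})

test_that("planted pairs share miRNAs strictly above the background expectation", {
  ds <- generateDataset(smallConfig(rngSeed = 5L))
  tr <- truthManifest(ds)
  e <- interactionEdges(ds@interactions)
  partners <- split(e$mirna_id, e$target_id)
  overlap <- function(l, m)
    length(intersect(partners[[l]], partners[[m]]))
  planted <- mapply(overlap, tr$planted_pairs$lncrna_id,
                    tr$planted_pairs$mrna_id)
  expect_true(all(planted >= ds@config$sharedMirnaCount))
  # background expectation under the generator's edge density: average
  # overlap of random non-planted lncRNA x mRNA combinations
  set.seed(1)
  lncs <- setdiff(unique(e$target_id[e$target_class == "lncRNA"]),
                  tr$planted_pairs$lncrna_id)
  mrnas <- setdiff(unique(e$target_id[e$target_class == "mRNA"]),
                   tr$planted_pairs$mrna_id)
  bg <- replicate(200, overlap(sample(lncs, 1), sample(mrnas, 1)))
  expect_true(all(planted > mean(bg)))
})

test_that("infeasible planted structure is rejected with a sizing error", {
  expect_error(syntheticConfig(sharedMirnaCount = 99L, nMirna = 50L),
               "sizing")
  expect_error(generateDataset(
    syntheticConfig(nPlantedCernaPairs = 4L, nHubLncrna = 1L,
                    hubPairCount = 12L)), "sizing")
  expect_error(generateDataset(
    syntheticConfig(fracDe = 0, nPlantedCernaPairs = 10L)), "sizing")
  expect_error(generateDataset(
    syntheticConfig(nMrna = 20L, fracDe = 0.1, nPlantedCernaPairs = 40L)),
    "sizing")
})

test_that("fixtures round-trip losslessly through the readers", {
  ds <- generateDataset(smallConfig(rngSeed = 2L))
  dir <- withr::local_tempdir()
  writeFixture(ds, dir)
  fx <- readFixture(dir)
  for (cl in c("mRNA", "lncRNA", "miRNA"))
    expect_equal(exprMatrix(fx$expression, cl),
                 exprMatrix(ds@expression, cl), tolerance = 1e-12)
  eA <- interactionEdges(ds@interactions)
  eB <- interactionEdges(fx$interactions)
  key <- function(e) sort(paste(e$mirna_id, e$target_id, e$target_class))
  expect_identical(key(eA), key(eB))
  expect_identical(fx$seeds, truthManifest(ds)$seed_genes)
  expect_equal(fx$truth, truthManifest(ds), tolerance = 0)
})

test_that("the sample sheet pairs every patient twice across 16 rows", {
  ds <- generateDataset(smallConfig(rngSeed = 4L))
  ss <- sampleSheet(ds@expression)
  expect_identical(nrow(ss), 16L)
  expect_identical(length(unique(ss$patient_id)), 8L)
  expect_true(all(table(ss$patient_id) == 2L))
  expect_true(all(table(ss$patient_id, ss$condition) == 1L))
})

test_that("an empty interaction set still writes a valid file with header only", {
  nullCfg <- syntheticConfig(nMrna = 20L, nLncrna = 5L, nMirna = 5L,
                             fracDe = 0, nPlantedCernaPairs = 0L,
                             nHubLncrna = 0L, nDiseaseLncrna = 0L,
                             seedGeneCount = 0L, bgEdgesMrna = 0L,
                             bgEdgesLncrna = 0L, rngSeed = 1L)
  ds <- generateDataset(nullCfg)
  dir <- withr::local_tempdir()
  writeFixture(ds, dir)
  lines <- readLines(file.path(dir, "interactions.tsv"))
  expect_identical(lines, "mirna_id\ttarget_id\ttarget_class")
  fx <- readFixture(dir)
  expect_identical(nrow(interactionEdges(fx$interactions)), 0L)
})
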