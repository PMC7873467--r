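#' Read a log2 expression matrix with its sample sheet
#'
#' Expression files are UTF-8 tab-separated with the feature ID in the first
#' column and one column per sample; \code{#} lines are ignored.  The sample
#' sheet is a TSV with columns \code{sample_id}, \code{patient_id},
#' \code{condition} (\code{EC} or \code{EU}).  Pairing invariants are
#' enforced at load: every sample must be on the sheet and every patient
#' must have exactly one EC and one EU sample present.
#'
#' @param matrixPath path to the expression TSV
#' @param sampleSheetPath path to the sample-sheet TSV
#' @param rnaClass RNA class the matrix belongs to (\code{"mRNA"},
#'   \code{"lncRNA"} or \code{"miRNA"})
#' @return a [PairedExpressionSet-class] holding the one class
#' @export
readExpression <- function(matrixPath, sampleSheetPath, rnaClass = "mRNA") {
  rnaClass <- match.arg(rnaClass, RNA_CLASSES)
  for (p in c(matrixPath, sampleSheetPath))
    if (!file.exists(p)) stop("file not found: ", p)
  raw <- utils::read.delim(matrixPath, comment.char = "#", check.names = FALSE,
                           colClasses = "character", stringsAsFactors = FALSE)
  if (ncol(raw) < 2) stop("expression file needs a feature column and ",
                          "at least one sample column: ", matrixPath)
  feats <- raw[[1]]
  dup <- feats[duplicated(feats)]
  if (length(dup))
    stop("duplicated feature ID(s) in ", matrixPath, ": ",
         paste(unique(dup), collapse = ", "))
  m <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(m), nrow(m), ncol(m)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric value at row '", feats[bad[1]], "', column '",
         colnames(m)[bad[2]], "' in ", matrixPath)
  }
  dimnames(num) <- list(feats, colnames(raw)[-1])
  ss <- utils::read.delim(sampleSheetPath, comment.char = "#",
                          stringsAsFactors = FALSE)
  tryCatch(
    pairedExpressionSet(stats::setNames(list(num), rnaClass), ss),
    error = function(e) stop("pairing error loading ", matrixPath, ": ",
                             conditionMessage(e), call. = FALSE))
}

#' Read a miRNA-target interaction table
#'
#' TSV with columns \code{mirna_id}, \code{target_id}, \code{target_class}
#' (\code{mRNA} or \code{lncRNA}).  Duplicate edges are collapsed with a
#' message; per-class edge counts are reported.
#'
#' @param path path to the TSV
#' @return a [MirnaInteractionSet-class]
#' @export
readInteractions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  e <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  out <- mirnaInteractionSet(e)
  tab <- table(interactionEdges(out)$target_class)
  message("loaded ", nrow(interactionEdges(out)), " interaction edges (",
          paste(sprintf("%s: %d", names(tab), as.integer(tab)),
                collapse = ", "), ")")
  out
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields
#' \code{name}, \code{description}, then the member gene IDs.
#'
#' @param path path to the GMT file
#' @return a [GeneSetCollection-class]
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list(); desc <- character(0)
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("malformed GMT line ", i, " (", length(f),
           " fields, need at least 3) in ", path)
    sets[[f[1]]] <- unique(f[-(1:2)])
    desc[f[1]] <- f[2]
  }
  geneSetCollection(sets, desc)
}

#' Read a plain-text seed-gene list
#'
#' One gene ID per line; blank lines and \code{#} comments are ignored.
#'
#' @param path path to the file
#' @return character vector of gene IDs
#' @export
readSeedList <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- trimws(readLines(path, warn = FALSE))
  x[nzchar(x) & !startsWith(x, "#")]
}

#' Write a ceRNA network to disk
#'
#' The edge-list TSV carries the full hypergeometric evidence (T, t, N, r,
#' p_value) plus the shared miRNAs as a comma-joined column; GraphML export
#' (via \pkg{igraph}) carries the node \code{class} attribute.
#'
#' @param network a [CeRNANetwork-class]
#' @param path output file path
#' @param format \code{"tsv"} (edge list, default) or \code{"graphml"}
#' @return the path, invisibly
#' @export
writeNetwork <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  e <- networkEdges(network)
  if (format == "tsv") {
    flat <- e
    flat$shared_mirnas <- vapply(e$shared_mirnas, paste, "", collapse = ",")
    utils::write.table(flat, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    igraph::write_graph(cernaGraph(network), path, format = "graphml")
  }
  invisible(path)
}

#' Read a ceRNA network edge list written by [writeNetwork()]
#'
#' @param path path to the edge-list TSV
#' @param alpha the filter threshold the edges were written under
#'   (default 0.01); stored on the returned object
#' @param universe optional miRNA universe IDs to attach
#' @return a [CeRNANetwork-class]
#' @export
readNetworkEdges <- function(path, alpha = 0.01, universe = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  e$shared_mirnas <- lapply(strsplit(e$shared_mirnas, ",", fixed = TRUE),
                            function(x) x[nzchar(x)])
  e$lncrna_id <- as.character(e$lncrna_id)
  e$mrna_id <- as.character(e$mrna_id)
  new("CeRNANetwork", edges = e, alpha = alpha,
      universe = as.character(universe))
}

# ---------------------------------------------------------------------------
# fixture writing / reading (synthetic datasets on disk)

.fixtureFiles <- function(directory) {
  files <- c(mRNA = "expr_mrna.tsv", lncRNA = "expr_lncrna.tsv",
             miRNA = "expr_mirna.tsv", sheet = "samples.tsv",
             interactions = "interactions.tsv",
             seeds = "seed_genes.txt", truth = "truth.txt")
  stats::setNames(file.path(directory, files), names(files))
}

.writeMatrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Write a synthetic dataset as a plain-text fixture
#'
#' Emits one expression TSV per RNA class, the sample sheet, the interaction
#' table, the seed-gene list and a sectioned key-value truth manifest.  The
#' file set round-trips losslessly through [readFixture()].
#'
#' @param dataset a [SyntheticDataset-class]
#' @param directory output directory (created if needed)
#' @return named character vector of the written paths, invisibly
#' @export
writeFixture <- function(dataset, directory) {
  stopifnot(is(dataset, "SyntheticDataset"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  if (file.access(directory, 2) != 0)
    stop("directory not writable: ", directory)
  paths <- .fixtureFiles(directory)
  expr <- dataset@expression
  for (cls in rnaClasses(expr))
    .writeMatrix(exprMatrix(expr, cls), paths[[cls]])
  utils::write.table(sampleSheet(expr), paths[["sheet"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(interactionEdges(dataset@interactions),
                     paths[["interactions"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(truthManifest(dataset)$seed_genes, paths[["seeds"]])
  .writeTruth(truthManifest(dataset), paths[["truth"]])
  invisible(paths)
}

.writeTruth <- function(truth, path) {
  con <- file(path, "w"); on.exit(close(con))
  wr <- function(...) writeLines(paste0(...), con)
  for (cls in names(truth$planted_de)) {
    wr("[planted_de_", cls, "]")
    de <- truth$planted_de[[cls]]
    if (nrow(de)) wr(de$feature, "\t", de$direction)
  }
  wr("[planted_pairs]")
  pp <- truth$planted_pairs
  if (nrow(pp))
    wr(pp$lncrna_id, "\t", pp$mrna_id, "\t",
       vapply(pp$shared_mirnas, paste, "", collapse = ","))
  wr("[hub_lncrnas]"); if (length(truth$hub_lncrnas)) wr(truth$hub_lncrnas)
  wr("[seed_genes]"); if (length(truth$seed_genes)) wr(truth$seed_genes)
  wr("[disease_lncrnas]")
  if (length(truth$disease_lncrnas)) wr(truth$disease_lncrnas)
}

#' Read a planted-truth manifest
#'
#' @param path path to a \code{truth.txt} written by [writeFixture()]
#' @return list with the same structure as [truthManifest()]
#' @export
readTruth <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  sec <- cumsum(grepl("^\\[", lines))
  names <- gsub("^\\[|\\]$", "", lines[grepl("^\\[", lines)])
  body <- split(lines[!grepl("^\\[", lines)],
                factor(sec[!grepl("^\\[", lines)], levels = seq_along(names),
                       labels = names))
  deOf <- function(nm) {
    x <- body[[nm]]
    if (!length(x))
      return(data.frame(feature = character(0), direction = character(0)))
    f <- do.call(rbind, strsplit(x, "\t", fixed = TRUE))
    data.frame(feature = f[, 1], direction = f[, 2], stringsAsFactors = FALSE)
  }
  pp <- body[["planted_pairs"]]
  pairs <- if (length(pp)) {
    f <- do.call(rbind, strsplit(pp, "\t", fixed = TRUE))
    d <- data.frame(lncrna_id = f[, 1], mrna_id = f[, 2],
                    stringsAsFactors = FALSE)
    d$shared_mirnas <- strsplit(f[, 3], ",", fixed = TRUE)
    d
  } else {
    d <- data.frame(lncrna_id = character(0), mrna_id = character(0),
                    stringsAsFactors = FALSE)
    d$shared_mirnas <- list()
    d
  }
  list(planted_de = list(mRNA = deOf("planted_de_mRNA"),
                         lncRNA = deOf("planted_de_lncRNA"),
                         miRNA = deOf("planted_de_miRNA")),
       planted_pairs = pairs,
       hub_lncrnas = as.character(body[["hub_lncrnas"]]),
       seed_genes = as.character(body[["seed_genes"]]),
       disease_lncrnas = as.character(body[["disease_lncrnas"]]))
}

#' Read a fixture directory back into memory
#'
#' @param directory a directory written by [writeFixture()]
#' @return list with elements \code{expression}
#'   ([PairedExpressionSet-class] with all classes present on disk),
#'   \code{interactions}, \code{seeds} and \code{truth}
#' @export
readFixture <- function(directory) {
  paths <- .fixtureFiles(directory)
  assays <- list()
  for (cls in RNA_CLASSES)
    if (file.exists(paths[[cls]])) {
      one <- readExpression(paths[[cls]], paths[["sheet"]], cls)
      assays[[cls]] <- exprMatrix(one, cls)
    }
  ss <- utils::read.delim(paths[["sheet"]], stringsAsFactors = FALSE)
  list(expression = pairedExpressionSet(assays, ss),
       interactions = suppressMessages(readInteractions(paths[["interactions"]])),
       seeds = readSeedList(paths[["seeds"]]),
       truth = readTruth(paths[["truth"]]))
}
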