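#' Paired empirical-Bayes moderated differential expression
#'
#' Tests each feature for differential expression between ectopic (EC) and
#' eutopic (EU) samples with a moderated one-sample t-test on the per-patient
#' EC - EU log2 differences.  Per-feature sample variances are shrunk toward
#' a common prior by empirical Bayes: the prior degrees of freedom d0 and
#' prior variance s0^2 are estimated by moments matching on the log sample
#' variances (using the exact mean/variance of log chi-square), the posterior
#' variance is \eqn{\tilde s^2 = (d_0 s_0^2 + d s^2) / (d_0 + d)} with
#' \eqn{d = n - 1}, and the moderated t has \eqn{d_0 + d} degrees of freedom.
#' P-values are Benjamini-Hochberg adjusted across the features of the class.
#'
#' A feature is flagged significant when its adjusted p is below \code{alpha}
#' and its absolute fold change exceeds \code{fcThreshold} (i.e.
#' \eqn{|log2FC| > log2(fcThreshold)}).
#'
#' @param expr a [PairedExpressionSet-class] (log2 scale)
#' @param rnaClass which class matrix to test (\code{"mRNA"},
#'   \code{"lncRNA"} or \code{"miRNA"})
#' @param alpha adjusted-p significance threshold (default 0.05)
#' @param fcThreshold fold-change gate in linear fold units (default 2)
#' @param moderation optional list with elements \code{d0} and \code{s0_sq}
#'   overriding the estimated hyperparameters (mainly for sensitivity
#'   analysis; \code{d0 = 0} recovers the ordinary paired t-test)
#' @return data.frame with columns \code{feature}, \code{log2fc},
#'   \code{t}, \code{p_raw}, \code{p_adj}, \code{direction} (\code{Up} iff
#'   log2fc > 0), \code{significant}; the estimated moderation
#'   hyperparameters are attached as \code{attr(, "moderation")} (a list with
#'   \code{d0}, \code{s0_sq}, \code{d}).
#' @export
pairedModeratedTest <- function(expr, rnaClass, alpha = 0.05, fcThreshold = 2,
                                moderation = NULL) {
  stopifnot(is(expr, "PairedExpressionSet"))
  mat <- exprMatrix(expr, rnaClass)
  ss <- sampleSheet(expr)
  ss <- ss[match(colnames(mat), ss$sample_id), ]
  patients <- sort(unique(ss$patient_id))
  n <- length(patients)
  if (n < 3) stop("paired moderated test needs at least 3 complete pairs, got ", n)
  ecCols <- vapply(patients, function(p)
    ss$sample_id[ss$patient_id == p & ss$condition == "EC"], "")
  euCols <- vapply(patients, function(p)
    ss$sample_id[ss$patient_id == p & ss$condition == "EU"], "")
  D <- mat[, ecCols, drop = FALSE] - mat[, euCols, drop = FALSE]

  meanD <- rowMeans(D)
  d <- n - 1
  s2 <- rowSums((D - meanD)^2) / d
  if (all(s2 == 0)) {
    # no variance information at all (e.g. EC identical to EU, or constant
    # shifts): the moderated test is undefined, so p-values are NA and the
    # fold-change gate alone decides nothing is called significant
    warning("all per-feature variances of the paired differences are zero; ",
            "p-values are undefined (NA). Supply real (noisy) log2 values ",
            "for a meaningful test.")
    mod <- list(d0 = Inf, s0_sq = NA_real_)
    tstat <- pRaw <- pAdj <- rep(NA_real_, length(s2))
  } else {
    mod <- if (is.null(moderation)) .estimateModeration(s2, d) else moderation
    s2post <- if (is.infinite(mod$d0)) rep(mod$s0_sq, length(s2))
              else (mod$d0 * mod$s0_sq + d * s2) / (mod$d0 + d)
    tstat <- meanD / sqrt(s2post / n)
    dfTotal <- mod$d0 + d
    pRaw <- 2 * stats::pt(-abs(tstat), df = dfTotal)
    pAdj <- stats::p.adjust(pRaw, method = "BH")
  }
  res <- data.frame(feature = rownames(mat), log2fc = meanD, t = tstat,
                    p_raw = pRaw, p_adj = pAdj,
                    direction = ifelse(meanD > 0, "Up", "Down"),
                    significant = !is.na(pAdj) & pAdj < alpha &
                      abs(meanD) > log2(fcThreshold),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(res, "moderation") <- list(d0 = mod$d0, s0_sq = mod$s0_sq, d = d)
  res
}

# Moments matching on z = log(s^2): with s^2 ~ s0^2 F(d, d0),
#   E[z] = log s0^2 + (digamma(d/2) - log(d/2)) - (digamma(d0/2) - log(d0/2))
#   Var[z] = trigamma(d/2) + trigamma(d0/2)
# so trigamma(d0/2) is the excess of var(e) over trigamma(d/2), where
# e = z - digamma(d/2) + log(d/2).  Nonpositive excess means no dispersion
# of the true variances: d0 = Inf and s0^2 = exp(mean(e)).
.estimateModeration <- function(s2, d) {
  pos <- s2[s2 > 0]
  if (length(pos) < 2) {
    warning("fewer than 2 positive variances; using d0 = Inf")
    s0 <- if (length(pos)) pos else mean(s2) + 1e-8
    return(list(d0 = Inf, s0_sq = mean(s0)))
  }
  e <- log(pos) - digamma(d / 2) + log(d / 2)
  excess <- stats::var(e) - trigamma(d / 2)
  if (!is.finite(excess) || excess <= 1e-10)
    return(list(d0 = Inf, s0_sq = exp(mean(e))))
  d0 <- 2 * .trigammaInverse(excess)
  s0_sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

# solve trigamma(y) = x for y > 0 (trigamma is strictly decreasing)
.trigammaInverse <- function(x) {
  if (x <= 0) return(Inf)
  if (x > 1e7) return(1 / sqrt(x))
  f <- function(u) trigamma(exp(u)) - x
  u <- stats::uniroot(f, lower = -35, upper = 35, tol = 1e-12)$root
  exp(u)
}

#' Tabulate up/down differential-expression counts per RNA class
#'
#' @param results named list of differential-expression tables (one per RNA
#'   class) as returned by [pairedModeratedTest()]
#' @return data.frame with columns \code{rna_class}, \code{up}, \code{down},
#'   \code{total_significant}, \code{tested}
#' @export
deSummary <- function(results) {
  stopifnot(is.list(results), length(results) >= 1, !is.null(names(results)))
  rows <- lapply(names(results), function(cls) {
    r <- results[[cls]]
    data.frame(rna_class = cls,
               up = sum(r$significant & r$direction == "Up"),
               down = sum(r$significant & r$direction == "Down"),
               total_significant = sum(r$significant),
               tested = nrow(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
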