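#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson coefficient with the two-sided tail probability from
#' t = r * sqrt((n - 2) / (1 - r^2)) on n - 2 degrees of freedom. Errors on
#' constant input, where the correlation is undefined.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return list(r, p, n).
#' @export
pearsonWithP <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("at least 3 complete pairs are required")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: constant input vector")
  r <- stats::cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    t <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(t), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Flag significant-and-strong correlations
#'
#' The screening rule for methylation-phenotype hits: significant
#' (p < alpha) and strong (|r| > rMin). The magnitude criterion is applied
#' to |r| so that strong negative correlations qualify; set
#' `signed = TRUE` to require r > rMin instead.
#'
#' @param r,p Numeric vectors (recycled).
#' @param alpha Significance threshold (default 0.05).
#' @param rMin Strength threshold on the coefficient (default 0.65).
#' @param signed If TRUE, only positive r can be strong.
#' @return Logical vector.
#' @export
flagStrong <- function(r, p, alpha = 0.05, rMin = 0.65, signed = FALSE) {
  mag <- if (signed) r else abs(r)
  p < alpha & mag > rMin
}

#' Screen MITE methylation against a phenotype
#'
#' Pearson-correlates every regulatory-region MITE's methylation level with
#' a trait across samples and flags significant-and-strong hits. Elements
#' with undefined levels in more than half the samples, or fewer than
#' `nMin` complete pairs, or constant levels, are excluded (a message
#' reports counts). One output row per (MITE, linked gene) pair, sorted by
#' |r| descending. Raw p-values are reported; an optional
#' Benjamini-Hochberg `q` column is an extension over the raw-threshold
#' screening rule.
#'
#' @param levels SummarizedExperiment from [methylationMatrix()] (assay
#'   `level`) or a numeric matrix with MITE ids as rownames and sample ids
#'   as colnames.
#' @param phenotypes Long-format data.frame(sample_id, trait, value).
#' @param links data.frame(mite_id, gene_id, ...) from
#'   [assignRegulatoryContext()]; restricts the screen to regulatory-region
#'   elements.
#' @param trait Trait name to screen.
#' @param nMin Minimum complete pairs per element (default 6).
#' @param alpha,rMin,signed Passed to [flagStrong()].
#' @param adjust Add a BH-adjusted `q` column.
#' @return data.frame(mite_id, gene_id, trait, r, p, n, strong[, q]) with an
#'   `excluded` attribute counting skipped elements.
#' @export
screenMitePhenotype <- function(levels, phenotypes, links, trait,
                                nMin = 6, alpha = 0.05, rMin = 0.65,
                                signed = FALSE, adjust = FALSE) {
  if (is(levels, "SummarizedExperiment"))
    levels <- SummarizedExperiment::assay(levels, "level")
  stopifnot(is.matrix(levels), !is.null(rownames(levels)),
            !is.null(colnames(levels)))
  ph <- phenotypes[phenotypes$trait == trait, , drop = FALSE]
  if (nrow(ph) == 0)
    stop("trait '", trait, "' absent from the phenotype table")
  samples <- intersect(colnames(levels), ph$sample_id)
  if (length(samples) < 3)
    stop("fewer than 3 samples shared between levels and phenotypes")
  y <- ph$value[match(samples, ph$sample_id)]
  mitesToTest <- intersect(unique(links$mite_id), rownames(levels))
  excluded <- 0L
  rows <- lapply(mitesToTest, function(m) {
    x <- levels[m, samples]
    defined <- sum(is.finite(x))
    ok <- is.finite(x) & is.finite(y)
    if (defined < length(samples) / 2 || sum(ok) < nMin ||
        stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      excluded <<- excluded + 1L
      return(NULL)
    }
    ct <- pearsonWithP(x[ok], y[ok])
    data.frame(mite_id = m, r = ct$r, p = ct$p, n = ct$n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (excluded > 0)
    msg(excluded, " element(s) excluded from the ", trait, " screen")
  if (is.null(res))
    res <- data.frame(mite_id = character(), r = numeric(), p = numeric(),
                      n = integer())
  res$strong <- flagStrong(res$r, res$p, alpha, rMin, signed)
  if (adjust) res$q <- stats::p.adjust(res$p, method = "BH")
  out <- merge(links[, c("mite_id", "gene_id")], res, by = "mite_id")
  out <- cbind(out[, c("mite_id", "gene_id")], trait = trait,
               out[, setdiff(names(out), c("mite_id", "gene_id"))])
  out <- out[order(-abs(out$r), out$mite_id, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}

#' Relative expression by the ddCt method
#'
#' Fold change of a target gene in a treated sample relative to a
#' calibrator, each normalised to a reference gene:
#' fold = 2^-ddCt with
#' ddCt = (Ct_target,treated - Ct_ref,treated) -
#'        (Ct_target,calibrator - Ct_ref,calibrator).
#' Replicate Ct values are averaged before differencing.
#'
#' @param ctTargetTreated,ctRefTreated,ctTargetCalibrator,ctRefCalibrator
#'   Numeric vectors of cycle-threshold replicates.
#' @return list(fold, ddct).
#' @export
ddctFoldChange <- function(ctTargetTreated, ctRefTreated,
                           ctTargetCalibrator, ctRefCalibrator) {
  cts <- c(ctTargetTreated, ctRefTreated, ctTargetCalibrator,
           ctRefCalibrator)
  if (!all(is.finite(cts))) stop("all Ct values must be finite")
  ddct <- (mean(ctTargetTreated) - mean(ctRefTreated)) -
    (mean(ctTargetCalibrator) - mean(ctRefCalibrator))
  list(fold = 2^(-ddct), ddct = ddct)
}

#' Two-sided t-test between treated and control values
#'
#' Independent two-sample t-test (classical equal-variance form) when
#' `control` is a vector, or a single-sample t-test against a fixed
#' reference value when `reference` is given instead.
#'
#' @param space Numeric vector of treated values (n >= 2).
#' @param control Numeric vector of control values (two-sample mode).
#' @param reference Single reference value (single-sample mode).
#' @param varEqual Pool variances in two-sample mode (default TRUE).
#' @return list(statistic, p, df, method).
#' @export
groupDifferenceTest <- function(space, control = NULL, reference = NULL,
                                varEqual = TRUE) {
  stopifnot(length(space) >= 2)
  if (!is.null(reference)) {
    if (stats::sd(space) == 0)
      stop("zero variance: t statistic undefined")
    tt <- stats::t.test(space, mu = reference)
    method <- "single-sample"
  } else {
    stopifnot(!is.null(control), length(control) >= 2)
    if (stats::sd(space) == 0 && stats::sd(control) == 0)
      stop("zero variance in both groups: t statistic undefined")
    tt <- stats::t.test(space, control, var.equal = varEqual)
    method <- if (varEqual) "two-sample pooled" else "two-sample Welch"
  }
  list(statistic = unname(tt$statistic), p = tt$p.value,
       df = unname(tt$parameter), method = method)
}
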