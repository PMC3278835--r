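#' Time-averaged edge activity per cell
#'
#' Arithmetic mean of the protrusion and of the retraction velocities over
#' all intervals: the two scalar edge summaries (`protrusion_velocity`,
#' `retraction_velocity`) that enter the correlation analyses alongside the
#' eight motility features.
#'
#' @param prints an [EdgePrintSet-class].
#' @return data.frame with `cell_id`, `protrusion_velocity`,
#'   `retraction_velocity` (um/min).
#' @export
timeAverageEdge <- function(prints) {
  stopifnot(is(prints, "EdgePrintSet"))
  data.frame(cell_id = rownames(protrusion(prints)),
             protrusion_velocity = rowMeans(protrusion(prints)),
             retraction_velocity = rowMeans(retraction(prints)),
             row.names = NULL)
}

#' Spearman correlation matrix with t-transform p-values
#'
#' Pairwise Spearman rank correlations (average ranks on ties) over the
#' columns of a feature table. P-values come from the t transform
#' `t = rho * sqrt((N - 2) / (1 - rho^2))` on `N - 2` degrees of freedom,
#' two-sided; pairs are flagged significant at `alpha` on the raw p-value
#' (the conventional report), with Benjamini-Hochberg adjusted flags supplied
#' alongside.
#'
#' @param table numeric data.frame or matrix (rows = cells, columns =
#'   features); N >= 4.
#' @param alpha significance level (default 0.05).
#' @return list with matrices `rho`, `p`, `significant`,
#'   `significant_adjusted`, plus `n` and `alpha`.
#' @export
spearmanWithP <- function(table, alpha = 0.05) {
  X <- as.matrix(table)
  N <- nrow(X)
  stopifnot(N >= 4L)
  rho <- cor(X, method = "spearman")
  tstat <- rho * sqrt((N - 2) / pmax(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = N - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  diag(p) <- 0
  padj <- matrix(stats::p.adjust(p[upper.tri(p)], "BH"), nrow = 1)
  adjMat <- matrix(NA_real_, nrow(p), ncol(p), dimnames = dimnames(p))
  adjMat[upper.tri(adjMat)] <- padj
  adjMat[lower.tri(adjMat)] <- t(adjMat)[lower.tri(adjMat)]
  diag(adjMat) <- 0
  list(rho = rho, p = p, significant = p < alpha,
       significant_adjusted = adjMat < alpha, n = N, alpha = alpha)
}

#' Multiple correlation of one feature on all others
#'
#' Ordinary least squares of the response feature on every remaining column;
#' `R^2 = 1 - SS_res / SS_tot` measures how much of the response (by
#' convention, speed) the remaining motility and edge features jointly
#' explain.
#'
#' @param table numeric data.frame of features.
#' @param response name of the dependent column (default
#'   `"speed_um_per_h"`).
#' @return list with `r_squared`, `n`, `n_predictors` and the `lm` fit.
#' @export
multipleCorrelation <- function(table, response = "speed_um_per_h") {
  stopifnot(response %in% colnames(table))
  df <- as.data.frame(table)
  preds <- setdiff(colnames(df), response)
  stopifnot(nrow(df) > length(preds))
  fit <- lm(stats::reformulate(sprintf("`%s`", preds), response), data = df)
  # summary.lm warns on exact fits; R^2 = 1 is a legitimate outcome here
  list(r_squared = suppressWarnings(summary(fit)$r.squared), n = nrow(df),
       n_predictors = length(preds), fit = fit)
}

#' Leave-one-out jackknife of pairwise correlations
#'
#' For every (motility feature, edge feature) pair, the correlation is
#' recomputed N times leaving out one cell; the mean and standard deviation
#' of the N delete-one estimates expose pairs whose correlation hinges on
#' single influential cells.
#'
#' @param table data.frame with cells as rows.
#' @param motilityCols,edgeCols column names of the two feature groups.
#' @param method correlation type (default `"spearman"` for consistency with
#'   the main analysis; `"pearson"` available).
#' @return list of matrices `mean` and `sd` (motility x edge), plus
#'   `estimates` (motility x edge x N array of delete-one values).
#' @export
jackknifeCorrelation <- function(table, motilityCols, edgeCols,
                                 method = c("spearman", "pearson")) {
  method <- match.arg(method)
  X <- as.matrix(table[, motilityCols, drop = FALSE])
  Y <- as.matrix(table[, edgeCols, drop = FALSE])
  N <- nrow(X)
  stopifnot(N >= 3L)
  est <- array(NA_real_, c(length(motilityCols), length(edgeCols), N),
               dimnames = list(motilityCols, edgeCols, NULL))
  for (i in seq_len(N))
    est[, , i] <- cor(X[-i, , drop = FALSE], Y[-i, , drop = FALSE],
                      method = method)
  list(mean = apply(est, 1:2, mean), sd = apply(est, 1:2, sd),
       estimates = est)
}

#' Covariance-based factor analysis with Kaiser retention
#'
#' Principal-axis extraction from the feature covariance matrix: loadings are
#' eigenvectors scaled by the square roots of their eigenvalues. The number
#' of retained factors follows the Kaiser criterion -- eigenvalues of the
#' *correlation-scaled* matrix at least 1, i.e. factors explaining at least
#' one standardized feature's worth of variance -- while the reported
#' loadings stay on the covariance scale. Retained loadings are
#' varimax-rotated by default; per-factor and cumulative explained variance
#' (percent of total) are computed from the rotated loadings.
#'
#' @param table numeric data.frame (rows = cells, columns = the motility +
#'   edge features). Needs more rows than columns.
#' @param rotate `"varimax"` (default) or `"none"`.
#' @param suppress loadings with magnitude below this threshold are blanked
#'   (NA) in the `loadings_suppressed` view (default 0.4); the full matrix is
#'   always returned too.
#' @param ridge diagonal ridge (fraction of mean variance) ensuring a
#'   positive-definite covariance (default 0).
#' @return list with `loadings`, `loadings_suppressed`, `eigenvalues`
#'   (covariance scale), `kaiser_eigenvalues` (correlation scale),
#'   `n_retained`, `variance_explained` and `cumulative_variance` (percent),
#'   and `rotation`.
#' @export
factorAnalysisFeatures <- function(table, rotate = c("varimax", "none"),
                                   suppress = 0.4, ridge = 0) {
  rotate <- match.arg(rotate)
  X <- as.matrix(table)
  stopifnot(nrow(X) > ncol(X))
  C <- cov(X)
  if (ridge > 0) C <- C + diag(ridge * mean(diag(C)), ncol(C))
  eg <- eigen(C, symmetric = TRUE)
  egCor <- eigen(stats::cov2cor(C), symmetric = TRUE, only.values = TRUE)
  nRet <- max(1L, sum(egCor$values >= 1))
  L <- eg$vectors[, seq_len(nRet), drop = FALSE] %*%
    diag(sqrt(pmax(eg$values[seq_len(nRet)], 0)), nRet)
  rownames(L) <- colnames(X)
  if (rotate == "varimax" && nRet > 1L) {
    vr <- varimax(L, normalize = TRUE)
    L <- unclass(vr$loadings)
  }
  colnames(L) <- paste0("factor", seq_len(nRet))
  ve <- colSums(L^2) / sum(diag(C)) * 100
  ord <- order(ve, decreasing = TRUE)
  L <- L[, ord, drop = FALSE]
  colnames(L) <- paste0("factor", seq_len(nRet))
  ve <- ve[ord]; names(ve) <- colnames(L)
  Ls <- L; Ls[abs(Ls) < suppress] <- NA_real_
  list(loadings = L, loadings_suppressed = Ls,
       eigenvalues = eg$values, kaiser_eigenvalues = egCor$values,
       n_retained = nRet, variance_explained = ve,
       cumulative_variance = cumsum(ve), rotation = rotate)
}

#' Correlation report for one class of cells
#'
#' Joins the eight motility features with the two time-averaged edge
#' features and runs the full association panel: Spearman matrix with
#' t-transform p-values, multiple correlation with speed as the response,
#' leave-one-out jackknife of every (motility, edge) pair, and bar-plot
#' export data (feature, rho against each edge feature, significance flag).
#'
#' @param motility data.frame from [motilityFeatures()].
#' @param edgeSummary data.frame from [timeAverageEdge()].
#' @param alpha significance level (default 0.05).
#' @return list with `spearman`, `r_squared`, `jackknife`, `barplot_data`
#'   and the joined `table`.
#' @export
correlationReport <- function(motility, edgeSummary, alpha = 0.05) {
  tab <- merge(motility[, c("cell_id", motilityFeatureNames())],
               edgeSummary, by = "cell_id")
  feat <- tab[, -1]
  sp <- spearmanWithP(feat, alpha = alpha)
  mc <- multipleCorrelation(feat)
  jk <- jackknifeCorrelation(tab, motilityFeatureNames(),
                             c("protrusion_velocity", "retraction_velocity"))
  edgeCols <- c("protrusion_velocity", "retraction_velocity")
  bp <- do.call(rbind, lapply(edgeCols, function(e)
    data.frame(feature = motilityFeatureNames(), edge = e,
               rho = sp$rho[motilityFeatureNames(), e],
               significant = sp$significant[motilityFeatureNames(), e],
               row.names = NULL)))
  list(spearman = sp, r_squared = mc$r_squared, jackknife = jk,
       barplot_data = bp, table = tab)
}
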