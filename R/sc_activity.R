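# Rank-AUC gene-set activity (AUCell-style): for each cell, genes are
# ranked by decreasing expression and the recovery of the gene set within
# the top `top_fraction` of ranks is integrated and normalized by the best
# achievable recovery.  The score depends only on within-cell ranks, so it
# is invariant to any monotone normalization of the cell's expression.

#' Rank-AUC activity score for one cell
#'
#' Ranks the cell's genes by decreasing expression (ties broken
#' deterministically: descending expression, then lexicographic gene id),
#' builds the recovery step curve of the gene set over the top
#' \code{k = ceiling(top_fraction * n_genes)} ranks, and returns the area
#' under that curve normalized by the maximum achievable area (all set
#' genes at the very top).  When the set is larger than \code{k} the
#' achievable plateau is \code{min(|set|, k)}.
#'
#' @param expression named numeric vector: one cell's expression over all
#'   genes (raw or normalized; only ranks matter).
#' @param gene_set character vector of set gene ids; must intersect the
#'   expression names.
#' @param top_fraction fraction of top-ranked genes integrated, in (0, 1].
#' @return AUC in \code{[0, 1]}.
#' @examples
#' expr <- setNames(10:1, paste0("g", 1:10))
#' rank_auc(expr, c("g1", "g2"), top_fraction = 0.5)  # set at the top: 1
#' @export
rank_auc <- function(expression, gene_set, top_fraction = 0.05) {
  if (top_fraction <= 0 || top_fraction > 1)
    stop("top_fraction must lie in (0, 1]")
  if (is.null(names(expression))) stop("expression must be a named vector")
  gene_set <- unique(gene_set)
  if (!any(gene_set %in% names(expression)))
    stop("gene_set does not intersect the expression gene ids")
  n <- length(expression)
  k <- as.integer(ceiling(top_fraction * n))
  ord <- order(-expression, names(expression))
  in_set <- names(expression)[ord[seq_len(k)]] %in% gene_set
  recovery <- cumsum(in_set)
  m <- min(sum(gene_set %in% names(expression)), k)
  # unit-width step rectangles; best case recovers min(x, m) at rank x
  recovery_max <- pmin(seq_len(k), m)
  sum(recovery) / sum(recovery_max)
}

#' Rank-AUC scores for every cell of a matrix
#'
#' @param counts genes x cells matrix (dense or sparse) with dimnames.
#' @inheritParams rank_auc
#' @return Named numeric vector of per-cell AUCs.
#' @export
auc_scores <- function(counts, gene_set, top_fraction = 0.05) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  counts <- as.matrix(counts)
  vapply(seq_len(ncol(counts)), function(j)
    rank_auc(setNames(counts[, j], rownames(counts)), gene_set, top_fraction),
    numeric(1)) -> auc
  setNames(auc, colnames(counts))
}

#' Automatic AUC threshold by bimodal density analysis
#'
#' Fits a Gaussian kernel density (Sheather-Jones plug-in bandwidth) to the
#' AUC values.  With two genuine modes, the threshold is placed at the
#' density minimum between the two highest modes -- the valley separating
#' inactive from active cells.  Two local maxima only count as genuine
#' bimodality when the smaller mode reaches at least \code{min_mode_height}
#' of the dominant one and the valley drops below \code{max_valley_ratio}
#' of the smaller mode's density; this keeps kernel-density ripples on a
#' single-population distribution from being mistaken for a second mode.
#' Otherwise the fallback is \code{mean + 3 sd} of the dominant mode
#' (clamped to the data range) and the result is flagged.
#'
#' @param aucs numeric AUC values (>= 50 recommended; fewer warns).
#' @param min_mode_height minimum density of the secondary mode, relative
#'   to the dominant mode.
#' @param max_valley_ratio maximum valley density relative to the smaller
#'   of the two modes.
#' @return List: \code{threshold} (always within the data range),
#'   \code{method} (\code{"bimodal"} or \code{"unimodal_fallback"}),
#'   \code{modes} (positions of the two used modes, or the single mode).
#' @export
find_threshold <- function(aucs, min_mode_height = 0.05,
                           max_valley_ratio = 0.8) {
  aucs <- aucs[is.finite(aucs)]
  if (length(unique(aucs)) == 1L)
    stop("AUC values are constant; no threshold structure")
  if (length(aucs) < 50L)
    warning("fewer than 50 cells; threshold estimate may be unstable")
  bw <- tryCatch(stats::bw.SJ(aucs), error = function(e) stats::bw.nrd0(aucs))
  d <- stats::density(aucs, bw = bw)
  y <- d$y; n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
              FALSE)
  peaks <- which(is_max)
  bimodal <- FALSE
  if (length(peaks) >= 2L) {
    top2 <- peaks[order(y[peaks], decreasing = TRUE)][1:2]
    lo <- min(top2); hi <- max(top2)
    valley <- lo + which.min(y[lo:hi]) - 1L
    smaller <- min(y[top2])
    bimodal <- smaller >= min_mode_height * max(y[top2]) &&
      y[valley] <= max_valley_ratio * smaller
  }
  if (bimodal) {
    thr <- d$x[valley]
    method <- "bimodal"
    modes <- sort(d$x[top2])
  } else {
    peak <- if (length(peaks)) peaks[which.max(y[peaks])] else which.max(y)
    thr <- mean(aucs) + 3 * sd(aucs)
    method <- "unimodal_fallback"
    modes <- d$x[peak]
  }
  thr <- min(max(thr, min(aucs)), max(aucs))
  list(threshold = thr, method = method, modes = modes)
}

#' Label cells as spliceosome-gene positive or negative
#'
#' Cells with AUC strictly above the threshold are SG+; cells at or below
#' it are SG- (strict "above" rule, so boundary cells are SG-).
#'
#' @param aucs named numeric AUC vector.
#' @param threshold finite AUC cut value.
#' @return Factor (\code{SG-}, \code{SG+}) named by cell.
#' @export
label_cells <- function(aucs, threshold) {
  if (!is.finite(threshold)) stop("threshold must be finite")
  factor(ifelse(aucs > threshold, "SG+", "SG-"), levels = c("SG-", "SG+"))
}

#' Score and classify all cells of a matrix
#'
#' Convenience wrapper: computes per-cell rank-AUCs, determines the
#' threshold (automatically unless one is given), and labels the cells.
#'
#' @inheritParams auc_scores
#' @param threshold fixed AUC threshold; \code{NULL} (default) uses
#'   \code{\link{find_threshold}}.
#' @return Object of class \code{"cell_activity"}: \code{auc},
#'   \code{threshold}, \code{method}, \code{labels}, \code{top_fraction}.
#' @examples
#' sim <- simulate_cells(sim_config(seed = 1, n_cells = 120), paste0("S", 1:20))
#' act <- score_cells(sim$counts, sim$gene_set)
#' act
#' @export
score_cells <- function(counts, gene_set, top_fraction = 0.05,
                        threshold = NULL) {
  auc <- auc_scores(counts, gene_set, top_fraction)
  if (is.null(threshold)) {
    th <- find_threshold(auc)
  } else {
    th <- list(threshold = threshold, method = "fixed", modes = numeric(0))
  }
  out <- list(auc = auc, threshold = th$threshold, method = th$method,
              modes = th$modes, labels = label_cells(auc, th$threshold),
              top_fraction = top_fraction)
  class(out) <- "cell_activity"
  out
}

#' @export
print.cell_activity <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf(
    "Cell activity: %d cells, threshold %.4f (%s), top fraction %.2f\n",
    length(x$auc), x$threshold, x$method, x$top_fraction))
  cat(sprintf("  SG+: %d (%.1f%%), SG-: %d\n", tab[["SG+"]],
              100 * tab[["SG+"]] / length(x$auc), tab[["SG-"]]))
  invisible(x)
}

#' @export
plot.cell_activity <- function(x, breaks = 40, ...) {
  hist(x$auc, breaks = breaks, main = "Rank-AUC distribution",
       xlab = "AUC", ...)
  abline(v = x$threshold, col = "red", lwd = 2)
  legend("topright", legend = sprintf("threshold = %.3f (%s)",
                                      x$threshold, x$method), bty = "n")
  invisible(x)
}

#' Chi-square comparison of SG+ proportions between groups
#'
#' Pearson chi-square test (no continuity correction by default) on the
#' 2x2 contingency of label (SG+/SG-) by group, as used for comparing the
#' SG+ cancer-cell fraction between responder groups.
#'
#' @param labels factor/character of SG labels per cell.
#' @param group_assignment group label per cell (two groups).
#' @param correct apply Yates continuity correction.
#' @return List: \code{statistic}, \code{p}, \code{table},
#'   \code{proportions} (SG+ fraction per group).
#' @export
compare_proportions <- function(labels, group_assignment, correct = FALSE) {
  if (!is.factor(labels)) labels <- factor(labels)
  tab <- table(labels, factor(group_assignment))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero margin in the contingency table; use an exact test instead")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  prop <- tab["SG+", ] / colSums(tab)
  list(statistic = unname(ct$statistic), p = ct$p.value, table = tab,
       proportions = prop)
}
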