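#' Distribution distance (r.m.s.d.) between two expression profiles
#'
#' Root-mean-square difference of log-expression over a gene subset:
#' \code{sqrt(mean((a[g] - b[g])^2))}.  Genes with a missing value in
#' either vector are dropped (recorded in the \code{"dropped"} attribute);
#' an empty effective subset is an error.
#'
#' @param vector_a,vector_b named numeric log-expression vectors.
#' @param gene_subset genes to compare over (default: shared names).
#' @return Nonnegative r.m.s.d.; zero iff the profiles agree on the subset.
#' @examples
#' pair_rmsd(c(g1 = 1, g2 = 2, g3 = 3), c(g1 = 2, g2 = 2, g3 = 5))
#' @export
pair_rmsd <- function(vector_a, vector_b, gene_subset = NULL) {
  if (is.null(gene_subset))
    gene_subset <- intersect(names(vector_a), names(vector_b))
  a <- vector_a[gene_subset]; b <- vector_b[gene_subset]
  keep <- is.finite(a) & is.finite(b)
  if (!any(keep)) stop("no usable genes in the requested subset")
  out <- sqrt(mean((a[keep] - b[keep])^2))
  if (any(!keep)) attr(out, "dropped") <- gene_subset[!keep]
  out
}

#' Per-comparison r.m.s.d. distributions with group tests
#'
#' For each named comparison, computes the r.m.s.d. between tumor samples
#' of a subtype stratum and normal tissue over the gene subset, under one
#' of two pairing policies: \code{"matched-pairs"} (each tumor against its
#' pair-id-matched normal; unpaired samples are excluded and recorded) or
#' \code{"all-cross-pairs"} (every sample of the first stratum against
#' every sample of the second -- used e.g. for the normal-vs-normal
#' baseline).  Comparisons are then tested against each other with
#' two-sided Wilcoxon rank-sum tests, plus an omnibus Kruskal-Wallis test
#' when three or more comparisons remain.
#'
#' @param expr genes x samples matrix of log expression.
#' @param annot sample annotation: data frame \code{sample}, \code{type}
#'   (\code{tumor}/\code{normal}), \code{subtype}, \code{pair_id}.
#' @param comparisons named list; each element is
#'   \code{list(subtype =, policy =)} where policy is
#'   \code{"matched-pairs"} or \code{"all-cross-pairs"}.  The default
#'   compares each subtype's matched tumor/normal pairs plus an
#'   all-cross-pairs normal-vs-normal baseline.
#' @param gene_subset genes used for the distances (default: all rows).
#' @return Object of class \code{"distance_result"}: \code{rmsd} (named
#'   list of per-pair distances), \code{pairwise_p} (matrix of Wilcoxon p
#'   values), \code{kruskal_p}, \code{excluded} (samples lacking a
#'   partner under matched pairing).
#' @export
group_distances <- function(expr, annot, comparisons = NULL,
                            gene_subset = rownames(expr)) {
  stopifnot(all(c("sample", "type", "subtype", "pair_id") %in% names(annot)))
  if (is.null(comparisons)) {
    subs <- setdiff(unique(annot$subtype[annot$type == "tumor"]), "none")
    comparisons <- lapply(subs, function(s)
      list(subtype = s, policy = "matched-pairs"))
    names(comparisons) <- subs
    comparisons$normal_vs_normal <- list(subtype = NULL,
                                         policy = "all-cross-pairs")
  }
  rmsd <- list(); excluded <- character(0)
  for (nm in names(comparisons)) {
    cmp <- comparisons[[nm]]
    policy <- match.arg(cmp$policy, c("matched-pairs", "all-cross-pairs"))
    if (policy == "matched-pairs") {
      tum <- annot[annot$type == "tumor" & annot$subtype == cmp$subtype, ]
      nor <- annot[annot$type == "normal", ]
      partner <- nor$sample[match(tum$pair_id, nor$pair_id)]
      unmatched <- tum$sample[is.na(partner) | is.na(tum$pair_id)]
      if (length(unmatched)) excluded <- c(excluded, unmatched)
      keep <- !is.na(partner) & !is.na(tum$pair_id)
      d <- mapply(function(t, n)
        pair_rmsd(expr[, t], expr[, n], gene_subset),
        tum$sample[keep], partner[keep])
    } else {
      if (is.null(cmp$subtype)) {
        grp1 <- grp2 <- annot$sample[annot$type == "normal"]
        pairs <- t(utils::combn(grp1, 2))
      } else {
        grp1 <- annot$sample[annot$type == "tumor" &
                               annot$subtype == cmp$subtype]
        grp2 <- annot$sample[annot$type == "normal"]
        pairs <- as.matrix(expand.grid(grp1, grp2,
                                       stringsAsFactors = FALSE))
      }
      d <- apply(pairs, 1, function(p)
        pair_rmsd(expr[, p[1]], expr[, p[2]], gene_subset))
    }
    if (length(d) < 2L) {
      warning("comparison '", nm, "' has fewer than 2 pairs; dropped")
      next
    }
    rmsd[[nm]] <- unname(d)
  }
  k <- length(rmsd)
  pairwise_p <- matrix(NA_real_, k, k, dimnames = list(names(rmsd),
                                                       names(rmsd)))
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) for (j in seq(i + 1L, k)) {
      p <- suppressWarnings(
        stats::wilcox.test(rmsd[[i]], rmsd[[j]])$p.value)
      pairwise_p[i, j] <- pairwise_p[j, i] <- p
    }
  }
  kruskal_p <- if (k >= 3L)
    stats::kruskal.test(rmsd)$p.value else NA_real_
  out <- list(rmsd = rmsd, pairwise_p = pairwise_p, kruskal_p = kruskal_p,
              excluded = excluded, n_genes = length(gene_subset))
  class(out) <- "distance_result"
  out
}

#' @export
print.distance_result <- function(x, ...) {
  cat("Distribution distances (r.m.s.d.) over", x$n_genes, "genes\n")
  for (nm in names(x$rmsd))
    cat(sprintf("  %-18s n = %3d, median = %.3f\n", nm,
                length(x$rmsd[[nm]]), median(x$rmsd[[nm]])))
  if (!is.na(x$kruskal_p))
    cat(sprintf("  Kruskal-Wallis p = %.3g\n", x$kruskal_p))
  if (length(x$excluded))
    cat("  excluded (no matched partner):", length(x$excluded), "\n")
  invisible(x)
}

#' Per-sample single-set enrichment score
#'
#' A simple per-sample pathway activity score: each gene is standardized
#' across samples (z-score), then the score of a sample is the mean z over
#' the pathway genes.  By construction the scores have cohort mean zero
#' per pathway.  Genes with zero variance are dropped with a warning.
#'
#' @param expr genes x samples matrix of log expression.
#' @param pathway_genes >= 2 gene ids present in \code{expr}.
#' @return Named numeric score per sample.
#' @export
ss_enrichment <- function(expr, pathway_genes) {
  genes <- intersect(unique(pathway_genes), rownames(expr))
  if (length(genes) < 2L) stop("need at least 2 resolvable pathway genes")
  sub <- expr[genes, , drop = FALSE]
  sds <- apply(sub, 1, sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance genes: ",
            paste(genes[sds == 0], collapse = ", "))
    sub <- sub[sds > 0, , drop = FALSE]
    if (nrow(sub) < 2L) stop("fewer than 2 genes with variance remain")
    sds <- sds[sds > 0]
  }
  z <- (sub - rowMeans(sub)) / sds
  colMeans(z)
}

#' Correlate two per-sample score vectors
#'
#' Spearman correlation (tie-average ranks) between paired scores, e.g. a
#' spliceosome gene's expression versus per-sample metabolic pathway
#' scores.  The p value uses the exact permutation distribution for
#' \code{n <= 9} without ties and the t approximation otherwise.
#' \code{method = "pearson"} is available for linear correlation.
#'
#' @param x_scores,y_scores paired numeric vectors, \code{n >= 4}.
#' @param method \code{"spearman"} (default) or \code{"pearson"}.
#' @return List: \code{rho}, \code{p}, \code{n}, \code{method}.
#' @examples
#' correlate_scores(1:5, c(3, 1, 2, 5, 4))
#' @export
correlate_scores <- function(x_scores, y_scores,
                             method = c("spearman", "pearson")) {
  method <- match.arg(method)
  keep <- is.finite(x_scores) & is.finite(y_scores)
  x <- x_scores[keep]; y <- y_scores[keep]
  n <- length(x)
  if (n < 4L) stop("need at least 4 paired observations")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- method == "spearman" && n <= 9L && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = method,
                                         exact = exact))
  list(rho = unname(ct$estimate), p = ct$p.value, n = n, method = method)
}
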