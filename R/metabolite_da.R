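#' Per-metabolite nonparametric differential testing
#'
#' Runs a two-sided Mann-Whitney U test per metabolite between two sample
#' groups and Benjamini-Hochberg adjusts across all metabolites in the
#' table (a single family).  The change direction is the sign of the
#' median difference (\code{group_b - group_a}) for metabolites with
#' \code{q < alpha}, and \code{"null"} otherwise.  Metabolites constant
#' across all samples get \code{p = 1} and a null direction.
#'
#' @param table metabolite table: data frame with \code{metabolite_id},
#'   optional \code{pathways}, then one abundance column per sample (as
#'   produced by \code{\link{simulate_metabolites}} or
#'   \code{\link{read_metabolite_table}}), or a numeric matrix with
#'   metabolite rownames.
#' @param groups data frame \code{sample}, \code{group} (defaults to the
#'   table's \code{"groups"} attribute).
#' @param group_a,group_b group labels; \code{group_a} is the baseline.
#' @param alpha significance level applied to the adjusted values.
#' @return Data frame: \code{metabolite_id}, \code{log2_md} (median log2
#'   difference), \code{p}, \code{q}, \code{direction}
#'   (\code{up}/\code{down}/\code{null}).
#' @examples
#' spec <- pathway_spec(paste0("m", 1:6), rep("p1", 6), c(2, 2, 2, 0, 0, -2))
#' tab <- simulate_metabolites(sim_config(seed = 1, n_samples_per_group = 8), spec)
#' test_metabolites(tab, group_a = "A", group_b = "B")
#' @export
test_metabolites <- function(table, groups = attr(table, "groups"),
                             group_a = "A", group_b = "B", alpha = 0.05) {
  mat <- metabolite_matrix(table)
  if (is.null(groups)) stop("no sample-to-group mapping supplied")
  if (any(is.na(mat)) || any(mat < 0)) stop("abundances must be nonnegative")
  a_samples <- groups$sample[groups$group == group_a]
  b_samples <- groups$sample[groups$group == group_b]
  if (length(a_samples) < 2L || length(b_samples) < 2L)
    stop("need at least 2 samples per group")
  missing <- setdiff(c(a_samples, b_samples), colnames(mat))
  if (length(missing)) stop("samples absent from table: ",
                            paste(missing, collapse = ", "))
  res <- t(vapply(seq_len(nrow(mat)), function(i) {
    a <- mat[i, a_samples]; b <- mat[i, b_samples]
    if (length(unique(c(a, b))) == 1L) return(c(p = 1, md = 0))
    p <- suppressWarnings(stats::wilcox.test(b, a)$p.value)
    c(p = p, md = median(log2(pmax(b, .Machine$double.xmin))) -
        median(log2(pmax(a, .Machine$double.xmin))))
  }, numeric(2)))
  q <- stats::p.adjust(res[, "p"], method = "BH")
  direction <- ifelse(q < alpha & res[, "md"] > 0, "up",
                      ifelse(q < alpha & res[, "md"] < 0, "down", "null"))
  data.frame(metabolite_id = rownames(mat), log2_md = unname(res[, "md"]),
             p = unname(res[, "p"]), q = unname(q), direction = direction,
             stringsAsFactors = FALSE, row.names = NULL)
}

metabolite_matrix <- function(table) {
  if (is.matrix(table)) {
    if (is.null(rownames(table))) stop("matrix input needs metabolite rownames")
    return(table)
  }
  stopifnot(is.data.frame(table), "metabolite_id" %in% names(table))
  meta_cols <- intersect(c("metabolite_id", "pathways"), names(table))
  mat <- as.matrix(table[, setdiff(names(table), meta_cols), drop = FALSE])
  rownames(mat) <- table$metabolite_id
  mat
}

#' Pathway differential-abundance (DA) score
#'
#' The DA score summarizes a pathway's tendency toward higher metabolite
#' levels in the comparison group:
#' \deqn{DA = (n_{increased} - n_{decreased}) / n_{measured}}
#' counting the significantly increased and decreased member metabolites
#' over all measured members.  It ranges from -1 (every member decreased)
#' to 1 (every member increased).
#'
#' @param n_increased,n_decreased counts of significantly increased /
#'   decreased member metabolites.
#' @param n_measured number of measured member metabolites (>= 1).
#' @return DA score in \code{[-1, 1]}.
#' @examples
#' da_score(8, 0, 8)   #  1
#' da_score(0, 8, 8)   # -1
#' da_score(3, 1, 8)   #  0.25
#' @export
da_score <- function(n_increased, n_decreased, n_measured) {
  if (any(n_measured < 1)) stop("n_measured must be >= 1")
  if (any(n_increased < 0) || any(n_decreased < 0))
    stop("counts must be nonnegative")
  if (any(n_increased + n_decreased > n_measured))
    stop("n_increased + n_decreased must not exceed n_measured")
  (n_increased - n_decreased) / n_measured
}

#' Pathway-level DA scoring
#'
#' Tests all metabolites once (a single Benjamini-Hochberg family across
#' the table), then aggregates the significant directions within each
#' pathway into the DA score.  A metabolite belonging to several pathways
#' contributes to each of them.  Pathways with fewer than \code{min_size}
#' measured members are dropped (recorded in the \code{"dropped"}
#' attribute).
#'
#' @inheritParams test_metabolites
#' @param pathways pathway membership: either taken from the table's
#'   \code{pathways} column (semicolon-separated ids) or a named list
#'   \code{pathway -> metabolite ids}.
#' @param min_size minimum measured members per pathway.
#' @return Data frame of class \code{"pathway_da"}, sorted by score:
#'   \code{pathway_id}, \code{n_measured}, \code{n_increased},
#'   \code{n_decreased}, \code{da_score}.  The per-metabolite test results
#'   are attached as the \code{"metabolite_tests"} attribute.
#' @examples
#' spec <- pathway_spec(paste0("m", 1:8), rep("glycolysis", 8), rep(2, 8))
#' tab <- simulate_metabolites(sim_config(seed = 1, n_samples_per_group = 10), spec)
#' pathway_da(tab)
#' @export
pathway_da <- function(table, pathways = NULL, groups = attr(table, "groups"),
                       group_a = "A", group_b = "B", alpha = 0.05,
                       min_size = 2L) {
  tests <- test_metabolites(table, groups, group_a, group_b, alpha)
  if (is.null(pathways)) {
    if (!is.data.frame(table) || !"pathways" %in% names(table))
      stop("no pathway membership supplied")
    members <- strsplit(table$pathways, ";", fixed = TRUE)
    members <- lapply(members, function(x) trimws(x[nzchar(trimws(x))]))
    pathways <- split(rep(table$metabolite_id, lengths(members)),
                      unlist(members))
  }
  if (length(pathways) == 0L) stop("no pathways to score")
  rows <- list(); dropped <- character(0)
  for (pw in names(pathways)) {
    measured <- intersect(pathways[[pw]], tests$metabolite_id)
    if (length(measured) < min_size) {
      dropped <- c(dropped, pw)
      next
    }
    dirs <- tests$direction[match(measured, tests$metabolite_id)]
    n_inc <- sum(dirs == "up"); n_dec <- sum(dirs == "down")
    rows[[pw]] <- data.frame(pathway_id = pw, n_measured = length(measured),
                             n_increased = n_inc, n_decreased = n_dec,
                             da_score = da_score(n_inc, n_dec, length(measured)),
                             stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L)
    stop("every pathway has fewer than ", min_size, " measured metabolites")
  out <- do.call(rbind, rows)
  out <- out[order(out$da_score, out$pathway_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "metabolite_tests") <- tests
  attr(out, "dropped") <- dropped
  attr(out, "alpha") <- alpha
  class(out) <- c("pathway_da", "data.frame")
  out
}

#' @export
print.pathway_da <- function(x, ...) {
  cat(sprintf("Pathway DA scores (%d pathways, alpha = %g)\n",
              nrow(x), attr(x, "alpha")))
  if (length(attr(x, "dropped")))
    cat("  dropped (too few measured members):",
        paste(attr(x, "dropped"), collapse = ", "), "\n")
  print.data.frame(as.data.frame(x), digits = 3)
  invisible(x)
}

#' Volcano-style classification of metabolites
#'
#' Labels each tested metabolite as increased, decreased, or unchanged
#' using the adjusted significance level and an optional absolute
#' median-log2-difference cutoff (default 0, i.e. significance only).
#'
#' @param tests result of \code{\link{test_metabolites}}.
#' @param alpha adjusted-p significance level.
#' @param lfc_cutoff minimum \code{|log2_md|} to call a change.
#' @return The input with a \code{volcano_class} column.
#' @export
classify_volcano <- function(tests, alpha = 0.05, lfc_cutoff = 0) {
  cls <- ifelse(tests$q < alpha & tests$log2_md > lfc_cutoff, "increased",
                ifelse(tests$q < alpha & tests$log2_md < -lfc_cutoff,
                       "decreased", "unchanged"))
  tests$volcano_class <- cls
  tests
}
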