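# Plain-text readers/writers for the pipeline's exchange formats.  All
# tables are tab-separated with a header row.

#' Read / write the long-format event count table
#'
#' Columns: \code{event_id}, \code{sample}, \code{condition},
#' \code{ir_reads}, \code{sj_reads}.
#'
#' @param file path to a counts TSV.
#' @param counts a counts data frame.
#' @return \code{read_counts_tsv}: the counts data frame.
#' @export
read_counts_tsv <- function(file) {
  x <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("event_id", "sample", "condition", "ir_reads", "sj_reads")
  if (!all(need %in% names(x)))
    stop("counts TSV must have columns: ", paste(need, collapse = ", "))
  x
}

#' @rdname read_counts_tsv
#' @export
write_counts_tsv <- function(counts, file) {
  write.table(counts, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a metabolite table with pathway membership
#'
#' Expected layout: \code{metabolite_id}, \code{pathways}
#' (semicolon-separated ids, possibly empty), then one abundance column per
#' sample.  Group labels come from a separate two-column TSV
#' (\code{sample}, \code{group}) and are attached as the \code{"groups"}
#' attribute.
#'
#' @param file metabolite TSV path.
#' @param groups_file optional groups TSV path.
#' @return Metabolite data frame ready for \code{\link{pathway_da}}.
#' @export
read_metabolite_table <- function(file, groups_file = NULL) {
  x <- read.delim(file, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("metabolite_id", "pathways") %in% names(x)))
    stop("metabolite TSV must start with metabolite_id and pathways columns")
  if (!is.null(groups_file))
    attr(x, "groups") <- read.delim(groups_file, stringsAsFactors = FALSE)
  x
}

#' Read an expression matrix and its sample annotation
#'
#' @param expr_file genes x samples TSV (first column gene ids).
#' @param annot_file TSV with columns \code{sample}, \code{type},
#'   \code{subtype}, \code{pair_id}.
#' @return List \code{expr} (matrix), \code{annot} (data frame).
#' @export
read_expression_cohort <- function(expr_file, annot_file) {
  tab <- read.delim(expr_file, stringsAsFactors = FALSE, check.names = FALSE)
  expr <- as.matrix(tab[, -1, drop = FALSE])
  rownames(expr) <- tab[[1]]
  list(expr = expr,
       annot = read.delim(annot_file, stringsAsFactors = FALSE))
}

write_tsv_matrix <- function(mat, file, id_col = "gene_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
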