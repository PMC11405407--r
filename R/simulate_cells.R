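#' Simulate a single-cell expression matrix with a spliceosome-high subset
#'
#' Draws negative-binomial counts for background genes everywhere and for
#' the gene set at a high mean in an \code{sg_fraction} subset of cells
#' (SG+) versus a low mean elsewhere (SG-), emulating a cell population
#' with bimodal gene-set activity.
#'
#' @param config a \code{\link{sim_config}} (seed, \code{n_cells},
#'   \code{sg_fraction}).
#' @param gene_set nonempty character vector of gene ids forming the
#'   activity set (e.g. \code{\link{spliceosome_genes}()}).
#' @param n_background number of background genes added to the matrix.
#' @param mu_high,mu_low,mu_bg negative-binomial means for set genes in SG+
#'   cells, set genes in SG- cells, and background genes.
#' @return List with \code{counts} (sparse \code{dgCMatrix}, genes x cells),
#'   \code{labels} (factor \code{SG+}/\code{SG-} per cell, the ground
#'   truth), and \code{gene_set}.
#' @examples
#' sim <- simulate_cells(sim_config(seed = 1, n_cells = 50), paste0("S", 1:10))
#' dim(sim$counts)
#' @export
simulate_cells <- function(config, gene_set, n_background = 258L,
                           mu_high = 20, mu_low = 1, mu_bg = 2) {
  validate_sim_config(config)
  gene_set <- unique(as.character(gene_set))
  if (length(gene_set) == 0L) stop("gene_set must be nonempty")
  with_seed(child_seed(config$seed, 4L), {
    nc <- config$n_cells
    genes <- c(gene_set, sprintf("BG%04d", seq_len(n_background)))
    ng <- length(genes)
    n_pos <- round(config$sg_fraction * nc)
    labels <- rep("SG-", nc)
    if (n_pos > 0) labels[sample.int(nc, n_pos)] <- "SG+"
    mu <- matrix(mu_bg, nrow = ng, ncol = nc)
    mu[seq_along(gene_set), labels == "SG+"] <- mu_high
    mu[seq_along(gene_set), labels == "SG-"] <- mu_low
    counts <- matrix(rnbinom(ng * nc, mu = mu, size = 2), nrow = ng)
    dimnames(counts) <- list(genes, sprintf("cell_%04d", seq_len(nc)))
    list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"),
         labels = factor(labels, levels = c("SG-", "SG+")),
         gene_set = gene_set)
  })
}

#' Write / read a cell matrix in MatrixMarket triplet form
#'
#' Companion files \code{genes.txt} and \code{barcodes.txt} hold the row and
#' column names, one per line.
#'
#' @param counts genes x cells matrix (coerced to sparse).
#' @param dir output directory (created if needed).
#' @return \code{write_cell_matrix}: invisibly, the three paths.
#'   \code{read_cell_matrix}: the genes x cells \code{dgCMatrix}.
#' @export
write_cell_matrix <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(m, mtx)
  writeLines(rownames(m), file.path(dir, "genes.txt"))
  writeLines(colnames(m), file.path(dir, "barcodes.txt"))
  invisible(file.path(dir, c("matrix.mtx", "genes.txt", "barcodes.txt")))
}

#' @rdname write_cell_matrix
#' @export
read_cell_matrix <- function(dir) {
  m <- methods::as(Matrix::readMM(file.path(dir, "matrix.mtx")), "CsparseMatrix")
  dimnames(m) <- list(readLines(file.path(dir, "genes.txt")),
                      readLines(file.path(dir, "barcodes.txt")))
  m
}

#' Packaged spliceosome gene list
#'
#' A curated list of 42 core spliceosome genes (U1, U2, U4/U6 and U5 snRNP
#' components, including SNRNP200, PRPF8 and EFTUD2) used as the default
#' activity gene set and cohort gene subset.  It is a plain-text fixture:
#' replace it with any newline-delimited gene list via \code{file}.
#'
#' @param file path to a newline-delimited gene list; defaults to the
#'   packaged list.
#' @return Character vector of gene symbols.
#' @export
spliceosome_genes <- function(file = system.file("extdata",
                                                 "spliceosome_genes.txt",
                                                 package = "spliceometab")) {
  x <- readLines(file)
  x <- trimws(x[nzchar(trimws(x))])
  x[!startsWith(x, "#")]
}

#' Simulate a paired tumor/normal expression cohort
#'
#' Builds a log-scale expression matrix over the spliceosome gene list for
#' three tumor subtypes (MPS1 lipogenic, MPS2 glycolytic, MPS3 mixed), each
#' tumor matched to a normal sample via a pairing id, plus unpaired extra
#' normal samples for the normal-vs-normal baseline.  Subtype-specific
#' upshifts on the gene subset (largest in MPS2) give the subtypes
#' increasing distribution distances from their matched normals.
#'
#' @param config a \code{\link{sim_config}} (seed, noise level).
#' @param genes gene subset to simulate (default the packaged list).
#' @param n_pairs matched tumor/normal pairs per subtype.
#' @param n_extra_normals additional unpaired normal samples.
#' @param shifts named per-subtype mean log2 upshift of the gene subset.
#' @return List with \code{expr} (genes x samples matrix of log2
#'   expression) and \code{annot} (data frame \code{sample}, \code{type},
#'   \code{subtype}, \code{pair_id}).
#' @export
simulate_expression_cohort <- function(config, genes = spliceosome_genes(),
                                       n_pairs = 10L, n_extra_normals = 10L,
                                       shifts = c(MPS1 = 0.4, MPS2 = 1.6,
                                                  MPS3 = 0.9)) {
  validate_sim_config(config)
  with_seed(child_seed(config$seed, 6L), {
    ng <- length(genes)
    cols <- list(); annot <- list()
    add <- function(name, type, subtype, pair, values) {
      cols[[length(cols) + 1L]] <<- values
      names(cols)[length(cols)] <<- name
      annot[[length(annot) + 1L]] <<- data.frame(
        sample = name, type = type, subtype = subtype, pair_id = pair,
        stringsAsFactors = FALSE)
    }
    base <- rnorm(ng, 5, 0.5)  # gene-wise baseline, shared by all samples
    for (sub in names(shifts)) {
      for (i in seq_len(n_pairs)) {
        pid <- sprintf("P_%s_%02d", sub, i)
        add(sprintf("N_%s_%02d", sub, i), "normal", sub, pid,
            base + rnorm(ng, 0, config$noise_sd))
        add(sprintf("T_%s_%02d", sub, i), "tumor", sub, pid,
            base + shifts[[sub]] + rnorm(ng, 0, config$noise_sd))
      }
    }
    for (i in seq_len(n_extra_normals))
      add(sprintf("N_extra_%02d", i), "normal", "none", NA_character_,
          base + rnorm(ng, 0, config$noise_sd))
    expr <- do.call(cbind, cols)
    rownames(expr) <- genes
    list(expr = expr, annot = do.call(rbind, annot))
  })
}
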