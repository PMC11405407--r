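#' Describe a pathway-structured metabolite effect design
#'
#' Convenience constructor for the \code{pathway_spec} consumed by
#' \code{\link{simulate_metabolites}}: one row per metabolite with its
#' pathway memberships (semicolon-separated; may be empty) and the signed
#' log2 shift applied to group B.
#'
#' @param metabolite character vector of metabolite ids (unique).
#' @param pathways character vector of semicolon-separated pathway ids.
#' @param effect numeric signed log2-fold shift for group B (0 = null).
#' @return A validated data frame with class \code{"pathway_spec"}.
#' @export
pathway_spec <- function(metabolite, pathways, effect) {
  stopifnot(length(metabolite) == length(pathways),
            length(metabolite) == length(effect))
  if (anyDuplicated(metabolite)) stop("metabolite ids must be unique")
  out <- data.frame(metabolite = as.character(metabolite),
                    pathways = as.character(pathways),
                    effect = as.numeric(effect), stringsAsFactors = FALSE)
  class(out) <- c("pathway_spec", "data.frame")
  out
}

#' Simulate a metabolite abundance table with pathway-structured shifts
#'
#' Draws log-normal abundances: per-metabolite baseline log2 level plus
#' per-sample Gaussian noise (\code{noise_sd}); group B samples are shifted
#' by each metabolite's \code{effect}.  Column order follows the on-disk
#' convention: metabolite id, pathway ids, then samples.
#'
#' @param config a \code{\link{sim_config}} (supplies seed, group size,
#'   noise level).
#' @param spec a \code{\link{pathway_spec}}.
#' @return Data frame \code{metabolite_id}, \code{pathways}, then
#'   \code{A_1..A_n, B_1..B_n} abundance columns (positive reals).
#'   Attributes: \code{groups} (sample-to-group map) and
#'   \code{ground_truth} (true direction per metabolite:
#'   \code{up}/\code{down}/\code{null}).
#' @examples
#' spec <- pathway_spec(paste0("m", 1:4), rep("glycolysis", 4), c(2, 2, 0, -2))
#' tab <- simulate_metabolites(sim_config(seed = 1, n_samples_per_group = 5), spec)
#' tab[, 1:4]
#' @export
simulate_metabolites <- function(config, spec) {
  validate_sim_config(config)
  if (!inherits(spec, "pathway_spec")) stop("spec must be a pathway_spec()")
  with_seed(child_seed(config$seed, 3L), {
    n <- nrow(spec)
    m <- config$n_samples_per_group
    samples <- c(sprintf("A_%d", seq_len(m)), sprintf("B_%d", seq_len(m)))
    groups <- data.frame(sample = samples,
                         group = rep(c("A", "B"), each = m),
                         stringsAsFactors = FALSE)
    baseline <- rnorm(n, mean = 10, sd = 1)
    logmat <- matrix(rnorm(n * 2L * m, 0, config$noise_sd), nrow = n) + baseline
    logmat[, groups$group == "B"] <- logmat[, groups$group == "B"] + spec$effect
    ab <- 2^logmat
    colnames(ab) <- samples
    out <- data.frame(metabolite_id = spec$metabolite,
                      pathways = spec$pathways, ab,
                      stringsAsFactors = FALSE, check.names = FALSE)
    attr(out, "groups") <- groups
    attr(out, "ground_truth") <- data.frame(
      metabolite_id = spec$metabolite,
      direction = ifelse(spec$effect > 0, "up",
                         ifelse(spec$effect < 0, "down", "null")),
      stringsAsFactors = FALSE)
    out
  })
}
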