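# Deterministic orchestration: simulate -> diff-ir -> site-features -> da
# -> sg-score -> cohort-dist.  All randomness flows from one seed; a
# manifest records the config hash and per-stage row counts so reruns can
# be verified byte-identically.

PIPELINE_STAGES <- c("simulate", "diff_ir", "site_features", "da",
                     "sg_score", "cohort_dist")

#' Read and validate a pipeline run configuration
#'
#' Accepts a YAML file path or a list.  Recognized top-level keys:
#' \code{seed}, \code{outdir}, \code{stages}, \code{simulation} (fields of
#' \code{\link{sim_config}}), \code{thresholds} (\code{fdr}, \code{dpsi},
#' \code{alpha}, \code{top_fraction}).  Unknown keys are rejected.
#'
#' @param config YAML path or list.
#' @return Validated config list of class \code{"run_config"}.
#' @export
read_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  known <- c("seed", "outdir", "stages", "simulation", "thresholds")
  unknown <- setdiff(names(config), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  config$seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  config$stages <- if (is.null(config$stages)) PIPELINE_STAGES
                   else match.arg(config$stages, PIPELINE_STAGES,
                                  several.ok = TRUE)
  th <- config$thresholds
  defaults <- list(fdr = 0.05, dpsi = 0.02, alpha = 0.05,
                   top_fraction = 0.05)
  unknown_th <- setdiff(names(th), names(defaults))
  if (length(unknown_th))
    stop("unknown threshold keys: ", paste(unknown_th, collapse = ", "))
  config$thresholds <- utils::modifyList(defaults, th %||% list())
  sim_args <- config$simulation %||% list()
  unknown_sim <- setdiff(names(sim_args),
                         setdiff(names(formals(sim_config)), "seed"))
  if (length(unknown_sim))
    stop("unknown simulation keys: ", paste(unknown_sim, collapse = ", "))
  class(config) <- "run_config"
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Demonstration pathway design
#'
#' Three synthetic pathways for the demo pipeline: glycolysis (all members
#' shifted up), glutathione (all members shifted down), and a null pathway.
#'
#' @return A \code{\link{pathway_spec}}.
#' @export
demo_pathway_spec <- function() {
  pathway_spec(
    metabolite = c(sprintf("glyc_%d", 1:8), sprintf("gsh_%d", 1:6),
                   sprintf("null_%d", 1:8)),
    pathways = c(rep("glycolysis", 8), rep("glutathione", 6),
                 rep("null_pathway", 8)),
    effect = c(rep(2, 8), rep(-2, 6), rep(0, 8)))
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs under \code{outdir} and a \code{manifest.json} recording the
#' package version, seed, a hash of the canonical configuration, and per
#' stage the row counts and md5 checksums of every output file.  A failing
#' stage stops the run with the stage name; re-running with an identical
#' configuration and seed reproduces all outputs byte-identically.
#'
#' @param config YAML path, list, or \code{\link{read_run_config}} result.
#' @param outdir output directory (overrides the config's).
#' @return Invisibly, the manifest list.
#' @examples
#' \donttest{
#' cfg <- system.file("extdata", "demo_config.yaml", package = "spliceometab")
#' manifest <- run_pipeline(cfg, outdir = tempfile("demo"))
#' names(manifest$stages)
#' }
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (!inherits(config, "run_config")) config <- read_run_config(config)
  outdir <- outdir %||% config$outdir %||% stop("no output directory given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  scfg <- do.call(sim_config, c(list(seed = config$seed),
                                config$simulation %||% list()))
  canonical <- jsonlite::toJSON(list(seed = config$seed,
                                     stages = config$stages,
                                     simulation = unclass(scfg),
                                     thresholds = th),
                                auto_unbox = TRUE, digits = NA)
  cfg_file <- file.path(outdir, "config.json")
  writeLines(as.character(canonical), cfg_file)
  manifest <- list(tool = "spliceometab",
                   version = as.character(packageVersion("spliceometab")),
                   seed = config$seed,
                   config_hash = unname(tools::md5sum(cfg_file)),
                   stages = list())
  path <- function(...) file.path(outdir, ...)
  record <- function(stage, rows, files) {
    manifest$stages[[stage]] <<- list(
      rows = rows,
      outputs = lapply(setNames(files, basename(files)),
                       function(f) unname(tools::md5sum(f))))
  }
  run_stage <- function(stage, fn) {
    if (!stage %in% config$stages) return(invisible(NULL))
    tryCatch(fn(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  need <- function(...) {
    for (f in c(...)) if (!file.exists(f)) stop("missing input: ", f)
  }

  run_stage("simulate", function() {
    txs <- simulate_annotation(scfg)
    write_annotation(txs, path("annotation.gtf"), path("genome.fa"))
    counts <- simulate_ir_counts(txs, scfg)
    write_counts_tsv(counts, path("ir_counts.tsv"))
    met <- simulate_metabolites(scfg, demo_pathway_spec())
    write.table(met, path("metabolites.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    write.table(attr(met, "groups"), path("metabolite_groups.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cells <- simulate_cells(scfg, spliceosome_genes())
    write_cell_matrix(cells$counts, path("cells"))
    cohort <- simulate_expression_cohort(scfg)
    write_tsv_matrix(cohort$expr, path("cohort_expr.tsv"))
    write.table(cohort$annot, path("cohort_annot.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    truth <- list(
      weak_donor = txs$ground_truth$gene_id[txs$ground_truth$weak_donor],
      metabolite_direction = attr(met, "ground_truth"),
      cell_label = setNames(as.character(cells$labels),
                            colnames(cells$counts)))
    writeLines(as.character(jsonlite::toJSON(truth, auto_unbox = TRUE)),
               path("ground_truth.json"))
    record("simulate", nrow(counts),
           path(c("annotation.gtf", "genome.fa", "ir_counts.tsv",
                  "metabolites.tsv", "metabolite_groups.tsv",
                  "cohort_expr.tsv", "cohort_annot.tsv",
                  "ground_truth.json", file.path("cells", "matrix.mtx"))))
  })

  run_stage("diff_ir", function() {
    need(path("ir_counts.tsv"))
    counts <- read_counts_tsv(path("ir_counts.tsv"))
    res <- diff_ir(counts, "control", "knockdown",
                   fdr_threshold = th$fdr, dpsi_threshold = th$dpsi)
    write.table(as.data.frame(res), path("splice_events.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    record("diff_ir", nrow(res), path("splice_events.tsv"))
  })

  run_stage("site_features", function() {
    need(path("annotation.gtf"), path("genome.fa"), path("splice_events.tsv"))
    txs <- load_annotation(path("annotation.gtf"), path("genome.fa"))
    events <- read.delim(path("splice_events.tsv"),
                         stringsAsFactors = FALSE)
    retained <- events$event_id[events$significant]
    feats <- intron_features(txs, retained)
    write.table(feats, path("intron_features.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    ri_donors <- extract_site_sequences(txs, "donor")[retained]
    ri_donors <- ri_donors[!is.na(ri_donors)]
    if (length(ri_donors) >= 2)
      write_motif_matrix(build_site_model(unname(ri_donors), "donor"),
                         path("ri_donor_motif.tsv"))
    else
      write_motif_matrix(consensus_donor_model(), path("ri_donor_motif.tsv"))
    record("site_features", nrow(feats),
           path(c("intron_features.tsv", "ri_donor_motif.tsv")))
  })

  run_stage("da", function() {
    need(path("metabolites.tsv"), path("metabolite_groups.tsv"))
    met <- read_metabolite_table(path("metabolites.tsv"),
                                 path("metabolite_groups.tsv"))
    res <- pathway_da(met, alpha = th$alpha)
    write.table(as.data.frame(res), path("pathway_da.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(attr(res, "metabolite_tests"), path("metabolite_tests.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    record("da", nrow(res),
           path(c("pathway_da.tsv", "metabolite_tests.tsv")))
  })

  run_stage("sg_score", function() {
    need(file.path(outdir, "cells", "matrix.mtx"))
    counts <- read_cell_matrix(path("cells"))
    act <- score_cells(counts, spliceosome_genes(),
                       top_fraction = th$top_fraction)
    percell <- data.frame(cell_id = names(act$auc), auc = act$auc,
                          label = as.character(act$labels),
                          row.names = NULL)
    write.table(percell, path("cell_activity.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    counts_tab <- table(act$labels)
    summary <- list(threshold = act$threshold, method = act$method,
                    top_fraction = act$top_fraction,
                    n_sg_pos = unname(counts_tab[["SG+"]]),
                    n_sg_neg = unname(counts_tab[["SG-"]]),
                    prop_sg_pos = unname(counts_tab[["SG+"]]) /
                      length(act$auc))
    writeLines(as.character(jsonlite::toJSON(summary, auto_unbox = TRUE,
                                             digits = NA)),
               path("sg_summary.json"))
    record("sg_score", length(act$auc),
           path(c("cell_activity.tsv", "sg_summary.json")))
  })

  run_stage("cohort_dist", function() {
    need(path("cohort_expr.tsv"), path("cohort_annot.tsv"))
    cohort <- read_expression_cohort(path("cohort_expr.tsv"),
                                     path("cohort_annot.tsv"))
    dist <- group_distances(cohort$expr, cohort$annot)
    long <- do.call(rbind, lapply(names(dist$rmsd), function(nm)
      data.frame(comparison = nm, rmsd = dist$rmsd[[nm]])))
    write.table(long, path("cohort_distances.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    score <- ss_enrichment(cohort$expr, rownames(cohort$expr))
    cors <- do.call(rbind, lapply(rownames(cohort$expr)[1:3], function(g) {
      ct <- correlate_scores(cohort$expr[g, ], score)
      data.frame(gene = g, rho = ct$rho, p = ct$p)
    }))
    write.table(cors, path("cohort_correlations.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    record("cohort_dist", nrow(long),
           path(c("cohort_distances.tsv", "cohort_correlations.tsv")))
  })

  manifest_file <- path("manifest.json")
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA)), manifest_file)
  invisible(manifest)
}
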