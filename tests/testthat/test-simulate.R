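test_that("annotation generator honors weak fraction and determinism", {
  cfg <- sim_config(seed = 1, n_genes = 10, weak_fraction = 0.5)
  txs <- simulate_annotation(cfg)
  expect_equal(sum(txs$ground_truth$weak_donor), 5)
  expect_length(txs$transcripts, 10)

  # identical config + seed -> byte-identical GTF and FASTA
  f1 <- tempfile(); f2 <- tempfile()
  write_annotation(txs, paste0(f1, ".gtf"), paste0(f1, ".fa"))
  write_annotation(simulate_annotation(cfg), paste0(f2, ".gtf"), paste0(f2, ".fa"))
  for (ext in c(".gtf", ".fa"))
    expect_identical(readLines(paste0(f1, ext)), readLines(paste0(f2, ext)))

  # different seed -> different genome
  other <- simulate_annotation(sim_config(seed = 2, n_genes = 10,
                                          weak_fraction = 0.5))
  expect_false(identical(as.character(txs$genome), as.character(other$genome)))
})

test_that("with weak_fraction 0 every donor scores the model maximum", {
  cfg <- sim_config(seed = 4, n_genes = 8, weak_fraction = 0)
  txs <- simulate_annotation(cfg)
  model <- consensus_donor_model()
  scores <- score_splice_site(extract_site_sequences(txs, "donor"), model)
  max_score <- sum(apply(model$weights, 2, max))
  expect_equal(unname(scores), rep(max_score, 8))
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(weak_fraction = 1.2), "fractions")
  expect_error(sim_config(n_genes = 0), "counts")
  expect_error(sim_config(depth = 0), "depth")
  expect_error(sim_config(intron_length = 50), "70")
})

test_that("ir count simulation matches its sampling model", {
  cfg <- sim_config(seed = 7, n_genes = 50, weak_fraction = 0.5,
                    depth = 50, ir_effect = 0, n_samples_per_group = 3)
  txs <- simulate_annotation(cfg)
  counts <- simulate_ir_counts(txs, cfg)
  # 50 events x 3 samples x 2 conditions
  expect_equal(nrow(counts), 300)
  expect_true(all(counts$ir_reads >= 0 & counts$sj_reads >= 0))

  # null effect: mean observed delta-PSI within 3 SE of 0
  res <- diff_ir(counts, "control", "knockdown")
  se <- sd(res$delta_psi) / sqrt(nrow(res))
  expect_lt(abs(mean(res$delta_psi)), 3 * se)

  # reproducibility of the table itself
  expect_identical(counts, simulate_ir_counts(txs, cfg))
})

test_that("at large depth observed PSI converges to true PSI", {
  cfg <- sim_config(seed = 11, n_genes = 20, weak_fraction = 0.5,
                    depth = 1e5, ir_effect = 0.3, n_samples_per_group = 2)
  txs <- simulate_annotation(cfg)
  counts <- simulate_ir_counts(txs, cfg)
  gt <- attr(counts, "ground_truth")
  counts$psi <- compute_psi(counts$ir_reads, counts$sj_reads)
  obs <- aggregate(psi ~ event_id + condition, counts, mean)
  merged <- merge(obs, gt, by = c("event_id", "condition"))
  expect_true(all(abs(merged$psi - merged$true_psi) < 0.01))
})

test_that("qPCR generator encodes PSI in cycle-threshold differences", {
  # PSI 1 and no noise: the two assays amplify identically
  q <- simulate_qpcr(1, noise_sd = 0, replicates = 3, seed = 1)
  expect_equal(q$ct_in, q$ct_all)
  # PSI 0.25: the intron assay lags by exactly 2 cycles
  q <- simulate_qpcr(0.25, noise_sd = 0, replicates = 3, seed = 1)
  expect_equal(q$ct_in - q$ct_all, rep(2, 3))
  # zero retention has no finite cycle threshold
  expect_error(simulate_qpcr(0), "0, 1")

  # Monte-Carlo: replicate-mean estimates track the truth
  est <- vapply(1:100, function(s) {
    q <- simulate_qpcr(0.3, noise_sd = 0.1, replicates = 3, seed = s)
    mean(qpcr_psi(q$ct_all, q$ct_in))
  }, numeric(1))
  expect_lt(abs(mean(est) - 0.3), 0.05)
})

test_that("metabolite simulation is pathway-structured and reproducible", {
  spec <- pathway_spec(paste0("m", 1:6), c(rep("p1;p2", 3), rep("p1", 3)),
                       c(2, 2, 2, 0, 0, -2))
  cfg <- sim_config(seed = 2, n_samples_per_group = 4)
  tab <- simulate_metabolites(cfg, spec)
  expect_equal(names(tab)[1:2], c("metabolite_id", "pathways"))
  expect_equal(ncol(tab), 2 + 8)
  expect_true(all(tab[, -(1:2)] > 0))
  expect_equal(attr(tab, "ground_truth")$direction,
               c("up", "up", "up", "null", "null", "down"))
  expect_identical(tab, simulate_metabolites(cfg, spec))
  expect_error(pathway_spec(c("a", "a"), c("p", "p"), c(0, 0)), "unique")
})

test_that("null metabolite simulation stays calibrated under BH", {
  spec <- pathway_spec(paste0("m", 1:200), rep("null_pw", 200), rep(0, 200))
  cfg <- sim_config(seed = 9, n_samples_per_group = 10)
  tab <- simulate_metabolites(cfg, spec)
  tests <- test_metabolites(tab, group_a = "A", group_b = "B")
  expect_lte(mean(tests$q < 0.05), 0.10)
})

test_that("cell simulation has the documented shape and ground truth", {
  cfg <- sim_config(seed = 3, n_cells = 1000, sg_fraction = 0.4)
  sim <- simulate_cells(cfg, paste0("S", 1:42), n_background = 458)
  expect_equal(dim(sim$counts), c(500, 1000))
  expect_true(all(sim$counts@x >= 0))
  expect_equal(sum(sim$labels == "SG+"), 400)
  expect_error(simulate_cells(cfg, character(0)), "nonempty")

  # MTX round trip preserves the matrix
  d <- tempfile()
  write_cell_matrix(sim$counts, d)
  back <- read_cell_matrix(d)
  expect_equal(as.matrix(back), as.matrix(sim$counts))
})

test_that("single-population simulations have no bimodal structure", {
  cfg <- sim_config(seed = 5, n_cells = 200, sg_fraction = 0)
  sim <- simulate_cells(cfg, paste0("S", 1:20), n_background = 180)
  auc <- auc_scores(sim$counts, sim$gene_set)
  th <- find_threshold(auc)
  expect_identical(th$method, "unimodal_fallback")
})
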