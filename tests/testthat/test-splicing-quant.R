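test_that("count-based PSI follows the retention fraction", {
  expect_equal(compute_psi(c(0, 30, 10), c(50, 30, 30)), c(0, 0.5, 0.25))
  expect_true(is.na(compute_psi(0, 0)))    # undefined, never 0
  expect_error(compute_psi(-1, 5), "nonnegative")
})

test_that("qPCR PSI inverts cycle-threshold differences and flags overflow", {
  expect_equal(as.numeric(qpcr_psi(20, 20)), 1)
  expect_equal(as.numeric(qpcr_psi(20, 25)), 2^-5)
  over <- qpcr_psi(25, 20)
  expect_equal(as.numeric(over), 32)
  expect_true(attr(over, "out_of_range"))
  expect_error(qpcr_psi(Inf, 20), "finite")

  # monotone decreasing in ct_in
  ct_in <- seq(18, 30, by = 0.5)
  psi <- as.numeric(qpcr_psi(20, ct_in))
  expect_true(all(diff(psi) < 0))
})

test_that("differential retention matches the Fisher/BH construction", {
  mk <- function(ir_a, sj_a, ir_b, sj_b, event = "e1") {
    data.frame(event_id = event, sample = c("a1", "b1"),
               condition = c("A", "B"), ir_reads = c(ir_a, ir_b),
               sj_reads = c(sj_a, sj_b))
  }
  # identical counts: no difference
  res <- diff_ir(mk(10, 90, 10, 90), "A", "B")
  expect_equal(res$p_value, 1)
  expect_false(res$significant)
  expect_equal(res$delta_psi, 0)

  # Fisher p equals hypergeometric enumeration on desk-scale tables
  cases <- list(c(1, 99, 50, 50), c(3, 17, 12, 8), c(0, 20, 5, 15),
                c(40, 60, 55, 45))
  for (cs in cases) {
    res <- diff_ir(mk(cs[1], cs[2], cs[3], cs[4]), "A", "B")
    expect_equal(res$p_value, enum_fisher_p(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-10)
  }

  # sign convention: group_b minus group_a
  res <- diff_ir(mk(10, 90, 30, 70), "A", "B")
  expect_equal(res$delta_psi, 0.2)
  res_rev <- diff_ir(mk(10, 90, 30, 70), "B", "A")
  expect_equal(res_rev$delta_psi, -0.2)

  expect_error(diff_ir(mk(1, 1, 1, 1), "A", "C"), "unknown group")
})

test_that("events with an all-zero group are skipped and recorded", {
  counts <- data.frame(
    event_id = rep(c("ok", "dead"), each = 2),
    sample = rep(c("a1", "b1"), 2),
    condition = rep(c("A", "B"), 2),
    ir_reads = c(5, 9, 0, 4), sj_reads = c(45, 41, 0, 46))
  res <- diff_ir(counts, "A", "B")
  expect_equal(res$event_id, "ok")
  expect_identical(attr(res, "skipped"), "dead")
})

test_that("BH adjustment is invariant to event order", {
  cfg <- sim_config(seed = 21, n_genes = 30, weak_fraction = 0.5, depth = 80)
  counts <- simulate_ir_counts(simulate_annotation(cfg), cfg)
  res <- diff_ir(counts, "control", "knockdown")
  shuffled <- counts[with_fixed_order(nrow(counts)), ]
  res2 <- diff_ir(shuffled, "control", "knockdown")
  expect_equal(res2$fdr[match(res$event_id, res2$event_id)], res$fdr)
  # adjusted values are monotone in raw p-value rank
  ord <- order(res$p_value)
  expect_true(all(diff(res$fdr[ord]) >= -1e-12))
})

test_that("injected retention effects are recovered from counts", {
  cfg <- sim_config(seed = 42, n_genes = 60, weak_fraction = 0.5,
                    depth = 200, ir_effect = 0.3, n_samples_per_group = 3)
  txs <- simulate_annotation(cfg)
  counts <- simulate_ir_counts(txs, cfg)
  res <- diff_ir(counts, "control", "knockdown")
  truth <- txs$ground_truth
  called <- res$event_id[res$significant]
  true_events <- truth$event_id[truth$weak_donor]
  sensitivity <- mean(true_events %in% called)
  fdr_obs <- if (length(called)) mean(!called %in% true_events) else 0
  expect_gte(sensitivity, 0.9)
  expect_lte(fdr_obs, 0.1)

  # pooled-count estimates track the injected effect at this depth
  resp <- res[res$event_id %in% true_events, ]
  expect_lt(max(abs(resp$delta_psi - 0.3)), 0.1)
})

test_that("coding consequences follow intron length and stop content", {
  orf <- function(n) strrep("GCT", n / 3)  # alanine runs, stop-free
  # 90-nt intron, no in-frame stop: frame kept, no truncation
  txs <- toy_tx(c(orf(30), orf(30)), strrep("CCA", 30))
  cc <- detect_ptc(txs, "TOY1", 1)
  expect_false(cc$frameshift)
  expect_true(is.na(cc$ptc_offset))
  expect_false(cc$truncation_flag)

  # 91-nt intron: frameshift
  txs <- toy_tx(c(orf(30), orf(30)), paste0(strrep("CCA", 30), "C"))
  expect_true(detect_ptc(txs, "TOY1", 1)$frameshift)

  # in-frame TAA at codon 5 of the intron
  intron <- paste0(strrep("CCA", 4), "TAA", strrep("CCA", 25))
  txs <- toy_tx(c(orf(30), orf(30)), intron)
  cc <- detect_ptc(txs, "TOY1", 1)
  expect_equal(cc$ptc_offset, 5)
  expect_true(cc$truncation_flag)

  # brute-force translation oracle on the minus strand
  txs_minus <- toy_tx(c(orf(30), orf(30)), intron, strand = "-")
  cc_minus <- detect_ptc(txs_minus, "TOY1", 1)
  expect_equal(cc_minus, cc)

  expect_error(detect_ptc(txs, "TOY1", 5), "out of range")
  expect_error(detect_ptc(txs, "NOPE", 1), "unknown gene")
})
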