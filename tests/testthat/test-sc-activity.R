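test_that("rank-AUC matches brute-force recovery-curve integration", {
  genes <- sprintf("g%03d", 1:100)
  # set genes occupy the top ranks -> maximal recovery
  expr <- setNames(seq(100, 1), genes)
  expect_equal(rank_auc(expr, genes[1:5], top_fraction = 0.05), 1)
  # no set gene within the top k -> zero
  expect_equal(rank_auc(expr, genes[50:60], top_fraction = 0.05), 0)
  # set of 2 genes at ranks 2 and 4 with k = 5
  expect_equal(rank_auc(expr, genes[c(2, 4)], top_fraction = 0.05),
               brute_auc(expr, genes[c(2, 4)], 0.05))
  expect_equal(rank_auc(expr, genes[c(2, 4)], top_fraction = 0.05), 6 / 9)

  # random cases, including sets larger than k
  set.seed(5)
  for (i in 1:20) {
    e <- setNames(rpois(100, 5), genes)
    s <- sample(genes, sample(c(2, 10, 30), 1))
    tf <- sample(c(0.05, 0.1, 0.5), 1)
    expect_equal(rank_auc(e, s, tf), brute_auc(e, s, tf))
  }
  expect_error(rank_auc(expr, "absent"), "intersect")
  expect_error(rank_auc(expr, genes[1], top_fraction = 0), "top_fraction")
})

test_that("rank-AUC is rank-based and respects the step-curve geometry", {
  genes <- sprintf("g%03d", 1:100)
  set.seed(6)
  e <- setNames(rexp(100), genes)
  s <- genes[c(3, 8, 20)]
  a0 <- rank_auc(e, s, 0.1)
  # invariant under strictly monotone transforms of the expression
  expect_equal(rank_auc(log1p(e), s, 0.1), a0)
  expect_equal(rank_auc(e^3, s, 0.1), a0)
  expect_equal(rank_auc(rank(e), s, 0.1), a0)
  # promoting a non-set gene into the top k never increases the AUC
  k <- 10
  low_gene <- names(sort(e))[1]
  e2 <- e; e2[low_gene] <- max(e) + 1
  expect_lte(rank_auc(e2, s, 0.1), a0)
})

test_that("threshold detection finds the valley between two modes", {
  set.seed(7)
  auc <- pmin(pmax(c(rnorm(500, 0.05, 0.01), rnorm(500, 0.30, 0.02)), 0), 1)
  truth <- rep(c("SG-", "SG+"), each = 500)
  th <- find_threshold(auc)
  expect_identical(th$method, "bimodal")
  expect_gt(th$threshold, 0.10)
  expect_lt(th$threshold, 0.25)
  labels <- label_cells(auc, th$threshold)
  expect_gt(mean(as.character(labels) == truth), 0.99)

  # threshold always within the data range
  for (i in 1:5) {
    a <- runif(100)
    t2 <- find_threshold(a)$threshold
    expect_gte(t2, min(a)); expect_lte(t2, max(a))
  }

  # unimodal data takes the flagged fallback path
  set.seed(8)
  uni <- rnorm(500, 0.1, 0.01)
  th_uni <- find_threshold(uni)
  expect_identical(th_uni$method, "unimodal_fallback")

  expect_error(find_threshold(rep(0.2, 100)), "constant")
  expect_warning(find_threshold(runif(20)), "50")
})

test_that("labeling is strictly above-threshold", {
  labs <- label_cells(c(a = 0.10, b = 0.16, c = 0.1600001, d = 0.30), 0.16)
  expect_equal(as.character(labs), c("SG-", "SG-", "SG+", "SG+"))
  expect_equal(sum(label_cells(c(0.1, 0.15), 0.2) == "SG+"), 0)
  expect_error(label_cells(c(0.1), NA), "finite")
})

test_that("end-to-end cell scoring recovers the planted population", {
  cfg <- sim_config(seed = 10, n_cells = 400, sg_fraction = 0.4)
  sim <- simulate_cells(cfg, spliceosome_genes())
  act <- score_cells(sim$counts, sim$gene_set)
  expect_true(all(act$auc >= 0 & act$auc <= 1))
  agreement <- mean(as.character(act$labels) == as.character(sim$labels))
  expect_gte(agreement, 0.95)
  # planted mixture proportion recovered within 2 points
  expect_lt(abs(mean(act$labels == "SG+") - 0.4), 0.02)
})

test_that("proportion comparison equals the Pearson chi-square construction", {
  # identical proportions: statistic 0, p 1
  labels <- rep(c("SG+", "SG-"), each = 100)
  groups <- rep(c("R", "NR"), 100)
  res <- compare_proportions(labels, groups)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  # [[30,10],[10,30]]: brute-force sum((O-E)^2/E) = 20
  labels <- c(rep("SG+", 30), rep("SG-", 10), rep("SG+", 10), rep("SG-", 30))
  groups <- rep(c("R", "NR"), each = 40)
  res <- compare_proportions(labels, groups)
  O <- res$table
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(res$statistic, sum((O - E)^2 / E))
  expect_equal(res$statistic, 20)
  expect_equal(res$p, pchisq(20, df = 1, lower.tail = FALSE))

  # permuting rows with their labels leaves the statistic unchanged
  perm <- with_fixed_order(length(labels))
  expect_equal(compare_proportions(labels[perm], groups[perm])$statistic,
               res$statistic)

  expect_error(compare_proportions(factor(rep("SG-", 40),
                                          levels = c("SG-", "SG+")),
                                   rep(c("R", "NR"), 20)),
               "margin")
})
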