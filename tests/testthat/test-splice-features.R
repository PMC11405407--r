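test_that("site model frequencies, weights and smoothing behave", {
  # identical sequences, no smoothing, uniform background:
  # consensus scores sum(log2(1/0.25)) = 2 bits per position
  m <- build_site_model(rep("CAGGTAAGT", 5), "donor", pseudocount = 0)
  expect_equal(score_splice_site("CAGGTAAGT", m), 2 * 9)
  # recoverable frequencies sum to 1 per position
  expect_equal(unname(colSums(m$freq)), rep(1, 9))

  # background equal to observed frequencies: all weights 0
  seqs <- c("AAAA", "CCCC", "GGGG", "TTTT")
  m0 <- build_site_model(seqs, "donor", background = rep(0.25, 4),
                         pseudocount = 0, window = 4)
  expect_equal(unname(m0$weights), matrix(0, 4, 4))
  expect_equal(score_splice_site("ACGT", m0), 0)

  # positive pseudocount keeps every weight finite
  m1 <- build_site_model(rep("CAGGTAAGT", 3), "donor", pseudocount = 0.5)
  expect_true(all(is.finite(m1$weights)))

  expect_error(build_site_model(c("CAGGTAAGT", "CAGG"), "donor"), "window")
  expect_error(build_site_model("CAGGTNAGT", "donor"), "alphabet")
  expect_error(score_splice_site("CAGGTNAGT", m1), "ambiguity")
  expect_true(is.na(score_splice_site("CAGGTNAGT", m1, on_ambiguous = "na")))
})

test_that("the consensus is the maximum-scoring sequence (full enumeration)", {
  # window-4 toy model dominated by one consensus
  seqs <- c(rep("GTAA", 8), "GTCA", "ATAA", "GGAA")
  m <- build_site_model(seqs, "donor", window = 4)
  all4 <- apply(expand.grid(rep(list(c("A", "C", "G", "T")), 4)), 1,
                function(r) paste(rev(r), collapse = ""))
  scores <- score_splice_site(all4, m)
  expect_equal(all4[which.max(scores)], "GTAA")
  # score never exceeds the sum of per-position maxima
  expect_true(all(scores <= sum(apply(m$weights, 2, max)) + 1e-12))
  # consensus beats every single-mismatch variant
  cons <- "GTAA"
  variants <- unlist(lapply(1:4, function(i)
    vapply(setdiff(c("A", "C", "G", "T"), substr(cons, i, i)), function(b) {
      v <- cons; substr(v, i, i) <- b; v
    }, character(1))))
  expect_true(all(score_splice_site(variants, m) <
                    score_splice_site(cons, m)))
})

test_that("minus-strand extraction round-trips through reverse complement", {
  orf <- function(n) strrep("GCT", n / 3)
  intron <- paste0("GTAAGT", strrep("A", 61), "TTTTTTTTTTTTTTTTTCAG")
  plus <- toy_tx(c(paste0(orf(27), "CAG"), paste0("GTC", orf(27))), intron)
  minus <- toy_tx(c(paste0(orf(27), "CAG"), paste0("GTC", orf(27))), intron,
                  strand = "-")
  for (kind in c("donor", "acceptor"))
    expect_identical(extract_site_sequences(plus, kind),
                     extract_site_sequences(minus, kind))
  m <- consensus_donor_model()
  expect_equal(score_splice_site(extract_site_sequences(minus, "donor"), m),
               score_splice_site(extract_site_sequences(plus, "donor"), m))
})

test_that("trimmed GC ratio matches hand counts and symmetry", {
  expect_equal(relative_gc(strrep("G", 100), strrep("G", 50), strrep("G", 50)), 1)
  # intron core 50% GC, exon cores 50% GC
  expect_equal(relative_gc(strrep("GT", 50), strrep("GA", 25), strrep("CT", 25)),
               1)
  # hand-counted example: core 30 nt with 12 G/C vs exon cores 20 nt with 10 G/C
  intron <- paste0(strrep("A", 20), strrep("G", 12), strrep("A", 18),
                   strrep("T", 20))
  exon <- paste0("AAA", strrep("GT", 10), "AAA")  # 26 nt, core 10/20 GC
  expect_equal(relative_gc(intron, exon, exon), (12 / 30) / 0.5)

  # invariant to reverse-complementing all three sequences together
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  expect_equal(relative_gc(rc(intron), rc(exon), rc(exon)),
               relative_gc(intron, exon, exon))

  # empty core after trimming -> missing value with a reason
  short <- relative_gc(strrep("G", 30), exon, exon)
  expect_true(is.na(short))
  expect_match(attr(short, "reason"), "core")
})

test_that("rank comparison agrees with enumeration and separates groups", {
  # exact route: {1,2,3} vs {4,5,6} is the most extreme of C(6,3) orderings
  res <- compare_ri_nri(1:3, 4:6)
  expect_true(res$exact)
  expect_equal(res$p, 0.1)
  expect_equal(res$p, enum_wilcox_p(1:3, 4:6))

  # exact p equals the enumeration oracle across small samples
  set.seed(17)
  for (i in 1:5) {
    x <- round(rnorm(sample(4:8, 1)), 3)
    y <- round(rnorm(sample(4:8, 1), 0.5), 3)
    res <- compare_ri_nri(x, y)
    expect_equal(res$p, enum_wilcox_p(x, y), tolerance = 1e-10)
  }

  # clear separation at moderate n
  expect_lt(compare_ri_nri(rnorm(50), rnorm(50) + 10)$p, 1e-6)
  expect_error(compare_ri_nri(1, 1:5), "at least 2")
})

test_that("weak-donor genes score below consensus genes on simulated data", {
  cfg <- sim_config(seed = 31, n_genes = 30, weak_fraction = 0.5,
                    depth = 150, ir_effect = 0.3)
  txs <- simulate_annotation(cfg)
  counts <- simulate_ir_counts(txs, cfg)
  res <- diff_ir(counts, "control", "knockdown")
  feats <- intron_features(txs, res$event_id[res$significant])
  # NRI set restricted to genes harboring a retained intron
  expect_true(all(feats$gene_id %in% feats$gene_id[feats$retained]))
  ri <- feats$donor_score[feats$retained]
  nri <- feats$donor_score[!feats$retained]
  expect_lt(mean(ri), mean(nri))
  cmp <- compare_ri_nri(ri, nri)
  expect_lt(cmp$p, 0.01)
  expect_true(all(feats$gc_ratio > 0, na.rm = TRUE))
})
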