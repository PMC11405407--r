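#' Simulate intron-retention and junction read counts
#'
#' For the first intron of every gene, draws per-sample read totals around
#' \code{depth} (Poisson) and splits them into intron-retention and junction
#' reads by a binomial whose success probability is the event's true PSI.
#' Weak-donor genes receive \code{ir_effect} additional true PSI in the
#' knockdown condition; all other genes are null.  True PSI values are
#' clipped to \code{[0, 1]} and the clipped events recorded; clipping more
#' than 10\% of events raises a warning.
#'
#' @param annotation a \code{"transcript_set"} from
#'   \code{\link{simulate_annotation}} (its ground truth supplies the
#'   weak-donor flags).
#' @param config a \code{\link{sim_config}}.
#' @return A data frame with columns \code{event_id}, \code{sample},
#'   \code{condition} (\code{"control"}/\code{"knockdown"}),
#'   \code{ir_reads}, \code{sj_reads}.  Attributes: \code{ground_truth}
#'   (per event and condition true PSI plus the responsive flag) and
#'   \code{clipped} (event ids whose true PSI was clipped).
#' @examples
#' cfg <- sim_config(seed = 1, n_genes = 6, depth = 100)
#' counts <- simulate_ir_counts(simulate_annotation(cfg), cfg)
#' head(counts)
#' @export
simulate_ir_counts <- function(annotation, config) {
  stopifnot(inherits(annotation, "transcript_set"))
  validate_sim_config(config)
  gt <- annotation$ground_truth
  if (is.null(gt)) stop("annotation carries no ground truth; use simulate_annotation()")
  with_seed(child_seed(config$seed, 2L), {
    n <- nrow(gt)
    base_psi <- runif(n, 0.05, 0.15)
    kd_psi_raw <- base_psi + ifelse(gt$weak_donor, config$ir_effect, 0)
    kd_psi <- pmin(pmax(kd_psi_raw, 0), 1)
    clipped <- gt$event_id[kd_psi != kd_psi_raw]
    if (length(clipped) > 0.1 * n)
      warning(sprintf("true PSI clipped for %d of %d events", length(clipped), n))
    m <- config$n_samples_per_group
    rows <- vector("list", 2L * m)
    ri <- 0L
    for (cond in c("control", "knockdown")) {
      psi <- if (cond == "control") base_psi else kd_psi
      for (s in seq_len(m)) {
        trials <- pmax(rpois(n, config$depth), 1L)
        ir <- rbinom(n, trials, psi)
        ri <- ri + 1L
        rows[[ri]] <- data.frame(
          event_id = gt$event_id,
          sample = sprintf("%s_%d", cond, s),
          condition = cond, ir_reads = ir, sj_reads = trials - ir,
          stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "ground_truth") <- data.frame(
      event_id = rep(gt$event_id, 2L),
      condition = rep(c("control", "knockdown"), each = n),
      true_psi = c(base_psi, kd_psi),
      responsive = rep(gt$weak_donor, 2L),
      stringsAsFactors = FALSE)
    attr(out, "clipped") <- clipped
    out
  })
}

#' Simulate qPCR cycle-threshold pairs for a retained intron
#'
#' Emulates the PSI-by-qPCR design: one primer pair spanning the adjacent
#' exons measures all transcripts (\code{ct_all}, fixed baseline) and one
#' pair inside the retained intron measures retaining transcripts
#' (\code{ct_in}).  Since each PCR cycle doubles product,
#' \code{ct_in = ct_all - log2(true_psi)} plus Gaussian noise per replicate;
#' \code{\link{qpcr_psi}} then inverts this to \code{2^(ct_all - ct_in)}.
#'
#' @param true_psi true retention fraction, in \code{(0, 1]}.  Zero is
#'   rejected (infinite cycle threshold): callers must apply their own
#'   detection-limit convention.
#' @param noise_sd per-replicate Gaussian noise on \code{ct_in}, in cycles.
#' @param replicates number of technical replicates.
#' @param seed RNG seed.
#' @param ct_all_baseline fixed cycle threshold of the exon-spanning assay.
#' @return Data frame with columns \code{event_id}, \code{replicate},
#'   \code{ct_all}, \code{ct_in}.
#' @examples
#' simulate_qpcr(0.25, noise_sd = 0, replicates = 2, seed = 1)
#' @export
simulate_qpcr <- function(true_psi, noise_sd = 0.1, replicates = 3L,
                          seed = 1L, ct_all_baseline = 20) {
  if (!is.finite(true_psi) || true_psi <= 0 || true_psi > 1)
    stop("true_psi must lie in (0, 1]; zero retention has no finite cycle threshold")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  with_seed(child_seed(seed, 5L), {
    data.frame(
      event_id = "event",
      replicate = seq_len(replicates),
      ct_all = ct_all_baseline,
      ct_in = ct_all_baseline - log2(true_psi) + rnorm(replicates, 0, noise_sd))
  })
}
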