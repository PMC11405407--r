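# Position-weight log2-odds models over the standard MaxEntScan-style
# windows: donor = 9 positions (3 exonic + 6 intronic), acceptor = 23
# positions (20 intronic + 3 exonic).  The scorer interface is pluggable:
# anything with per-position weights summing a sequence to a strength score
# can replace the bundled PWM.

DONOR_WINDOW <- 9L
ACCEPTOR_WINDOW <- 23L
DNA_BASES <- c("A", "C", "G", "T")

#' Build a splice-site position-weight model
#'
#' Computes per-position base frequencies over aligned window sequences with
#' additive pseudocount smoothing, converts them to log2-odds weights
#' against a background distribution, and records the per-position
#' information content (in bits) for motif-matrix export and logo rendering.
#'
#' @param sequences character vector of aligned site sequences, all of the
#'   window length for \code{site_kind} (donor 9, acceptor 23), alphabet
#'   \code{A/C/G/T}.
#' @param site_kind \code{"donor"} or \code{"acceptor"}.
#' @param background base frequencies (A, C, G, T) summing to 1.
#' @param pseudocount additive smoothing applied per position and base
#'   (default 0.5; any positive value keeps every weight finite).
#' @param window expected window length; defaults to the standard width for
#'   \code{site_kind}.  Override for non-standard models (e.g. toy models).
#' @return An object of class \code{"splice_site_model"}: \code{weights}
#'   (4 x window log2-odds matrix), \code{freq} (smoothed frequencies),
#'   \code{ic} (information-content vector), plus the build parameters.
#' @examples
#' m <- build_site_model(c("CAGGTAAGT", "CAGGTAAGT", "AAGGTAAGT"), "donor")
#' score_splice_site("CAGGTAAGT", m)
#' @export
build_site_model <- function(sequences, site_kind = c("donor", "acceptor"),
                             background = rep(0.25, 4), pseudocount = 0.5,
                             window = NULL) {
  site_kind <- match.arg(site_kind)
  if (is.null(window))
    window <- if (site_kind == "donor") DONOR_WINDOW else ACCEPTOR_WINDOW
  sequences <- toupper(sequences)
  bad <- which(nchar(sequences) != window)
  if (length(bad))
    stop(sprintf("sequence %d ('%s') does not have the %d-nt %s window",
                 bad[1], sequences[bad[1]], window, site_kind))
  if (abs(sum(background) - 1) > 1e-8 || length(background) != 4L)
    stop("background must be 4 base frequencies summing to 1")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  chars <- do.call(rbind, strsplit(sequences, "", fixed = TRUE))
  if (!all(chars %in% DNA_BASES))
    stop("sequences must use the A/C/G/T alphabet only")
  counts <- vapply(seq_len(window), function(j)
    table(factor(chars[, j], levels = DNA_BASES)), numeric(4))
  freq <- (counts + pseudocount) /
    rep(colSums(counts + pseudocount), each = 4)
  weights <- log2(freq / background)
  # information content per position (uniform-background convention)
  ic <- colSums(freq * log2(pmax(freq, .Machine$double.xmin) / 0.25))
  dimnames(weights) <- dimnames(freq) <- list(DNA_BASES, NULL)
  out <- list(site_kind = site_kind, window = window, weights = weights,
              freq = freq, ic = ic, background = setNames(background, DNA_BASES),
              pseudocount = pseudocount, n_sequences = length(sequences))
  class(out) <- "splice_site_model"
  out
}

#' @export
print.splice_site_model <- function(x, ...) {
  cat(sprintf("Splice-site PWM (%s, %d positions) built from %d sequences\n",
              x$site_kind, x$window, x$n_sequences))
  cat("  consensus:", paste(DNA_BASES[apply(x$weights, 2, which.max)],
                            collapse = ""), "\n")
  cat("  max attainable score:", round(sum(apply(x$weights, 2, max)), 3),
      "bits\n")
  invisible(x)
}

#' @export
plot.splice_site_model <- function(x, ...) {
  barplot(x$ic, names.arg = seq_len(x$window),
          xlab = "window position", ylab = "information content (bits)",
          main = sprintf("%s site model", x$site_kind), ...)
  invisible(x)
}

#' Score a splice site against a position-weight model
#'
#' Strength is the sum of per-position log2-odds weights, in bits.  This is
#' the model-scorer contract the downstream rank comparisons consume: any
#' monotone strength score can be plugged in instead.
#'
#' @param sequence character vector of site sequences (each the model's
#'   window length).
#' @param model a \code{\link{build_site_model}} result.
#' @param on_ambiguous \code{"error"} (default) or \code{"na"}: what to do
#'   with sequences containing non-A/C/G/T codes.
#' @return Numeric score vector (bits).
#' @export
score_splice_site <- function(sequence, model, on_ambiguous = c("error", "na")) {
  on_ambiguous <- match.arg(on_ambiguous)
  stopifnot(inherits(model, "splice_site_model"))
  sequence <- toupper(sequence)
  vapply(sequence, function(s) {
    if (nchar(s) != model$window)
      stop(sprintf("sequence length %d does not match the %d-nt window",
                   nchar(s), model$window))
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    if (!all(ch %in% DNA_BASES)) {
      if (on_ambiguous == "error")
        stop("ambiguity code in sequence '", s, "'")
      return(NA_real_)
    }
    sum(model$weights[cbind(match(ch, DNA_BASES), seq_len(model$window))])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Bundled consensus splice-site models
#'
#' Reference models built from the implanted consensus window sequences
#' (donor \code{CAGGTAAGT}; acceptor polypyrimidine tract + \code{CAG} +
#' exonic \code{GTC}) with default smoothing against a uniform background.
#' Under these models the consensus sequence attains the maximum score,
#' making them convenient yardsticks for synthetic annotations.
#'
#' @return A \code{\link{build_site_model}} object.
#' @export
consensus_donor_model <- function() {
  build_site_model(rep(DONOR_CONSENSUS, 20L), "donor")
}

#' @rdname consensus_donor_model
#' @export
consensus_acceptor_model <- function() {
  build_site_model(rep(ACCEPTOR_CONSENSUS, 20L), "acceptor")
}

#' Export a motif matrix
#'
#' Writes the position x base frequency matrix (plus information content)
#' of a site model as TSV, the exchange format for logo rendering.
#'
#' @param model a \code{"splice_site_model"}.
#' @param file output path.
#' @return Invisibly, the exported data frame.
#' @export
write_motif_matrix <- function(model, file) {
  stopifnot(inherits(model, "splice_site_model"))
  df <- data.frame(position = seq_len(model$window), t(model$freq),
                   ic = model$ic)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
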