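#' Per-contig QC parameters
#'
#' @param max_fold_differential maximum coverage max/min ratio across the
#'   coding region (default 100, strict `<`).
#' @param min_segmentation_prob minimum probability of non-chimerism
#'   (default 0.9, strict `>`).
#' @param bins number of coverage bins for the segmentation model
#'   (default 30; reduced to the coding-region length for short CDS).
#' @param variance_floor floor on the pooled log2-coverage variance of the
#'   segmentation model (default 0.25, i.e. sd 0.5 in log2 units ~ 1.4-fold
#'   depth fluctuation -- the null variability of binned read coverage, so
#'   that evidence of segmentation must exceed read-sampling noise).
#' @return A `qc_params` list.
#' @export
qc_params <- function(max_fold_differential = 100, min_segmentation_prob = 0.9,
                      bins = 30L, variance_floor = 0.25) {
  stopifnot(max_fold_differential > 1, min_segmentation_prob > 0,
            min_segmentation_prob < 1, bins >= 2, variance_floor > 0)
  structure(list(max_fold_differential = max_fold_differential,
                 min_segmentation_prob = min_segmentation_prob,
                 bins = as.integer(bins), variance_floor = variance_floor),
            class = "qc_params")
}

#' Zero-mismatch read mapping
#'
#' An alignment is reported at every position where the full read (or its
#' reverse complement) is an exact substring of the coding sequence.
#' Reads containing N never map; reads overhanging the CDS ends do not
#' map; multi-mapping reads are reported at every position (depth is
#' evidence of sequence support, not fragment assignment).
#'
#' @param reads merged `venom_reads`.
#' @param cds a coding sequence (character scalar).
#' @return A data frame with columns read_id, start, end (0-based
#'   half-open) and strand.
#' @export
map_exact <- function(reads, cds) {
  res <- cpp_map_exact(reads$seq, toupper(cds))
  len <- nchar(reads$seq)[res$read]
  data.frame(read_id = reads$id[res$read], start = res$start,
             end = res$start + len, strand = res$strand)
}

#' Per-base coverage from alignments
#'
#' @param alignments data frame with 0-based half-open `start`/`end`
#'   columns (as from [map_exact()]).
#' @param cds_len coding-sequence length.
#' @return A `coverage_profile`: integer vector of per-base depths.
#' @export
coverage_profile <- function(alignments, cds_len) {
  if (nrow(alignments) > 0 &&
      (min(alignments$start) < 0 || max(alignments$end) > cds_len)) {
    stop("alignment outside the coding region")
  }
  delta <- integer(cds_len + 1L)
  if (nrow(alignments) > 0) {
    inc <- tabulate(alignments$start + 1L, nbins = cds_len + 1L)
    dec <- tabulate(alignments$end + 1L, nbins = cds_len + 1L)
    delta <- inc - dec
  }
  cumsum(delta)[seq_len(cds_len)]
}

#' Coverage filters
#'
#' The two published coverage criteria: depth above zero at every base of
#' the coding region, and a max/min depth ratio strictly below
#' `max_fold_differential`.
#'
#' @param depth per-base depth vector (a [coverage_profile()]).
#' @param params a [qc_params()] object.
#' @return A list: `min_depth_ok`, `fold_ok`, `min_depth`,
#'   `fold_differential` (`Inf` when any base has zero depth).
#' @export
coverage_filters <- function(depth, params = qc_params()) {
  mn <- min(depth)
  fold <- if (mn > 0) max(depth) / mn else Inf
  list(min_depth_ok = mn > 0, fold_ok = fold < params$max_fold_differential,
       min_depth = mn, fold_differential = fold)
}

#' Segmentation probability of non-chimerism
#'
#' A per-contig surrogate for the Transrate-style segmentation score.
#' Per-base depths are transformed to `log2(depth + 1)` and averaged into
#' `bins` contiguous equal-width bins. Two Gaussian models are compared:
#' M1, one segment (mean + variance, 2 parameters), and M2, the best
#' two-segment split over all change points (two means + pooled variance +
#' the change point, 4 parameters). Segment variances are maximum
#' likelihood with a floor of `variance_floor`. The returned probability
#' is the BIC weight of M1, `exp(-BIC1/2) / (exp(-BIC1/2) + exp(-BIC2/2))`,
#' computed in log space; exactly uniform profiles return 1. A genuine
#' single transcript scores near 1, while the coverage step or junction
#' trough left by a chimera (no reads span the junction) drives the score
#' toward 0; contigs at or below 0.9 fail the published filter.
#'
#' Under strict full-read containment mapping no read can cover the
#' terminal bases of the coding region at full depth, so the profile
#' ramps structurally within one read length of each end; `edge_trim`
#' (set to the median read length by [classify_cds()]) excludes that
#' region, capped at a quarter of the CDS from each end so an interior of
#' at least half the CDS (and at least `bins` bases) always remains. The
#' likelihood is evaluated at the floored variance MLE, so variation
#' below the noise floor contributes no segmentation evidence.
#'
#' @param depth per-base depth vector.
#' @param bins number of bins (default 30).
#' @param variance_floor variance floor in log2 units (default 0.25).
#' @param edge_trim bases to drop from each end before binning (default 0).
#' @return Probability in \[0, 1\] that the profile is a single segment.
#' @export
segmentation_probability <- function(depth, bins = 30L, variance_floor = 0.25,
                                     edge_trim = 0L) {
  n <- length(depth)
  B <- min(as.integer(bins), n)
  if (B < 2) return(1.0)
  trim <- min(as.integer(edge_trim), floor(n / 4), floor((n - B) / 2))
  if (trim > 0) {
    depth <- depth[(trim + 1):(n - trim)]
    n <- length(depth)
  }
  x <- log2(depth + 1)
  grp <- floor((seq_len(n) - 1) * B / n) + 1L
  m <- as.numeric(tapply(x, grp, mean))
  if (max(m) - min(m) < 1e-12) return(1.0)
  # profile log-likelihood at the (floored) variance MLE: variation below
  # the floor contributes no segmentation evidence
  loglik <- function(ss, nn) {
    v <- max(ss / nn, variance_floor)
    -nn / 2 * (log(2 * pi * v) + 1)
  }
  ss1 <- sum((m - mean(m))^2)
  bic1 <- -2 * loglik(ss1, B) + 2 * log(B)
  ss2 <- min(vapply(seq_len(B - 1), function(cp) {
    sum((m[1:cp] - mean(m[1:cp]))^2) +
      sum((m[(cp + 1):B] - mean(m[(cp + 1):B]))^2)
  }, numeric(1)))
  bic2 <- -2 * loglik(ss2, B) + 4 * log(B)
  # BIC weight of the single-segment model, in log space
  1 / (1 + exp((bic1 - bic2) / 2))
}

#' Classify a coding sequence as good or chimeric/misassembled
#'
#' Runs the full per-contig QC chain -- zero-mismatch mapping, coverage
#' profiling, the two coverage filters and the segmentation probability --
#' and issues the published verdict: `good` iff every base is covered, the
#' coverage fold differential is strictly below `max_fold_differential`,
#' and the segmentation probability is strictly above
#' `min_segmentation_prob`.
#'
#' @param cds a coding sequence (character scalar) with an optional name
#'   used as `cds_id`.
#' @param reads the sample's merged `venom_reads`.
#' @param params a [qc_params()] object.
#' @return A `qc_verdict` list: cds_id, n_mapped, min_depth,
#'   fold_differential, segmentation_prob, verdict (`"good"` or
#'   `"chimeric_or_misassembled"`).
#' @export
classify_cds <- function(cds, reads, params = qc_params()) {
  cds_id <- if (!is.null(names(cds))) names(cds)[1] else NA_character_
  cds <- toupper(as.character(cds)[1])
  aln <- map_exact(reads, cds)
  depth <- coverage_profile(aln, nchar(cds))
  cov <- coverage_filters(depth, params)
  trim <- if (nrow(reads)) stats::median(nchar(reads$seq)) else 0
  seg <- segmentation_probability(depth, params$bins, params$variance_floor,
                                  edge_trim = trim)
  good <- cov$min_depth_ok && cov$fold_ok && seg > params$min_segmentation_prob
  structure(list(cds_id = cds_id, n_mapped = nrow(aln),
                 min_depth = cov$min_depth,
                 fold_differential = cov$fold_differential,
                 segmentation_prob = seg,
                 verdict = if (good) "good" else "chimeric_or_misassembled"),
            class = "qc_verdict")
}
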