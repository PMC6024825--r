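#' Count canonical k-mers in a read set
#'
#' Counts every N-free length-`k` window of every read in canonical form
#' (the lexicographic minimum of the k-mer and its reverse complement;
#' library orientation is arbitrary, so forward and reverse occurrences of
#' the same sequence must pool). `k` must be odd so that no k-mer is its
#' own reverse complement; the lane-leakage screen uses k = 57.
#'
#' @param reads a `venom_reads` object (or any data frame with a `seq` column).
#' @param k odd window size, `1 <= k`.
#' @return A `kmer_table`: list with elements `k` and `counts` (named
#'   integer vector of canonical k-mer counts).
#' @examples
#' tab <- count_kmers(new_reads("r", "ACGTA", "IIIII"), k = 3)
#' tab$counts  # ACG counted twice (once via reverse complement), GTA once
#' @export
count_kmers <- function(reads, k = 57L) {
  k <- as.integer(k)
  if (k < 1) stop("k must be >= 1")
  if (k %% 2 == 0) stop("k must be odd (canonicalization is undefined for even k)")
  counts <- cpp_count_kmers(reads$seq, k)
  structure(list(k = k, counts = counts), class = "kmer_table")
}

#' Flag k-mers leaked between two samples in a lane
#'
#' Index misassignment moves reads between samples multiplexed in one
#' sequencing lane. A k-mer is flagged as leaked in direction a -> b when
#' its count in sample a exceeds `ratio` times its count in sample b
#' (strict; a zero count in b is treated as 1, so an absent k-mer still
#' needs a count above `ratio` to be flagged -- this keeps sequencing-error
#' singletons out of the flag set). Both directions are returned.
#'
#' @param table_a,table_b `kmer_table` objects built with the same `k`.
#' @param ratio count-differential threshold (default 500).
#' @return A `leak_report`: list with `a_to_b` and `b_to_a` (character
#'   vectors of flagged canonical k-mers), `k` and `ratio`.
#' @export
flag_leaked_kmers <- function(table_a, table_b, ratio = 500) {
  stopifnot(inherits(table_a, "kmer_table"), inherits(table_b, "kmer_table"))
  if (table_a$k != table_b$k) {
    stop("k-mer tables have different k (", table_a$k, " vs ", table_b$k, ")")
  }
  one_dir <- function(hi, lo) {
    other <- lo$counts[match(names(hi$counts), names(lo$counts))]
    other[is.na(other)] <- 0L
    names(hi$counts)[hi$counts / pmax(other, 1) > ratio]
  }
  structure(list(a_to_b = one_dir(table_a, table_b),
                 b_to_a = one_dir(table_b, table_a),
                 k = table_a$k, ratio = ratio),
            class = "leak_report")
}

#' Remove reads dominated by leaked k-mers
#'
#' A read is removed when at least `fraction` of its N-free k-mer windows
#' are in the flagged set (windows containing N count toward neither the
#' numerator nor the denominator). Reads with no usable window are kept.
#'
#' @param reads a `venom_reads` object.
#' @param flagged character vector of flagged canonical k-mers.
#' @param k the k used to build the flag set.
#' @param fraction removal threshold in (0, 1]; the lane screen uses 0.25
#'   ("25% or more" -- the comparison is `>=`).
#' @return A list with `kept` and `removed` (`venom_reads`), a partition of
#'   the input.
#' @export
filter_leaked_reads <- function(reads, flagged, k, fraction = 0.25) {
  stopifnot(fraction > 0, fraction <= 1)
  stats <- cpp_flagged_window_stats(reads$seq, as.character(flagged), as.integer(k))
  usable <- stats[, 2]
  frac <- ifelse(usable > 0, stats[, 1] / usable, 0)
  removed <- usable > 0 & frac >= fraction
  list(kept = reads[!removed, , drop = FALSE],
       removed = reads[removed, , drop = FALSE])
}

#' Lane-wide crosstalk filter
#'
#' Applies the k-mer leakage screen to every ordered pair of samples in a
#' lane: k-mers with a count differential above `ratio` are flagged per
#' pair, and a read is removed from a sample if any pairwise rule removes
#' it (it is dominated by k-mers that are `ratio`-fold more abundant in
#' another sample of the lane).
#'
#' @param samples named list of `venom_reads`, one per sample in the lane.
#' @param k odd k-mer size (default 57).
#' @param ratio count-differential threshold (default 500).
#' @param fraction read-removal window fraction (default 0.25).
#' @return A list with `kept` (named list of filtered `venom_reads`),
#'   `removed` (named list) and `report` (data frame: sample_hi, sample_lo,
#'   n_flagged, n_removed).
#' @export
crosstalk_filter <- function(samples, k = 57L, ratio = 500, fraction = 0.25) {
  stopifnot(is.list(samples), length(samples) >= 2, !is.null(names(samples)))
  tabs <- lapply(samples, count_kmers, k = k)
  nm <- names(samples)
  drop <- lapply(samples, function(s) logical(nrow(s)))
  report <- NULL
  for (i in seq_along(samples)) {
    for (j in seq_along(samples)) {
      if (i >= j) next
      rep_ij <- flag_leaked_kmers(tabs[[i]], tabs[[j]], ratio = ratio)
      for (dir in list(c(i, j), c(j, i))) {
        hi <- dir[1]; lo <- dir[2]
        flagged <- if (hi == i) rep_ij$a_to_b else rep_ij$b_to_a
        res <- filter_leaked_reads(samples[[lo]], flagged, k, fraction)
        rm_ids <- res$removed$id
        drop[[lo]] <- drop[[lo]] | samples[[lo]]$id %in% rm_ids
        report <- rbind(report, data.frame(
          sample_hi = nm[hi], sample_lo = nm[lo],
          n_flagged = length(flagged), n_removed = length(rm_ids)))
      }
    }
  }
  list(kept = Map(function(s, d) s[!d, , drop = FALSE], samples, drop),
       removed = Map(function(s, d) s[d, , drop = FALSE], samples, drop),
       report = report)
}
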