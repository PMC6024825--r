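#' Trimming and merging parameters
#'
#' @param quality_threshold phred threshold for 3' quality trimming
#'   (default 5).
#' @param min_length minimum retained read length in nt (default 75);
#'   shorter reads are discarded after trimming.
#' @return A `trim_params` list.
#' @export
trim_params <- function(quality_threshold = 5L, min_length = 75L) {
  stopifnot(quality_threshold >= 0, quality_threshold <= 60, min_length >= 1)
  structure(list(quality_threshold = as.integer(quality_threshold),
                 min_length = as.integer(min_length)), class = "trim_params")
}

#' @rdname trim_params
#' @param min_overlap minimum read-pair overlap in nt (default 10).
#' @param max_mismatch_fraction maximum mismatch fraction inside an
#'   admissible overlap (default 0.02).
#' @return A `merge_params` list.
#' @export
merge_params <- function(min_overlap = 10L, max_mismatch_fraction = 0.02) {
  stopifnot(min_overlap >= 1, max_mismatch_fraction >= 0, max_mismatch_fraction < 1)
  structure(list(min_overlap = as.integer(min_overlap),
                 max_mismatch_fraction = max_mismatch_fraction),
            class = "merge_params")
}

#' 3' quality trimming
#'
#' Running-sum (BWA-style) trimming: for each read the 3' suffix cut point
#' maximizing the sum of (threshold - q) over the removed bases is taken;
#' if no suffix has a positive sum the read is unchanged. Reads shorter
#' than `min_length` after trimming are discarded. The operation is
#' idempotent.
#'
#' @param reads a `venom_reads` object.
#' @param params a [trim_params()] object.
#' @return A `venom_reads` object of the retained, trimmed reads.
#' @export
quality_trim <- function(reads, params = trim_params()) {
  stopifnot(inherits(params, "trim_params"))
  if (nrow(reads) == 0) return(reads)
  thr <- params$quality_threshold
  newlen <- vapply(read_qualities(reads), function(q) {
    s <- cumsum(thr - rev(q))
    m <- max(s)
    if (m <= 0) length(q) else length(q) - which.max(s)
  }, integer(1))
  keep <- newlen >= params$min_length
  out <- reads[keep, , drop = FALSE]
  out$seq <- substr(out$seq, 1L, newlen[keep])
  out$qual <- substr(out$qual, 1L, newlen[keep])
  out
}

#' Merge overlapping read pairs
#'
#' `r2` is reverse-complemented, then every overlap of length at least
#' `min_overlap` between the 3' end of `r1` and the 5' end of the
#' reverse-complemented `r2` with mismatch fraction at most
#' `max_mismatch_fraction` is scored as matches minus mismatches (ties go
#' to the longest overlap). Disagreeing overlap positions take the base
#' with the higher quality; merged qualities are the columnwise maximum.
#' Pairs with no admissible overlap are returned unmerged.
#'
#' @param r1,r2 `venom_reads` of equal length; row i of `r2` is the mate
#'   of row i of `r1`.
#' @param params a [merge_params()] object.
#' @return A list with `merged` (a `venom_reads` with `mate == "merged"`)
#'   and `unmerged` (list of the `r1`/`r2` rows that did not merge).
#' @export
merge_pairs <- function(r1, r2, params = merge_params()) {
  stopifnot(inherits(params, "merge_params"), nrow(r1) == nrow(r2))
  if (nrow(r1) == 0) {
    return(list(merged = r1, unmerged = list(r1 = r1, r2 = r2)))
  }
  res <- cpp_merge_pairs(r1$seq, r1$qual, r2$seq, r2$qual,
                         params$min_overlap, params$max_mismatch_fraction)
  ok <- !is.na(res$seq)
  merged <- if (any(ok)) {
    new_reads(r1$id[ok], res$seq[ok], res$qual[ok], "merged")
  } else {
    new_reads(character(), character(), character(), character())
  }
  list(merged = merged,
       unmerged = list(r1 = r1[!ok, , drop = FALSE], r2 = r2[!ok, , drop = FALSE]))
}
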