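#' Seed-and-extend assembler parameters
#'
#' Defaults follow the published parameterization for venom-gland
#' transcriptomes: 1000 random seed reads with minimum base quality 30,
#' mismatch-free extension overlaps of at least 120 bp drawn from reads
#' with minimum base quality 20, 20 replicate extensions per seed per
#' direction, and seed retention only when, in each direction, at least
#' `max(min_extended_replicates, ceiling(retain_fraction * replicates))`
#' replicates extended.
#'
#' @param n_seeds number of seed reads to draw (default 1000).
#' @param seed_min_quality minimum phred at every base of a seed (default 30).
#' @param overlap_len minimum exact extension overlap in nt (default 120).
#' @param extend_min_quality minimum phred at every base of a read used for
#'   extension (default 20).
#' @param replicates_per_direction replicate extensions per seed per
#'   direction (default 20).
#' @param retain_fraction fraction of replicates that must extend for a
#'   seed to be retained (default 0.20).
#' @param min_extended_replicates absolute minimum extended replicates per
#'   direction (default 2); also the consensus column support floor.
#' @param rng_seed integer seed driving seed selection and replicate
#'   randomness in [assemble()].
#' @param max_contig_len loop guard: replicates stop once the growing
#'   contig reaches this length (default 50000 nt).
#' @return An `extender_params` list.
#' @export
extender_params <- function(n_seeds = 1000L, seed_min_quality = 30L,
                            overlap_len = 120L, extend_min_quality = 20L,
                            replicates_per_direction = 20L,
                            retain_fraction = 0.20,
                            min_extended_replicates = 2L,
                            rng_seed = 1L, max_contig_len = 50000L) {
  stopifnot(n_seeds >= 1, overlap_len >= 1, replicates_per_direction >= 1,
            retain_fraction > 0, retain_fraction <= 1,
            min_extended_replicates >= 1, max_contig_len > overlap_len)
  structure(list(n_seeds = as.integer(n_seeds),
                 seed_min_quality = as.integer(seed_min_quality),
                 overlap_len = as.integer(overlap_len),
                 extend_min_quality = as.integer(extend_min_quality),
                 replicates_per_direction = as.integer(replicates_per_direction),
                 retain_fraction = retain_fraction,
                 min_extended_replicates = as.integer(min_extended_replicates),
                 rng_seed = as.integer(rng_seed),
                 max_contig_len = as.integer(max_contig_len)),
            class = "extender_params")
}

#' Select seed reads
#'
#' Draws up to `n_seeds` reads uniformly without replacement from the
#' reads whose every base has quality at least `seed_min_quality` and
#' whose length is at least `overlap_len`. A drawn candidate is rejected
#' when any of its `overlap_len`-mers (either strand) was already
#' contributed by an accepted seed, so no two seeds can nucleate the same
#' extension path. Uses the current RNG stream; [assemble()] seeds it from
#' `params$rng_seed`.
#'
#' @param reads merged (single-end) `venom_reads`.
#' @param params an [extender_params()] object.
#' @return A `venom_reads` object of accepted seeds.
#' @export
select_seeds <- function(reads, params = extender_params()) {
  if (nrow(reads) == 0) return(reads)
  eligible <- cpp_min_phred(reads$qual) >= params$seed_min_quality &
    nchar(reads$seq) >= params$overlap_len & !grepl("N", reads$seq, fixed = TRUE)
  idx <- which(eligible)
  if (length(idx) == 0) return(reads[0, , drop = FALSE])
  ord <- idx[sample.int(length(idx))]
  acc <- cpp_select_seeds_scan(reads$seq[ord], params$overlap_len, params$n_seeds)
  reads[ord[acc], , drop = FALSE]
}

#' Build the extension overlap index
#'
#' Indexes every read whose bases all have quality at least
#' `extend_min_quality`, in both orientations, for exact-overlap candidate
#' lookup. Reads containing N are never extension candidates. Entries are
#' keyed by each oriented read's 5'-terminal `overlap_len`-mer; candidate
#' search slides the key over the contig's terminal window so that the
#' candidate set is exactly the reads with a mismatch-free overlap of at
#' least `overlap_len` that protrude past the contig end.
#'
#' @param reads merged `venom_reads`.
#' @param params an [extender_params()] object.
#' @return An `overlap_index` object.
#' @export
build_overlap_index <- function(reads, params = extender_params()) {
  eligible <- nrow(reads) > 0 &
    cpp_min_phred(reads$qual) >= params$extend_min_quality
  sub <- reads[which(eligible), , drop = FALSE]
  structure(list(ptr = cpp_build_overlap_index(sub$seq, params$overlap_len),
                 k = params$overlap_len, read_ids = sub$id,
                 n_reads = nrow(sub)),
            class = "overlap_index")
}

#' @export
print.overlap_index <- function(x, ...) {
  cat("overlap_index: ", x$n_reads, " reads, overlap_len = ", x$k,
      ", ", cpp_index_size(x$ptr), " distinct terminal k-mers\n", sep = "")
  invisible(x)
}

#' Single extension step
#'
#' Candidates are reads (either strand) aligning to the contig's terminal
#' window with an exact, mismatch-free overlap of at least `overlap_len`
#' bases and protruding at least one base beyond the contig end in
#' `direction`; one is chosen uniformly at random.
#'
#' @param contig_seq current contig sequence (length >= `overlap_len`).
#' @param index an [build_overlap_index()] object.
#' @param direction `"right"` or `"left"`.
#' @return `NULL` when no candidate exists, else a list with the grown
#'   `seq`, the incorporated `read` id, its `strand` and the `overlap`
#'   length used.
#' @export
extend_once <- function(contig_seq, index, direction = c("right", "left")) {
  direction <- match.arg(direction)
  stopifnot(inherits(index, "overlap_index"), nchar(contig_seq) >= index$k)
  res <- cpp_extend_once(index$ptr, contig_seq, if (direction == "right") 0L else 1L)
  if (length(res) == 0) return(NULL)
  seq <- if (direction == "right") {
    paste0(contig_seq, res$addition)
  } else {
    paste0(res$addition, contig_seq)
  }
  list(seq = seq, read = index$read_ids[res$read], strand = res$strand,
       overlap = res$overlap)
}

#' Run one replicate extension
#'
#' Applies [extend_once()] repeatedly in one direction until no candidate
#' remains (or the contig reaches `max_contig_len`). Reads are reusable
#' across and within replicates: coverage is not consumed.
#'
#' @param seed_seq the seed read sequence.
#' @inheritParams extend_once
#' @param params an [extender_params()] object.
#' @return A list with `extension` (bases added beyond the seed, possibly
#'   empty, in contig orientation) and `steps` (reads incorporated;
#'   `steps == 0` iff `extension == ""`).
#' @export
run_replicate <- function(seed_seq, index, direction = c("right", "left"),
                          params = extender_params()) {
  direction <- match.arg(direction)
  stopifnot(inherits(index, "overlap_index"))
  cpp_run_replicate(index$ptr, seed_seq, if (direction == "right") 0L else 1L,
                    params$max_contig_len)
}

# Extended replicates required per direction to retain a seed: the
# conjunction of the absolute minimum ("at least two extensions for each
# direction") and the fraction rule ("20% of replicates per seed").
required_extensions <- function(params) {
  max(params$min_extended_replicates,
      ceiling(params$retain_fraction * params$replicates_per_direction))
}

# Column-wise majority consensus of replicate extensions, truncated at the
# first column with support below min_support or with a tied majority.
# Columns are counted outward from the seed (pass reversed strings for
# leftward extensions).
consensus_extension <- function(exts, min_support) {
  exts <- exts[nzchar(exts)]
  if (length(exts) < min_support) return("")
  mat <- vapply(exts, function(e) {
    c(strsplit(e, "", fixed = TRUE)[[1]], rep(NA_character_, max(nchar(exts)) - nchar(e)))
  }, character(max(nchar(exts))))
  if (is.null(dim(mat))) mat <- matrix(mat, nrow = 1)
  out <- character(0)
  for (col in seq_len(nrow(mat))) {
    chars <- mat[col, !is.na(mat[col, ])]
    if (length(chars) < min_support) break
    tab <- sort(table(chars), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) break
    out <- c(out, names(tab)[1])
  }
  paste(out, collapse = "")
}

#' Assemble one seed into a contig
#'
#' Runs `replicates_per_direction` replicate extensions in each direction.
#' A replicate counts as extended when it incorporated at least one read.
#' The seed is retained only if, in each direction, the number of extended
#' replicates reaches `max(min_extended_replicates,
#' ceiling(retain_fraction * replicates_per_direction))`. The contig is
#' the seed flanked, per direction, by the column-wise majority consensus
#' of the extended replicates' extensions, truncated at the first column
#' supported by fewer than `min_extended_replicates` replicates (a tied
#' majority also truncates -- no base is emitted on the evidence of a
#' single replicate).
#'
#' @param seed one row of a `venom_reads` object.
#' @param index an [build_overlap_index()] object.
#' @param params an [extender_params()] object.
#' @return A `venom_contigs` row, or `NULL` when the seed is not retained.
#' @export
assemble_seed <- function(seed, index, params = extender_params()) {
  stopifnot(nrow(seed) == 1)
  reps <- params$replicates_per_direction
  need <- required_extensions(params)
  exts <- list(right = character(reps), left = character(reps))
  for (dir in c("right", "left")) {
    for (r in seq_len(reps)) {
      exts[[dir]][r] <- run_replicate(seed$seq, index, dir, params)$extension
    }
    if (sum(nzchar(exts[[dir]])) < need) return(NULL)
  }
  right <- consensus_extension(exts$right, params$min_extended_replicates)
  left_rev <- consensus_extension(
    vapply(exts$left, function(e) paste(rev(strsplit(e, "", fixed = TRUE)[[1]]), collapse = ""),
           character(1)),
    params$min_extended_replicates)
  left <- paste(rev(strsplit(left_rev, "", fixed = TRUE)[[1]]), collapse = "")
  support <- min(sum(nzchar(exts$right)), sum(nzchar(exts$left)))
  new_contigs(id = paste0("ctg_", seed$id), seq = paste0(left, seed$seq, right),
              source_method = "extender", seed_id = seed$id,
              replicate_support = support)
}

# Collapse exact duplicates and exact substrings (either strand),
# keeping the longest representative.
collapse_contigs <- function(contigs) {
  if (nrow(contigs) <= 1) return(contigs)
  ord <- order(-nchar(contigs$seq))
  keep_rows <- integer(0)
  kept_seqs <- character(0)
  for (i in ord) {
    s <- contigs$seq[i]
    rc <- revcomp(s)
    contained <- any(vapply(kept_seqs, function(k) {
      grepl(s, k, fixed = TRUE) || grepl(rc, k, fixed = TRUE)
    }, logical(1)))
    if (!contained) {
      keep_rows <- c(keep_rows, i)
      kept_seqs <- c(kept_seqs, s)
    }
  }
  contigs[sort(keep_rows), , drop = FALSE]
}

#' Seed-and-extend assembly
#'
#' The full assembler: seed selection, per-seed replicate extension with
#' consensus, then collapsing of exact-duplicate and exact-substring
#' contigs (the longest representative is kept). Deterministic for a fixed
#' `params$rng_seed`.
#'
#' @param reads merged `venom_reads`.
#' @param params an [extender_params()] object.
#' @return A `venom_contigs` data frame.
#' @export
assemble <- function(reads, params = extender_params()) {
  stopifnot(nrow(reads) > 0)
  withr::with_seed(params$rng_seed, {
    seeds <- select_seeds(reads, params)
    index <- build_overlap_index(reads, params)
    contigs <- NULL
    for (i in seq_len(nrow(seeds))) {
      ctg <- assemble_seed(seeds[i, , drop = FALSE], index, params)
      if (!is.null(ctg)) contigs <- rbind(contigs, ctg)
    }
  })
  if (is.null(contigs)) {
    return(new_contigs(character(), character()))
  }
  class(contigs) <- c("venom_contigs", "data.frame")
  collapse_contigs(contigs)
}
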