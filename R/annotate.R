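#' Annotation and clustering parameters
#'
#' @param annotate_identity minimum glocal identity to call a contig a
#'   toxin (default 0.80, the published global match percentage).
#' @param dedup_identity identity at which near-duplicate coding regions
#'   (allelic variants, assembly duplicates) collapse (default 0.98).
#' @param min_contig_len minimum contig length in nt (default 150; no
#'   shorter venom gene is known in snakes or scorpions).
#' @return A `cluster_params` list.
#' @export
cluster_params <- function(annotate_identity = 0.80, dedup_identity = 0.98,
                           min_contig_len = 150L) {
  stopifnot(annotate_identity > 0, annotate_identity <= dedup_identity,
            dedup_identity <= 1, min_contig_len >= 1)
  structure(list(annotate_identity = annotate_identity,
                 dedup_identity = dedup_identity,
                 min_contig_len = as.integer(min_contig_len)),
            class = "cluster_params")
}

#' Remove short contigs
#'
#' @param contigs a `venom_contigs` object.
#' @param min_len contigs strictly shorter than this are removed
#'   (default 150 nt).
#' @return The retained contigs, input order preserved.
#' @export
length_filter <- function(contigs, min_len = 150L) {
  contigs[nchar(contigs$seq) >= min_len, , drop = FALSE]
}

#' Global alignment identity
#'
#' Optimal Needleman-Wunsch global alignment under unit scoring (match +1,
#' mismatch -1, gap -1); identity is the number of matching columns
#' divided by the total number of alignment columns (gap columns
#' included). Symmetric in its arguments.
#'
#' @param a,b non-empty nucleotide sequences.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' global_identity("ACGT", "ACGA")  # 0.75
#' global_identity("ACGT", "ACG")   # 0.75: one gap column
#' @export
global_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("global_identity: empty sequence")
  cpp_global_identity(toupper(a), toupper(b))
}

#' Annotate contigs against a toxin reference
#'
#' Each reference coding sequence is aligned to each contig (both strands)
#' semi-globally: the reference end-to-end, the contig locally ("glocal"),
#' so contig UTRs are free but any unmatched reference portion counts as
#' gap columns against the identity. A contig whose best reference
#' identity reaches `annotate_identity` is annotated with that single best
#' reference (ties broken by longer reference, then lexicographic name);
#' the coding interval is the contig span of the winning alignment,
#' 0-based half-open on the forward strand of the contig.
#'
#' @param contigs length-filtered `venom_contigs`.
#' @param reference a [toxin_reference()] object.
#' @param params a [cluster_params()] object.
#' @return A data frame of annotations: contig_id, ref_name, family,
#'   identity, start, end, strand.
#' @export
annotate_contigs <- function(contigs, reference, params = cluster_params()) {
  stopifnot(inherits(reference, "toxin_reference"))
  out <- NULL
  for (i in seq_len(nrow(contigs))) {
    fwd <- contigs$seq[i]
    rev <- revcomp(fwd)
    L <- nchar(fwd)
    best <- NULL
    for (j in seq_len(nrow(reference))) {
      for (strand in c("+", "-")) {
        aln <- cpp_glocal_identity(reference$cds[j],
                                   if (strand == "+") fwd else rev)
        better <- is.null(best) ||
          aln$identity > best$identity ||
          (aln$identity == best$identity &&
             (nchar(reference$cds[j]) > nchar(reference$cds[best$j]) ||
                (nchar(reference$cds[j]) == nchar(reference$cds[best$j]) &&
                   reference$name[j] < reference$name[best$j])))
        if (better) {
          best <- list(j = j, strand = strand, identity = aln$identity,
                       start = aln$start, end = aln$end)
        }
      }
    }
    if (!is.null(best) && best$identity >= params$annotate_identity) {
      # map the span back to forward-strand contig coordinates
      if (best$strand == "+") {
        s <- best$start; e <- best$end
      } else {
        s <- L - best$end; e <- L - best$start
      }
      out <- rbind(out, data.frame(
        contig_id = contigs$id[i], ref_name = reference$name[best$j],
        family = reference$family[best$j], identity = best$identity,
        start = s, end = e, strand = best$strand))
    }
  }
  if (is.null(out)) {
    out <- data.frame(contig_id = character(), ref_name = character(),
                      family = character(), identity = numeric(),
                      start = integer(), end = integer(), strand = character())
  }
  out
}

#' Extract annotated coding regions
#'
#' Slices each annotated interval out of its contig (0-based half-open
#' coordinates), reverse-complementing minus-strand calls so the returned
#' coding sequences are in reference orientation.
#'
#' @param contigs a `venom_contigs` object.
#' @param annotations the data frame returned by [annotate_contigs()].
#' @return A data frame with columns id (contig id), ref_name, family and
#'   seq (the coding region).
#' @export
extract_cds <- function(contigs, annotations) {
  idx <- match(annotations$contig_id, contigs$id)
  if (anyNA(idx)) stop("annotation refers to unknown contig: ",
                       annotations$contig_id[which(is.na(idx))[1]])
  L <- nchar(contigs$seq[idx])
  if (any(annotations$end > L) || any(annotations$start < 0) ||
      any(annotations$end <= annotations$start)) {
    stop("coding interval out of contig bounds")
  }
  seq <- substr(contigs$seq[idx], annotations$start + 1L, annotations$end)
  minus <- annotations$strand == "-"
  seq[minus] <- revcomp(seq[minus])
  data.frame(id = annotations$contig_id, ref_name = annotations$ref_name,
             family = annotations$family, seq = seq)
}

#' Collapse near-duplicate coding sequences
#'
#' Greedy clustering in the style of cd-hit-est: sequences are visited
#' longest first; each joins the first existing representative it matches
#' at `threshold` global identity or better (either strand), otherwise it
#' founds a new cluster. Representatives are returned in founding order.
#' Identity here is exact alignment identity rather than the word
#' heuristic of the clustering tool, so calls at the threshold are exact.
#'
#' @param cds_records data frame with columns `id` and `seq`.
#' @param threshold identity threshold (default 0.98); comparison is `>=`.
#' @return The representative subset of `cds_records`, with an added
#'   `cluster_size` column.
#' @export
dedup_cds <- function(cds_records, threshold = 0.98) {
  n <- nrow(cds_records)
  if (n == 0) {
    out <- cds_records
    out$cluster_size <- integer(0)
    return(out)
  }
  ord <- order(-nchar(cds_records$seq))
  reps <- integer(0)
  size <- integer(0)
  for (i in ord) {
    s <- cds_records$seq[i]
    rc <- revcomp(s)
    joined <- FALSE
    for (r in seq_along(reps)) {
      rseq <- cds_records$seq[reps[r]]
      if (s == rseq || global_identity(s, rseq) >= threshold ||
          global_identity(rc, rseq) >= threshold) {
        size[r] <- size[r] + 1L
        joined <- TRUE
        break
      }
    }
    if (!joined) {
      reps <- c(reps, i)
      size <- c(size, 1L)
    }
  }
  out <- cds_records[reps, , drop = FALSE]
  out$cluster_size <- size
  out
}
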