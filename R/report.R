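#' Per-family good/chimeric counts
#'
#' Partitions annotated coding sequences by toxin family and QC verdict,
#' the accounting behind per-assembler quality comparisons.
#'
#' @param annotations data frame from [annotate_contigs()] (or any frame
#'   with `contig_id` and `family`).
#' @param verdicts a list of `qc_verdict` objects (from [classify_cds()])
#'   whose `cds_id`s cover every annotated contig, or a data frame with
#'   `cds_id` and `verdict` columns.
#' @return A data frame: family, good, chimeric. Totals over families
#'   equal the number of annotated coding sequences.
#' @export
family_counts <- function(annotations, verdicts) {
  if (nrow(annotations) == 0) {
    return(data.frame(family = character(), good = integer(),
                      chimeric = integer()))
  }
  if (!is.data.frame(verdicts)) {
    verdicts <- data.frame(
      cds_id = vapply(verdicts, `[[`, character(1), "cds_id"),
      verdict = vapply(verdicts, `[[`, character(1), "verdict"))
  }
  idx <- match(annotations$contig_id, verdicts$cds_id)
  if (anyNA(idx)) {
    stop("missing verdict for annotated contig: ",
         annotations$contig_id[which(is.na(idx))[1]])
  }
  v <- verdicts$verdict[idx]
  fams <- sort(unique(annotations$family))
  data.frame(
    family = fams,
    good = vapply(fams, function(f) sum(annotations$family == f & v == "good"),
                  integer(1)),
    chimeric = vapply(fams, function(f) sum(annotations$family == f & v != "good"),
                      integer(1)),
    row.names = NULL)
}

#' Short/long length classes
#'
#' Scorpion-style length classification of coding sequences: `short` is a
#' strict `< cutoff`. The published analyses use 500 bp in the figure and
#' 1000 bp in the text, so the cutoff is a parameter.
#'
#' @param cds_records data frame with a `seq` column (or character vector).
#' @param cutoff length cutoff in nt (default 500).
#' @return A list with integer `short` and `long` counts.
#' @export
length_class_counts <- function(cds_records, cutoff = 500L) {
  stopifnot(cutoff > 0)
  len <- if (is.data.frame(cds_records)) nchar(cds_records$seq) else nchar(cds_records)
  list(short = sum(len < cutoff), long = sum(len >= cutoff))
}

#' Presence/absence matrix against a reference transcript set
#'
#' A reference transcript is marked present in a method's assembly when
#' any of the method's coding sequences matches it at `threshold` global
#' identity or better (either strand; comparison is `>=`). The same CDS
#' may mark several references only if each meets the threshold.
#'
#' @param per_method_cds named list: method -> data frame with a `seq`
#'   column (or character vector of sequences).
#' @param reference data frame with unique `name` (or `id`) and `seq`
#'   columns; a [toxin_reference()] works (its `cds` column is used).
#' @param threshold identity threshold (default 0.98).
#' @return A `presence_matrix`: logical matrix, methods x transcripts.
#' @export
presence_matrix <- function(per_method_cds, reference, threshold = 0.98) {
  nm <- if ("name" %in% names(reference)) reference$name else reference$id
  rseq <- if ("cds" %in% names(reference)) reference$cds else reference$seq
  if (anyDuplicated(nm)) stop("reference names must be unique")
  methods <- names(per_method_cds)
  stopifnot(!is.null(methods))
  cells <- matrix(FALSE, nrow = length(methods), ncol = length(nm),
                  dimnames = list(methods, nm))
  for (m in methods) {
    cds <- per_method_cds[[m]]
    seqs <- if (is.data.frame(cds)) cds$seq else as.character(cds)
    for (s in seqs) {
      rc <- revcomp(s)
      for (t in seq_along(nm)) {
        if (cells[m, t]) next
        if (global_identity(s, rseq[t]) >= threshold ||
            global_identity(rc, rseq[t]) >= threshold) {
          cells[m, t] <- TRUE
        }
      }
    }
  }
  structure(cells, class = c("presence_matrix", "matrix"))
}

#' Best assembler combination
#'
#' Exhaustive search over all method subsets of the given size for the
#' subset whose union recovers the most reference transcripts -- the
#' complementarity question: which few assemblers together give the most
#' complete transcript set. Ties break lexicographically on method names.
#'
#' @param matrix a [presence_matrix()].
#' @param size subset size, between 1 and the number of methods.
#' @return A list with `methods` (character vector) and `union_count`.
#' @export
best_combination <- function(matrix, size) {
  methods <- rownames(matrix)
  stopifnot(size >= 1, size <= length(methods))
  subsets <- combn(sort(methods), size, simplify = FALSE)
  best <- NULL
  for (s in subsets) {
    cnt <- sum(apply(matrix[s, , drop = FALSE], 2, any))
    if (is.null(best) || cnt > best$union_count) {
      best <- list(methods = s, union_count = cnt)
    }
  }
  best
}

#' Simple linear regression with slope test
#'
#' Ordinary least squares of y on x with a two-sided t-test on the slope
#' (n - 2 df), as used to relate k-mer size to transcript recovery. When
#' the residual variance is zero the p-value degenerates to 0 for a
#' nonzero slope and 1 for a zero slope.
#'
#' @param x,y numeric vectors of equal length, at least 3 points, x not
#'   constant.
#' @return A list: slope, intercept, p_value, n.
#' @export
ols_regression <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (max(x) - min(x) == 0) stop("x is constant; the slope is undefined")
  fit <- lm(y ~ x)
  slope <- unname(coef(fit)[2])
  intercept <- unname(coef(fit)[1])
  rss <- sum(fit$residuals^2)
  if (rss < .Machine$double.eps * sum(y^2 + 1)) {
    p <- if (abs(slope) > 1e-12 * (max(abs(y)) + 1)) 0 else 1
  } else {
    n <- length(x)
    se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
    p <- 2 * pt(abs(slope / se), df = n - 2, lower.tail = FALSE)
  }
  list(slope = slope, intercept = intercept, p_value = p, n = length(x))
}

#' Probability that a transcript is sampled as a seed
#'
#' Independent-draw approximation `1 - (1 - f)^S` with
#' `f = transcript_reads / total_reads` and `S = n_seeds`: the chance
#' that at least one of the assembler's random seed reads originates from
#' the transcript. For a transcript represented by 1000 reads in a
#' 10-million-read sample and 1000 seeds this is about 0.095 -- roughly
#' 1 in 10, the scale at which low-expression transcripts start escaping
#' seed-and-extend assembly. (The exact without-replacement probability
#' differs by under 1e-4 at these scales.)
#'
#' @param transcript_reads reads originating from the transcript.
#' @param total_reads total reads in the sample (>= 1).
#' @param n_seeds number of random seeds (>= 0).
#' @return Sampling probability in \[0, 1\].
#' @export
seed_sampling_probability <- function(transcript_reads, total_reads, n_seeds) {
  stopifnot(total_reads >= 1, transcript_reads >= 0,
            transcript_reads <= total_reads, n_seeds >= 0)
  f <- transcript_reads / total_reads
  1 - (1 - f)^n_seeds
}
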