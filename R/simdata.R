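#' Specification of a simulated toxin gene family
#'
#' Describes a multigene family of paralogous toxin transcripts: an
#' ancestor sequence is drawn and each paralog is derived by independent
#' per-site substitution calibrated so that realized pairwise identity
#' matches `target_pairwise_identity`. For multi-paralog families with
#' target identity at most 0.99, every paralog pair is additionally
#' guaranteed to differ at one or more sites in every 120 nt window (a
#' divergence floor that makes perfect-overlap paralog separation a
#' well-defined property); higher targets cannot satisfy the window rule
#' and are an error.
#'
#' @param family family label, e.g. `"SVMP"`.
#' @param n_paralogs number of paralogs (>= 1).
#' @param length_range `c(min, max)` ancestor length in nt.
#' @param target_pairwise_identity target mean pairwise identity within
#'   the family (in `[0.5, 0.99]` for multi-paralog families).
#' @param expression_weights positive expression weight per paralog.
#' @return A `family_spec` list.
#' @export
family_spec <- function(family, n_paralogs, length_range,
                        target_pairwise_identity = 0.96,
                        expression_weights = rep(1, n_paralogs)) {
  stopifnot(n_paralogs >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[2] >= length_range[1],
            length(expression_weights) == n_paralogs,
            all(expression_weights > 0))
  if (n_paralogs > 1 &&
      (target_pairwise_identity < 0.5 || target_pairwise_identity >= 1)) {
    stop("target_pairwise_identity must be in [0.5, 1) for multi-paralog families")
  }
  if (n_paralogs > 1 && target_pairwise_identity > 0.99) {
    stop("target_pairwise_identity > 0.99 cannot satisfy the ",
         "one-divergent-site-per-120-nt rule")
  }
  structure(list(family = family, n_paralogs = as.integer(n_paralogs),
                 length_range = as.integer(length_range),
                 target_pairwise_identity = target_pairwise_identity,
                 expression_weights = expression_weights),
            class = "family_spec")
}

#' Simulation configuration
#'
#' The default configuration emulates the structure of a snake venom-gland
#' transcriptome: an SVMP-like family (6 paralogs, 1400-1800 nt), an
#' SVSP-like family (4 paralogs, 700-800 nt), a CTL-like family
#' (5 paralogs, 400-500 nt), 8 single-copy toxins of mixed length at low
#' expression, and 50 nontoxins -- 73 transcripts in all, with expression
#' heavily skewed toward the toxin families, sequenced as 150 bp
#' paired-end reads.
#'
#' @param families list of [family_spec()] objects.
#' @param nontoxin_count number of nontoxin transcripts (random sequences,
#'   lengths uniform 500-3000 nt).
#' @param nontoxin_weight expression weight of each nontoxin.
#' @param read_length read length in nt (default 150).
#' @param fragment_length `c(mean, sd)` of fragment length in nt.
#' @param n_read_pairs number of read pairs to simulate.
#' @param error_rate per-base substitution error probability (in
#'   `[0, 0.1]`).
#' @param quality_model `list(high, low, fraction_low)`: each base gets
#'   phred `high` except a `fraction_low` share drawn at phred `low`.
#' @param rng_seed integer seed; every simulation operation is
#'   deterministic given the seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(families = default_families(),
                       nontoxin_count = 50L, nontoxin_weight = 2,
                       read_length = 150L, fragment_length = c(250, 25),
                       n_read_pairs = 100000L, error_rate = 0.001,
                       quality_model = list(high = 38L, low = 12L,
                                            fraction_low = 0.03),
                       rng_seed = 1L) {
  stopifnot(error_rate >= 0, error_rate <= 0.1, n_read_pairs >= 0,
            read_length >= 1, fragment_length[1] >= read_length,
            nontoxin_count >= 0)
  structure(list(families = families, nontoxin_count = as.integer(nontoxin_count),
                 nontoxin_weight = nontoxin_weight,
                 read_length = as.integer(read_length),
                 fragment_length = fragment_length,
                 n_read_pairs = as.integer(n_read_pairs),
                 error_rate = error_rate, quality_model = quality_model,
                 rng_seed = as.integer(rng_seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_families <- function() {
  list(
    family_spec("SVMP", 6, c(1400, 1800), 0.96,
                c(2000, 1200, 800, 500, 300, 200)),
    family_spec("SVSP", 4, c(700, 800), 0.96, c(900, 500, 250, 150)),
    family_spec("CTL", 5, c(400, 500), 0.96, c(600, 300, 200, 100, 80)),
    family_spec("PLA2", 1, c(400, 500), expression_weights = 400),
    family_spec("LAAO", 1, c(1500, 1600), expression_weights = 200),
    family_spec("CRISP", 1, c(700, 800), expression_weights = 100),
    family_spec("BPP", 1, c(500, 600), expression_weights = 50),
    family_spec("NGF", 1, c(700, 750), expression_weights = 20),
    family_spec("HYAL", 1, c(1300, 1400), expression_weights = 10),
    family_spec("KUN", 1, c(350, 400), expression_weights = 8),
    family_spec("VEGF", 1, c(550, 600), expression_weights = 5)
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# per-site substitution rate giving expected pairwise identity t between
# two sequences independently mutated from a common ancestor:
# identity = (1-r)^2 + r^2/3
substitution_rate_for_identity <- function(t) {
  0.75 * (1 - sqrt(1 - 4 / 3 * (1 - t)))
}

mutate_chars <- function(chars, rate) {
  hit <- which(runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  chars
}

# Enforce >= 1 divergent site per k-length window for every paralog pair
# by substituting a base at the midpoint of any identical run of length
# >= k (changed to differ from both paralogs at that site).
enforce_window_divergence <- function(mat, k = 120L) {
  n <- ncol(mat)
  L <- nrow(mat)
  if (n < 2 || L < k) return(mat)
  for (iter in 1:200) {
    fixed_any <- FALSE
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        d <- which(mat[, i] != mat[, j])
        bounds <- c(0L, d, L + 1L)
        runs <- which(diff(bounds) > k)
        for (r in runs) {
          mid <- floor((bounds[r] + bounds[r + 1]) / 2)
          mat[mid, j] <- sample(setdiff(c("A", "C", "G", "T"),
                                        c(mat[mid, i], mat[mid, j])), 1)
          fixed_any <- TRUE
        }
      }
    }
    if (!fixed_any) return(mat)
  }
  stop("could not satisfy the per-window divergence rule")
}

#' Simulate one toxin gene family
#'
#' Draws a uniform-random ancestor at a length uniform in `length_range`
#' and derives each paralog by independent per-site substitution at the
#' rate that yields the target pairwise identity, then enforces the
#' one-divergent-site-per-120-nt rule for every pair (when the target is
#' at most 0.99). Uses the current RNG stream;
#' [simulate_transcriptome()] seeds it from the configuration.
#'
#' @param spec a [family_spec()] object.
#' @return A data frame with columns `name` (e.g. `"SVMP-2"`), `family`
#'   and `seq`.
#' @export
simulate_family <- function(spec) {
  stopifnot(inherits(spec, "family_spec"))
  L <- if (spec$length_range[1] == spec$length_range[2]) {
    spec$length_range[1]
  } else {
    sample(spec$length_range[1]:spec$length_range[2], 1)
  }
  anc <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
  if (spec$n_paralogs == 1) {
    return(data.frame(name = if (spec$family %in% c("SVMP", "SVSP", "CTL")) {
      paste0(spec$family, "-1")
    } else {
      spec$family
    }, family = spec$family, seq = paste(anc, collapse = "")))
  }
  rate <- substitution_rate_for_identity(spec$target_pairwise_identity)
  mat <- vapply(seq_len(spec$n_paralogs), function(i) mutate_chars(anc, rate),
                character(L))
  if (spec$target_pairwise_identity <= 0.99) {
    mat <- enforce_window_divergence(mat, 120L)
  }
  data.frame(name = paste0(spec$family, "-", seq_len(spec$n_paralogs)),
             family = spec$family,
             seq = apply(mat, 2, paste, collapse = ""))
}

#' Simulate a venom-gland transcriptome with known truth
#'
#' Concatenates all configured toxin families plus `nontoxin_count`
#' nontoxin transcripts (uniform-random sequences, lengths uniform
#' 500-3000 nt) and normalizes expression weights to sampling
#' probabilities. Deterministic given `config$rng_seed`.
#'
#' @param config a [sim_config()] object.
#' @return A `venom_truth` data frame: name, family, seq, weight.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, {
    parts <- lapply(config$families, function(spec) {
      fam <- simulate_family(spec)
      fam$weight <- spec$expression_weights
      fam
    })
    truth <- do.call(rbind, parts)
    if (config$nontoxin_count > 0) {
      nt_len <- sample(500:3000, config$nontoxin_count, replace = TRUE)
      truth <- rbind(truth, data.frame(
        name = paste0("NTX-", seq_len(config$nontoxin_count)),
        family = "nontoxin",
        seq = vapply(nt_len, random_dna, character(1)),
        weight = config$nontoxin_weight))
    }
  })
  truth$weight <- truth$weight / sum(truth$weight)
  rownames(truth) <- NULL
  class(truth) <- c("venom_truth", "data.frame")
  truth
}

# Draw fragments from transcripts chosen proportional to expression.
# Fragment starts are drawn on [-(fl - rl), len - rl] and fragments are
# clipped to the transcript, so fragments pile up at the boundaries the
# way size-selected libraries do and transcript termini keep coverage.
draw_fragments <- function(truth, config, n) {
  rl <- config$read_length
  usable <- nchar(truth$seq) >= rl
  if (!all(usable)) {
    warning(sum(!usable), " transcript(s) shorter than the read length excluded")
  }
  w <- truth$weight * usable
  t_idx <- sample.int(nrow(truth), n, replace = TRUE, prob = w)
  len <- nchar(truth$seq)[t_idx]
  fl <- pmax(round(rnorm(n, config$fragment_length[1], config$fragment_length[2])),
             rl)
  smin <- -(fl - rl)
  s <- smin + floor(runif(n) * (len - rl - smin + 1))
  start <- pmax(0L, s)
  end <- pmin(len, s + fl)
  data.frame(t_idx = t_idx, start = start, end = end)
}

apply_errors <- function(seqs, rate) {
  if (rate == 0 || length(seqs) == 0) return(seqs)
  len <- nchar(seqs)
  nerr <- rbinom(length(seqs), len, rate)
  for (i in which(nerr > 0)) {
    pos <- sample.int(len[i], nerr[i])
    for (p in pos) {
      cur <- substr(seqs[i], p, p)
      substr(seqs[i], p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
    }
  }
  seqs
}

draw_quals <- function(lens, qm) {
  high <- intToUtf8(qm$high + 33L)
  if (qm$fraction_low <= 0 || length(lens) == 0) {
    return(strrep(high, lens))
  }
  low <- intToUtf8(qm$low + 33L)
  total <- sum(lens)
  chars <- ifelse(runif(total) < qm$fraction_low, low, high)
  big <- paste(chars, collapse = "")
  ends <- cumsum(lens)
  substring(big, ends - lens + 1L, ends)
}

#' Simulate paired-end reads
#'
#' Each pair is drawn by choosing a transcript proportional to expression
#' and a fragment (Gaussian length, clipped to the transcript); R1 is the
#' fragment's 5' `read_length` bases and R2 the reverse complement of its
#' 3' `read_length` bases. Substitution errors are i.i.d. at
#' `error_rate`; qualities follow the two-level quality model. With zero
#' error rate every read is an exact substring of its origin transcript
#' (or of its reverse complement). Deterministic given `config$rng_seed`
#' (offset so transcriptome and read draws are independent streams).
#'
#' @param truth a [simulate_transcriptome()] result.
#' @param config a [sim_config()] object.
#' @return A list: `r1`, `r2` (`venom_reads`) and `origin` (data frame
#'   with fragment id, transcript name, fragment start/end).
#' @export
simulate_reads <- function(truth, config = sim_config()) {
  n <- config$n_read_pairs
  rl <- config$read_length
  withr::with_seed(config$rng_seed + 1L, {
    fr <- draw_fragments(truth, config, n)
    frag <- substr(truth$seq[fr$t_idx], fr$start + 1L, fr$end)
    r1 <- substr(frag, 1L, rl)
    r2 <- revcomp(substr(frag, nchar(frag) - rl + 1L, nchar(frag)))
    r1 <- apply_errors(r1, config$error_rate)
    r2 <- apply_errors(r2, config$error_rate)
    q1 <- draw_quals(nchar(r1), config$quality_model)
    q2 <- draw_quals(nchar(r2), config$quality_model)
  })
  ids <- sprintf("f%07d", seq_len(n))
  list(r1 = new_reads(ids, r1, q1, "R1"),
       r2 = new_reads(ids, r2, q2, "R2"),
       origin = data.frame(id = ids, transcript = truth$name[fr$t_idx],
                           start = fr$start, end = fr$end))
}

#' @rdname simulate_reads
#' @details `simulate_merged_reads()` emits each fragment as a single
#'   merged read (the product of a perfectly merged overlapping pair),
#'   on a uniform-random strand, as consumed by the assembler.
#' @export
simulate_merged_reads <- function(truth, config = sim_config()) {
  n <- config$n_read_pairs
  withr::with_seed(config$rng_seed + 2L, {
    fr <- draw_fragments(truth, config, n)
    seqs <- substr(truth$seq[fr$t_idx], fr$start + 1L, fr$end)
    flip <- runif(n) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    seqs <- apply_errors(seqs, config$error_rate)
    quals <- draw_quals(nchar(seqs), config$quality_model)
  })
  ids <- sprintf("m%07d", seq_len(n))
  list(reads = new_reads(ids, seqs, quals, "merged"),
       origin = data.frame(id = ids, transcript = truth$name[fr$t_idx],
                           start = fr$start, end = fr$end,
                           strand = ifelse(flip, "-", "+")))
}

#' Spike index-hopping contamination between samples
#'
#' Copies a uniform-random `fraction` of sample A's reads into sample B
#' (the donor keeps its originals), labelling the copies so that
#' downstream filter recall and precision are exactly computable.
#'
#' @param sample_a,sample_b `venom_reads` objects.
#' @param fraction hopping fraction in `[0, 1)`.
#' @param rng_seed optional seed; when `NULL` the current RNG stream is
#'   used.
#' @return A list: `a` (unchanged), `b` (with contaminants appended) and
#'   `labels` (data frame over rows of `b`: read id, `contaminant` flag).
#' @export
spike_index_hopping <- function(sample_a, sample_b, fraction,
                                rng_seed = NULL) {
  stopifnot(fraction >= 0, fraction < 1)
  pick <- function() which(runif(nrow(sample_a)) < fraction)
  sel <- if (is.null(rng_seed)) pick() else withr::with_seed(rng_seed, pick())
  spiked <- sample_a[sel, , drop = FALSE]
  b <- rbind(sample_b, spiked)
  class(b) <- class(sample_b)
  list(a = sample_a, b = b,
       labels = data.frame(id = b$id,
                           contaminant = c(rep(FALSE, nrow(sample_b)),
                                           rep(TRUE, length(sel)))))
}

#' Construct a chimeric transcript
#'
#' Joins the prefix of `t1` up to `round(len1 * breakpoint_fraction)` to
#' the suffix of `t2` from `round(len2 * breakpoint_fraction)` -- the
#' signature misassembly of multi-isoform data. Reads are never simulated
#' from the chimera itself; QC experiments map parent-derived reads onto
#' it, which leaves the junction without spanning reads.
#'
#' @param t1,t2 parent sequences.
#' @param breakpoint_fraction breakpoint position as a fraction in (0, 1).
#' @return The chimeric sequence.
#' @export
make_chimera <- function(t1, t2, breakpoint_fraction = 0.5) {
  stopifnot(breakpoint_fraction > 0, breakpoint_fraction < 1)
  paste0(substr(t1, 1, round(nchar(t1) * breakpoint_fraction)),
         substring(t2, round(nchar(t2) * breakpoint_fraction) + 1))
}
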