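# Independent oracles and small fixture builders used across the suite.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rc_chr <- function(s) {
  vapply(s, function(x) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", x), "", fixed = TRUE)[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

canonical_kmer <- function(k) {
  rc <- rc_chr(k)
  ifelse(k <= rc, k, rc)
}

# Brute-force canonical k-mer counting: nested loops over reads and
# window positions, dictionary in an environment.
oracle_count_kmers <- function(seqs, k) {
  dict <- new.env(parent = emptyenv())
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1)) {
      w <- substr(s, i, i + k - 1)
      if (grepl("[^ACGT]", w)) next
      cw <- canonical_kmer(w)
      cur <- if (exists(cw, envir = dict)) get(cw, envir = dict) else 0L
      assign(cw, cur + 1L, envir = dict)
    }
  }
  out <- vapply(ls(dict), get, integer(1), envir = dict)
  out[order(names(out))]
}

# Brute-force Needleman-Wunsch (unit scoring) with diagonal-preferring
# traceback; returns matches / columns.
oracle_global_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  m <- length(ca); n <- length(cb)
  D <- matrix(0L, m + 1, n + 1)
  D[1, ] <- -(0:n)
  D[, 1] <- -(0:m)
  for (i in 1:m) {
    for (j in 1:n) {
      D[i + 1, j + 1] <- max(D[i, j] + ifelse(ca[i] == cb[j], 1L, -1L),
                             D[i, j + 1] - 1L, D[i + 1, j] - 1L)
    }
  }
  i <- m; j <- n; matches <- 0L; cols <- 0L
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 &&
        D[i + 1, j + 1] == D[i, j] + ifelse(ca[i] == cb[j], 1L, -1L)) {
      if (ca[i] == cb[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (i > 0 && D[i + 1, j + 1] == D[i, j + 1] - 1L) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1L
  }
  matches / cols
}

# Exhaustive enumeration of all maximal perfect-overlap extension paths
# (rightward) from a starting contig: returns the set of terminal
# sequences reachable by any replicate.
oracle_extension_paths <- function(contig, seqs, k, max_len = 10000) {
  seqs <- unique(c(seqs, rc_chr(seqs)))
  grow <- function(ctg) {
    L <- nchar(ctg)
    adds <- character(0)
    for (s in seqs) {
      ls <- nchar(s)
      omax <- min(L, ls - 1)
      if (omax < k) next
      for (o in k:omax) {
        if (substr(ctg, L - o + 1, L) == substr(s, 1, o)) {
          adds <- c(adds, substr(s, o + 1, ls))
        }
      }
    }
    unique(adds)
  }
  out <- character(0)
  stack <- contig
  seen <- character(0)
  while (length(stack)) {
    ctg <- stack[[1]]
    stack <- stack[-1]
    if (ctg %in% seen) next
    seen <- c(seen, ctg)
    adds <- if (nchar(ctg) < max_len) grow(ctg) else character(0)
    if (length(adds) == 0) {
      out <- unique(c(out, ctg))
    } else {
      stack <- c(stack, paste0(ctg, adds))
    }
  }
  sort(out)
}

# Merged-read simulator for a single known sequence: fragments clip at
# the boundaries so termini keep coverage (mirrors the package's
# fragment model, but written independently of it).
qc_reads_for <- function(seq, depth, rl = 150, flm = 250, flsd = 25,
                         prefix = "r") {
  len <- nchar(seq)
  nfrag <- round(depth * len / flm)
  fl <- pmax(round(rnorm(nfrag, flm, flsd)), rl)
  smin <- -(fl - rl)
  s <- smin + floor(runif(nfrag) * (len - rl - smin + 1))
  start <- pmax(0L, s)
  end <- pmin(len, s + fl)
  frag <- substr(rep(seq, nfrag), start + 1, end)
  new_reads(sprintf("%s%06d", prefix, seq_len(nfrag)), frag,
            strrep("I", nchar(frag)), "merged")
}

bind_reads <- function(...) {
  out <- rbind(...)
  class(out) <- c("venom_reads", "data.frame")
  out
}

# quality string helper: phred integer vector -> phred+33 string
qstr <- function(q) intToUtf8(q + 33L)
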