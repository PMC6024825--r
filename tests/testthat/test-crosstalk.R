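test_that("canonical k-mer counting matches hand enumeration", {
  tab <- count_kmers(new_reads("r", "ACGTA", "IIIII"), k = 3)
  expect_equal(tab$counts[order(names(tab$counts))], c(ACG = 2L, GTA = 1L))
  expect_length(count_kmers(new_reads("r", "AC", "II"), k = 3)$counts, 0)
  empty <- new_reads(character(), character(), character(), character())
  expect_length(count_kmers(empty, k = 3)$counts, 0)
})

test_that("k-mer counting rejects even or non-positive k and skips N windows", {
  r <- new_reads("r", "ACGTACGT", "IIIIIIII")
  expect_error(count_kmers(r, k = 4), "odd")
  expect_error(count_kmers(r, k = 0), ">= 1")
  withN <- count_kmers(new_reads("r", "ACGNACG", "IIIIIII"), k = 3)
  # windows overlapping the N (positions 2-5) are skipped
  expect_equal(sum(withN$counts), 2L)
})

test_that("k-mer counts equal a brute-force dictionary on small inputs", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- vapply(sample(5:30, sample(1:20, 1), TRUE), rand_dna, character(1))
    reads <- new_reads(sprintf("r%d", seq_along(seqs)), seqs,
                       strrep("I", nchar(seqs)))
    got <- count_kmers(reads, k = 5)$counts
    expect_equal(got[order(names(got))], oracle_count_kmers(seqs, 5))
  }
})

make_tab <- function(counts, k = 5) {
  structure(list(k = k, counts = counts), class = "kmer_table")
}

test_that("leak flagging applies the strict >ratio rule with zero-count floor", {
  a <- make_tab(c(AAACC = 1000L, AACCC = 400L, ACCCC = 600L, AAAAC = 10L))
  b <- make_tab(c(AAACC = 1L, AACCC = 1L, AAAAC = 10L))
  rep <- flag_leaked_kmers(a, b, ratio = 500)
  expect_setequal(rep$a_to_b, c("AAACC", "ACCCC"))  # 1000/1 and 600/max(0,1)
  expect_false("AACCC" %in% rep$a_to_b)             # 400 <= 500
  expect_length(rep$b_to_a, 0)
  expect_error(flag_leaked_kmers(a, make_tab(c(AAA = 5L), k = 3)), "different k")
})

test_that("leak flagging is symmetric in its arguments", {
  set.seed(7)
  a <- make_tab(setNames(sample(1:2000, 30),
                         canonical_kmer(vapply(rep(5, 30), rand_dna, character(1)))))
  b <- make_tab(setNames(sample(1:2000, 30),
                         canonical_kmer(vapply(rep(5, 30), rand_dna, character(1)))))
  expect_setequal(flag_leaked_kmers(a, b)$a_to_b, flag_leaked_kmers(b, a)$b_to_a)
  expect_setequal(flag_leaked_kmers(a, b)$b_to_a, flag_leaked_kmers(b, a)$a_to_b)
})

test_that("read removal uses the >=25% flagged-window rule", {
  set.seed(11)
  s <- rand_dna(150)  # 94 windows at k = 57
  wins <- substring(s, 1:94, 57:150)
  canon <- canonical_kmer(wins)
  expect_length(unique(canon), 94)
  r <- new_reads("r", s, strrep("I", 150))
  res24 <- filter_leaked_reads(r, canon[1:24], 57)   # 24/94 = 0.255 >= 0.25
  expect_equal(nrow(res24$removed), 1L)
  res23 <- filter_leaked_reads(r, canon[1:23], 57)   # 23/94 = 0.245 < 0.25
  expect_equal(nrow(res23$kept), 1L)
  # a read of exactly k whose single k-mer is flagged: fraction 1
  r57 <- new_reads("x", substr(s, 1, 57), strrep("I", 57))
  expect_equal(nrow(filter_leaked_reads(r57, canon[1], 57)$removed), 1L)
  # no flagged k-mers, or no usable windows: kept
  expect_equal(nrow(filter_leaked_reads(r, character(), 57)$kept), 1L)
  rshort <- new_reads("s", "ACGT", "IIII")
  expect_equal(nrow(filter_leaked_reads(rshort, canon, 57)$kept), 1L)
})

test_that("filtering conserves reads and is monotone in the flag set", {
  set.seed(13)
  seqs <- vapply(sample(57:150, 40, TRUE), rand_dna, character(1))
  reads <- new_reads(sprintf("r%d", 1:40), seqs, strrep("I", nchar(seqs)))
  all_wins <- unique(canonical_kmer(unlist(
    lapply(seqs, function(s) substring(s, 1:(nchar(s) - 56), 57:nchar(s))))))
  prev_removed <- character(0)
  for (frac_of_set in c(0.1, 0.3, 0.6, 1)) {
    flagged <- all_wins[seq_len(floor(length(all_wins) * frac_of_set))]
    res <- filter_leaked_reads(reads, flagged, 57)
    expect_equal(nrow(res$kept) + nrow(res$removed), 40L)
    expect_length(intersect(res$kept$id, res$removed$id), 0)
    # enlarging the flag set never un-removes a read
    expect_true(all(prev_removed %in% res$removed$id))
    prev_removed <- res$removed$id
  }
})

test_that("lane filter removes hopped reads from the lower-count sample", {
  set.seed(17)
  tr_a <- rand_dna(600)
  tr_b <- rand_dna(600)
  mk <- function(tr, n, prefix) {
    starts <- sample(1:(600 - 150 + 1), n, TRUE)
    new_reads(sprintf("%s%04d", prefix, 1:n),
              substring(tr, starts, starts + 149),
              rep(strrep("I", 150), n), "single")
  }
  # deep sample A (57-mer counts well above ratio x the hopped copies)
  a <- mk(tr_a, 5000, "a")
  b <- mk(tr_b, 800, "b")
  hopped <- mk(tr_a, 5, "hop")
  b_cont <- bind_reads(b, hopped)
  res <- crosstalk_filter(list(A = a, B = b_cont), k = 57, ratio = 500,
                          fraction = 0.25)
  expect_true(all(hopped$id %in% res$removed$B$id))
  expect_false(any(startsWith(res$removed$B$id, "b")))
  expect_equal(nrow(res$kept$A), 5000L)
})
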