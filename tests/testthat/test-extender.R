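# small parameter set used throughout: short overlaps keep fixtures tiny
small_params <- function(...) {
  extender_params(overlap_len = 20L, n_seeds = 10L,
                  replicates_per_direction = 10L, rng_seed = 1L, ...)
}

tile_reads <- function(tr, read_len, step, prefix = "t", q = 40) {
  starts <- seq(1, nchar(tr) - read_len + 1, by = step)
  starts <- unique(c(starts, nchar(tr) - read_len + 1))
  new_reads(sprintf("%s%04d", prefix, seq_along(starts)),
            substring(tr, starts, starts + read_len - 1),
            rep(strrep(qstr(q), read_len), length(starts)), "merged")
}

test_that("seed selection enforces the all-base quality threshold", {
  set.seed(21)
  seqs <- vapply(rep(150, 20), rand_dna, character(1))
  # every read carries one base at q29
  quals <- vapply(rep(150, 20), function(n) {
    q <- rep(40, n); q[sample(n, 1)] <- 29; qstr(q)
  }, character(1))
  reads <- new_reads(sprintf("r%d", 1:20), seqs, quals)
  expect_equal(nrow(select_seeds(reads, extender_params(n_seeds = 20))), 0L)
})

test_that("seeds may not share any overlap-length k-mer", {
  set.seed(22)
  s <- rand_dna(150)
  reads <- new_reads(c("a", "b"), c(s, s), strrep("I", c(150, 150)))
  got <- withr::with_seed(1, select_seeds(reads, extender_params(n_seeds = 2)))
  expect_equal(nrow(got), 1L)
  # reverse-complement copies also share k-mers
  reads2 <- new_reads(c("a", "b"), c(s, rc_chr(s)), strrep("I", c(150, 150)))
  got2 <- withr::with_seed(1, select_seeds(reads2, extender_params(n_seeds = 2)))
  expect_equal(nrow(got2), 1L)
})

test_that("seed selection returns all eligible reads when exhausted", {
  set.seed(23)
  seqs <- vapply(rep(150, 5), rand_dna, character(1))  # mutually k-mer disjoint
  reads <- new_reads(sprintf("r%d", 1:5), seqs, strrep("I", nchar(seqs)))
  got <- select_seeds(reads, extender_params(n_seeds = 1000))
  expect_equal(sort(got$id), sprintf("r%d", 1:5))
})

test_that("extension incorporates only mismatch-free protruding overlaps", {
  set.seed(24)
  tr <- rand_dna(300)
  contig <- substr(tr, 1, 150)
  p <- small_params()
  # candidate overlapping the terminal 120 with a 30-base protrusion
  cand <- substr(tr, 31, 180)
  reads <- new_reads("c1", cand, strrep("I", 150))
  idx <- build_overlap_index(reads, extender_params(overlap_len = 120L))
  res <- extend_once(contig, idx, "right")
  expect_equal(res$seq, substr(tr, 1, 180))
  expect_equal(res$read, "c1")
  expect_equal(res$overlap, 120L)
  # a single mismatch inside the overlap disqualifies the candidate
  bad <- cand
  substr(bad, 60, 60) <- setdiff(c("A", "C", "G", "T"), substr(bad, 60, 60))[1]
  idx_bad <- build_overlap_index(new_reads("b1", bad, strrep("I", 150)),
                                 extender_params(overlap_len = 120L))
  expect_null(extend_once(contig, idx_bad, "right"))
  # no read sharing the terminal window at all
  idx_none <- build_overlap_index(new_reads("n1", rand_dna(150), strrep("I", 150)),
                                  extender_params(overlap_len = 120L))
  expect_null(extend_once(contig, idx_none, "right"))
})

test_that("reverse-strand candidates extend and leftward extension works", {
  set.seed(25)
  tr <- rand_dna(260)
  contig <- substr(tr, 81, 200)  # 120 nt
  params <- extender_params(overlap_len = 100L)
  reads <- new_reads(c("rc_right", "left"),
                     c(rc_chr(substr(tr, 101, 230)), substr(tr, 51, 180)),
                     strrep("I", c(130, 130)))
  idx <- build_overlap_index(reads, params)
  r <- extend_once(contig, idx, "right")
  expect_equal(r$seq, substr(tr, 81, 230))
  expect_equal(r$read, "rc_right")
  expect_equal(r$strand, "-")
  l <- extend_once(contig, idx, "left")
  expect_equal(l$seq, substr(tr, 51, 200))
  expect_equal(l$read, "left")
})

test_that("reads below the extension quality never enter the index", {
  tr <- rand_dna(200)
  q <- rep(40, 150); q[75] <- 19
  reads <- new_reads("low", substr(tr, 31, 180), qstr(q))
  idx <- build_overlap_index(reads, extender_params(overlap_len = 120L))
  expect_null(extend_once(substr(tr, 1, 150), idx, "right"))
})

test_that("a replicate walks an error-free transcript to its end", {
  set.seed(26)
  tr <- rand_dna(800)
  reads <- tile_reads(tr, 100, 5)
  p <- extender_params(overlap_len = 60L, max_contig_len = 5000L)
  idx <- build_overlap_index(reads, p)
  seed_seq <- substr(tr, 301, 400)
  res <- withr::with_seed(9, run_replicate(seed_seq, idx, "right", p))
  expect_gt(res$steps, 0)
  expect_equal(paste0(seed_seq, res$extension), substr(tr, 301, 800))
  resl <- withr::with_seed(9, run_replicate(seed_seq, idx, "left", p))
  expect_equal(paste0(resl$extension, seed_seq), substr(tr, 1, 400))
  # a seed with no overlapping reads does not extend
  lone <- build_overlap_index(new_reads("x", rand_dna(100), strrep("I", 100)), p)
  res0 <- run_replicate(seed_seq, lone, "right", p)
  expect_equal(res0$steps, 0L)
  expect_equal(res0$extension, "")
})

test_that("replicates explore both paralog paths beyond a shared seed", {
  set.seed(27)
  common <- rand_dna(200)
  tailA <- rand_dna(120)
  tailB <- rand_dna(120)
  trA <- paste0(common, tailA)
  trB <- paste0(common, tailB)
  reads <- bind_reads(tile_reads(trA, 80, 7, "a"), tile_reads(trB, 80, 7, "b"))
  p <- extender_params(overlap_len = 40L)
  idx <- build_overlap_index(reads, p)
  seed_seq <- substr(common, 61, 140)
  ends <- withr::with_seed(5, vapply(1:40, function(i) {
    run_replicate(seed_seq, idx, "right", p)$extension
  }, character(1)))
  finals <- unique(paste0(seed_seq, ends))
  expect_setequal(finals, c(substr(trA, 61, 320), substr(trB, 61, 320)))
})

test_that("reachable replicate sequences equal exhaustive path enumeration", {
  set.seed(28)
  for (case in 1:3) {
    common <- rand_dna(60)
    branches <- replicate(sample(2:3, 1), rand_dna(40))
    trs <- paste0(common, branches)
    reads <- do.call(bind_reads, lapply(seq_along(trs), function(i) {
      tile_reads(trs[i], 30, sample(3:5, 1), sprintf("c%d", i))
    }))
    expect_lte(nrow(reads), 50)
    p <- extender_params(overlap_len = 15L)
    idx <- build_overlap_index(reads, p)
    seed_seq <- substr(common, 21, 50)
    oracle <- oracle_extension_paths(seed_seq, reads$seq, 15)
    got <- unique(withr::with_seed(2, vapply(1:150, function(i) {
      paste0(seed_seq, run_replicate(seed_seq, idx, "right", p)$extension)
    }, character(1))))
    expect_setequal(sort(got), oracle)
  }
})

test_that("the retention rule is the conjunction of both published criteria", {
  expect_equal(venomtx:::required_extensions(extender_params()), 4)  # 3/20 fails, 4/20 passes
  expect_equal(venomtx:::required_extensions(
    extender_params(replicates_per_direction = 10L)), 2)
  expect_equal(venomtx:::required_extensions(
    extender_params(replicates_per_direction = 5L)), 2)  # absolute floor of 2
  expect_equal(venomtx:::required_extensions(
    extender_params(replicates_per_direction = 40L)), 8)
})

test_that("seeds failing a direction are dropped; extending seeds keep consensus", {
  set.seed(29)
  tr <- rand_dna(600)
  reads <- tile_reads(tr, 100, 4)
  p <- extender_params(overlap_len = 60L, replicates_per_direction = 20L)
  idx <- build_overlap_index(reads, p)
  # interior seed: both directions extend in every replicate -> retained
  mid <- new_reads("mid", substr(tr, 251, 350), strrep("I", 100), "merged")
  ctg <- withr::with_seed(3, assemble_seed(mid, idx, p))
  expect_equal(ctg$seq, tr)
  expect_equal(ctg$replicate_support, 20L)
  # seed at the 5' terminus: no leftward candidate ever -> dropped
  left <- new_reads("end", substr(tr, 1, 100), strrep("I", 100), "merged")
  expect_null(withr::with_seed(3, assemble_seed(left, idx, p)))
})

test_that("consensus is columnwise majority with tie and support truncation", {
  cons <- venomtx:::consensus_extension
  expect_equal(cons(c("AAAA", "AAAC"), 2), "AAA")          # tie truncates
  expect_equal(cons(rep(c("GGA", "GGC"), each = 10), 2), "GG")
  expect_equal(cons(c("TTTT", "TTTT", "TT"), 2), "TTTT")   # support 2 suffices
  expect_equal(cons(c("TTTTA", "TTTT", "TT"), 2), "TTTT")  # col 5 support 1
  expect_equal(cons(c("CCC", "CCC", "ACC"), 2), "CCC")     # majority wins
  expect_equal(cons(c("", "", "AA"), 2), "")               # empty never counted
})

test_that("assembly is deterministic and collapses duplicate contigs", {
  set.seed(30)
  tr <- rand_dna(700)
  reads <- tile_reads(tr, 120, 3)
  p <- extender_params(overlap_len = 80L, n_seeds = 6L, rng_seed = 77L)
  a1 <- assemble(reads, p)
  a2 <- assemble(reads, p)
  expect_identical(a1, a2)
  # every seed reconstructs the same transcript; collapse leaves one contig
  expect_equal(nrow(a1), 1L)
  expect_equal(a1$seq, tr)
})

test_that("raising n_seeds never loses recovered transcripts", {
  set.seed(31)
  trs <- vapply(rep(500, 3), rand_dna, character(1))
  reads <- do.call(bind_reads, lapply(1:3, function(i) {
    tile_reads(trs[i], 120, 6, sprintf("t%d", i))
  }))
  p_small <- extender_params(overlap_len = 80L, n_seeds = 2L, rng_seed = 13L)
  p_big <- extender_params(overlap_len = 80L, n_seeds = 30L, rng_seed = 13L)
  rec <- function(ctgs) {
    which(vapply(trs, function(tr) {
      any(vapply(ctgs$seq, function(s) {
        grepl(s, tr, fixed = TRUE) || grepl(rc_chr(s), tr, fixed = TRUE)
      }, logical(1)))
    }, logical(1)))
  }
  small <- rec(assemble(reads, p_small))
  big <- rec(assemble(reads, p_big))
  expect_true(all(small %in% big))
  expect_equal(unname(big), 1:3)
})

test_that("no replicate crosses between window-divergent paralogs", {
  set.seed(32)
  fam <- withr::with_seed(8, simulate_family(
    family_spec("SVMP", 2, c(500, 500), 0.9)))
  reads <- bind_reads(tile_reads(fam$seq[1], 150, 4, "p1"),
                      tile_reads(fam$seq[2], 150, 4, "p2"))
  p <- extender_params(overlap_len = 120L)
  idx <- build_overlap_index(reads, p)
  seeds <- substring(fam$seq, 151, 300)
  for (s in seeds) {
    res <- withr::with_seed(6, replicate(20, {
      r <- run_replicate(s, idx, "right", p)
      paste0(s, r$extension)
    }))
    ok <- vapply(res, function(ctg) {
      grepl(ctg, fam$seq[1], fixed = TRUE) || grepl(ctg, fam$seq[2], fixed = TRUE)
    }, logical(1))
    expect_true(all(ok))
  }
})
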