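test_that("a single-copy family is its ancestor", {
  fam <- withr::with_seed(70, simulate_family(
    family_spec("PLA2", 1, c(450, 450), expression_weights = 1)))
  expect_equal(nrow(fam), 1L)
  expect_equal(nchar(fam$seq), 450L)
  expect_match(fam$seq, "^[ACGT]+$")
})

test_that("families hit the target identity and the per-window divergence rule", {
  fam <- withr::with_seed(71, simulate_family(
    family_spec("SVMP", 6, c(1600, 1600), 0.96)))
  expect_equal(fam$name, paste0("SVMP-", 1:6))
  ids <- combn(6, 2, function(p) global_identity(fam$seq[p[1]], fam$seq[p[2]]))
  expect_gte(mean(ids), 0.94)
  expect_lte(mean(ids), 0.98)
  # no 120 nt window identical between any pair
  for (p in combn(6, 2, simplify = FALSE)) {
    a <- strsplit(fam$seq[p[1]], "")[[1]]
    b <- strsplit(fam$seq[p[2]], "")[[1]]
    d <- which(a != b)
    gaps <- diff(c(0L, d, length(a) + 1L))
    expect_lte(max(gaps), 120)
  }
})

test_that("impossible family constraints error", {
  expect_error(family_spec("F", 2, c(500, 500), 1.0), "multi-paralog")
  expect_error(family_spec("F", 2, c(500, 500), 0.999), "120")
  expect_error(family_spec("F", 2, c(500, 500), 0.4), "multi-paralog")
})

test_that("the default transcriptome has the documented structure", {
  truth <- simulate_transcriptome(sim_config(rng_seed = 5))
  expect_equal(nrow(truth), 73L)
  fam <- table(truth$family)
  expect_equal(as.integer(fam[c("SVMP", "SVSP", "CTL", "nontoxin")]),
               c(6L, 4L, 5L, 50L))
  expect_equal(sum(fam) - 6L - 4L - 5L - 50L, 8L)  # single-copy toxins
  expect_equal(sum(truth$weight), 1)
  expect_true(all(nchar(truth$seq[truth$family == "nontoxin"]) >= 500))
})

test_that("expression weights drive origin frequencies", {
  cfg <- sim_config(
    families = list(family_spec("A", 1, c(600, 600), expression_weights = 9),
                    family_spec("B", 1, c(600, 600), expression_weights = 1)),
    nontoxin_count = 0, n_read_pairs = 20000, error_rate = 0, rng_seed = 9)
  truth <- simulate_transcriptome(cfg)
  rd <- simulate_reads(truth, cfg)
  frac <- mean(rd$origin$transcript == "A")
  expect_gt(frac, 0.9 - 3 * sqrt(0.09 / 20000))
  expect_lt(frac, 0.9 + 3 * sqrt(0.09 / 20000))
})

test_that("error-free reads are exact substrings of their origins", {
  cfg <- sim_config(nontoxin_count = 5, n_read_pairs = 300, error_rate = 0,
                    rng_seed = 12)
  truth <- simulate_transcriptome(cfg)
  rd <- simulate_reads(truth, cfg)
  tr <- truth$seq[match(rd$origin$transcript, truth$name)]
  ok1 <- mapply(function(r, t) grepl(r, t, fixed = TRUE), rd$r1$seq, tr)
  ok2 <- mapply(function(r, t) grepl(rc_chr(r), t, fixed = TRUE), rd$r2$seq, tr)
  expect_true(all(ok1))
  expect_true(all(ok2))
  mg <- simulate_merged_reads(truth, cfg)
  trm <- truth$seq[match(mg$origin$transcript, truth$name)]
  okm <- mapply(function(r, t) grepl(r, t, fixed = TRUE) ||
                  grepl(rc_chr(r), t, fixed = TRUE), mg$reads$seq, trm)
  expect_true(all(okm))
  # every read has exactly one origin label
  expect_equal(rd$origin$id, rd$r1$id)
  expect_equal(mg$origin$id, mg$reads$id)
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- sim_config(nontoxin_count = 3, n_read_pairs = 200, rng_seed = 31)
  t1 <- simulate_transcriptome(cfg)
  t2 <- simulate_transcriptome(cfg)
  expect_identical(t1, t2)
  r1 <- simulate_reads(t1, cfg)
  r2 <- simulate_reads(t2, cfg)
  expect_identical(r1, r2)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(r1$r1, f1)
  write_fastq(r2$r1, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("the realized substitution error rate matches the configuration", {
  cfg <- sim_config(
    families = list(family_spec("A", 1, c(2000, 2000), expression_weights = 1)),
    nontoxin_count = 0, n_read_pairs = 20000, error_rate = 0.01, rng_seed = 14,
    quality_model = list(high = 40, low = 40, fraction_low = 0))
  truth <- simulate_transcriptome(cfg)
  rd <- simulate_reads(truth, cfg)
  truth_r1 <- substr(rep(truth$seq, nrow(rd$origin)), rd$origin$start + 1,
                     rd$origin$start + cfg$read_length)
  got <- charToRaw(paste(rd$r1$seq, collapse = ""))
  want <- charToRaw(paste(truth_r1, collapse = ""))
  rate <- mean(got != want)
  expect_gte(rate, 0.009)
  expect_lte(rate, 0.011)
})

test_that("index-hopping spikes are labelled and sized binomially", {
  set.seed(80)
  a <- new_reads(sprintf("a%05d", 1:20000), strrep("A", rep(60, 20000)),
                 strrep("I", rep(60, 20000)))
  b <- new_reads(sprintf("b%03d", 1:500), strrep("C", rep(60, 500)),
                 strrep("I", rep(60, 500)))
  sp0 <- spike_index_hopping(a, b, 0, rng_seed = 1)
  expect_identical(sp0$b$id, b$id)
  sp <- spike_index_hopping(a, b, 0.005, rng_seed = 2)
  n_spiked <- sum(sp$labels$contaminant)
  expect_gt(n_spiked, 100 - 3 * sqrt(100))
  expect_lt(n_spiked, 100 + 3 * sqrt(100))
  expect_equal(nrow(sp$b), 500 + n_spiked)
  expect_true(all(startsWith(sp$labels$id[sp$labels$contaminant], "a")))
  expect_identical(sp$a, a)
})

test_that("chimeras join parent halves traceably", {
  set.seed(81)
  p1 <- rand_dna(1000)
  p2 <- rand_dna(1000)
  ch <- make_chimera(p1, p2, 0.5)
  expect_equal(nchar(ch), 1000L)
  expect_equal(substr(ch, 1, 500), substr(p1, 1, 500))
  expect_equal(substr(ch, 501, 1000), substr(p2, 501, 1000))
  ch3 <- make_chimera(p1, p2, 0.3)
  expect_equal(substr(ch3, 1, 300), substr(p1, 1, 300))
  expect_error(make_chimera(p1, p2, 0))
  expect_error(make_chimera(p1, p2, 1))
})
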