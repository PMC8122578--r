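test_that("index enumerates exactly the N-free k-mer positions", {
  # k equal to the chromosome length stores exactly one position
  idx <- build_index(c(c1 = "ACGTACGT"), k = 8L)
  expect_identical(nrow(idx$kmers), 1L)

  # a periodic sequence: 5 windows, the repeated 8-mer at offsets 0 and 4
  idx4 <- build_index(c(c1 = "ACGTACGTACGT"), k = 8L)
  expect_identical(nrow(idx4$kmers), 5L)
  expect_identical(sort(idx4$kmers[kmer == "ACGTACGT", offset]), c(0L, 4L))

  # windows overlapping an N are excluded
  idxn <- build_index(c(c1 = "AAAAAAAANAAAAAAAA"), k = 8L)
  expect_identical(sort(idxn$kmers$offset), c(0L, 9L))

  expect_error(build_index(c(c1 = "ACGT"), k = 8L), "exceeds")
})

test_that("perfect-match reads align with identity 1 on both strands", {
  withr::local_seed(21)
  ref <- oracle_random_seq(3000)
  genome <- c(c1 = ref)
  idx <- build_index(genome, 15L)
  cfg <- pipeline_config()
  sub <- substr(ref, 1001, 1100)
  h <- best_hit(align_read(list(fst_id = "r", sequence = sub), idx, cfg))
  expect_identical(h$ref_start, 1001L)
  expect_identical(h$ref_end, 1100L)
  expect_identical(h$strand, "+")
  expect_identical(h$identity, 1)
  expect_identical(h$aln_len, 100L)
  expect_identical(h$score, 100)

  hrc <- best_hit(align_read(list(fst_id = "r", sequence = oracle_revcomp(sub)),
                             idx, cfg))
  expect_identical(hrc$ref_start, 1001L)
  expect_identical(hrc$ref_end, 1100L)
  expect_identical(hrc$strand, "-")
  expect_identical(hrc$score, 100)
})

test_that("a read with interior substitutions scores the brute-force optimum", {
  withr::local_seed(22)
  ref <- oracle_random_seq(2000)
  genome <- c(c1 = ref)
  idx <- build_index(genome, 15L)
  cfg <- pipeline_config()
  read <- oracle_mutate_at(substr(ref, 501, 600), c(20, 35, 50, 65, 80))
  h <- best_hit(align_read(list(fst_id = "r", sequence = read), idx, cfg))
  expect_identical(h$identity, 0.95)
  expect_identical(h$aln_len, 100L)
  expect_identical(h$score,
                   oracle_best_ungapped_score(read, ref, cfg$match,
                                              cfg$mismatch))
})

test_that("reads shorter than the seed are rejected", {
  idx <- build_index(c(c1 = strrep("ACGT", 10)), 15L)
  expect_error(align_read(list(fst_id = "r", sequence = "ACGTACGT"), idx,
                          pipeline_config()), "shorter than seed")
})

test_that("Karlin lambda matches an independent bisection and K the published constants", {
  # oracle: stats::uniroot on E[exp(lambda s)] = 1
  for (sc in list(c(1, -2), c(1, -3), c(2, -3))) {
    p <- karlin_params(sc[1], sc[2])
    phi <- function(l) 0.25 * exp(l * sc[1]) + 0.75 * exp(l * sc[2]) - 1
    lam <- stats::uniroot(phi, c(1e-6, 10), tol = 1e-12)$root
    expect_equal(p$lambda, lam, tolerance = 1e-6)
  }
  # published BLASTN ungapped (lambda, K) pairs at uniform base frequencies
  p12 <- karlin_params(1, -2)
  expect_equal(p12$lambda, 1.33, tolerance = 0.01)
  expect_equal(p12$K, 0.621, tolerance = 0.01)
  p13 <- karlin_params(1, -3)
  expect_equal(p13$lambda, 1.37, tolerance = 0.01)
  expect_equal(p13$K, 0.711, tolerance = 0.01)

  # non-negative expected score has no lambda
  expect_error(karlin_params(3, -1), "non-negative")
})

test_that("E-values are monotone in score and linear in both lengths", {
  p <- karlin_params(1, -2)
  e1 <- score_to_evalue(50, 100, 1e6, p)
  expect_equal(score_to_evalue(50, 100, 2e6, p), 2 * e1)
  expect_equal(score_to_evalue(50, 200, 1e6, p), 2 * e1)
  expect_lt(score_to_evalue(51, 100, 1e6, p), e1)
  scores <- seq(10, 100, by = 5)
  ev <- score_to_evalue(scores, 100, 1e6, p)
  expect_true(all(diff(ev) < 0))
})

test_that("best_hit applies the documented tie-breaks", {
  base <- data.frame(fst_id = "r", ref_start = 10L, ref_end = 50L,
                     read_start = 1L, read_end = 41L, read_len = 41L,
                     strand = "+", matches = 41L, aln_len = 41L,
                     identity = 1, evalue = 1e-10, stringsAsFactors = FALSE)
  h1 <- transform(base, chrom = "c1", score = 90)
  h2 <- transform(base, chrom = "c1", score = 100)
  expect_identical(best_hit(rbind(h1, h2))$score, 100)

  t1 <- transform(base, chrom = "chr2", score = 100)
  t2 <- transform(base, chrom = "chr1", score = 100)
  expect_identical(best_hit(rbind(t1, t2))$chrom, "chr1")

  s1 <- transform(base, chrom = "c1", score = 100, ref_start = 500L)
  s2 <- transform(base, chrom = "c1", score = 100, ref_start = 100L)
  expect_identical(best_hit(rbind(s1, s2))$ref_start, 100L)

  expect_null(best_hit(base[0, ]))
  expect_null(best_hit(NULL))
})

test_that("insertion calls sit at the signature-proximal junction", {
  hit <- data.frame(fst_id = "r", chrom = "c1", ref_start = 1001L,
                    ref_end = 1100L, read_start = 8L, read_end = 107L,
                    read_len = 107L, strand = "+", matches = 100L,
                    aln_len = 100L, identity = 1, score = 100,
                    evalue = 1e-20, stringsAsFactors = FALSE)
  qc <- data.frame(fst_id = "r", which_end = "head", start_offset = 0L,
                   end_distance = 93L, motif = "CCCAACA",
                   stringsAsFactors = FALSE)
  s <- call_insertion_site(hit, qc)
  expect_identical(s$position, 1001L)
  expect_identical(s$strand, "+")

  hit$strand <- "-"
  s2 <- call_insertion_site(hit, qc)
  expect_identical(s2$position, 1100L)

  # id mismatch is an error
  qc_bad <- transform(qc, fst_id = "other")
  expect_error(call_insertion_site(hit, qc_bad), "does not match")
})

test_that("zero-noise simulated reads are called at the exact truth coordinate", {
  cfg <- simulation_config(n_chroms = 2, chrom_length = 40000, n_lines = 25,
                           insertions_per_line = c(4, 4), n_genes = 10,
                           substitution_rate = 0, frac_no_signature = 0,
                           frac_too_short = 0, frac_internal_signature = 0,
                           rng_seed = 55)
  pc <- pipeline_config()
  sim <- suppressMessages(simulate_fst_dataset(cfg))
  fb <- filter_batch(sim$records, pc, verbose = FALSE)
  mb <- suppressWarnings(map_batch(fb$pass, sim$genome, pc, fb$outcomes,
                                   verbose = FALSE))
  m <- merge(mb$sites, sim$truth[, c("fst_id", "chrom", "position")],
             by = "fst_id")
  expect_identical(nrow(m), nrow(fb$pass))
  expect_true(all(m$chrom.x == m$chrom.y))
  expect_true(all(m$position.x == m$position.y))
})

test_that("mapping a read and its reverse complement is strand-symmetric", {
  withr::local_seed(33)
  ref <- oracle_random_seq(4000)
  idx <- build_index(c(c1 = ref), 15L)
  cfg <- pipeline_config()
  for (i in 1:10) {
    st <- sample.int(3800, 1)
    read <- oracle_mutate_at(substr(ref, st, st + 149),
                             sample.int(150, 3))
    h <- best_hit(align_read(list(fst_id = "r", sequence = read), idx, cfg))
    hr <- best_hit(align_read(list(fst_id = "r",
                                   sequence = oracle_revcomp(read)),
                              idx, cfg))
    expect_identical(h$ref_start, hr$ref_start)
    expect_identical(h$ref_end, hr$ref_end)
    expect_identical(h$score, hr$score)
    expect_true(h$strand != hr$strand)
  }
})

test_that("reported hits always satisfy the thresholds", {
  withr::local_seed(44)
  ref <- oracle_random_seq(3000)
  idx <- build_index(c(c1 = ref), 15L)
  cfg <- pipeline_config()
  for (i in 1:25) {
    st <- sample.int(2800, 1)
    n_mut <- sample(0:12, 1)
    read <- oracle_mutate_at(substr(ref, st, st + 119),
                             sample.int(120, n_mut))
    hits <- align_read(list(fst_id = "r", sequence = read), idx, cfg)
    if (nrow(hits) > 0) {
      expect_true(all(hits$identity >= cfg$min_identity))
      expect_true(all(hits$evalue <= cfg$max_evalue))
    }
  }
})

test_that("mapped-percent arithmetic matches the published convention", {
  # integer percent, round half up: 202,788 of 221,275 prints as 92
  expect_identical(percent_of(202788, 221275, 0), 92)
  withr::local_seed(3)
  recs <- data.frame(fst_id = "x", line_id = "x", sequence = "ACGT")
  expect_warning(out <- map_batch(recs[0, ], c(c1 = "ACGT"),
                                  pipeline_config()),
                 "percent")
  expect_identical(out$summary$percent_mapped, 0)
})
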