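# Phase 1: cumulative k-mer scoring and highly repetitive region extraction.

test_that("scores match the brute-force window scorer on planted repeats", {
  p_dna <- default_params("nucleotide")
  p_aa <- default_params("amino_acid")
  cases <- list(
    list(seq = generate_repeat(repeat_spec("nucleotide", copies = 8,
                                           unit_size = 36, flank_size = 300,
                                           seed = 1))$record$sequence,
         p = p_dna),
    list(seq = generate_repeat(repeat_spec("nucleotide", copies = 6,
                                           unit_size = 31,
                                           spacer = spacer_uniform(30, 38),
                                           flank_size = 200, noise_rate = 0.05,
                                           seed = 2))$record$sequence,
         p = p_dna),
    list(seq = generate_repeat(repeat_spec("amino_acid", copies = 8,
                                           unit_size = 34, flank_size = 150,
                                           noise_rate = 0.1,
                                           seed = 3))$record$sequence,
         p = p_aa),
    list(seq = random_seq(800, "amino_acid", seed = 4), p = p_aa))
  for (cs in cases) {
    expect_equal(cumulative_kmer_scores(cs$seq, cs$p)$scores,
                 brute_scores(cs$seq, cs$p))
  }
})

test_that("sequences with every k-mer unique in the window score zero", {
  # deliberately aperiodic de Bruijn-style fragment: no 10-mer repeats
  set.seed(10)
  seq <- random_seq(500, "nucleotide")
  p <- default_params("nucleotide")
  km <- substring(seq, 1:491, 10:500)
  expect_equal(anyDuplicated(km), 0L)  # this seeded draw has no repeated 10-mer
  expect_true(all(cumulative_kmer_scores(seq, p)$scores == 0))
})

test_that("sequences shorter than the window are still fully scanned", {
  p <- default_params("nucleotide")
  seq <- strrep("ACGTACGTAA", 5)  # 50 bp < w
  tr <- cumulative_kmer_scores(seq, p)
  expect_equal(tr$scores, brute_scores(seq, p))
  expect_gt(max(tr$scores), 0)
  expect_error(cumulative_kmer_scores("ACGT", p), "shorter than k")
})

test_that("peak areas are maximal positive runs with peak >= s", {
  p <- default_params("nucleotide")
  track <- structure(list(scores = c(0, 0, 5, 25, 5, 0), params = p,
                          length = 6L), class = "score_track")
  ck <- extract_ckpas(track, s = 20)
  expect_equal(ck$start, 2)
  expect_equal(ck$end, 5)
  expect_equal(nrow(extract_ckpas(structure(list(scores = rep(0, 6), params = p,
                                                 length = 6L),
                                            class = "score_track"))), 0)
  # run with max 19 < s is not extracted
  track$scores <- c(0, 19, 19, 0, 0, 0)
  expect_equal(nrow(extract_ckpas(track, s = 20)), 0)
})

test_that("HRR merging bridges gaps of at most g and keeps chain extent", {
  p <- default_params("nucleotide", g = 4)
  mk <- function(scores) structure(list(scores = scores, params = p,
                                        length = length(scores)),
                                   class = "score_track")
  # two peaks separated by exactly g zeros -> one HRR
  tr <- mk(c(25, 25, rep(0, 4), 30, 30))
  h <- merge_to_hrrs(extract_ckpas(tr), tr)
  expect_equal(nrow(h), 1)
  expect_equal(c(h$start, h$end), c(0, 8))
  expect_equal(h$peak_height, 30)
  # g + 1 zeros -> two HRRs
  tr2 <- mk(c(25, 25, rep(0, 5), 30, 30))
  expect_equal(nrow(merge_to_hrrs(extract_ckpas(tr2), tr2)), 2)
  # sub-threshold blips do not extend the chain beyond the peak areas
  tr3 <- mk(c(25, 25, 0, 0, 3, 3, rep(0, 10), 2))
  h3 <- merge_to_hrrs(extract_ckpas(tr3), tr3)
  expect_equal(nrow(h3), 1)
  expect_equal(c(h3$start, h3$end), c(0, 2))
  # no qualifying peak, no region
  tr4 <- mk(c(3, 3, 0, 0, 3))
  expect_equal(nrow(merge_to_hrrs(extract_ckpas(tr4), tr4)), 0)
})

test_that("HRRs are disjoint, sorted, and merging is idempotent", {
  p <- default_params("nucleotide", g = 50)
  for (seed in 1:5) {
    g <- generate_repeat(repeat_spec("nucleotide", copies = 6, unit_size = 20,
                                     flank_size = 400, noise_rate = 0.05,
                                     seed = seed))
    tr <- cumulative_kmer_scores(g$record$sequence, p)
    h <- merge_to_hrrs(extract_ckpas(tr), tr)
    if (nrow(h) >= 2) {
      expect_true(all(diff(h$start) > 0))
      expect_true(all(h$start[-1] > h$end[-nrow(h)] + p$g))
    }
    expect_true(all(h$end - h$start >= p$k))
    expect_true(all(h$peak_height >= p$s))
  }
})

test_that("adding a k-mer copy inside a window never decreases any score", {
  p <- default_params("nucleotide", w = 60)
  base <- random_seq(120, "nucleotide", seed = 42)
  kmer <- substr(base, 11, 20)
  # overwrite positions 41..50 with a copy of the 10-mer at 11..20
  modified <- paste0(substr(base, 1, 40), kmer, substr(base, 51, 120))
  s0 <- cumulative_kmer_scores(base, p)$scores
  s1 <- cumulative_kmer_scores(modified, p)$scores
  expect_true(all(s1[11:20] >= s0[11:20]))
})

test_that("wildcard-containing k-mers are skipped as window seeds", {
  p <- default_params("nucleotide", w = 40, s = 5)
  seq <- paste0(strrep("N", 30), strrep("A", 0), random_seq(60, seed = 9))
  tr <- cumulative_kmer_scores(seq, p)
  expect_equal(tr$scores, brute_scores(seq, p))
  # N-runs are identical letter-wise but must not seed windows
  expect_true(all(tr$scores[1:20] == 0))
})
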