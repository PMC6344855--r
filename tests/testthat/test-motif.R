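# Phase 3: seed k-mer, unit alignment, punctuation, representative mapping.

dna_p <- default_params("nucleotide")
aa_p <- default_params("amino_acid")

test_that("seed k-mer of a perfect tandem is the left-most recurring k-mer", {
  g <- generate_repeat(repeat_spec("nucleotide", copies = 10, unit_size = 36,
                                   seed = 51))
  prr <- detect_prrs(g$record$sequence, dna_p)[1, ]
  ks <- find_kseed(g$record$sequence, prr, dna_p)
  # all rotations tie on mass; the left-most wins: the PRR's first k-mer
  expect_equal(ks, substr(g$record$sequence, prr$start + 1, prr$start + dna_p$k))
})

test_that("seed of an interspaced array lies in the repeat, never a spacer", {
  for (seed in c(52, 53)) {
    g <- generate_repeat(repeat_spec("nucleotide", copies = 8, unit_size = 31,
                                     spacer = spacer_uniform(30, 38),
                                     seed = seed))
    prr <- detect_prrs(g$record$sequence, dna_p)[1, ]
    ks <- find_kseed(g$record$sequence, prr, dna_p)
    expect_true(grepl(ks, g$truth$unit, fixed = TRUE))
  }
})

test_that("seed comes from the repeat family with larger in-band mass", {
  # two interleaved families in one region: 8 copies of A-unit, 3 of B-unit
  set.seed(54)
  ua <- random_seq(30); ub <- random_seq(30)
  seq <- paste0(random_seq(300), strrep(ua, 8), strrep(ub, 3), random_seq(300))
  prr <- detect_prrs(seq, dna_p)[1, ]
  ks <- find_kseed(seq, prr, dna_p)
  expect_true(grepl(ks, ua, fixed = TRUE))
})

test_that("unit extraction cuts period-sized fragments at seed occurrences", {
  g <- generate_repeat(repeat_spec("nucleotide", copies = 6, unit_size = 72,
                                   seed = 55))
  prr <- detect_prrs(g$record$sequence, dna_p)[1, ]
  ks <- find_kseed(g$record$sequence, prr, dna_p)
  un <- extract_units(g$record$sequence, prr, ks, dna_p)
  expect_equal(length(un$fragments), 6)
  expect_true(all(nchar(un$fragments[-6]) == 72))
  expect_error(extract_units(g$record$sequence, prr, "ACGTACGTXX", dna_p),
               "insufficient units")
})

test_that("center-star alignment recovers a hand-constructed optimum", {
  frs <- c("ACGTACGTAC", "ACGTACGTAC", "ACGTTACGTAC", "ACGTACGTAC")
  aln <- align_units(frs, "nucleotide")
  expect_equal(length(unique(nchar(aln$rows))), 1)
  expect_equal(nchar(aln$rows[1]), 11)       # one inserted column
  expect_equal(gsub("-", "", aln$rows), frs) # degapping recovers fragments
  gap_cols <- which(strsplit(aln$rows[1], "")[[1]] == "-")
  expect_equal(length(gap_cols), 1)
  # identical fragments align without gaps
  aln2 <- align_units(c("MKVLHW", "MKVLHW"), "amino_acid")
  expect_equal(aln2$rows, c("MKVLHW", "MKVLHW"))
})

test_that("internal and MAFFT backends give the same masked motif", {
  for (cs in list(list(ab = "nucleotide", u = 36, noise = 0.05, p = dna_p),
                  list(ab = "amino_acid", u = 28, noise = 0.10, p = aa_p))) {
    g <- generate_repeat(repeat_spec(cs$ab, copies = 10, unit_size = cs$u,
                                     noise_rate = cs$noise, seed = 56))
    prr <- detect_prrs(g$record$sequence, cs$p)[1, ]
    m_int <- annotate_motif(g$record$sequence, prr, cs$p)
    m_ext <- annotate_motif(g$record$sequence, prr, cs$p, backend = "mafft")
    expect_equal(m_int$masked_motif, m_ext$masked_motif)
  }
})

test_that("column profiles follow the information-content definitions", {
  aln <- structure(list(rows = c("CA-", "CAG", "CA-", "CAG"),
                        alphabet = "amino_acid"), class = "unit_alignment")
  prof <- column_profile(aln)
  st <- prof$stats
  expect_equal(st$b[1], log2(20), tolerance = 1e-9)   # all C, no gaps
  expect_equal(st$consistency[1], log2(20), tolerance = 1e-9)
  expect_equal(st$gap_fraction, c(0, 0, 0.5))
  expect_equal(st$b[3], log2(20), tolerance = 1e-9)   # letters all G
  expect_equal(st$consistency[3], log2(20) / 2, tolerance = 1e-9)
  # uniform DNA column has zero information
  aln2 <- structure(list(rows = c("A", "C", "G", "T"),
                         alphabet = "nucleotide"), class = "unit_alignment")
  expect_equal(column_profile(aln2)$stats$b, 0)
  # frequencies per column sum to one over letters + gap
  expect_equal(colSums(prof$freq), rep(1, 3))
})

test_that("circular punctuation removes the longest nonconsensus run", {
  mkprof <- function(l, gapf = rep(0, length(l)))
    structure(list(freq = NULL,
                   stats = data.frame(b = l, gap_fraction = gapf,
                                      consistency = l * (1 - gapf))),
              class = "column_profile")
  p <- default_params("nucleotide")   # q=0.5 u=0.8 r=5
  rows <- paste(rep(strsplit("ABCDEFGHIJKL", "")[[1]], 1), collapse = "")
  aln <- structure(list(rows = c(rows, rows), alphabet = "nucleotide"),
                   class = "unit_alignment")
  # all consistent -> untouched
  keep <- punctuate_circular(aln, mkprof(rep(2, 12)), p)
  expect_equal(keep$rows, c(rows, rows))
  expect_false(attr(keep, "rotated"))
  # low-l run of exactly r columns is NOT removed ("more than r letters")
  l5 <- rep(2, 12); l5[4:8] <- 0.1
  expect_false(attr(punctuate_circular(aln, mkprof(l5), p), "rotated"))
  # run of 6 wrapping the ring boundary is removed as one run, output rotated
  lw <- rep(2, 12); lw[c(10, 11, 12, 1, 2, 3)] <- 0.1
  pun <- punctuate_circular(aln, mkprof(lw), p)
  expect_true(attr(pun, "rotated"))
  expect_equal(pun$rows[1], "DEFGHI")  # begins right after the removed run
  # gap-heavy columns are dropped before the ring analysis
  gp <- rep(0, 12); gp[6] <- 0.75
  pg <- punctuate_circular(aln, mkprof(rep(2, 12), gp), p)
  expect_equal(pg$rows[1], "ABCDEGHIJKL")
})

test_that("representative mapping: tandem units, masking, exact-scan path", {
  # perfect tandem: every unit mapped, no masking
  g <- generate_repeat(repeat_spec("nucleotide", copies = 10, unit_size = 36,
                                   seed = 57))
  prr <- detect_prrs(g$record$sequence, dna_p)[1, ]
  mot <- annotate_motif(g$record$sequence, prr, dna_p)
  expect_equal(mot$n_units, 10)
  expect_false(grepl("*", mot$masked_motif, fixed = TRUE))
  expect_true(grepl(mot$representative,
                    paste0(g$truth$unit, g$truth$unit), fixed = TRUE))
  expect_true(all(mot$units$start[-1] >= head(mot$units$end, -1)))
  # a position with top letter frequency 0.55 is masked
  set.seed(58)
  u <- random_seq(30)
  units <- vapply(1:20, function(i) {
    v <- strsplit(u, "")[[1]]
    v[15] <- if (i <= 11) "A" else "C"
    paste(v, collapse = "")
  }, character(1))
  seq <- paste0(random_seq(200), paste(units, collapse = ""), random_seq(200))
  prr2 <- detect_prrs(seq, dna_p)[1, ]
  mot2 <- annotate_motif(seq, prr2, dna_p)
  masked_at <- which(strsplit(mot2$masked_motif, "")[[1]] == "*")
  expect_equal(length(masked_at), 1)
  top <- apply(mot2$logo, 2, max)
  expect_equal(unname(top[masked_at]), 0.55)
  # representative shorter than k uses the exact-scan path
  g3 <- generate_repeat(repeat_spec("nucleotide", copies = 12, unit_size = 5,
                                    seed = 59))
  prr3 <- detect_prrs(g3$record$sequence, dna_p)[1, ]
  mot3 <- annotate_motif(g3$record$sequence, prr3, dna_p)
  expect_equal(mot3$method, "exact_scan")
  expect_equal(mot3$n_units, 12)
  expect_true(grepl(mot3$representative, paste0(g3$truth$unit, g3$truth$unit),
                    fixed = TRUE))
})

test_that("phase shift rotates the representative without changing units", {
  set.seed(60)
  u <- random_seq(36)
  mk <- function(shift) {
    ru <- paste0(substr(u, shift + 1, 36), substr(u, 1, shift))
    paste0(random_seq(500), strrep(ru, 10), random_seq(500))
  }
  s0 <- mk(0); s7 <- mk(7)
  m0 <- annotate_motif(s0, detect_prrs(s0, dna_p)[1, ], dna_p)
  m7 <- annotate_motif(s7, detect_prrs(s7, dna_p)[1, ], dna_p)
  expect_true(grepl(m7$representative, paste0(m0$representative,
                                              m0$representative), fixed = TRUE))
  expect_equal(m0$n_units, m7$n_units)
})

test_that("noise never unmasks: masked positions grow with noise", {
  n_masked <- vapply(c(0.05, 0.25), function(noise) {
    tot <- 0
    for (seed in 61:63) {
      g <- generate_repeat(repeat_spec("amino_acid", copies = 20,
                                       unit_size = 28, noise_rate = noise,
                                       seed = seed))
      prr <- detect_prrs(g$record$sequence, aa_p)
      prr <- prr[which.max(pmin(prr$end, g$truth$region_end) -
                             pmax(prr$start, g$truth$region_start)), ]
      mot <- annotate_motif(g$record$sequence, prr, aa_p)
      tot <- tot + lengths(regmatches(mot$masked_motif,
                                      gregexpr("*", mot$masked_motif,
                                               fixed = TRUE)))
    }
    tot
  }, numeric(1))
  expect_lte(n_masked[1], n_masked[2])
})

test_that("conserved anchor residues stay unmasked in noisy protein repeats", {
  g <- generate_repeat(repeat_spec("amino_acid", copies = 20, unit_size = 28,
                                   noise_rate = 0.25,
                                   keep_positions = c(3, 6, 19, 23),
                                   seed = 64))
  prr <- detect_prrs(g$record$sequence, aa_p)[1, ]
  mot <- annotate_motif(g$record$sequence, prr, aa_p)
  # locate the template rotation matching the representative
  tmpl <- g$truth$unit
  doubled <- paste0(tmpl, tmpl)
  anchors <- strsplit(tmpl, "")[[1]][c(3, 6, 19, 23)]
  mm <- strsplit(mot$masked_motif, "")[[1]]
  expect_true(all(anchors %in% mm[mm != "*"]))
})
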